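reader,slide_id,t_without_sec,t_with_sec
reader1,S2012-xxx201,37,126
reader1,S2018-xxx884,50,89
reader1,S2018-xxx153,32,22
reader1,S2018-xxx810,54,19
reader1,S2019-xxx702,70,131
reader1,S2019-xxx637,160,75
reader1,S2020-xxx911,90,44
reader1,S2020-xxx163,30,26
reader1,S2021-xxx140,77,49
reader1,S2021-xxx542,108,21
reader2,S2012-xxx201,20,72
reader2,S2018-xxx884,45,32
reader2,S2018-xxx153,55,14
reader2,S2018-xxx810,175,12
reader2,S2019-xxx702,55,131
reader2,S2019-xxx637,101,110
reader2,S2020-xxx911,51,98
reader2,S2020-xxx163,36,12
reader2,S2021-xxx140,42,57
reader2,S2021-xxx542,138,10
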