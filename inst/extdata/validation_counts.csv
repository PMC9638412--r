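context,level,tp,fp,fn,tn
nerve_roi,nerve_structures,106,3,8,15
pni_roi,nerve_structures,116,14,7,54
wsi_reader1,nerve_structures,12,7,4,384
wsi_reader2,nerve_structures,11,8,1,385
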