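// Low-level numeric kernels: 2-D convolution (im2col + GEMM), bilinear
// resampling and its adjoint, and connected-component labeling.
// Array layout is R column-major throughout: x[H, W, C, N].

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int n, int stride) { return (n + stride - 1) / stride; }

// Fill the im2col matrix for one sample. Columns are ordered
// di + k*dj + k*k*ci to match the column-major layout of w[k,k,Ci,Co].
static void im2col(const double* xs, int H, int W, int Ci,
                   int k, int pad, int stride, arma::mat& Xc) {
  const int Ho = out_size(H, stride), Wo = out_size(W, stride);
  for (int ci = 0; ci < Ci; ++ci) {
    const double* xc = xs + (size_t)ci * H * W;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = di + k * dj + k * k * ci;
        double* dst = Xc.colptr(col);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride + dj - pad;
          double* d = dst + (size_t)wo * Ho;
          if (wi < 0 || wi >= W) {
            std::fill(d, d + Ho, 0.0);
            continue;
          }
          const double* src = xc + (size_t)wi * H;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride + di - pad;
            d[ho] = (hi >= 0 && hi < H) ? src[hi] : 0.0;
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector w, int stride) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  const int H = dx[0], W = dx[1], Ci = dx[2], N = dx[3];
  const int k = dw[0], Co = dw[3];
  if (dw[1] != k || dw[2] != Ci) stop("weight dims do not match input channels");
  const int pad = (k - 1) / 2;
  const int Ho = out_size(H, stride), Wo = out_size(W, stride);

  NumericVector y((R_xlen_t)Ho * Wo * Co * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  arma::mat Wm(const_cast<double*>(w.begin()), k * k * Ci, Co, false, true);
  arma::mat Xc(Ho * Wo, k * k * Ci);
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)n * H * W * Ci;
    im2col(xs, H, W, Ci, k, pad, stride, Xc);
    arma::mat Y(y.begin() + (size_t)n * Ho * Wo * Co, Ho * Wo, Co, false, true);
    Y = Xc * Wm;
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericVector w, NumericVector gy, int stride) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  const int H = dx[0], W = dx[1], Ci = dx[2], N = dx[3];
  const int k = dw[0], Co = dw[3];
  const int pad = (k - 1) / 2;
  const int Ho = out_size(H, stride), Wo = out_size(W, stride);

  NumericVector gx((R_xlen_t)H * W * Ci * N), gw((R_xlen_t)k * k * Ci * Co);
  gx.attr("dim") = dx;
  gw.attr("dim") = dw;
  arma::mat Wm(const_cast<double*>(w.begin()), k * k * Ci, Co, false, true);
  arma::mat Gw(gw.begin(), k * k * Ci, Co, false, true);
  arma::mat Xc(Ho * Wo, k * k * Ci);
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)n * H * W * Ci;
    im2col(xs, H, W, Ci, k, pad, stride, Xc);
    arma::mat Gy(const_cast<double*>(gy.begin()) + (size_t)n * Ho * Wo * Co,
                 Ho * Wo, Co, false, true);
    Gw += Xc.t() * Gy;
    arma::mat Gxc = Gy * Wm.t();  // (Ho*Wo, k*k*Ci)
    double* gxs = gx.begin() + (size_t)n * H * W * Ci;
    for (int ci = 0; ci < Ci; ++ci) {
      double* gxc = gxs + (size_t)ci * H * W;
      for (int dj = 0; dj < k; ++dj) {
        for (int di = 0; di < k; ++di) {
          const int col = di + k * dj + k * k * ci;
          const double* g = Gxc.colptr(col);
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride + dj - pad;
            if (wi < 0 || wi >= W) continue;
            double* dst = gxc + (size_t)wi * H;
            const double* gsrc = g + (size_t)wo * Ho;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride + di - pad;
              if (hi >= 0 && hi < H) dst[hi] += gsrc[ho];
            }
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

// Half-pixel-center mapping used by all bilinear resampling here:
// source coordinate of output index i is (i + 0.5) * in/out - 0.5, clamped.
static void lin_weights(int in, int out, std::vector<int>& i0,
                        std::vector<int>& i1, std::vector<double>& t) {
  i0.resize(out); i1.resize(out); t.resize(out);
  for (int i = 0; i < out; ++i) {
    double s = (i + 0.5) * (double)in / out - 0.5;
    if (s < 0) s = 0;
    if (s > in - 1) s = in - 1;
    int a = (int)std::floor(s);
    if (a > in - 2) a = in - 2;
    if (a < 0) a = 0;
    i0[i] = a;
    i1[i] = (in > 1) ? a + 1 : 0;
    t[i] = (in > 1) ? s - a : 0.0;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear(NumericMatrix x, int out_h, int out_w) {
  const int H = x.nrow(), W = x.ncol();
  std::vector<int> r0, r1, c0, c1;
  std::vector<double> tr, tc;
  lin_weights(H, out_h, r0, r1, tr);
  lin_weights(W, out_w, c0, c1, tc);
  NumericMatrix y(out_h, out_w);
  for (int j = 0; j < out_w; ++j) {
    const double* xa = &x(0, c0[j]);
    const double* xb = &x(0, c1[j]);
    const double u = tc[j];
    for (int i = 0; i < out_h; ++i) {
      const double v = tr[i];
      const double top = xa[r0[i]] * (1 - u) + xb[r0[i]] * u;
      const double bot = xa[r1[i]] * (1 - u) + xb[r1[i]] * u;
      y(i, j) = top * (1 - v) + bot * v;
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_bilinear_up(NumericVector x, int factor) {
  IntegerVector dx = x.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int Hf = H * factor, Wf = W * factor;
  std::vector<int> r0, r1, c0, c1;
  std::vector<double> tr, tc;
  lin_weights(H, Hf, r0, r1, tr);
  lin_weights(W, Wf, c0, c1, tc);
  NumericVector y((R_xlen_t)Hf * Wf * C * N);
  y.attr("dim") = IntegerVector::create(Hf, Wf, C, N);
  for (int q = 0; q < C * N; ++q) {
    const double* xs = x.begin() + (size_t)q * H * W;
    double* ys = y.begin() + (size_t)q * Hf * Wf;
    for (int j = 0; j < Wf; ++j) {
      const double* xa = xs + (size_t)c0[j] * H;
      const double* xb = xs + (size_t)c1[j] * H;
      const double u = tc[j];
      double* yc = ys + (size_t)j * Hf;
      for (int i = 0; i < Hf; ++i) {
        const double v = tr[i];
        const double top = xa[r0[i]] * (1 - u) + xb[r0[i]] * u;
        const double bot = xa[r1[i]] * (1 - u) + xb[r1[i]] * u;
        yc[i] = top * (1 - v) + bot * v;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_bilinear_up_bwd(NumericVector gy, int factor, int H, int W) {
  IntegerVector dg = gy.attr("dim");
  const int Hf = dg[0], Wf = dg[1], C = dg[2], N = dg[3];
  std::vector<int> r0, r1, c0, c1;
  std::vector<double> tr, tc;
  lin_weights(H, Hf, r0, r1, tr);
  lin_weights(W, Wf, c0, c1, tc);
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int q = 0; q < C * N; ++q) {
    const double* gs = gy.begin() + (size_t)q * Hf * Wf;
    double* xs = gx.begin() + (size_t)q * H * W;
    for (int j = 0; j < Wf; ++j) {
      const double u = tc[j];
      double* xa = xs + (size_t)c0[j] * H;
      double* xb = xs + (size_t)c1[j] * H;
      const double* gc = gs + (size_t)j * Hf;
      for (int i = 0; i < Hf; ++i) {
        const double v = tr[i], g = gc[i];
        xa[r0[i]] += g * (1 - u) * (1 - v);
        xb[r0[i]] += g * u * (1 - v);
        xa[r1[i]] += g * (1 - u) * v;
        xb[r1[i]] += g * u * v;
      }
    }
  }
  return gx;
}

// Connected-component labeling. Labels are assigned in order of the first
// pixel encountered in a row-major scan (row 0 left to right, then row 1, ...).
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 1, 0, 0};
  const int dc4[4] = {0, 0, -1, 1};
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  const int nn = (connectivity == 8) ? 8 : 4;
  std::vector<int> stack;
  int next = 0;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + H * c);
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pr = p % H, pc = p / H;
        for (int q = 0; q < nn; ++q) {
          const int nr = pr + dr[q], nc = pc + dc[q];
          if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
          if (mask(nr, nc) && lab(nr, nc) == 0) {
            lab(nr, nc) = next;
            stack.push_back(nr + H * nc);
          }
        }
      }
    }
  }
  return lab;
}
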