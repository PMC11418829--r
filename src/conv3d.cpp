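#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Spatiotemporal (3D) convolution kernels for single-sample tensors.
// Tensors are column-major R arrays with dims (T, H, W, C):
//   idx(t,h,w,c) = t + T*(h + H*(w + W*c))
// Weights have dims (kt, kh, kw, Cin, Cout). Padding is TF-style "same"
// with ceil-mode output sizing; pad offsets are precomputed in R.
//
// The loops run one kernel tap at a time and accumulate whole temporal
// lines, so the hot path is a branch-free strided axpy. Per output element
// the contribution order is (ci, kw, kh, kt), matching the definition.

static inline long long tidx(int t, int h, int w, int c, int T, int H, int W) {
  return t + (long long)T * (h + (long long)H * (w + (long long)W * c));
}

// valid output range [o0, o1] for a kernel tap k: 0 <= o*s - p + k <= n-1
static inline void tap_range(int k, int s, int p, int n, int n_out,
                             int &o0, int &o1) {
  const int num = n - 1 + p - k;
  o0 = (p - k) > 0 ? (p - k + s - 1) / s : 0;
  o1 = num < 0 ? -1 : std::min(n_out - 1, num / s);  // empty range if num < 0
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_forward(NumericVector x, IntegerVector in_dim,
                                 NumericVector wts, IntegerVector k_dim,
                                 NumericVector bias, IntegerVector stride,
                                 IntegerVector pad, IntegerVector out_dim) {
  const int T = in_dim[0], H = in_dim[1], W = in_dim[2], Ci = in_dim[3];
  const int KT = k_dim[0], KH = k_dim[1], KW = k_dim[2], Co = k_dim[4];
  const int sT = stride[0], sH = stride[1], sW = stride[2];
  const int pT = pad[0], pH = pad[1], pW = pad[2];
  const int oT = out_dim[0], oH = out_dim[1], oW = out_dim[2];

  NumericVector out((R_xlen_t)oT * oH * oW * Co);
  const double *px = x.begin(), *pw = wts.begin();
  double *po = out.begin();

  for (int co = 0; co < Co; ++co) {
    double *oc = po + (R_xlen_t)oT * oH * oW * co;
    const double b = bias[co];
    for (R_xlen_t i = 0; i < (R_xlen_t)oT * oH * oW; ++i) oc[i] = b;
    const double *wco = pw + (long long)KT * KH * KW * Ci * co;
    for (int ci = 0; ci < Ci; ++ci) {
      const double *xc = px + (R_xlen_t)T * H * W * ci;
      const double *wci = wco + (long long)KT * KH * KW * ci;
      for (int kw = 0; kw < KW; ++kw) {
        int ow0, ow1; tap_range(kw, sW, pW, W, oW, ow0, ow1);
        for (int kh = 0; kh < KH; ++kh) {
          int oh0, oh1; tap_range(kh, sH, pH, H, oH, oh0, oh1);
          for (int kt = 0; kt < KT; ++kt) {
            int ot0, ot1; tap_range(kt, sT, pT, T, oT, ot0, ot1);
            const double wv = wci[kt + KT * (kh + KH * kw)];
            if (wv == 0.0) continue;
            for (int ow = ow0; ow <= ow1; ++ow) {
              const int iw = ow * sW - pW + kw;
              for (int oh = oh0; oh <= oh1; ++oh) {
                const int ih = oh * sH - pH + kh;
                const double *xl = xc + ((R_xlen_t)iw * H + ih) * T
                                   + (-pT + kt);
                double *ol = oc + ((R_xlen_t)ow * oH + oh) * oT;
                for (int ot = ot0; ot <= ot1; ++ot)
                  ol[ot] += wv * xl[(R_xlen_t)ot * sT];
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// need_gx = false skips the input-gradient accumulation (used for the first
// layer, whose input gradient is never consumed).
// [[Rcpp::export]]
List cpp_conv3d_backward(NumericVector x, IntegerVector in_dim,
                         NumericVector wts, IntegerVector k_dim,
                         NumericVector gout, IntegerVector out_dim,
                         IntegerVector stride, IntegerVector pad,
                         bool need_gx = true) {
  const int T = in_dim[0], H = in_dim[1], W = in_dim[2], Ci = in_dim[3];
  const int KT = k_dim[0], KH = k_dim[1], KW = k_dim[2], Co = k_dim[4];
  const int sT = stride[0], sH = stride[1], sW = stride[2];
  const int pT = pad[0], pH = pad[1], pW = pad[2];
  const int oT = out_dim[0], oH = out_dim[1], oW = out_dim[2];

  NumericVector gx_full((R_xlen_t)T * H * W * Ci);
  NumericVector gw(wts.size());
  NumericVector gb(Co);
  const double *px = x.begin(), *pw = wts.begin(), *pg = gout.begin();
  double *pgx = gx_full.begin(), *pgw = gw.begin(), *pgb = gb.begin();

  for (int co = 0; co < Co; ++co) {
    const double *gc = pg + (R_xlen_t)oT * oH * oW * co;
    // bias gradient: plain sum over the channel's outputs
    double bsum = 0.0;
    for (R_xlen_t i = 0; i < (R_xlen_t)oT * oH * oW; ++i) bsum += gc[i];
    pgb[co] = bsum;
    const double *wco = pw + (long long)KT * KH * KW * Ci * co;
    double *gwco = pgw + (long long)KT * KH * KW * Ci * co;
    for (int ci = 0; ci < Ci; ++ci) {
      const double *xc = px + (R_xlen_t)T * H * W * ci;
      double *gxc = pgx + (R_xlen_t)T * H * W * ci;
      const double *wci = wco + (long long)KT * KH * KW * ci;
      double *gwci = gwco + (long long)KT * KH * KW * ci;
      for (int kw = 0; kw < KW; ++kw) {
        int ow0, ow1; tap_range(kw, sW, pW, W, oW, ow0, ow1);
        for (int kh = 0; kh < KH; ++kh) {
          int oh0, oh1; tap_range(kh, sH, pH, H, oH, oh0, oh1);
          for (int kt = 0; kt < KT; ++kt) {
            int ot0, ot1; tap_range(kt, sT, pT, T, oT, ot0, ot1);
            const double wv = wci[kt + KT * (kh + KH * kw)];
            double wsum = 0.0;
            for (int ow = ow0; ow <= ow1; ++ow) {
              const int iw = ow * sW - pW + kw;
              for (int oh = oh0; oh <= oh1; ++oh) {
                const int ih = oh * sH - pH + kh;
                const double *xl = xc + ((R_xlen_t)iw * H + ih) * T
                                   + (-pT + kt);
                double *gxl = gxc + ((R_xlen_t)iw * H + ih) * T + (-pT + kt);
                const double *gl = gc + ((R_xlen_t)ow * oH + oh) * oT;
                if (need_gx) {
                  for (int ot = ot0; ot <= ot1; ++ot) {
                    const double g = gl[ot];
                    wsum += g * xl[(R_xlen_t)ot * sT];
                    gxl[(R_xlen_t)ot * sT] += g * wv;
                  }
                } else {
                  for (int ot = ot0; ot <= ot1; ++ot)
                    wsum += gl[ot] * xl[(R_xlen_t)ot * sT];
                }
              }
            }
            gwci[kt + KT * (kh + KH * kw)] += wsum;
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx_full, _["gw"] = gw, _["gb"] = gb);
}
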