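// Minimal CPU kernels for the detector: im2col convolution (forward,
// input/weight backward) and max pooling with argmax cache.
// Array layout throughout: column-major (H, W, C, N); weights (KH, KW, Cin, Cout).
// The col matrix is (Ho*Wo x KH*KW*Cin) so spatial writes are contiguous;
// 1x1/stride-1 convolutions skip im2col entirely and use the input memory
// as the col matrix.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int s, int p) {
  return (in + 2 * p - k) / s + 1;
}

// col: (Ho*Wo) x (KH*KW*Cin), column index = kh + KH*(kw + KW*c)
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int s, int p, arma::mat& col) {
  const int Ho = out_size(H, kh, s, p), Wo = out_size(W, kw, s, p);
  const int nr = Ho * Wo;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (std::size_t)c * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        double* dst = col.colptr(i + kh * (j + kw * c));
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * s - p + j;
          double* d2 = dst + (std::size_t)wo * Ho;
          if (wi < 0 || wi >= W) {
            std::fill(d2, d2 + Ho, 0.0);
            continue;
          }
          const double* xcol = xc + (std::size_t)wi * H;
          if (s == 1) {
            const int hi0 = -p + i;
            int ho = 0;
            for (; ho < Ho && hi0 + ho < 0; ++ho) d2[ho] = 0.0;
            int hend = std::min(Ho, H - hi0);
            for (; ho < hend; ++ho) d2[ho] = xcol[hi0 + ho];
            for (; ho < Ho; ++ho) d2[ho] = 0.0;
          } else {
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * s - p + i;
              d2[ho] = (hi < 0 || hi >= H) ? 0.0 : xcol[hi];
            }
          }
        }
      }
    }
  }
  (void)nr;
}

static void col2im_add(const arma::mat& col, int H, int W, int C,
                       int kh, int kw, int s, int p, double* x) {
  const int Ho = out_size(H, kh, s, p), Wo = out_size(W, kw, s, p);
  for (int c = 0; c < C; ++c) {
    double* xc = x + (std::size_t)c * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const double* src = col.colptr(i + kh * (j + kw * c));
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * s - p + j;
          if (wi < 0 || wi >= W) continue;
          const double* s2 = src + (std::size_t)wo * Ho;
          double* xcol = xc + (std::size_t)wi * H;
          if (s == 1) {
            const int hi0 = -p + i;
            const int lo = std::max(0, -hi0), hi_end = std::min(Ho, H - hi0);
            for (int ho = lo; ho < hi_end; ++ho) xcol[hi0 + ho] += s2[ho];
          } else {
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * s - p + i;
              if (hi >= 0 && hi < H) xcol[hi] += s2[ho];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_forward(NumericVector x, NumericVector w,
                               int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int KH = wd[0], KW = wd[1], CI = wd[2], CO = wd[3];
  if (CI != C) stop("channel mismatch in conv forward");
  const int Ho = out_size(H, KH, stride, pad), Wo = out_size(W, KW, stride, pad);
  if (Ho <= 0 || Wo <= 0) stop("non-positive conv output size");
  const bool fast11 = (KH == 1 && KW == 1 && stride == 1 && pad == 0);
  NumericVector y(Ho * (R_xlen_t)Wo * CO * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, CO, N);
  arma::mat wm(w.begin(), KH * KW * CI, CO, false, true);
  arma::mat col;
  if (!fast11) col.set_size(Ho * Wo, KH * KW * CI);
  for (int n = 0; n < N; ++n) {
    arma::mat ym(y.begin() + (std::size_t)n * Ho * Wo * CO, Ho * Wo, CO, false, true);
    if (fast11) {
      const arma::mat xm(const_cast<double*>(x.begin()) + (std::size_t)n * H * W * C,
                         H * W, C, false, true);
      ym = xm * wm;
    } else {
      im2col(x.begin() + (std::size_t)n * H * W * C, H, W, C, KH, KW, stride, pad, col);
      ym = col * wm;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv_backward(NumericVector x, NumericVector w, NumericVector dy,
                       int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int KH = wd[0], KW = wd[1], CI = wd[2], CO = wd[3];
  const int Ho = yd[0], Wo = yd[1];
  const bool fast11 = (KH == 1 && KW == 1 && stride == 1 && pad == 0);
  NumericVector dx(x.size()), dw(w.size());
  dx.attr("dim") = xd; dw.attr("dim") = wd;
  arma::mat wm(w.begin(), KH * KW * CI, CO, false, true);
  arma::mat dwm(dw.begin(), KH * KW * CI, CO, false, true);
  arma::mat col;
  if (!fast11) col.set_size(Ho * Wo, KH * KW * CI);
  for (int n = 0; n < N; ++n) {
    arma::mat dym(const_cast<double*>(dy.begin()) + (std::size_t)n * Ho * Wo * CO,
                  Ho * Wo, CO, false, true);
    if (fast11) {
      const arma::mat xm(const_cast<double*>(x.begin()) + (std::size_t)n * H * W * C,
                         H * W, C, false, true);
      arma::mat dxm(dx.begin() + (std::size_t)n * H * W * C, H * W, C, false, true);
      dwm += xm.t() * dym;
      dxm += dym * wm.t();
    } else {
      const double* xn = x.begin() + (std::size_t)n * H * W * C;
      im2col(xn, H, W, C, KH, KW, stride, pad, col);
      dwm += col.t() * dym;
      arma::mat dcol = dym * wm.t();           // (HoWo x KHKWCI)
      col2im_add(dcol, H, W, C, KH, KW, stride, pad,
                 dx.begin() + (std::size_t)n * H * W * C);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// [[Rcpp::export]]
List cpp_maxpool_forward(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  NumericVector y(Ho * (R_xlen_t)Wo * C * N);
  IntegerVector idx(y.size());      // 0-based linear index into x, -1 if all-pad
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (std::size_t)n * H * W * C;
    const std::size_t nbase = (std::size_t)n * H * W * C;
    for (int c = 0; c < C; ++c) {
      const double* xc = xn + (std::size_t)c * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -1e300; long bi = -1;
          for (int j = 0; j < k; ++j) {
            const int wi = wo * stride - pad + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < k; ++i) {
              const int hi = ho * stride - pad + i;
              if (hi < 0 || hi >= H) continue;
              const double v = xc[(std::size_t)wi * H + hi];
              if (v > best) { best = v; bi = nbase + (std::size_t)c * H * W + (std::size_t)wi * H + hi; }
            }
          }
          R_xlen_t pos = ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * (c + (R_xlen_t)C * n));
          y[pos] = (bi < 0) ? 0.0 : best;
          idx[pos] = (int)bi;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(NumericVector dy, IntegerVector idx,
                                   IntegerVector xdim) {
  R_xlen_t n = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i)
    if (idx[i] >= 0) dx[idx[i]] += dy[i];
  return dx;
}

// channel-wise mean and mean-square over (H, W, N) in one pass
// [[Rcpp::export]]
List cpp_channel_moments(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const std::size_t hw = (std::size_t)H * W;
  NumericVector mu(C), m2(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + hw * (c + (std::size_t)C * n);
      double s = 0, s2 = 0;
      for (std::size_t i = 0; i < hw; ++i) { s += p[i]; s2 += p[i] * p[i]; }
      mu[c] += s; m2[c] += s2;
    }
  const double denom = (double)hw * N;
  for (int c = 0; c < C; ++c) { mu[c] /= denom; m2[c] /= denom; }
  return List::create(_["mean"] = mu, _["meansq"] = m2);
}

// y = x * a[c] + b[c], per channel (fused broadcast)
// [[Rcpp::export]]
NumericVector cpp_affine_ch(NumericVector x, NumericVector a, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const std::size_t hw = (std::size_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = xd;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + hw * (c + (std::size_t)C * n);
      double* q = y.begin() + hw * (c + (std::size_t)C * n);
      const double ac = a[c], bc = b[c];
      for (std::size_t i = 0; i < hw; ++i) q[i] = p[i] * ac + bc;
    }
  return y;
}

// dx = (dy - dbm[c] - xhat * dgm[c]) * gi[c]   (fused BN backward)
// [[Rcpp::export]]
NumericVector cpp_bn_backward_dx(NumericVector dy, NumericVector xhat,
                                 NumericVector dbm, NumericVector dgm,
                                 NumericVector gi) {
  IntegerVector xd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const std::size_t hw = (std::size_t)H * W;
  NumericVector dx(dy.size());
  dx.attr("dim") = xd;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const std::size_t off = hw * (c + (std::size_t)C * n);
      const double* pd = dy.begin() + off;
      const double* px = xhat.begin() + off;
      double* q = dx.begin() + off;
      const double b = dbm[c], g = dgm[c], gic = gi[c];
      for (std::size_t i = 0; i < hw; ++i)
        q[i] = (pd[i] - b - px[i] * g) * gic;
    }
  return dx;
}

// Fused BatchNorm(+SiLU) forward: y = act(g[c]*(z - mu[c])*istd[c] + b[c])
// [[Rcpp::export]]
NumericVector cpp_bnact_forward(NumericVector z, NumericVector g,
                                NumericVector b, NumericVector mu,
                                NumericVector istd, bool act) {
  IntegerVector xd = z.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const std::size_t hw = (std::size_t)H * W;
  NumericVector y(z.size());
  y.attr("dim") = xd;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const std::size_t off = hw * (c + (std::size_t)C * n);
      const double* p = z.begin() + off;
      double* q = y.begin() + off;
      const double a = g[c] * istd[c], bb = b[c] - mu[c] * g[c] * istd[c];
      if (act) {
        for (std::size_t i = 0; i < hw; ++i) {
          const double pre = p[i] * a + bb;
          q[i] = pre / (1.0 + std::exp(-pre));
        }
      } else {
        for (std::size_t i = 0; i < hw; ++i) q[i] = p[i] * a + bb;
      }
    }
  return y;
}

// Fused BatchNorm(+SiLU) backward; recomputes pre-activation from z.
// train = TRUE propagates through the batch statistics.
// [[Rcpp::export]]
List cpp_bnact_backward(NumericVector dy, NumericVector z, NumericVector g,
                        NumericVector b, NumericVector mu, NumericVector istd,
                        bool act, bool train) {
  IntegerVector xd = z.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const std::size_t hw = (std::size_t)H * W;
  const double m = (double)hw * N;
  NumericVector dz(z.size()), dg(C), db(C);
  dz.attr("dim") = xd;
  // pass 1: dpre stored in dz; accumulate dgamma, dbeta
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const std::size_t off = hw * (c + (std::size_t)C * n);
      const double* pz = z.begin() + off;
      const double* pd = dy.begin() + off;
      double* q = dz.begin() + off;
      const double mc = mu[c], ic = istd[c], gc = g[c], bc = b[c];
      double sg = 0, sb = 0;
      for (std::size_t i = 0; i < hw; ++i) {
        const double xh = (pz[i] - mc) * ic;
        double dpre;
        if (act) {
          const double pre = gc * xh + bc;
          const double s = 1.0 / (1.0 + std::exp(-pre));
          dpre = pd[i] * s * (1.0 + pre * (1.0 - s));
        } else dpre = pd[i];
        q[i] = dpre;
        sg += dpre * xh; sb += dpre;
      }
      dg[c] += sg; db[c] += sb;
    }
  // pass 2: dz = (dpre - db/m - xhat*dg/m) * g * istd  (or plain scale in eval)
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const std::size_t off = hw * (c + (std::size_t)C * n);
      const double* pz = z.begin() + off;
      double* q = dz.begin() + off;
      const double mc = mu[c], ic = istd[c], gic = g[c] * istd[c];
      const double tb = db[c] / m, tg = dg[c] / m;
      if (train) {
        for (std::size_t i = 0; i < hw; ++i) {
          const double xh = (pz[i] - mc) * ic;
          q[i] = (q[i] - tb - xh * tg) * gic;
        }
      } else {
        for (std::size_t i = 0; i < hw; ++i) q[i] *= gic;
      }
    }
  return List::create(_["dx"] = dz, _["dgamma"] = dg, _["dbeta"] = db);
}
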