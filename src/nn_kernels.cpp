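#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <cstring>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// Activations are stored channels-first: column p + H*W*n of a
// (C, H*W*N) matrix holds the C channel values of pixel p (column-major
// H x W plane) of image n. All large tensors live in preallocated
// workspace vectors that these kernels write into; explicit dimensions
// are passed because a buffer's capacity can exceed the used extent
// (the last minibatch of an epoch may be smaller).
//
// im2col implements a 3x3 window with zero padding 1 and stride 1
// ("same" padding): block k of the 9*C rows (offset dh, dw with
// k = (dw+1)*3 + dh+1) holds the C channels of the pixel shifted by
// (dh, dw).

// [[Rcpp::export(name = ".cpp_im2col3_into")]]
void cpp_im2col3_into(NumericVector out, const NumericVector& x, int C,
                      int H, int W, int N) {
  const int HW = H * W;
  const double* px = x.begin();
  double* po = out.begin();
  const size_t csz = (size_t)C * sizeof(double);
  for (int n = 0; n < N; ++n) {
    const double* xn = px + (R_xlen_t)n * HW * C;
    double* on = po + (R_xlen_t)n * HW * 9 * C;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        double* col = on + (R_xlen_t)(w * H + h) * 9 * C;
        int k = 0;
        for (int dw = -1; dw <= 1; ++dw) {
          const int ww = w + dw;
          const bool wok = (ww >= 0 && ww < W);
          for (int dh = -1; dh <= 1; ++dh, ++k) {
            const int hh = h + dh;
            double* dst = col + (R_xlen_t)k * C;
            if (wok && hh >= 0 && hh < H)
              std::memcpy(dst, xn + (R_xlen_t)(ww * H + hh) * C, csz);
            else
              std::memset(dst, 0, csz);
          }
        }
      }
    }
  }
}

// C (M x Ncol) = op(A) %*% op(B); matrices are contiguous column-major
// with their stored leading dimension implied by the transpose flags.
// [[Rcpp::export(name = ".cpp_dgemm_into")]]
void cpp_dgemm_into(NumericVector Cbuf, const NumericVector& A,
                    const NumericVector& B, int M, int Ncol, int K,
                    bool ta, bool tb) {
  const char cta = ta ? 'T' : 'N';
  const char ctb = tb ? 'T' : 'N';
  const int lda = ta ? K : M;
  const int ldb = tb ? Ncol : K;
  const double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)(&cta, &ctb, &M, &Ncol, &K, &one, A.begin(), &lda,
                  B.begin(), &ldb, &zero, Cbuf.begin(), &M
                  FCONE FCONE);
}

// Fused conv-bias + batch-norm (batch statistics) + ReLU forward:
// out = relu(gamma * xhat + beta), xhat = (x + b - mu) / sd.
// Returns the batch moments for the running-statistics update.
// [[Rcpp::export(name = ".cpp_bn_relu_fwd_into")]]
List cpp_bn_relu_fwd_into(const NumericVector& x, const NumericVector& b,
                          const NumericVector& gamma,
                          const NumericVector& beta, double eps, int C,
                          R_xlen_t S, NumericVector out,
                          NumericVector xhat) {
  NumericVector mu(C), var(C), invstd(C);
  const double* px = x.begin();
  for (R_xlen_t j = 0; j < S; ++j) {
    const double* col = px + j * C;
    for (int c = 0; c < C; ++c) {
      mu[c] += col[c];
      var[c] += col[c] * col[c];
    }
  }
  for (int c = 0; c < C; ++c) {
    mu[c] = mu[c] / S + b[c];
    var[c] = var[c] / S - (mu[c] - b[c]) * (mu[c] - b[c]);
    if (var[c] < 0) var[c] = 0;
    invstd[c] = 1.0 / std::sqrt(var[c] + eps);
  }
  double* po = out.begin();
  double* ph = xhat.begin();
  for (R_xlen_t j = 0; j < S; ++j) {
    const double* col = px + j * C;
    double* oc = po + j * C;
    double* hc = ph + j * C;
    for (int c = 0; c < C; ++c) {
      const double h = (col[c] + b[c] - mu[c]) * invstd[c];
      hc[c] = h;
      const double y = h * gamma[c] + beta[c];
      oc[c] = y > 0 ? y : 0.0;
    }
  }
  return List::create(_["mu"] = mu, _["var"] = var,
                      _["invstd"] = invstd);
}

// Inference-mode conv-bias + batch-norm + ReLU using running statistics.
// [[Rcpp::export(name = ".cpp_bn_relu_inf_into")]]
void cpp_bn_relu_inf_into(const NumericVector& x, const NumericVector& b,
                          const NumericVector& gamma,
                          const NumericVector& beta,
                          const NumericVector& mean,
                          const NumericVector& var, double eps, int C,
                          R_xlen_t S, NumericVector out) {
  std::vector<double> scale(C), shift(C);
  for (int c = 0; c < C; ++c) {
    scale[c] = gamma[c] / std::sqrt(var[c] + eps);
    shift[c] = beta[c] + scale[c] * (b[c] - mean[c]);
  }
  const double* px = x.begin();
  double* po = out.begin();
  for (R_xlen_t j = 0; j < S; ++j) {
    const double* col = px + j * C;
    double* oc = po + j * C;
    for (int c = 0; c < C; ++c) {
      const double y = col[c] * scale[c] + shift[c];
      oc[c] = y > 0 ? y : 0.0;
    }
  }
}

// Fused ReLU + batch-norm backward. dy is the gradient at the ReLU
// output; out is the forward output (its positivity is the ReLU mask).
// [[Rcpp::export(name = ".cpp_bn_relu_bwd_into")]]
List cpp_bn_relu_bwd_into(const NumericVector& dy,
                          const NumericVector& out,
                          const NumericVector& xhat,
                          const NumericVector& invstd,
                          const NumericVector& gamma, int C, R_xlen_t S,
                          NumericVector dx) {
  NumericVector dgamma(C), dbeta(C);
  const double* pd = dy.begin();
  const double* po = out.begin();
  const double* ph = xhat.begin();
  for (R_xlen_t j = 0; j < S; ++j) {
    const double* dc = pd + j * C;
    const double* oc = po + j * C;
    const double* hc = ph + j * C;
    for (int c = 0; c < C; ++c) {
      const double g = oc[c] > 0 ? dc[c] : 0.0;
      dbeta[c] += g;
      dgamma[c] += g * hc[c];
    }
  }
  std::vector<double> m1(C), m2(C);
  for (int c = 0; c < C; ++c) {
    m1[c] = gamma[c] * dbeta[c] / S;   // mean of dxhat
    m2[c] = gamma[c] * dgamma[c] / S;  // mean of dxhat * xhat
  }
  double* px = dx.begin();
  for (R_xlen_t j = 0; j < S; ++j) {
    const double* dc = pd + j * C;
    const double* oc = po + j * C;
    const double* hc = ph + j * C;
    double* xc = px + j * C;
    for (int c = 0; c < C; ++c) {
      const double g = oc[c] > 0 ? dc[c] : 0.0;
      xc[c] = invstd[c] * (g * gamma[c] - m1[c] - hc[c] * m2[c]);
    }
  }
  return List::create(_["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Non-overlapping max pooling with floor division: trailing rows and
// columns that do not fill a window are dropped (140 -> 70 -> 23 -> 7).
// argmax records absolute indices into the input buffer for backward.
// [[Rcpp::export(name = ".cpp_maxpool_fwd_into")]]
void cpp_maxpool_fwd_into(const NumericVector& x, int C, int H, int W,
                          int N, int p, NumericVector out,
                          IntegerVector argmax) {
  const int H2 = H / p, W2 = W / p;
  const int HW = H * W, HW2 = H2 * W2;
  const double* px = x.begin();
  double* po = out.begin();
  int* pa = argmax.begin();
  for (int n = 0; n < N; ++n) {
    const R_xlen_t xoff = (R_xlen_t)n * HW * C;
    const R_xlen_t ooff = (R_xlen_t)n * HW2 * C;
    for (int w2 = 0; w2 < W2; ++w2) {
      for (int h2 = 0; h2 < H2; ++h2) {
        double* oc = po + ooff + (R_xlen_t)(w2 * H2 + h2) * C;
        int* ac = pa + ooff + (R_xlen_t)(w2 * H2 + h2) * C;
        bool first = true;
        for (int dw = 0; dw < p; ++dw) {
          for (int dh = 0; dh < p; ++dh) {
            const R_xlen_t src =
              xoff + (R_xlen_t)((w2 * p + dw) * H + h2 * p + dh) * C;
            const double* xc = px + src;
            if (first) {
              for (int c = 0; c < C; ++c) {
                oc[c] = xc[c];
                ac[c] = (int)(src + c);
              }
              first = false;
            } else {
              for (int c = 0; c < C; ++c) {
                if (xc[c] > oc[c]) {
                  oc[c] = xc[c];
                  ac[c] = (int)(src + c);
                }
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_maxpool_bwd_into")]]
void cpp_maxpool_bwd_into(const NumericVector& dy,
                          const IntegerVector& argmax, R_xlen_t nOut,
                          R_xlen_t nIn, NumericVector dx) {
  double* pd = dx.begin();
  std::memset(pd, 0, (size_t)nIn * sizeof(double));
  const double* py = dy.begin();
  const int* pa = argmax.begin();
  for (R_xlen_t i = 0; i < nOut; ++i) pd[pa[i]] += py[i];
}

// Inverted dropout applied in place; the mask (0 or 1/(1-rate)) is
// stored for the backward pass. Uses R's RNG so runs are seeded.
// [[Rcpp::export(name = ".cpp_dropout_inplace")]]
void cpp_dropout_inplace(NumericVector x, R_xlen_t len, double rate,
                         NumericVector mask) {
  GetRNGstate();
  double* px = x.begin();
  double* pm = mask.begin();
  const double inv = 1.0 / (1.0 - rate);
  for (R_xlen_t i = 0; i < len; ++i) {
    const double m = unif_rand() >= rate ? inv : 0.0;
    pm[i] = m;
    px[i] *= m;
  }
  PutRNGstate();
}

// [[Rcpp::export(name = ".cpp_mul_inplace")]]
void cpp_mul_inplace(NumericVector x, const NumericVector& mask,
                     R_xlen_t len) {
  double* px = x.begin();
  const double* pm = mask.begin();
  for (R_xlen_t i = 0; i < len; ++i) px[i] *= pm[i];
}

// [[Rcpp::export(name = ".cpp_scale_into")]]
void cpp_scale_into(NumericVector out, const NumericVector& x,
                    R_xlen_t len, double factor) {
  double* po = out.begin();
  const double* px = x.begin();
  for (R_xlen_t i = 0; i < len; ++i) po[i] = px[i] * factor;
}

// [[Rcpp::export(name = ".cpp_rowsums")]]
NumericVector cpp_rowsums(const NumericVector& x, int C, R_xlen_t S) {
  NumericVector out(C);
  const double* px = x.begin();
  for (R_xlen_t j = 0; j < S; ++j) {
    const double* col = px + j * C;
    for (int c = 0; c < C; ++c) out[c] += col[c];
  }
  return out;
}

// Global average pool (C, HW*N) -> (C, N) and its transpose spread.
// [[Rcpp::export(name = ".cpp_gap_fwd")]]
NumericMatrix cpp_gap_fwd(const NumericVector& x, int C, int HW, int N) {
  NumericMatrix out(C, N);
  const double* px = x.begin();
  double* po = out.begin();
  for (int n = 0; n < N; ++n) {
    double* oc = po + (R_xlen_t)n * C;
    for (int p = 0; p < HW; ++p) {
      const double* col = px + ((R_xlen_t)n * HW + p) * C;
      for (int c = 0; c < C; ++c) oc[c] += col[c];
    }
    for (int c = 0; c < C; ++c) oc[c] /= HW;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_gap_bwd")]]
NumericVector cpp_gap_bwd(const NumericMatrix& dG, int C, int HW,
                          int N) {
  NumericVector out((R_xlen_t)C * HW * N);
  const double* pg = dG.begin();
  double* po = out.begin();
  for (int n = 0; n < N; ++n) {
    const double* gc = pg + (R_xlen_t)n * C;
    for (int p = 0; p < HW; ++p) {
      double* col = po + ((R_xlen_t)n * HW + p) * C;
      for (int c = 0; c < C; ++c) col[c] = gc[c] / HW;
    }
  }
  return out;
}
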