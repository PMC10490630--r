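// Compiled kernels for the CNN training engine: 2-D "same" convolution
// (with fused ReLU) and max-pooling (with fused ReLU backward), forward
// and backward. Convolutions are evaluated as im2col gathers followed by
// a single-precision GEMM; for small patch sizes (first layer) a
// register-blocked kernel replaces the GEMM, which is memory-bound there.
// Activations and gradients cross the R boundary as double arrays.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Gather x (h, w, ci, m) into the im2col matrix (npos*m) x (kh*kw*ci),
// zero-padded "same" convolution, stride 1.  Row order: spatial position
// (i fastest), then image; column order: (ki, kj, c) with ki fastest,
// matching R's flattening of a (kh, kw, ci, co) weight array.
static void im2col(const double* x, int h, int w, int ci, int m,
                   int kh, int kw, arma::fmat& xcol) {
  const int npos = h * w;
  const int ph = kh / 2, pw = kw / 2;
  for (int c = 0; c < ci; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int colidx = ki + kh * kj + kh * kw * c;
        float* dst = xcol.colptr(colidx);
        for (int img = 0; img < m; ++img) {
          const double* xs = x + (size_t)npos * (c + (size_t)ci * img);
          float* drow = dst + (size_t)npos * img;
          for (int j = 0; j < w; ++j) {
            const int sj = j + kj - pw;
            if (sj < 0 || sj >= w) {
              for (int i = 0; i < h; ++i) drow[i + h * j] = 0.0f;
              continue;
            }
            const double* xcolsrc = xs + (size_t)h * sj;
            const int ioff = ki - ph;
            for (int i = 0; i < h; ++i) {
              const int si = i + ioff;
              drow[i + h * j] = (si < 0 || si >= h) ? 0.0f
                                                    : (float)xcolsrc[si];
            }
          }
        }
      }
    }
  }
}

// y = xcol * wmat for small k (patch size), blocked so the co-wide
// accumulator stays in registers/L1; beats BLAS when k ~ 9.
static void small_k_gemm(const arma::fmat& xcol, const arma::fmat& wmat,
                         arma::fmat& y) {
  const size_t N = xcol.n_rows, K = xcol.n_cols, co = wmat.n_cols;
  arma::fmat wT(co, K);             // co contiguous per patch entry
  for (size_t k = 0; k < K; ++k)
    for (size_t l = 0; l < co; ++l) wT(l, k) = wmat(k, l);
  std::vector<float> acc(co);
  std::vector<const float*> xc(K);
  for (size_t k = 0; k < K; ++k) xc[k] = xcol.colptr(k);
  for (size_t i = 0; i < N; ++i) {
    std::fill(acc.begin(), acc.end(), 0.0f);
    for (size_t k = 0; k < K; ++k) {
      const float a = xc[k][i];
      const float* wrow = wT.colptr(k);
      for (size_t l = 0; l < co; ++l) acc[l] += a * wrow[l];
    }
    for (size_t l = 0; l < co; ++l) y(i, l) = acc[l];
  }
}

// [[Rcpp::export]]
List conv2d_fwd_cpp(NumericVector x, NumericVector wgt, NumericVector bias,
                    bool relu) {
  IntegerVector xd = x.attr("dim"), wd = wgt.attr("dim");
  const int h = xd[0], w = xd[1], ci = xd[2], m = xd[3];
  const int kh = wd[0], kw = wd[1], co = wd[3];
  if (wd[2] != ci) stop("conv2d: input channels do not match filter shape");
  const int npos = h * w;
  const size_t K = (size_t)kh * kw * ci;

  // the im2col matrix is kept alive behind an external pointer so the
  // backward pass can reuse it instead of re-gathering
  XPtr<arma::fmat> xcolp(new arma::fmat((size_t)npos * m, K), true);
  arma::fmat& xcol = *xcolp;
  im2col(REAL(x), h, w, ci, m, kh, kw, xcol);
  arma::fmat wmat(K, co);
  for (size_t i = 0; i < wmat.n_elem; ++i) wmat(i) = (float)wgt[i];

  arma::fmat y((size_t)npos * m, co);
  if (K <= 16) small_k_gemm(xcol, wmat, y);
  else y = xcol * wmat;

  NumericVector out((size_t)npos * co * m);
  out.attr("dim") = IntegerVector::create(h, w, co, m);
  double* o = REAL(out);
  for (int l = 0; l < co; ++l) {
    const float* yc = y.colptr(l);
    const double bl = bias[l];
    for (int img = 0; img < m; ++img) {
      const float* src = yc + (size_t)npos * img;
      double* dst = o + (size_t)npos * (l + (size_t)co * img);
      if (relu) {
        for (int p = 0; p < npos; ++p) {
          const double v = (double)src[p] + bl;
          dst[p] = v > 0 ? v : 0.0;
        }
      } else {
        for (int p = 0; p < npos; ++p) dst[p] = (double)src[p] + bl;
      }
    }
  }
  return List::create(_["y"] = out, _["xcol"] = xcolp);
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector wgt, NumericVector gy,
                    bool need_gx, SEXP xcol_cache) {
  IntegerVector xd = x.attr("dim"), wd = wgt.attr("dim");
  const int h = xd[0], w = xd[1], ci = xd[2], m = xd[3];
  const int kh = wd[0], kw = wd[1], co = wd[3];
  const int npos = h * w;
  const int ph = kh / 2, pw = kw / 2;

  arma::fmat own;
  arma::fmat* xcp;
  if (xcol_cache != R_NilValue) {
    XPtr<arma::fmat> p(xcol_cache);
    xcp = p.get();
  } else {
    own.set_size((size_t)npos * m, (size_t)kh * kw * ci);
    im2col(REAL(x), h, w, ci, m, kh, kw, own);
    xcp = &own;
  }
  arma::fmat& xcol = *xcp;

  // gy (h, w, co, m) -> (npos*m) x co
  arma::fmat gym((size_t)npos * m, co);
  const double* g = REAL(gy);
  for (int l = 0; l < co; ++l) {
    float* dst = gym.colptr(l);
    for (int img = 0; img < m; ++img) {
      const double* src = g + (size_t)npos * (l + (size_t)co * img);
      float* d2 = dst + (size_t)npos * img;
      for (int p = 0; p < npos; ++p) d2[p] = (float)src[p];
    }
  }

  arma::fmat gwm = xcol.t() * gym; // (kh*kw*ci) x co
  NumericVector gw((size_t)kh * kw * ci * co);
  gw.attr("dim") = IntegerVector::create(kh, kw, ci, co);
  for (size_t i = 0; i < gwm.n_elem; ++i) gw[i] = (double)gwm(i);

  NumericVector gb(co);
  for (int l = 0; l < co; ++l)
    gb[l] = (double)arma::accu(gym.col(l));

  List res = List::create(_["gw"] = gw, _["gb"] = gb);
  if (need_gx) {
    arma::fmat wmat(kh * kw * ci, co);
    for (size_t i = 0; i < wmat.n_elem; ++i) wmat(i) = (float)wgt[i];
    arma::fmat gxcol = gym * wmat.t(); // (npos*m) x (kh*kw*ci)
    NumericVector gx((size_t)npos * ci * m);
    gx.attr("dim") = IntegerVector::create(h, w, ci, m);
    double* go = REAL(gx);
    std::fill(go, go + (size_t)npos * ci * m, 0.0);
    for (int c = 0; c < ci; ++c) {
      for (int kj = 0; kj < kw; ++kj) {
        for (int ki = 0; ki < kh; ++ki) {
          const float* src = gxcol.colptr(ki + kh * kj + kh * kw * c);
          for (int img = 0; img < m; ++img) {
            const float* s2 = src + (size_t)npos * img;
            double* dst = go + (size_t)npos * (c + (size_t)ci * img);
            for (int j = 0; j < w; ++j) {
              const int sj = j + kj - pw;
              if (sj < 0 || sj >= w) continue;
              const int ioff = ki - ph;
              const int ilo = std::max(0, -ioff), ihi = std::min(h, h - ioff);
              for (int i = ilo; i < ihi; ++i)
                dst[(i + ioff) + h * sj] += (double)s2[i + h * j];
            }
          }
        }
      }
    }
    res["gx"] = gx;
  }
  return res;
}

// [[Rcpp::export]]
NumericVector relu_fwd_cpp(NumericVector x) {
  NumericVector y = clone(x);
  double* p = REAL(y);
  const R_xlen_t n = y.size();
  for (R_xlen_t i = 0; i < n; ++i) if (p[i] < 0) p[i] = 0;
  return y;
}

// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, int size, int stride) {
  IntegerVector xd = x.attr("dim");
  const int h = xd[0], w = xd[1], c = xd[2], m = xd[3];
  const int ho = (h - size) / stride + 1;
  const int wo = (w - size) / stride + 1;
  if (ho < 1 || wo < 1) stop("maxpool: window larger than input");
  if (size > 16) stop("maxpool: window size above 16 not supported");
  NumericVector y((size_t)ho * wo * c * m);
  IntegerVector idx((size_t)ho * wo * c * m); // 1-based linear index into x
  y.attr("dim") = IntegerVector::create(ho, wo, c, m);
  idx.attr("dim") = IntegerVector::create(ho, wo, c, m);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  int* ip = INTEGER(idx);
  size_t o = 0;
  for (int img = 0; img < m; ++img) {
    for (int ch = 0; ch < c; ++ch) {
      const size_t base = (size_t)h * w * (ch + (size_t)c * img);
      for (int jo = 0; jo < wo; ++jo) {
        size_t coff[16];
        for (int dj = 0; dj < size; ++dj)
          coff[dj] = base + (size_t)h * (jo * stride + dj);
        for (int io = 0; io < ho; ++io, ++o) {
          const int r = io * stride;
          double best = -HUGE_VAL;
          size_t besti = 0;
          for (int dj = 0; dj < size; ++dj) {
            const double* col = xp + coff[dj] + r;
            for (int di = 0; di < size; ++di) {
              if (col[di] > best) { best = col[di]; besti = coff[dj] + r + di; }
            }
          }
          yp[o] = best;
          ip[o] = (int)(besti + 1);
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// Scatter pooled gradients back to the argmax positions; `act` is the
// (pre-pool, post-ReLU) activation map, used to fuse the ReLU backward:
// positions whose activation is zero receive no gradient.
// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(IntegerVector idx, NumericVector gy,
                              IntegerVector xdim, NumericVector act) {
  size_t n = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(n);
  gx.attr("dim") = xdim;
  double* gp = REAL(gx);
  const double* gyp = REAL(gy);
  const double* ap = REAL(act);
  const int* ip = INTEGER(idx);
  const R_xlen_t ne = gy.size();
  for (R_xlen_t i = 0; i < ne; ++i) {
    const int k = ip[i] - 1;
    if (ap[k] > 0) gp[k] += gyp[i];
  }
  return gx;
}
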