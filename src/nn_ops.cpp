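#include <Rcpp.h>
using namespace Rcpp;

// Tensors are numeric arrays with dim (H, W, C, N), column-major.
// im2col unrolls kh x kw windows (stride 1, optional zero padding) into a
// matrix with rows ordered (i, j, n) fastest-to-slowest and columns ordered
// (p, q, channel). Convolution is then a single matrix product.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int kh, int kw, int pad) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int oh = H - kh + 1 + 2 * pad;
  const int ow = W - kw + 1 + 2 * pad;
  if (oh <= 0 || ow <= 0)
    stop("kernel larger than (padded) input");
  NumericMatrix out((R_xlen_t)oh * ow * N, (R_xlen_t)kh * kw * C);
  const double* px = REAL(x);
  double* po = REAL(out);
  const R_xlen_t HW = (R_xlen_t)H * W;
  const R_xlen_t nrow = (R_xlen_t)oh * ow * N;
  for (int ch = 0; ch < C; ++ch) {
    for (int q = 0; q < kw; ++q) {
      for (int p = 0; p < kh; ++p) {
        const R_xlen_t col = (R_xlen_t)p + (R_xlen_t)q * kh + (R_xlen_t)ch * kh * kw;
        double* ocol = po + col * nrow;
        for (int n = 0; n < N; ++n) {
          const double* xc = px + ((R_xlen_t)n * C + ch) * HW;
          for (int j = 0; j < ow; ++j) {
            const int jj = j + q - pad;
            double* orow = ocol + (R_xlen_t)n * oh * ow + (R_xlen_t)j * oh;
            if (jj < 0 || jj >= W) continue;  // stays zero
            const double* xcol = xc + (R_xlen_t)jj * H;
            const int i0 = std::max(0, pad - p);
            const int i1 = std::min(oh, H - p + pad);
            for (int i = i0; i < i1; ++i) orow[i] = xcol[i + p - pad];
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-add the column matrix back onto the input grid.

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, IntegerVector xdim,
                         int kh, int kw, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int oh = H - kh + 1 + 2 * pad;
  const int ow = W - kw + 1 + 2 * pad;
  NumericVector out((R_xlen_t)H * W * C * N);
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  double* po = REAL(out);
  const double* pc = REAL(cols);
  const R_xlen_t HW = (R_xlen_t)H * W;
  const R_xlen_t nrow = (R_xlen_t)oh * ow * N;
  for (int ch = 0; ch < C; ++ch) {
    for (int q = 0; q < kw; ++q) {
      for (int p = 0; p < kh; ++p) {
        const R_xlen_t col = (R_xlen_t)p + (R_xlen_t)q * kh + (R_xlen_t)ch * kh * kw;
        const double* ccol = pc + col * nrow;
        for (int n = 0; n < N; ++n) {
          double* xc = po + ((R_xlen_t)n * C + ch) * HW;
          for (int j = 0; j < ow; ++j) {
            const int jj = j + q - pad;
            if (jj < 0 || jj >= W) continue;
            const double* crow = ccol + (R_xlen_t)n * oh * ow + (R_xlen_t)j * oh;
            double* xcol = xc + (R_xlen_t)jj * H;
            const int i0 = std::max(0, pad - p);
            const int i1 = std::min(oh, H - p + pad);
            for (int i = i0; i < i1; ++i) xcol[i + p - pad] += crow[i];
          }
        }
      }
    }
  }
  return out;
}

// Max pooling with floor semantics on odd sizes (trailing rows/cols beyond
// the last full window are dropped), matching the layer-size arithmetic of
// the stacked architectures. Returns pooled values and 1-based argmax
// indices into the input for the backward pass.

// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, int ph, int pw) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int oh = H / ph, ow = W / pw;
  if (oh <= 0 || ow <= 0) stop("pool window larger than input");
  NumericVector out((R_xlen_t)oh * ow * C * N);
  out.attr("dim") = IntegerVector::create(oh, ow, C, N);
  IntegerVector idx((R_xlen_t)oh * ow * C * N);
  idx.attr("dim") = IntegerVector::create(oh, ow, C, N);
  const double* px = REAL(x);
  double* po = REAL(out);
  int* pi = INTEGER(idx);
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const R_xlen_t base = ((R_xlen_t)n * C + c) * H * W;
      for (int j = 0; j < ow; ++j) {
        for (int i = 0; i < oh; ++i) {
          double best = R_NegInf;
          R_xlen_t bestk = 0;
          for (int q = 0; q < pw; ++q) {
            const R_xlen_t coloff = base + (R_xlen_t)(j * pw + q) * H + i * ph;
            for (int p = 0; p < ph; ++p) {
              const double v = px[coloff + p];
              if (v > best) { best = v; bestk = coloff + p; }
            }
          }
          po[o] = best;
          pi[o] = (int)(bestk + 1);
          ++o;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector gout, IntegerVector idx,
                              IntegerVector xdim) {
  NumericVector gin((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  gin.attr("dim") = xdim;
  double* pg = REAL(gin);
  const double* po = REAL(gout);
  const int* pi = INTEGER(idx);
  const R_xlen_t n = gout.size();
  for (R_xlen_t k = 0; k < n; ++k) pg[pi[k] - 1] += po[k];
  return gin;
}

// Fused batch-norm column ops: a column of the conv matrix is a channel.

// [[Rcpp::export]]
List bn_fwd_cpp(NumericMatrix x, NumericVector gamma, NumericVector beta,
                double eps) {
  const R_xlen_t m = x.nrow();
  const int C = x.ncol();
  NumericMatrix y(m, C), xhat(m, C);
  NumericVector mu(C), var(C), invstd(C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    double s = 0;
    for (R_xlen_t i = 0; i < m; ++i) s += xc[i];
    const double mc = s / m;
    double v = 0;
    for (R_xlen_t i = 0; i < m; ++i) { const double d = xc[i] - mc; v += d * d; }
    v /= m;
    const double is = 1.0 / std::sqrt(v + eps);
    const double g = gamma[c], b = beta[c];
    double* xh = &xhat(0, c);
    double* yc = &y(0, c);
    for (R_xlen_t i = 0; i < m; ++i) {
      const double h = (xc[i] - mc) * is;
      xh[i] = h;
      yc[i] = g * h + b;
    }
    mu[c] = mc; var[c] = v; invstd[c] = is;
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mu"] = mu,
                      _["var"] = var, _["invstd"] = invstd);
}

// [[Rcpp::export]]
NumericMatrix bn_eval_cpp(NumericMatrix x, NumericVector rm, NumericVector rv,
                          NumericVector gamma, NumericVector beta, double eps) {
  const R_xlen_t m = x.nrow();
  const int C = x.ncol();
  NumericMatrix y(m, C);
  for (int c = 0; c < C; ++c) {
    const double is = 1.0 / std::sqrt(rv[c] + eps);
    const double a = gamma[c] * is;
    const double b = beta[c] - rm[c] * a;
    const double* xc = &x(0, c);
    double* yc = &y(0, c);
    for (R_xlen_t i = 0; i < m; ++i) yc[i] = a * xc[i] + b;
  }
  return y;
}

// [[Rcpp::export]]
List bn_bwd_cpp(NumericMatrix gp, NumericMatrix xhat, NumericVector invstd,
                NumericVector gamma) {
  const R_xlen_t m = gp.nrow();
  const int C = gp.ncol();
  NumericMatrix gx(m, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* g = &gp(0, c);
    const double* xh = &xhat(0, c);
    double s1 = 0, s2 = 0, dg = 0;
    for (R_xlen_t i = 0; i < m; ++i) {
      dg += g[i] * xh[i];
      s1 += g[i];
      s2 += g[i] * xh[i];
    }
    dgamma[c] = dg;
    dbeta[c] = s1;
    const double ga = gamma[c];
    const double k = invstd[c] / m;
    const double gs1 = ga * s1, gs2 = ga * s2;
    double* gxc = &gx(0, c);
    for (R_xlen_t i = 0; i < m; ++i)
      gxc[i] = (ga * g[i] * m - gs1 - xh[i] * gs2) * k;
  }
  return List::create(_["gx"] = gx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
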