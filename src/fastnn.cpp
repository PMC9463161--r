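// Compute kernels for the small networks: 1-D convolution (kernel 3,
// stride 1, pad 1), fused ReLU+dropout, and weight-normalization algebra.
// Batches are (C, T*B) matrices with columns grouped by example.
// Inputs are borrowed from R memory (no copies) via advanced constructors.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat borrow(const NumericMatrix& m) {
  return arma::mat(const_cast<double*>(m.begin()), m.nrow(), m.ncol(), false, true);
}
static inline arma::vec borrow(const NumericVector& v) {
  return arma::vec(const_cast<double*>(v.begin()), v.size(), false, true);
}

// effective weight W = g * v / ||v||_row, plus the row norms
// [[Rcpp::export]]
List cpp_wn_weight(NumericMatrix v_, NumericVector g_) {
  const int nr = v_.nrow(), nc = v_.ncol();
  const double* v = v_.begin();
  const double* g = g_.begin();
  NumericVector rn_(nr);
  double* rn = rn_.begin();
  for (int j = 0; j < nc; ++j) {
    const double* vc = v + (R_xlen_t)j * nr;
    for (int i = 0; i < nr; ++i) rn[i] += vc[i] * vc[i];
  }
  std::vector<double> s(nr);
  for (int i = 0; i < nr; ++i) {
    rn[i] = std::sqrt(rn[i]);
    s[i] = g[i] / rn[i];
  }
  NumericMatrix W_(nr, nc);
  double* W = W_.begin();
  for (int j = 0; j < nc; ++j) {
    const double* vc = v + (R_xlen_t)j * nr;
    double* wc = W + (R_xlen_t)j * nr;
    for (int i = 0; i < nr; ++i) wc[i] = vc[i] * s[i];
  }
  return List::create(_["W"] = W_, _["rn"] = rn_);
}

// gradient of a weight-normalized layer w.r.t. direction v and scale g,
// given the gradient w.r.t. the effective weight
// [[Rcpp::export]]
List cpp_wn_backward(NumericMatrix dW_, NumericMatrix v_, NumericVector g_,
                     NumericVector rn_) {
  const int nr = v_.nrow(), nc = v_.ncol();
  const double* dW = dW_.begin();
  const double* v = v_.begin();
  const double* g = g_.begin();
  const double* rn = rn_.begin();
  std::vector<double> dot(nr, 0.0);
  for (int j = 0; j < nc; ++j) {
    const double* dc = dW + (R_xlen_t)j * nr;
    const double* vc = v + (R_xlen_t)j * nr;
    for (int i = 0; i < nr; ++i) dot[i] += dc[i] * vc[i];
  }
  NumericVector dg_(nr);
  std::vector<double> s1(nr), s2(nr);
  for (int i = 0; i < nr; ++i) {
    dg_[i] = dot[i] / rn[i];
    s1[i] = g[i] / rn[i];
    s2[i] = g[i] * dot[i] / (rn[i] * rn[i] * rn[i]);
  }
  NumericMatrix dv_(nr, nc);
  double* dv = dv_.begin();
  for (int j = 0; j < nc; ++j) {
    const double* dc = dW + (R_xlen_t)j * nr;
    const double* vc = v + (R_xlen_t)j * nr;
    double* ov = dv + (R_xlen_t)j * nr;
    for (int i = 0; i < nr; ++i) ov[i] = dc[i] * s1[i] - vc[i] * s2[i];
  }
  return List::create(_["v"] = dv_, _["g"] = dg_);
}

// y[o, t] = b[o] + sum_{d=0..2} sum_c W[o, d*C+c] * x[c, t+d-1]  (zero padded)
// [[Rcpp::export]]
NumericMatrix cpp_conv1d_forward(NumericMatrix x_, NumericMatrix W_,
                                 NumericVector b_, const int T, const int B) {
  const arma::mat x = borrow(x_), W = borrow(W_);
  const arma::vec b = borrow(b_);
  const int C = x.n_rows, Co = W.n_rows;
  NumericMatrix out_(Co, T * B);
  arma::mat y(out_.begin(), Co, T * B, false, true);
  y.each_col() = b;
  arma::mat Wd[3];
  for (int d = 0; d < 3; ++d) Wd[d] = W.cols(d * C, (d + 1) * C - 1);
  for (int bb = 0; bb < B; ++bb) {
    const int o = bb * T;
    y.cols(o, o + T - 1) += Wd[1] * x.cols(o, o + T - 1);
    y.cols(o + 1, o + T - 1) += Wd[0] * x.cols(o, o + T - 2);
    y.cols(o, o + T - 2) += Wd[2] * x.cols(o + 1, o + T - 1);
  }
  return out_;
}

// backward of the convolution; returns dW (Co, C*3), db, and optionally dx
// [[Rcpp::export]]
List cpp_conv1d_backward(NumericMatrix x_, NumericMatrix W_, NumericMatrix dy_,
                         const int T, const int B, const bool need_dx,
                         const bool need_dw) {
  const arma::mat x = borrow(x_), W = borrow(W_), dy = borrow(dy_);
  const int C = x.n_rows, Co = W.n_rows;
  arma::vec db = arma::sum(dy, 1);
  NumericMatrix dx_(need_dx ? C : 1, need_dx ? T * B : 1);
  arma::mat dx(dx_.begin(), dx_.nrow(), dx_.ncol(), false, true);
  arma::mat Wd[3];
  for (int d = 0; d < 3; ++d) Wd[d] = W.cols(d * C, (d + 1) * C - 1);
  arma::mat d0(Co, C, arma::fill::zeros), d1(Co, C, arma::fill::zeros),
            d2(Co, C, arma::fill::zeros);
  for (int bb = 0; bb < B; ++bb) {
    const int o = bb * T;
    const arma::mat& xb = x.cols(o, o + T - 1);
    const arma::mat& dyb = dy.cols(o, o + T - 1);
    if (need_dw) {
      d1 += dyb * xb.t();
      d0 += dyb.cols(1, T - 1) * xb.cols(0, T - 2).t();
      d2 += dyb.cols(0, T - 2) * xb.cols(1, T - 1).t();
    }
    if (need_dx) {
      dx.cols(o, o + T - 1) += Wd[1].t() * dyb;
      dx.cols(o, o + T - 2) += Wd[0].t() * dyb.cols(1, T - 1);
      dx.cols(o + 1, o + T - 1) += Wd[2].t() * dyb.cols(0, T - 2);
    }
  }
  NumericMatrix dW_(Co, 3 * C);
  arma::mat dW(dW_.begin(), Co, 3 * C, false, true);
  dW.cols(0, C - 1) = d0;
  dW.cols(C, 2 * C - 1) = d1;
  dW.cols(2 * C, 3 * C - 1) = d2;
  if (need_dx)
    return List::create(_["dW"] = dW_, _["db"] = db, _["dx"] = dx_);
  return List::create(_["dW"] = dW_, _["db"] = db);
}

// fused ReLU + inverted dropout; draws the mask from R's RNG stream so the
// caller's seed fully determines it. The returned mask m already folds the
// ReLU derivative with the dropout keep/scale factor, so the backward pass
// is a single elementwise product.
// [[Rcpp::export]]
List cpp_relu_dropout(NumericMatrix y_, const double p, const bool training) {
  const R_xlen_t n = y_.size();
  const double* y = y_.begin();
  NumericMatrix h_(y_.nrow(), y_.ncol());
  NumericMatrix m_(y_.nrow(), y_.ncol());
  double* h = h_.begin();
  double* m = m_.begin();
  if (training) {
    const double scale = 1.0 / (1.0 - p);
    GetRNGstate();
    for (R_xlen_t i = 0; i < n; ++i) {
      const double keep = (unif_rand() >= p) ? scale : 0.0;
      if (y[i] > 0) { m[i] = keep; h[i] = y[i] * keep; }
      else { m[i] = 0.0; h[i] = 0.0; }
    }
    PutRNGstate();
  } else {
    for (R_xlen_t i = 0; i < n; ++i) {
      if (y[i] > 0) { m[i] = 1.0; h[i] = y[i]; }
      else { m[i] = 0.0; h[i] = 0.0; }
    }
  }
  return List::create(_["h"] = h_, _["m"] = m_);
}

// elementwise product, used to route gradients through ReLU/dropout masks
// [[Rcpp::export]]
NumericMatrix cpp_mask_mult(NumericMatrix a_, NumericMatrix b_) {
  const R_xlen_t n = a_.size();
  NumericMatrix out_(a_.nrow(), a_.ncol());
  const double* a = a_.begin();
  const double* b = b_.begin();
  double* o = out_.begin();
  for (R_xlen_t i = 0; i < n; ++i) o[i] = a[i] * b[i];
  return out_;
}

// fused Adam step with historical-averaging penalty: adds the penalty
// gradient 2*hc*(p - avg), updates the moments and the running average in
// place (they are owned by the optimizer loop), and returns the new
// parameter values. With hc = 0 the penalty and average update are skipped
// unless decay > 0 is still wanted for monitoring (avg untouched when
// decay < 0).
// [[Rcpp::export]]
NumericVector cpp_adam_hist_step(NumericVector p_, NumericVector g_,
                                 NumericVector m_, NumericVector v_,
                                 NumericVector avg_, const int t,
                                 const double lr, const double b1,
                                 const double b2, const double eps,
                                 const double hc, const double decay) {
  const R_xlen_t n = p_.size();
  const double* p = p_.begin();
  const double* g = g_.begin();
  double* m = m_.begin();
  double* v = v_.begin();
  double* avg = avg_.begin();
  NumericVector out_(n);
  double* o = out_.begin();
  out_.attr("dim") = p_.attr("dim");
  const double c1 = 1.0 - std::pow(b1, t);
  const double c2 = 1.0 - std::pow(b2, t);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = (hc > 0) ? g[i] + 2.0 * hc * (p[i] - avg[i]) : g[i];
    m[i] = b1 * m[i] + (1.0 - b1) * gi;
    v[i] = b2 * v[i] + (1.0 - b2) * gi * gi;
    o[i] = p[i] - lr * (m[i] / c1) / (std::sqrt(v[i] / c2) + eps);
    if (decay >= 0) avg[i] = decay * avg[i] + (1.0 - decay) * o[i];
  }
  return out_;
}

// direct-form-II-transposed IIR filter with initial state, a[0] = 1
// [[Rcpp::export]]
NumericVector cpp_iir_filter(NumericVector b_, NumericVector a_,
                             NumericVector x_, NumericVector zi_) {
  const int nb = b_.size(), na = a_.size();
  const int nz = std::max(nb, na) - 1;
  const R_xlen_t n = x_.size();
  std::vector<double> b(nb), a(na), z(nz, 0.0);
  for (int i = 0; i < nb; ++i) b[i] = b_[i];
  for (int i = 0; i < na; ++i) a[i] = a_[i];
  for (int i = 0; i < nz && i < zi_.size(); ++i) z[i] = zi_[i];
  NumericVector y_(n);
  for (R_xlen_t k = 0; k < n; ++k) {
    const double xk = x_[k];
    const double yk = b[0] * xk + z[0];
    for (int i = 0; i < nz - 1; ++i) {
      const double bi = (i + 1 < nb) ? b[i + 1] : 0.0;
      const double ai = (i + 1 < na) ? a[i + 1] : 0.0;
      z[i] = bi * xk + z[i + 1] - ai * yk;
    }
    const double bl = (nz < nb) ? b[nz] : 0.0;
    const double al = (nz < na) ? a[nz] : 0.0;
    z[nz - 1] = bl * xk - al * yk;
    y_[k] = yk;
  }
  return y_;
}
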