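// Hot inner loops of the network engine: im2col/col2im for the 1D
// convolutions along time and the (2,1) max pooling. The matrix products
// themselves stay in R (BLAS).

#include <Rcpp.h>
using namespace Rcpp;

// x: array [cin, tin, bsz]; returns matrix [cin*k, tout*bsz] where column
// (b-1)*tout + t stacks x[, t:(t+k-1), b] slice-by-slice.
// [[Rcpp::export(name = ".im2col_time")]]
NumericMatrix im2col_time(NumericVector x, int k) {
  IntegerVector d = x.attr("dim");
  const int cin = d[0], tin = d[1], bsz = d[2];
  const int tout = tin - k + 1;
  if (tout < 1) stop("kernel longer than input");
  NumericMatrix out(cin * k, tout * bsz);
  const double* px = x.begin();
  double* po = out.begin();
  const int ncol_rows = cin * k;
  for (int b = 0; b < bsz; ++b) {
    const double* xb = px + (R_xlen_t)b * cin * tin;
    for (int t = 0; t < tout; ++t) {
      double* col = po + (R_xlen_t)(b * tout + t) * ncol_rows;
      const double* src = xb + (R_xlen_t)t * cin;
      std::copy(src, src + (R_xlen_t)cin * k, col);
    }
  }
  return out;
}

// inverse scatter-add of im2col_time
// [[Rcpp::export(name = ".col2im_time")]]
NumericVector col2im_time(NumericMatrix dxmat, int cin, int tin, int bsz,
                          int k) {
  const int tout = tin - k + 1;
  NumericVector dx((R_xlen_t)cin * tin * bsz);
  dx.attr("dim") = IntegerVector::create(cin, tin, bsz);
  const double* pm = dxmat.begin();
  double* pd = dx.begin();
  const int ncol_rows = cin * k;
  for (int b = 0; b < bsz; ++b) {
    double* db = pd + (R_xlen_t)b * cin * tin;
    for (int t = 0; t < tout; ++t) {
      const double* col = pm + (R_xlen_t)(b * tout + t) * ncol_rows;
      double* dst = db + (R_xlen_t)t * cin;
      const R_xlen_t n = (R_xlen_t)cin * k;
      for (R_xlen_t i = 0; i < n; ++i) dst[i] += col[i];
    }
  }
  return dx;
}

// (2,1) max pooling along time; returns pooled values and the argmax mask
// [[Rcpp::export(name = ".pool2_fwd")]]
List pool2_fwd(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int c = d[0], tin = d[1], bsz = d[2];
  const int p = tin / 2;
  if (p < 1) stop("time length too short for (2,1) max pooling");
  NumericVector out((R_xlen_t)c * p * bsz);
  LogicalVector first((R_xlen_t)c * p * bsz);
  out.attr("dim") = IntegerVector::create(c, p, bsz);
  first.attr("dim") = IntegerVector::create(c, p, bsz);
  const double* px = x.begin();
  double* po = out.begin();
  int* pf = first.begin();
  for (int b = 0; b < bsz; ++b) {
    const double* xb = px + (R_xlen_t)b * c * tin;
    double* ob = po + (R_xlen_t)b * c * p;
    int* fb = pf + (R_xlen_t)b * c * p;
    for (int t = 0; t < p; ++t) {
      const double* a1 = xb + (R_xlen_t)(2 * t) * c;
      const double* a2 = a1 + c;
      double* o = ob + (R_xlen_t)t * c;
      int* f = fb + (R_xlen_t)t * c;
      for (int i = 0; i < c; ++i) {
        if (a1[i] >= a2[i]) { o[i] = a1[i]; f[i] = 1; }
        else { o[i] = a2[i]; f[i] = 0; }
      }
    }
  }
  return List::create(_["out"] = out, _["take_first"] = first);
}

// [[Rcpp::export(name = ".pool2_bwd")]]
NumericVector pool2_bwd(NumericVector dy, LogicalVector first, int tin) {
  IntegerVector d = dy.attr("dim");
  const int c = d[0], p = d[1], bsz = d[2];
  NumericVector dx((R_xlen_t)c * tin * bsz);
  dx.attr("dim") = IntegerVector::create(c, tin, bsz);
  const double* pdy = dy.begin();
  const int* pf = first.begin();
  double* pdx = dx.begin();
  for (int b = 0; b < bsz; ++b) {
    const double* yb = pdy + (R_xlen_t)b * c * p;
    const int* fb = pf + (R_xlen_t)b * c * p;
    double* xb = pdx + (R_xlen_t)b * c * tin;
    for (int t = 0; t < p; ++t) {
      const double* y = yb + (R_xlen_t)t * c;
      const int* f = fb + (R_xlen_t)t * c;
      double* x1 = xb + (R_xlen_t)(2 * t) * c;
      double* x2 = x1 + c;
      for (int i = 0; i < c; ++i) {
        if (f[i]) x1[i] += y[i]; else x2[i] += y[i];
      }
    }
  }
  return dx;
}

// batch-norm + ReLU fused forward over a [c, m] matrix view (m = time*batch).
// In training mode returns batch statistics for the state update.
// [[Rcpp::export(name = ".bnrelu_fwd")]]
List bnrelu_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                NumericVector mean_in, NumericVector var_in, bool training,
                double eps) {
  IntegerVector d = x.attr("dim");
  const int c = d[0];
  const R_xlen_t m = x.size() / c;
  NumericVector mu(c), var(c);
  const double* px = x.begin();
  if (training) {
    for (R_xlen_t j = 0; j < m; ++j) {
      const double* col = px + j * c;
      for (int i = 0; i < c; ++i) mu[i] += col[i];
    }
    for (int i = 0; i < c; ++i) mu[i] /= (double)m;
    for (R_xlen_t j = 0; j < m; ++j) {
      const double* col = px + j * c;
      for (int i = 0; i < c; ++i) {
        const double dvi = col[i] - mu[i];
        var[i] += dvi * dvi;
      }
    }
    for (int i = 0; i < c; ++i) var[i] /= (double)m;
  } else {
    mu = clone(mean_in);
    var = clone(var_in);
  }
  NumericVector inv_sd(c);
  for (int i = 0; i < c; ++i) inv_sd[i] = 1.0 / std::sqrt(var[i] + eps);
  NumericVector out(x.size()), xhat(x.size());
  LogicalVector mask(x.size());
  out.attr("dim") = d;
  double* po = out.begin();
  double* ph = xhat.begin();
  int* pm = mask.begin();
  for (R_xlen_t j = 0; j < m; ++j) {
    const double* col = px + j * c;
    double* o = po + j * c;
    double* h = ph + j * c;
    int* mk = pm + j * c;
    for (int i = 0; i < c; ++i) {
      const double xh = (col[i] - mu[i]) * inv_sd[i];
      h[i] = xh;
      const double y = gamma[i] * xh + beta[i];
      if (y > 0) { o[i] = y; mk[i] = 1; } else { o[i] = 0.0; mk[i] = 0; }
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["inv_sd"] = inv_sd,
                      _["mask"] = mask, _["batch_mean"] = mu,
                      _["batch_var"] = var);
}

// fused ReLU + batch-norm backward; dy has the activation's dims
// [[Rcpp::export(name = ".bnrelu_bwd")]]
List bnrelu_bwd(NumericVector dy, LogicalVector mask, NumericVector xhat,
                NumericVector inv_sd, NumericVector gamma) {
  IntegerVector d = dy.attr("dim");
  const int c = d[0];
  const R_xlen_t m = dy.size() / c;
  NumericVector dgamma(c), dbeta(c);
  const double* py = dy.begin();
  const int* pm = mask.begin();
  const double* ph = xhat.begin();
  // first pass: per-channel sums of dxhat-contributions
  for (R_xlen_t j = 0; j < m; ++j) {
    const double* y = py + j * c;
    const int* mk = pm + j * c;
    const double* h = ph + j * c;
    for (int i = 0; i < c; ++i) {
      if (mk[i]) {
        dgamma[i] += y[i] * h[i];
        dbeta[i] += y[i];
      }
    }
  }
  NumericVector dx(dy.size());
  dx.attr("dim") = d;
  double* pdx = dx.begin();
  NumericVector s1(c), s2(c);
  for (int i = 0; i < c; ++i) {
    s1[i] = gamma[i] * dbeta[i] / (double)m;   // mean of dxhat
    s2[i] = gamma[i] * dgamma[i] / (double)m;  // mean of dxhat*xhat
  }
  for (R_xlen_t j = 0; j < m; ++j) {
    const double* y = py + j * c;
    const int* mk = pm + j * c;
    const double* h = ph + j * c;
    double* o = pdx + j * c;
    for (int i = 0; i < c; ++i) {
      const double dxh = mk[i] ? gamma[i] * y[i] : 0.0;
      o[i] = inv_sd[i] * (dxh - s1[i] - h[i] * s2[i]);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// fused Adam update; returns fresh vectors so earlier snapshots stay valid
// [[Rcpp::export(name = ".adam_update")]]
List adam_update(NumericVector p, NumericVector g, NumericVector m,
                 NumericVector v, double lr, double b1, double b2, double eps,
                 double bc1, double bc2) {
  const R_xlen_t n = p.size();
  NumericVector p2(n), m2(n), v2(n);
  if (!Rf_isNull(p.attr("dim"))) p2.attr("dim") = p.attr("dim");
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = g[i];
    const double mi = b1 * m[i] + (1 - b1) * gi;
    const double vi = b2 * v[i] + (1 - b2) * gi * gi;
    m2[i] = mi;
    v2[i] = vi;
    p2[i] = p[i] - lr * (mi / bc1) / (std::sqrt(vi / bc2) + eps);
  }
  return List::create(_["p"] = p2, _["m"] = m2, _["v"] = v2);
}
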