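// Compiled inner loops of the CNN-TCN layers. Feature maps are numeric
// arrays of dim (C, T, B): channels fastest, then time, then batch —
// x[c + C*(t + T*b)]. The convolutions are expressed as im2col gathers plus
// one BLAS matmul (via Armadillo); pooling, activations and batch
// normalization are plain loops.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static IntegerVector dims3(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("expected a 3-d array");
  return d;
}

// ---- standard 1-D convolution ("same"-style padding given explicitly) ----

// [[Rcpp::export]]
List conv1d_fw_cpp(NumericVector x, NumericMatrix Wmat, Nullable<NumericVector> bias,
                   int k, int pad_l) {
  IntegerVector d = dims3(x);
  const int C = d[0], T = d[1], B = d[2];
  const int c_out = Wmat.nrow();
  if (Wmat.ncol() != C * k) stop("weight matrix must be c_out x (c_in*k)");
  arma::mat xcol(C * k, (size_t)T * B, arma::fill::zeros);
  const double* xp = x.begin();
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < T; ++t) {
      double* col = xcol.colptr((size_t)b * T + t);
      for (int j = 0; j < k; ++j) {
        int ti = t + j - pad_l;
        if (ti < 0 || ti >= T) continue;
        const double* src = xp + (size_t)C * (ti + (size_t)T * b);
        double* dst = col + (size_t)C * j;
        for (int c = 0; c < C; ++c) dst[c] = src[c];
      }
    }
  }
  arma::mat W(Wmat.begin(), c_out, C * k, false, true);
  arma::mat ymat = W * xcol;
  if (bias.isNotNull()) {
    NumericVector bv(bias);
    arma::vec b(bv.begin(), c_out, false, true);
    ymat.each_col() += b;
  }
  NumericVector y(ymat.begin(), ymat.end());
  y.attr("dim") = IntegerVector::create(c_out, T, B);
  NumericVector xc(xcol.begin(), xcol.end());
  xc.attr("dim") = IntegerVector::create(C * k, T * B);
  return List::create(_["y"] = y, _["xcol"] = xc);
}

// [[Rcpp::export]]
List conv1d_bw_cpp(NumericMatrix xcol, NumericMatrix Wmat, NumericVector dy,
                   int c_in, int k, int pad_l, bool has_bias) {
  IntegerVector d = dims3(dy);
  const int c_out = d[0], T = d[1], B = d[2];
  arma::mat dymat(dy.begin(), c_out, (size_t)T * B, false, true);
  arma::mat xc(xcol.begin(), xcol.nrow(), xcol.ncol(), false, true);
  arma::mat W(Wmat.begin(), c_out, c_in * k, false, true);
  arma::mat dW = dymat * xc.t();
  arma::mat dxcol = W.t() * dymat;
  NumericVector dx(Dimension(c_in, T, B));
  double* dxp = dx.begin();
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < T; ++t) {
      const double* col = dxcol.colptr((size_t)b * T + t);
      for (int j = 0; j < k; ++j) {
        int ti = t + j - pad_l;
        if (ti < 0 || ti >= T) continue;
        double* dst = dxp + (size_t)c_in * (ti + (size_t)T * b);
        const double* src = col + (size_t)c_in * j;
        for (int c = 0; c < c_in; ++c) dst[c] += src[c];
      }
    }
  }
  NumericMatrix dWr(c_out, c_in * k, dW.begin());
  List out = List::create(_["dx"] = dx, _["dW"] = dWr);
  if (has_bias) {
    arma::vec db = arma::sum(dymat, 1);
    out["db"] = NumericVector(db.begin(), db.end());
  }
  return out;
}

// ---- depthwise-pointwise dilated causal convolution ----

// [[Rcpp::export]]
List dwpw_fw_cpp(NumericVector x, NumericMatrix Wd, NumericMatrix Wp, int dil) {
  IntegerVector d = dims3(x);
  const int C = d[0], T = d[1], B = d[2];
  const int k = Wd.ncol();
  const int c_out = Wp.nrow();
  if (Wd.nrow() != C || Wp.ncol() != C) stop("weight shapes do not match input");
  arma::mat zmat(C, (size_t)T * B, arma::fill::zeros);
  const double* xp = x.begin();
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < T; ++t) {
      double* zc = zmat.colptr((size_t)b * T + t);
      for (int j = 0; j < k; ++j) {
        int ti = t - j * dil;                 // causal: reach into the past only
        if (ti < 0) break;
        const double* src = xp + (size_t)C * (ti + (size_t)T * b);
        for (int c = 0; c < C; ++c) zc[c] += src[c] * Wd(c, j);
      }
    }
  }
  arma::mat Wpm(Wp.begin(), c_out, C, false, true);
  arma::mat ymat = Wpm * zmat;
  NumericVector y(ymat.begin(), ymat.end());
  y.attr("dim") = IntegerVector::create(c_out, T, B);
  NumericVector z(zmat.begin(), zmat.end());
  z.attr("dim") = IntegerVector::create(C, T, B);
  return List::create(_["y"] = y, _["z"] = z);
}

// [[Rcpp::export]]
List dwpw_bw_cpp(NumericVector x, NumericVector z, NumericMatrix Wd,
                 NumericMatrix Wp, int dil, NumericVector dy) {
  IntegerVector d = dims3(x);
  const int C = d[0], T = d[1], B = d[2];
  const int k = Wd.ncol();
  const int c_out = Wp.nrow();
  arma::mat dymat(dy.begin(), c_out, (size_t)T * B, false, true);
  arma::mat zmat(z.begin(), C, (size_t)T * B, false, true);
  arma::mat Wpm(Wp.begin(), c_out, C, false, true);
  arma::mat dWp = dymat * zmat.t();
  arma::mat dz = Wpm.t() * dymat;            // C x (T*B)
  NumericVector dx(Dimension(C, T, B));
  NumericMatrix dWd(C, k);
  double* dxp = dx.begin();
  const double* xp = x.begin();
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < T; ++t) {
      const double* dzc = dz.colptr((size_t)b * T + t);
      for (int j = 0; j < k; ++j) {
        int ti = t - j * dil;
        if (ti < 0) break;
        double* dst = dxp + (size_t)C * (ti + (size_t)T * b);
        const double* src = xp + (size_t)C * (ti + (size_t)T * b);
        for (int c = 0; c < C; ++c) {
          dst[c] += dzc[c] * Wd(c, j);
          dWd(c, j) += dzc[c] * src[c];
        }
      }
    }
  }
  NumericMatrix dWpr(c_out, C, dWp.begin());
  return List::create(_["dx"] = dx, _["dWd"] = dWd, _["dWp"] = dWpr);
}

// ---- max pooling ----

// [[Rcpp::export]]
List maxpool_fw_cpp(NumericVector x, int k, int stride, int pad) {
  IntegerVector d = dims3(x);
  const int C = d[0], T = d[1], B = d[2];
  const int To = (T + 2 * pad - k) / stride + 1;
  NumericVector y(Dimension(C, To, B));
  IntegerVector src(Dimension(C, To, B));   // winning source time index
  const double* xp = x.begin();
  double* yp = y.begin();
  int* sp = src.begin();
  for (int b = 0; b < B; ++b) {
    for (int to = 0; to < To; ++to) {
      int t0 = to * stride - pad;
      double* yc = yp + (size_t)C * (to + (size_t)To * b);
      int* sc = sp + (size_t)C * (to + (size_t)To * b);
      for (int c = 0; c < C; ++c) { yc[c] = R_NegInf; sc[c] = -1; }
      for (int j = 0; j < k; ++j) {
        int ti = t0 + j;
        if (ti < 0 || ti >= T) continue;
        const double* xc = xp + (size_t)C * (ti + (size_t)T * b);
        for (int c = 0; c < C; ++c) {
          if (xc[c] > yc[c]) { yc[c] = xc[c]; sc[c] = ti; }
        }
      }
    }
  }
  return List::create(_["y"] = y, _["src"] = src);
}

// [[Rcpp::export]]
NumericVector maxpool_bw_cpp(IntegerVector src, NumericVector dy, int T) {
  IntegerVector d = dims3(dy);
  const int C = d[0], To = d[1], B = d[2];
  NumericVector dx(Dimension(C, T, B));
  double* dxp = dx.begin();
  const double* dyp = dy.begin();
  const int* sp = src.begin();
  for (int b = 0; b < B; ++b) {
    for (int to = 0; to < To; ++to) {
      const double* dc = dyp + (size_t)C * (to + (size_t)To * b);
      const int* sc = sp + (size_t)C * (to + (size_t)To * b);
      for (int c = 0; c < C; ++c) {
        if (sc[c] >= 0) dxp[c + (size_t)C * (sc[c] + (size_t)T * b)] += dc[c];
      }
    }
  }
  return dx;
}

// ---- activations ----

// [[Rcpp::export]]
NumericVector elu_fw_cpp(NumericVector x) {
  NumericVector y = clone(x);
  for (double& v : y) if (v < 0) v = std::exp(v) - 1;
  return y;
}

// [[Rcpp::export]]
NumericVector elu_bw_cpp(NumericVector y, NumericVector dy) {
  NumericVector dx = clone(dy);
  for (R_xlen_t i = 0; i < y.size(); ++i) {
    if (y[i] < 0) dx[i] = dy[i] * (y[i] + 1);
  }
  return dx;
}

// [[Rcpp::export]]
NumericVector relu_fw_cpp(NumericVector x) {
  NumericVector y = clone(x);
  for (double& v : y) if (v < 0) v = 0;
  return y;
}

// [[Rcpp::export]]
NumericVector relu_bw_cpp(NumericVector x, NumericVector dy) {
  NumericVector dx = clone(dy);
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    if (x[i] <= 0) dx[i] = 0;
  }
  return dx;
}

// ---- batch normalization over (time, batch) per channel ----

// [[Rcpp::export]]
List bn_fw_cpp(NumericVector x, NumericVector gamma, NumericVector beta,
               double eps) {
  IntegerVector d = dims3(x);
  const int C = d[0];
  const R_xlen_t n = (R_xlen_t)d[1] * d[2];
  std::vector<double> mu(C, 0.0), v(C, 0.0);
  const double* xp = x.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double* col = xp + (size_t)C * i;
    for (int c = 0; c < C; ++c) mu[c] += col[c];
  }
  for (int c = 0; c < C; ++c) mu[c] /= n;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double* col = xp + (size_t)C * i;
    for (int c = 0; c < C; ++c) {
      double e = col[c] - mu[c];
      v[c] += e * e;
    }
  }
  for (int c = 0; c < C; ++c) v[c] /= n;
  NumericVector xhat(Dimension(C, d[1], d[2])), y(Dimension(C, d[1], d[2]));
  NumericVector invstd(C), mean(C), var(C);
  for (int c = 0; c < C; ++c) {
    invstd[c] = 1.0 / std::sqrt(v[c] + eps);
    mean[c] = mu[c];
    var[c] = v[c];
  }
  double* hp = xhat.begin();
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double* col = xp + (size_t)C * i;
    double* hc = hp + (size_t)C * i;
    double* yc = yp + (size_t)C * i;
    for (int c = 0; c < C; ++c) {
      hc[c] = (col[c] - mu[c]) * invstd[c];
      yc[c] = hc[c] * gamma[c] + beta[c];
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["invstd"] = invstd,
                      _["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export]]
List bn_bw_cpp(NumericVector xhat, NumericVector invstd, NumericVector gamma,
               NumericVector dy) {
  IntegerVector d = dims3(dy);
  const int C = d[0];
  const R_xlen_t n = (R_xlen_t)d[1] * d[2];
  std::vector<double> s1(C, 0.0), s2(C, 0.0);   // sums of dxhat and dxhat*xhat
  NumericVector dgamma(C), dbeta(C);
  const double* hp = xhat.begin();
  const double* dp = dy.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double* hc = hp + (size_t)C * i;
    const double* dc = dp + (size_t)C * i;
    for (int c = 0; c < C; ++c) {
      dgamma[c] += dc[c] * hc[c];
      dbeta[c] += dc[c];
      double dxh = dc[c] * gamma[c];
      s1[c] += dxh;
      s2[c] += dxh * hc[c];
    }
  }
  NumericVector dx(Dimension(C, d[1], d[2]));
  double* op = dx.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double* hc = hp + (size_t)C * i;
    const double* dc = dp + (size_t)C * i;
    double* oc = op + (size_t)C * i;
    for (int c = 0; c < C; ++c) {
      double dxh = dc[c] * gamma[c];
      oc[c] = (dxh - s1[c] / n - hc[c] * s2[c] / n) * invstd[c];
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// ---- dropout (mask generated with a fast generator seeded from R's RNG) ----

// [[Rcpp::export]]
List dropout_fw_cpp(NumericVector x, double p) {
  NumericVector y(x.size());
  NumericVector mask(x.size());
  const double scale = 1.0 / (1.0 - p);
  // xorshift64* stream seeded from R's RNG keeps runs reproducible under set.seed
  uint64_t s = (uint64_t)(unif_rand() * 9007199254740992.0) | 1ull;
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    double u = (double)((s * 2685821657736338717ull) >> 11) / 9007199254740992.0;
    double m = (u >= p) ? scale : 0.0;
    mask[i] = m;
    y[i] = x[i] * m;
  }
  y.attr("dim") = x.attr("dim");
  return List::create(_["y"] = y, _["mask"] = mask);
}

// [[Rcpp::export]]
NumericVector dropout_bw_cpp(NumericVector mask, NumericVector dy) {
  NumericVector dx(dy.size());
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[i] = dy[i] * mask[i];
  dx.attr("dim") = dy.attr("dim");
  return dx;
}

// ---- Adam/AMSGrad parameter update (in place) ----

// [[Rcpp::export]]
void adam_update_cpp(NumericVector w, NumericVector g, NumericVector m,
                     NumericVector v, NumericVector h, double lr, double wd,
                     double beta1, double beta2, double eps, int t, bool amsgrad) {
  const double bc1 = 1.0 - std::pow(beta1, t);
  const double bc2 = 1.0 - std::pow(beta2, t);
  for (R_xlen_t i = 0; i < w.size(); ++i) {
    double gi = g[i] + wd * w[i];
    m[i] = beta1 * m[i] + (1 - beta1) * gi;
    v[i] = beta2 * v[i] + (1 - beta2) * gi * gi;
    double vv = v[i];
    if (amsgrad) {
      if (vv > h[i]) h[i] = vv;
      vv = h[i];
    }
    w[i] -= lr * (m[i] / bc1) / (std::sqrt(vv / bc2) + eps);
  }
}
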