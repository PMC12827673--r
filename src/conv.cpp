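// Compiled kernels for the temporal convolutions -- the only hot spots of the
// network. Layout matches R arrays: column-major cubes (C, L, M) with the
// channel axis fastest. "Same" padding: floor(k/2) left, k-1-floor(k/2) right.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static cube pad_time(const cube& x, int k) {
  int pl = k / 2;
  cube xp(x.n_rows, x.n_cols + k - 1, x.n_slices, fill::zeros);
  xp.cols(pl, pl + x.n_cols - 1) = x;
  return xp;
}

// x: (Cin, L, M); W: (Cout, Cin, k) cube; b: length Cout (may be empty)
// [[Rcpp::export]]
arma::cube conv_time_fwd_cpp(const arma::cube& x, const arma::cube& W,
                             const arma::vec& b) {
  const int Cin = x.n_rows, L = x.n_cols, M = x.n_slices;
  const int Cout = W.n_rows, k = W.n_slices;
  cube xp = pad_time(x, k);
  cube y(Cout, L, M, fill::zeros);
  for (int m = 0; m < M; ++m) {
    mat ym(Cout, L, fill::zeros);
    const mat& xm = xp.slice(m);
    for (int j = 0; j < k; ++j)
      ym += W.slice(j) * xm.cols(j, j + L - 1);
    if (b.n_elem == (unsigned)Cout) ym.each_col() += b;
    y.slice(m) = ym;
  }
  (void)Cin;
  return y;
}

// [[Rcpp::export]]
Rcpp::List conv_time_bwd_cpp(const arma::cube& dy, const arma::cube& x,
                             const arma::cube& W) {
  const int Cin = x.n_rows, L = x.n_cols, M = x.n_slices;
  const int Cout = W.n_rows, k = W.n_slices;
  const int pl = k / 2;
  cube xp = pad_time(x, k);
  cube dW(Cout, Cin, k, fill::zeros);
  cube dxp(Cin, L + k - 1, M, fill::zeros);
  vec db(Cout, fill::zeros);
  for (int m = 0; m < M; ++m) {
    const mat& dym = dy.slice(m);
    const mat& xm = xp.slice(m);
    mat& dxm = dxp.slice(m);
    for (int j = 0; j < k; ++j) {
      dW.slice(j) += dym * xm.cols(j, j + L - 1).t();
      dxm.cols(j, j + L - 1) += W.slice(j).t() * dym;
    }
    db += sum(dym, 1);
  }
  cube dx = dxp.cols(pl, pl + L - 1);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// depthwise: x (C, L, M); W (C, k) matrix
// [[Rcpp::export]]
arma::cube conv_dw_fwd_cpp(const arma::cube& x, const arma::mat& W,
                           const arma::vec& b) {
  const int C = x.n_rows, L = x.n_cols, M = x.n_slices;
  const int k = W.n_cols;
  cube xp = pad_time(x, k);
  cube y(C, L, M, fill::zeros);
  for (int m = 0; m < M; ++m) {
    const mat& xm = xp.slice(m);
    mat ym(C, L, fill::zeros);
    for (int j = 0; j < k; ++j)
      ym += diagmat(W.col(j)) * xm.cols(j, j + L - 1);
    if (b.n_elem == (unsigned)C) ym.each_col() += b;
    y.slice(m) = ym;
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List conv_dw_bwd_cpp(const arma::cube& dy, const arma::cube& x,
                           const arma::mat& W) {
  const int C = x.n_rows, L = x.n_cols, M = x.n_slices;
  const int k = W.n_cols;
  const int pl = k / 2;
  cube xp = pad_time(x, k);
  mat dW(C, k, fill::zeros);
  cube dxp(C, L + k - 1, M, fill::zeros);
  vec db(C, fill::zeros);
  for (int m = 0; m < M; ++m) {
    const mat& dym = dy.slice(m);
    const mat& xm = xp.slice(m);
    mat& dxm = dxp.slice(m);
    for (int j = 0; j < k; ++j) {
      dW.col(j) += sum(dym % xm.cols(j, j + L - 1), 1);
      dxm.cols(j, j + L - 1) += diagmat(W.col(j)) * dym;
    }
    db += sum(dym, 1);
  }
  cube dx = dxp.cols(pl, pl + L - 1);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// ---- elementwise / normalization kernels ----------------------------------

// [[Rcpp::export]]
arma::cube elu_fwd_cpp(const arma::cube& x) {
  cube y = x;
  for (uword i = 0; i < y.n_elem; ++i)
    if (y[i] < 0) y[i] = std::expm1(y[i]);
  return y;
}

// derivative recovered from the output: slope 1 where y >= 0, y + 1 below
// [[Rcpp::export]]
arma::cube elu_bwd_cpp(const arma::cube& dy, const arma::cube& y) {
  cube dx = dy;
  for (uword i = 0; i < dx.n_elem; ++i)
    if (y[i] < 0) dx[i] = dy[i] * (y[i] + 1.0);
  return dx;
}

// batch norm over all non-channel elements of a (C, L, M) cube
// [[Rcpp::export]]
Rcpp::List bn_fwd_cpp(const arma::cube& x, const arma::vec& gamma,
                      const arma::vec& beta, const arma::vec& rmean,
                      const arma::vec& rvar, const bool training,
                      const double eps) {
  const uword C = x.n_rows;
  const uword M = x.n_cols * x.n_slices;
  const mat X(const_cast<double*>(x.memptr()), C, M, false, true);
  vec mu, v;
  if (training) {
    mu = mean(X, 1);
    mat xc = X.each_col() - mu;
    v = mean(xc % xc, 1);
  } else {
    mu = rmean;
    v = rvar;
  }
  vec istd = 1.0 / sqrt(v + eps);
  cube xhat(x.n_rows, x.n_cols, x.n_slices);
  mat XH(xhat.memptr(), C, M, false, true);
  XH = (X.each_col() - mu).each_col() % istd;
  cube y(x.n_rows, x.n_cols, x.n_slices);
  mat Y(y.memptr(), C, M, false, true);
  Y = (XH.each_col() % gamma).each_col() + beta;
  return Rcpp::List::create(
      Rcpp::Named("y") = y, Rcpp::Named("xhat") = xhat,
      Rcpp::Named("istd") = istd, Rcpp::Named("mu") = mu,
      Rcpp::Named("var") = v);
}

// [[Rcpp::export]]
Rcpp::List bn_bwd_cpp(const arma::cube& dy, const arma::cube& xhat,
                      const arma::vec& istd, const arma::vec& gamma,
                      const bool training) {
  const uword C = dy.n_rows;
  const uword M = dy.n_cols * dy.n_slices;
  const mat DY(const_cast<double*>(dy.memptr()), C, M, false, true);
  const mat XH(const_cast<double*>(xhat.memptr()), C, M, false, true);
  vec dgamma = sum(DY % XH, 1);
  vec dbeta = sum(DY, 1);
  cube dx(dy.n_rows, dy.n_cols, dy.n_slices);
  mat DX(dx.memptr(), C, M, false, true);
  mat dxhat = DY.each_col() % gamma;
  if (training) {
    vec m1 = mean(dxhat, 1);
    vec m2 = mean(dxhat % XH, 1);
    DX = dxhat - (XH.each_col() % m2);
    DX.each_col() -= m1;
    DX.each_col() %= istd;
  } else {
    DX = dxhat.each_col() % istd;
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}

// average pooling along the length axis: (C, L, M) -> (C, L/p, M)
// [[Rcpp::export]]
arma::cube avgpool_fwd_cpp(const arma::cube& x, const int p) {
  const int C = x.n_rows, L = x.n_cols, M = x.n_slices;
  const int Lout = L / p;
  cube y(C, Lout, M, fill::zeros);
  for (int m = 0; m < M; ++m)
    for (int l = 0; l < Lout; ++l) {
      for (int j = 0; j < p; ++j) y.slice(m).col(l) += x.slice(m).col(l * p + j);
      y.slice(m).col(l) /= p;
    }
  return y;
}

// [[Rcpp::export]]
arma::cube avgpool_bwd_cpp(const arma::cube& dy, const int p, const int L) {
  const int C = dy.n_rows, Lout = dy.n_cols, M = dy.n_slices;
  cube dx(C, L, M, fill::zeros);
  for (int m = 0; m < M; ++m)
    for (int l = 0; l < Lout; ++l)
      for (int j = 0; j < p; ++j)
        dx.slice(m).col(l * p + j) = dy.slice(m).col(l) / p;
  return dx;
}

// ---- fused batch-norm + ELU ------------------------------------------------
// Every normalization in the network is immediately followed by an ELU, so
// the pair is fused into single two-pass kernels to minimize memory traffic.

// [[Rcpp::export]]
Rcpp::List bn_elu_fwd_cpp(const arma::cube& x, const arma::vec& gamma,
                          const arma::vec& beta, const arma::vec& rmean,
                          const arma::vec& rvar, const bool training,
                          const double eps) {
  const uword C = x.n_rows;
  const uword n = x.n_cols * x.n_slices;
  const double* xd = x.memptr();
  vec mu(C), v(C);
  if (training) {
    vec s(C, fill::zeros), ss(C, fill::zeros);
    for (uword t = 0; t < n; ++t) {
      const double* col = xd + t * C;
      for (uword c = 0; c < C; ++c) { s[c] += col[c]; ss[c] += col[c] * col[c]; }
    }
    mu = s / n;
    v = ss / n - mu % mu;
    v.transform([](double a) { return a < 0 ? 0 : a; });
  } else {
    mu = rmean;
    v = rvar;
  }
  vec istd = 1.0 / sqrt(v + eps);
  cube y(x.n_rows, x.n_cols, x.n_slices), xhat(x.n_rows, x.n_cols, x.n_slices);
  double* yd = y.memptr();
  double* xh = xhat.memptr();
  for (uword t = 0; t < n; ++t) {
    const double* col = xd + t * C;
    double* ycol = yd + t * C;
    double* hcol = xh + t * C;
    for (uword c = 0; c < C; ++c) {
      const double h = (col[c] - mu[c]) * istd[c];
      hcol[c] = h;
      const double a = gamma[c] * h + beta[c];
      ycol[c] = a < 0 ? std::expm1(a) : a;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("y") = y, Rcpp::Named("xhat") = xhat,
      Rcpp::Named("istd") = istd, Rcpp::Named("mu") = mu,
      Rcpp::Named("var") = v);
}

// [[Rcpp::export]]
Rcpp::List bn_elu_bwd_cpp(const arma::cube& dy, const arma::cube& y,
                          const arma::cube& xhat, const arma::vec& istd,
                          const arma::vec& gamma, const bool training) {
  const uword C = dy.n_rows;
  const uword n = dy.n_cols * dy.n_slices;
  const double* dyd = dy.memptr();
  const double* yd = y.memptr();
  const double* xh = xhat.memptr();
  cube dx(dy.n_rows, dy.n_cols, dy.n_slices);
  double* dxd = dx.memptr();
  vec dgamma(C, fill::zeros), dbeta(C, fill::zeros);
  vec m1(C, fill::zeros), m2(C, fill::zeros);
  for (uword t = 0; t < n; ++t) {
    const double* dcol = dyd + t * C;
    const double* ycol = yd + t * C;
    const double* hcol = xh + t * C;
    double* xcol = dxd + t * C;
    for (uword c = 0; c < C; ++c) {
      const double d = ycol[c] < 0 ? dcol[c] * (ycol[c] + 1.0) : dcol[c];
      xcol[c] = d;                       // stash pre-BN gradient
      dgamma[c] += d * hcol[c];
      dbeta[c] += d;
      const double dh = d * gamma[c];
      m1[c] += dh;
      m2[c] += dh * hcol[c];
    }
  }
  if (training) {
    m1 /= n; m2 /= n;
    for (uword t = 0; t < n; ++t) {
      const double* hcol = xh + t * C;
      double* xcol = dxd + t * C;
      for (uword c = 0; c < C; ++c)
        xcol[c] = istd[c] * (xcol[c] * gamma[c] - m1[c] - hcol[c] * m2[c]);
    }
  } else {
    for (uword t = 0; t < n; ++t) {
      double* xcol = dxd + t * C;
      for (uword c = 0; c < C; ++c) xcol[c] = istd[c] * xcol[c] * gamma[c];
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}
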