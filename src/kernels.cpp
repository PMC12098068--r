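// Compute kernels for the TCN / LSTM branches.
//
// Conventions: a batch of multichannel series is an arma::cube with
// dimensions (channels x timesteps x batch); its memory is contiguous, so
// it doubles as a (channels x timesteps*batch) matrix whose column s*T + t
// holds timestep t of batch item s.  Convolution weights are a cube
// (out_channels x in_channels x kernel_size); tap k reads the input
// k * dilation samples in the past (tap 0 is the current sample), which
// together with implicit left zero-padding makes the operation causal and
// length-preserving.  Activation codes: 0 identity, 1 ReLU, 2 tanh.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LN_EPS = 1e-5;

static inline mat act_fwd(const mat& x, const int act) {
  if (act == 1) return clamp(x, 0.0, datum::inf);
  if (act == 2) return tanh(x);
  return x;
}

static inline mat act_grad(const mat& pre, const int act) {
  if (act == 1) return conv_to<mat>::from(pre > 0.0);
  if (act == 2) { mat t = tanh(pre); return 1.0 - t % t; }
  return mat(size(pre), fill::ones);
}

static inline mat flat_view(const cube& X) {
  return mat(const_cast<double*>(X.memptr()), X.n_rows,
             X.n_cols * X.n_slices, false, true);
}

// y[co, t, s] = b[co] + sum_k sum_ci W[co, ci, k] * x[ci, t - k*d, s]
// [[Rcpp::export]]
arma::cube conv_causal_fwd_cpp(const arma::cube& X, const arma::cube& W,
                               const arma::vec& b, const int dilation) {
  const uword T = X.n_cols, B = X.n_slices;
  const uword Cout = W.n_rows, K = W.n_slices;
  cube Y(Cout, T, B);
  for (uword s = 0; s < B; ++s) {
    mat Ys(Cout, T);
    Ys.each_col() = b;
    for (uword k = 0; k < K; ++k) {
      const uword off = k * static_cast<uword>(dilation);
      if (off >= T) continue;
      Ys.cols(off, T - 1) += W.slice(k) * X.slice(s).cols(0, T - 1 - off);
    }
    Y.slice(s) = Ys;
  }
  return Y;
}

// Gradients of the causal convolution w.r.t. input, weights and bias,
// given the upstream gradient dY (same shape as the forward output).
// [[Rcpp::export]]
Rcpp::List conv_causal_bwd_cpp(const arma::cube& X, const arma::cube& W,
                               const arma::cube& dY, const int dilation) {
  const uword T = X.n_cols, B = X.n_slices;
  const uword Cout = W.n_rows, K = W.n_slices;
  cube dX(size(X), fill::zeros);
  cube dW(size(W), fill::zeros);
  vec db(Cout, fill::zeros);
  for (uword s = 0; s < B; ++s) {
    db += sum(dY.slice(s), 1);
    for (uword k = 0; k < K; ++k) {
      const uword off = k * static_cast<uword>(dilation);
      if (off >= T) continue;
      const mat dYk = dY.slice(s).cols(off, T - 1);
      dW.slice(k) += dYk * X.slice(s).cols(0, T - 1 - off).t();
      dX.slice(s).cols(0, T - 1 - off) += W.slice(k).t() * dYk;
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// One full TCN block: channel-wise layer normalization (optional),
// causal dilated convolution, activation, channel dropout (mask supplied
// by the caller, empty when inactive) and residual addition (identity or
// 1x1 projection P).  Returns the output plus the caches the backward
// pass needs.
// [[Rcpp::export]]
Rcpp::List tcn_block_fwd_cpp(const arma::cube& X, const arma::cube& W,
                             const arma::vec& b, const arma::mat& P,
                             const int dilation, const int act,
                             const bool use_ln, const arma::mat& mask) {
  const uword C = X.n_rows, T = X.n_cols, B = X.n_slices;
  const uword Cout = W.n_rows, K = W.n_slices;
  const bool has_p = P.n_elem > 0;
  const bool has_mask = mask.n_elem > 0;
  cube Xn(C, T, B), pre(Cout, T, B), out(Cout, T, B);
  mat sdv(T, B);
  for (uword s = 0; s < B; ++s) {
    if (use_ln) {
      const rowvec mu = mean(X.slice(s), 0);
      mat Xc = X.slice(s);
      Xc.each_row() -= mu;
      const rowvec sd = sqrt(mean(Xc % Xc, 0) + LN_EPS);
      Xc.each_row() /= sd;
      Xn.slice(s) = Xc;
      sdv.col(s) = sd.t();
    } else {
      Xn.slice(s) = X.slice(s);
    }
    mat Ys(Cout, T);
    Ys.each_col() = b;
    for (uword k = 0; k < K; ++k) {
      const uword off = k * static_cast<uword>(dilation);
      if (off >= T) continue;
      Ys.cols(off, T - 1) += W.slice(k) * Xn.slice(s).cols(0, T - 1 - off);
    }
    pre.slice(s) = Ys;
    mat a = act_fwd(Ys, act);
    if (has_mask) a.each_col() %= mask.col(s);
    if (has_p) out.slice(s) = a + P * X.slice(s);
    else out.slice(s) = a + X.slice(s);
  }
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("Xn") = Xn,
                            Rcpp::Named("sd") = sdv,
                            Rcpp::Named("pre") = pre);
}

// Backward pass of one TCN block; mirrors tcn_block_fwd_cpp.
// [[Rcpp::export]]
Rcpp::List tcn_block_bwd_cpp(const arma::cube& dOut, const arma::cube& X,
                             const arma::cube& Xn, const arma::mat& sdv,
                             const arma::cube& pre, const arma::cube& W,
                             const arma::mat& P, const int dilation,
                             const int act, const bool use_ln,
                             const arma::mat& mask) {
  const uword C = X.n_rows, T = X.n_cols, B = X.n_slices;
  const uword Cout = W.n_rows, K = W.n_slices;
  const bool has_p = P.n_elem > 0;
  const bool has_mask = mask.n_elem > 0;
  cube dX(C, T, B);
  cube dW(size(W), fill::zeros);
  vec db(Cout, fill::zeros);
  mat dP;
  if (has_p) dP.zeros(P.n_rows, P.n_cols);
  for (uword s = 0; s < B; ++s) {
    // residual path
    if (has_p) {
      dP += dOut.slice(s) * X.slice(s).t();
      dX.slice(s) = P.t() * dOut.slice(s);
    } else {
      dX.slice(s) = dOut.slice(s);
    }
    // dropout + activation
    mat dPre = dOut.slice(s);
    if (has_mask) dPre.each_col() %= mask.col(s);
    dPre %= act_grad(pre.slice(s), act);
    // convolution
    db += sum(dPre, 1);
    mat dXn(C, T, fill::zeros);
    for (uword k = 0; k < K; ++k) {
      const uword off = k * static_cast<uword>(dilation);
      if (off >= T) continue;
      const mat dYk = dPre.cols(off, T - 1);
      dW.slice(k) += dYk * Xn.slice(s).cols(0, T - 1 - off).t();
      dXn.cols(0, T - 1 - off) += W.slice(k).t() * dYk;
    }
    // layer normalization
    if (use_ln) {
      const mat& Z = Xn.slice(s);
      const rowvec m1 = mean(dXn, 0);
      const rowvec m2 = mean(dXn % Z, 0);
      mat dZ = dXn;
      dZ.each_row() -= m1;
      dZ -= Z % repmat(m2, C, 1);
      dZ.each_row() /= sdv.col(s).t();
      dX.slice(s) += dZ;
    } else {
      dX.slice(s) += dXn;
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db,
                            Rcpp::Named("dP") = dP);
}

// Gather X (Cin x T x B) into timestep-major columns: column t*B + s.
static mat gather_tmajor(const cube& X) {
  const uword Cin = X.n_rows, T = X.n_cols, B = X.n_slices;
  mat Xt(Cin, T * B);
  for (uword s = 0; s < B; ++s)
    for (uword t = 0; t < T; ++t) Xt.col(t * B + s) = X.slice(s).col(t);
  return Xt;
}

// Single-layer LSTM forward over a batch of series, vectorized over the
// batch at every timestep.  Gate layout in Wx / Wh / b rows:
// [input; forget; cell; output], H rows each.  Hidden states, cell
// states and post-nonlinearity gates are returned batch-major:
// (H x B x T) and (4H x B x T) cubes with one slice per timestep.
// [[Rcpp::export]]
Rcpp::List lstm_fwd_cpp(const arma::cube& X, const arma::mat& Wx,
                        const arma::mat& Wh, const arma::vec& b) {
  const uword T = X.n_cols, B = X.n_slices;
  const uword H = Wh.n_cols;
  mat A0 = Wx * gather_tmajor(X);
  A0.each_col() += b;
  cube Hs(H, B, T), Cs(H, B, T), Gs(4 * H, B, T);
  mat h(H, B, fill::zeros), c(H, B, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat At = A0.cols(t * B, t * B + B - 1) + Wh * h;
    const mat gi = 1.0 / (1.0 + exp(-At.rows(0, H - 1)));
    const mat gf = 1.0 / (1.0 + exp(-At.rows(H, 2 * H - 1)));
    const mat gc = tanh(At.rows(2 * H, 3 * H - 1));
    const mat go = 1.0 / (1.0 + exp(-At.rows(3 * H, 4 * H - 1)));
    c = gf % c + gi % gc;
    h = go % tanh(c);
    Hs.slice(t) = h;
    Cs.slice(t) = c;
    Gs.slice(t).rows(0, H - 1) = gi;
    Gs.slice(t).rows(H, 2 * H - 1) = gf;
    Gs.slice(t).rows(2 * H, 3 * H - 1) = gc;
    Gs.slice(t).rows(3 * H, 4 * H - 1) = go;
  }
  return Rcpp::List::create(Rcpp::Named("H") = Hs,
                            Rcpp::Named("C") = Cs,
                            Rcpp::Named("G") = Gs);
}

// Backpropagation through time from a gradient on the final hidden state
// only (the model reads out the last timestep).  Input gradients are not
// needed because the LSTM is the first layer of its branch.
// [[Rcpp::export]]
Rcpp::List lstm_bwd_cpp(const arma::cube& X, const arma::mat& Wx,
                        const arma::mat& Wh, const arma::cube& Hs,
                        const arma::cube& Cs, const arma::cube& Gs,
                        const arma::mat& dHlast) {
  const uword T = X.n_cols, B = X.n_slices;
  const uword H = Wh.n_cols;
  mat dWh(size(Wh), fill::zeros);
  vec db(4 * H, fill::zeros);
  mat dh = dHlast, dc(H, B, fill::zeros);
  mat Da(4 * H, T * B);  // timestep-major, for the final dWx GEMM
  const mat zero_hb(H, B, fill::zeros);
  for (uword tt = T; tt-- > 0;) {
    const mat gi = Gs.slice(tt).rows(0, H - 1);
    const mat gf = Gs.slice(tt).rows(H, 2 * H - 1);
    const mat gc = Gs.slice(tt).rows(2 * H, 3 * H - 1);
    const mat go = Gs.slice(tt).rows(3 * H, 4 * H - 1);
    const mat tc = tanh(Cs.slice(tt));
    const mat& c_prev = (tt > 0) ? Cs.slice(tt - 1) : zero_hb;
    const mat& h_prev = (tt > 0) ? Hs.slice(tt - 1) : zero_hb;
    dc += dh % go % (1.0 - tc % tc);
    mat da(4 * H, B);
    da.rows(0, H - 1) = (dc % gc) % gi % (1.0 - gi);
    da.rows(H, 2 * H - 1) = (dc % c_prev) % gf % (1.0 - gf);
    da.rows(2 * H, 3 * H - 1) = (dc % gi) % (1.0 - gc % gc);
    da.rows(3 * H, 4 * H - 1) = (dh % tc) % go % (1.0 - go);
    Da.cols(tt * B, tt * B + B - 1) = da;
    dWh += da * h_prev.t();
    db += sum(da, 1);
    dh = Wh.t() * da;
    dc %= gf;
  }
  const mat dWx = Da * gather_tmajor(X).t();
  return Rcpp::List::create(Rcpp::Named("dWx") = dWx,
                            Rcpp::Named("dWh") = dWh,
                            Rcpp::Named("db") = db);
}

// Direct-form II transposed IIR filter with explicit initial state
// (coefficients normalized so a[0] == 1; zi has length(a) - 1 entries).
// [[Rcpp::export]]
arma::vec iir_filter_cpp(const arma::vec& b, const arma::vec& a,
                         const arma::vec& x, const arma::vec& zi) {
  const uword n = b.n_elem;
  vec z = zi;
  vec y(x.n_elem);
  for (uword i = 0; i < x.n_elem; ++i) {
    const double xi = x(i);
    const double yi = b(0) * xi + z(0);
    for (uword j = 0; j + 2 < n; ++j)
      z(j) = b(j + 1) * xi + z(j + 1) - a(j + 1) * yi;
    z(n - 2) = b(n - 1) * xi - a(n - 1) * yi;
    y(i) = yi;
  }
  return y;
}
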