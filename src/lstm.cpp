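// LSTM layer forward / backward-through-time kernels.
//
// Sequence tensors arrive in their matrix view [B*T, D]: rows (b, t) with b
// fastest, so timestep t occupies the contiguous row block t*B .. t*B+B-1
// (0-based). Gate column blocks in the 4H-wide matrices are, in order:
// input (i), forget (f), candidate (g), output (o).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// [[Rcpp::export]]
Rcpp::List lstm_layer_fwd_cpp(const arma::mat& xm, const arma::mat& Wx,
                              const arma::mat& Wh, const arma::rowvec& b,
                              const arma::mat& h0, const arma::mat& c0,
                              int B, int T, bool reverse) {
  const int H = Wh.n_rows;
  mat zx = xm * Wx;
  zx.each_row() += b;
  mat h = h0, c = c0;
  mat ym(B * T, H), gates(B * T, 4 * H);
  mat cAll(B * T, H), cprevAll(B * T, H), hprevAll(B * T, H);
  for (int k = 0; k < T; ++k) {
    const int t = reverse ? (T - 1 - k) : k;
    const int r0 = t * B, r1 = t * B + B - 1;
    mat z = zx.rows(r0, r1) + h * Wh;
    mat gi = sigm(z.cols(0, H - 1));
    mat gf = sigm(z.cols(H, 2 * H - 1));
    mat gg = tanh(z.cols(2 * H, 3 * H - 1));
    mat go = sigm(z.cols(3 * H, 4 * H - 1));
    cprevAll.rows(r0, r1) = c;
    hprevAll.rows(r0, r1) = h;
    c = gf % c + gi % gg;
    h = go % tanh(c);
    gates.submat(r0, 0, r1, H - 1) = gi;
    gates.submat(r0, H, r1, 2 * H - 1) = gf;
    gates.submat(r0, 2 * H, r1, 3 * H - 1) = gg;
    gates.submat(r0, 3 * H, r1, 4 * H - 1) = go;
    cAll.rows(r0, r1) = c;
    ym.rows(r0, r1) = h;
  }
  return Rcpp::List::create(
      Rcpp::Named("y") = ym, Rcpp::Named("hFinal") = h,
      Rcpp::Named("cFinal") = c, Rcpp::Named("gates") = gates,
      Rcpp::Named("cAll") = cAll, Rcpp::Named("cprevAll") = cprevAll,
      Rcpp::Named("hprevAll") = hprevAll);
}

// [[Rcpp::export]]
Rcpp::List lstm_layer_bwd_cpp(const arma::mat& dym, const arma::mat& dhFinal,
                              const arma::mat& dcFinal, const arma::mat& xm,
                              const arma::mat& Wx, const arma::mat& Wh,
                              const arma::mat& gates, const arma::mat& cAll,
                              const arma::mat& cprevAll,
                              const arma::mat& hprevAll,
                              int B, int T, bool reverse) {
  const int H = Wh.n_rows;
  mat dzAll(B * T, 4 * H);
  mat dhNext = dhFinal, dcNext = dcFinal;
  for (int k = T - 1; k >= 0; --k) {
    const int t = reverse ? (T - 1 - k) : k;
    const int r0 = t * B, r1 = t * B + B - 1;
    const mat gi = gates.submat(r0, 0, r1, H - 1);
    const mat gf = gates.submat(r0, H, r1, 2 * H - 1);
    const mat gg = gates.submat(r0, 2 * H, r1, 3 * H - 1);
    const mat go = gates.submat(r0, 3 * H, r1, 4 * H - 1);
    const mat tc = tanh(cAll.rows(r0, r1));
    mat dh = dym.rows(r0, r1) + dhNext;
    mat dc = dcNext + dh % go % (1.0 - tc % tc);
    mat dgo = dh % tc;
    mat dgi = dc % gg;
    mat dgf = dc % cprevAll.rows(r0, r1);
    mat dgg = dc % gi;
    mat dz(B, 4 * H);
    dz.cols(0, H - 1) = dgi % gi % (1.0 - gi);
    dz.cols(H, 2 * H - 1) = dgf % gf % (1.0 - gf);
    dz.cols(2 * H, 3 * H - 1) = dgg % (1.0 - gg % gg);
    dz.cols(3 * H, 4 * H - 1) = dgo % go % (1.0 - go);
    dzAll.rows(r0, r1) = dz;
    dhNext = dz * Wh.t();
    dcNext = dc % gf;
  }
  mat dx = dzAll * Wx.t();
  mat dWx = xm.t() * dzAll;
  mat dWh = hprevAll.t() * dzAll;
  rowvec db = sum(dzAll, 0);
  return Rcpp::List::create(
      Rcpp::Named("dx") = dx, Rcpp::Named("dWx") = dWx,
      Rcpp::Named("dWh") = dWh, Rcpp::Named("db") = db,
      Rcpp::Named("dh0") = dhNext, Rcpp::Named("dc0") = dcNext);
}
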