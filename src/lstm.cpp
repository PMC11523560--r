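// Batched multi-layer LSTM forward pass and backprop-through-time.
// Layout: X is a cube (batch x channels x time); each layer's weights are
// W (d_in x 4H), U (H x 4H), b (4H) with gate order [input, forget, cell,
// output]. All state is carried in R; these routines are pure functions.
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline arma::mat sigmoid(const arma::mat& x) {
  return 1.0 / (1.0 + arma::exp(-x));
}

// [[Rcpp::export]]
List lstm_forward_cpp(List W, List U, List b, arma::cube X) {
  const int L = W.size();
  const int B = X.n_rows;
  const int T = X.n_slices;
  List Hs(L), Gs(L), Cs(L);
  arma::cube input = X;
  for (int l = 0; l < L; ++l) {
    arma::mat Wl = as<arma::mat>(W[l]);
    arma::mat Ul = as<arma::mat>(U[l]);
    arma::rowvec bl = as<arma::rowvec>(b[l]);
    const int H = Ul.n_rows;
    arma::cube G(B, 4 * H, T), C(B, H, T), Hc(B, H, T);
    arma::mat h(B, H, arma::fill::zeros), c(B, H, arma::fill::zeros);
    for (int t = 0; t < T; ++t) {
      arma::mat a = input.slice(t) * Wl + h * Ul;
      a.each_row() += bl;
      arma::mat gi = sigmoid(a.cols(0, H - 1));
      arma::mat gf = sigmoid(a.cols(H, 2 * H - 1));
      arma::mat gg = arma::tanh(a.cols(2 * H, 3 * H - 1));
      arma::mat go = sigmoid(a.cols(3 * H, 4 * H - 1));
      c = gf % c + gi % gg;
      h = go % arma::tanh(c);
      G.slice(t) = arma::join_rows(gi, gf, gg, go);
      C.slice(t) = c;
      Hc.slice(t) = h;
    }
    Gs[l] = G; Cs[l] = C; Hs[l] = Hc;
    input = Hc;
  }
  return List::create(_["H"] = Hs, _["G"] = Gs, _["C"] = Cs);
}

// dHtop: gradient of the loss w.r.t. the top layer's hidden outputs
// (cube B x H x T). Returns per-layer gradients dW, dU, db.
// [[Rcpp::export]]
List lstm_backward_cpp(List W, List U, List b, arma::cube X,
                       List Hs, List Gs, List Cs, arma::cube dHtop) {
  const int L = W.size();
  const int B = X.n_rows;
  const int T = X.n_slices;
  List dW(L), dU(L), db(L);
  arma::cube dH_ext = dHtop;  // external gradient flowing into layer l's h
  for (int l = L - 1; l >= 0; --l) {
    arma::mat Wl = as<arma::mat>(W[l]);
    arma::mat Ul = as<arma::mat>(U[l]);
    const int H = Ul.n_rows;
    const arma::cube& G = as<arma::cube>(Gs[l]);
    const arma::cube& C = as<arma::cube>(Cs[l]);
    const arma::cube Hprev = (l > 0) ? as<arma::cube>(Hs[l - 1]) : X;
    const arma::cube& Hown = as<arma::cube>(Hs[l]);
    const int D = Wl.n_rows;
    arma::mat dWl(D, 4 * H, arma::fill::zeros);
    arma::mat dUl(H, 4 * H, arma::fill::zeros);
    arma::rowvec dbl(4 * H, arma::fill::zeros);
    arma::cube dX(B, D, T, arma::fill::zeros);
    arma::mat dh_next(B, H, arma::fill::zeros), dc_next(B, H, arma::fill::zeros);
    for (int t = T - 1; t >= 0; --t) {
      arma::mat gi = G.slice(t).cols(0, H - 1);
      arma::mat gf = G.slice(t).cols(H, 2 * H - 1);
      arma::mat gg = G.slice(t).cols(2 * H, 3 * H - 1);
      arma::mat go = G.slice(t).cols(3 * H, 4 * H - 1);
      arma::mat ct = C.slice(t);
      arma::mat cprev = (t > 0) ? C.slice(t - 1)
                                : arma::mat(B, H, arma::fill::zeros);
      arma::mat hprev = (t > 0) ? Hown.slice(t - 1)
                                : arma::mat(B, H, arma::fill::zeros);
      arma::mat xt = Hprev.slice(t);

      arma::mat dh = dH_ext.slice(t) + dh_next;
      arma::mat tc = arma::tanh(ct);
      arma::mat do_ = dh % tc;
      arma::mat dc = dc_next + dh % go % (1.0 - tc % tc);
      arma::mat di = dc % gg;
      arma::mat df = dc % cprev;
      arma::mat dg = dc % gi;
      arma::mat da = arma::join_rows(di % gi % (1.0 - gi),
                                     df % gf % (1.0 - gf),
                                     dg % (1.0 - gg % gg),
                                     do_ % go % (1.0 - go));
      dWl += xt.t() * da;
      dUl += hprev.t() * da;
      dbl += arma::sum(da, 0);
      dX.slice(t) = da * Wl.t();
      dh_next = da * Ul.t();
      dc_next = dc % gf;
    }
    dW[l] = dWl; dU[l] = dUl; db[l] = arma::vec(dbl.t());
    if (l > 0) dH_ext = dX;
  }
  return List::create(_["dW"] = dW, _["dU"] = dU, _["db"] = db);
}
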