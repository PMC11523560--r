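// Forward-Euler integration of the three-compartment motor-unit model,
// channels in lockstep. TL: steps x channels target loads in [0,1];
// init: 3 x channels (MR, MA, MF). Row i of the outputs is the state at
// time (i-1)*dt; TL row i drives the step to row i+1.
#include <RcppArmadillo.h>
using namespace Rcpp;

// [[Rcpp::export]]
List integrate_channels_cpp(const arma::mat& TL, const arma::mat& init,
                            double F, double R, double LD, double LR,
                            double dt) {
  const int n = TL.n_rows, k = TL.n_cols;
  arma::mat MR(n, k), MA(n, k), MF(n, k);
  arma::rowvec mr = init.row(0), ma = init.row(1), mf = init.row(2);
  for (int i = 0; i < n; ++i) {
    MR.row(i) = mr; MA.row(i) = ma; MF.row(i) = mf;
    if (i == n - 1) break;
    for (int j = 0; j < k; ++j) {
      double tl = TL(i, j);
      double gap = tl - ma(j);
      double C = (ma(j) < tl) ? LD * std::min(gap, mr(j)) : LR * (tl - ma(j));
      double mr2 = mr(j) + dt * (-C + R * mf(j));
      double ma2 = ma(j) + dt * (C - F * ma(j));
      double mf2 = mf(j) + dt * (F * ma(j) - R * mf(j));
      mr2 = std::min(std::max(mr2, 0.0), 1.0);
      ma2 = std::min(std::max(ma2, 0.0), 1.0);
      mf2 = std::min(std::max(mf2, 0.0), 1.0);
      double s = mr2 + ma2 + mf2;
      mr(j) = mr2 / s; ma(j) = ma2 / s; mf(j) = mf2 / s;
    }
  }
  return List::create(_["MR"] = MR, _["MA"] = MA, _["MF"] = MF);
}
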