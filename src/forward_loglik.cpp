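// Forward aggregated-Markov likelihood over dwell sequences.
//
// Each dwell of class a and apparent duration t contributes
//   expmat(Qcorr_aa * (t - td)) * Cross_ab
// where Qcorr_aa is the missed-event-corrected within-class sub-generator and
// Cross_ab = Q_ab * expmat(Q_bb * td) (built on the R side). Per-dwell
// rescaling keeps the forward vector in range; the log-likelihood is the sum
// of the log scale factors.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
double forward_loglik_cpp(const arma::mat& qc_shut,
                          const arma::mat& qc_open,
                          const arma::mat& cross_so,
                          const arma::mat& cross_os,
                          const arma::rowvec& phi_shut,
                          const arma::rowvec& phi_open,
                          const Rcpp::IntegerVector& cls,      // 0 shut, 1 open
                          const Rcpp::NumericVector& dur,      // t - td, >= 0
                          const Rcpp::IntegerVector& burst_ptr, // 0-based starts
                          const Rcpp::IntegerVector& burst_len) {
  const int nburst = burst_ptr.size();
  double loglik = 0.0;
  for (int b = 0; b < nburst; ++b) {
    const int start = burst_ptr[b];
    const int len = burst_len[b];
    if (len <= 0) continue;
    arma::rowvec v = (cls[start] == 0) ? phi_shut : phi_open;
    for (int i = start; i < start + len; ++i) {
      if (cls[i] == 0) {
        v = v * arma::expmat(qc_shut * dur[i]) * cross_so;
      } else {
        v = v * arma::expmat(qc_open * dur[i]) * cross_os;
      }
      const double s = arma::accu(v);
      if (!(s > 0.0) || !std::isfinite(s)) return -1e15;
      loglik += std::log(s);
      v /= s;
    }
  }
  return loglik;
}
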