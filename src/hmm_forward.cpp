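#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Scaled forward recursion for the banded, covariate-modulated movement HMM.
// Data arrive flattened across sessions; influences for edge/centre are
// recomputed inside from distances because their logistic parameters are
// estimated. The banded (birth-death) structure makes each per-step chain
// reversible, so the stationary initial distribution has the closed form
// pi_k  proportional to  prod_{j<k} Gamma[j][j+1] / Gamma[j+1][j].

static inline double logistic(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// [[Rcpp::export]]
double cpp_forward_loglik(NumericVector l, NumericVector logl, NumericVector cosphi,
                          NumericVector w_step, NumericVector w_angle,
                          NumericVector d_edge, NumericVector d_center,
                          NumericVector I_cliff,
                          IntegerVector sess_start, IntegerVector sess_len,
                          NumericVector m, NumericVector a,
                          NumericMatrix rho,
                          NumericMatrix alpha_tpm,
                          NumericMatrix b_cliff, NumericMatrix b_edge,
                          NumericMatrix b_center,
                          double x_edge, double beta_edge,
                          double x_center, double beta_center) {
  const int K = m.size();

  // gamma emission constants: log f(l) = c1 + (a-1) log l - (a/m) l
  std::vector<double> c1(K), am1(K), rate(K);
  for (int k = 0; k < K; ++k) {
    rate[k] = a[k] / m[k];
    am1[k] = a[k] - 1.0;
    c1[k] = a[k] * std::log(rate[k]) - R::lgammafn(a[k]);
  }
  // atanh of concentrations, columns: basal, cliff, edge, center
  std::vector<double> at(K * 4);
  for (int k = 0; k < K; ++k)
    for (int c = 0; c < 4; ++c)
      at[k + K * c] = std::atanh(rho(k, c));

  std::vector<double> alpha(K), anew(K), b(K), rowG(K * K), pi0(K);
  double ll = 0.0;

  for (int s = 0; s < sess_start.size(); ++s) {
    const int t0 = sess_start[s], T = sess_len[s];
    for (int t = t0; t < t0 + T; ++t) {
      const double Ie = logistic(beta_edge * (d_edge[t] - x_edge));
      const double Ice = logistic(beta_center * (d_center[t] - x_center));
      const double Ic = I_cliff[t];
      const double we = Ie;
      const double wc = Ic * (1.0 - Ie);
      const double wce = Ice * (1.0 - Ie) * (1.0 - Ic);
      const double wb = 1.0 - we - wc - wce;

      // emissions (linear space; the forward recursion is rescaled each step)
      for (int k = 0; k < K; ++k) {
        double bk = 1.0;
        if (w_step[t] > 0.0)
          bk = std::exp(w_step[t] * (c1[k] + am1[k] * logl[t] - rate[k] * l[t]));
        if (w_angle[t] > 0.0) {
          const double re = std::tanh(wb * at[k] + wc * at[k + K] +
                                      we * at[k + 2 * K] + wce * at[k + 3 * K]);
          const double dens = (1.0 - re * re) /
            (2.0 * M_PI * (1.0 + re * re - 2.0 * re * cosphi[t]));
          bk *= (w_angle[t] == 1.0) ? dens : std::pow(dens, w_angle[t]);
        }
        b[k] = bk;
      }

      // banded TPM row by row (softmax, diagonal as reference)
      for (int i = 0; i < K; ++i) {
        double denom = 1.0;
        for (int j = std::max(0, i - 1); j <= std::min(K - 1, i + 1); ++j) {
          if (j == i) continue;
          const double eta = alpha_tpm(i, j) + b_cliff(i, j) * Ic +
                             b_edge(i, j) * Ie + b_center(i, j) * Ice;
          const double e = std::exp(eta);
          rowG[i + K * j] = e;
          denom += e;
        }
        for (int j = 0; j < K; ++j) {
          if (std::abs(i - j) > 1) { rowG[i + K * j] = 0.0; continue; }
          if (j == i) rowG[i + K * j] = 1.0 / denom;
          else rowG[i + K * j] /= denom;
        }
      }

      double ssum = 0.0;
      if (t == t0) {
        // stationary initial distribution (closed form for the banded chain)
        double acc = 1.0, tot = 1.0;
        pi0[0] = 1.0;
        for (int k = 1; k < K; ++k) {
          acc *= rowG[(k - 1) + K * k] / rowG[k + K * (k - 1)];
          pi0[k] = acc;
          tot += acc;
        }
        for (int k = 0; k < K; ++k) {
          alpha[k] = (pi0[k] / tot) * b[k];
          ssum += alpha[k];
        }
      } else {
        for (int j = 0; j < K; ++j) {
          double acc = 0.0;
          for (int i = 0; i < K; ++i) acc += alpha[i] * rowG[i + K * j];
          anew[j] = acc * b[j];
          ssum += anew[j];
        }
        for (int k = 0; k < K; ++k) alpha[k] = anew[k];
      }
      if (!(ssum > 0.0) || !std::isfinite(ssum)) return R_NegInf;
      for (int k = 0; k < K; ++k) alpha[k] /= ssum;
      ll += std::log(ssum);
    }
  }
  return ll;
}
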