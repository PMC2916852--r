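#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Monte-Carlo response generation and binned likelihood for the
// causal-inference observer. Mirrors the R reference path
// (simulate_trial_responses + bin_probs) exactly; kept in C++ because the
// fitting optimizer evaluates it thousands of times per subject.
//
// Codes: cond_type 0 = auditory-only, 1 = visual-only, 2 = bisensory;
// strategy 0 = averaging, 1 = selection, 2 = matching.

static inline int bin_of(double x, double lo, double bw, int nbins) {
  int i = (int)std::floor((x - lo) / bw);
  if (i < 0) i = 0;
  if (i >= nbins) i = nbins - 1;
  return i;
}

// Fill `counts` (nbins rows x 2*ncond cols; col 2*c auditory, 2*c+1 visual)
static void accumulate_counts(const IntegerVector& samp_cond,
                              const IntegerVector& cond_type,
                              const NumericVector& cond_sA,
                              const NumericVector& cond_sV,
                              const NumericVector& z_A,
                              const NumericVector& z_V,
                              const NumericVector& xi,
                              double sigma_A, double sigma_V, double sigma_P,
                              double p_common, double criterion, int strategy,
                              double lo, double bw, int nbins,
                              std::vector<int>& counts,
                              std::vector<int>& n_per_cond) {
  const double vA = sigma_A * sigma_A;
  const double vV = sigma_V * sigma_V;
  const double vP = sigma_P * sigma_P;
  const double vsum = vA * vV + vA * vP + vV * vP;
  const double log_norm_c1 = -std::log(2.0 * M_PI) - 0.5 * std::log(vsum);
  const double sdA2 = std::sqrt(vA + vP), sdV2 = std::sqrt(vV + vP);
  const double log_norm_c2 =
      -std::log(2.0 * M_PI) - std::log(sdA2) - std::log(sdV2);
  const double wA = 1.0 / vA, wV = 1.0 / vV, wP = 1.0 / vP;
  const double wsum = wA + wV + wP;
  const double shrinkA = vP / (vP + vA), shrinkV = vP / (vP + vV);
  const double log_prior_odds =
      (p_common > 0.0 && p_common < 1.0)
          ? std::log(p_common) - std::log1p(-p_common)
          : 0.0;

  const int n = samp_cond.size();
  for (int i = 0; i < n; ++i) {
    const int c = samp_cond[i];
    ++n_per_cond[c];
    const int type = cond_type[c];
    if (type == 0) {  // auditory-only: single-cue shrinkage
      double x = cond_sA[c] + sigma_A * z_A[i];
      ++counts[(size_t)(2 * c) * nbins + bin_of(x * shrinkA, lo, bw, nbins)];
    } else if (type == 1) {
      double x = cond_sV[c] + sigma_V * z_V[i];
      ++counts[(size_t)(2 * c + 1) * nbins +
               bin_of(x * shrinkV, lo, bw, nbins)];
    } else {
      const double xA = cond_sA[c] + sigma_A * z_A[i];
      const double xV = cond_sV[c] + sigma_V * z_V[i];
      double post;
      if (p_common <= 0.0) {
        post = 0.0;
      } else if (p_common >= 1.0) {
        post = 1.0;
      } else {
        const double d = xA - xV;
        const double l1 =
            log_norm_c1 - 0.5 * (d * d * vP + xA * xA * vV + xV * xV * vA) / vsum;
        const double l2 = log_norm_c2 -
                          0.5 * (xA * xA / (vA + vP) + xV * xV / (vV + vP));
        post = 1.0 / (1.0 + std::exp(-(log_prior_odds + l1 - l2)));
      }
      const double fused = (xA * wA + xV * wV) / wsum;
      const double segA = xA * shrinkA, segV = xV * shrinkV;
      double rA, rV;
      if (strategy == 0) {
        rA = post * fused + (1.0 - post) * segA;
        rV = post * fused + (1.0 - post) * segV;
      } else {
        const double thr = (strategy == 1) ? criterion : xi[i];
        const bool c1 = post > thr;  // tie -> independent causes
        rA = c1 ? fused : segA;
        rV = c1 ? fused : segV;
      }
      ++counts[(size_t)(2 * c) * nbins + bin_of(rA, lo, bw, nbins)];
      ++counts[(size_t)(2 * c + 1) * nbins + bin_of(rV, lo, bw, nbins)];
    }
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_response_counts(IntegerVector samp_cond,
                                  IntegerVector cond_type,
                                  NumericVector cond_sA, NumericVector cond_sV,
                                  NumericVector z_A, NumericVector z_V,
                                  NumericVector xi, double sigma_A,
                                  double sigma_V, double sigma_P,
                                  double p_common, double criterion,
                                  int strategy, double lo, double bw,
                                  int nbins) {
  const int ncond = cond_type.size();
  std::vector<int> counts((size_t)2 * ncond * nbins, 0);
  std::vector<int> n_per_cond(ncond, 0);
  accumulate_counts(samp_cond, cond_type, cond_sA, cond_sV, z_A, z_V, xi,
                    sigma_A, sigma_V, sigma_P, p_common, criterion, strategy,
                    lo, bw, nbins, counts, n_per_cond);
  IntegerMatrix out(nbins, 2 * ncond);
  for (int j = 0; j < 2 * ncond; ++j)
    for (int b = 0; b < nbins; ++b) out(b, j) = counts[(size_t)j * nbins + b];
  return out;
}

// [[Rcpp::export]]
double cpp_mc_loglik(IntegerVector samp_cond, IntegerVector cond_type,
                     NumericVector cond_sA, NumericVector cond_sV,
                     NumericVector z_A, NumericVector z_V, NumericVector xi,
                     double sigma_A, double sigma_V, double sigma_P,
                     double p_common, double criterion, int strategy,
                     double lo, double bw, int nbins, IntegerVector obs_cond,
                     IntegerVector obs_mod, IntegerVector obs_bin,
                     double floor_p) {
  const int ncond = cond_type.size();
  std::vector<int> counts((size_t)2 * ncond * nbins, 0);
  std::vector<int> n_per_cond(ncond, 0);
  accumulate_counts(samp_cond, cond_type, cond_sA, cond_sV, z_A, z_V, xi,
                    sigma_A, sigma_V, sigma_P, p_common, criterion, strategy,
                    lo, bw, nbins, counts, n_per_cond);

  // per-column normalizers: sum_b max(count/m, floor)
  std::vector<double> log_colsum((size_t)2 * ncond,
                                 -std::numeric_limits<double>::infinity());
  std::vector<bool> have((size_t)2 * ncond, false);
  const int nobs = obs_cond.size();
  double ll = 0.0;
  for (int k = 0; k < nobs; ++k) {
    const int c = obs_cond[k];
    const int col = 2 * c + obs_mod[k];
    if (!have[col]) {
      const double m = (double)n_per_cond[c];
      double s = 0.0;
      for (int b = 0; b < nbins; ++b) {
        double p = counts[(size_t)col * nbins + b] / m;
        s += (p > floor_p) ? p : floor_p;
      }
      log_colsum[col] = std::log(s);
      have[col] = true;
    }
    const double m = (double)n_per_cond[c];
    double p = counts[(size_t)col * nbins + obs_bin[k]] / m;
    if (p < floor_p) p = floor_p;
    ll += std::log(p) - log_colsum[col];
  }
  return ll;
}
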