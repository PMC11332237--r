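#include <Rcpp.h>
using namespace Rcpp;

// Inner loop of the TCC response model: each simulated response is the
// argmax over options of dprime * score + standard normal noise.
// Ties (possible in floating point, measure zero in theory) break to the
// lowest index. Uses R's RNG stream so results are reproducible under
// set.seed().

// [[Rcpp::export]]
IntegerVector tcc_simulate_cpp(NumericVector scores, double dprime, int n_sims) {
  const int k = scores.size();
  std::vector<double> signal(k);
  for (int j = 0; j < k; ++j) signal[j] = dprime * scores[j];
  IntegerVector out(n_sims);
  for (int i = 0; i < n_sims; ++i) {
    double best = R_NegInf;
    int arg = 0;
    for (int j = 0; j < k; ++j) {
      const double v = signal[j] + norm_rand();
      if (v > best) { best = v; arg = j; }
    }
    out[i] = arg + 1; // 1-based option index
  }
  return out;
}

// Counts-only variant: avoids materializing per-draw indices when only the
// response histogram is needed (model fitting, convergence checks).

// [[Rcpp::export]]
IntegerVector tcc_simulate_counts_cpp(NumericVector scores, double dprime,
                                      double n_sims) {
  const int k = scores.size();
  std::vector<double> signal(k);
  for (int j = 0; j < k; ++j) signal[j] = dprime * scores[j];
  IntegerVector counts(k);
  const R_xlen_t n = (R_xlen_t)n_sims;
  for (R_xlen_t i = 0; i < n; ++i) {
    double best = R_NegInf;
    int arg = 0;
    for (int j = 0; j < k; ++j) {
      const double v = signal[j] + norm_rand();
      if (v > best) { best = v; arg = j; }
    }
    ++counts[arg];
  }
  return counts;
}
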