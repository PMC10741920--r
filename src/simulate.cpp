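#include <Rcpp.h>
using namespace Rcpp;

// Discrete-time trajectory sampling on the transition network, CSR layout.
// Neighbour probabilities exclude the self-loop; the residual probability is
// the stay probability. Uses R's RNG so set.seed() controls reproducibility.

static inline int step_node(int cur, const IntegerVector &row_ptr,
                            const IntegerVector &col_idx,
                            const NumericVector &prob) {
  double u = unif_rand();
  double cum = 0.0;
  for (int k = row_ptr[cur]; k < row_ptr[cur + 1]; ++k) {
    cum += prob[k];
    if (u < cum) return col_idx[k];
  }
  return cur;  // self-loop
}

// Run one trajectory per start node until it is absorbed in the reactant or
// product set. Outcomes: 1 = product first, 0 = reactant first, -1 = truncated
// at max_steps.
// [[Rcpp::export]]
IntegerVector run_paths_cpp(IntegerVector row_ptr, IntegerVector col_idx,
                            NumericVector prob, IntegerVector starts,
                            LogicalVector is_reactant, LogicalVector is_product,
                            double max_steps) {
  int n_paths = starts.size();
  IntegerVector out(n_paths);
  RNGScope scope;
  for (int p = 0; p < n_paths; ++p) {
    int cur = starts[p];
    int res = -1;
    for (double s = 0; s <= max_steps; ++s) {
      if (is_product[cur]) { res = 1; break; }
      if (is_reactant[cur]) { res = 0; break; }
      cur = step_node(cur, row_ptr, col_idx, prob);
    }
    out[p] = res;
  }
  return out;
}

// Occupation counts of a single equilibrium trajectory of n_steps moves.
// [[Rcpp::export]]
NumericVector run_occupation_cpp(IntegerVector row_ptr, IntegerVector col_idx,
                                 NumericVector prob, int start,
                                 double n_steps) {
  int n = row_ptr.size() - 1;
  NumericVector counts(n);
  RNGScope scope;
  int cur = start;
  for (double s = 0; s < n_steps; ++s) {
    counts[cur] += 1.0;
    cur = step_node(cur, row_ptr, col_idx, prob);
  }
  counts[cur] += 1.0;
  return counts;
}
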