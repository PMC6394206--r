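#include <Rcpp.h>
using namespace Rcpp;

// Evolve a duplicated CDS pair to a target Ks under the same NG86 tables
// used for estimation.  Both copies start identical (the ancestor);
// single-base substitutions are proposed uniformly, mutations creating stop
// codons are rejected, nonsynonymous changes are accepted with probability
// omega (ka/ks), and the walk stops at the first crossing of
// target - tol.  All bookkeeping (synonymous site sums and pairwise
// difference sums) is updated incrementally so each step is O(1).
//
// Codon indices are 1-based (R convention) in the interface.

// [[Rcpp::export]]
List evolve_pair_cpp(IntegerVector ancestor, double target, double tol,
                     double omega, NumericVector syn, NumericMatrix Sd,
                     NumericMatrix Nd, IntegerMatrix mut_new,
                     LogicalMatrix mut_syn, LogicalMatrix mut_stop,
                     int max_steps) {
  int n = ancestor.size();
  std::vector<int> a(n), b(n);   // 0-based codon indices
  double sumS = 0.0;             // per-sequence synonymous sites (a)
  for (int i = 0; i < n; ++i) {
    a[i] = ancestor[i] - 1;
    b[i] = a[i];
    sumS += syn[a[i]];
  }
  double sumS_a = sumS, sumS_b = sumS;
  double sd_sum = 0.0, nd_sum = 0.0;
  bool saturated = false;
  int steps = 0;
  double ks = 0.0;

  for (;;) {
    double S = (sumS_a + sumS_b) / 2.0;
    double ps = (S > 0) ? sd_sum / S : 0.0;
    if (4.0 / 3.0 * ps >= 1.0) { saturated = true; ks = NA_REAL; break; }
    ks = -0.75 * std::log(1.0 - 4.0 / 3.0 * ps);
    if (ks >= target - tol) break;
    if (steps >= max_steps) { saturated = true; break; }
    ++steps;

    bool on_a = unif_rand() < 0.5;
    int ci = (int)(unif_rand() * n);
    if (ci >= n) ci = n - 1;
    int mi = (int)(unif_rand() * 9);
    if (mi >= 9) mi = 8;
    int c_old = on_a ? a[ci] : b[ci];
    if (mut_stop(c_old, mi)) continue;
    bool is_syn = mut_syn(c_old, mi);
    if (!is_syn && unif_rand() > omega) continue;
    int c_new = mut_new(c_old, mi) - 1;
    int partner = on_a ? b[ci] : a[ci];
    sd_sum += Sd(c_new, partner) - Sd(c_old, partner);
    nd_sum += Nd(c_new, partner) - Nd(c_old, partner);
    if (on_a) {
      sumS_a += syn[c_new] - syn[c_old];
      a[ci] = c_new;
    } else {
      sumS_b += syn[c_new] - syn[c_old];
      b[ci] = c_new;
    }
  }

  IntegerVector ra(n), rb(n);
  for (int i = 0; i < n; ++i) { ra[i] = a[i] + 1; rb[i] = b[i] + 1; }
  return List::create(_["a"] = ra, _["b"] = rb, _["ks"] = ks,
                      _["sd_sum"] = sd_sum, _["nd_sum"] = nd_sum,
                      _["saturated"] = saturated, _["steps"] = steps);
}
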