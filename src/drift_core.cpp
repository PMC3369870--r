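#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Core walk/parse loops for unifilar machines.  States and symbols are 1-based
// integer indices; target(s, a) == 0 means "no transition".  Both functions are
// called once (or |S| times) per drift generation, so they carry the bulk of a
// simulation's work.

// Generate M symbols by walking the machine from `start`, sampling each step
// from the current state's outgoing distribution.  Uses R's RNG so results are
// reproducible under set.seed().
// [[Rcpp::export]]
IntegerVector cpp_generate(const IntegerMatrix& target, const NumericMatrix& prob,
                           int start, int M) {
  const int K = target.ncol();
  IntegerVector out(M);
  int s = start - 1;
  for (int t = 0; t < M; ++t) {
    double u = R::unif_rand();
    double acc = 0.0;
    int chosen = -1;
    for (int a = 0; a < K; ++a) {
      if (target(s, a) > 0) {
        acc += prob(s, a);
        if (u <= acc) { chosen = a; break; }
      }
    }
    if (chosen < 0) {
      // numerical tail (acc slightly < 1): take the last available symbol
      for (int a = K - 1; a >= 0; --a) {
        if (target(s, a) > 0) { chosen = a; break; }
      }
      if (chosen < 0) stop("state with no outgoing transitions reached");
    }
    out[t] = chosen + 1;
    s = target(s, chosen) - 1;
  }
  return out;
}

// Follow the unique unifilar path for `symbols` from `start`, accumulating
// per-edge counts and the base-2 log-likelihood.  If a required transition is
// missing the log-likelihood is -Inf and counts cover only the parsed prefix.
// [[Rcpp::export]]
List cpp_parse(const IntegerMatrix& target, const NumericMatrix& prob,
               const IntegerVector& symbols, int start) {
  const int S = target.nrow(), K = target.ncol(), M = symbols.size();
  IntegerMatrix counts(S, K);
  IntegerVector path(M + 1);
  double ll = 0.0;
  bool complete = true;
  int s = start - 1;
  path[0] = start;
  int t = 0;
  for (; t < M; ++t) {
    int a = symbols[t] - 1;
    int nxt = target(s, a);
    if (nxt == 0) { complete = false; break; }
    counts(s, a) += 1;
    ll += std::log2(prob(s, a));
    s = nxt - 1;
    path[t + 1] = nxt;
  }
  if (!complete) ll = R_NegInf;
  return List::create(_["log_likelihood"] = ll,
                      _["counts"] = counts,
                      _["path"] = path,
                      _["parsed"] = t,
                      _["end_state"] = s + 1,
                      _["complete"] = complete);
}
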