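#include <Rcpp.h>
using namespace Rcpp;

// Sample an order-k Markov nucleotide sequence.
//
// cumprob: (4^k) x 4 matrix of cumulative conditional probabilities
//          P(next <= b | context), rows indexed by the base-4 encoding of the
//          context (first base most significant), each row ending at 1.
// Returns integer base codes 0..3 (A,C,G,T). Uses R's RNG so results are
// reproducible under set.seed().
// [[Rcpp::export]]
IntegerVector markov_sample_cpp(int n, NumericMatrix cumprob, int order,
                                IntegerVector init) {
  if (init.size() != order)
    stop("init must supply exactly 'order' base codes");
  IntegerVector out(n);
  int nctx = cumprob.nrow();
  // rolling context as base-4 integer
  int ctx = 0;
  for (int i = 0; i < order; ++i) ctx = ctx * 4 + init[i];
  int mask = nctx - 1; // nctx is a power of 4
  for (int i = 0; i < n; ++i) {
    double u = unif_rand();
    int b = 0;
    while (b < 3 && u > cumprob(ctx, b)) ++b;
    out[i] = b;
    ctx = ((ctx << 2) | b) & mask;
  }
  return out;
}
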