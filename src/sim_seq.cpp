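#include <Rcpp.h>
using namespace Rcpp;

// Simulate a DNA sequence (integer codes 0=A,1=C,2=G,3=T) from an order-2
// background Markov chain, optionally reweighted by a k-mer boost table.
//
// trans: 16 x 4 matrix of P(next | two previous bases), rows indexed by
//        4*b[i-2] + b[i-1].
// boost: either length 0 (plain background chain) or length 4^k; when the
//        k-mer formed by the last (k-1) emitted bases plus the candidate
//        base has boost > 1, that base's emission odds are multiplied.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export(name = ".sim_seq_cpp")]]
IntegerVector sim_seq_cpp(int n, NumericMatrix trans, NumericVector boost,
                          int k) {
  if (n <= 0) return IntegerVector(0);
  IntegerVector out(n);
  bool boosted = boost.size() > 0;
  int kmask = 1;
  if (boosted) {
    for (int i = 0; i < k - 1; ++i) kmask *= 4; // 4^(k-1)
    if (boost.size() != kmask * 4)
      stop("boost table must have length 4^k");
  }
  GetRNGstate();
  int ctx2 = 0;   // 4*b[i-2] + b[i-1]
  int ctxk = 0;   // last (k-1) bases, base-4
  double w[4];
  for (int i = 0; i < n; ++i) {
    double tot = 0.0;
    for (int b = 0; b < 4; ++b) {
      double p = (i < 2) ? 0.25 : trans(ctx2, b);
      if (boosted && i >= k - 1) p *= boost[ctxk * 4 + b];
      w[b] = p;
      tot += p;
    }
    double u = unif_rand() * tot;
    int b = 0;
    double acc = w[0];
    while (b < 3 && u > acc) acc += w[++b];
    out[i] = b;
    ctx2 = (ctx2 * 4 + b) % 16;
    if (boosted) ctxk = (ctxk * 4 + b) % kmask;
  }
  PutRNGstate();
  return out;
}
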