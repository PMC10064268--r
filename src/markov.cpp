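#include <Rcpp.h>
using namespace Rcpp;

// First-order Markov chain over {A,C,G,T}. Uses R's RNG so that set.seed()
// makes output reproducible. `init` and rows of `trans` must be proper
// probability vectors; validation happens on the R side.
// [[Rcpp::export(name = ".markov_chain_cpp")]]
CharacterVector markov_chain_cpp(int n, NumericVector init, NumericMatrix trans) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  if (n < 1) stop("n must be >= 1");
  std::string out(n, 'A');

  // cumulative rows
  double cinit[4];
  double ctrans[4][4];
  double acc = 0.0;
  for (int j = 0; j < 4; ++j) { acc += init[j]; cinit[j] = acc; }
  for (int i = 0; i < 4; ++i) {
    acc = 0.0;
    for (int j = 0; j < 4; ++j) { acc += trans(i, j); ctrans[i][j] = acc; }
  }

  RNGScope scope;
  double u = unif_rand();
  int state = 0;
  while (state < 3 && u > cinit[state]) ++state;
  out[0] = bases[state];
  for (int i = 1; i < n; ++i) {
    u = unif_rand();
    int s = 0;
    while (s < 3 && u > ctrans[state][s]) ++s;
    state = s;
    out[i] = bases[state];
  }
  return CharacterVector::create(out);
}
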