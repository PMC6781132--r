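#include <Rcpp.h>
using namespace Rcpp;

// Generation loop of the two-deme allele-frequency simulator.
// Mutation first, then migration (synchronous across demes), then a
// binomial draw of the next generation's allele-copy counts. Uses R's
// rbinom in the same deme-major order as the vectorised R implementation,
// so for a given seed the two engines produce identical trajectories.

// [[Rcpp::export]]
IntegerMatrix forward_sim_cpp(IntegerMatrix counts0, int copies, double u,
                              double m, int n_generations) {
  const int D = counts0.nrow(), L = counts0.ncol();
  NumericMatrix p(D, L), pe(D, L);
  IntegerMatrix counts(clone(counts0));

  for (int g = 0; g < n_generations; ++g) {
    for (int d = 0; d < D; ++d)
      for (int l = 0; l < L; ++l) {
        double f = static_cast<double>(counts(d, l)) / copies;
        p(d, l) = f * (1.0 - u) + (1.0 - f) * u;
      }
    for (int d = 0; d < D; ++d) {
      int other = 1 - d;  // two demes
      for (int l = 0; l < L; ++l)
        pe(d, l) = (1.0 - m) * p(d, l) + m * p(other, l);
    }
    // R's vectorised rbinom fills column-major over (deme, locus)
    for (int l = 0; l < L; ++l)
      for (int d = 0; d < D; ++d)
        counts(d, l) = static_cast<int>(R::rbinom(copies, pe(d, l)));
  }
  return counts;
}
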