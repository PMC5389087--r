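#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Inject per-base substitution errors at `rate` using geometric skipping.
// Uses R's RNG so set.seed() governs the draw.
// [[Rcpp::export]]
CharacterVector cpp_add_errors(CharacterVector reads, double rate) {
  const char bases[4] = {'A', 'C', 'G', 'T'};
  if (rate <= 0.0) return reads;
  const double log1m = std::log1p(-rate);
  CharacterVector out(reads.size());
  std::string s;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    s.assign(CHAR(STRING_ELT(reads, i)));
    const R_xlen_t n = (R_xlen_t)s.size();
    // jump from error to error: P(gap) geometric(rate)
    double pos = std::floor(std::log(unif_rand()) / log1m);
    while (pos < n) {
      const R_xlen_t j = (R_xlen_t)pos;
      char cur = s[j];
      char sub;
      do {
        sub = bases[(int)(unif_rand() * 4.0) & 3];
      } while (sub == cur);
      s[j] = sub;
      pos += 1.0 + std::floor(std::log(unif_rand()) / log1m);
    }
    out[i] = s;
  }
  return out;
}
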