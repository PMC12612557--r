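#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Counter-based uniform generator (splitmix64 finalizer chain).
// Each draw is a pure hash of (seed, person id, cycle, channel), so a
// person's stream is independent of cohort storage order and of how many
// other draws were made -- the property the simulator relies on for
// common-random-number comparisons and permutation invariance.

static inline uint64_t mix64(uint64_t z) {
  z += 0x9e3779b97f4a7c15ULL;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

//' Counter-based uniforms keyed by (seed, id, cycle, channel)
//'
//' @param seed master seed (non-negative, < 2^31)
//' @param id integer person identifiers
//' @param cycle cycle counter (e.g. current age)
//' @param channel draw-purpose channel code
//' @return numeric vector of uniforms in [0, 1), one per id
//' @keywords internal
// [[Rcpp::export]]
NumericVector cb_uniform(double seed, IntegerVector id, int cycle, int channel) {
  uint64_t base = mix64(mix64((uint64_t)seed) ^
                        mix64(((uint64_t)(uint32_t)cycle << 20) +
                              (uint64_t)(uint32_t)channel));
  R_xlen_t n = id.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t z = mix64(base ^ mix64((uint64_t)(uint32_t)id[i] + 0x51ed270b
    ));
    out[i] = (double)(z >> 11) * (1.0 / 9007199254740992.0);
  }
  return out;
}
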