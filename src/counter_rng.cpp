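#include <Rcpp.h>
#include <cstdint>

// Counter-based uniform generator: each (seed, record id, slot, draw) tuple is
// hashed independently through the splitmix64 finalizer, so record i's draws
// are identical whatever the cohort size and whatever was generated before it.

static inline uint64_t mix64(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline double u01(uint64_t key) {
  // 53 random bits, offset to the open interval (0, 1)
  return (static_cast<double>(key >> 11) + 0.5) / 9007199254740992.0;
}

// [[Rcpp::export(name = ".cb_runif_cpp")]]
Rcpp::NumericVector cb_runif_cpp(double seed, Rcpp::IntegerVector id,
                                 int slot, int draw) {
  const uint64_t s0 = mix64(static_cast<uint64_t>(seed));
  const uint64_t s1 = mix64(s0 ^ (static_cast<uint64_t>(slot) << 32 |
                                  static_cast<uint64_t>(draw)));
  R_xlen_t n = id.size();
  Rcpp::NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = u01(mix64(s1 ^ static_cast<uint64_t>(id[i])));
  }
  return out;
}
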