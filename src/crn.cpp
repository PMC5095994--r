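#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Counter-based uniform streams for common-random-numbers simulation.
// Each draw is a pure function of (master seed, actor id, stream id, counter),
// so draws are identical across scenarios, counterfactual twins and actor
// processing orders -- the property the CRN design of the engine relies on.

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline double u01(uint64_t seed, uint64_t id, uint64_t stream,
                         uint64_t counter) {
  uint64_t h = splitmix64(seed ^ splitmix64(id));
  h = splitmix64(h ^ splitmix64(stream + 0x632BE59BD9B4E019ULL));
  h = splitmix64(h ^ splitmix64(counter + 0x9E3779B97F4A7C15ULL));
  // strictly inside (0,1): 53-bit mantissa, offset by half an ulp
  return ((h >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

// [[Rcpp::export(name = ".crn_uniform")]]
NumericVector crn_uniform_cpp(double master_seed, NumericVector actor_id,
                              int stream, NumericVector counter) {
  R_xlen_t n = actor_id.size();
  if (counter.size() != n && counter.size() != 1)
    stop("counter must have length 1 or length(actor_id)");
  NumericVector out(n);
  uint64_t seed = (uint64_t)(int64_t)master_seed;
  uint64_t str = (uint64_t)stream;
  bool scalar_ctr = (counter.size() == 1);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t id = (uint64_t)(int64_t)actor_id[i];
    uint64_t ctr = (uint64_t)(int64_t)(scalar_ctr ? counter[0] : counter[i]);
    out[i] = u01(seed, id, str, ctr);
  }
  return out;
}
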