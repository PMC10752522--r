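#ifndef SPLENOSIM_RNG_H
#define SPLENOSIM_RNG_H

#include <cstdint>
#include <cmath>

// Counter-based RNG (splitmix64 finalizer chain). Stateless: every draw is a
// pure function of (seed, stream, step, index), which makes runs bitwise
// reproducible and restartable from any step without serializing RNG state.
namespace simrng {

inline uint64_t mix(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

inline uint64_t draw_u64(uint64_t seed, uint64_t stream, uint64_t step,
                         uint64_t idx) {
  uint64_t h = mix(seed ^ 0x853C49E6748FEA9BULL);
  h = mix(h ^ stream);
  h = mix(h ^ step);
  h = mix(h ^ idx);
  return h;
}

// Uniform in [0, 1)
inline double unif(uint64_t seed, uint64_t stream, uint64_t step,
                   uint64_t idx) {
  return (draw_u64(seed, stream, step, idx) >> 11) *
         (1.0 / 9007199254740992.0);
}

// Standard normal via Box-Muller; consumes indices (2*idx, 2*idx+1).
inline double gauss(uint64_t seed, uint64_t stream, uint64_t step,
                    uint64_t idx) {
  double u1 = ((draw_u64(seed, stream, step, 2 * idx) >> 11) + 1.0) *
              (1.0 / 9007199254740993.0);  // (0, 1]
  double u2 = unif(seed, stream, step, 2 * idx + 1);
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
}

// Named streams
enum Stream : uint64_t {
  STREAM_INIT = 1,
  STREAM_FLUID = 2,
  STREAM_BOND_FORM = 3,
  STREAM_BOND_DISS = 4,
  STREAM_DPD = 5
};

}  // namespace simrng

#endif
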