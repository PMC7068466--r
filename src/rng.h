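#ifndef LBPNOTES_RNG_H
#define LBPNOTES_RNG_H

#include <cstdint>
#include <cmath>

// Small deterministic RNG (xoshiro-style splitmix/mt-free) so results are
// bit-reproducible for a given seed independently of R's RNG state.
class DetRNG {
 public:
  explicit DetRNG(uint64_t seed) : state_(seed ? seed : 0x9E3779B97F4A7C15ULL) {
    // warm up
    for (int i = 0; i < 8; ++i) next();
  }

  uint64_t next() {  // splitmix64
    uint64_t z = (state_ += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  double unif() {  // in [0, 1)
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }

  // integer in [0, n)
  int below(int n) { return static_cast<int>(unif() * n) % n; }

  double normal() {  // Box-Muller, one draw per call (discard pair partner)
    double u1 = unif(), u2 = unif();
    while (u1 <= 0.0) u1 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }

 private:
  uint64_t state_;
};

#endif
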