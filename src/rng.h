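#ifndef CMTRADEOFF_RNG_H
#define CMTRADEOFF_RNG_H

#include <cstdint>
#include <cmath>

// Self-contained counter-seeded RNG so lookup-table cells can each own an
// independent, platform-stable stream derived from (seed, cell index).
// xoshiro256++ seeded through splitmix64; normals via Box-Muller.

namespace cmt {

inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

class Rng {
 public:
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
    have_spare = false;
  }

  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in (0, 1); never exactly 0 so log() below is safe
  double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  double normal() {
    if (have_spare) {
      have_spare = false;
      return spare;
    }
    double u = unif();
    double v = unif();
    double r = std::sqrt(-2.0 * std::log(u));
    double a = 6.283185307179586476925286766559 * v;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }

 private:
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t s[4];
  double spare;
  bool have_spare;
};

// stable stream id for (seed, index) pairs
inline uint64_t stream_seed(uint64_t seed, uint64_t index) {
  uint64_t x = seed * 0x9E3779B97F4A7C15ULL + index + 0x632BE59BD9B4E019ULL;
  uint64_t h = splitmix64(x);
  return h ^ splitmix64(x);
}

}  // namespace cmt

#endif
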