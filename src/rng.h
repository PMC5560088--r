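#pragma once
#include <cstdint>
#include <vector>
#include <utility>

// Deterministic, platform-independent RNG (xorshift128+ seeded via splitmix64).
// Used everywhere compiled code needs randomness so results are reproducible
// from an integer seed independently of R's RNG state.
struct XRng {
  uint64_t s0, s1;

  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  explicit XRng(uint64_t seed) {
    uint64_t x = seed;
    s0 = splitmix(x);
    s1 = splitmix(x);
    if (!(s0 | s1)) s1 = 0x9E3779B97F4A7C15ULL;
  }

  uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }

  // uniform integer in [0, n); modulo bias is negligible for the small n used here
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }

  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }

  template <typename T> void shuffle(std::vector<T> &v) {
    for (int i = static_cast<int>(v.size()) - 1; i > 0; --i) {
      int j = below(i + 1);
      std::swap(v[static_cast<size_t>(i)], v[static_cast<size_t>(j)]);
    }
  }
};

// stable derivation of a stream seed from (base seed, stream index)
inline uint64_t derive_seed(uint64_t seed, uint64_t idx) {
  uint64_t x = seed * 0x2545F4914F6CDD1DULL + idx;
  return XRng::splitmix(x);
}
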