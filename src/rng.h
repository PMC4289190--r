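#ifndef ZEBRASCREEN_RNG_H
#define ZEBRASCREEN_RNG_H

#include <cstdint>

// splitmix64 counter-based generator: deterministic across platforms,
// cheap substreams (one stream per tree / per draw site).
struct ZsRng {
  uint64_t state;
  explicit ZsRng(uint64_t seed) : state(seed) {
    for (int i = 0; i < 4; ++i) next();  // burn-in decorrelates close seeds
  }
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform on the open interval (0, 1)
  double unif_open() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  int randint(int n) { return static_cast<int>(next() % (uint64_t)n); }
};

#endif
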