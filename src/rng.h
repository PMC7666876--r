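#ifndef MELSCI_RNG_H
#define MELSCI_RNG_H

#include <cstdint>
#include <cmath>

// Self-contained counter-seeded RNG so that simulations are reproducible from
// an explicit integer seed, independent of R's global RNG state.
// Generator: xoshiro256++ (Blackman & Vigna), seeded through splitmix64.
// Normals: 128-strip ziggurat with an exact tail sampler.

namespace melsci {

struct Rng {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  // seed: user-visible seed; stream: sub-generator index so that distinct
  // stacks / sensors / components get independent, reproducible streams.
  void seed(uint64_t seed_, uint64_t stream) {
    uint64_t x = seed_ ^ (0xD2B74407B1CE6E93ULL * (stream + 1));
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
    // avoid the (practically impossible) all-zero state
    if ((s[0] | s[1] | s[2] | s[3]) == 0) s[0] = 1;
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
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

  // uniform in (0,1), 53-bit resolution, never exactly 0 or 1
  inline double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

// Ziggurat tables (Doornik's ZIGNOR layout, 128 strips)
struct Ziggurat {
  static const int C = 128;
  double X[C + 1];   // strip right edges, X[0] = V/f(R) > R, X[C] = 0
  double Ratio[C];   // X[i+1]/X[i]

  Ziggurat() {
    const double R = 3.442619855899;
    const double V = 9.91256303526217e-3;
    double f = std::exp(-0.5 * R * R);
    X[0] = V / f;
    X[1] = R;
    X[C] = 0.0;
    for (int i = 2; i < C; ++i) {
      X[i] = std::sqrt(-2.0 * std::log(V / X[i - 1] +
                                       std::exp(-0.5 * X[i - 1] * X[i - 1])));
    }
    for (int i = 0; i < C; ++i) Ratio[i] = X[i + 1] / X[i];
  }
};

inline const Ziggurat &zigg_tables() {
  static const Ziggurat z;
  return z;
}

inline double norm_tail(Rng &r, double R, bool negative) {
  double x, y;
  do {
    x = std::log(r.unif()) / R;  // x <= 0
    y = std::log(r.unif());
  } while (-2.0 * y < x * x);
  return negative ? x - R : R - x;
}

inline double rnorm1(Rng &r) {
  const Ziggurat &z = zigg_tables();
  const double R = 3.442619855899;
  for (;;) {
    uint64_t bits = r.next();
    int i = (int)(bits & 0x7F);
    double u = 2.0 * (((bits >> 11) + 0.5) * (1.0 / 9007199254740992.0)) - 1.0;
    if (std::fabs(u) < z.Ratio[i]) return u * z.X[i];
    if (i == 0) return norm_tail(r, R, u < 0.0);
    double x = u * z.X[i];
    double f0 = std::exp(-0.5 * (z.X[i] * z.X[i] - x * x));
    double f1 = std::exp(-0.5 * (z.X[i + 1] * z.X[i + 1] - x * x));
    if (f1 + r.unif() * (f0 - f1) < 1.0) return x;
  }
}

}  // namespace melsci

#endif
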