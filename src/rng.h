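#ifndef ABGAS_RNG_H
#define ABGAS_RNG_H

#include <cstdint>
#include <cmath>

// Small self-contained RNG (splitmix64 seeding + xoshiro256++) so that seeded
// results are bit-reproducible across platforms and standard-library versions.
namespace abgas {

struct Rng {
  uint64_t s[4];

  explicit Rng(uint64_t seed) {
    // splitmix64 to expand the seed
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }

  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }

  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in [0, 1)
  double unif() {
    return (next() >> 11) * 0x1.0p-53;
  }

  // standard normal via Marsaglia polar method (cached pair)
  bool have_cached = false;
  double cached = 0.0;
  double norm() {
    if (have_cached) {
      have_cached = false;
      return cached;
    }
    double u, v, s2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    double f = std::sqrt(-2.0 * std::log(s2) / s2);
    cached = v * f;
    have_cached = true;
    return u * f;
  }

  // uniform random rotation matrix (row-major 3x3) via Shoemake quaternions
  void rotation(double R[9]) {
    double u1 = unif(), u2 = unif(), u3 = unif();
    double q0 = std::sqrt(1.0 - u1) * std::sin(2.0 * M_PI * u2);
    double q1 = std::sqrt(1.0 - u1) * std::cos(2.0 * M_PI * u2);
    double q2 = std::sqrt(u1) * std::sin(2.0 * M_PI * u3);
    double q3 = std::sqrt(u1) * std::cos(2.0 * M_PI * u3);
    R[0] = 1 - 2 * (q2 * q2 + q3 * q3);
    R[1] = 2 * (q1 * q2 - q0 * q3);
    R[2] = 2 * (q1 * q3 + q0 * q2);
    R[3] = 2 * (q1 * q2 + q0 * q3);
    R[4] = 1 - 2 * (q1 * q1 + q3 * q3);
    R[5] = 2 * (q2 * q3 - q0 * q1);
    R[6] = 2 * (q1 * q3 - q0 * q2);
    R[7] = 2 * (q2 * q3 + q0 * q1);
    R[8] = 1 - 2 * (q1 * q1 + q2 * q2);
  }
};

}  // namespace abgas

#endif
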