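#ifndef RESERVOIRTASK_RNG_H
#define RESERVOIRTASK_RNG_H

#include <cstdint>
#include <cmath>

// Counter-based stream RNG: xoshiro256++ seeded through splitmix64 from a
// (master seed, stream id, counter) key.  Streams keyed this way are
// independent of call order, so a manipulation that skips one consumer's
// draws cannot shift another consumer's sequence.

namespace rtrng {

inline std::uint64_t splitmix64(std::uint64_t &state) {
  std::uint64_t z = (state += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

class Xoshiro256 {
 public:
  Xoshiro256(std::uint64_t master, std::uint64_t stream, std::uint64_t counter) {
    std::uint64_t sm = master ^ (0x9e3779b97f4a7c15ULL * (stream + 1))
                              ^ (0xbf58476d1ce4e5b9ULL * (counter + 1));
    for (int i = 0; i < 4; ++i) s_[i] = splitmix64(sm);
  }

  std::uint64_t next() {
    const std::uint64_t result = rotl(s_[0] + s_[3], 23) + s_[0];
    const std::uint64_t t = s_[1] << 17;
    s_[2] ^= s_[0];
    s_[3] ^= s_[1];
    s_[1] ^= s_[2];
    s_[0] ^= s_[3];
    s_[2] ^= t;
    s_[3] = rotl(s_[3], 45);
    return result;
  }

  // uniform on [0, 1)
  double unif() { return (next() >> 11) * 0x1.0p-53; }

  // standard normal via Box-Muller; draws are consumed in pairs
  double norm() {
    if (have_spare_) {
      have_spare_ = false;
      return spare_;
    }
    double u1, u2;
    do { u1 = unif(); } while (u1 <= 0.0);
    u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double theta = 6.283185307179586476925286766559 * u2;
    spare_ = r * std::sin(theta);
    have_spare_ = true;
    return r * std::cos(theta);
  }

 private:
  static std::uint64_t rotl(std::uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  std::uint64_t s_[4];
  double spare_ = 0.0;
  bool have_spare_ = false;
};

}  // namespace rtrng

#endif
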