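#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Self-contained RNG (splitmix64-seeded xoshiro256++, Box-Muller normals):
// bit-reproducible for a given seed on any platform, independent of the C++
// standard library's distribution implementations, and fast enough for the
// ~1.5e8 samples of a full four-stack imaging session.
namespace {

struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
    // splitmix64 expansion of the seed
    for (int i = 0; i < 4; ++i) {
      seed += 0x9E3779B97F4A7C15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1]
  double unif_pos() {
    return ((next() >> 11) + 1.0) * 0x1.0p-53;
  }
};

// Marsaglia-Tsang ziggurat normal sampler (128 layers) on top of the
// xoshiro stream; ~99% of draws take the one-multiply fast path.
struct NormalGen {
  Xoshiro256pp rng;
  uint32_t kn[128];
  double wn[128], fn[128];
  explicit NormalGen(uint64_t seed) : rng(seed) {
    const double m = 2147483648.0;          // 2^31
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m);
    kn[1] = 0;
    wn[0] = q / m;
    wn[127] = dn / m;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m;
    }
  }
  double next() {
    for (;;) {
      const int32_t hz = (int32_t)(uint32_t)(rng.next() >> 32);
      const int i = hz & 127;
      if ((uint32_t)std::abs(hz) < kn[i]) return hz * wn[i];
      if (i == 0) {                          // tail beyond +-3.4426
        const double r = 3.442619855899;
        double x, y;
        do {
          x = -std::log(rng.unif_pos()) / r;
          y = -std::log(rng.unif_pos());
        } while (y + y < x * x);
        return hz > 0 ? r + x : -(r + x);
      }
      const double x = hz * wn[i];
      if (fn[i] + rng.unif_pos() * (fn[i - 1] - fn[i]) <
          std::exp(-0.5 * x * x))
        return x;
    }
  }
};

} // namespace

// Periodic-stimulus reflectance movie, one (eye x direction) acquisition.
// Per pixel p and frame t (0-based):
//   R[t, p] = r0 * (1 + a[p] * cos(2*pi*f_rel*t + phase)) + noise_sd * N(0,1)
// f_rel = stim_freq / frame_rate (cycles per frame).
// [[Rcpp::export]]
NumericVector gen_stack_cpp(NumericVector amp, int nt, double f_rel,
                            double phase, double r0, double noise_sd,
                            int seed) {
  const int np = amp.size();
  NumericVector out((R_xlen_t)nt * np);
  std::vector<double> cosv(nt);
  const double w = 2.0 * M_PI * f_rel;
  for (int t = 0; t < nt; ++t) cosv[t] = std::cos(w * t + phase);

  NormalGen gen((uint64_t)(uint32_t)seed);
  double* o = REAL(out);
  if (noise_sd > 0.0) {
    for (int p = 0; p < np; ++p) {
      const double a = amp[p];
      double* col = o + (R_xlen_t)nt * p;
      for (int t = 0; t < nt; ++t)
        col[t] = r0 * (1.0 + a * cosv[t]) + noise_sd * gen.next();
    }
  } else {
    for (int p = 0; p < np; ++p) {
      const double a = amp[p];
      double* col = o + (R_xlen_t)nt * p;
      for (int t = 0; t < nt; ++t) col[t] = r0 * (1.0 + a * cosv[t]);
    }
  }
  return out;
}

// Single-frequency DFT projection: for each pixel column of `frames`
// (nt x np, column-major), returns re = sum_t x_t cos(2*pi*k*t/nt),
// im = -sum_t x_t sin(2*pi*k*t/nt), and x0 = sum_t x_t.
// [[Rcpp::export]]
List dft_bin_cpp(NumericVector frames, int nt, int k) {
  const R_xlen_t np = frames.size() / nt;
  NumericVector re(np), im(np), x0(np);
  std::vector<double> cv(nt), sv(nt);
  const double w = 2.0 * M_PI * (double)k / (double)nt;
  for (int t = 0; t < nt; ++t) {
    cv[t] = std::cos(w * t);
    sv[t] = std::sin(w * t);
  }
  const double* f = REAL(frames);
  for (R_xlen_t p = 0; p < np; ++p) {
    const double* col = f + (R_xlen_t)nt * p;
    double sre = 0.0, sim = 0.0, s0 = 0.0;
    for (int t = 0; t < nt; ++t) {
      sre += col[t] * cv[t];
      sim -= col[t] * sv[t];
      s0 += col[t];
    }
    re[p] = sre;
    im[p] = sim;
    x0[p] = s0;
  }
  return List::create(_["re"] = re, _["im"] = im, _["x0"] = x0);
}
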