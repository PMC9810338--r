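#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static inline bool inside_capsule(double x, double y, double z,
                                  double half_cyl, double r2);
static inline void fold_into_capsule(double &x, double &y, double &z,
                                     double half_cyl, double r);
struct Rng;
static inline void draw_uniform_inside(Rng &rng, double L, double d,
                                       double &x, double &y, double &z);

// ---------------------------------------------------------------------------
// Self-contained RNG: xoshiro256++ seeded via splitmix64, with a ziggurat
// normal sampler (Marsaglia & Tsang, 128 layers). Keeps per-particle
// substreams deterministic and platform-independent.
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t sm = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(sm);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next64() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { // (0, 1)
    return ((next64() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

struct Ziggurat {
  uint32_t kn[128];
  double wn[128], fn[128];
  Ziggurat() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn, vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
  inline double normal(Rng &rng) const {
    const double r = 3.442619855899;
    for (;;) {
      int32_t hz = (int32_t)(rng.next64() >> 32);
      uint32_t iz = hz & 127;
      if ((uint32_t)std::abs(hz) < kn[iz]) return hz * wn[iz];
      if (iz == 0) { // tail
        double x, y;
        do {
          x = -std::log(rng.unif()) / r;
          y = -std::log(rng.unif());
        } while (y + y < x * x);
        return (hz > 0) ? r + x : -r - x;
      }
      double x = hz * wn[iz];
      if (fn[iz] + rng.unif() * (fn[iz - 1] - fn[iz]) <
          std::exp(-0.5 * x * x)) {
        return x;
      }
    }
  }
};

static const Ziggurat zig;

// ---------------------------------------------------------------------------
// Iterative radix-2 complex FFT (power-of-two length), used by the
// circulant-embedding synthesis of fractional Gaussian noise.
// ---------------------------------------------------------------------------

struct FFTPlan {
  int m;
  std::vector<double> wre, wim;
  std::vector<int> rev;
  explicit FFTPlan(int m_) : m(m_), wre(m_ / 2), wim(m_ / 2), rev(m_) {
    if (m & (m - 1)) stop("FFT length must be a power of two");
    for (int j = 0; j < m / 2; ++j) {
      double a = -2.0 * M_PI * j / m;
      wre[j] = std::cos(a);
      wim[j] = std::sin(a);
    }
    rev[0] = 0;
    for (int i = 1; i < m; ++i) {
      rev[i] = (rev[i >> 1] >> 1) | ((i & 1) ? (m >> 1) : 0);
    }
  }
  void fft(double *re, double *im) const {
    for (int i = 0; i < m; ++i) {
      int j = rev[i];
      if (j > i) { std::swap(re[i], re[j]); std::swap(im[i], im[j]); }
    }
    for (int len = 2; len <= m; len <<= 1) {
      const int half = len >> 1, stride = m / len;
      for (int i = 0; i < m; i += len) {
        for (int j = 0; j < half; ++j) {
          const double wr = wre[j * stride], wi = wim[j * stride];
          const int a = i + j, b = a + half;
          const double tr = re[b] * wr - im[b] * wi;
          const double ti = re[b] * wi + im[b] * wr;
          re[b] = re[a] - tr; im[b] = im[a] - ti;
          re[a] += tr; im[a] += ti;
        }
      }
    }
  }
};

// One circulant synthesis: fill the buffers with sq[k] * complex white
// noise, transform; Re and Im of the first n entries are two independent
// fGn paths.
static void synth_pair(const double *sq, int m, const FFTPlan &plan,
                       Rng &rng, double *re, double *im) {
  for (int k = 0; k < m; ++k) {
    re[k] = sq[k] * zig.normal(rng);
    im[k] = sq[k] * zig.normal(rng);
  }
  plan.fft(re, im);
}

// [[Rcpp::export]]
NumericVector cpp_fft_complex(NumericVector re_in, NumericVector im_in) {
  // small helper used to validate the internal FFT against R's fft()
  int m = re_in.size();
  std::vector<double> re(re_in.begin(), re_in.end());
  std::vector<double> im(im_in.begin(), im_in.end());
  FFTPlan plan(m);
  plan.fft(re.data(), im.data());
  NumericVector out(2 * m);
  for (int i = 0; i < m; ++i) { out[i] = re[i]; out[m + i] = im[i]; }
  return out;
}

// Draw n_paths independent fGn paths of length n from the circulant
// square-root spectrum sq (length m, already divided by sqrt(m)).
// [[Rcpp::export]]
NumericMatrix cpp_fgn_paths(int n, NumericVector sq, int n_paths,
                            double seed) {
  const int m = sq.size();
  if (m < 2 * n) stop("embedding shorter than 2 n");
  FFTPlan plan(m);
  uint64_t mix = (uint64_t)(long long)seed * 0x9E3779B97F4A7C15ULL + 0x51ULL;
  Rng rng(mix);
  std::vector<double> re(m), im(m);
  NumericMatrix out(n, n_paths);
  for (int j = 0; j < n_paths; j += 2) {
    synth_pair(REAL(sq), m, plan, rng, re.data(), im.data());
    for (int t = 0; t < n; ++t) out(t, j) = re[t];
    if (j + 1 < n_paths) for (int t = 0; t < n; ++t) out(t, j + 1) = im[t];
  }
  return out;
}

// Full fBm acquisition: per particle, three fGn increment streams are
// synthesized (paths recycled in pairs across axes/particles), cumulated
// under reflective confinement, and the summed confocal intensity recorded
// at every step.
// [[Rcpp::export]]
NumericVector cpp_fbm_trace(int n_steps, NumericVector sq,
                            double L, double d,
                            double cx, double cy, double cz,
                            double omega0, double z0,
                            int n_particles, double seed,
                            Nullable<NumericMatrix> init = R_NilValue) {
  const int m = sq.size();
  if (m < 2 * n_steps) stop("embedding shorter than 2 n");
  FFTPlan plan(m);
  uint64_t mix = (uint64_t)(long long)seed * 0x9E3779B97F4A7C15ULL + 0xFB2ULL;
  Rng rng(mix);
  NumericMatrix init_pos;
  bool has_init = init.isNotNull();
  if (has_init) init_pos = NumericMatrix(init);

  const double half_cyl = 0.5 * (L - d), r = 0.5 * d;
  const double inv_w2 = 1.0 / (omega0 * omega0), inv_z2 = 1.0 / (z0 * z0);
  NumericVector intensity(n_steps);
  double *I = REAL(intensity);

  std::vector<double> re(m), im(m);
  std::vector<double> paths(3 * (size_t)n_steps);
  std::vector<double> spare(n_steps);
  bool have_spare = false;

  for (int i = 0; i < n_particles; ++i) {
    // fetch three paths, consuming syntheses in pairs
    int got = 0;
    if (have_spare) {
      std::copy(spare.begin(), spare.end(), paths.begin());
      got = 1;
      have_spare = false;
    }
    while (got < 3) {
      synth_pair(REAL(sq), m, plan, rng, re.data(), im.data());
      std::copy(re.begin(), re.begin() + n_steps,
                paths.begin() + (size_t)got * n_steps);
      ++got;
      if (got < 3) {
        std::copy(im.begin(), im.begin() + n_steps,
                  paths.begin() + (size_t)got * n_steps);
        ++got;
      } else {
        std::copy(im.begin(), im.begin() + n_steps, spare.begin());
        have_spare = true;
      }
    }
    double x, y, z;
    if (has_init) {
      x = init_pos(i, 0); y = init_pos(i, 1); z = init_pos(i, 2);
    } else {
      draw_uniform_inside(rng, L, d, x, y, z);
    }
    const double *px = paths.data();
    const double *py = paths.data() + n_steps;
    const double *pz = paths.data() + 2 * (size_t)n_steps;
    for (int t = 0; t < n_steps; ++t) {
      x += px[t]; y += py[t]; z += pz[t];
      fold_into_capsule(x, y, z, half_cyl, r);
      double dx = x - cx, dy = y - cy, dz = z - cz;
      double q = 2.0 * ((dx * dx + dy * dy) * inv_w2 + dz * dz * inv_z2);
      if (q < 30.0) I[t] += std::exp(-q);
    }
  }
  return intensity;
}

// capsule test: cylinder of length L-d along x, radius d/2, hemispherical caps
static inline bool inside_capsule(double x, double y, double z,
                                  double half_cyl, double r2) {
  double ax = std::fabs(x);
  if (ax <= half_cyl) {
    return y * y + z * z <= r2;
  }
  double ex = ax - half_cyl;
  return ex * ex + y * y + z * z <= r2;
}

// specular fold of a point outside the capsule across the capsule surface;
// the fold is radial about the closest point on the axis segment, which is
// exact for the cylindrical wall and for the spherical caps
static inline void fold_into_capsule(double &x, double &y, double &z,
                                     double half_cyl, double r) {
  const double r2 = r * r;
  for (int k = 0; k < 100 && !inside_capsule(x, y, z, half_cyl, r2); ++k) {
    double ax = (x > half_cyl) ? half_cyl : ((x < -half_cyl) ? -half_cyl : x);
    double vx = x - ax, vy = y, vz = z;
    double dist = std::sqrt(vx * vx + vy * vy + vz * vz);
    if (dist <= 0) return;
    double f = (2.0 * r - dist) / dist; // may be negative for huge steps
    x = ax + vx * f;
    y = vy * f;
    z = vz * f;
  }
  if (!inside_capsule(x, y, z, half_cyl, r2)) { // pathological step: clamp
    double ax = (x > half_cyl) ? half_cyl : ((x < -half_cyl) ? -half_cyl : x);
    double vx = x - ax, vy = y, vz = z;
    double dist = std::sqrt(vx * vx + vy * vy + vz * vz);
    double f = 0.999 * r / dist;
    x = ax + vx * f; y = vy * f; z = vz * f;
  }
}

static inline void draw_uniform_inside(Rng &rng, double L, double d,
                                       double &x, double &y, double &z) {
  const double half_cyl = 0.5 * (L - d), r = 0.5 * d, r2 = r * r;
  do {
    x = (rng.unif() - 0.5) * L;
    y = (rng.unif() * 2.0 - 1.0) * r;
    z = (rng.unif() * 2.0 - 1.0) * r;
  } while (!inside_capsule(x, y, z, half_cyl, r2));
}

// Simulate the summed confocal intensity of n_particles independent Brownian
// walkers confined to the capsule. Each particle uses its own deterministic
// RNG substream derived from `seed`. boundary: 0 = redraw, 1 = reflect.
// Returns the intensity trace plus a redraw-exhaustion counter.
// [[Rcpp::export]]
List cpp_bd_trace(int n_steps, double dt, double D, double L, double d,
                  double cx, double cy, double cz,
                  double omega0, double z0,
                  int n_particles, double seed, int boundary,
                  double bleach_rate, int max_redraw,
                  Nullable<NumericMatrix> init = R_NilValue) {
  NumericMatrix init_pos;
  bool has_init = init.isNotNull();
  if (has_init) init_pos = NumericMatrix(init);
  NumericVector intensity(n_steps);
  double *I = REAL(intensity);
  const double half_cyl = 0.5 * (L - d), r = 0.5 * d, r2 = r * r;
  const double sd = std::sqrt(2.0 * D * dt);
  const double inv_w2 = 1.0 / (omega0 * omega0), inv_z2 = 1.0 / (z0 * z0);
  long exhausted = 0;

  for (int i = 0; i < n_particles; ++i) {
    // per-particle substream: mix the user seed with the particle index
    uint64_t mix = (uint64_t)(long long)seed;
    mix = mix * 0x100000001B3ULL + (uint64_t)(i + 1);
    Rng rng(mix);
    // separate substream for bleaching decisions, so that runs with and
    // without bleaching share identical trajectories at equal seed
    Rng rng_bleach(mix ^ 0xB1EAC4B1EAC4ULL);
    double x, y, z;
    if (has_init) {
      x = init_pos(i, 0); y = init_pos(i, 1); z = init_pos(i, 2);
    } else {
      draw_uniform_inside(rng, L, d, x, y, z);
    }
    for (int t = 0; t < n_steps; ++t) {
      if (sd > 0) {
        if (boundary == 0) { // redraw
          double nx, ny, nz;
          int k = 0;
          do {
            nx = x + sd * zig.normal(rng);
            ny = y + sd * zig.normal(rng);
            nz = z + sd * zig.normal(rng);
            ++k;
          } while (!inside_capsule(nx, ny, nz, half_cyl, r2) && k < max_redraw);
          if (inside_capsule(nx, ny, nz, half_cyl, r2)) {
            x = nx; y = ny; z = nz;
          } else {
            ++exhausted; // leave particle in place
          }
        } else { // reflect
          x += sd * zig.normal(rng);
          y += sd * zig.normal(rng);
          z += sd * zig.normal(rng);
          fold_into_capsule(x, y, z, half_cyl, r);
        }
      }
      double dx = x - cx, dy = y - cy, dz = z - cz;
      double q = 2.0 * ((dx * dx + dy * dy) * inv_w2 + dz * dz * inv_z2);
      if (q < 30.0) { // exp(-30) ~ 1e-13: below any detectable contribution
        double ig = std::exp(-q);
        I[t] += ig;
        if (bleach_rate > 0 && rng_bleach.unif() < bleach_rate * ig * dt) {
          break; // emitter irreversibly dark; it contributes nothing further
        }
      }
    }
  }
  return List::create(_["intensity"] = intensity,
                      _["redraw_exhausted"] = (double)exhausted);
}

// Apply precomputed per-axis increments (fractional Gaussian noise) to one
// particle with reflective (specular fold) boundaries, accumulating its
// confocal intensity into `intensity` (modified in place).
// [[Rcpp::export]]
NumericVector cpp_fbm_accumulate(NumericVector incx, NumericVector incy,
                                 NumericVector incz, NumericVector p0,
                                 double L, double d,
                                 double cx, double cy, double cz,
                                 double omega0, double z0,
                                 NumericVector intensity) {
  const int n = incx.size();
  if (intensity.size() != n) stop("intensity length must match increments");
  const double half_cyl = 0.5 * (L - d), r = 0.5 * d;
  const double inv_w2 = 1.0 / (omega0 * omega0), inv_z2 = 1.0 / (z0 * z0);
  double x = p0[0], y = p0[1], z = p0[2];
  double *I = REAL(intensity);
  const double *ix = REAL(incx), *iy = REAL(incy), *iz = REAL(incz);
  for (int t = 0; t < n; ++t) {
    x += ix[t]; y += iy[t]; z += iz[t];
    fold_into_capsule(x, y, z, half_cyl, r);
    double dx = x - cx, dy = y - cy, dz = z - cz;
    double q = 2.0 * ((dx * dx + dy * dy) * inv_w2 + dz * dz * inv_z2);
    if (q < 30.0) I[t] += std::exp(-q);
  }
  return intensity;
}

// Normalized intensity autocorrelation at integer sample lags:
// C(k) = <I(t+k) I(t)> / (<I(t+k)> <I(t)>) - 1, means over the overlap.
// [[Rcpp::export]]
NumericVector cpp_acf_lags(NumericVector trace, IntegerVector lags) {
  const int n = trace.size(), m = lags.size();
  const double *x = REAL(trace);
  NumericVector out(m);
  for (int j = 0; j < m; ++j) {
    const int k = lags[j];
    if (k < 0 || k >= n) stop("lag out of range");
    const int nk = n - k;
    double sxy = 0, sx = 0, sy = 0;
    for (int t = 0; t < nk; ++t) {
      sxy += x[t] * x[t + k];
      sx += x[t];
      sy += x[t + k];
    }
    out[j] = (double)nk * sxy / (sx * sy) - 1.0;
  }
  return out;
}
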