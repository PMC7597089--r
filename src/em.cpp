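#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Fine-path noise generator: xoshiro256++ uniforms mapped to Gaussians by the
// Marsaglia polar method. The generator is seeded from two 31-bit integers
// drawn from R's RNG stream, so every simulation remains reproducible through
// set.seed() while the 10^7-step inner loops stay cheap. rng_normals_cpp()
// exposes the identical stream to the pure-R reference simulator.
namespace {

struct XoshiroNormal {
  uint64_t s[4];
  bool have_spare = false;
  double spare = 0.0;

  XoshiroNormal(uint32_t seed1, uint32_t seed2) {
    uint64_t x = (static_cast<uint64_t>(seed1) << 32) ^ static_cast<uint64_t>(seed2);
    for (int i = 0; i < 4; ++i) {  // splitmix64 expansion
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }

  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

  inline uint64_t next_u64() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  inline double unif() { return (next_u64() >> 11) * 0x1.0p-53; }

  inline double normal() {
    if (have_spare) { have_spare = false; return spare; }
    double u, v, w;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      w = u * u + v * v;
    } while (w >= 1.0 || w == 0.0);
    const double f = std::sqrt(-2.0 * std::log(w) / w);
    spare = v * f;
    have_spare = true;
    return u * f;
  }
};

}  // namespace

// [[Rcpp::export]]
NumericVector rng_normals_cpp(int n, int seed1, int seed2) {
  XoshiroNormal rng(static_cast<uint32_t>(seed1), static_cast<uint32_t>(seed2));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.normal();
  return out;
}

// Euler-Maruyama for affine models: drift b(x) = B x + c, constant diffusion
// matrix S (d x r). Returns the full fine path (one row per step).
// [[Rcpp::export]]
NumericMatrix em_affine_cpp(NumericMatrix B, NumericVector cvec, NumericMatrix S,
                            NumericVector x0, double h, int nsteps,
                            int seed1, int seed2) {
  const int d = x0.size(), r = S.ncol();
  XoshiroNormal rng(static_cast<uint32_t>(seed1), static_cast<uint32_t>(seed2));
  NumericMatrix out(nsteps + 1, d);
  std::vector<double> x(x0.begin(), x0.end()), xn(d), z(r);
  const double sqh = std::sqrt(h);
  for (int j = 0; j < d; ++j) out(0, j) = x[j];
  for (int k = 0; k < nsteps; ++k) {
    for (int l = 0; l < r; ++l) z[l] = rng.normal();
    for (int i = 0; i < d; ++i) {
      double drift = cvec[i], noise = 0.0;
      for (int j = 0; j < d; ++j) drift += B(i, j) * x[j];
      for (int l = 0; l < r; ++l) noise += S(i, l) * z[l];
      xn[i] = x[i] + drift * h + sqh * noise;
    }
    for (int i = 0; i < d; ++i) {
      if (!std::isfinite(xn[i]))
        stop("non-finite state (explosion) at fine step %d, axis %d", k + 1, i + 1);
      x[i] = xn[i];
      out(k + 1, i) = xn[i];
    }
  }
  return out;
}

// Fused Euler-Maruyama + convolution-by-summation for affine models: keeps
// only a ring buffer of the trailing fine states and emits the (n_obs + 1) x d
// observation matrix directly. K[l] is the window length in fine steps for
// axis l (0 = direct observation); windows are summed newest-to-oldest in the
// same order as conv_mean_cpp, so the result is bitwise identical to the
// two-stage path under the same seeds.
// [[Rcpp::export]]
NumericMatrix sim_convobs_affine_cpp(NumericMatrix B, NumericVector cvec, NumericMatrix S,
                                     NumericVector x0, double h, int burn_in, int n_obs,
                                     int stride, IntegerVector K,
                                     int seed1, int seed2) {
  const int d = x0.size(), r = S.ncol();
  XoshiroNormal rng(static_cast<uint32_t>(seed1), static_cast<uint32_t>(seed2));
  int maxK = 1;
  for (int l = 0; l < d; ++l) {
    if (K[l] > burn_in + 1) stop("convolution window exceeds the available burn-in (axis %d)", l + 1);
    if (K[l] > maxK) maxK = K[l];
  }
  const int bufsz = maxK;
  std::vector<double> buf(static_cast<size_t>(bufsz) * d);
  NumericMatrix out(n_obs + 1, d);
  std::vector<double> x(x0.begin(), x0.end()), xn(d), z(r);
  const double sqh = std::sqrt(h);
  const long long nsteps = static_cast<long long>(burn_in) +
    static_cast<long long>(n_obs) * stride;

  for (int i = 0; i < d; ++i) buf[i] = x[i];  // fine step 0
  long long next_obs_step = burn_in;
  int obs_i = 0;
  if (burn_in == 0) {  // observation 0 falls on the initial state
    for (int l = 0; l < d; ++l) out(0, l) = x[l];
    next_obs_step += stride;
    obs_i = 1;
  }

  for (long long k = 1; k <= nsteps; ++k) {
    for (int l = 0; l < r; ++l) z[l] = rng.normal();
    for (int i = 0; i < d; ++i) {
      double drift = cvec[i], noise = 0.0;
      for (int j = 0; j < d; ++j) drift += B(i, j) * x[j];
      for (int l = 0; l < r; ++l) noise += S(i, l) * z[l];
      xn[i] = x[i] + drift * h + sqh * noise;
      if (!std::isfinite(xn[i]))
        stop("non-finite state (explosion) at fine step %lld, axis %d", k, i + 1);
      x[i] = xn[i];
    }
    const int pos = static_cast<int>(k % bufsz);
    for (int i = 0; i < d; ++i) buf[static_cast<size_t>(pos) * d + i] = x[i];
    if (k == next_obs_step) {
      for (int l = 0; l < d; ++l) {
        if (K[l] < 1) {
          out(obs_i, l) = x[l];
        } else {
          double ssum = 0.0;
          int p = pos;
          for (int kk = 0; kk < K[l]; ++kk) {  // newest to oldest
            ssum += buf[static_cast<size_t>(p) * d + l];
            p = (p == 0) ? bufsz - 1 : p - 1;
          }
          out(obs_i, l) = ssum / K[l];
        }
      }
      ++obs_i;
      next_obs_step += stride;
    }
  }
  return out;
}

// Moving-average of a fine path over a trailing window of K fine steps,
// evaluated at the (1-based) fine indices `pos`.
// [[Rcpp::export]]
NumericVector conv_mean_cpp(NumericVector x, IntegerVector pos, int K) {
  const int n = pos.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const int p = pos[i] - 1;
    if (p - (K - 1) < 0 || p >= x.size())
      stop("convolution window exceeds the available burn-in at observation %d", i);
    double ssum = 0.0;
    for (int k = 0; k < K; ++k) ssum += x[p - k];
    out[i] = ssum / K;
  }
  return out;
}
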