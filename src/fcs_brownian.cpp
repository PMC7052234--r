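// Brownian-dynamics photon-rate engine for FCS simulation.
//
// Molecules diffuse in a periodic box around a 3D Gaussian detection
// volume (molecule detection function exp(-2 r_lat^2 / w0^2 - 2 z^2 / z0^2));
// the per-bin expected photon count is accumulated at each time step.
// The inner loop executes ~1e10 molecule-steps for a 20 s trace, so the
// normal deviates come from a Marsaglia-Tsang ziggurat over a xorshift
// generator rather than R's RNG; the integer seed fully determines the
// trajectory.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

namespace {

class ZigguratRNG {
 public:
  explicit ZigguratRNG(uint32_t seed) : jsr_(123456789u ^ seed) {
    if (jsr_ == 0) jsr_ = 362436069u;
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn, vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn_[0] = static_cast<uint32_t>((dn / q) * m1);
    kn_[1] = 0;
    wn_[0] = q / m1;
    wn_[127] = dn / m1;
    fn_[0] = 1.0;
    fn_[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; i--) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn_[i + 1] = static_cast<uint32_t>((dn / tn) * m1);
      tn = dn;
      fn_[i] = std::exp(-0.5 * dn * dn);
      wn_[i] = dn / m1;
    }
  }

  uint32_t shr3() {
    uint32_t jz = jsr_;
    jsr_ ^= jsr_ << 13;
    jsr_ ^= jsr_ >> 17;
    jsr_ ^= jsr_ << 5;
    return jz + jsr_;
  }

  double uniform() {  // (0, 1)
    return 0.5 + static_cast<int32_t>(shr3()) * 2.328306e-10;
  }

  double normal() {
    int32_t hz = static_cast<int32_t>(shr3());
    uint32_t iz = static_cast<uint32_t>(hz) & 127u;
    uint32_t ahz = hz < 0 ? static_cast<uint32_t>(-static_cast<int64_t>(hz))
                          : static_cast<uint32_t>(hz);
    return (ahz < kn_[iz]) ? hz * wn_[iz] : nfix(hz, iz);
  }

 private:
  double nfix(int32_t hz, uint32_t iz) {
    const double r = 3.442619855899;
    for (;;) {
      double x = hz * wn_[iz];
      if (iz == 0) {  // base-strip tail
        double y;
        do {
          x = -std::log(uniform()) / r;
          y = -std::log(uniform());
        } while (y + y < x * x);
        return (hz > 0) ? r + x : -r - x;
      }
      if (fn_[iz] + uniform() * (fn_[iz - 1] - fn_[iz]) <
          std::exp(-0.5 * x * x))
        return x;
      hz = static_cast<int32_t>(shr3());
      iz = static_cast<uint32_t>(hz) & 127u;
      uint32_t ahz = hz < 0 ? static_cast<uint32_t>(-static_cast<int64_t>(hz))
                            : static_cast<uint32_t>(hz);
      if (ahz < kn_[iz]) return hz * wn_[iz];
    }
  }

  uint32_t jsr_;
  uint32_t kn_[128];
  double wn_[128], fn_[128];
};

inline double wrap(double v, double half, double full) {
  if (v > half) return v - full;
  if (v < -half) return v + full;
  return v;
}

}  // namespace

// Expected photon counts per time bin from diffusing molecules.
// Lengths in um; rate_per_bin = brightness (counts/s at focus) * dt.
// [[Rcpp::export(name = ".fcs_brownian_intensity")]]
Rcpp::NumericVector fcs_brownian_intensity(int n_steps, int n_mol,
                                           double sigma_step,
                                           double Lx, double Ly, double Lz,
                                           double w0, double z0,
                                           double rate_per_bin,
                                           int seed) {
  ZigguratRNG rng(static_cast<uint32_t>(seed));
  std::vector<double> X(n_mol), Y(n_mol), Z(n_mol);
  for (int m = 0; m < n_mol; m++) {
    X[m] = (rng.uniform() - 0.5) * Lx;
    Y[m] = (rng.uniform() - 0.5) * Ly;
    Z[m] = (rng.uniform() - 0.5) * Lz;
  }
  const double hx = Lx / 2, hy = Ly / 2, hz = Lz / 2;
  const double aw = 2.0 / (w0 * w0), az = 2.0 / (z0 * z0);
  const double qmax = 30.0;  // exp(-30) ~ 1e-13: below shot noise
  Rcpp::NumericVector out(n_steps);
  for (int s = 0; s < n_steps; s++) {
    double lam = 0.0;
    for (int m = 0; m < n_mol; m++) {
      double x = wrap(X[m] + sigma_step * rng.normal(), hx, Lx);
      double y = wrap(Y[m] + sigma_step * rng.normal(), hy, Ly);
      double z = wrap(Z[m] + sigma_step * rng.normal(), hz, Lz);
      X[m] = x; Y[m] = y; Z[m] = z;
      double q = aw * (x * x + y * y) + az * z * z;
      if (q < qmax) lam += std::exp(-q);
    }
    out[s] = lam * rate_per_bin;
    if ((s & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Raw normal deviates from the same generator (statistical validation).
// [[Rcpp::export(name = ".ziggurat_normals")]]
Rcpp::NumericVector ziggurat_normals(int n, int seed) {
  ZigguratRNG rng(static_cast<uint32_t>(seed));
  Rcpp::NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = rng.normal();
  return out;
}
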