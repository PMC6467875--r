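#include <Rcpp.h>
using namespace Rcpp;

// Overdamped Langevin (Euler-Maruyama) integrator for independent
// particles in a 1D trans-bilayer potential
//   G(z) = H * [exp(-(z-zp)^2/(2 s^2)) + exp(-(z+zp)^2/(2 s^2))]
//          - d * exp(-z^2/(2 sw^2))
// on a periodic box z in (-Lz/2, Lz/2].  Uses R's RNG so runs are
// reproducible from set.seed().  Positions are recorded every `thin`
// steps after `burnin` unrecorded steps.

static inline double grad_potential(double z, double H, double s,
                                    double zp, double d, double sw) {
  double s2 = s * s;
  double a1 = z - zp, a2 = z + zp;
  double g = H * (-(a1 / s2) * std::exp(-a1 * a1 / (2.0 * s2))
                  - (a2 / s2) * std::exp(-a2 * a2 / (2.0 * s2)));
  if (d != 0.0) {
    double sw2 = sw * sw;
    g += d * (z / sw2) * std::exp(-z * z / (2.0 * sw2));
  }
  return g;
}

// [[Rcpp::export(name = ".langevin_run")]]
NumericMatrix langevin_run(NumericVector z0, int n_steps, int thin,
                           int burnin, double dt, double D, double kT,
                           double Lz, double H, double sigma, double zpk,
                           double well_depth, double well_sigma) {
  const int n_part = z0.size();
  const int n_frames = n_steps / thin + 1;  // includes the initial frame
  NumericMatrix out(n_frames, n_part);
  const double mob = D / kT;                 // mobility, nm^2/(ps kcal/mol)
  const double noise = std::sqrt(2.0 * D * dt);
  const double halfL = Lz / 2.0;

  RNGScope scope;
  std::vector<double> z(z0.begin(), z0.end());

  for (int b = 0; b < burnin; ++b) {
    for (int p = 0; p < n_part; ++p) {
      double zz = z[p];
      zz += -mob * grad_potential(zz, H, sigma, zpk, well_depth, well_sigma) * dt
            + noise * norm_rand();
      zz -= Lz * std::floor(zz / Lz + 0.5);
      if (zz <= -halfL) zz += Lz;           // keep (-Lz/2, Lz/2]
      z[p] = zz;
    }
  }
  for (int p = 0; p < n_part; ++p) out(0, p) = z[p];

  int frame = 1;
  for (int s = 1; s <= n_steps; ++s) {
    for (int p = 0; p < n_part; ++p) {
      double zz = z[p];
      zz += -mob * grad_potential(zz, H, sigma, zpk, well_depth, well_sigma) * dt
            + noise * norm_rand();
      zz -= Lz * std::floor(zz / Lz + 0.5);
      if (zz <= -halfL) zz += Lz;
      z[p] = zz;
    }
    if (s % thin == 0) {
      for (int p = 0; p < n_part; ++p) out(frame, p) = z[p];
      ++frame;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".potential_eval")]]
NumericVector potential_eval(NumericVector z, double H, double sigma,
                             double zpk, double well_depth,
                             double well_sigma) {
  int n = z.size();
  NumericVector out(n);
  double s2 = sigma * sigma, sw2 = well_sigma * well_sigma;
  for (int i = 0; i < n; ++i) {
    double a1 = z[i] - zpk, a2 = z[i] + zpk;
    double g = H * (std::exp(-a1 * a1 / (2.0 * s2))
                    + std::exp(-a2 * a2 / (2.0 * s2)));
    if (well_depth != 0.0)
      g -= well_depth * std::exp(-z[i] * z[i] / (2.0 * sw2));
    out[i] = g;
  }
  return out;
}
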