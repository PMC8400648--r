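// Binary Lennard-Jones molecular dynamics engine (reduced units).
//
// Velocity-Verlet integration of an 80:20-style binary LJ mixture with
// non-additive cross parameters, shifted-potential cutoff, optional
// Berendsen-style thermostat / isotropic barostat.  All randomness stays
// on the R side; this loop is deterministic.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct PairTable {
  // indexed [a*2 + b] for species a, b in {0, 1}
  double eps[4], sig2[4], rc2[4], ushift[4];
};

inline double min_image(double d, double L) {
  return d - L * std::round(d / L);
}

// forces, potential energy and virial sum (r.f) for one configuration
void forces(const std::vector<double>& x, const std::vector<double>& y,
            const std::vector<double>& z, const IntegerVector& type,
            double L, const PairTable& pt,
            std::vector<double>& fx, std::vector<double>& fy,
            std::vector<double>& fz, double& upot, double& virial) {
  const int n = (int)x.size();
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  upot = 0.0;
  virial = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const int k = type[i] * 2 + type[j];
      const double dx = min_image(x[i] - x[j], L);
      const double dy = min_image(y[i] - y[j], L);
      const double dz = min_image(z[i] - z[j], L);
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= pt.rc2[k]) continue;
      const double s2 = pt.sig2[k] / r2;
      const double s6 = s2 * s2 * s2;
      const double s12 = s6 * s6;
      upot += 4.0 * pt.eps[k] * (s12 - s6) - pt.ushift[k];
      // f = 24 eps (2 s12 - s6) / r2 * rvec
      const double fr = 24.0 * pt.eps[k] * (2.0 * s12 - s6) / r2;
      fx[i] += fr * dx; fx[j] -= fr * dx;
      fy[i] += fr * dy; fy[j] -= fr * dy;
      fz[i] += fr * dz; fz[j] -= fr * dz;
      virial += fr * r2;
    }
  }
}

} // namespace

// [[Rcpp::export(name = ".lj_run_cpp")]]
List lj_run_cpp(NumericMatrix coords, NumericMatrix vel, IntegerVector type,
                double L, int n_steps, double dt,
                NumericVector eps_pairs,   // AA, AB, BB
                NumericVector sig_pairs,   // AA, AB, BB
                double cutoff_factor,      // rc = factor * sigma_ab
                int mode,                  // 0 NVE, 1 NVT, 2 NPT
                double T_target, double P_target,
                double tau_T, double tau_P,
                int sample_every, int frame_every) {
  const int n = coords.nrow();
  if (n_steps < 0) stop("n_steps must be non-negative");

  PairTable pt;
  const int map[4] = {0, 1, 1, 2};  // AA, AB, BA, BB
  for (int k = 0; k < 4; ++k) {
    const double eps = eps_pairs[map[k]];
    const double sig = sig_pairs[map[k]];
    const double rc = cutoff_factor * sig;
    pt.eps[k] = eps;
    pt.sig2[k] = sig * sig;
    pt.rc2[k] = rc * rc;
    const double s6 = std::pow(sig / rc, 6.0);
    pt.ushift[k] = 4.0 * eps * (s6 * s6 - s6);
  }

  std::vector<double> x(n), y(n), z(n), vx(n), vy(n), vz(n);
  for (int i = 0; i < n; ++i) {
    x[i] = coords(i, 0); y[i] = coords(i, 1); z[i] = coords(i, 2);
    vx[i] = vel(i, 0); vy[i] = vel(i, 1); vz[i] = vel(i, 2);
  }
  std::vector<double> fx(n), fy(n), fz(n);
  double upot = 0.0, virial = 0.0;
  forces(x, y, z, type, L, pt, fx, fy, fz, upot, virial);

  const int n_samples = (sample_every > 0 && n_steps > 0)
    ? n_steps / sample_every : 0;
  NumericVector s_step(n_samples), s_T(n_samples), s_P(n_samples),
    s_V(n_samples), s_U(n_samples), s_E(n_samples), s_H(n_samples);
  const int n_framed = (frame_every > 0 && n_steps > 0)
    ? n_steps / frame_every : 0;
  NumericVector fr_box(n_framed), fr_step(n_framed);
  NumericVector fr_coords(Dimension(n_framed > 0 ? n_framed : 1, n, 3));
  int si = 0, fi = 0;

  for (int step = 1; step <= n_steps; ++step) {
    // velocity Verlet
    const double half = 0.5 * dt;
    for (int i = 0; i < n; ++i) {
      vx[i] += half * fx[i]; vy[i] += half * fy[i]; vz[i] += half * fz[i];
      x[i] += dt * vx[i]; y[i] += dt * vy[i]; z[i] += dt * vz[i];
    }
    forces(x, y, z, type, L, pt, fx, fy, fz, upot, virial);
    double ke = 0.0;
    for (int i = 0; i < n; ++i) {
      vx[i] += half * fx[i]; vy[i] += half * fy[i]; vz[i] += half * fz[i];
      ke += vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i];
    }
    ke *= 0.5;
    if (!std::isfinite(upot) || !std::isfinite(ke))
      stop("non-finite energy at step %d: integration blew up", step);

    double Tinst = 2.0 * ke / (3.0 * n);
    double V = L * L * L;
    double Pinst = (n * Tinst + virial / 3.0) / V;

    if (mode >= 1 && tau_T > 0.0) {
      // Berendsen-style weak coupling toward T_target
      double lam2 = 1.0 + dt / tau_T * (T_target / Tinst - 1.0);
      if (lam2 < 0.25) lam2 = 0.25;
      if (lam2 > 4.0) lam2 = 4.0;
      const double lam = std::sqrt(lam2);
      for (int i = 0; i < n; ++i) { vx[i] *= lam; vy[i] *= lam; vz[i] *= lam; }
      ke *= lam2;
      Tinst = 2.0 * ke / (3.0 * n);
      Pinst = (n * Tinst + virial / 3.0) / V;
    }
    if (mode == 2 && tau_P > 0.0) {
      // isotropic Berendsen-style barostat (unit compressibility scale)
      double mu3 = 1.0 - dt / tau_P * (P_target - Pinst);
      if (mu3 < 0.9) mu3 = 0.9;
      if (mu3 > 1.1) mu3 = 1.1;
      const double mu = std::cbrt(mu3);
      L *= mu;
      for (int i = 0; i < n; ++i) { x[i] *= mu; y[i] *= mu; z[i] *= mu; }
      forces(x, y, z, type, L, pt, fx, fy, fz, upot, virial);
      V = L * L * L;
      Pinst = (n * Tinst + virial / 3.0) / V;
    }

    if (sample_every > 0 && step % sample_every == 0 && si < n_samples) {
      s_step[si] = step; s_T[si] = Tinst; s_P[si] = Pinst; s_V[si] = V;
      s_U[si] = upot; s_E[si] = upot + ke;
      s_H[si] = upot + ke + P_target * V;
      ++si;
    }
    if (frame_every > 0 && step % frame_every == 0 && fi < n_framed) {
      fr_step[fi] = step; fr_box[fi] = L;
      for (int i = 0; i < n; ++i) {
        fr_coords[fi + n_framed * i] = x[i] - L * std::floor(x[i] / L);
        fr_coords[fi + n_framed * (n + i)] = y[i] - L * std::floor(y[i] / L);
        fr_coords[fi + n_framed * (2 * n + i)] = z[i] - L * std::floor(z[i] / L);
      }
      ++fi;
    }
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix out_coords(n, 3), out_vel(n, 3);
  for (int i = 0; i < n; ++i) {
    out_coords(i, 0) = x[i] - L * std::floor(x[i] / L);
    out_coords(i, 1) = y[i] - L * std::floor(y[i] / L);
    out_coords(i, 2) = z[i] - L * std::floor(z[i] / L);
    out_vel(i, 0) = vx[i]; out_vel(i, 1) = vy[i]; out_vel(i, 2) = vz[i];
  }
  return List::create(
    _["coords"] = out_coords, _["vel"] = out_vel, _["L"] = L,
    _["thermo"] = DataFrame::create(
      _["step"] = s_step, _["T"] = s_T, _["P"] = s_P, _["V"] = s_V,
      _["U"] = s_U, _["E"] = s_E, _["H"] = s_H),
    _["frames"] = fr_coords, _["frame_box"] = fr_box,
    _["frame_step"] = fr_step, _["n_frames"] = fi);
}

// [[Rcpp::export(name = ".lj_energy_cpp")]]
List lj_energy_cpp(NumericMatrix coords, IntegerVector type, double L,
                   NumericVector eps_pairs, NumericVector sig_pairs,
                   double cutoff_factor) {
  PairTable pt;
  const int map[4] = {0, 1, 1, 2};
  for (int k = 0; k < 4; ++k) {
    const double eps = eps_pairs[map[k]];
    const double sig = sig_pairs[map[k]];
    const double rc = cutoff_factor * sig;
    pt.eps[k] = eps; pt.sig2[k] = sig * sig; pt.rc2[k] = rc * rc;
    const double s6 = std::pow(sig / rc, 6.0);
    pt.ushift[k] = 4.0 * eps * (s6 * s6 - s6);
  }
  const int n = coords.nrow();
  std::vector<double> x(n), y(n), z(n), fx(n), fy(n), fz(n);
  for (int i = 0; i < n; ++i) {
    x[i] = coords(i, 0); y[i] = coords(i, 1); z[i] = coords(i, 2);
  }
  double upot = 0.0, virial = 0.0;
  forces(x, y, z, type, L, pt, fx, fy, fz, upot, virial);
  return List::create(_["U"] = upot, _["virial"] = virial);
}
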