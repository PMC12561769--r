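// Staggered-grid pressure-velocity FDTD solver for heterogeneous media.
//
// First-order coupled system
//   du/dt = -(1/rho) grad p
//   dp/dt = -rho c^2 div u  (+ source, + viscous loss)
// discretised with 8th-order staggered spatial stencils and leapfrog time
// stepping, split-field PML on all outer boundaries (medium properties are
// edge-replicated into the PML region by the R wrapper).
//
// Source drive conventions (src_mode):
//   0 "pressure"      : the waveform is imposed incrementally, so the source
//                       voxel's pressure follows amplitude * pulse(t).
//   1 "pressure_rate" : mass-rate drive, d p/dt += amplitude * pulse(t)/sigma.
//
// Absorption: viscous (diffusive) loss term delta(r) * laplacian(p), with
// delta precomputed in R to match a power-law alpha0 * omega^d at a
// reference frequency.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#if defined(__SSE2__)
#include <xmmintrin.h>
#endif

// Absorbing media drive the residual field towards denormal magnitudes,
// where x87/SSE arithmetic slows by orders of magnitude; flush-to-zero is
// physically harmless here (the fields of interest are > 1e-30 Pa).
struct FlushDenormalsGuard {
#if defined(__SSE2__)
  unsigned int saved;
  FlushDenormalsGuard() : saved(_mm_getcsr()) { _mm_setcsr(saved | 0x8040); }
  ~FlushDenormalsGuard() { _mm_setcsr(saved); }
#endif
};

using namespace Rcpp;

// 8th-order staggered first-derivative coefficients.
static const double A1 = 1225.0 / 1024.0;
static const double A2 = -245.0 / 3072.0;
static const double A3 = 49.0 / 5120.0;
static const double A4 = -5.0 / 7168.0;

// PML absorption profile sigma(x) in 1/s at fractional grid coordinate x
// (cell units; cell centres at integers). alpha is in the toolbox-style
// dimensionless convention: sigma_max = alpha * c_ref / dx.
// The outermost 4 cells lie beyond the update stencils and stay frozen, so
// the profile ramps over the *updated* part of the layer (pml - 4 cells) and
// saturates at sigma_max before the frozen rim.
static inline double pml_sigma(double x, int n, int pml, double alpha,
                               double c_ref_over_dx) {
  const double ramp = pml - 4 > 1 ? pml - 4 : 1;
  double depth = 0.0;
  if (x < pml) depth = (pml - x) / ramp;
  else if (x > n - 1 - pml) depth = (x - (n - 1 - pml)) / ramp;
  if (depth <= 0.0) return 0.0;
  if (depth > 1.0) depth = 1.0;
  double d2 = depth * depth;
  return alpha * c_ref_over_dx * d2 * d2;
}

template <typename T>
static void make_pml_factors(std::vector<T>& cent, std::vector<T>& stag,
                             int n, int pml, double alpha,
                             double c_ref_over_dx, double dt) {
  cent.resize(n);
  stag.resize(n);
  for (int i = 0; i < n; ++i) {
    cent[i] = (T)std::exp(-pml_sigma(i, n, pml, alpha, c_ref_over_dx) * dt / 2);
    stag[i] = (T)std::exp(-pml_sigma(i + 0.5, n, pml, alpha, c_ref_over_dx) * dt / 2);
  }
}

template <typename T>
static List fdtd_core(const NumericVector& speed, const NumericVector& density,
                      const NumericVector& delta_abs, const IntegerVector& dims,
                      double dx_m, double dt, int n_steps,
                      const IntegerMatrix& src_pos, const NumericVector& src_amp,
                      const NumericVector& pulse, int src_mode, double pulse_sigma,
                      const IntegerMatrix& det_pos, int pml, double pml_alpha,
                      int energy_stride) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const bool three_d = nz > 1;
  const size_t N = (size_t)nx * ny * nz;
  const size_t sxy = (size_t)nx * ny;
  const bool absorbing = delta_abs.size() > 0;

  double c_max = 0.0;
  for (R_xlen_t i = 0; i < speed.size(); ++i)
    if (speed[i] > c_max) c_max = speed[i];
  const double c_ref_over_dx = c_max / dx_m;

  // Material coefficient fields.
  std::vector<T> kap(N);                     // rho * c^2
  std::vector<T> irx(N, 0), iry(N, 0), irz(N, 0);  // 1/rho at staggered faces
  std::vector<T> dl;                          // viscous delta / dx^2
  if (absorbing) dl.resize(N);
  for (size_t q = 0; q < N; ++q) {
    kap[q] = (T)(density[q] * speed[q] * speed[q] * dt / dx_m);
    if (absorbing) dl[q] = (T)(delta_abs[q] * dt / (dx_m * dx_m));
  }
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t q = i + (size_t)nx * j + sxy * k;
        if (i + 1 < nx) irx[q] = (T)(2.0 / (density[q] + density[q + 1]) * dt / dx_m);
        if (j + 1 < ny) iry[q] = (T)(2.0 / (density[q] + density[q + nx]) * dt / dx_m);
        if (three_d && k + 1 < nz)
          irz[q] = (T)(2.0 / (density[q] + density[q + sxy]) * dt / dx_m);
      }

  std::vector<T> bxc, bxs, byc, bys, bzc, bzs;
  make_pml_factors<T>(bxc, bxs, nx, pml, pml_alpha, c_ref_over_dx, dt);
  make_pml_factors<T>(byc, bys, ny, pml, pml_alpha, c_ref_over_dx, dt);
  if (three_d) make_pml_factors<T>(bzc, bzs, nz, pml, pml_alpha, c_ref_over_dx, dt);

  std::vector<T> p(N, 0), px(N, 0), py(N, 0), pz;
  std::vector<T> ux(N, 0), uy(N, 0), uz;
  std::vector<T> lap;
  if (three_d) { pz.assign(N, 0); uz.assign(N, 0); }
  if (absorbing) lap.assign(N, 0);

  const int n_src = src_pos.nrow();
  std::vector<size_t> sidx(n_src);
  for (int s = 0; s < n_src; ++s)
    sidx[s] = (src_pos(s, 0) - 1) + (size_t)nx * (src_pos(s, 1) - 1) +
              sxy * (size_t)(src_pos(s, 2) - 1);
  const int n_det = det_pos.nrow();
  std::vector<size_t> didx(n_det);
  for (int m = 0; m < n_det; ++m)
    didx[m] = (det_pos(m, 0) - 1) + (size_t)nx * (det_pos(m, 1) - 1) +
              sxy * (size_t)(det_pos(m, 2) - 1);

  NumericMatrix traces(n_steps, n_det);
  std::vector<double> energy;

  const int kz0 = three_d ? 4 : 0, kz1 = three_d ? nz - 5 : 0;

  for (int n = 0; n < n_steps; ++n) {
    // --- velocity updates (u at t+dt/2 from p at t) ---
    for (int k = (three_d ? 3 : 0); k <= (three_d ? nz - 5 : 0); ++k)
      for (int j = 0; j < ny; ++j) {
        const size_t row = (size_t)nx * j + sxy * k;
        if (j >= 3 && j <= ny - 5) {
          for (int i = 3; i <= nx - 5; ++i) {
            const size_t q = i + row;
            T dpx = (T)(A1 * (p[q + 1] - p[q]) + A2 * (p[q + 2] - p[q - 1]) +
                        A3 * (p[q + 3] - p[q - 2]) + A4 * (p[q + 4] - p[q - 3]));
            ux[q] = bxs[i] * (bxs[i] * ux[q] - irx[q] * dpx);
            T dpy = (T)(A1 * (p[q + nx] - p[q]) + A2 * (p[q + 2 * nx] - p[q - nx]) +
                        A3 * (p[q + 3 * nx] - p[q - 2 * nx]) +
                        A4 * (p[q + 4 * nx] - p[q - 3 * nx]));
            uy[q] = bys[j] * (bys[j] * uy[q] - iry[q] * dpy);
            if (three_d) {
              T dpz = (T)(A1 * (p[q + sxy] - p[q]) + A2 * (p[q + 2 * sxy] - p[q - sxy]) +
                          A3 * (p[q + 3 * sxy] - p[q - 2 * sxy]) +
                          A4 * (p[q + 4 * sxy] - p[q - 3 * sxy]));
              uz[q] = bzs[k] * (bzs[k] * uz[q] - irz[q] * dpz);
            }
          }
        }
      }

    // --- optional viscous-loss laplacian of the previous pressure ---
    if (absorbing) {
      for (int k = kz0 ? kz0 : 0; k <= (three_d ? kz1 : 0); ++k)
        for (int j = 1; j < ny - 1; ++j) {
          const size_t row = (size_t)nx * j + sxy * k;
          for (int i = 1; i < nx - 1; ++i) {
            const size_t q = i + row;
            T l = p[q + 1] + p[q - 1] + p[q + nx] + p[q - nx] - (T)4 * p[q];
            if (three_d) l += p[q + sxy] + p[q - sxy] - (T)2 * p[q];
            lap[q] = l;
          }
        }
    }

    // --- pressure updates (p at t+dt from u at t+dt/2) ---
    for (int k = (three_d ? 4 : 0); k <= (three_d ? nz - 5 : 0); ++k)
      for (int j = 4; j <= ny - 5; ++j) {
        const size_t row = (size_t)nx * j + sxy * k;
        for (int i = 4; i <= nx - 5; ++i) {
          const size_t q = i + row;
          T dux = (T)(A1 * (ux[q] - ux[q - 1]) + A2 * (ux[q + 1] - ux[q - 2]) +
                      A3 * (ux[q + 2] - ux[q - 3]) + A4 * (ux[q + 3] - ux[q - 4]));
          T duy = (T)(A1 * (uy[q] - uy[q - nx]) + A2 * (uy[q + nx] - uy[q - 2 * nx]) +
                      A3 * (uy[q + 2 * nx] - uy[q - 3 * nx]) +
                      A4 * (uy[q + 3 * nx] - uy[q - 4 * nx]));
          px[q] = bxc[i] * (bxc[i] * px[q] - kap[q] * dux);
          py[q] = byc[j] * (byc[j] * py[q] - kap[q] * duy);
          if (three_d) {
            T duz = (T)(A1 * (uz[q] - uz[q - sxy]) + A2 * (uz[q + sxy] - uz[q - 2 * sxy]) +
                        A3 * (uz[q + 2 * sxy] - uz[q - 3 * sxy]) +
                        A4 * (uz[q + 3 * sxy] - uz[q - 4 * sxy]));
            pz[q] = bzc[k] * (bzc[k] * pz[q] - kap[q] * duz);
          }
          if (absorbing) px[q] += dl[q] * lap[q];
        }
      }

    // --- source injection ---
    const double g_now = pulse[n + 1];
    const double g_prev = pulse[n];
    for (int s = 0; s < n_src; ++s) {
      const size_t q = sidx[s];
      if (src_mode == 0) px[q] += (T)(src_amp[s] * (g_now - g_prev));
      else px[q] += (T)(src_amp[s] * g_now * dt / pulse_sigma);
    }

    // --- combine and record ---
    if (three_d) {
      for (size_t q = 0; q < N; ++q) p[q] = px[q] + py[q] + pz[q];
    } else {
      for (size_t q = 0; q < N; ++q) p[q] = px[q] + py[q];
    }
    for (int m = 0; m < n_det; ++m) traces(n, m) = (double)p[didx[m]];

    if (energy_stride > 0 && (n % energy_stride) == 0) {
      double e = 0.0;
      for (size_t q = 0; q < N; ++q) {
        double pp = (double)p[q];
        double uu = (double)ux[q] * ux[q] + (double)uy[q] * uy[q];
        if (three_d) uu += (double)uz[q] * uz[q];
        e += pp * pp / (density[q] * speed[q] * speed[q]) + density[q] * uu;
      }
      energy.push_back(0.5 * e);
    }

    if ((n % 200) == 0 || n == n_steps - 1) {
      if (!std::isfinite((double)p[didx.size() ? didx[0] : N / 2]) ||
          !std::isfinite((double)p[N / 2]))
        stop("solver state became non-finite at step %d", n);
    }
  }

  return List::create(_["traces"] = traces,
                      _["energy"] = NumericVector(energy.begin(), energy.end()));
}

// [[Rcpp::export(name = ".fdtd_run")]]
List fdtd_run(NumericVector speed, NumericVector density, NumericVector delta_abs,
              IntegerVector dims, double dx_m, double dt, int n_steps,
              IntegerMatrix src_pos, NumericVector src_amp, NumericVector pulse,
              int src_mode, double pulse_sigma, IntegerMatrix det_pos,
              int pml, double pml_alpha, bool single_precision,
              int energy_stride) {
  if (pulse.size() < n_steps + 1)
    stop("pulse vector must have n_steps + 1 samples (zero-padded)");
  FlushDenormalsGuard ftz;
  if (single_precision)
    return fdtd_core<float>(speed, density, delta_abs, dims, dx_m, dt, n_steps,
                            src_pos, src_amp, pulse, src_mode, pulse_sigma,
                            det_pos, pml, pml_alpha, energy_stride);
  return fdtd_core<double>(speed, density, delta_abs, dims, dx_m, dt, n_steps,
                           src_pos, src_amp, pulse, src_mode, pulse_sigma,
                           det_pos, pml, pml_alpha, energy_stride);
}
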