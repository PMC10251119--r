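// Agent-based biofilm core: Park-Miller stream, cell division, mechanical
// relaxation (shoving), quasi-static substrate diffusion-reaction solve, and
// the full growth loop. All randomness flows through one Park-Miller stream
// per run so that a (config, seed) pair fully determines the outcome.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

static const int64_t PM_A = 16807;
static const int64_t PM_M = 2147483647; // 2^31 - 1

static inline int64_t pm_step(int64_t state) {
  return (PM_A * state) % PM_M;
}

static inline void pm_check(int64_t state) {
  if (state < 1 || state >= PM_M)
    stop("Park-Miller state must be an integer in [1, 2^31 - 2]");
}

// [[Rcpp::export]]
List pm_next_cpp(double state) {
  int64_t s = (int64_t)state;
  pm_check(s);
  s = pm_step(s);
  return List::create(_["state"] = (double)s,
                      _["deviate"] = (double)s / (double)PM_M);
}

// [[Rcpp::export]]
List pm_draws_cpp(double state, int n) {
  int64_t s = (int64_t)state;
  pm_check(s);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    s = pm_step(s);
    out[i] = (double)s / (double)PM_M;
  }
  return List::create(_["state"] = (double)s, _["deviates"] = out);
}

// Draw order at division is fixed: (1) biomass fraction f ~ U(0.4, 0.6),
// (2) z-component of direction ~ U(-1, 1), (3) azimuth ~ U(0, 2*pi).
// [[Rcpp::export]]
List division_draws_cpp(double state) {
  int64_t s = (int64_t)state;
  pm_check(s);
  s = pm_step(s);
  double f = 0.4 + 0.2 * ((double)s / (double)PM_M);
  s = pm_step(s);
  double uz = 2.0 * ((double)s / (double)PM_M) - 1.0;
  s = pm_step(s);
  double phi = 2.0 * M_PI * ((double)s / (double)PM_M);
  double r = std::sqrt(std::max(0.0, 1.0 - uz * uz));
  return List::create(_["state"] = (double)s, _["f"] = f,
                      _["ux"] = r * std::cos(phi), _["uy"] = r * std::sin(phi),
                      _["uz"] = uz);
}

// ---------------------------------------------------------------------------
// internal cell state used by the run loop
struct Cells {
  std::vector<double> x, y, z, d, m, mumax, Ks;
  std::vector<int> lin;
  size_t n() const { return x.size(); }
};

static inline double wrap(double v, double L) {
  v -= L * std::floor(v / L);
  if (v >= L) v = 0.0; // guard the v/L == -0 rounding edge
  return v;
}

static inline double min_image(double dv, double L) {
  if (dv > 0.5 * L) dv -= L;
  else if (dv < -0.5 * L) dv += L;
  return dv;
}

// Pairwise overlap projection with a cell-list neighbour search.  Each
// overlapping pair is pushed apart half the overlap each, sequentially;
// sweeps repeat until the worst overlap is below tol_frac * (ri + rj) or the
// iteration cap is hit.  Periodic in X/Y, floor at z = radius, ceiling at
// z = H - radius.
static int relax_core(Cells &c, double Lx, double Ly, double H,
                      double tol_frac, int max_iter, bool &converged) {
  size_t n = c.n();
  converged = true;
  if (n < 2) return 0;
  double dmax = 0;
  for (size_t i = 0; i < n; ++i) dmax = std::max(dmax, c.d[i]);
  double cell = dmax * 1.0001;
  int nbx = std::max(1, (int)std::floor(Lx / cell));
  int nby = std::max(1, (int)std::floor(Ly / cell));
  double bx = Lx / nbx, by = Ly / nby;
  int nbz = std::max(1, (int)std::floor(H / cell) + 1);
  std::vector<std::vector<int>> bins((size_t)nbx * nby * nbz);
  int iter = 0;
  for (; iter < max_iter; ++iter) {
    // bin by (x, y, z); bins are reused across sweeps
    for (size_t b = 0; b < bins.size(); ++b) bins[b].clear();
    for (size_t i = 0; i < n; ++i) {
      int ix = std::min(nbx - 1, (int)(wrap(c.x[i], Lx) / bx));
      int iy = std::min(nby - 1, (int)(wrap(c.y[i], Ly) / by));
      int iz = std::min(nbz - 1, std::max(0, (int)(c.z[i] / cell)));
      bins[(size_t)(iz * nby + iy) * nbx + ix].push_back((int)i);
    }
    double worst = 0.0;
    for (int iz = 0; iz < nbz; ++iz) {
      for (int iy = 0; iy < nby; ++iy) {
        for (int ix = 0; ix < nbx; ++ix) {
          const std::vector<int> &bi = bins[(size_t)(iz * nby + iy) * nbx + ix];
          if (bi.empty()) continue;
          for (int dz = -1; dz <= 1; ++dz) {
            int jz = iz + dz;
            if (jz < 0 || jz >= nbz) continue;
            for (int dy = -1; dy <= 1; ++dy) {
              int jy = (iy + dy + nby) % nby;
              for (int dx = -1; dx <= 1; ++dx) {
                int jx = (ix + dx + nbx) % nbx;
                const std::vector<int> &bj =
                    bins[(size_t)(jz * nby + jy) * nbx + jx];
                for (size_t a = 0; a < bi.size(); ++a) {
                  int i = bi[a];
                  for (size_t b = 0; b < bj.size(); ++b) {
                    int j = bj[b];
                    if (j <= i) continue;
                    double ddx = min_image(c.x[j] - c.x[i], Lx);
                    double ddy = min_image(c.y[j] - c.y[i], Ly);
                    double ddz = c.z[j] - c.z[i];
                    double rsum = 0.5 * (c.d[i] + c.d[j]);
                    double dist2 = ddx * ddx + ddy * ddy + ddz * ddz;
                    if (dist2 >= rsum * rsum) continue;
                    double dist = std::sqrt(dist2);
                    double ov;
                    double ux, uy, uz;
                    if (dist < 1e-15 * rsum) {
                      // coincident centres: deterministic separation axis
                      ov = rsum;
                      ux = 0.6; uy = 0.48; uz = 0.64;
                    } else {
                      ov = rsum - dist;
                      ux = ddx / dist; uy = ddy / dist; uz = ddz / dist;
                    }
                    worst = std::max(worst, ov / rsum);
                    double half = 0.5 * ov;
                    c.x[i] -= ux * half; c.y[i] -= uy * half; c.z[i] -= uz * half;
                    c.x[j] += ux * half; c.y[j] += uy * half; c.z[j] += uz * half;
                  }
                }
              }
            }
          }
        }
      }
    }
    for (size_t i = 0; i < n; ++i) {
      c.x[i] = wrap(c.x[i], Lx);
      c.y[i] = wrap(c.y[i], Ly);
      double r = 0.5 * c.d[i];
      if (c.z[i] < r) c.z[i] = r;
      if (c.z[i] > H - r) c.z[i] = H - r;
    }
    if (worst < tol_frac) { ++iter; break; }
  }
  if (iter >= max_iter) converged = false;
  return iter;
}

// [[Rcpp::export]]
List relax_cells_cpp(NumericVector x, NumericVector y, NumericVector z,
                     NumericVector diameter, double Lx, double Ly, double H,
                     double tol_frac, int max_iter) {
  Cells c;
  c.x = as<std::vector<double>>(x);
  c.y = as<std::vector<double>>(y);
  c.z = as<std::vector<double>>(z);
  c.d = as<std::vector<double>>(diameter);
  bool conv;
  int it = relax_core(c, Lx, Ly, H, tol_frac, max_iter, conv);
  return List::create(_["x"] = wrap(c.x), _["y"] = wrap(c.y),
                      _["z"] = wrap(c.z), _["iterations"] = it,
                      _["converged"] = conv);
}

// Quasi-static diffusion-reaction solve on the voxel grid.
// Semi-implicit Gauss-Seidel: the Monod sink is linearised about the current
// iterate, which keeps every update positive and bounded by the bulk value
// (discrete maximum principle).  Boundaries: Dirichlet bulk ghost layer above
// the top, zero-flux floor, periodic X/Y.
static bool substrate_core(std::vector<double> &S, int nx, int ny, int nz,
                           double h, double bulk, double D,
                           const Cells &c, double yield_, double tol,
                           int max_iter, double Lx, double Ly, double H) {
  size_t nv = (size_t)nx * ny * nz;
  double vvox = h * h * h;
  // per-voxel Monod sink accumulators: sum of mumax_i * m_i for each distinct
  // Ks is approximated by accumulating a(S) = sum mumax_i*m_i/(Ks_i + S) on
  // the fly; store cell lists per voxel instead
  std::vector<std::vector<int>> occ(nv);
  for (size_t i = 0; i < c.n(); ++i) {
    int ix = std::min(nx - 1, std::max(0, (int)(wrap(c.x[i], Lx) / h)));
    int iy = std::min(ny - 1, std::max(0, (int)(wrap(c.y[i], Ly) / h)));
    int iz = std::min(nz - 1, std::max(0, (int)(c.z[i] / h)));
    occ[(size_t)(iz * ny + iy) * nx + ix].push_back((int)i);
  }
  double Dh2 = D / (h * h);
  for (int iter = 0; iter < max_iter; ++iter) {
    double delta = 0.0;
    for (int iz = 0; iz < nz; ++iz) {
      for (int iy = 0; iy < ny; ++iy) {
        for (int ix = 0; ix < nx; ++ix) {
          size_t v = (size_t)(iz * ny + iy) * nx + ix;
          double nbsum = 0.0;
          int nnb = 0;
          if (nx > 1) {
            nbsum += S[(size_t)(iz * ny + iy) * nx + (ix + 1) % nx];
            nbsum += S[(size_t)(iz * ny + iy) * nx + (ix - 1 + nx) % nx];
            nnb += 2;
          }
          if (ny > 1) {
            nbsum += S[(size_t)(iz * ny + (iy + 1) % ny) * nx + ix];
            nbsum += S[(size_t)(iz * ny + (iy - 1 + ny) % ny) * nx + ix];
            nnb += 2;
          }
          if (iz + 1 < nz) { nbsum += S[(size_t)((iz + 1) * ny + iy) * nx + ix]; ++nnb; }
          else { nbsum += bulk; ++nnb; } // ghost bulk above top layer
          if (iz > 0) { nbsum += S[(size_t)((iz - 1) * ny + iy) * nx + ix]; ++nnb; }
          double q = 0.0; // linearised sink coefficient (1/h)
          double Sv = S[v];
          for (size_t a = 0; a < occ[v].size(); ++a) {
            int i = occ[v][a];
            q += c.mumax[i] * c.m[i] / ((c.Ks[i] + Sv) * yield_ * vvox);
          }
          double Snew = (Dh2 * nbsum) / (Dh2 * nnb + q);
          if (Snew > bulk) Snew = bulk;
          if (Snew < 0) Snew = 0;
          delta = std::max(delta, std::fabs(Snew - Sv));
          S[v] = Snew;
        }
      }
    }
    if (delta < tol * bulk) return true;
  }
  return false;
}

// [[Rcpp::export]]
List solve_substrate_cpp(NumericVector S, int nx, int ny, int nz, double h,
                         double bulk, double D, NumericVector x,
                         NumericVector y, NumericVector z, NumericVector mass,
                         NumericVector mumax, NumericVector Ks, double yield_,
                         double tol, int max_iter, double Lx, double Ly,
                         double H) {
  std::vector<double> Sv = as<std::vector<double>>(S);
  Cells c;
  c.x = as<std::vector<double>>(x);
  c.y = as<std::vector<double>>(y);
  c.z = as<std::vector<double>>(z);
  c.m = as<std::vector<double>>(mass);
  c.mumax = as<std::vector<double>>(mumax);
  c.Ks = as<std::vector<double>>(Ks);
  bool conv = substrate_core(Sv, nx, ny, nz, h, bulk, D, c, yield_, tol,
                             max_iter, Lx, Ly, H);
  if (!conv) stop("substrate solver failed to converge within iteration cap");
  return List::create(_["S"] = wrap(Sv), _["converged"] = conv);
}

static inline double diam_from_mass(double m, double rho) {
  return std::cbrt(6.0 * m / (rho * M_PI));
}

// One growth step: exponential mass update at the local substrate
// concentration, threshold division (parent replaced in place, second
// daughter appended), then mechanical relaxation.
static void grow_divide(Cells &c, const std::vector<double> &S, int nx, int ny,
                        int nz, double h, double dt, double rho,
                        double div_diam, int64_t &state, double Lx, double Ly) {
  size_t n0 = c.n();
  for (size_t i = 0; i < n0; ++i) {
    int ix = std::min(nx - 1, std::max(0, (int)(wrap(c.x[i], Lx) / h)));
    int iy = std::min(ny - 1, std::max(0, (int)(wrap(c.y[i], Ly) / h)));
    int iz = std::min(nz - 1, std::max(0, (int)(c.z[i] / h)));
    double Sloc = S[(size_t)(iz * ny + iy) * nx + ix];
    double mu = c.mumax[i] * Sloc / (c.Ks[i] + Sloc);
    c.m[i] *= std::exp(mu * dt);
    c.d[i] = diam_from_mass(c.m[i], rho);
  }
  for (size_t i = 0; i < n0; ++i) {
    if (c.d[i] <= div_diam) continue;
    state = pm_step(state);
    double f = 0.4 + 0.2 * ((double)state / (double)PM_M);
    state = pm_step(state);
    double uz = 2.0 * ((double)state / (double)PM_M) - 1.0;
    state = pm_step(state);
    double phi = 2.0 * M_PI * ((double)state / (double)PM_M);
    double rr = std::sqrt(std::max(0.0, 1.0 - uz * uz));
    double ux = rr * std::cos(phi), uy = rr * std::sin(phi);
    double m1 = f * c.m[i], m2 = c.m[i] - m1;
    double d1 = diam_from_mass(m1, rho), d2 = diam_from_mass(m2, rho);
    double sep = 0.5 * (0.5 * d1 + 0.5 * d2); // half the tangent separation
    double px = c.x[i], py = c.y[i], pz = c.z[i];
    c.x[i] = wrap(px + ux * sep, Lx); c.y[i] = wrap(py + uy * sep, Ly);
    c.z[i] = std::max(0.5 * d1, pz + uz * sep);
    c.m[i] = m1; c.d[i] = d1;
    c.x.push_back(wrap(px - ux * sep, Lx));
    c.y.push_back(wrap(py - uy * sep, Ly));
    c.z.push_back(std::max(0.5 * d2, pz - uz * sep));
    c.d.push_back(d2); c.m.push_back(m2);
    c.lin.push_back(c.lin[i]);
    c.mumax.push_back(c.mumax[i]);
    c.Ks.push_back(c.Ks[i]);
  }
}

// [[Rcpp::export]]
List grow_step_cpp(NumericVector x, NumericVector y, NumericVector z,
                   NumericVector diameter, NumericVector mass,
                   IntegerVector lineage, NumericVector mumax,
                   NumericVector Ks, NumericVector S, int nx, int ny, int nz,
                   double h, double dt, double rho, double div_diam,
                   double state, double Lx, double Ly, double H,
                   double relax_tol, int relax_max_iter) {
  Cells c;
  c.x = as<std::vector<double>>(x);
  c.y = as<std::vector<double>>(y);
  c.z = as<std::vector<double>>(z);
  c.d = as<std::vector<double>>(diameter);
  c.m = as<std::vector<double>>(mass);
  c.lin = as<std::vector<int>>(lineage);
  c.mumax = as<std::vector<double>>(mumax);
  c.Ks = as<std::vector<double>>(Ks);
  std::vector<double> Sv = as<std::vector<double>>(S);
  int64_t st = (int64_t)state;
  pm_check(st);
  if (dt > 0) grow_divide(c, Sv, nx, ny, nz, h, dt, rho, div_diam, st, Lx, Ly);
  bool conv = true;
  int it = 0;
  if (dt > 0) it = relax_core(c, Lx, Ly, H, relax_tol, relax_max_iter, conv);
  return List::create(
      _["x"] = wrap(c.x), _["y"] = wrap(c.y), _["z"] = wrap(c.z),
      _["diameter"] = wrap(c.d), _["mass"] = wrap(c.m),
      _["lineage"] = wrap(c.lin), _["mumax"] = wrap(c.mumax),
      _["Ks"] = wrap(c.Ks), _["state"] = (double)st,
      _["relax_iterations"] = it, _["relax_converged"] = conv);
}

// Full run loop: (substrate steady state) -> (grow/divide/relax) until the
// biomass volume fraction of the full cuboid reaches the stop fraction.
// [[Rcpp::export]]
List run_sim_cpp(NumericVector x0, NumericVector y0, NumericVector z0,
                 NumericVector d0, NumericVector m0, IntegerVector lin0,
                 NumericVector mumax0, NumericVector Ks0, double yield_,
                 double Lx, double Ly, double H, double bulk, double D,
                 double voxel_edge, double dt, double dt_max, double rho,
                 double div_diam, double stop_frac, double seed,
                 int max_steps, double relax_tol, int relax_sweeps,
                 double sub_tol, int sub_max_iter, bool return_cells) {
  Cells c;
  c.x = as<std::vector<double>>(x0);
  c.y = as<std::vector<double>>(y0);
  c.z = as<std::vector<double>>(z0);
  c.d = as<std::vector<double>>(d0);
  c.m = as<std::vector<double>>(m0);
  c.lin = as<std::vector<int>>(lin0);
  c.mumax = as<std::vector<double>>(mumax0);
  c.Ks = as<std::vector<double>>(Ks0);
  int64_t st = (int64_t)seed;
  pm_check(st);
  int nx = std::max(1, (int)std::lround(Lx / voxel_edge));
  int ny = std::max(1, (int)std::lround(Ly / voxel_edge));
  // voxel edge adjusted so voxels tile the domain; near-cubic by construction
  double hx = Lx / nx;
  int nz = std::max(1, (int)std::lround(H / hx));
  std::vector<double> S((size_t)nx * ny * nz, bulk);
  double vdom = Lx * Ly * H;
  int nlin = 0;
  for (size_t i = 0; i < c.n(); ++i) nlin = std::max(nlin, c.lin[i]);
  int steps = 0, relax_warn = 0;
  double volfrac = 0.0;
  for (size_t i = 0; i < c.n(); ++i)
    volfrac += M_PI * c.d[i] * c.d[i] * c.d[i] / 6.0;
  volfrac /= vdom;
  double sim_time = 0.0;
  while (volfrac < stop_frac) {
    if (steps >= max_steps)
      stop("simulation exceeded step cap (%d) before reaching stop fraction "
           "(at %.3f of %.3f)", max_steps, volfrac, stop_frac);
    bool sconv = substrate_core(S, nx, ny, nz, hx, bulk, D, c, yield_,
                                sub_tol, sub_max_iter, Lx, Ly, H);
    if (!sconv) stop("substrate solver failed to converge at step %d", steps);
    double step_dt = dt;
    if (dt <= 0) {
      // adaptive: cap the per-step relative mass change at 10% for the
      // fastest-growing cell; starved populations advance by dt_max
      double mumax_now = 0.0;
      for (size_t i = 0; i < c.n(); ++i) {
        int ix = std::min(nx - 1, std::max(0, (int)(wrap(c.x[i], Lx) / hx)));
        int iy = std::min(ny - 1, std::max(0, (int)(wrap(c.y[i], Ly) / hx)));
        int iz = std::min(nz - 1, std::max(0, (int)(c.z[i] / hx)));
        double Sloc = S[(size_t)(iz * ny + iy) * nx + ix];
        double mu = c.mumax[i] * Sloc / (c.Ks[i] + Sloc);
        if (mu > mumax_now) mumax_now = mu;
      }
      step_dt = (mumax_now > 0) ? std::min(dt_max, 0.1 / mumax_now) : dt_max;
    }
    grow_divide(c, S, nx, ny, nz, hx, step_dt, rho, div_diam, st, Lx, Ly);
    sim_time += step_dt;
    // bounded sweep budget per step: residual overlaps relax over
    // subsequent steps, like damped contact dynamics
    bool rconv = true;
    relax_core(c, Lx, Ly, H, relax_tol, relax_sweeps, rconv);
    if (!rconv) ++relax_warn;
    ++steps;
    volfrac = 0.0;
    for (size_t i = 0; i < c.n(); ++i)
      volfrac += M_PI * c.d[i] * c.d[i] * c.d[i] / 6.0;
    volfrac /= vdom;
  }
  NumericVector lin_mass(nlin);
  for (size_t i = 0; i < c.n(); ++i) lin_mass[c.lin[i] - 1] += c.m[i];
  List out = List::create(
      _["lineage_mass"] = lin_mass, _["n_steps"] = steps,
      _["n_cells"] = (int)c.n(), _["volume_fraction"] = volfrac,
      _["relax_warnings"] = relax_warn, _["final_state"] = (double)st,
      _["sim_time"] = sim_time);
  if (return_cells) {
    out["cells"] = DataFrame::create(
        _["x"] = wrap(c.x), _["y"] = wrap(c.y), _["z"] = wrap(c.z),
        _["diameter"] = wrap(c.d), _["mass"] = wrap(c.m),
        _["lineage"] = wrap(c.lin));
  }
  return out;
}
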