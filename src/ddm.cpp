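#include <Rcpp.h>
#include <cmath>
#include <random>
using namespace Rcpp;

// Total bound separation B(t) = a / (1 + exp(beta_alpha * t - beta_d)).
static inline double bound_sep(double t, double a, double beta_alpha, double beta_d) {
  return a / (1.0 + std::exp(beta_alpha * t - beta_d));
}

// Core propagation: forward convolution with a discrete Gaussian transition
// kernel, end-of-step absorption at the collapsing bounds. Fills up/lo with
// per-step crossing densities (1/s) and resid with interior mass; returns the
// number of steps actually used (early stop once interior < stop_mass).
static int propagate(double drift, double z, double a,
                     double beta_alpha, double beta_d,
                     double dt, double dx, double horizon,
                     double margin, double stop_mass,
                     std::vector<double> &up, std::vector<double> &lo,
                     std::vector<double> &resid) {
  const double sd = std::sqrt(dt);
  const int nt = (int)std::round(horizon / dt);

  // the grid always contains the start point 0 as an exact node, so that
  // mirror-symmetric problems produce exactly mirrored solutions
  const double B0 = bound_sep(0.0, a, beta_alpha, beta_d);
  const int n_lo = (int)std::ceil((z * B0 + margin) / dx);
  const int n_hi = (int)std::ceil(((1.0 - z) * B0 + margin) / dx);
  const int nx = n_lo + n_hi + 1;
  std::vector<double> x(nx);
  for (int j = 0; j < nx; ++j) x[j] = (j - n_lo) * dx;

  // transition kernel: displacement ~ N(drift*dt, dt), discretised and
  // renormalised so each step conserves probability exactly
  const double mu = drift * dt;
  const int K = (int)std::ceil((4.0 * sd + std::fabs(mu)) / dx);
  std::vector<double> w(2 * K + 1);
  double wsum = 0.0;
  for (int m = -K; m <= K; ++m) {
    double d = (m * dx - mu) / sd;
    w[m + K] = std::exp(-0.5 * d * d);
    wsum += w[m + K];
  }
  for (double &wi : w) wi /= wsum;

  // initial delta exactly at the start node
  std::vector<double> f(nx, 0.0), fnew(nx, 0.0);
  f[n_lo] = 1.0;

  up.assign(nt, 0.0);
  lo.assign(nt, 0.0);
  resid.assign(nt, 0.0);
  double interior = 1.0;
  int used = nt;

  double bu_prev = (1.0 - z) * B0, bl_prev = -z * B0;
  const double gate = 8.0 * dt;   // d0*d1 beyond this makes the bridge ~0

  for (int i = 0; i < nt; ++i) {
    double t = (i + 1) * dt;
    double bu = (1.0 - z) * bound_sep(t, a, beta_alpha, beta_d);
    double bl = -z * bound_sep(t, a, beta_alpha, beta_d);
    // Convolve with absorption at the destination: mass landing beyond a
    // bound is absorbed outright, and mass staying inside is absorbed with
    // the Brownian-bridge within-step crossing probability
    // exp(-2 (b - x_start)(b - x_end) / dt). This is the lattice analogue
    // of the Euler simulator and varies continuously as the collapsing
    // bounds sweep across grid nodes.
    std::fill(fnew.begin(), fnew.end(), 0.0);
    for (int j = 0; j < nx; ++j) {
      double fj = f[j];
      if (fj <= 0.0) continue;
      int mlo = std::max(-K, -j), mhi = std::min(K, nx - 1 - j);
      const double *wp = &w[K];
      double *fp = &fnew[j];
      double du0 = bu_prev - x[j];
      double dl0 = x[j] - bl_prev;
      for (int m = mlo; m <= mhi; ++m) {
        double moved = fj * wp[m];
        double xi = x[j + m];
        double du1 = bu - xi;
        if (du1 <= 0.0) { up[i] += moved; continue; }
        double dl1 = xi - bl;
        if (dl1 <= 0.0) { lo[i] += moved; continue; }
        if (du0 * du1 < gate) {
          double pc = std::exp(-2.0 * du0 * du1 / dt);
          up[i] += moved * pc;
          moved *= (1.0 - pc);
        }
        if (dl0 * dl1 < gate) {
          double pc = std::exp(-2.0 * dl0 * dl1 / dt);
          lo[i] += moved * pc;
          moved *= (1.0 - pc);
        }
        fp[m] += moved;
      }
      // mass that would leave the grid is absorbed at the corresponding side
      for (int m = -K; m < mlo; ++m) lo[i] += fj * wp[m];
      for (int m = mhi + 1; m <= K; ++m) up[i] += fj * wp[m];
    }
    std::swap(f, fnew);
    interior -= (up[i] + lo[i]);
    up[i] /= dt;
    lo[i] /= dt;
    resid[i] = interior;
    bu_prev = bu;
    bl_prev = bl;
    if (interior < stop_mass) { used = i + 1; break; }
  }
  return used;
}

// First-passage-time densities on a uniform decision-time grid.
// [[Rcpp::export]]
List cpp_fpt_grid(double drift, double z, double a,
                  double beta_alpha, double beta_d,
                  double dt, double dx, double horizon,
                  double margin, double stop_mass) {
  if (dx > std::sqrt(dt))
    stop("grid too coarse: dx must be <= sqrt(dt) (unit diffusion)");
  std::vector<double> up, lo, resid;
  int used = propagate(drift, z, a, beta_alpha, beta_d, dt, dx, horizon,
                       margin, stop_mass, up, lo, resid);
  NumericVector tgrid(used), upv(used), lov(used), rv(used);
  for (int i = 0; i < used; ++i) {
    tgrid[i] = (i + 1) * dt;
    upv[i] = up[i]; lov[i] = lo[i]; rv[i] = resid[i];
  }
  return List::create(_["time"] = tgrid, _["upper"] = upv, _["lower"] = lov,
                      _["residual"] = rv);
}

// Total choice/RT log-likelihood for a session. Conditions (unique
// coherence x context cells) are passed as per-condition drift and z plus
// the response times of upper- and lower-bound choices in that cell; the
// density of (choice, rt - t0) is linearly interpolated in time between
// solver grid points and floored at floor_dens.
// [[Rcpp::export]]
double cpp_ddm_loglik(NumericVector drift, NumericVector z, double a,
                      double beta_alpha, double beta_d, double t0,
                      double dt, double dx, double horizon, double margin,
                      double stop_mass, List rt_upper, List rt_lower,
                      double floor_dens) {
  if (dx > std::sqrt(dt))
    stop("grid too coarse: dx must be <= sqrt(dt) (unit diffusion)");
  const int nc = drift.size();
  double ll = 0.0;
  std::vector<double> up, lo, resid;
  for (int c = 0; c < nc; ++c) {
    int used = propagate(drift[c], z[c], a, beta_alpha, beta_d, dt, dx,
                         horizon, margin, stop_mass, up, lo, resid);
    for (int side = 0; side < 2; ++side) {
      NumericVector rts = side == 0 ? (SEXP)rt_upper[c] : (SEXP)rt_lower[c];
      const std::vector<double> &dens = side == 0 ? up : lo;
      for (int i = 0; i < rts.size(); ++i) {
        double td = rts[i] - t0;
        double d = 0.0;
        double pos = td / dt - 1.0;  // grid times are (j+1)*dt
        if (pos >= 0.0 && pos <= used - 1) {
          int j0 = (int)std::floor(pos);
          if (j0 >= used - 1) d = dens[used - 1];
          else {
            double w = pos - j0;
            d = (1.0 - w) * dens[j0] + w * dens[j0 + 1];
          }
        } else if (pos > -1.0 && pos < 0.0) {
          d = dens[0] * (pos + 1.0);  // ramp from 0 at t=0 to the first node
        }
        ll += std::log(std::max(d, floor_dens));
      }
    }
  }
  return ll;
}

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97f4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// Euler simulation of the accumulator between collapsing bounds.
// Per-trial drift and z allow trial-wise parameter fluctuation.
// choice: +1 upper, -1 lower, 0 not absorbed by the horizon.
// Each trial uses its own counter-based RNG stream derived from (seed, trial).
// [[Rcpp::export]]
List cpp_sim_trials(NumericVector drift, NumericVector z, double a,
                    double beta_alpha, double beta_d,
                    double dt, double horizon, int seed) {
  const int n = drift.size();
  const double sd = std::sqrt(dt);
  const int nt = (int)std::round(horizon / dt);
  IntegerVector choice(n);
  NumericVector dtime(n);

  // bounds depend only on t: precompute
  std::vector<double> bu(nt + 1), bl_(nt + 1);
  for (int i = 0; i <= nt; ++i) {
    double B = bound_sep(i * dt, a, beta_alpha, beta_d);
    bu[i] = B; // scaled by (1-z)/z per trial below
    bl_[i] = B;
  }

  for (int tr = 0; tr < n; ++tr) {
    uint64_t s = splitmix64((uint64_t)seed * 0x100000001ULL + (uint64_t)tr);
    std::mt19937_64 rng(s);
    std::normal_distribution<double> norm(0.0, 1.0);
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    const double mu = drift[tr] * dt;
    const double zu = 1.0 - z[tr], zl = z[tr];
    double xv = 0.0;
    int ch = 0;
    double td = NA_REAL;
    for (int i = 0; i < nt; ++i) {
      double xn = xv + mu + sd * norm(rng);
      double u0 = zu * bu[i], u1 = zu * bu[i + 1];
      double l0 = -zl * bl_[i], l1 = -zl * bl_[i + 1];
      // linear interpolation of the path and of the bounds within the step;
      // earliest interpolated crossing wins
      double su = 2.0, sl = 2.0;
      double du0 = xv - u0, du1 = xn - u1;
      if (du1 >= 0.0) su = (du0 >= 0.0) ? 0.0 : du0 / (du0 - du1);
      double dl0 = xv - l0, dl1 = xn - l1;
      if (dl1 <= 0.0) sl = (dl0 <= 0.0) ? 0.0 : dl0 / (dl0 - dl1);
      if (su <= 1.0 || sl <= 1.0) {
        if (su <= sl) { ch = 1; td = (i + su) * dt; }
        else { ch = -1; td = (i + sl) * dt; }
        break;
      }
      // endpoints inside: Brownian-bridge probability of an unseen
      // within-step excursion to either bound
      if (du1 < 0.0 && du0 < 0.0) {
        double pc = std::exp(-2.0 * du0 * du1 / dt);
        if (pc > 1e-12 && unif(rng) < pc) {
          ch = 1; td = (i + 0.5) * dt; break;
        }
      }
      if (dl1 > 0.0 && dl0 > 0.0) {
        double pc = std::exp(-2.0 * dl0 * dl1 / dt);
        if (pc > 1e-12 && unif(rng) < pc) {
          ch = -1; td = (i + 0.5) * dt; break;
        }
      }
      xv = xn;
    }
    choice[tr] = ch;
    dtime[tr] = td;
  }
  return List::create(_["choice"] = choice, _["decision_time"] = dtime);
}
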