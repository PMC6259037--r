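#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Synthetic-trajectory generators. RNG comes from R's stream (unif_rand /
// norm_rand), so set.seed() on the R side makes runs reproducible.

static inline double wrap1g(double d, double L) {
  return d - L * std::round(d / L);
}

static inline double mi_d2g(const double* a, const double* p,
                            const double* box) {
  double dx = wrap1g(a[0] - p[0], box[0]);
  double dy = wrap1g(a[1] - p[1], box[1]);
  double dz = wrap1g(a[2] - p[2], box[2]);
  return dx * dx + dy * dy + dz * dz;
}

static inline void rand_unit(double* u) {
  double n2 = 0.0;
  do {
    n2 = 0.0;
    for (int k = 0; k < 3; ++k) { u[k] = norm_rand(); n2 += u[k] * u[k]; }
  } while (n2 < 1e-12);
  const double inv = 1.0 / std::sqrt(n2);
  for (int k = 0; k < 3; ++k) u[k] *= inv;
}

static double nearest_dist_pt(const double* x, const std::vector<double>& P,
                              int m, const double* box) {
  double best = R_PosInf;
  for (int j = 0; j < m; ++j) {
    double d2 = mi_d2g(x, &P[3 * j], box);
    if (d2 < best) best = d2;
  }
  return std::sqrt(best);
}

// Place chains consistent with a per-frame adsorbed/free state sequence.
// Adsorbed: every bead at surface distance in (lo, cutoff - delta];
// free: every bead farther than cutoff + delta (or anywhere, if
// free_uniform). Placement is rejection-sampled against the *discrete*
// protein atom set, so the geometric state is exactly recoverable by the
// contact-count detector. Adsorption anchors are drawn from the first
// n_anchor protein atoms (a "binding patch" when n_anchor < m); distance
// validation always uses the full set. Positions are resampled every frame
// when resample_all, otherwise only at state changes.
// Returns flat array (nchains*nbeads) x 3 x nframes.
// [[Rcpp::export]]
NumericVector cpp_markov_place(IntegerMatrix states, NumericMatrix Pm,
                               int n_anchor, NumericVector box, double cutoff,
                               double delta, int nbeads, double bond,
                               bool has_sphere, NumericVector center,
                               double Rp, double r_excl,
                               bool resample_all, bool free_uniform) {
  const int nf = states.nrow(), nc = states.ncol(), m = Pm.nrow();
  const double b[3] = {box[0], box[1], box[2]};
  std::vector<double> P(3 * m);
  for (int j = 0; j < m; ++j)
    for (int k = 0; k < 3; ++k) P[3 * j + k] = Pm(j, k);
  const int natoms = nc * nbeads;
  NumericVector out((R_xlen_t)natoms * 3 * nf);
  std::vector<double> rel(3 * nbeads), pos(3 * nbeads);
  const double hi = cutoff - delta;
  if (hi <= 0) stop("shell too thin: cutoff - delta must be > 0");
  if (n_anchor <= 0 || n_anchor > m)
    stop("n_anchor must be in 1..nrow(P)");

  for (int c = 0; c < nc; ++c) {
    for (int f = 0; f < nf; ++f) {
      const bool changed = (f == 0) || (states(f, c) != states(f - 1, c));
      if (!resample_all && !changed) {
        // copy previous frame
        const R_xlen_t o0 = (R_xlen_t)natoms * 3 * (f - 1);
        const R_xlen_t o1 = (R_xlen_t)natoms * 3 * f;
        for (int a = 0; a < nbeads; ++a) {
          const int row = c * nbeads + a;
          for (int k = 0; k < 3; ++k)
            out[o1 + (R_xlen_t)natoms * k + row] =
              out[o0 + (R_xlen_t)natoms * k + row];
        }
        continue;
      }
      const bool ads = states(f, c) == 1;
      bool ok = false;
      for (int attempt = 0; attempt < 20000 && !ok; ++attempt) {
        // fresh compact random-walk conformation
        rel[0] = rel[1] = rel[2] = 0.0;
        for (int a = 1; a < nbeads; ++a) {
          double u[3]; rand_unit(u);
          for (int k = 0; k < 3; ++k)
            rel[3 * a + k] = rel[3 * (a - 1) + k] + bond * u[k];
        }
        double anchor[3];
        if (ads) {
          const int j = (int)(unif_rand() * n_anchor);
          double u[3]; rand_unit(u);
          const double s = unif_rand() * hi;
          for (int k = 0; k < 3; ++k) anchor[k] = P[3 * j + k] + u[k] * s;
        } else {
          for (int k = 0; k < 3; ++k) anchor[k] = unif_rand() * b[k];
        }
        ok = true;
        for (int a = 0; a < nbeads && ok; ++a) {
          double x[3];
          for (int k = 0; k < 3; ++k) {
            x[k] = anchor[k] + rel[3 * a + k];
            x[k] -= b[k] * std::floor(x[k] / b[k]);  // wrap into [0, L)
          }
          // protein-interior exclusion
          if (has_sphere) {
            double dc2 = mi_d2g(x, &center[0], b);
            if (dc2 <= Rp * Rp) { ok = false; break; }
          }
          const double d = nearest_dist_pt(x, P, m, b);
          if (ads) {
            if (d > hi || (!has_sphere && d <= r_excl)) ok = false;
          } else if (!free_uniform) {
            if (d <= cutoff + delta) ok = false;
          } else {
            if (has_sphere) {
              // uniform mode still keeps beads out of the solid sphere
            } else if (d <= r_excl) ok = false;
          }
          if (ok) for (int k = 0; k < 3; ++k) pos[3 * a + k] = x[k];
        }
        if (ok) {
          const R_xlen_t o1 = (R_xlen_t)natoms * 3 * f;
          for (int a = 0; a < nbeads; ++a) {
            const int row = c * nbeads + a;
            for (int k = 0; k < 3; ++k)
              out[o1 + (R_xlen_t)natoms * k + row] = pos[3 * a + k];
          }
        }
      }
      if (!ok)
        stop("chain placement failed after 20000 attempts; the shell "
             "(cutoff - delta) is too thin for the chain geometry");
    }
  }
  return out;
}

// Overdamped (Brownian) dynamics of bead-spring chains around a spherical
// protein. Potentials (kcal/mol, Angstrom):
//   bonds:    k_bond/2 (r - r0)^2
//   angles:   k_angle (1 + cos theta)   (minimum at the straight chain)
//   surface:  -eps_surf exp(-d^2 / 2 sigma_surf^2) outside the sphere
//             (d = radial distance - Rp), harmonic wall k_wall/2 d^2 inside
//   chains:   a_rep exp(-d^2/2 sigma_rep^2)
//             - eps_cc exp(-(d - cc_d0)^2 / 2 sigma_cc^2)  (inter-chain)
// Update: x += (D/kBT) F dt + sqrt(2 D dt) xi. Coordinates are NOT wrapped
// (so displacement statistics need no unwrapping); all pair displacements
// use the minimum image.
// [[Rcpp::export]]
NumericVector cpp_bd_run(NumericMatrix X0, IntegerMatrix bonds,
                         double k_bond, double r0, IntegerMatrix angles,
                         double k_angle, IntegerVector chain_of,
                         double eps_surf, double sigma_surf,
                         NumericVector center, double Rp, double k_wall,
                         double eps_cc, double sigma_cc, double cc_d0,
                         double a_rep, double sigma_rep,
                         double D, double kBT, double dt,
                         int nsteps, int save_every, NumericVector box) {
  const int n = X0.nrow(), nb = bonds.nrow(), na = angles.nrow();
  const double b[3] = {box[0], box[1], box[2]};
  const int nsave = nsteps / save_every;
  NumericVector out((R_xlen_t)n * 3 * nsave);
  std::vector<double> x(3 * n), F(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = X0(i, k);
  const double mob = D / kBT;
  const double noise = std::sqrt(2.0 * D * dt);
  const double cc_cut = cc_d0 + 4.0 * sigma_cc + 4.0 * sigma_rep;
  const double cc_cut2 = cc_cut * cc_cut;
  const bool pair_on = (eps_cc != 0.0 || a_rep != 0.0);
  int isave = 0;

  for (int step = 1; step <= nsteps; ++step) {
    std::fill(F.begin(), F.end(), 0.0);
    // bonds
    for (int e = 0; e < nb; ++e) {
      const int i = bonds(e, 0), j = bonds(e, 1);
      double d[3];
      for (int k = 0; k < 3; ++k)
        d[k] = wrap1g(x[3 * i + k] - x[3 * j + k], b[k]);
      const double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
      if (r < 1e-9) continue;
      const double fmag = -k_bond * (r - r0) / r;
      for (int k = 0; k < 3; ++k) {
        F[3 * i + k] += fmag * d[k];
        F[3 * j + k] -= fmag * d[k];
      }
    }
    // angles: U = k_angle (1 + cos theta), i-j-k with j central
    for (int e = 0; e < na; ++e) {
      const int i = angles(e, 0), j = angles(e, 1), kk = angles(e, 2);
      double a[3], c[3];
      for (int k = 0; k < 3; ++k) {
        a[k] = wrap1g(x[3 * i + k] - x[3 * j + k], b[k]);
        c[k] = wrap1g(x[3 * kk + k] - x[3 * j + k], b[k]);
      }
      const double la = std::sqrt(a[0]*a[0] + a[1]*a[1] + a[2]*a[2]);
      const double lc = std::sqrt(c[0]*c[0] + c[1]*c[1] + c[2]*c[2]);
      if (la < 1e-9 || lc < 1e-9) continue;
      const double dot = a[0]*c[0] + a[1]*c[1] + a[2]*c[2];
      const double cosq = dot / (la * lc);
      // dU/dcos = k_angle; F = -k_angle * dcos/dx
      for (int k = 0; k < 3; ++k) {
        const double dca = c[k] / (la * lc) - cosq * a[k] / (la * la);
        const double dcc = a[k] / (la * lc) - cosq * c[k] / (lc * lc);
        F[3 * i + k]  += -k_angle * dca;
        F[3 * kk + k] += -k_angle * dcc;
        F[3 * j + k]  +=  k_angle * (dca + dcc);
      }
    }
    // protein surface well / wall (radial, about the sphere center)
    if (eps_surf != 0.0 || k_wall != 0.0) {
      for (int i = 0; i < n; ++i) {
        double d[3];
        for (int k = 0; k < 3; ++k)
          d[k] = wrap1g(x[3 * i + k] - center[k], b[k]);
        const double r = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
        if (r < 1e-9) continue;
        const double h = r - Rp;
        double dudh;
        if (h >= 0.0) {
          const double s2 = sigma_surf * sigma_surf;
          dudh = eps_surf * h / s2 * std::exp(-h * h / (2.0 * s2));
        } else {
          dudh = k_wall * h;
        }
        const double fmag = -dudh / r;
        for (int k = 0; k < 3; ++k) F[3 * i + k] += fmag * d[k];
      }
    }
    // inter-chain pair interactions
    if (pair_on) {
      for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
          if (chain_of[i] == chain_of[j]) continue;
          double d[3];
          for (int k = 0; k < 3; ++k)
            d[k] = wrap1g(x[3 * i + k] - x[3 * j + k], b[k]);
          const double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
          if (r2 > cc_cut2 || r2 < 1e-12) continue;
          const double r = std::sqrt(r2);
          const double sr2 = sigma_rep * sigma_rep;
          const double sc2 = sigma_cc * sigma_cc;
          double dudr = -a_rep * r / sr2 * std::exp(-r2 / (2.0 * sr2));
          dudr += eps_cc * (r - cc_d0) / sc2 *
                  std::exp(-(r - cc_d0) * (r - cc_d0) / (2.0 * sc2));
          const double fmag = -dudr / r;
          for (int k = 0; k < 3; ++k) {
            F[3 * i + k] += fmag * d[k];
            F[3 * j + k] -= fmag * d[k];
          }
        }
      }
    }
    // Euler-Maruyama update
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k)
        x[3 * i + k] += mob * F[3 * i + k] * dt + noise * norm_rand();
    // divergence check
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k)
        if (!std::isfinite(x[3 * i + k]) ||
            std::fabs(x[3 * i + k]) > 10.0 * b[k])
          stop("Brownian dynamics diverged (|x| > 10 box); "
               "use a smaller timestep");
    if (step % save_every == 0) {
      const R_xlen_t off = (R_xlen_t)n * 3 * isave;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k)
          out[off + (R_xlen_t)n * k + i] = x[3 * i + k];
      ++isave;
    }
  }
  return out;
}
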