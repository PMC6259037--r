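#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Minimum-image convention for orthorhombic boxes. All coordinates in
// Angstrom. Hot loops for trajectory analysis live here.

static inline double wrap1(double d, double L) {
  return d - L * std::round(d / L);
}

static inline double mi_d2(double ax, double ay, double az,
                           double bx, double by, double bz,
                           const double* box) {
  double dx = wrap1(ax - bx, box[0]);
  double dy = wrap1(ay - by, box[1]);
  double dz = wrap1(az - bz, box[2]);
  return dx * dx + dy * dy + dz * dz;
}

// distance of every row of X to its nearest row of P (minimum image)
// [[Rcpp::export]]
NumericVector cpp_nearest_dist(NumericMatrix X, NumericMatrix P,
                               NumericVector box) {
  const int n = X.nrow(), m = P.nrow();
  const double b[3] = {box[0], box[1], box[2]};
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    const double xi = X(i, 0), yi = X(i, 1), zi = X(i, 2);
    for (int j = 0; j < m; ++j) {
      double d2 = mi_d2(xi, yi, zi, P(j, 0), P(j, 1), P(j, 2), b);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// 1 if a row of X lies within cutoff of any row of P. Uses a periodic
// cell list (cells >= cutoff) so bulk queries touch only 27 cells.
// [[Rcpp::export]]
IntegerVector cpp_within_any(NumericMatrix X, NumericMatrix P,
                             NumericVector box, double cutoff) {
  const int n = X.nrow(), m = P.nrow();
  const double b[3] = {box[0], box[1], box[2]};
  const double c2 = cutoff * cutoff;
  IntegerVector out(n);
  int nc[3];
  for (int k = 0; k < 3; ++k) {
    nc[k] = (int)std::floor(b[k] / cutoff);
    if (nc[k] < 1) nc[k] = 1;
    if (nc[k] > 64) nc[k] = 64;
  }
  const int ncell = nc[0] * nc[1] * nc[2];
  if (ncell < 27) {
    // box too small for a useful grid: plain early-exit scan
    for (int i = 0; i < n; ++i) {
      const double xi = X(i, 0), yi = X(i, 1), zi = X(i, 2);
      for (int j = 0; j < m; ++j)
        if (mi_d2(xi, yi, zi, P(j, 0), P(j, 1), P(j, 2), b) <= c2) {
          out[i] = 1; break;
        }
    }
    return out;
  }
  // bin the reference atoms
  std::vector< std::vector<int> > cells(ncell);
  std::vector<double> Pw(3 * m);
  for (int j = 0; j < m; ++j) {
    int c[3];
    for (int k = 0; k < 3; ++k) {
      double w = P(j, k) - b[k] * std::floor(P(j, k) / b[k]);
      Pw[3 * j + k] = w;
      c[k] = (int)(w / b[k] * nc[k]);
      if (c[k] >= nc[k]) c[k] = nc[k] - 1;
    }
    cells[c[0] + nc[0] * (c[1] + nc[1] * c[2])].push_back(j);
  }
  for (int i = 0; i < n; ++i) {
    double xw[3];
    int ci[3];
    for (int k = 0; k < 3; ++k) {
      xw[k] = X(i, k) - b[k] * std::floor(X(i, k) / b[k]);
      ci[k] = (int)(xw[k] / b[k] * nc[k]);
      if (ci[k] >= nc[k]) ci[k] = nc[k] - 1;
    }
    int hit = 0;
    for (int dz = -1; dz <= 1 && !hit; ++dz)
      for (int dy = -1; dy <= 1 && !hit; ++dy)
        for (int dx = -1; dx <= 1 && !hit; ++dx) {
          const int cx = (ci[0] + dx + nc[0]) % nc[0];
          const int cy = (ci[1] + dy + nc[1]) % nc[1];
          const int cz = (ci[2] + dz + nc[2]) % nc[2];
          const std::vector<int>& cell = cells[cx + nc[0] * (cy + nc[1] * cz)];
          for (size_t a = 0; a < cell.size(); ++a) {
            const int j = cell[a];
            if (mi_d2(xw[0], xw[1], xw[2], Pw[3 * j], Pw[3 * j + 1],
                      Pw[3 * j + 2], b) <= c2) { hit = 1; break; }
          }
        }
    out[i] = hit;
  }
  return out;
}

// nearest-protein distances for selected atoms over selected frames.
// coords: natoms x 3 x nframes array (as a flat vector), indices 0-based.
// [[Rcpp::export]]
NumericMatrix cpp_surface_dist_traj(NumericVector coords, int natoms,
                                    IntegerVector sel_idx,
                                    IntegerVector prot_idx,
                                    NumericMatrix boxes,
                                    IntegerVector frames) {
  const int ns = sel_idx.size(), np = prot_idx.size(), nf = frames.size();
  NumericMatrix out(nf, ns);
  std::vector<double> P(np * 3);
  for (int fi = 0; fi < nf; ++fi) {
    const int f = frames[fi];
    const double b[3] = {boxes(f, 0), boxes(f, 1), boxes(f, 2)};
    const R_xlen_t off = (R_xlen_t)natoms * 3 * f;
    for (int j = 0; j < np; ++j)
      for (int k = 0; k < 3; ++k)
        P[j * 3 + k] = coords[off + (R_xlen_t)natoms * k + prot_idx[j]];
    for (int i = 0; i < ns; ++i) {
      const double xi = coords[off + sel_idx[i]];
      const double yi = coords[off + natoms + sel_idx[i]];
      const double zi = coords[off + 2 * (R_xlen_t)natoms + sel_idx[i]];
      double best = R_PosInf;
      for (int j = 0; j < np; ++j) {
        double d2 = mi_d2(xi, yi, zi, P[j * 3], P[j * 3 + 1], P[j * 3 + 2], b);
        if (d2 < best) best = d2;
      }
      out(fi, i) = std::sqrt(best);
    }
  }
  return out;
}

// per-frame, per-chain counts of polymer heavy atoms within cutoff of any
// protein heavy atom (the quantity driving the hysteresis state machine).
// [[Rcpp::export]]
IntegerMatrix cpp_contact_counts(NumericVector coords, int natoms,
                                 IntegerVector poly_idx,
                                 IntegerVector chain_of, int nchains,
                                 IntegerVector prot_idx,
                                 NumericMatrix boxes, double cutoff) {
  const int np = prot_idx.size(), na = poly_idx.size();
  const int nf = boxes.nrow();
  const double c2 = cutoff * cutoff;
  IntegerMatrix out(nf, nchains);
  std::vector<double> P(np * 3);
  for (int f = 0; f < nf; ++f) {
    const double b[3] = {boxes(f, 0), boxes(f, 1), boxes(f, 2)};
    const R_xlen_t off = (R_xlen_t)natoms * 3 * f;
    for (int j = 0; j < np; ++j)
      for (int k = 0; k < 3; ++k)
        P[j * 3 + k] = coords[off + (R_xlen_t)natoms * k + prot_idx[j]];
    for (int i = 0; i < na; ++i) {
      const double xi = coords[off + poly_idx[i]];
      const double yi = coords[off + natoms + poly_idx[i]];
      const double zi = coords[off + 2 * (R_xlen_t)natoms + poly_idx[i]];
      for (int j = 0; j < np; ++j) {
        if (mi_d2(xi, yi, zi, P[j * 3], P[j * 3 + 1], P[j * 3 + 2], b) <= c2) {
          out(f, chain_of[i]) += 1;
          break;
        }
      }
    }
  }
  return out;
}

// dual-threshold (hysteresis) state machine: a free chain becomes adsorbed
// when more than half of its heavy atoms are within the cutoff; an adsorbed
// chain becomes free only when no atom remains within the cutoff.
// states: 1 = adsorbed, 0 = free. Initial state from the adsorption rule.
// [[Rcpp::export]]
IntegerMatrix cpp_hysteresis(IntegerMatrix counts, IntegerVector nheavy) {
  const int nf = counts.nrow(), nc = counts.ncol();
  IntegerMatrix st(nf, nc);
  for (int c = 0; c < nc; ++c) {
    const int half = nheavy[c] / 2;  // "more than half" = count > floor(n/2)
    int s = counts(0, c) > half ? 1 : 0;
    st(0, c) = s;
    for (int f = 1; f < nf; ++f) {
      const int k = counts(f, c);
      if (s == 0 && k > half) s = 1;
      else if (s == 1 && k == 0) s = 0;
      st(f, c) = s;
    }
  }
  return st;
}

// histogram of all cross pair distances between rows of X and rows of W
// (minimum image); bin i counts distances in ((i)*dr, (i+1)*dr] with the
// first bin closed at 0.
// [[Rcpp::export]]
NumericVector cpp_cross_dist_counts(NumericMatrix X, NumericMatrix W,
                                    NumericVector box, double rmax,
                                    double dr) {
  const int n = X.nrow(), m = W.nrow();
  const double b[3] = {box[0], box[1], box[2]};
  const int nbins = (int)std::ceil(rmax / dr);
  const double r2max = rmax * rmax;
  NumericVector out(nbins);
  for (int i = 0; i < n; ++i) {
    const double xi = X(i, 0), yi = X(i, 1), zi = X(i, 2);
    for (int j = 0; j < m; ++j) {
      double d2 = mi_d2(xi, yi, zi, W(j, 0), W(j, 1), W(j, 2), b);
      if (d2 <= r2max) {
        int bin = (int)(std::sqrt(d2) / dr);
        if (bin >= nbins) bin = nbins - 1;
        out[bin] += 1.0;
      }
    }
  }
  return out;
}

// per-residue counts: each row of X is counted once for every residue that
// has at least one atom within cutoff (overlapping residue shells allowed).
// resid0: 0-based residue index per protein atom row.
// [[Rcpp::export]]
NumericVector cpp_residue_counts(NumericMatrix X, NumericMatrix P,
                                 IntegerVector resid0, int nres,
                                 NumericVector box, double cutoff) {
  const int n = X.nrow(), m = P.nrow();
  const double b[3] = {box[0], box[1], box[2]};
  const double c2 = cutoff * cutoff;
  NumericVector out(nres);
  std::vector<int> stamp(nres, -1);
  for (int i = 0; i < n; ++i) {
    const double xi = X(i, 0), yi = X(i, 1), zi = X(i, 2);
    for (int j = 0; j < m; ++j) {
      if (mi_d2(xi, yi, zi, P(j, 0), P(j, 1), P(j, 2), b) <= c2) {
        const int r = resid0[j];
        if (stamp[r] != i) { stamp[r] = i; out[r] += 1.0; }
      }
    }
  }
  return out;
}

// chain-chain contact edges: chains u < v connected when the minimum
// inter-chain heavy-atom distance is <= cutoff (early exit per pair).
// chain_of: 0-based chain index per row of X. Returns 1-based edge matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_chain_edges(NumericMatrix X, IntegerVector chain_of,
                              int nchains, NumericVector box, double cutoff) {
  const int n = X.nrow();
  const double b[3] = {box[0], box[1], box[2]};
  const double c2 = cutoff * cutoff;
  // group atom indices per chain
  std::vector< std::vector<int> > members(nchains);
  for (int i = 0; i < n; ++i) members[chain_of[i]].push_back(i);
  std::vector<int> eu, ev;
  for (int u = 0; u < nchains; ++u) {
    for (int v = u + 1; v < nchains; ++v) {
      bool hit = false;
      for (size_t a = 0; a < members[u].size() && !hit; ++a) {
        const int i = members[u][a];
        const double xi = X(i, 0), yi = X(i, 1), zi = X(i, 2);
        for (size_t bb_ = 0; bb_ < members[v].size(); ++bb_) {
          const int j = members[v][bb_];
          if (mi_d2(xi, yi, zi, X(j, 0), X(j, 1), X(j, 2), b) <= c2) {
            hit = true; break;
          }
        }
      }
      if (hit) { eu.push_back(u + 1); ev.push_back(v + 1); }
    }
  }
  IntegerMatrix out(eu.size(), 2);
  for (size_t e = 0; e < eu.size(); ++e) {
    out(e, 0) = eu[e]; out(e, 1) = ev[e];
  }
  return out;
}

// mean square displacement over lag times with all available time origins.
// coords must be unwrapped; natoms x 3 x nframes flat array.
// [[Rcpp::export]]
NumericVector cpp_msd(NumericVector coords, int natoms, int nframes,
                      IntegerVector sel_idx, IntegerVector lags) {
  const int ns = sel_idx.size(), nl = lags.size();
  NumericVector out(nl);
  for (int li = 0; li < nl; ++li) {
    const int lag = lags[li];
    if (lag <= 0 || lag >= nframes) { out[li] = NA_REAL; continue; }
    double acc = 0.0;
    R_xlen_t cnt = 0;
    for (int t = 0; t + lag < nframes; ++t) {
      const R_xlen_t o1 = (R_xlen_t)natoms * 3 * t;
      const R_xlen_t o2 = (R_xlen_t)natoms * 3 * (t + lag);
      for (int i = 0; i < ns; ++i) {
        const int a = sel_idx[i];
        double dx = coords[o2 + a] - coords[o1 + a];
        double dy = coords[o2 + natoms + a] - coords[o1 + natoms + a];
        double dz = coords[o2 + 2 * (R_xlen_t)natoms + a] -
                    coords[o1 + 2 * (R_xlen_t)natoms + a];
        acc += dx * dx + dy * dy + dz * dz;
        ++cnt;
      }
    }
    out[li] = acc / (double)cnt;
  }
  return out;
}
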