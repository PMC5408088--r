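// Numerical kernels for the vascular-factory simulator.
//
// Grid convention (shared with the R side): fields are numeric matrices with
// row i = y index (row 1 at the bottom of the domain), column j = x index;
// the center of pixel (i, j) (1-based in R) sits at ((j - 0.5) h, (i - 0.5) h)
// in micrometres. All boundaries are zero-flux (mirror).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Solute field stepper: one explicit forward-Euler diffusion step (5-point
// Laplacian, mirror borders), source added explicitly, first-order decay
// applied as an exact exponential factor (unconditionally sign-preserving).
// C_new = exp(-beta dt) * (C + dt D lap C) + dt S
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_step_solute(const NumericMatrix& C, const NumericMatrix& S,
                              double D, double beta, double dt, double h) {
  const int nr = C.nrow(), nc = C.ncol();
  NumericMatrix out(nr, nc);
  const double a = dt * D / (h * h);
  const double e = std::exp(-beta * dt);
  for (int j = 0; j < nc; ++j) {
    const int jl = (j == 0) ? 0 : j - 1;
    const int jr = (j == nc - 1) ? nc - 1 : j + 1;
    for (int i = 0; i < nr; ++i) {
      const int id = (i == 0) ? 0 : i - 1;
      const int iu = (i == nr - 1) ? nr - 1 : i + 1;
      const double c = C(i, j);
      const double lap = C(iu, j) + C(id, j) + C(i, jr) + C(i, jl) - 4.0 * c;
      out(i, j) = e * (c + a * lap) + dt * S(i, j);
    }
  }
  return out;
}

// Repeated step_solute until the relative per-step change falls below tol
// (warm start friendly). Returns the relaxed field, iterations used and the
// final relative change.
// [[Rcpp::export]]
List cpp_relax_solute(NumericMatrix C, const NumericMatrix& S,
                      double D, double beta, double dt, double h,
                      int max_iters, double tol) {
  const int nr = C.nrow(), nc = C.ncol();
  NumericMatrix cur = clone(C);
  double rel = R_PosInf;
  int it = 0;
  for (; it < max_iters; ++it) {
    NumericMatrix nxt = cpp_step_solute(cur, S, D, beta, dt, h);
    double dmax = 0.0, vmax = 0.0;
    for (int j = 0; j < nc; ++j) for (int i = 0; i < nr; ++i) {
      const double d = std::fabs(nxt(i, j) - cur(i, j));
      if (d > dmax) dmax = d;
      const double v = std::fabs(nxt(i, j));
      if (v > vmax) vmax = v;
    }
    cur = nxt;
    rel = (vmax > 0.0) ? dmax / vmax : 0.0;
    if (rel < tol) { ++it; break; }
  }
  return List::create(_["field"] = cur, _["iters"] = it, _["rel_change"] = rel);
}

// ---------------------------------------------------------------------------
// Bilinear sampling of a field at continuous (x, y) positions, clamped to the
// domain interior (nearest valid sample point).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_bilinear(const NumericMatrix& C, const NumericVector& x,
                           const NumericVector& y, double h) {
  const int nr = C.nrow(), nc = C.ncol(), n = x.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    double fx = x[k] / h - 0.5;
    double fy = y[k] / h - 0.5;
    if (fx < 0) fx = 0; else if (fx > nc - 1) fx = nc - 1;
    if (fy < 0) fy = 0; else if (fy > nr - 1) fy = nr - 1;
    int j0 = (int)std::floor(fx), i0 = (int)std::floor(fy);
    if (j0 > nc - 2) j0 = std::max(0, nc - 2);
    if (i0 > nr - 2) i0 = std::max(0, nr - 2);
    const int j1 = std::min(j0 + 1, nc - 1), i1 = std::min(i0 + 1, nr - 1);
    const double tx = fx - j0, ty = fy - i0;
    out[k] = (1 - ty) * ((1 - tx) * C(i0, j0) + tx * C(i0, j1)) +
             ty  * ((1 - tx) * C(i1, j0) + tx * C(i1, j1));
  }
  return out;
}

// ---------------------------------------------------------------------------
// Particle rasterization: pixel true iff its center lies within distance
// radius of any selected particle.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalMatrix cpp_rasterize(const NumericVector& x, const NumericVector& y,
                            const NumericVector& r, int nr, int nc, double h) {
  LogicalMatrix M(nr, nc);
  const int n = x.size();
  for (int k = 0; k < n; ++k) {
    const double rk = r[k], r2 = rk * rk;
    int j0 = (int)std::floor((x[k] - rk) / h - 0.5);
    int j1 = (int)std::ceil((x[k] + rk) / h - 0.5);
    int i0 = (int)std::floor((y[k] - rk) / h - 0.5);
    int i1 = (int)std::ceil((y[k] + rk) / h - 0.5);
    j0 = std::max(j0, 0); i0 = std::max(i0, 0);
    j1 = std::min(j1, nc - 1); i1 = std::min(i1, nr - 1);
    for (int j = j0; j <= j1; ++j) {
      const double dx = (j + 0.5) * h - x[k];
      for (int i = i0; i <= i1; ++i) {
        const double dy = (i + 0.5) * h - y[k];
        if (dx * dx + dy * dy <= r2) M(i, j) = true;
      }
    }
  }
  return M;
}

// Deposit per-particle rates onto the pixels each particle covers, divided by
// the covered area (rate is mass/time per particle; the source field is in
// concentration/time, concentration = mass per unit area). Returns a new
// source matrix = base + deposits.
// [[Rcpp::export]]
NumericMatrix cpp_deposit(const NumericMatrix& base, const NumericVector& x,
                          const NumericVector& y, const NumericVector& r,
                          const NumericVector& rate, double h) {
  NumericMatrix S = clone(base);
  const int nr = S.nrow(), nc = S.ncol(), n = x.size();
  std::vector<int> px;
  px.reserve(64);
  for (int k = 0; k < n; ++k) {
    if (rate[k] == 0.0) continue;
    const double rk = r[k], r2 = rk * rk;
    int j0 = std::max((int)std::floor((x[k] - rk) / h - 0.5), 0);
    int j1 = std::min((int)std::ceil((x[k] + rk) / h - 0.5), nc - 1);
    int i0 = std::max((int)std::floor((y[k] - rk) / h - 0.5), 0);
    int i1 = std::min((int)std::ceil((y[k] + rk) / h - 0.5), nr - 1);
    px.clear();
    for (int j = j0; j <= j1; ++j) {
      const double dx = (j + 0.5) * h - x[k];
      for (int i = i0; i <= i1; ++i) {
        const double dy = (i + 0.5) * h - y[k];
        if (dx * dx + dy * dy <= r2) px.push_back(i + j * nr);
      }
    }
    if (px.empty()) {
      // particle smaller than a pixel or centered off-grid: nearest pixel
      int j = std::min(std::max((int)std::floor(x[k] / h), 0), nc - 1);
      int i = std::min(std::max((int)std::floor(y[k] / h), 0), nr - 1);
      px.push_back(i + j * nr);
    }
    const double add = rate[k] / (px.size() * h * h);
    for (size_t q = 0; q < px.size(); ++q) S[px[q]] += add;
  }
  return S;
}

// ---------------------------------------------------------------------------
// Uniform-grid neighbor search helpers for pairwise mechanics.
// ---------------------------------------------------------------------------

struct BinGrid {
  double cell;            // bin side
  int nx, ny;
  std::vector<std::vector<int>> bins;
  BinGrid(const NumericVector& x, const NumericVector& y,
          double W, double H, double cell_)
      : cell(cell_) {
    nx = std::max(1, (int)std::floor(W / cell));
    ny = std::max(1, (int)std::floor(H / cell));
    bins.assign((size_t)nx * ny, {});
    for (int k = 0; k < x.size(); ++k) bins[index(x[k], y[k])].push_back(k);
  }
  int index(double px, double py) const {
    int bx = std::min(std::max((int)(px / cell), 0), nx - 1);
    int by = std::min(std::max((int)(py / cell), 0), ny - 1);
    return by + bx * ny;
  }
  template <typename F>
  void for_neighbors(double px, double py, F f) const {
    int bx = std::min(std::max((int)(px / cell), 0), nx - 1);
    int by = std::min(std::max((int)(py / cell), 0), ny - 1);
    for (int dx = -1; dx <= 1; ++dx) {
      const int cx = bx + dx;
      if (cx < 0 || cx >= nx) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        const int cy = by + dy;
        if (cy < 0 || cy >= ny) continue;
        const std::vector<int>& b = bins[(size_t)cy + (size_t)cx * ny];
        for (size_t q = 0; q < b.size(); ++q) f(b[q]);
      }
    }
  }
};

// Pairwise adhesion between vascular particles: attractive force of magnitude
// strength * (1 - g / range) along the separation axis for surface gaps
// 0 < g <= range; antisymmetric. Returns an n x 2 force matrix.
// [[Rcpp::export]]
NumericMatrix cpp_adhesion_forces(const NumericVector& x, const NumericVector& y,
                                  const NumericVector& r, const LogicalVector& vasc,
                                  double strength, double range,
                                  double W, double H) {
  const int n = x.size();
  NumericMatrix F(n, 2);
  if (strength == 0.0 || range <= 0.0) return F;
  double rmax = 0.0;
  for (int k = 0; k < n; ++k) rmax = std::max(rmax, r[k]);
  BinGrid grid(x, y, W, H, 2.0 * rmax + range);
  for (int a = 0; a < n; ++a) {
    if (!vasc[a]) continue;
    grid.for_neighbors(x[a], y[a], [&](int b) {
      if (b <= a || !vasc[b]) return;
      const double dx = x[b] - x[a], dy = y[b] - y[a];
      const double d = std::sqrt(dx * dx + dy * dy);
      const double g = d - (r[a] + r[b]);
      if (g <= 0.0 || g > range || d == 0.0) return;
      const double mag = strength * (1.0 - g / range);
      const double fx = mag * dx / d, fy = mag * dy / d;
      F(a, 0) += fx; F(a, 1) += fy;
      F(b, 0) -= fx; F(b, 1) -= fy;
    });
  }
  return F;
}

// Count, for each selected particle, selected neighbors with surface gap
// <= range (used for cord-formation metrics).
// [[Rcpp::export]]
IntegerVector cpp_neighbor_counts(const NumericVector& x, const NumericVector& y,
                                  const NumericVector& r, const LogicalVector& sel,
                                  double range, double W, double H) {
  const int n = x.size();
  IntegerVector cnt(n);
  double rmax = 0.0;
  for (int k = 0; k < n; ++k) rmax = std::max(rmax, r[k]);
  BinGrid grid(x, y, W, H, 2.0 * rmax + std::max(range, 1e-9));
  for (int a = 0; a < n; ++a) {
    if (!sel[a]) continue;
    grid.for_neighbors(x[a], y[a], [&](int b) {
      if (b == a || !sel[b]) return;
      const double dx = x[b] - x[a], dy = y[b] - y[a];
      const double d = std::sqrt(dx * dx + dy * dy);
      if (d - (r[a] + r[b]) <= range) cnt[a] += 1;
    });
  }
  return cnt;
}

// All unordered pairs (a, b), a < b, of selected particles whose surface gap
// is <= gap. Returns an m x 2 matrix of 1-based indices (used to form
// adhesion bonds).
// [[Rcpp::export]]
IntegerMatrix cpp_pairs_within(const NumericVector& x, const NumericVector& y,
                               const NumericVector& r, const LogicalVector& sel,
                               double gap, double W, double H) {
  const int n = x.size();
  std::vector<int> ia, ib;
  double rmax = 0.0;
  for (int k = 0; k < n; ++k) rmax = std::max(rmax, r[k]);
  BinGrid grid(x, y, W, H, 2.0 * rmax + std::max(gap, 1e-9));
  for (int a = 0; a < n; ++a) {
    if (!sel[a]) continue;
    grid.for_neighbors(x[a], y[a], [&](int b) {
      if (b <= a || !sel[b]) return;
      const double dx = x[b] - x[a], dy = y[b] - y[a];
      const double d = std::sqrt(dx * dx + dy * dy);
      if (d - (r[a] + r[b]) <= gap) { ia.push_back(a + 1); ib.push_back(b + 1); }
    });
  }
  IntegerMatrix out(ia.size(), 2);
  for (size_t k = 0; k < ia.size(); ++k) { out(k, 0) = ia[k]; out(k, 1) = ib[k]; }
  return out;
}

// Rasterize capsules (thickened segments): a pixel is set when its center
// lies within rad of any segment (x1,y1)-(x2,y2). Grid convention matches
// cpp_rasterize: pixel (i, j) center is at ((j-0.5)h, (i-0.5)h), row 1 at the
// bottom.
// [[Rcpp::export]]
LogicalMatrix cpp_rasterize_capsules(const NumericVector& x1, const NumericVector& y1,
                                     const NumericVector& x2, const NumericVector& y2,
                                     double rad, int nr, int nc, double h) {
  LogicalMatrix out(nr, nc);
  for (int k = 0; k < x1.size(); ++k) {
    const double ax = x1[k], ay = y1[k], bx = x2[k], by = y2[k];
    const double lo_x = std::min(ax, bx) - rad, hi_x = std::max(ax, bx) + rad;
    const double lo_y = std::min(ay, by) - rad, hi_y = std::max(ay, by) + rad;
    const int j0 = std::max(0, (int)std::floor(lo_x / h - 0.5));
    const int j1 = std::min(nc - 1, (int)std::ceil(hi_x / h - 0.5));
    const int i0 = std::max(0, (int)std::floor(lo_y / h - 0.5));
    const int i1 = std::min(nr - 1, (int)std::ceil(hi_y / h - 0.5));
    const double ux = bx - ax, uy = by - ay;
    const double len2 = ux * ux + uy * uy;
    for (int i = i0; i <= i1; ++i) {
      const double py = (i + 0.5) * h;
      for (int j = j0; j <= j1; ++j) {
        if (out(i, j)) continue;
        const double px = (j + 0.5) * h;
        double t = len2 > 0 ? ((px - ax) * ux + (py - ay) * uy) / len2 : 0.0;
        t = std::min(1.0, std::max(0.0, t));
        const double dx = px - (ax + t * ux), dy = py - (ay + t * uy);
        if (dx * dx + dy * dy <= rad * rad) out(i, j) = true;
      }
    }
  }
  return out;
}

// Contact geometry of selected particles: for each selected particle, the
// number of selected neighbors whose surface gap is <= range and the sum of
// unit vectors pointing from the particle to those neighbors (the "contact
// direction"; near zero for particles contacted symmetrically on all sides).
// [[Rcpp::export]]
List cpp_contact_vectors(const NumericVector& x, const NumericVector& y,
                         const NumericVector& r, const LogicalVector& sel,
                         double range, double W, double H) {
  const int n = x.size();
  IntegerVector cnt(n);
  NumericVector vx(n), vy(n);
  double rmax = 0.0;
  for (int k = 0; k < n; ++k) rmax = std::max(rmax, r[k]);
  BinGrid grid(x, y, W, H, 2.0 * rmax + std::max(range, 1e-9));
  for (int a = 0; a < n; ++a) {
    if (!sel[a]) continue;
    grid.for_neighbors(x[a], y[a], [&](int b) {
      if (b == a || !sel[b]) return;
      const double dx = x[b] - x[a], dy = y[b] - y[a];
      const double d = std::sqrt(dx * dx + dy * dy);
      if (d > 0 && d - (r[a] + r[b]) <= range) {
        cnt[a] += 1;
        vx[a] += dx / d;
        vy[a] += dy / d;
      }
    });
  }
  return List::create(_["count"] = cnt, _["vx"] = vx, _["vy"] = vy);
}

// Shoving relaxation: sequential passes over overlapping pairs; each pair
// overlapping by o > tol is displaced o/2 each along the separation axis
// (immovable particles pass their share to the partner). Positions are
// clamped into [0, W) x [0, H). Returns updated positions, the largest
// single-particle displacement of the final pass, the number of passes and
// whether the pass loop converged.
// [[Rcpp::export]]
List cpp_relax_shoving(NumericVector x0, NumericVector y0, const NumericVector& r,
                       const LogicalVector& movable, double tol, int max_iters,
                       double W, double H) {
  NumericVector x = clone(x0), y = clone(y0);
  const int n = x.size();
  double rmax = 0.0;
  for (int k = 0; k < n; ++k) rmax = std::max(rmax, r[k]);
  const double eps = 1e-9;
  double last_max_disp = 0.0;
  bool converged = false;
  int pass = 0;
  for (; pass < max_iters; ++pass) {
    BinGrid grid(x, y, W, H, 2.0 * rmax + eps);
    double max_disp = 0.0;
    for (int a = 0; a < n; ++a) {
      grid.for_neighbors(x[a], y[a], [&](int b) {
        if (b <= a) return;
        double dx = x[b] - x[a], dy = y[b] - y[a];
        double d = std::sqrt(dx * dx + dy * dy);
        const double o = (r[a] + r[b]) - d;
        if (o <= tol) return;
        double ux, uy;
        if (d < eps) { ux = 1.0; uy = 0.0; }   // coincident: deterministic axis
        else { ux = dx / d; uy = dy / d; }
        const bool ma = movable[a], mb = movable[b];
        if (ma && mb) {
          x[a] -= 0.5 * o * ux; y[a] -= 0.5 * o * uy;
          x[b] += 0.5 * o * ux; y[b] += 0.5 * o * uy;
          max_disp = std::max(max_disp, 0.5 * o);
        } else if (ma) {
          x[a] -= o * ux; y[a] -= o * uy;
          max_disp = std::max(max_disp, o);
        } else if (mb) {
          x[b] += o * ux; y[b] += o * uy;
          max_disp = std::max(max_disp, o);
        }
      });
    }
    // clamp into the half-open domain
    for (int k = 0; k < n; ++k) {
      if (!movable[k]) continue;
      if (x[k] < 0) x[k] = 0; else if (x[k] >= W) x[k] = W - 1e-6;
      if (y[k] < 0) y[k] = 0; else if (y[k] >= H) y[k] = H - 1e-6;
    }
    last_max_disp = max_disp;
    if (max_disp <= tol) { converged = true; ++pass; break; }
  }
  return List::create(_["x"] = x, _["y"] = y,
                      _["max_displacement"] = last_max_disp,
                      _["passes"] = pass, _["converged"] = converged);
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher):
// distance, in pixel units, from each true pixel to the nearest false pixel
// center. False pixels get 0.
// ---------------------------------------------------------------------------

static void dt1d(const std::vector<double>& f, std::vector<double>& d) {
  const int n = (int)f.size();
  d.assign(n, 0.0);
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_edt(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e18;
  std::vector<double> g((size_t)nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      g[(size_t)i + (size_t)j * nr] = mask(i, j) ? INF : 0.0;
  // columns
  std::vector<double> f(nr), d;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = g[(size_t)i + (size_t)j * nr];
    dt1d(f, d);
    for (int i = 0; i < nr; ++i) g[(size_t)i + (size_t)j * nr] = d[i];
  }
  // rows
  std::vector<double> fr(nc), dr;
  NumericMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) fr[j] = g[(size_t)i + (size_t)j * nr];
    dt1d(fr, dr);
    for (int j = 0; j < nc; ++j) out(i, j) = std::sqrt(dr[j]);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Topology-preserving sequential thinning to a 1-pixel 8-connected medial
// axis. A pixel is deletable when it is "simple" (its removal preserves the
// local topology: exactly one 8-connected foreground component in the
// punctured 8-neighborhood) and not an endpoint (>= 2 foreground neighbors).
// Deletions are ordered by ascending distance-transform priority, so the
// skeleton stays medial; sequential deletion of simple pixels preserves the
// number of connected components and holes exactly.
// ---------------------------------------------------------------------------

static inline bool fg(const std::vector<char>& m, int nr, int nc, int i, int j) {
  if (i < 0 || i >= nr || j < 0 || j >= nc) return false;
  return m[(size_t)i + (size_t)j * nr] != 0;
}

// neighbors in circular order: E, NE, N, NW, W, SW, S, SE
static const int NBI[8] = {0, 1, 1, 1, 0, -1, -1, -1};
static const int NBJ[8] = {1, 1, 0, -1, -1, -1, 0, 1};

static inline int yokoi8(const std::vector<char>& m, int nr, int nc, int i, int j,
                         int* ncount) {
  bool b[8];
  int cnt = 0;
  for (int k = 0; k < 8; ++k) {
    b[k] = fg(m, nr, nc, i + NBI[k], j + NBJ[k]);
    if (b[k]) ++cnt;
  }
  *ncount = cnt;
  // number of distinct 8-connected foreground components adjacent to p
  int c = 0;
  for (int k = 0; k < 8; k += 2)
    if (!b[k] && (b[(k + 1) % 8] || b[(k + 2) % 8])) ++c;
  if (c == 0 && cnt == 8) c = 1;  // interior pixel: one (surrounding) component
  return c;
}

// [[Rcpp::export]]
LogicalMatrix cpp_thin(const LogicalMatrix& mask, const NumericMatrix& priority) {
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<char> m((size_t)nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      m[(size_t)i + (size_t)j * nr] = mask(i, j) ? 1 : 0;

  typedef std::pair<double, int> Cand;  // (priority, linear index), row-major i + j*nr
  bool changed = true;
  std::vector<Cand> cand;
  while (changed) {
    changed = false;
    cand.clear();
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        const size_t idx = (size_t)i + (size_t)j * nr;
        if (!m[idx]) continue;
        int ncount;
        const int c = yokoi8(m, nr, nc, i, j, &ncount);
        if (c == 1 && ncount >= 2 && ncount < 8)
          cand.push_back(Cand(priority(i, j), (int)idx));
      }
    std::sort(cand.begin(), cand.end());
    for (size_t q = 0; q < cand.size(); ++q) {
      const int idx = cand[q].second;
      const int i = idx % nr, j = idx / nr;
      if (!m[(size_t)idx]) continue;
      int ncount;
      const int c = yokoi8(m, nr, nc, i, j, &ncount);  // re-check after deletions
      if (c == 1 && ncount >= 2) {
        m[(size_t)idx] = 0;
        changed = true;
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = m[(size_t)i + (size_t)j * nr] != 0;
  return out;
}

// ---------------------------------------------------------------------------
// Factory inner loop. Per time step, in fixed order:
//   1. per-edge nutrient delivery (Hill in |Q|, inhibited by local N),
//      deposited uniformly over the edge's path pixels;
//   2. per-edge product uptake (Hill in |Q|, saturating in local X), removed
//      from the path pixels, clipped so X stays non-negative;
//   3. per-producer synthesis (Michaelis-Menten in N, product-inhibited) and
//      nutrient consumption (same Hill structure, rate mu_n), consumption
//      clipped so N stays non-negative;
//   4. explicit diffusion of both fields (no decay).
// Local field values are means over precomputed pixel neighborhoods.
// All pixel indices are 0-based linear (i + j*nr).
// ---------------------------------------------------------------------------

static double mean_at(const NumericMatrix& F, const IntegerVector& idx) {
  double s = 0.0;
  const int n = idx.size();
  for (int k = 0; k < n; ++k) s += F[idx[k]];
  return n > 0 ? s / n : 0.0;
}

// [[Rcpp::export]]
List cpp_factory_run(NumericMatrix N0, NumericMatrix X0,
                     const List& edge_path, const List& edge_nbhd,
                     const NumericVector& edge_Q, const NumericVector& edge_r,
                     const NumericVector& edge_len,
                     const List& prod_px,
                     double rho_n, double rho_p, double k_out, double k_in,
                     double k_l, double mu_p, double mu_n, double k_p,
                     double k_i, double M_p, double D, double dt, double h,
                     int nsteps, int record_every,
                     NumericVector delivered0, NumericVector removed0,
                     double produced0, double consumed0) {
  NumericMatrix N = clone(N0), X = clone(X0);
  NumericVector delivered = clone(delivered0), removed = clone(removed0);
  double produced = produced0, consumed = consumed0;
  const int ne = edge_path.size(), np = prod_px.size();
  const double area = h * h;
  const double twopi = 2.0 * M_PI;
  const int nr = N.nrow(), nc = N.ncol();
  const double a = dt * D / (h * h);
  // scratch buffers so the diffusion step allocates nothing per iteration
  NumericMatrix Nbuf(nr, nc), Xbuf(nr, nc);
  // unwrap the list-of-index-vectors once, not per time step
  std::vector<IntegerVector> paths(ne), nbhds(ne);
  for (int e = 0; e < ne; ++e) {
    paths[e] = edge_path[e];
    nbhds[e] = edge_nbhd[e];
  }
  std::vector<IntegerVector> prods(np);
  for (int p = 0; p < np; ++p) prods[p] = prod_px[p];

  std::vector<double> rate_series;
  double block_removed = 0.0;

  for (int s = 0; s < nsteps; ++s) {
    // 1+2: vessel-wall exchange
    for (int e = 0; e < ne; ++e) {
      const IntegerVector& path = paths[e];
      const IntegerVector& nb = nbhds[e];
      const int npx = path.size();
      if (npx == 0) continue;
      const double q = std::fabs(edge_Q[e]);
      if (q == 0.0) continue;
      const double hq_out = q / (k_out + q), hq_in = q / (k_in + q);
      const double Nloc = mean_at(N, nb);
      const double del = rho_n * twopi * edge_r[e] * hq_out *
                         (k_l / (k_l + Nloc)) * edge_len[e];   // mass / time
      if (del > 0.0) {
        const double add = del * dt / (npx * area);
        for (int k = 0; k < npx; ++k) N[path[k]] += add;
        delivered[e] += del * dt;
      }
      const double Xloc = mean_at(X, nb);
      if (Xloc > 0.0) {
        const double upt = rho_p * twopi * edge_r[e] * hq_in *
                           (Xloc / (k_p + Xloc)) * edge_len[e];
        const double want = upt * dt / (npx * area);  // concentration per pixel
        double got = 0.0;
        for (int k = 0; k < npx; ++k) {
          const double take = std::min(want, X[path[k]]);
          X[path[k]] -= take;
          got += take;
        }
        const double mass = got * area;
        removed[e] += mass;
        block_removed += mass;
      }
    }
    // 3: producer kinetics
    for (int p = 0; p < np; ++p) {
      const IntegerVector& px = prods[p];
      const int npx = px.size();
      if (npx == 0) continue;
      const double Nloc = mean_at(N, px);
      if (Nloc <= 0.0) continue;
      const double Xloc = mean_at(X, px);
      const double hill = (Nloc / (Nloc + k_p)) * (k_i / (k_i + Xloc));
      const double prod = mu_p * hill * M_p;
      const double addX = prod * dt / (npx * area);
      for (int k = 0; k < npx; ++k) X[px[k]] += addX;
      produced += prod * dt;
      const double cons = mu_n * hill * M_p;
      const double wantN = cons * dt / (npx * area);
      double gotN = 0.0;
      for (int k = 0; k < npx; ++k) {
        const double take = std::min(wantN, N[px[k]]);
        N[px[k]] -= take;
        gotN += take;
      }
      consumed += gotN * area;
    }
    // 4: diffusion (zero-flux boundary; same arithmetic as cpp_step_solute
    // with beta = 0 and no source, into preallocated buffers)
    {
      const double* cn = N.begin(); double* on = Nbuf.begin();
      const double* cx = X.begin(); double* ox = Xbuf.begin();
      for (int j = 0; j < nc; ++j) {
        const int jl = (j == 0) ? 0 : j - 1;
        const int jr = (j == nc - 1) ? nc - 1 : j + 1;
        const int b = j * nr, bl = jl * nr, br = jr * nr;
        for (int i = 0; i < nr; ++i) {
          const int id = (i == 0) ? 0 : i - 1;
          const int iu = (i == nr - 1) ? nr - 1 : i + 1;
          const double n0 = cn[b + i];
          on[b + i] = n0 + a * (cn[b + iu] + cn[b + id] +
                                cn[br + i] + cn[bl + i] - 4.0 * n0);
          const double x0 = cx[b + i];
          ox[b + i] = x0 + a * (cx[b + iu] + cx[b + id] +
                                cx[br + i] + cx[bl + i] - 4.0 * x0);
        }
      }
      std::swap(N, Nbuf);
      std::swap(X, Xbuf);
    }

    if (record_every > 0 && (s + 1) % record_every == 0) {
      rate_series.push_back(block_removed / (record_every * dt));
      block_removed = 0.0;
    }
  }
  return List::create(_["N"] = N, _["X"] = X,
                      _["delivered"] = delivered, _["removed"] = removed,
                      _["produced"] = produced, _["consumed"] = consumed,
                      _["rate_series"] = NumericVector(rate_series.begin(),
                                                       rate_series.end()));
}
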