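// Numeric kernels for the hybrid DCIS model.
//
// All kernels are deterministic (no RNG, fixed iteration order) so that a
// simulation is bit-reproducible for a fixed R-side seed.  Grids are stored
// as full nx*ny*nz arrays in R column-major order; nodes outside the duct
// cylinder are masked (nodeId == 0).  Inner loops use raw pointers.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Gauss-Seidel / SOR relaxation to the implicit solution of
//   D * lap(u) - Lambda * u + P = 0            (quasi-steady)
// or, with Lambda += 1/dt and P += u_old/dt, the backward Euler step of
// du/dt = D*lap(u) - Lambda*u + P.  Missing neighbours (masked nodes, domain
// edges) are zero-flux (mirror), realising the homogeneous Neumann condition
// on end caps and on the outer surface of Neumann species.  `fixed`
// (Dirichlet) nodes are never updated.
// [[Rcpp::export]]
List sor_solve_cpp(NumericVector u0, IntegerMatrix nbr, LogicalVector fixed,
                   NumericVector lambda, NumericVector prod,
                   double D, double h2, double tol, int maxSweeps,
                   double omega) {
  const int n = u0.size();
  NumericVector u = clone(u0);
  double* up = REAL(u);
  const int* nb = INTEGER(nbr);
  const int* fx = LOGICAL(fixed);
  const double* lam = REAL(lambda);
  const double* pr = REAL(prod);
  const double Dh2 = D / h2;
  double delta = R_PosInf;
  int sweep = 0;
  for (sweep = 0; sweep < maxSweeps; ++sweep) {
    double maxd = 0.0, scale = 1e-300;
    for (int i = 0; i < n; ++i) {
      if (fx[i]) continue;
      double s = 0.0; int m = 0;
      for (int k = 0; k < 6; ++k) {
        int j = nb[i + n * k];
        if (j > 0) { s += up[j - 1]; ++m; }
      }
      double denom = Dh2 * m + lam[i];
      if (denom <= 0.0) continue;   // isolated node with no loss: leave as is
      double unew = (Dh2 * s + pr[i]) / denom;
      unew = (1.0 - omega) * up[i] + omega * unew;
      if (unew < 0.0) unew = 0.0;   // concentrations are non-negative
      double d = std::fabs(unew - up[i]);
      if (d > maxd) maxd = d;
      double a = std::fabs(unew);
      if (a > scale) scale = a;
      up[i] = unew;
    }
    delta = maxd / std::max(scale, 1e-12);
    if (delta < tol) { ++sweep; break; }
  }
  return List::create(_["values"] = u, _["sweeps"] = sweep, _["delta"] = delta);
}

// Explicit forward-time central-space step of du/dt = D*lap(u) - lambda*u + P.
// Uptake is applied implicitly (exp factor) to guarantee non-negativity.
// [[Rcpp::export]]
NumericVector ftcs_step_cpp(NumericVector u0, IntegerMatrix nbr,
                            LogicalVector fixed, NumericVector lambda,
                            NumericVector prod, double D, double h2,
                            double dt) {
  const int n = u0.size();
  NumericVector u(n);
  const double* u0p = REAL(u0);
  double* up = REAL(u);
  const int* nb = INTEGER(nbr);
  const int* fx = LOGICAL(fixed);
  const double* lam = REAL(lambda);
  const double* pr = REAL(prod);
  const double Dh2 = D / h2;
  for (int i = 0; i < n; ++i) {
    if (fx[i]) { up[i] = u0p[i]; continue; }
    double s = 0.0; int m = 0;
    for (int k = 0; k < 6; ++k) {
      int j = nb[i + n * k];
      if (j > 0) { s += u0p[j - 1]; ++m; }
    }
    double lap = Dh2 * (s - m * u0p[i]);
    double val = u0p[i] * std::exp(-lam[i] * dt) + dt * (lap + pr[i]);
    up[i] = (val > 0.0) ? val : 0.0;
  }
  return u;
}

// ---------------------------------------------------------------------------
// Trilinear interpolation on the full grid (ghost-filled outside the mask).
// [[Rcpp::export]]
NumericVector trilinear_cpp(NumericVector arr, IntegerVector dims,
                            NumericVector origin, double h,
                            NumericMatrix pts) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int m = pts.nrow();
  NumericVector out(m);
  const double* a = REAL(arr);
  const double* px = REAL(pts);
  const double* py = px + m;
  const double* pz = py + m;
  double* o = REAL(out);
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  for (int p = 0; p < m; ++p) {
    double fxq = (px[p] - ox) / h;
    double fyq = (py[p] - oy) / h;
    double fzq = (pz[p] - oz) / h;
    int i0 = (int)std::floor(fxq), j0 = (int)std::floor(fyq),
        k0 = (int)std::floor(fzq);
    if (i0 < 0) i0 = 0; if (i0 > nx - 2) i0 = nx - 2;
    if (j0 < 0) j0 = 0; if (j0 > ny - 2) j0 = ny - 2;
    if (k0 < 0) k0 = 0; if (k0 > nz - 2) k0 = nz - 2;
    double tx = fxq - i0, ty = fyq - j0, tz = fzq - k0;
    if (tx < 0) tx = 0; if (tx > 1) tx = 1;
    if (ty < 0) ty = 0; if (ty > 1) ty = 1;
    if (tz < 0) tz = 0; if (tz > 1) tz = 1;
    const int b000 = i0 + nx * (j0 + ny * k0);
    const int b100 = b000 + 1;
    const int b010 = b000 + nx;
    const int b001 = b000 + nx * ny;
    double c00 = a[b000] * (1 - tx) + a[b100] * tx;
    double c10 = a[b010] * (1 - tx) + a[b010 + 1] * tx;
    double c01 = a[b001] * (1 - tx) + a[b001 + 1] * tx;
    double c11 = a[b001 + nx] * (1 - tx) + a[b001 + nx + 1] * tx;
    double c0 = c00 * (1 - ty) + c10 * ty;
    double c1 = c01 * (1 - ty) + c11 * ty;
    o[p] = c0 * (1 - tz) + c1 * tz;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Nearest masked node for each point (Voronoi ownership on the grid),
// ties broken toward the lowest node index.  Expanding cube search.
// [[Rcpp::export]]
IntegerVector nearest_node_cpp(NumericMatrix pts, IntegerVector nodeId,
                               IntegerVector dims, NumericVector origin,
                               double h) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int m = pts.nrow();
  IntegerVector out(m);
  const int* idp = INTEGER(nodeId);
  const double* px = REAL(pts);
  const double* py = px + m;
  const double* pz = py + m;
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const int maxRing = std::max(nx, std::max(ny, nz));
  for (int p = 0; p < m; ++p) {
    double qx = px[p], qy = py[p], qz = pz[p];
    int ci = (int)std::lround((qx - ox) / h);
    int cj = (int)std::lround((qy - oy) / h);
    int ck = (int)std::lround((qz - oz) / h);
    int best = 0;
    double bestd = R_PosInf;
    for (int ring = 0; ring < maxRing; ++ring) {
      for (int i = ci - ring; i <= ci + ring; ++i) {
        if (i < 0 || i >= nx) continue;
        for (int j = cj - ring; j <= cj + ring; ++j) {
          if (j < 0 || j >= ny) continue;
          for (int k = ck - ring; k <= ck + ring; ++k) {
            if (k < 0 || k >= nz) continue;
            if (ring > 0 && std::abs(i - ci) != ring &&
                std::abs(j - cj) != ring && std::abs(k - ck) != ring)
              continue;                     // only the shell of the cube
            int id = idp[i + nx * (j + ny * k)];
            if (id == 0) continue;
            double dx = ox + i * h - qx;
            double dy = oy + j * h - qy;
            double dz = oz + k * h - qz;
            double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 < bestd - 1e-12 ||
                (std::fabs(d2 - bestd) <= 1e-12 && id < best)) {
              bestd = d2; best = id;
            }
          }
        }
      }
      if (best > 0) {
        // nodes in the next ring are at least (ring + 0.5) * h away
        double nextMin = (ring + 0.5) * h;
        if (nextMin * nextMin > bestd) break;
      }
    }
    out[p] = best;
  }
  return out;
}

// ---------------------------------------------------------------------------
// One-pass accumulation of per-agent rates onto their assigned nodes.
// map: 1-based node ids; rates: nAgents x k; returns nNodes x k sums.
// [[Rcpp::export]]
NumericMatrix deposit_sum_cpp(IntegerVector map, NumericMatrix rates,
                              int nNodes) {
  const int n = map.size();
  const int k = rates.ncol();
  NumericMatrix out(nNodes, k);
  const int* mp = INTEGER(map);
  const double* rp = REAL(rates);
  double* op = REAL(out);
  for (int c = 0; c < k; ++c) {
    const double* rc = rp + (size_t)c * n;
    double* oc = op + (size_t)c * nNodes;
    for (int i = 0; i < n; ++i) oc[mp[i] - 1] += rc[i];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Uniform spatial hash over positions given as separate coordinate arrays.
struct HashGrid {
  double minx, miny, minz, bin;
  int nbx, nby, nbz;
  std::vector<int> head;     // first agent in bin (-1 none)
  std::vector<int> next;     // linked list
  HashGrid(const double* x, const double* y, const double* z, int n,
           double bin_) : bin(bin_) {
    minx = miny = minz = R_PosInf;
    double maxx = -R_PosInf, maxy = -R_PosInf, maxz = -R_PosInf;
    for (int i = 0; i < n; ++i) {
      minx = std::min(minx, x[i]); maxx = std::max(maxx, x[i]);
      miny = std::min(miny, y[i]); maxy = std::max(maxy, y[i]);
      minz = std::min(minz, z[i]); maxz = std::max(maxz, z[i]);
    }
    if (n == 0) { minx = miny = minz = maxx = maxy = maxz = 0; }
    nbx = (int)((maxx - minx) / bin) + 1;
    nby = (int)((maxy - miny) / bin) + 1;
    nbz = (int)((maxz - minz) / bin) + 1;
    head.assign((size_t)nbx * nby * nbz, -1);
    next.assign(n, -1);
    // insert in reverse so lists iterate in increasing index order
    for (int i = n - 1; i >= 0; --i) {
      size_t b = binOf(x[i], y[i], z[i]);
      next[i] = head[b];
      head[b] = i;
    }
  }
  inline int clampx(int v, int hi) const {
    return v < 0 ? 0 : (v >= hi ? hi - 1 : v);
  }
  inline size_t binOf(double x, double y, double z) const {
    int bx = clampx((int)((x - minx) / bin), nbx);
    int by = clampx((int)((y - miny) / bin), nby);
    int bz = clampx((int)((z - minz) / bin), nbz);
    return (size_t)bx + (size_t)nbx * ((size_t)by + (size_t)nby * bz);
  }
};

// Count, for each query agent, other "countable" agents within radius R.
// query: 1-based indices of agents to evaluate (others return 0).
// [[Rcpp::export]]
IntegerVector neighbor_count_cpp(NumericMatrix pos, LogicalVector countable,
                                 double R, Nullable<IntegerVector> query =
                                   R_NilValue) {
  const int n = pos.nrow();
  IntegerVector out(n);
  if (n == 0) return out;
  const double* x = REAL(pos);
  const double* y = x + n;
  const double* z = y + n;
  const int* ct = LOGICAL(countable);
  int* o = INTEGER(out);
  HashGrid grid(x, y, z, n, R);
  const double R2 = R * R;
  std::vector<int> qs;
  if (query.isNotNull()) {
    IntegerVector q(query);
    qs.assign(q.begin(), q.end());
    for (int& v : qs) --v;
  } else {
    qs.resize(n);
    for (int i = 0; i < n; ++i) qs[i] = i;
  }
  for (int i : qs) {
    int bx = grid.clampx((int)((x[i] - grid.minx) / grid.bin), grid.nbx);
    int by = grid.clampx((int)((y[i] - grid.miny) / grid.bin), grid.nby);
    int bz = grid.clampx((int)((z[i] - grid.minz) / grid.bin), grid.nbz);
    int cnt = 0;
    for (int dx = -1; dx <= 1; ++dx) {
      int cx = bx + dx; if (cx < 0 || cx >= grid.nbx) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int cy = by + dy; if (cy < 0 || cy >= grid.nby) continue;
        for (int dz = -1; dz <= 1; ++dz) {
          int cz = bz + dz; if (cz < 0 || cz >= grid.nbz) continue;
          for (int j = grid.head[(size_t)cx + (size_t)grid.nbx *
                                 ((size_t)cy + (size_t)grid.nby * cz)];
               j >= 0; j = grid.next[j]) {
            if (j == i || !ct[j]) continue;
            double ddx = x[i] - x[j], ddy = y[i] - y[j], ddz = z[i] - z[j];
            if (ddx * ddx + ddy * ddy + ddz * ddz <= R2) ++cnt;
          }
        }
      }
    }
    o[i] = cnt;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Iterative pairwise soft-sphere overlap relaxation.
// Displacements along the centre line, proportional to overlap, split by
// inverse radius (larger cells move less); immobile agents never move.
// Jacobi accumulation within an iteration (order-independent), damping 0.5,
// an active set limits work to disturbed regions, and a Verlet pair list
// (skin 2 um) is built once per call.
// [[Rcpp::export]]
List relax_overlaps_cpp(NumericMatrix pos0, NumericVector rad,
                        LogicalVector mobile, double tol, int maxIter) {
  const int n = pos0.nrow();
  NumericMatrix pos = clone(pos0);
  if (n == 0)
    return List::create(_["pos"] = pos, _["iterations"] = 0,
                        _["maxOverlap"] = 0.0, _["converged"] = true);
  double* x = REAL(pos);
  double* y = x + n;
  double* z = y + n;
  const double* r = REAL(rad);
  const int* mob = LOGICAL(mobile);
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, r[i]);
  const double cutoff = 2.0 * rmax;
  const double skin = 2.0;
  const double damp = 0.5;

  // pair list; only pairs with at least one mobile agent
  std::vector<int> pi, pj;
  {
    HashGrid grid(x, y, z, n, cutoff + skin);
    const double c2 = (cutoff + skin) * (cutoff + skin);
    // scan from the mobile side only; mobile-mobile pairs dedupe by index
    for (int i = 0; i < n; ++i) {
      if (!mob[i]) continue;
      int bx = grid.clampx((int)((x[i] - grid.minx) / grid.bin), grid.nbx);
      int by = grid.clampx((int)((y[i] - grid.miny) / grid.bin), grid.nby);
      int bz = grid.clampx((int)((z[i] - grid.minz) / grid.bin), grid.nbz);
      for (int dx = -1; dx <= 1; ++dx) {
        int cx = bx + dx; if (cx < 0 || cx >= grid.nbx) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int cy = by + dy; if (cy < 0 || cy >= grid.nby) continue;
          for (int dz = -1; dz <= 1; ++dz) {
            int cz = bz + dz; if (cz < 0 || cz >= grid.nbz) continue;
            for (int j = grid.head[(size_t)cx + (size_t)grid.nbx *
                                   ((size_t)cy + (size_t)grid.nby * cz)];
                 j >= 0; j = grid.next[j]) {
              if (j == i) continue;
              if (mob[j] && j < i) continue;
              double ddx = x[i] - x[j], ddy = y[i] - y[j], ddz = z[i] - z[j];
              if (ddx * ddx + ddy * ddy + ddz * ddz <= c2) {
                pi.push_back(i); pj.push_back(j);
              }
            }
          }
        }
      }
    }
  }
  const size_t np = pi.size();
  std::vector<double> dxv(n, 0.0), dyv(n, 0.0), dzv(n, 0.0);
  std::vector<uint8_t> active(n, 1), touched(n), nxt(n);
  double maxOv = 0.0;
  int iter = 0;
  for (iter = 0; iter < maxIter; ++iter) {
    std::fill(dxv.begin(), dxv.end(), 0.0);
    std::fill(dyv.begin(), dyv.end(), 0.0);
    std::fill(dzv.begin(), dzv.end(), 0.0);
    std::fill(touched.begin(), touched.end(), 0);
    maxOv = 0.0;
    for (size_t p = 0; p < np; ++p) {
      int i = pi[p], j = pj[p];
      if (!active[i] && !active[j]) continue;
      double ddx = x[i] - x[j], ddy = y[i] - y[j], ddz = z[i] - z[j];
      double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
      double rsum = r[i] + r[j];
      if (d2 >= rsum * rsum) continue;
      double d = std::sqrt(d2);
      double ov = rsum - d;
      if (ov > maxOv) maxOv = ov;
      if (ov <= tol) continue;
      double ux, uy, uz;
      if (d > 1e-9) { ux = ddx / d; uy = ddy / d; uz = ddz / d; }
      else { ux = 1.0; uy = 0.0; uz = 0.0; }  // coincident: deterministic axis
      double wi = mob[i] ? (mob[j] ? r[j] / rsum : 1.0) : 0.0;
      double wj = mob[j] ? (mob[i] ? r[i] / rsum : 1.0) : 0.0;
      dxv[i] += wi * ov * ux; dyv[i] += wi * ov * uy; dzv[i] += wi * ov * uz;
      dxv[j] -= wj * ov * ux; dyv[j] -= wj * ov * uy; dzv[j] -= wj * ov * uz;
      touched[i] = 1; touched[j] = 1;
    }
    if (maxOv <= tol) break;
    bool movedAny = false;
    for (int i = 0; i < n; ++i) {
      if (touched[i] && (dxv[i] != 0.0 || dyv[i] != 0.0 || dzv[i] != 0.0)) {
        x[i] += damp * dxv[i];
        y[i] += damp * dyv[i];
        z[i] += damp * dzv[i];
        movedAny = true;
      }
    }
    if (!movedAny) break;
    std::fill(nxt.begin(), nxt.end(), 0);
    for (size_t p = 0; p < np; ++p) {
      int i = pi[p], j = pj[p];
      if (touched[i] || touched[j]) { nxt[i] = 1; nxt[j] = 1; }
    }
    active.swap(nxt);
  }
  // final audit over the pair list
  maxOv = 0.0;
  for (size_t p = 0; p < np; ++p) {
    int i = pi[p], j = pj[p];
    double ddx = x[i] - x[j], ddy = y[i] - y[j], ddz = z[i] - z[j];
    double ov = r[i] + r[j] - std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
    if (ov > maxOv) maxOv = ov;
  }
  return List::create(_["pos"] = pos, _["iterations"] = iter,
                      _["maxOverlap"] = maxOv,
                      _["converged"] = (maxOv <= tol));
}

// Total pairwise overlap energy sum(ov^2), max overlap, overlapping pairs.
// [[Rcpp::export]]
List overlap_audit_cpp(NumericMatrix pos, NumericVector rad) {
  const int n = pos.nrow();
  double e = 0.0, mx = 0.0;
  int count = 0;
  if (n > 1) {
    const double* x = REAL(pos);
    const double* y = x + n;
    const double* z = y + n;
    const double* r = REAL(rad);
    double rmax = 0.0;
    for (int i = 0; i < n; ++i) rmax = std::max(rmax, r[i]);
    HashGrid grid(x, y, z, n, 2.0 * rmax);
    for (int i = 0; i < n; ++i) {
      int bx = grid.clampx((int)((x[i] - grid.minx) / grid.bin), grid.nbx);
      int by = grid.clampx((int)((y[i] - grid.miny) / grid.bin), grid.nby);
      int bz = grid.clampx((int)((z[i] - grid.minz) / grid.bin), grid.nbz);
      for (int dx = -1; dx <= 1; ++dx) {
        int cx = bx + dx; if (cx < 0 || cx >= grid.nbx) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int cy = by + dy; if (cy < 0 || cy >= grid.nby) continue;
          for (int dz = -1; dz <= 1; ++dz) {
            int cz = bz + dz; if (cz < 0 || cz >= grid.nbz) continue;
            for (int j = grid.head[(size_t)cx + (size_t)grid.nbx *
                                   ((size_t)cy + (size_t)grid.nby * cz)];
                 j >= 0; j = grid.next[j]) {
              if (j <= i) continue;
              double ddx = x[i] - x[j], ddy = y[i] - y[j], ddz = z[i] - z[j];
              double ov = r[i] + r[j] -
                std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
              if (ov > 0) { e += ov * ov; ++count; if (ov > mx) mx = ov; }
            }
          }
        }
      }
    }
  }
  return List::create(_["energy"] = e, _["maxOverlap"] = mx,
                      _["pairs"] = count);
}
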