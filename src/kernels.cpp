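// Grid kernels for hydrological terrain analysis.
//
// All kernels share one neighbour convention: offsets are listed in the
// order E, NE, N, NW, W, SW, S, SE.  This order is also the tie-break
// order for D8 steepest descent (first maximal drop wins), so routing is
// deterministic on flats-with-epsilon surfaces.
//
// Matrices are oriented north-up: row 0 is the northernmost row.
// NA_REAL marks nodata; kernels never read through nodata cells.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>

using namespace Rcpp;

static const int DR[8] = { 0, -1, -1, -1,  0,  1,  1,  1 };
static const int DC[8] = { 1,  1,  0, -1, -1, -1,  0,  1 };
static const double SQRT2 = 1.4142135623730951;
static const double DIST[8] = { 1.0, SQRT2, 1.0, SQRT2, 1.0, SQRT2, 1.0, SQRT2 };

static inline bool valid_cell(const NumericMatrix& z, int r, int c) {
  return r >= 0 && r < z.nrow() && c >= 0 && c < z.ncol() &&
         !NumericMatrix::is_na(z(r, c));
}

// A cell is a border cell if it touches the grid edge or a nodata cell:
// water leaving it exits the modelled domain.
static bool is_border(const NumericMatrix& z, int r, int c) {
  if (r == 0 || c == 0 || r == z.nrow() - 1 || c == z.ncol() - 1) return true;
  for (int k = 0; k < 8; ++k)
    if (NumericMatrix::is_na(z(r + DR[k], c + DC[k]))) return true;
  return false;
}

// ---------------------------------------------------------------------------
// Hydrological conditioning: least-cost breaching of closed pits followed by
// priority-flood filling with an epsilon gradient for whatever remains
// (residual depressions and flats).  After this every valid non-border cell
// has a strictly lower valid neighbour.
// ---------------------------------------------------------------------------

struct HeapCell {
  double key;
  long long order;   // FIFO tie-break keeps the flood deterministic
  int r, c;
  bool operator>(const HeapCell& o) const {
    if (key != o.key) return key > o.key;
    return order > o.order;
  }
};

// [[Rcpp::export]]
NumericMatrix cpp_breach_fill(NumericMatrix dem, int max_breach_length,
                              double epsilon) {
  const int nr = dem.nrow(), nc = dem.ncol();
  NumericMatrix z = clone(dem);

  // --- stage 1: least-cost breaching of strict single-cell pit bottoms ---
  std::vector<std::pair<double, int>> pits;  // (elevation, linear index)
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!valid_cell(z, r, c) || is_border(z, r, c)) continue;
      bool lower = false, strict_pit = true;
      for (int k = 0; k < 8; ++k) {
        double zn = z(r + DR[k], c + DC[k]);
        if (zn < z(r, c)) lower = true;
        if (zn <= z(r, c)) strict_pit = false;
      }
      if (!lower && strict_pit) pits.push_back({ z(r, c), r * nc + c });
    }
  }
  std::sort(pits.begin(), pits.end());

  for (size_t p = 0; p < pits.size(); ++p) {
    const int pr = pits[p].second / nc, pc = pits[p].second % nc;
    const double zp = z(pr, pc);
    // earlier carving may already have drained this pit
    bool drained = false;
    for (int k = 0; k < 8; ++k)
      if (valid_cell(z, pr + DR[k], pc + DC[k]) &&
          z(pr + DR[k], pc + DC[k]) < zp) { drained = true; break; }
    if (drained) continue;

    // Dijkstra outward; cost of entering a cell is the material that would
    // have to be removed to bring it below the pit elevation.
    std::priority_queue<HeapCell, std::vector<HeapCell>, std::greater<HeapCell>> pq;
    std::vector<double> cost(nr * nc, std::numeric_limits<double>::infinity());
    std::vector<int> parent(nr * nc, -1), hops(nr * nc, 0);
    long long tick = 0;
    cost[pr * nc + pc] = 0.0;
    pq.push({ 0.0, tick++, pr, pc });
    int target = -1;
    while (!pq.empty()) {
      HeapCell cur = pq.top(); pq.pop();
      int ci = cur.r * nc + cur.c;
      if (cur.key > cost[ci]) continue;
      if ((z(cur.r, cur.c) < zp) ||
          (is_border(z, cur.r, cur.c) && ci != pr * nc + pc)) {
        target = ci; break;
      }
      if (hops[ci] >= max_breach_length) continue;
      for (int k = 0; k < 8; ++k) {
        int r2 = cur.r + DR[k], c2 = cur.c + DC[k];
        if (!valid_cell(z, r2, c2)) continue;
        int ni = r2 * nc + c2;
        double step = std::max(0.0, z(r2, c2) - zp);
        if (cost[ci] + step < cost[ni]) {
          cost[ni] = cost[ci] + step;
          parent[ni] = ci;
          hops[ni] = hops[ci] + 1;
          pq.push({ cost[ni], tick++, r2, c2 });
        }
      }
    }
    if (target < 0) continue;  // capped out; the fill stage will handle it

    std::vector<int> path;  // target .. pit
    for (int i = target; i != -1; i = parent[i]) path.push_back(i);
    std::reverse(path.begin(), path.end());  // pit .. target
    const int klen = (int)path.size() - 1;
    if (klen <= 0) continue;
    double zt = z(target / nc, target % nc);
    for (int i = 1; i <= klen; ++i) {
      int rr = path[i] / nc, cc = path[i] % nc;
      double want = (zt < zp)
        ? zp + (zt - zp) * (double)i / (double)klen  // ramp down to target
        : zp - epsilon * i;                          // carve out to the border
      if (z(rr, cc) > want) z(rr, cc) = want;
    }
  }

  // --- stage 2: priority-flood with epsilon gradient (fills residual
  // depressions, resolves flats) ---
  std::priority_queue<HeapCell, std::vector<HeapCell>, std::greater<HeapCell>> pq;
  std::vector<char> seen(nr * nc, 0);
  long long tick = 0;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      if (valid_cell(z, r, c) && is_border(z, r, c)) {
        seen[r * nc + c] = 1;
        pq.push({ z(r, c), tick++, r, c });
      }
  while (!pq.empty()) {
    HeapCell cur = pq.top(); pq.pop();
    for (int k = 0; k < 8; ++k) {
      int r2 = cur.r + DR[k], c2 = cur.c + DC[k];
      if (!valid_cell(z, r2, c2) || seen[r2 * nc + c2]) continue;
      seen[r2 * nc + c2] = 1;
      double floor_z = z(cur.r, cur.c) + epsilon;
      if (z(r2, c2) < floor_z) z(r2, c2) = floor_z;
      pq.push({ z(r2, c2), tick++, r2, c2 });
    }
  }
  return z;
}

// ---------------------------------------------------------------------------
// D8 pointer: codes 1..8 = E,NE,N,NW,W,SW,S,SE; 0 = outlet; NA = nodata.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_d8_pointer(NumericMatrix dem) {
  const int nr = dem.nrow(), nc = dem.ncol();
  IntegerMatrix ptr(nr, nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!valid_cell(dem, r, c)) { ptr(r, c) = NA_INTEGER; continue; }
      int best = -1;
      double best_grad = 0.0;
      for (int k = 0; k < 8; ++k) {
        int r2 = r + DR[k], c2 = c + DC[k];
        if (!valid_cell(dem, r2, c2)) continue;
        double grad = (dem(r, c) - dem(r2, c2)) / DIST[k];
        if (grad > best_grad) { best_grad = grad; best = k; }
      }
      if (best >= 0) {
        ptr(r, c) = best + 1;
      } else if (is_border(dem, r, c)) {
        ptr(r, c) = 0;  // outlet
      } else {
        stop("cell (%d, %d) has no lower neighbour and is not on the border: DEM is not hydrologically conditioned",
             r + 1, c + 1);
      }
    }
  }
  return ptr;
}

// ---------------------------------------------------------------------------
// D8 flow accumulation in cell counts (each cell contributes its own area).
// Kahn topological propagation; a cycle is a violated pointer invariant.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_d8_accumulation(IntegerMatrix ptr) {
  const int nr = ptr.nrow(), nc = ptr.ncol();
  NumericMatrix acc(nr, nc);
  std::vector<int> indeg(nr * nc, 0);
  int nvalid = 0;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (IntegerMatrix::is_na(ptr(r, c))) { acc(r, c) = NA_REAL; continue; }
      ++nvalid;
      acc(r, c) = 1.0;
      int k = ptr(r, c);
      if (k > 0) ++indeg[(r + DR[k - 1]) * nc + (c + DC[k - 1])];
    }
  std::queue<int> q;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      if (!IntegerMatrix::is_na(ptr(r, c)) && indeg[r * nc + c] == 0)
        q.push(r * nc + c);
  int processed = 0;
  while (!q.empty()) {
    int i = q.front(); q.pop();
    ++processed;
    int r = i / nc, c = i % nc, k = ptr(r, c);
    if (k > 0) {
      int j = (r + DR[k - 1]) * nc + (c + DC[k - 1]);
      acc(j / nc, j % nc) += acc(r, c);
      if (--indeg[j] == 0) q.push(j);
    }
  }
  if (processed != nvalid)
    stop("cycle detected in D8 pointer grid (%d of %d cells resolved)",
         processed, nvalid);
  return acc;
}

// ---------------------------------------------------------------------------
// D-infinity specific catchment area (Tarboton's triangular facets).
// Returns the accumulated area (m^2) per cell plus the total area exported
// across the grid border, which must equal the total valid area.
// Only facets whose both neighbours are valid in-grid cells are considered;
// cells with no positive facet slope (typically on the border, facing
// off-grid) are sinks whose accumulation leaves the domain.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_dinf_accumulation(NumericMatrix dem, double cell_size) {
  const int nr = dem.nrow(), nc = dem.ncol();
  // facets: (cardinal e1, diagonal e2) in neighbour-code space
  static const int F1[8] = { 0, 2, 2, 4, 4, 6, 6, 0 };  // E N N W W S S E
  static const int F2[8] = { 1, 1, 3, 3, 5, 5, 7, 7 };  // NE NE NW NW SW SW SE SE

  NumericMatrix acc(nr, nc);
  // per-cell: two receivers and proportions
  std::vector<int> rcv1(nr * nc, -1), rcv2(nr * nc, -1);
  std::vector<double> p1(nr * nc, 0.0), p2(nr * nc, 0.0);
  std::vector<std::pair<double, int>> order;
  order.reserve(nr * nc);
  const double pi4 = std::atan(1.0);

  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!valid_cell(dem, r, c)) { acc(r, c) = NA_REAL; continue; }
      acc(r, c) = cell_size * cell_size;
      order.push_back({ dem(r, c), r * nc + c });
      double best_s = 0.0, best_ang = 0.0;
      int best_f = -1;
      for (int f = 0; f < 8; ++f) {
        int k1 = F1[f], k2 = F2[f];
        if (!valid_cell(dem, r + DR[k1], c + DC[k1]) ||
            !valid_cell(dem, r + DR[k2], c + DC[k2])) continue;
        double z0 = dem(r, c);
        double z1 = dem(r + DR[k1], c + DC[k1]);
        double z2 = dem(r + DR[k2], c + DC[k2]);
        double s1 = (z0 - z1) / cell_size;
        double s2 = (z1 - z2) / cell_size;
        double ang = std::atan2(s2, s1), s;
        if (ang < 0.0)       { ang = 0.0; s = s1; }
        else if (ang > pi4)  { ang = pi4; s = (z0 - z2) / (SQRT2 * cell_size); }
        else                 { s = std::sqrt(s1 * s1 + s2 * s2); }
        if (s > best_s) { best_s = s; best_ang = ang; best_f = f; }
      }
      if (best_f < 0) continue;  // sink: no in-grid downslope facet
      int i = r * nc + c;
      double w2 = best_ang / pi4;
      int k1 = F1[best_f], k2 = F2[best_f];
      rcv1[i] = (r + DR[k1]) * nc + (c + DC[k1]);
      rcv2[i] = (r + DR[k2]) * nc + (c + DC[k2]);
      p1[i] = 1.0 - w2;
      p2[i] = w2;
    }
  }
  std::sort(order.begin(), order.end(),
            [](const std::pair<double, int>& a, const std::pair<double, int>& b) {
              if (a.first != b.first) return a.first > b.first;  // high to low
              return a.second < b.second;
            });
  double outflow = 0.0;
  for (auto& oi : order) {
    int i = oi.second, r = i / nc, c = i % nc;
    double a = acc(r, c);
    if (rcv1[i] < 0) { outflow += a; continue; }  // sink (border or flat)
    if (p1[i] > 0.0) acc(rcv1[i] / nc, rcv1[i] % nc) += a * p1[i];
    if (p2[i] > 0.0) acc(rcv2[i] / nc, rcv2[i] % nc) += a * p2[i];
  }
  return List::create(_["acc_m2"] = acc, _["edge_outflow_m2"] = outflow);
}

// ---------------------------------------------------------------------------
// Cartographic depth-to-water: multi-source Dijkstra from all surface-water
// cells.  The cost of a step into cell j is slope(j) * a * cell_size with
// a = 1 for cardinal and sqrt(2) for diagonal moves, so a path accumulates
// sum_i (dz/dx)_i * a_i * xc over the cells it enters.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_dtw(NumericMatrix slope, LogicalMatrix source,
                      double cell_size) {
  const int nr = slope.nrow(), nc = slope.ncol();
  NumericMatrix d(nr, nc);
  std::fill(d.begin(), d.end(), R_PosInf);
  std::priority_queue<HeapCell, std::vector<HeapCell>, std::greater<HeapCell>> pq;
  long long tick = 0;
  int nsource = 0;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (NumericMatrix::is_na(slope(r, c))) { d(r, c) = NA_REAL; continue; }
      if (source(r, c) == TRUE) {
        d(r, c) = 0.0;
        pq.push({ 0.0, tick++, r, c });
        ++nsource;
      }
    }
  if (nsource == 0) stop("source layer is empty: cannot compute depth-to-water");
  while (!pq.empty()) {
    HeapCell cur = pq.top(); pq.pop();
    if (cur.key > d(cur.r, cur.c)) continue;
    for (int k = 0; k < 8; ++k) {
      int r2 = cur.r + DR[k], c2 = cur.c + DC[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (NumericMatrix::is_na(slope(r2, c2))) continue;
      double nd = cur.key + slope(r2, c2) * DIST[k] * cell_size;
      if (nd < d(r2, c2)) {
        d(r2, c2) = nd;
        pq.push({ nd, tick++, r2, c2 });
      }
    }
  }
  for (int i = 0; i < nr * nc; ++i)
    if (!NumericMatrix::is_na(d[i]) && d[i] == R_PosInf) d[i] = NA_REAL;
  return d;
}

// ---------------------------------------------------------------------------
// Elevation above stream: z(cell) minus z of the first surface-water cell on
// its D8 flow path.  Memoized path walking; paths that exit the grid without
// meeting water yield NA.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_eas(NumericMatrix dem, IntegerMatrix ptr,
                      LogicalMatrix source) {
  const int nr = dem.nrow(), nc = dem.ncol();
  int nsource = 0;
  for (int i = 0; i < nr * nc; ++i) if (source[i] == TRUE) ++nsource;
  if (nsource == 0) stop("source layer is empty: cannot compute elevation above stream");

  // zsrc[i] = elevation of first source cell downstream of i (incl. i itself);
  // state: 0 unknown, 1 done-with-value, 2 done-no-source
  std::vector<double> zsrc(nr * nc, 0.0);
  std::vector<char> state(nr * nc, 0);
  NumericMatrix out(nr, nc);
  std::vector<int> stack;
  for (int r0 = 0; r0 < nr; ++r0) {
    for (int c0 = 0; c0 < nc; ++c0) {
      if (IntegerMatrix::is_na(ptr(r0, c0))) { out(r0, c0) = NA_REAL; continue; }
      if (state[r0 * nc + c0]) continue;
      stack.clear();
      int r = r0, c = c0;
      char term = 2;        // until proven otherwise: exits without source
      double zterm = 0.0;
      while (true) {
        int i = r * nc + c;
        if (state[i]) { term = state[i]; zterm = zsrc[i]; break; }
        if (source(r, c) == TRUE) { term = 1; zterm = dem(r, c); stack.push_back(i); break; }
        stack.push_back(i);
        state[i] = 3;  // on current path guard (acyclic pointers never revisit)
        int k = ptr(r, c);
        if (k == 0) { term = 2; break; }  // outlet, no source met
        r += DR[k - 1]; c += DC[k - 1];
        if (IntegerMatrix::is_na(ptr(r, c))) { term = 2; break; }
      }
      for (int idx : stack) { state[idx] = term; zsrc[idx] = zterm; }
    }
  }
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (IntegerMatrix::is_na(ptr(r, c))) { out(r, c) = NA_REAL; continue; }
      int i = r * nc + c;
      out(r, c) = (state[i] == 1) ? dem(r, c) - zsrc[i] : NA_REAL;
    }
  return out;
}

// ---------------------------------------------------------------------------
// Focal (moving-window) population standard deviation of elevation.
// Windows truncate at grid edges; nodata cells are excluded from the window
// statistics.  Even window sizes carry the extra row/column south/east.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_focal_sd(NumericMatrix dem, int w) {
  const int nr = dem.nrow(), nc = dem.ncol();
  // prefix sums over valid cells; centre values for numerical stability
  double mu = 0.0; long nval = 0;
  for (int i = 0; i < nr * nc; ++i)
    if (!NumericMatrix::is_na(dem[i])) { mu += dem[i]; ++nval; }
  if (nval > 0) mu /= nval;

  std::vector<double> S((nr + 1) * (nc + 1), 0.0), S2((nr + 1) * (nc + 1), 0.0);
  std::vector<int> Cn((nr + 1) * (nc + 1), 0);
  const int W = nc + 1;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      double v = NumericMatrix::is_na(dem(r, c)) ? 0.0 : dem(r, c) - mu;
      int ok = NumericMatrix::is_na(dem(r, c)) ? 0 : 1;
      S [(r + 1) * W + c + 1] = v     + S [r * W + c + 1] + S [(r + 1) * W + c] - S [r * W + c];
      S2[(r + 1) * W + c + 1] = v * v + S2[r * W + c + 1] + S2[(r + 1) * W + c] - S2[r * W + c];
      Cn[(r + 1) * W + c + 1] = ok    + Cn[r * W + c + 1] + Cn[(r + 1) * W + c] - Cn[r * W + c];
    }
  const int lo = (w - 1) / 2, hi = w / 2;  // even: extra row/col south/east
  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (NumericMatrix::is_na(dem(r, c))) { out(r, c) = NA_REAL; continue; }
      int r1 = std::max(0, r - lo), r2 = std::min(nr - 1, r + hi);
      int c1 = std::max(0, c - lo), c2 = std::min(nc - 1, c + hi);
      double s  = S [(r2 + 1) * W + c2 + 1] - S [r1 * W + c2 + 1] - S [(r2 + 1) * W + c1] + S [r1 * W + c1];
      double s2 = S2[(r2 + 1) * W + c2 + 1] - S2[r1 * W + c2 + 1] - S2[(r2 + 1) * W + c1] + S2[r1 * W + c1];
      int    n  = Cn[(r2 + 1) * W + c2 + 1] - Cn[r1 * W + c2 + 1] - Cn[(r2 + 1) * W + c1] + Cn[r1 * W + c1];
      if (n < 1) { out(r, c) = NA_REAL; continue; }
      double var = s2 / n - (s / n) * (s / n);
      out(r, c) = var > 0.0 ? std::sqrt(var) : 0.0;
    }
  }
  return out;
}
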