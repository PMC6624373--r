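#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Dijkstra shortest path on a 3-D grid with 26-connected moves and
// Euclidean edge weights, avoiding blocked cells. Used for
// solvent-accessible-surface (SAS) distances between atoms: blocked cells
// are those inside any obstructing atom's van-der-Waals sphere plus probe
// margin. Returns -1.0 if the goal is unreachable within `cutoff`.
// [[Rcpp::export(name = ".grid_dijkstra")]]
double grid_dijkstra(LogicalVector blocked, IntegerVector dims,
                     int start, int goal, double spacing, double cutoff) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  if (start < 0 || start >= n || goal < 0 || goal >= n)
    stop("start/goal index out of range");
  if (blocked[start] || blocked[goal]) return -1.0;

  // neighbour moves: first shell (26-connectivity) plus coprime
  // second-shell moves, which cut the lattice metric overestimate from
  // ~8% to ~2%; longer moves must not jump across blocked cells, so their
  // midpoint cell is checked during expansion
  std::vector<int> dxs, dys, dzs;
  std::vector<double> wts;
  std::vector<bool> longmove;
  for (int dx = -2; dx <= 2; ++dx)
    for (int dy = -2; dy <= 2; ++dy)
      for (int dz = -2; dz <= 2; ++dz) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int ax = std::abs(dx), ay = std::abs(dy), az = std::abs(dz);
        if (ax % 2 == 0 && ay % 2 == 0 && az % 2 == 0) continue; // collinear dup
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
        wts.push_back(spacing * std::sqrt((double)(dx*dx + dy*dy + dz*dz)));
        longmove.push_back(ax == 2 || ay == 2 || az == 2);
      }

  std::vector<double> dist(n, std::numeric_limits<double>::infinity());
  typedef std::pair<double, long> node;
  std::priority_queue<node, std::vector<node>, std::greater<node> > pq;
  dist[start] = 0.0;
  pq.push(node(0.0, start));

  while (!pq.empty()) {
    double d = pq.top().first;
    long idx = pq.top().second;
    pq.pop();
    if (idx == goal) return d;
    if (d > dist[idx] || d > cutoff) continue;
    int iz = idx / ((long)nx * ny);
    long rem = idx - (long)iz * nx * ny;
    int iy = rem / nx;
    int ix = rem - (long)iy * nx;
    for (size_t k = 0; k < dxs.size(); ++k) {
      int jx = ix + dxs[k], jy = iy + dys[k], jz = iz + dzs[k];
      if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz)
        continue;
      long jdx = (long)jz * nx * ny + (long)jy * nx + jx;
      if (blocked[jdx]) continue;
      if (longmove[k]) {
        // both cells nearest the segment midpoint must be clear
        int mx0 = ix + dxs[k] / 2, my0 = iy + dys[k] / 2, mz0 = iz + dzs[k] / 2;
        int mx1 = jx - dxs[k] / 2, my1 = jy - dys[k] / 2, mz1 = jz - dzs[k] / 2;
        if (blocked[(long)mz0 * nx * ny + (long)my0 * nx + mx0]) continue;
        if (blocked[(long)mz1 * nx * ny + (long)my1 * nx + mx1]) continue;
      }
      double nd = d + wts[k];
      if (nd < dist[jdx]) {
        dist[jdx] = nd;
        pq.push(node(nd, jdx));
      }
    }
  }
  return -1.0;
}

// Mark grid cells lying inside any sphere (centres cx/cy/cz, radii r).
// Grid cell (ix,iy,iz) has coordinates origin + spacing * index.
// [[Rcpp::export(name = ".grid_block_spheres")]]
LogicalVector grid_block_spheres(IntegerVector dims, NumericVector origin,
                                 double spacing, NumericVector cx,
                                 NumericVector cy, NumericVector cz,
                                 NumericVector r) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  LogicalVector blocked(n, false);
  for (int a = 0; a < cx.size(); ++a) {
    double rr = r[a], r2 = rr * rr;
    int ix0 = std::max(0, (int)std::ceil((cx[a] - rr - origin[0]) / spacing));
    int ix1 = std::min(nx - 1, (int)std::floor((cx[a] + rr - origin[0]) / spacing));
    int iy0 = std::max(0, (int)std::ceil((cy[a] - rr - origin[1]) / spacing));
    int iy1 = std::min(ny - 1, (int)std::floor((cy[a] + rr - origin[1]) / spacing));
    int iz0 = std::max(0, (int)std::ceil((cz[a] - rr - origin[2]) / spacing));
    int iz1 = std::min(nz - 1, (int)std::floor((cz[a] + rr - origin[2]) / spacing));
    for (int iz = iz0; iz <= iz1; ++iz) {
      double dz = origin[2] + spacing * iz - cz[a];
      for (int iy = iy0; iy <= iy1; ++iy) {
        double dy = origin[1] + spacing * iy - cy[a];
        for (int ix = ix0; ix <= ix1; ++ix) {
          double dx = origin[0] + spacing * ix - cx[a];
          if (dx * dx + dy * dy + dz * dz <= r2)
            blocked[(long)iz * nx * ny + (long)iy * nx + ix] = true;
        }
      }
    }
  }
  return blocked;
}
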