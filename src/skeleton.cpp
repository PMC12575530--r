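// 3-D binary image primitives used by the centerline module:
//  - connected-component labelling (6- or 26-connectivity)
//  - curve skeletonization by iterative topological thinning
//
// Thinning deletes simple points (Bertrand & Malandain characterization:
// exactly one 26-component of foreground in N26* and exactly one
// 6-component of background in N18 touching the centre face-wise) in six
// directional sub-iterations, preserving curve endpoints, until stable.

#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

static inline int lin(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dims,
                          int connectivity = 26) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  if ((int)mask.size() != n) stop("mask length does not match dims");
  IntegerVector labels(n, 0);
  int next_label = 0;
  std::queue<int> q;
  for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int idx = lin(i, j, k, nx, ny);
      if (!mask[idx] || labels[idx]) continue;
      labels[idx] = ++next_label;
      q.push(idx);
      while (!q.empty()) {
        int cur = q.front(); q.pop();
        int ci = cur % nx, cj = (cur / nx) % ny, ck = cur / (nx * ny);
        for (int dk = -1; dk <= 1; ++dk) for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int man = std::abs(di) + std::abs(dj) + std::abs(dk);
            if (connectivity == 6 && man > 1) continue;
            int ii = ci + di, jj = cj + dj, kk = ck + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            int nidx = lin(ii, jj, kk, nx, ny);
            if (mask[nidx] && !labels[nidx]) {
              labels[nidx] = next_label;
              q.push(nidx);
            }
          }
      }
    }
  return labels;
}

// ---- thinning helpers on a 3x3x3 local neighbourhood -----------------

// local cell index 0..26 for offsets in {-1,0,1}^3; centre = 13
static inline int loc(int di, int dj, int dk) {
  return (di + 1) + 3 * ((dj + 1) + 3 * (dk + 1));
}

// fill nb[27] with the neighbourhood of voxel (i,j,k); out-of-volume = false
static void fill_neighbourhood(const int* img, int i, int j, int k,
                               int nx, int ny, int nz, bool nb[27]) {
  for (int dk = -1; dk <= 1; ++dk) for (int dj = -1; dj <= 1; ++dj)
    for (int di = -1; di <= 1; ++di) {
      int ii = i + di, jj = j + dj, kk = k + dk;
      bool v = false;
      if (ii >= 0 && jj >= 0 && kk >= 0 && ii < nx && jj < ny && kk < nz)
        v = img[lin(ii, jj, kk, nx, ny)] != 0;
      nb[loc(di, dj, dk)] = v;
    }
}

static inline void cell_offsets(int c, int &di, int &dj, int &dk) {
  di = c % 3 - 1; dj = (c / 3) % 3 - 1; dk = c / 9 - 1;
}

// number of 26-connected components of foreground in N26* (centre excluded)
static int count_fg_components(const bool nb[27]) {
  bool seen[27] = {false};
  int ncomp = 0;
  for (int c = 0; c < 27; ++c) {
    if (c == 13 || !nb[c] || seen[c]) continue;
    ++ncomp;
    std::vector<int> stack(1, c);
    seen[c] = true;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int ci, cj, ck; cell_offsets(cur, ci, cj, ck);
      for (int c2 = 0; c2 < 27; ++c2) {
        if (c2 == 13 || !nb[c2] || seen[c2]) continue;
        int xi, xj, xk; cell_offsets(c2, xi, xj, xk);
        if (std::abs(xi - ci) <= 1 && std::abs(xj - cj) <= 1 &&
            std::abs(xk - ck) <= 1) {
          seen[c2] = true;
          stack.push_back(c2);
        }
      }
    }
  }
  return ncomp;
}

// number of 6-connected components of background in N18 that are
// 6-adjacent to the centre voxel
static int count_bg_components(const bool nb[27]) {
  bool in18[27], seen[27] = {false};
  for (int c = 0; c < 27; ++c) {
    int di, dj, dk; cell_offsets(c, di, dj, dk);
    int nz_off = (di != 0) + (dj != 0) + (dk != 0);
    in18[c] = (c != 13) && nz_off <= 2;
  }
  int ncomp = 0;
  for (int c = 0; c < 27; ++c) {
    if (!in18[c] || nb[c] || seen[c]) continue;
    int di, dj, dk; cell_offsets(c, di, dj, dk);
    if (std::abs(di) + std::abs(dj) + std::abs(dk) != 1) continue; // seed from face neighbours
    ++ncomp;
    std::vector<int> stack(1, c);
    seen[c] = true;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int ci, cj, ck; cell_offsets(cur, ci, cj, ck);
      for (int c2 = 0; c2 < 27; ++c2) {
        if (!in18[c2] || nb[c2] || seen[c2]) continue;
        int xi, xj, xk; cell_offsets(c2, xi, xj, xk);
        if (std::abs(xi - ci) + std::abs(xj - cj) + std::abs(xk - ck) == 1) {
          seen[c2] = true;
          stack.push_back(c2);
        }
      }
    }
  }
  return ncomp;
}

static inline int neighbour_count(const bool nb[27]) {
  int cnt = 0;
  for (int c = 0; c < 27; ++c) if (c != 13 && nb[c]) ++cnt;
  return cnt;
}

static inline bool is_simple(const bool nb[27]) {
  return count_fg_components(nb) == 1 && count_bg_components(nb) == 1;
}

// [[Rcpp::export(name = ".thin_3d")]]
LogicalVector thin_3d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  if ((int)mask.size() != n) stop("mask length does not match dims");
  std::vector<int> img(n);
  for (int i = 0; i < n; ++i) img[i] = mask[i] ? 1 : 0;

  // face-neighbour offsets defining the six directional sub-iterations
  const int dirs[6][3] = {{0,0,-1},{0,0,1},{0,-1,0},{0,1,0},{-1,0,0},{1,0,0}};
  bool nb[27];
  std::vector<int> candidates;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      candidates.clear();
      for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int idx = lin(i, j, k, nx, ny);
          if (!img[idx]) continue;
          int ii = i + dirs[d][0], jj = j + dirs[d][1], kk = k + dirs[d][2];
          bool border = (ii < 0 || jj < 0 || kk < 0 ||
                         ii >= nx || jj >= ny || kk >= nz) ||
                        !img[lin(ii, jj, kk, nx, ny)];
          if (!border) continue;
          fill_neighbourhood(img.data(), i, j, k, nx, ny, nz, nb);
          int ncnt = neighbour_count(nb);
          if (ncnt <= 1) continue;          // endpoint / isolated: keep
          if (!is_simple(nb)) continue;
          candidates.push_back(idx);
        }
      // sequential deletion with re-check so topology is never broken
      for (size_t c = 0; c < candidates.size(); ++c) {
        int idx = candidates[c];
        int i = idx % nx, j = (idx / nx) % ny, k = idx / (nx * ny);
        fill_neighbourhood(img.data(), i, j, k, nx, ny, nz, nb);
        if (neighbour_count(nb) <= 1) continue;
        if (!is_simple(nb)) continue;
        img[idx] = 0;
        changed = true;
      }
    }
  }
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = img[i] != 0;
  return out;
}
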