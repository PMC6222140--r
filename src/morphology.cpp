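#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Union-find with path compression for two-pass labeling.
static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra < rb) parent[rb] = ra; else if (rb < ra) parent[ra] = rb;
}

// 8-connected component labeling of a binary mask (nonzero = foreground).
// Returns an integer matrix with labels 1..K in raster (column-major) order
// of first appearance.
// [[Rcpp::export(name = ".label8_cpp")]]
IntegerMatrix label8_cpp(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0); // parent[0] unused
  int next = 1;

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      // neighbours already visited in column-major order:
      // (i-1, j), and (i-1..i+1, j-1)
      int best = 0;
      int cand[4][2] = {{i - 1, j}, {i - 1, j - 1}, {i, j - 1}, {i + 1, j - 1}};
      for (int k = 0; k < 4; ++k) {
        int ci = cand[k][0], cj = cand[k][1];
        if (ci < 0 || ci >= nr || cj < 0) continue;
        int l = lab(ci, cj);
        if (l > 0) {
          if (best == 0) best = l;
          else uf_union(parent, best, l);
        }
      }
      if (best == 0) {
        parent.push_back(next);
        lab(i, j) = next++;
      } else {
        lab(i, j) = best;
      }
    }
  }
  // Resolve equivalences and renumber in raster order of first appearance.
  std::vector<int> remap(next, 0);
  int out = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int l = lab(i, j);
      if (l == 0) continue;
      int r = uf_find(parent, l);
      if (remap[r] == 0) remap[r] = ++out;
      lab(i, j) = remap[r];
    }
  }
  return lab;
}

// Perinuclear ring construction with exact Euclidean pixel distances.
//
// For each nucleus label k: the nucleus is optionally eroded by the
// Euclidean disc of radius `erosion` (a pixel survives iff every integer
// offset (di,dj) with di^2+dj^2 <= erosion^2 stays inside label k;
// off-image counts as background). A non-nucleus pixel p belongs to ring k
// iff its exact Euclidean distance to the eroded pixel set of k is <= width.
// Pixels claimed by several rings go to the label at the smaller distance;
// exact ties go to the lower label id. Pixels inside ANY nucleus are never
// ring pixels.
// [[Rcpp::export(name = ".ring_rois_cpp")]]
IntegerMatrix ring_rois_cpp(const IntegerMatrix& nuclei, double width,
                            double erosion) {
  const int nr = nuclei.nrow(), nc = nuclei.ncol();
  IntegerMatrix ring(nr, nc);
  if (width <= 0) return ring;

  int K = 0;
  for (int idx = 0; idx < nr * nc; ++idx)
    if (nuclei[idx] > K) K = nuclei[idx];
  if (K == 0) return ring;

  const double w2 = width * width;
  const double e2 = erosion * erosion;
  const int wi = (int)std::floor(width);
  const int ei = (int)std::floor(erosion);

  std::vector<double> best(nr * nc, std::numeric_limits<double>::infinity());

  // pixels per label
  std::vector<std::vector<std::pair<int, int> > > px(K + 1);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (nuclei(i, j) > 0) px[nuclei(i, j)].push_back(std::make_pair(i, j));

  for (int k = 1; k <= K; ++k) {
    // erode label k
    std::vector<std::pair<int, int> > core;
    for (size_t s = 0; s < px[k].size(); ++s) {
      int i = px[k][s].first, j = px[k][s].second;
      bool keep = true;
      if (erosion > 0) {
        for (int di = -ei; di <= ei && keep; ++di)
          for (int dj = -ei; dj <= ei && keep; ++dj) {
            if ((double)(di * di + dj * dj) > e2) continue;
            int ii = i + di, jj = j + dj;
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc ||
                nuclei(ii, jj) != k)
              keep = false;
          }
      }
      if (keep) core.push_back(px[k][s]);
    }
    // paint min squared distance to the core within the width radius
    for (size_t s = 0; s < core.size(); ++s) {
      int i = core[s].first, j = core[s].second;
      for (int di = -wi; di <= wi; ++di) {
        int ii = i + di;
        if (ii < 0 || ii >= nr) continue;
        for (int dj = -wi; dj <= wi; ++dj) {
          double d2 = (double)(di * di + dj * dj);
          if (d2 > w2) continue;
          int jj = j + dj;
          if (jj < 0 || jj >= nc) continue;
          if (nuclei(ii, jj) > 0) continue; // never inside a nucleus
          int idx = ii + nr * jj;
          if (d2 < best[idx]) { // strict: ties keep the lower label
            best[idx] = d2;
            ring(ii, jj) = k;
          }
        }
      }
    }
  }
  return ring;
}
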