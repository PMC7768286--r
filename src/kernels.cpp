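#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Images are R matrices, column-major: element (r, c) at r + c * nrow.
// Point coordinates throughout: x = column index, y = row index, 0-based.

static inline int reflect_idx(int i, int n) {
  // half-sample symmetric reflection: -1 -> 0, n -> n-1
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Separable Gaussian convolution, reflective (half-sample symmetric) boundary.
// Kernel truncated at ceil(4*sigma), normalised to unit sum.
// [[Rcpp::export]]
NumericMatrix conv_gauss_reflect(NumericMatrix img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) stop("sigma must be > 0");
  int rad = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> k(2 * rad + 1);
  double s = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    double v = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    k[i + rad] = v; s += v;
  }
  for (double &v : k) v /= s;

  NumericMatrix tmp(nr, nc), out(nr, nc);
  // vertical pass (along rows within a column)
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int i = -rad; i <= rad; ++i)
        acc += k[i + rad] * img(reflect_idx(r + i, nr), c);
      tmp(r, c) = acc;
    }
  // horizontal pass
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int i = -rad; i <= rad; ++i)
        acc += k[i + rad] * tmp(r, reflect_idx(c + i, nc));
      out(r, c) = acc;
    }
  return out;
}

// Grayscale erosion (dilate = false) or dilation (dilate = true) with an
// arbitrary (possibly non-flat) structuring element given as offset lists
// (dx = column offset, dy = row offset) and heights. Out-of-bounds offsets
// are ignored (identity element for min/max).
// [[Rcpp::export]]
NumericMatrix gray_morph(NumericMatrix img, IntegerVector se_dx,
                         IntegerVector se_dy, NumericVector se_h,
                         bool dilate) {
  int nr = img.nrow(), nc = img.ncol(), m = se_dx.size();
  NumericMatrix out(nr, nc);
  const double *p = img.begin();
  double *q = out.begin();
  // flattened neighbour offsets (dilation uses the reflected element)
  std::vector<long> delta(m);
  std::vector<double> h(m);
  int maxdx = 0, maxdy = 0;
  for (int j = 0; j < m; ++j) {
    int dx = dilate ? -se_dx[j] : se_dx[j];
    int dy = dilate ? -se_dy[j] : se_dy[j];
    delta[j] = (long)dx * nr + dy;
    h[j] = se_h[j];
    maxdx = std::max(maxdx, std::abs(se_dx[j]));
    maxdy = std::max(maxdy, std::abs(se_dy[j]));
  }
  int r0 = maxdy, r1 = nr - maxdy, c0 = maxdx, c1 = nc - maxdx;
  // interior: no bounds checks
  for (int c = c0; c < c1; ++c) {
    for (int r = r0; r < r1; ++r) {
      long base = (long)c * nr + r;
      double best;
      if (dilate) {
        best = -INFINITY;
        for (int j = 0; j < m; ++j) {
          double v = p[base + delta[j]] + h[j];
          if (v > best) best = v;
        }
      } else {
        best = INFINITY;
        for (int j = 0; j < m; ++j) {
          double v = p[base + delta[j]] - h[j];
          if (v < best) best = v;
        }
      }
      q[base] = best;
    }
  }
  // border band: bounds-checked
  for (int c = 0; c < nc; ++c) {
    bool cedge = (c < c0 || c >= c1);
    for (int r = 0; r < nr; ++r) {
      if (!cedge && r >= r0 && r < r1) { if (!cedge) r = r1 - 1; continue; }
      double best = dilate ? -INFINITY : INFINITY;
      for (int j = 0; j < m; ++j) {
        int rr, cc;
        if (dilate) { rr = r - se_dy[j]; cc = c - se_dx[j]; }
        else        { rr = r + se_dy[j]; cc = c + se_dx[j]; }
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        double v = dilate ? img(rr, cc) + se_h[j] : img(rr, cc) - se_h[j];
        if (dilate ? (v > best) : (v < best)) best = v;
      }
      q[(long)c * nr + r] = best;
    }
  }
  return out;
}

// Connected-component labelling of a binary mask (non-zero = foreground).
// conn = 4 or 8. Labels assigned 1..K in raster scan order of first pixel.
// [[Rcpp::export]]
IntegerMatrix label_components(IntegerMatrix mask, int conn) {
  int nr = mask.nrow(), nc = mask.ncol();
  if (conn != 4 && conn != 8) stop("conn must be 4 or 8");
  IntegerMatrix lab(nr, nc);
  int dx4[] = {1, -1, 0, 0}, dy4[] = {0, 0, 1, -1};
  int dx8[] = {1, -1, 0, 0, 1, 1, -1, -1}, dy8[] = {0, 0, 1, -1, 1, -1, 1, -1};
  int *dx = conn == 4 ? dx4 : dx8, *dy = conn == 4 ? dy4 : dy8;
  int nn = conn;
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.clear(); stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int pr = idx % nr, pc = idx / nr;
        for (int j = 0; j < nn; ++j) {
          int rr = pr + dy[j], cc = pc + dx[j];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) != 0 && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(rr + cc * nr);
          }
        }
      }
    }
  return lab;
}

// Fill holes in a label map: background regions (8-connected) that do not
// touch the image border and are adjacent to exactly one object label are
// assigned that label. Regions enclosed jointly by several objects are kept.
// [[Rcpp::export]]
IntegerMatrix fill_holes_labels(IntegerMatrix lab) {
  int nr = lab.nrow(), nc = lab.ncol();
  IntegerMatrix out = clone(lab);
  IntegerMatrix bg(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      bg(r, c) = lab(r, c) == 0 ? 1 : 0;
  IntegerMatrix bglab = label_components(bg, 8);
  int nbg = 0;
  for (int i = 0; i < nr * nc; ++i) nbg = std::max(nbg, bglab[i]);
  if (nbg == 0) return out;
  std::vector<bool> border(nbg + 1, false);
  std::vector<int> owner(nbg + 1, 0);   // 0 = none yet, -1 = ambiguous
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int b = bglab(r, c);
      if (b == 0) continue;
      if (r == 0 || r == nr - 1 || c == 0 || c == nc - 1) border[b] = true;
      // 4-neighbour object adjacency
      int nbr[4][2] = {{r + 1, c}, {r - 1, c}, {r, c + 1}, {r, c - 1}};
      for (auto &p : nbr) {
        if (p[0] < 0 || p[0] >= nr || p[1] < 0 || p[1] >= nc) continue;
        int l = lab(p[0], p[1]);
        if (l > 0) {
          if (owner[b] == 0) owner[b] = l;
          else if (owner[b] != l) owner[b] = -1;
        }
      }
    }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int b = bglab(r, c);
      if (b > 0 && !border[b] && owner[b] > 0) out(r, c) = owner[b];
    }
  return out;
}

// ---- topographic-prominence maxima ----------------------------------------
// Union-find over pixels processed in descending intensity order. Plateaus
// (8-connected sets of equal value with no higher neighbour) count as one
// maximum reported at the plateau centroid, rounded to the nearest pixel.
// A maximum's prominence is its height minus the highest saddle connecting
// it to dominating terrain; maxima never dominated use the image minimum as
// reference. Equal-height peaks are ordered by the elder rule: the plateau
// whose first pixel comes earliest in column-major order dominates, so of
// two equal twins only the elder survives their connecting saddle.

struct Plateau { double sx, sy; int n; long birth; };

static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) { parent[i] = parent[parent[i]]; i = parent[i]; }
  return i;
}

// [[Rcpp::export]]
DataFrame find_maxima_prom(NumericMatrix img, double prominence) {
  int nr = img.nrow(), nc = img.ncol(), n = nr * nc;
  if (prominence <= 0) stop("prominence must be > 0");
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    return img[a] > img[b];
  });
  double vmin = img[ord[n - 1]];

  std::vector<int> parent(n, -1);           // -1 = not yet activated
  std::vector<double> peak(n, 0.0);
  // per-root peak plateau (coordinate sums, size, birth index)
  std::vector<Plateau> plat(n);

  std::vector<double> out_x, out_y, out_v, out_p;
  auto emit = [&](const Plateau &pl, double pk, double pr) {
    out_x.push_back(std::floor(pl.sx / pl.n + 0.5));
    out_y.push_back(std::floor(pl.sy / pl.n + 0.5));
    out_v.push_back(pk);
    out_p.push_back(pr);
  };

  int dx8[] = {1, -1, 0, 0, 1, 1, -1, -1}, dy8[] = {0, 0, 1, -1, 1, -1, 1, -1};

  int i = 0;
  while (i < n) {
    int j = i;
    double v = img[ord[i]];
    while (j < n && img[ord[j]] == v) ++j;
    // activate all pixels at this level
    for (int t = i; t < j; ++t) {
      int idx = ord[t];
      parent[idx] = idx;
      peak[idx] = v;
      plat[idx] = {(double)(idx / nr), (double)(idx % nr), 1, (long)idx};
    }
    // union with active neighbours
    for (int t = i; t < j; ++t) {
      int idx = ord[t];
      int pr_ = idx % nr, pc_ = idx / nr;
      for (int q = 0; q < 8; ++q) {
        int rr = pr_ + dy8[q], cc = pc_ + dx8[q];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int nidx = rr + cc * nr;
        if (parent[nidx] < 0) continue;    // not yet active (lower value)
        int ra = uf_find(parent, idx), rb = uf_find(parent, nidx);
        if (ra == rb) continue;
        if (peak[ra] < peak[rb]) std::swap(ra, rb);
        double pa = peak[ra], pb = peak[rb]; // pa >= pb >= v
        if (pa == v && pb == v) {
          // same-level plateau join: coalesce coordinate sums
          Plateau &A = plat[ra], &B = plat[rb];
          A.sx += B.sx; A.sy += B.sy; A.n += B.n;
          A.birth = std::min(A.birth, B.birth);
        } else if (pb == v) {
          // plateau at current level touching higher terrain: not a maximum
        } else {
          if (pa == pb && plat[rb].birth < plat[ra].birth)
            std::swap(ra, rb);       // elder rule: younger twin dies
          // dominated component dies at saddle level v
          double pr2 = peak[rb] - v;
          if (pr2 >= prominence) emit(plat[rb], peak[rb], pr2);
        }
        parent[rb] = ra;
      }
    }
    i = j;
  }
  // surviving roots: prominence relative to the image minimum
  for (int idx = 0; idx < n; ++idx) {
    if (parent[idx] == idx && plat[idx].n > 0) {
      double pr2 = peak[idx] - vmin;
      if (pr2 >= prominence) emit(plat[idx], peak[idx], pr2);
    }
  }
  // deterministic order: by y then x
  int m = out_x.size();
  std::vector<int> oo(m);
  for (int t = 0; t < m; ++t) oo[t] = t;
  std::sort(oo.begin(), oo.end(), [&](int a, int b) {
    if (out_y[a] != out_y[b]) return out_y[a] < out_y[b];
    return out_x[a] < out_x[b];
  });
  NumericVector X(m), Y(m), V(m), P(m);
  for (int t = 0; t < m; ++t) {
    X[t] = out_x[oo[t]]; Y[t] = out_y[oo[t]];
    V[t] = out_v[oo[t]]; P[t] = out_p[oo[t]];
  }
  return DataFrame::create(_["x"] = X, _["y"] = Y,
                           _["value"] = V, _["prominence"] = P);
}

// Seeded watershed by priority flood: regions grow from seed labels in
// order of ascending surface value, restricted to mask, 4-connected growth.
// [[Rcpp::export]]
IntegerMatrix watershed_seeded(NumericMatrix surface, IntegerMatrix seeds,
                               IntegerMatrix mask) {
  int nr = surface.nrow(), nc = surface.ncol();
  IntegerMatrix out(nr, nc);
  typedef std::pair<double, long long> QE; // (value, insertion order<<32 | idx)
  std::priority_queue<std::pair<double, std::pair<long long, int> >,
                      std::vector<std::pair<double, std::pair<long long, int> > >,
                      std::greater<std::pair<double, std::pair<long long, int> > > > pq;
  long long counter = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (seeds(r, c) > 0 && mask(r, c) != 0) {
        out(r, c) = seeds(r, c);
        pq.push({surface(r, c), {counter++, r + c * nr}});
      }
  int dx4[] = {1, -1, 0, 0}, dy4[] = {0, 0, 1, -1};
  while (!pq.empty()) {
    int idx = pq.top().second.second; pq.pop();
    int r = idx % nr, c = idx / nr, l = out(r, c);
    for (int q = 0; q < 4; ++q) {
      int rr = r + dy4[q], cc = c + dx4[q];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (mask(rr, cc) != 0 && out(rr, cc) == 0) {
        out(rr, cc) = l;
        pq.push({surface(rr, cc), {counter++, rr + cc * nr}});
      }
    }
  }
  return out;
}
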