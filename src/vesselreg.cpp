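#include <Rcpp.h>
#include <vector>
#include <deque>
#include <cmath>

using namespace Rcpp;

// Mirror index (reflect about the edge sample, no duplication): -1 -> 1, n -> n-2.
static inline int mirror(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

static std::vector<double> gauss_kernel(double sigma) {
  int radius = (int)std::ceil(3.0 * sigma);
  if (radius < 1) radius = 1;
  std::vector<double> k(2 * radius + 1);
  double s = 0.0;
  for (int i = -radius; i <= radius; ++i) {
    double v = std::exp(-0.5 * (double)i * (double)i / (sigma * sigma));
    k[i + radius] = v;
    s += v;
  }
  for (double& v : k) v /= s;
  return k;
}

// 1D convolution of a contiguous signal, mirror boundary, fast interior.
static void conv1d(const double* x, int n, const std::vector<double>& k,
                   double* y) {
  int radius = ((int)k.size() - 1) / 2;
  int lo = std::min(radius, n), hi = std::max(n - radius, lo);
  for (int i = 0; i < lo; ++i) {
    double acc = 0.0;
    for (int j = -radius; j <= radius; ++j)
      acc += k[j + radius] * x[mirror(i + j, n)];
    y[i] = acc;
  }
  for (int i = lo; i < hi; ++i) {
    double acc = 0.0;
    const double* p = x + i - radius;
    for (size_t j = 0; j < k.size(); ++j) acc += k[j] * p[j];
    y[i] = acc;
  }
  for (int i = hi; i < n; ++i) {
    double acc = 0.0;
    for (int j = -radius; j <= radius; ++j)
      acc += k[j + radius] * x[mirror(i + j, n)];
    y[i] = acc;
  }
}

// Separable Gaussian blur, mirror boundary. Image is [row, col].
// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(NumericMatrix img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<double> k = gauss_kernel(sigma);
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // along rows (within each column; contiguous in memory)
  for (int c = 0; c < nc; ++c)
    conv1d(&img(0, c), nr, k, &tmp(0, c));
  // along columns: gather each row into a buffer
  std::vector<double> rowbuf(nc), obuf(nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) rowbuf[c] = tmp(r, c);
    conv1d(rowbuf.data(), nc, k, obuf.data());
    for (int c = 0; c < nc; ++c) out(r, c) = obuf[c];
  }
  return out;
}

// Scale-normalised Hessian eigenvalues: Gaussian blur at sigma, central
// second differences multiplied by sigma^2, then the 2x2 symmetric
// eigenvalues ordered |lambda1| <= |lambda2|. x = column, y = row axis.
// [[Rcpp::export]]
List cpp_hessian_eigen(NumericMatrix img, double sigma) {
  NumericMatrix b = cpp_gauss_blur(img, sigma);
  int nr = b.nrow(), nc = b.ncol();
  NumericMatrix l1(nr, nc), l2(nr, nc);
  double s2 = sigma * sigma;
  for (int c = 0; c < nc; ++c) {
    int cm = mirror(c - 1, nc), cp = mirror(c + 1, nc);
    for (int r = 0; r < nr; ++r) {
      int rm = mirror(r - 1, nr), rp = mirror(r + 1, nr);
      double ixx = s2 * (b(r, cp) - 2.0 * b(r, c) + b(r, cm));
      double iyy = s2 * (b(rp, c) - 2.0 * b(r, c) + b(rm, c));
      double ixy = s2 * 0.25 * (b(rp, cp) - b(rp, cm) - b(rm, cp) + b(rm, cm));
      double m = 0.5 * (ixx + iyy);
      double d = std::sqrt(0.25 * (ixx - iyy) * (ixx - iyy) + ixy * ixy);
      double hi = m + d, lo = m - d;
      if (std::abs(lo) > std::abs(hi)) std::swap(hi, lo);
      l1(r, c) = lo;  // |l1| <= |l2|
      l2(r, c) = hi;
    }
  }
  return List::create(_["lambda1"] = l1, _["lambda2"] = l2);
}

// Dip response for one column, widths v in {vmin, vmin+stride, ...} <= vmax.
// Windows (inclusive, h = floor(v/2)): a over [x+h, x+v], b over [x-v, x-h],
// c over [x-h, x+h]; windows needing rows outside the column are skipped.
// Candidate value min(a-c, b-c) when c < a and c < b is spread over
// [x-h, x+h]; the output keeps the max over all covering candidates.
static void dip_column(const double* col, int nr, int vmin, int vmax, int stride,
                       double* out, std::vector<double>& cs,
                       std::vector<double>& cand) {
  cs[0] = 0.0;
  for (int r = 0; r < nr; ++r) cs[r + 1] = cs[r] + col[r];
  for (int r = 0; r < nr; ++r) out[r] = 0.0;
  for (int v = vmin; v <= vmax; v += stride) {
    int h = v / 2;
    std::fill(cand.begin(), cand.end(), 0.0);
    bool any = false;
    for (int x = v; x <= nr - 1 - v; ++x) {
      double a = (cs[x + v + 1] - cs[x + h]) / (double)(v - h + 1);
      double b = (cs[x - h + 1] - cs[x - v]) / (double)(v - h + 1);
      double cc = (cs[x + h + 1] - cs[x - h]) / (double)(2 * h + 1);
      if (cc < a && cc < b) {
        double bv = std::min(a - cc, b - cc);
        if (bv > cand[x]) cand[x] = bv;
        any = true;
      }
    }
    if (!any) continue;
    // sliding max of cand with radius h: out[i] = max over x in [i-h, i+h]
    std::deque<int> dq;
    for (int i = 0; i < nr + h; ++i) {
      if (i < nr) {
        while (!dq.empty() && cand[dq.back()] <= cand[i]) dq.pop_back();
        dq.push_back(i);
      }
      int pos = i - h;  // output index whose window [pos-h, pos+h] ends at i
      if (pos >= 0) {
        while (dq.front() < pos - h) dq.pop_front();
        if (cand[dq.front()] > out[pos]) out[pos] = cand[dq.front()];
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_dip(NumericMatrix img, int vmin, int vmax, int stride) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> cs(nr + 1), cand(nr), colbuf(nr), obuf(nr);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) colbuf[r] = img(r, c);
    dip_column(colbuf.data(), nr, vmin, vmax, stride, obuf.data(), cs, cand);
    for (int r = 0; r < nr; ++r) out(r, c) = obuf[r];
  }
  return out;
}

// Column-restricted dip: compute only for columns where active[c] is TRUE.
// [[Rcpp::export]]
NumericMatrix cpp_dip_columns(NumericMatrix img, int vmin, int vmax, int stride,
                              LogicalVector active) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> cs(nr + 1), cand(nr), colbuf(nr), obuf(nr);
  for (int c = 0; c < nc; ++c) {
    if (!active[c]) continue;
    for (int r = 0; r < nr; ++r) colbuf[r] = img(r, c);
    dip_column(colbuf.data(), nr, vmin, vmax, stride, obuf.data(), cs, cand);
    for (int r = 0; r < nr; ++r) out(r, c) = obuf[r];
  }
  return out;
}

static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// 8-connected component labelling of a binary mask; labels 1..K, 0 = background.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.reserve(1024);
  parent.push_back(0);  // dummy for background
  // first pass: scan column-major, union with already-visited 8-neighbours
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      int neigh[4][2] = {{r - 1, c}, {r - 1, c - 1}, {r, c - 1}, {r + 1, c - 1}};
      int lbl = 0;
      for (auto& n : neigh) {
        if (n[0] < 0 || n[0] >= nr || n[1] < 0) continue;
        int l2 = lab(n[0], n[1]);
        if (l2 == 0) continue;
        if (lbl == 0) lbl = uf_find(parent, l2);
        else {
          int root = uf_find(parent, l2);
          if (root != lbl) {
            if (root < lbl) std::swap(root, lbl);
            parent[root] = lbl;
          }
        }
      }
      if (lbl == 0) {
        lbl = (int)parent.size();
        parent.push_back(lbl);
      }
      lab(r, c) = lbl;
    }
  }
  // second pass: compress and renumber 1..K
  std::vector<int> newlab(parent.size(), 0);
  int k = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l == 0) continue;
      int root = uf_find(parent, l);
      if (newlab[root] == 0) newlab[root] = ++k;
      lab(r, c) = newlab[root];
    }
  return lab;
}
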