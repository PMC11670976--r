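#include <Rcpp.h>
#include <limits>
#include <vector>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// 3D connected-component labelling on a logical grid.
// Connectivity: 6 (faces), 18 (faces+edges) or 26 (faces+edges+corners).
// Labels are assigned contiguously 1..K in raster-scan order of each
// component's first voxel, so the labelling is deterministic.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  IntegerVector labels(n, 0);

  // neighbour offsets
  std::vector<int> ox, oy, oz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        ox.push_back(dx); oy.push_back(dy); oz.push_back(dz);
      }
  const int nn = (int)ox.size();

  std::vector<R_xlen_t> stack;
  int next_label = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++next_label;
    labels[s] = next_label;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int x = (int)(v % d1);
      int y = (int)((v / d1) % d2);
      int z = (int)(v / ((R_xlen_t)d1 * d2));
      for (int t = 0; t < nn; ++t) {
        int xx = x + ox[t], yy = y + oy[t], zz = z + oz[t];
        if (xx < 0 || xx >= d1 || yy < 0 || yy >= d2 || zz < 0 || zz >= d3) continue;
        R_xlen_t w = (R_xlen_t)xx + (R_xlen_t)d1 * (yy + (R_xlen_t)d2 * zz);
        if (mask[w] && labels[w] == 0) {
          labels[w] = next_label;
          stack.push_back(w);
        }
      }
    }
  }
  labels.attr("dim") = dim;
  return labels;
}

// ---------------------------------------------------------------------------
// Exact anisotropic squared Euclidean distance transform
// (Felzenszwalb & Huttenlocher lower-envelope algorithm, one pass per axis).
// `site` marks the feature voxels; distances are in world mm (squared),
// using the per-axis voxel spacing. Voxels on sites get distance 0.
// ---------------------------------------------------------------------------

static const double DT_INF = 1e20;

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n, double w,
                 std::vector<int>& v, std::vector<double>& z) {
  const double w2 = w * w;
  const double inf = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -inf;
  z[1] = inf;
  for (int q = 1; q < n; ++q) {
    double s = 0.0;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = inf;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    d[q] = f[p] + w2 * (q - p) * (q - p);
  }
}

// [[Rcpp::export]]
NumericVector edt_sq_3d(LogicalVector site, IntegerVector dim, NumericVector spacing) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = site[i] ? 0.0 : DT_INF;

  int nmax = std::max(d1, std::max(d2, d3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1 (stride 1)
  for (int zz = 0; zz < d3; ++zz)
    for (int yy = 0; yy < d2; ++yy) {
      R_xlen_t base = (R_xlen_t)d1 * (yy + (R_xlen_t)d2 * zz);
      for (int x = 0; x < d1; ++x) f[x] = out[base + x];
      dt1d(f, d, d1, spacing[0], v, z);
      for (int x = 0; x < d1; ++x) out[base + x] = d[x];
    }
  // axis 2 (stride d1)
  for (int zz = 0; zz < d3; ++zz)
    for (int xx = 0; xx < d1; ++xx) {
      R_xlen_t base = (R_xlen_t)xx + (R_xlen_t)d1 * d2 * zz;
      for (int y = 0; y < d2; ++y) f[y] = out[base + (R_xlen_t)d1 * y];
      dt1d(f, d, d2, spacing[1], v, z);
      for (int y = 0; y < d2; ++y) out[base + (R_xlen_t)d1 * y] = d[y];
    }
  // axis 3 (stride d1*d2)
  const R_xlen_t s3 = (R_xlen_t)d1 * d2;
  for (int yy = 0; yy < d2; ++yy)
    for (int xx = 0; xx < d1; ++xx) {
      R_xlen_t base = (R_xlen_t)xx + (R_xlen_t)d1 * yy;
      for (int zz = 0; zz < d3; ++zz) f[zz] = out[base + s3 * zz];
      dt1d(f, d, d3, spacing[2], v, z);
      for (int zz = 0; zz < d3; ++zz) out[base + s3 * zz] = d[zz];
    }
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Separable 3D convolution with zero padding; one (odd-length) kernel per
// axis. A kernel of length 1 with value 1 leaves that axis untouched.
// ---------------------------------------------------------------------------

static void conv_axis(std::vector<double>& buf, const NumericVector& src,
                      NumericVector& dst, int d1, int d2, int d3,
                      const NumericVector& kern, int axis) {
  int klen = (int)kern.size();
  int r = (klen - 1) / 2;
  int dims[3] = {d1, d2, d3};
  int n_axis = dims[axis];
  R_xlen_t stride = 1;
  for (int a = 0; a < axis; ++a) stride *= dims[a];

  int oa = (axis == 0) ? 1 : 0;
  int ob = (axis == 2) ? 1 : 2;
  R_xlen_t stride_a = 1, stride_b = 1;
  for (int a = 0; a < oa; ++a) stride_a *= dims[a];
  for (int a = 0; a < ob; ++a) stride_b *= dims[a];

  if ((int)buf.size() < n_axis) buf.resize(n_axis);
  for (int ib = 0; ib < dims[ob]; ++ib)
    for (int ia = 0; ia < dims[oa]; ++ia) {
      R_xlen_t base = stride_a * ia + stride_b * ib;
      for (int q = 0; q < n_axis; ++q) buf[q] = src[base + stride * q];
      for (int q = 0; q < n_axis; ++q) {
        double acc = 0.0;
        int lo = std::max(0, q - r), hi = std::min(n_axis - 1, q + r);
        for (int p = lo; p <= hi; ++p) acc += buf[p] * kern[(p - q) + r];
        dst[base + stride * q] = acc;
      }
    }
}

// [[Rcpp::export]]
NumericVector conv_sep_3d(NumericVector vol, IntegerVector dim,
                          NumericVector k1, NumericVector k2, NumericVector k3) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  NumericVector a(n), b(n);
  std::vector<double> buf;
  if (k1.size() > 1) conv_axis(buf, vol, a, d1, d2, d3, k1, 0); else a = clone(vol);
  if (k2.size() > 1) conv_axis(buf, a, b, d1, d2, d3, k2, 1); else b = clone(a);
  if (k3.size() > 1) { conv_axis(buf, b, a, d1, d2, d3, k3, 2); b = a; }
  b.attr("dim") = dim;
  return b;
}
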