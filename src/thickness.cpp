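#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>
using namespace Rcpp;

// 3D squared Euclidean distance transform (Felzenszwalb & Huttenlocher) and
// the Hildebrand-Ruegsegger local thickness transform: for every foreground
// voxel p, the diameter of the largest sphere that contains p and fits
// entirely inside the foreground. The volume border is treated as solid, so
// spheres may not extend outside the volume.

static const double INF = std::numeric_limits<double>::infinity();
// Large finite stand-in for "no background in sight" when seeding the EDT:
// infinity would make the parabola-intersection formula produce NaN
// (INF - INF) and corrupt the lower envelope.
static const double BIG = 1e15;

// 1D squared distance transform of sampled function f, length n.
static void dt1d(const double* f, double* d, int* v, double* z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared EDT of foreground to nearest background voxel centre, with a
// virtual one-voxel solid border around the volume.
static std::vector<double> edt_sq_padded(const LogicalVector& fg,
                                         int d1, int d2, int d3) {
  const int p1 = d1 + 2, p2 = d2 + 2, p3 = d3 + 2;
  const R_xlen_t np = (R_xlen_t)p1 * p2 * p3;
  std::vector<double> g(np, 0.0); // padding and background = 0
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        const R_xlen_t src = i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
        const R_xlen_t dst =
            (i + 1) + (R_xlen_t)p1 * ((j + 1) + (R_xlen_t)p2 * (k + 1));
        g[dst] = fg[src] ? BIG : 0.0;
      }
  const int nmax = std::max(p1, std::max(p2, p3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // axis 1 (stride 1)
  for (int k = 0; k < p3; ++k)
    for (int j = 0; j < p2; ++j) {
      double* line = &g[(R_xlen_t)p1 * (j + (R_xlen_t)p2 * k)];
      dt1d(line, d.data(), v.data(), z.data(), p1);
      std::copy(d.begin(), d.begin() + p1, line);
    }
  // axis 2 (stride p1)
  for (int k = 0; k < p3; ++k)
    for (int i = 0; i < p1; ++i) {
      const R_xlen_t base = i + (R_xlen_t)p1 * p2 * k;
      for (int j = 0; j < p2; ++j) f[j] = g[base + (R_xlen_t)p1 * j];
      dt1d(f.data(), d.data(), v.data(), z.data(), p2);
      for (int j = 0; j < p2; ++j) g[base + (R_xlen_t)p1 * j] = d[j];
    }
  // axis 3 (stride p1*p2)
  const R_xlen_t s3 = (R_xlen_t)p1 * p2;
  for (int j = 0; j < p2; ++j)
    for (int i = 0; i < p1; ++i) {
      const R_xlen_t base = i + (R_xlen_t)p1 * j;
      for (int k = 0; k < p3; ++k) f[k] = g[base + s3 * k];
      dt1d(f.data(), d.data(), v.data(), z.data(), p3);
      for (int k = 0; k < p3; ++k) g[base + s3 * k] = d[k];
    }
  return g;
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector fg, IntegerVector dims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int p1 = d1 + 2, p2 = d2 + 2;
  std::vector<double> g = edt_sq_padded(fg, d1, d2, d3);
  NumericVector out((R_xlen_t)d1 * d2 * d3);
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i)
        out[i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k)] =
            g[(i + 1) + (R_xlen_t)p1 * ((j + 1) + (R_xlen_t)p2 * (k + 1))];
  out.attr("dim") = dims;
  return out;
}

// Local thickness by sphere propagation: every foreground voxel c carries an
// inscribed-sphere squared radius r2(c) from the EDT; each sphere paints
// max(out, 2*sqrt(r2)) over the voxels it strictly contains (|q-c|^2 < r2,
// exact in integer arithmetic). Spheres are processed in decreasing radius.
// Returns diameters in voxel units.
// [[Rcpp::export]]
NumericVector cpp_local_thickness(LogicalVector fg, IntegerVector dims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  const int p1 = d1 + 2, p2 = d2 + 2;
  std::vector<double> g = edt_sq_padded(fg, d1, d2, d3);

  struct Center { double r2; int i, j, k; };
  std::vector<Center> centers;
  centers.reserve(1024);
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        const double r2 =
            g[(i + 1) + (R_xlen_t)p1 * ((j + 1) + (R_xlen_t)p2 * (k + 1))];
        if (r2 > 0.0) centers.push_back({r2, i, j, k});
      }
  std::sort(centers.begin(), centers.end(),
            [](const Center& a, const Center& b) { return a.r2 > b.r2; });

  std::vector<double> best(n, 0.0); // squared radius of the covering sphere
  for (const Center& c : centers) {
    const double r2 = c.r2;
    const int m = (int)std::floor(std::sqrt(r2 - 1.0 + 1e-9)); // max |offset|
    for (int dk = -m; dk <= m; ++dk) {
      const int kk = c.k + dk;
      if (kk < 0 || kk >= d3) continue;
      const double rk = r2 - (double)dk * dk;
      for (int dj = -m; dj <= m; ++dj) {
        const int jj = c.j + dj;
        if (jj < 0 || jj >= d2) continue;
        const double rjk = rk - (double)dj * dj;
        if (rjk <= 0.0) continue;
        const int mi =
            (rjk > 1.0) ? (int)std::floor(std::sqrt(rjk - 1.0 + 1e-9)) : 0;
        const R_xlen_t base = (R_xlen_t)d1 * (jj + (R_xlen_t)d2 * kk);
        const int lo = std::max(0, c.i - mi), hi = std::min(d1 - 1, c.i + mi);
        for (int ii = lo; ii <= hi; ++ii) {
          double& b = best[base + ii];
          if (r2 > b) b = r2;
        }
      }
    }
  }
  NumericVector out(n);
  for (R_xlen_t p = 0; p < n; ++p)
    out[p] = best[p] > 0.0 ? 2.0 * std::sqrt(best[p]) : 0.0;
  out.attr("dim") = dims;
  return out;
}

// Brute-force oracle used in tests: radii by exhaustive nearest-background
// scan, thickness by exhaustive sphere-containment scan. Independent of the
// EDT/propagation path above. Intended for small volumes only.
// [[Rcpp::export]]
NumericVector cpp_local_thickness_brute(LogicalVector fg, IntegerVector dims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  std::vector<int> ai, aj, ak, si, sj, sk;
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        const R_xlen_t p = i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
        if (fg[p]) { ai.push_back(i); aj.push_back(j); ak.push_back(k); }
        else { si.push_back(i); sj.push_back(j); sk.push_back(k); }
      }
  const size_t na = ai.size(), ns = si.size();
  std::vector<double> r2(na);
  for (size_t a = 0; a < na; ++a) {
    // virtual solid border: nearest point of each border plane
    double best = (double)(ai[a] + 1) * (ai[a] + 1);
    double t;
    t = (double)(d1 - ai[a]) * (d1 - ai[a]); if (t < best) best = t;
    t = (double)(aj[a] + 1) * (aj[a] + 1);   if (t < best) best = t;
    t = (double)(d2 - aj[a]) * (d2 - aj[a]); if (t < best) best = t;
    t = (double)(ak[a] + 1) * (ak[a] + 1);   if (t < best) best = t;
    t = (double)(d3 - ak[a]) * (d3 - ak[a]); if (t < best) best = t;
    for (size_t s = 0; s < ns; ++s) {
      const double di = ai[a] - si[s], dj = aj[a] - sj[s], dk = ak[a] - sk[s];
      const double d = di * di + dj * dj + dk * dk;
      if (d < best) best = d;
    }
    r2[a] = best;
  }
  NumericVector out(n);
  for (size_t p = 0; p < na; ++p) {
    double best = 0.0;
    for (size_t c = 0; c < na; ++c) {
      const double di = ai[p] - ai[c], dj = aj[p] - aj[c], dk = ak[p] - ak[c];
      if (di * di + dj * dj + dk * dk < r2[c] && r2[c] > best) best = r2[c];
    }
    out[ai[p] + (R_xlen_t)d1 * (aj[p] + (R_xlen_t)d2 * ak[p])] =
        2.0 * std::sqrt(best);
  }
  out.attr("dim") = dims;
  return out;
}
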