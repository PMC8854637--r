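#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Bilinear sample with zero padding outside the grid.
static inline double sample_bilinear(const NumericMatrix& img, double x, double y) {
  const int n1 = img.nrow(), n2 = img.ncol();
  if (x < -1.0 || y < -1.0 || x > n1 || y > n2) return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  double fx = x - x0, fy = y - y0;
  double v = 0.0;
  for (int dx = 0; dx <= 1; ++dx) {
    int xi = x0 + dx;
    if (xi < 0 || xi >= n1) continue;
    double wx = dx ? fx : 1.0 - fx;
    for (int dy = 0; dy <= 1; ++dy) {
      int yi = y0 + dy;
      if (yi < 0 || yi >= n2) continue;
      double wy = dy ? fy : 1.0 - fy;
      v += wx * wy * img(xi, yi);
    }
  }
  return v;
}

// Parallel-beam Radon transform of one square slice.
// p(t, theta) = sum_s img(t*cos - s*sin, t*sin + s*cos), unit (1 pixel) steps.
// Detector has as many elements as the slice is wide, centred on the slice centre.
// [[Rcpp::export]]
NumericMatrix radon_forward_cpp(NumericMatrix img, NumericVector angles_rad) {
  const int n = img.nrow();
  if (img.ncol() != n) stop("slice must be square");
  const int na = angles_rad.size();
  const double c = 0.5 * (n - 1);
  const int smax = (int)std::ceil(0.75 * n);
  NumericMatrix sino(n, na);
  for (int a = 0; a < na; ++a) {
    const double co = std::cos(angles_rad[a]), si = std::sin(angles_rad[a]);
    for (int it = 0; it < n; ++it) {
      const double t = it - c;
      double acc = 0.0;
      for (int is = -smax; is <= smax; ++is) {
        const double s = (double)is;
        const double x = t * co - s * si + c;
        const double y = t * si + s * co + c;
        acc += sample_bilinear(img, x, y);
      }
      sino(it, a) = acc;
    }
  }
  return sino;
}

// Back projection of a (ramp-)filtered sinogram onto an n x n slice, with
// linear interpolation along the detector and the pi/n_angles quadrature weight.
// [[Rcpp::export]]
NumericMatrix back_project_cpp(NumericMatrix fsino, NumericVector angles_rad, int n) {
  const int ndet = fsino.nrow();
  const int na = angles_rad.size();
  if ((int)angles_rad.size() != fsino.ncol()) stop("angle count mismatch");
  const double c = 0.5 * (n - 1);
  const double cdet = 0.5 * (ndet - 1);
  const double w = M_PI / na;
  NumericMatrix out(n, n);
  std::vector<double> cos_a(na), sin_a(na);
  for (int a = 0; a < na; ++a) { cos_a[a] = std::cos(angles_rad[a]); sin_a[a] = std::sin(angles_rad[a]); }
  for (int j = 0; j < n; ++j) {
    const double y = j - c;
    for (int i = 0; i < n; ++i) {
      const double x = i - c;
      double acc = 0.0;
      for (int a = 0; a < na; ++a) {
        const double t = x * cos_a[a] + y * sin_a[a] + cdet;
        if (t < 0.0 || t > ndet - 1) continue;
        const int t0 = (int)t;
        const double ft = t - t0;
        const double q = (t0 + 1 < ndet) ? (1.0 - ft) * fsino(t0, a) + ft * fsino(t0 + 1, a)
                                         : fsino(t0, a);
        acc += q;
      }
      out(i, j) = acc * w;
    }
  }
  return out;
}

// Correlation of a 3D array with a 1D kernel along one axis (0, 1 or 2),
// replicate (nearest) boundary handling:
//   out[i] = sum_{o=-r..r} ker[o + r] * in[clamp(i + o)]
// [[Rcpp::export]]
NumericVector conv_axis_cpp(NumericVector vol, NumericVector kernel, int axis) {
  IntegerVector dims = vol.attr("dim");
  if (dims.size() != 3) stop("vol must be a 3D array");
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int klen = kernel.size();
  if (klen % 2 == 0) stop("kernel length must be odd");
  const int r = klen / 2;
  NumericVector out(vol.size());
  out.attr("dim") = dims;
  const double* in = vol.begin();
  double* o = out.begin();
  const double* k = kernel.begin();
  const int dlen = (axis == 0) ? d1 : (axis == 1) ? d2 : d3;
  const long stride = (axis == 0) ? 1L : (axis == 1) ? (long)d1 : (long)d1 * d2;

  // iterate over all lines along `axis`
  const long nline = (long)d1 * d2 * d3 / dlen;
  std::vector<double> buf(dlen);
  for (long li = 0; li < nline; ++li) {
    // compute base offset of this line
    long base;
    if (axis == 0) {
      base = li * d1;
    } else if (axis == 1) {
      long z = li / d1, x = li % d1;
      base = x + z * (long)d1 * d2;
    } else {
      base = li; // x + y*d1 with li < d1*d2
    }
    for (int i = 0; i < dlen; ++i) buf[i] = in[base + (long)i * stride];
    for (int i = 0; i < dlen; ++i) {
      double acc = 0.0;
      for (int off = -r; off <= r; ++off) {
        int idx = i + off;
        if (idx < 0) idx = 0; else if (idx >= dlen) idx = dlen - 1;
        acc += k[off + r] * buf[idx];
      }
      o[base + (long)i * stride] = acc;
    }
  }
  return out;
}

// 26-connected component labelling of a 3D logical mask.
// Returns an integer array: 0 outside, components numbered from 1.
// [[Rcpp::export]]
IntegerVector label3d_cpp(LogicalVector mask) {
  IntegerVector dims = mask.attr("dim");
  if (dims.size() != 3) stop("mask must be a 3D array");
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const long n = (long)d1 * d2 * d3;
  IntegerVector labels(n);
  labels.attr("dim") = dims;
  int current = 0;
  std::vector<long> stack;
  stack.reserve(1024);
  for (long seed = 0; seed < n; ++seed) {
    if (!mask[seed] || labels[seed] != 0) continue;
    ++current;
    labels[seed] = current;
    stack.push_back(seed);
    while (!stack.empty()) {
      long v = stack.back();
      stack.pop_back();
      const int x = (int)(v % d1);
      const int y = (int)((v / d1) % d2);
      const int z = (int)(v / ((long)d1 * d2));
      for (int dz = -1; dz <= 1; ++dz) {
        const int zz = z + dz;
        if (zz < 0 || zz >= d3) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int yy = y + dy;
          if (yy < 0 || yy >= d2) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            const int xx = x + dx;
            if (xx < 0 || xx >= d1) continue;
            const long u = xx + (long)d1 * (yy + (long)d2 * zz);
            if (mask[u] && labels[u] == 0) {
              labels[u] = current;
              stack.push_back(u);
            }
          }
        }
      }
    }
  }
  labels.attr("n_components") = current;
  return labels;
}
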