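#include <Rcpp.h>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Connected-components labelling of a binary mask (rows = y, cols = x).
// Components are numbered 1..k in raster-scan order of their first
// (topmost, then leftmost) pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix labels(h, w);
  std::fill(labels.begin(), labels.end(), 0);
  const int dy8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dx8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dy4[4] = {-1, 0, 0, 1};
  const int dx4[4] = {0, -1, 1, 0};
  const int* dy = (connectivity == 8) ? dy8 : dy4;
  const int* dx = (connectivity == 8) ? dx8 : dx4;
  const int nn = connectivity;
  int next_label = 0;
  std::queue<std::pair<int, int> > q;
  for (int y = 0; y < h; ++y) {
    for (int x = 0; x < w; ++x) {
      if (!mask(y, x) || labels(y, x) != 0) continue;
      labels(y, x) = ++next_label;
      q.push(std::make_pair(y, x));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int k = 0; k < nn; ++k) {
          int ny = p.first + dy[k], nx = p.second + dx[k];
          if (ny < 0 || ny >= h || nx < 0 || nx >= w) continue;
          if (mask(ny, nx) && labels(ny, nx) == 0) {
            labels(ny, nx) = next_label;
            q.push(std::make_pair(ny, nx));
          }
        }
      }
    }
  }
  return labels;
}

static const double DT_INF = 1e20;

// Felzenszwalb-Huttenlocher 1D squared distance transform.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Exact Euclidean distance (in pixel units) from every pixel to the nearest
// seed pixel. Seeds get distance 0. Errors if there is no seed.
// [[Rcpp::export]]
NumericMatrix cpp_edt_seeded(const LogicalMatrix& seeds) {
  const int h = seeds.nrow(), w = seeds.ncol();
  bool any_seed = false;
  NumericMatrix sq(h, w);
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x) {
      sq(y, x) = seeds(y, x) ? 0.0 : DT_INF;
      if (seeds(y, x)) any_seed = true;
    }
  if (!any_seed) stop("seed mask is empty");
  int nmax = std::max(h, w);
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // columns
  for (int x = 0; x < w; ++x) {
    for (int y = 0; y < h; ++y) f[y] = sq(y, x);
    dt1d(f, d, h, v, z);
    for (int y = 0; y < h; ++y) sq(y, x) = d[y];
  }
  // rows
  for (int y = 0; y < h; ++y) {
    for (int x = 0; x < w; ++x) f[x] = sq(y, x);
    dt1d(f, d, w, v, z);
    for (int x = 0; x < w; ++x) sq(y, x) = d[x];
  }
  NumericMatrix out(h, w);
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x) out(y, x) = std::sqrt(sq(y, x));
  return out;
}

// Even-odd polygon rasterisation with the pixel-centre-inside rule. Pixel
// centres sit at integer coordinates (x = column, y = row, origin top-left).
// A centre is inside iff a ray cast towards +x crosses an odd number of
// edges strictly to its right; edges are taken half-open in y ([ymin, ymax))
// so shared vertices are not double-counted.
// [[Rcpp::export]]
LogicalMatrix cpp_rasterise_polygon(const NumericVector& xs,
                                    const NumericVector& ys,
                                    int height, int width) {
  const int n = xs.size();
  if (n < 3) stop("polygon needs at least 3 vertices");
  LogicalMatrix out(height, width);
  std::fill(out.begin(), out.end(), false);
  std::vector<double> cross;
  for (int y = 0; y < height; ++y) {
    cross.clear();
    for (int i = 0; i < n; ++i) {
      int j = (i + 1) % n;
      double y1 = ys[i], y2 = ys[j], x1 = xs[i], x2 = xs[j];
      if (y1 == y2) continue;
      double ymin = std::min(y1, y2), ymax = std::max(y1, y2);
      if (y < ymin || y >= ymax) continue;
      cross.push_back(x1 + (y - y1) * (x2 - x1) / (y2 - y1));
    }
    std::sort(cross.begin(), cross.end());
    for (size_t k = 0; k + 1 < cross.size(); k += 2) {
      int x0 = (int)std::ceil(cross[k]);
      int x1 = (int)std::ceil(cross[k + 1]) - 1;
      if (x0 < 0) x0 = 0;
      if (x1 >= width) x1 = width - 1;
      for (int x = x0; x <= x1; ++x) out(y, x) = true;
    }
  }
  return out;
}

// Separable convolution with a symmetric odd-length kernel; image borders
// are mirror-reflected (i < 0 -> -i - 1).
// [[Rcpp::export]]
NumericMatrix cpp_sep_convolve(const NumericMatrix& im,
                               const NumericVector& kernel) {
  const int h = im.nrow(), w = im.ncol(), kl = kernel.size();
  if (kl % 2 == 0) stop("kernel length must be odd");
  const int r = kl / 2;
  NumericMatrix tmp(h, w), out(h, w);
  // along rows (y direction)
  for (int x = 0; x < w; ++x) {
    for (int y = 0; y < h; ++y) {
      double acc = 0.0;
      for (int k = -r; k <= r; ++k) {
        int yy = y + k;
        if (yy < 0) yy = -yy - 1;
        if (yy >= h) yy = 2 * h - yy - 1;
        acc += im(yy, x) * kernel[k + r];
      }
      tmp(y, x) = acc;
    }
  }
  // along columns (x direction)
  for (int y = 0; y < h; ++y) {
    for (int x = 0; x < w; ++x) {
      double acc = 0.0;
      for (int k = -r; k <= r; ++k) {
        int xx = x + k;
        if (xx < 0) xx = -xx - 1;
        if (xx >= w) xx = 2 * w - xx - 1;
        acc += tmp(y, xx) * kernel[k + r];
      }
      out(y, x) = acc;
    }
  }
  return out;
}
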