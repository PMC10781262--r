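#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Z-buffer rasterizer over screen-space triangles.
//
// px, py: per-vertex continuous pixel coordinates (x in [0, width],
//         y in [0, height], y growing downward, pixel (r, c) has centre
//         (c + 0.5, r + 0.5) in 0-based indices).
// zc:     per-vertex camera-space z (negative in front of the camera, mm).
// faces:  1-based vertex index triples.
//
// Returns a height x width matrix of camera-space depths (positive mm,
// nearest surface per pixel); 0 marks background. Depth is interpolated
// perspective-correctly via 1/z.
// [[Rcpp::export]]
NumericMatrix rasterize_depth(NumericVector px, NumericVector py,
                              NumericVector zc, IntegerMatrix faces,
                              int width, int height) {
  NumericMatrix depth(height, width);
  const int nf = faces.nrow();
  for (int t = 0; t < nf; ++t) {
    const int i0 = faces(t, 0) - 1, i1 = faces(t, 1) - 1, i2 = faces(t, 2) - 1;
    const double z0 = zc[i0], z1 = zc[i1], z2 = zc[i2];
    // skip triangles touching or behind the camera plane
    if (z0 >= -1e-6 || z1 >= -1e-6 || z2 >= -1e-6) continue;
    const double x0 = px[i0], y0 = py[i0];
    const double x1 = px[i1], y1 = py[i1];
    const double x2 = px[i2], y2 = py[i2];
    const double minx = std::min(x0, std::min(x1, x2));
    const double maxx = std::max(x0, std::max(x1, x2));
    const double miny = std::min(y0, std::min(y1, y2));
    const double maxy = std::max(y0, std::max(y1, y2));
    int c0 = std::max(0, (int)std::floor(minx - 0.5));
    int c1 = std::min(width - 1, (int)std::ceil(maxx - 0.5));
    int r0 = std::max(0, (int)std::floor(miny - 0.5));
    int r1 = std::min(height - 1, (int)std::ceil(maxy - 0.5));
    if (c0 > c1 || r0 > r1) continue;
    const double area = (x1 - x0) * (y2 - y0) - (x2 - x0) * (y1 - y0);
    if (std::fabs(area) < 1e-12) continue;
    const double inv0 = 1.0 / z0, inv1 = 1.0 / z1, inv2 = 1.0 / z2;
    for (int r = r0; r <= r1; ++r) {
      const double pyc = r + 0.5;
      for (int c = c0; c <= c1; ++c) {
        const double pxc = c + 0.5;
        double w0 = ((x1 - pxc) * (y2 - pyc) - (x2 - pxc) * (y1 - pyc)) / area;
        double w1 = ((x2 - pxc) * (y0 - pyc) - (x0 - pxc) * (y2 - pyc)) / area;
        double w2 = 1.0 - w0 - w1;
        const double eps = -1e-9;
        if (w0 < eps || w1 < eps || w2 < eps) continue;
        const double invz = w0 * inv0 + w1 * inv1 + w2 * inv2;  // negative
        if (invz >= 0) continue;
        const double d = -1.0 / invz;  // positive mm
        const double cur = depth(r, c);
        if (cur == 0.0 || d < cur) depth(r, c) = d;
      }
    }
  }
  return depth;
}
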