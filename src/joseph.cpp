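#include <Rcpp.h>
using namespace Rcpp;

// Joseph-style ray-driven projector with linear interpolation.
//
// Geometry: square N x N image, center at pixel ((N-1)/2, (N-1)/2);
// pixel (i, j) sits at (x, y) = (j - c, i - c).  A ray for angle theta and
// detector coordinate t = s - rotation_center is the line
//     x cos(theta) + y sin(theta) = t .
// The ray is driven along the axis most aligned with its direction: one
// sample per crossed row (or column), linearly interpolated between the two
// neighbouring pixels of the other axis, weighted by the path length
// 1 / max(|cos|, |sin|) per step.  Out-of-support samples contribute zero.
// Along the driving axis the interpolated coordinate advances by a constant
// slope, so the inner loop is purely incremental.
//
// The backprojector scatters with the same weights in the same loop order,
// so it is the exact transpose of the projector up to rounding.

// [[Rcpp::export]]
NumericMatrix joseph_project_cpp(const NumericMatrix& img,
                                 const NumericVector& angles,
                                 const int nbins,
                                 const double center) {
  const int n = img.nrow();
  const int na = angles.size();
  NumericMatrix sino(na, nbins);
  const double c = (n - 1) / 2.0;
  const double* im = img.begin();

  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles[a]);
    const double st = std::sin(angles[a]);
    const bool row_drive = std::fabs(ct) >= std::fabs(st);
    const double maj = row_drive ? ct : st;
    const double dl = 1.0 / std::fabs(maj);
    const double slope = row_drive ? -st / ct : -ct / st;
    for (int s = 0; s < nbins; ++s) {
      const double t = s - center;
      // interpolated coordinate at driving index 0
      double p = (t - (0 - c) * (row_drive ? st : ct)) / maj + c;
      double acc = 0.0;
      if (row_drive) {
        for (int i = 0; i < n; ++i, p += slope) {
          const int j0 = (int)std::floor(p);
          const double w = p - j0;
          if (j0 >= 0 && j0 < n)         acc += (1.0 - w) * im[i + (size_t)n * j0];
          if (j0 + 1 >= 0 && j0 + 1 < n) acc += w * im[i + (size_t)n * (j0 + 1)];
        }
      } else {
        for (int j = 0; j < n; ++j, p += slope) {
          const int i0 = (int)std::floor(p);
          const double w = p - i0;
          const double* col = im + (size_t)n * j;
          if (i0 >= 0 && i0 < n)         acc += (1.0 - w) * col[i0];
          if (i0 + 1 >= 0 && i0 + 1 < n) acc += w * col[i0 + 1];
        }
      }
      sino(a, s) = acc * dl;
    }
  }
  return sino;
}

// [[Rcpp::export]]
NumericMatrix joseph_backproject_cpp(const NumericMatrix& sino,
                                     const NumericVector& angles,
                                     const int n,
                                     const double center) {
  const int na = angles.size();
  const int nbins = sino.ncol();
  NumericMatrix img(n, n);
  const double c = (n - 1) / 2.0;
  double* im = img.begin();

  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles[a]);
    const double st = std::sin(angles[a]);
    const bool row_drive = std::fabs(ct) >= std::fabs(st);
    const double maj = row_drive ? ct : st;
    const double dl = 1.0 / std::fabs(maj);
    const double slope = row_drive ? -st / ct : -ct / st;
    for (int s = 0; s < nbins; ++s) {
      const double t = s - center;
      double p = (t - (0 - c) * (row_drive ? st : ct)) / maj + c;
      const double v = sino(a, s) * dl;
      if (v == 0.0) continue;
      if (row_drive) {
        for (int i = 0; i < n; ++i, p += slope) {
          const int j0 = (int)std::floor(p);
          const double w = p - j0;
          if (j0 >= 0 && j0 < n)         im[i + (size_t)n * j0] += (1.0 - w) * v;
          if (j0 + 1 >= 0 && j0 + 1 < n) im[i + (size_t)n * (j0 + 1)] += w * v;
        }
      } else {
        for (int j = 0; j < n; ++j, p += slope) {
          const int i0 = (int)std::floor(p);
          const double w = p - i0;
          double* col = im + (size_t)n * j;
          if (i0 >= 0 && i0 < n)         col[i0] += (1.0 - w) * v;
          if (i0 + 1 >= 0 && i0 + 1 < n) col[i0 + 1] += w * v;
        }
      }
    }
  }
  return img;
}
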