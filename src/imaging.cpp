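#include <Rcpp.h>
using namespace Rcpp;

// Trilinear resampling of a 3-D volume under an affine (rigid) map.
// For each output voxel with 0-based index (i,j,k) the world position is
//   x_out = origin + idx * spacing
// and the source world position is x_src = M * x_out + b (M,b encode the
// inverse of the forward rigid transform). Values outside the source grid
// get `fill`.
// [[Rcpp::export]]
NumericVector resample_trilinear_cpp(NumericVector vox, IntegerVector dim,
                                     NumericVector spacing, NumericVector origin,
                                     NumericMatrix M, NumericVector b,
                                     double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2);
  const double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2);
  const double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2);
  const double b0 = b[0], b1 = b[1], b2 = b[2];
  const double *v = vox.begin();
  double *o = out.begin();

  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    const double wz = oz + k * sz;
    for (int j = 0; j < ny; ++j) {
      const double wy = oy + j * sy;
      for (int i = 0; i < nx; ++i, ++idx) {
        const double wx = ox + i * sx;
        // source world position
        const double px = m00*wx + m01*wy + m02*wz + b0;
        const double py = m10*wx + m11*wy + m12*wz + b1;
        const double pz = m20*wx + m21*wy + m22*wz + b2;
        // continuous 0-based source index; snap near-integer indices so
        // grid-aligned transforms (identity, whole-voxel shifts, axis
        // flips) reproduce source values exactly
        double fx = (px - ox) / sx;
        double fy = (py - oy) / sy;
        double fz = (pz - oz) / sz;
        if (std::fabs(fx - std::round(fx)) < 1e-7) fx = std::round(fx);
        if (std::fabs(fy - std::round(fy)) < 1e-7) fy = std::round(fy);
        if (std::fabs(fz - std::round(fz)) < 1e-7) fz = std::round(fz);
        const int x0 = (int)std::floor(fx);
        const int y0 = (int)std::floor(fy);
        const int z0 = (int)std::floor(fz);
        if (x0 < -1 || x0 > nx - 1 || y0 < -1 || y0 > ny - 1 ||
            z0 < -1 || z0 > nz - 1) { o[idx] = fill; continue; }
        const double dx = fx - x0, dy = fy - y0, dz = fz - z0;
        double acc = 0.0;
        for (int c = 0; c < 8; ++c) {
          const int xi = x0 + (c & 1);
          const int yi = y0 + ((c >> 1) & 1);
          const int zi = z0 + ((c >> 2) & 1);
          const double w = ((c & 1) ? dx : 1.0 - dx) *
                           (((c >> 1) & 1) ? dy : 1.0 - dy) *
                           (((c >> 2) & 1) ? dz : 1.0 - dz);
          double val;
          if (xi < 0 || xi >= nx || yi < 0 || yi >= ny || zi < 0 || zi >= nz)
            val = fill;
          else
            val = v[(R_xlen_t)zi * nx * ny + (R_xlen_t)yi * nx + xi];
          acc += w * val;
        }
        o[idx] = acc;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

static inline bool on_segment(double px, double py, double x1, double y1,
                              double x2, double y2, double tol) {
  const double vx = x2 - x1, vy = y2 - y1;
  const double wx = px - x1, wy = py - y1;
  const double len2 = vx*vx + vy*vy;
  double t = len2 > 0 ? (wx*vx + wy*vy) / len2 : 0.0;
  if (t < 0) t = 0; else if (t > 1) t = 1;
  const double dx = wx - t*vx, dy = wy - t*vy;
  return dx*dx + dy*dy <= tol*tol;
}

// Rasterize a simple closed polygon onto an nx-by-ny pixel grid whose pixel
// centres sit at integer coordinates (1..nx, 1..ny). A pixel belongs to the
// region iff its centre is strictly inside the polygon (even-odd rule) or
// lies on the polygon boundary (within `tol`). The polygon closes implicitly
// from the last vertex back to the first.
// [[Rcpp::export]]
LogicalMatrix fill_polygon_cpp(int nx, int ny, NumericVector px,
                               NumericVector py, double tol = 1e-9) {
  const int nv = px.size();
  LogicalMatrix out(nx, ny);
  if (nv == 0) return out;

  double xmin = px[0], xmax = px[0], ymin = py[0], ymax = py[0];
  for (int v = 1; v < nv; ++v) {
    xmin = std::min(xmin, px[v]); xmax = std::max(xmax, px[v]);
    ymin = std::min(ymin, py[v]); ymax = std::max(ymax, py[v]);
  }
  const int i0 = std::max(1, (int)std::floor(xmin - 1));
  const int i1 = std::min(nx, (int)std::ceil(xmax + 1));
  const int j0 = std::max(1, (int)std::floor(ymin - 1));
  const int j1 = std::min(ny, (int)std::ceil(ymax + 1));

  for (int j = j0; j <= j1; ++j) {
    const double cy = j;
    for (int i = i0; i <= i1; ++i) {
      const double cx = i;
      bool inside = false, boundary = false;
      for (int v = 0; v < nv; ++v) {
        const int w = (v + 1) % nv;
        const double x1 = px[v], y1 = py[v], x2 = px[w], y2 = py[w];
        if (on_segment(cx, cy, x1, y1, x2, y2, tol)) { boundary = true; break; }
        if ((y1 > cy) != (y2 > cy)) {
          const double xint = x1 + (cy - y1) / (y2 - y1) * (x2 - x1);
          if (cx < xint) inside = !inside;
        }
      }
      out(i - 1, j - 1) = boundary || inside;
    }
  }
  return out;
}
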