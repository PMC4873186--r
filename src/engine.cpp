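#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif
using namespace Rcpp;

// Paint anti-aliased circular dots into an image (in place).
// img: ny x nx matrix (column-major), luminance in [-1, 1], background 0.
// cx, cy: dot centres in pixel units (1-based, continuous); pol: +1 / -1.
// Coverage-weighted edge intensity: cov = clamp(r + 0.5 - dist, 0, 1),
// composited over the existing value so later dots occlude earlier ones.
static void paint_dots(NumericMatrix img,
                       const double* cx, const double* cy,
                       const double* pol, int n, double r) {
  const int ny = img.nrow(), nx = img.ncol();
  for (int k = 0; k < n; ++k) {
    const double x = cx[k], y = cy[k], p = pol[k];
    int c0 = (int)std::floor(x - r - 1.0), c1 = (int)std::ceil(x + r + 1.0);
    int r0 = (int)std::floor(y - r - 1.0), r1 = (int)std::ceil(y + r + 1.0);
    if (c0 < 1) c0 = 1; if (c1 > nx) c1 = nx;
    if (r0 < 1) r0 = 1; if (r1 > ny) r1 = ny;
    for (int c = c0; c <= c1; ++c) {
      const double dx = c - x;
      double* col = &img(0, c - 1);
      for (int rr = r0; rr <= r1; ++rr) {
        const double dy = rr - y;
        const double d = std::sqrt(dx * dx + dy * dy);
        double cov = r + 0.5 - d;
        if (cov <= 0.0) continue;
        if (cov > 1.0) cov = 1.0;
        col[rr - 1] = (1.0 - cov) * col[rr - 1] + cov * p;
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_paint_dots")]]
NumericMatrix cpp_paint_dots(int ny, int nx,
                             NumericVector cx, NumericVector cy,
                             NumericVector pol, double r_px) {
  NumericMatrix img(ny, nx);
  paint_dots(img, cx.begin(), cy.begin(), pol.begin(), cx.size(), r_px);
  return img;
}

// Responses of one separable quadrature patch on an image:
// z[c] = sum_r gy[r] * img[row0 + r, col0 + c], then the two inner
// products z . gx1 and z . gx2 (the quadrature pair shares the envelope).
static inline void patch_response(const NumericMatrix& img,
                                  int row0, int nrow, int col0, int ncol,
                                  const double* gy, const double* gx1,
                                  const double* gx2,
                                  double* zbuf, double& v1, double& v2) {
  const int lda = img.nrow(), one = 1;
  const double d_one = 1.0, d_zero = 0.0;
  // z = t(img[rows, cols]) %*% gy
  F77_CALL(dgemv)("T", &nrow, &ncol, &d_one, &img(row0, col0), &lda,
                  gy, &one, &d_zero, zbuf, &one FCONE);
  v1 = F77_CALL(ddot)(&ncol, zbuf, &one, gx1, &one);
  v2 = F77_CALL(ddot)(&ncol, zbuf, &one, gx2, &one);
}

// Per-frame monocular inner products for a bank of separable quadrature
// Gabor patches.
//
// Dots for all frames of a trial are passed concatenated, with frame_ptr
// (0-based, length n_frames + 1) delimiting frames; left and right eye
// have separate dot arrays (uncorrelated stimuli carry independent dots).
//
// The bank holds one patch per (unit, eye): 0-based patch bounds
// (row0/nrow/col0/ncol), eye (0 = left, 1 = right), the shared vertical
// envelope gy and the two quadrature horizontal profiles gx1/gx2
// (concatenated, delimited by gy_ptr / gx_ptr).  Patch 2u is unit u's
// left-eye patch and 2u+1 its right-eye patch.
//
// Returns an n_frames x (4 * n_units) matrix with unit u's responses in
// columns 4u+1 .. 4u+4 (1-based) ordered (s1L, s1R, s2L, s2R).
// [[Rcpp::export(name = ".cpp_frame_responses")]]
NumericMatrix cpp_frame_responses(int ny, int nx,
                                  NumericVector lx, NumericVector ly,
                                  NumericVector lpol,
                                  NumericVector rx, NumericVector ry,
                                  NumericVector rpol,
                                  IntegerVector frame_ptr, double r_px,
                                  IntegerVector row0, IntegerVector nrowv,
                                  IntegerVector col0, IntegerVector ncolv,
                                  IntegerVector eye,
                                  NumericVector gy, IntegerVector gy_ptr,
                                  NumericVector gx1, NumericVector gx2,
                                  IntegerVector gx_ptr) {
  const int n_frames = frame_ptr.size() - 1;
  const int n_patch = row0.size();
  const int n_units = n_patch / 2;
  NumericMatrix out(n_frames, 4 * n_units);
  NumericMatrix imgL(ny, nx), imgR(ny, nx);
  std::vector<double> zbuf((size_t)nx + 1);

  for (int f = 0; f < n_frames; ++f) {
    std::fill(imgL.begin(), imgL.end(), 0.0);
    std::fill(imgR.begin(), imgR.end(), 0.0);
    const int a = frame_ptr[f], n = frame_ptr[f + 1] - frame_ptr[f];
    paint_dots(imgL, &lx[a], &ly[a], &lpol[a], n, r_px);
    paint_dots(imgR, &rx[a], &ry[a], &rpol[a], n, r_px);
    for (int g = 0; g < n_patch; ++g) {
      const NumericMatrix& img = eye[g] == 0 ? imgL : imgR;
      double v1, v2;
      patch_response(img, row0[g], nrowv[g], col0[g], ncolv[g],
                     &gy[gy_ptr[g]], &gx1[gx_ptr[g]], &gx2[gx_ptr[g]],
                     zbuf.data(), v1, v2);
      const int u = g / 2, e = g % 2;
      out(f, 4 * u + e) = v1;
      out(f, 4 * u + 2 + e) = v2;
    }
  }
  return out;
}
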