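#include <Rcpp.h>
using namespace Rcpp;

// Trilinear / nearest-neighbour sampling of a 3D volume at continuous
// 0-based voxel coordinates. mode: 0 = linear, 1 = nearest.
// Outside the grid: NA if na_outside, else `fill`.
// [[Rcpp::export]]
NumericVector c_interp3(NumericVector vol, IntegerVector dims,
                        NumericMatrix coords, int mode, double fill,
                        bool na_outside) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = coords.nrow();
  NumericVector out(n);
  const double *v = vol.begin();
  for (R_xlen_t r = 0; r < n; ++r) {
    double x = coords(r, 0), y = coords(r, 1), z = coords(r, 2);
    if (!R_finite(x) || !R_finite(y) || !R_finite(z)) {
      out[r] = na_outside ? NA_REAL : fill;
      continue;
    }
    if (mode == 1) {
      int i = (int)std::floor(x + 0.5), j = (int)std::floor(y + 0.5),
          k = (int)std::floor(z + 0.5);
      if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) {
        out[r] = na_outside ? NA_REAL : fill;
      } else {
        out[r] = v[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
      }
      continue;
    }
    if (x < 0.0 || y < 0.0 || z < 0.0 || x > nx - 1.0 || y > ny - 1.0 ||
        z > nz - 1.0) {
      out[r] = na_outside ? NA_REAL : fill;
      continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y),
        k0 = (int)std::floor(z);
    if (i0 == nx - 1) i0--;
    if (j0 == ny - 1) j0--;
    if (k0 == nz - 1) k0--;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    double acc = 0.0;
    for (int dk = 0; dk < 2; ++dk)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) *
                     (dk ? fz : 1 - fz);
          acc += w * v[(i0 + di) +
                       (R_xlen_t)nx * ((j0 + dj) + (R_xlen_t)ny * (k0 + dk))];
        }
    out[r] = acc;
  }
  return out;
}

static inline void bspline_w(double t, double *w) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = (1 - 3 * t + 3 * t2 - t3) / 6.0;
  w[1] = (4 - 6 * t2 + 3 * t3) / 6.0;
  w[2] = (1 + 3 * t + 3 * t2 - 3 * t3) / 6.0;
  w[3] = t3 / 6.0;
}

static inline void bspline_dw(double t, double *w) {
  double t2 = t * t;
  w[0] = (-3 + 6 * t - 3 * t2) / 6.0;
  w[1] = (-12 * t + 9 * t2) / 6.0;
  w[2] = (3 + 6 * t - 9 * t2) / 6.0;
  w[3] = 3 * t2 / 6.0;
}

// Dense displacement (mm, world axes) of a cubic B-spline FFD evaluated at
// every voxel of the reference grid. coef has dim (ncx, ncy, ncz, 3);
// coefficient index 0 along an axis sits at voxel position -cps.
// Returns an N x 3 matrix in column-major grid order.
// [[Rcpp::export]]
NumericMatrix c_ffd_dense(NumericVector coef, IntegerVector cdims,
                          IntegerVector dims, double cps) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int cx = cdims[0], cy = cdims[1], cz = cdims[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  const R_xlen_t comp = (R_xlen_t)cx * cy * cz;
  NumericMatrix out(N, 3);
  const double *c = coef.begin();
  double wx[4], wy[4], wz[4];
  R_xlen_t r = 0;
  for (int k = 0; k < nz; ++k) {
    double sz = k / cps; int kz = (int)std::floor(sz);
    bspline_w(sz - kz, wz);
    for (int j = 0; j < ny; ++j) {
      double sy = j / cps; int jy = (int)std::floor(sy);
      bspline_w(sy - jy, wy);
      for (int i = 0; i < nx; ++i, ++r) {
        double sx = i / cps; int ix = (int)std::floor(sx);
        bspline_w(sx - ix, wx);
        double u0 = 0, u1 = 0, u2 = 0;
        for (int c3 = 0; c3 < 4; ++c3) {
          int zz = kz + c3; if (zz < 0 || zz >= cz) continue;
          for (int c2 = 0; c2 < 4; ++c2) {
            int yy = jy + c2; if (yy < 0 || yy >= cy) continue;
            double wyz = wy[c2] * wz[c3];
            R_xlen_t base = (R_xlen_t)cx * (yy + (R_xlen_t)cy * zz);
            for (int c1 = 0; c1 < 4; ++c1) {
              int xx = ix + c1; if (xx < 0 || xx >= cx) continue;
              double w = wx[c1] * wyz;
              R_xlen_t idx = xx + base;
              u0 += w * c[idx];
              u1 += w * c[idx + comp];
              u2 += w * c[idx + 2 * comp];
            }
          }
        }
        out(r, 0) = u0; out(r, 1) = u1; out(r, 2) = u2;
      }
    }
  }
  return out;
}

// Spatial derivative of the FFD displacement with respect to voxel index:
// returns N x 9 (du_d / dvox_a, column order d1a1 d2a1 d3a1 d1a2 ...),
// i.e. columns are the Jacobian matrix in column-major 3x3 layout.
// [[Rcpp::export]]
NumericMatrix c_ffd_jac(NumericVector coef, IntegerVector cdims,
                        IntegerVector dims, double cps) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int cx = cdims[0], cy = cdims[1], cz = cdims[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  const R_xlen_t comp = (R_xlen_t)cx * cy * cz;
  NumericMatrix out(N, 9);
  const double *c = coef.begin();
  double wx[4], wy[4], wz[4], dx[4], dy[4], dz[4];
  R_xlen_t r = 0;
  for (int k = 0; k < nz; ++k) {
    double sz = k / cps; int kz = (int)std::floor(sz);
    bspline_w(sz - kz, wz); bspline_dw(sz - kz, dz);
    for (int j = 0; j < ny; ++j) {
      double sy = j / cps; int jy = (int)std::floor(sy);
      bspline_w(sy - jy, wy); bspline_dw(sy - jy, dy);
      for (int i = 0; i < nx; ++i, ++r) {
        double sx = i / cps; int ix = (int)std::floor(sx);
        bspline_w(sx - ix, wx); bspline_dw(sx - ix, dx);
        double J[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0};
        for (int c3 = 0; c3 < 4; ++c3) {
          int zz = kz + c3; if (zz < 0 || zz >= cz) continue;
          for (int c2 = 0; c2 < 4; ++c2) {
            int yy = jy + c2; if (yy < 0 || yy >= cy) continue;
            R_xlen_t base = (R_xlen_t)cx * (yy + (R_xlen_t)cy * zz);
            for (int c1 = 0; c1 < 4; ++c1) {
              int xx = ix + c1; if (xx < 0 || xx >= cx) continue;
              R_xlen_t idx = xx + base;
              double w1 = dx[c1] * wy[c2] * wz[c3] / cps;
              double w2 = wx[c1] * dy[c2] * wz[c3] / cps;
              double w3 = wx[c1] * wy[c2] * dz[c3] / cps;
              for (int d = 0; d < 3; ++d) {
                double cv = c[idx + d * comp];
                J[d]     += w1 * cv;
                J[3 + d] += w2 * cv;
                J[6 + d] += w3 * cv;
              }
            }
          }
        }
        for (int q = 0; q < 9; ++q) out(r, q) = J[q];
      }
    }
  }
  return out;
}

static inline double beta3(double t) {
  double a = std::fabs(t);
  if (a >= 2.0) return 0.0;
  if (a < 1.0) return 2.0 / 3.0 - a * a + a * a * a / 2.0;
  double b = 2.0 - a;
  return b * b * b / 6.0;
}

static inline double dbeta3(double t) {
  double a = std::fabs(t), s = (t < 0) ? -1.0 : 1.0;
  if (a >= 2.0) return 0.0;
  if (a < 1.0) return s * (-2.0 * a + 1.5 * a * a);
  double b = 2.0 - a;
  return s * (-0.5 * b * b);
}

// Normalized mutual information (Studholme: (Hf+Hm)/Hj) between a fixed
// image and a moving image warped by affine-then-FFD, with the analytic
// gradient with respect to the FFD control-point displacements.
//
// fixb: fixed intensities pre-scaled to [0, nbins-1] (NaN = exclude voxel).
// movb: moving intensities pre-scaled to [1, nbins-2].
// Af: 4x4 voxel(fixed) -> world (mm).
// G:  4x4 world (after adding FFD displacement) -> voxel(moving); this
//     composes the linear pre-alignment with the moving image's affine.
// Sampling point: q = G * (Af * v + u(v)), u from the FFD.
// [[Rcpp::export]]
List c_nmi_grad(NumericVector fixb, IntegerVector fdims, NumericVector movb,
                IntegerVector mdims, NumericMatrix Af, NumericMatrix G,
                NumericVector coef, IntegerVector cdims, double cps,
                int nbins, bool want_grad) {
  const int nx = fdims[0], ny = fdims[1], nz = fdims[2];
  const int mx = mdims[0], my = mdims[1], mz = mdims[2];
  const int cx = cdims[0], cy = cdims[1], cz = cdims[2];
  const R_xlen_t comp = (R_xlen_t)cx * cy * cz;
  const double *mv = movb.begin();
  const double *fv = fixb.begin();
  const double *cf = coef.begin();

  std::vector<double> hist((size_t)nbins * nbins, 0.0);
  double wx[4], wy[4], wz[4];

  // pass 1: joint histogram
  double count = 0.0;
  R_xlen_t r = 0;
  for (int k = 0; k < nz; ++k) {
    double sz = k / cps; int kz = (int)std::floor(sz);
    bspline_w(sz - kz, wz);
    for (int j = 0; j < ny; ++j) {
      double sy = j / cps; int jy = (int)std::floor(sy);
      bspline_w(sy - jy, wy);
      for (int i = 0; i < nx; ++i, ++r) {
        double f = fv[r];
        if (!R_finite(f)) continue;
        double sx = i / cps; int ix = (int)std::floor(sx);
        bspline_w(sx - ix, wx);
        double u0 = 0, u1 = 0, u2 = 0;
        for (int c3 = 0; c3 < 4; ++c3) {
          int zz = kz + c3; if (zz < 0 || zz >= cz) continue;
          for (int c2 = 0; c2 < 4; ++c2) {
            int yy = jy + c2; if (yy < 0 || yy >= cy) continue;
            double wyz = wy[c2] * wz[c3];
            R_xlen_t base = (R_xlen_t)cx * (yy + (R_xlen_t)cy * zz);
            for (int c1 = 0; c1 < 4; ++c1) {
              int xx = ix + c1; if (xx < 0 || xx >= cx) continue;
              double w = wx[c1] * wyz;
              R_xlen_t idx = xx + base;
              u0 += w * cf[idx];
              u1 += w * cf[idx + comp];
              u2 += w * cf[idx + 2 * comp];
            }
          }
        }
        double X = Af(0, 0) * i + Af(0, 1) * j + Af(0, 2) * k + Af(0, 3) + u0;
        double Y = Af(1, 0) * i + Af(1, 1) * j + Af(1, 2) * k + Af(1, 3) + u1;
        double Z = Af(2, 0) * i + Af(2, 1) * j + Af(2, 2) * k + Af(2, 3) + u2;
        double qx = G(0, 0) * X + G(0, 1) * Y + G(0, 2) * Z + G(0, 3);
        double qy = G(1, 0) * X + G(1, 1) * Y + G(1, 2) * Z + G(1, 3);
        double qz = G(2, 0) * X + G(2, 1) * Y + G(2, 2) * Z + G(2, 3);
        if (qx < 0 || qy < 0 || qz < 0 || qx > mx - 1.000001 ||
            qy > my - 1.000001 || qz > mz - 1.000001)
          continue;
        int i0 = (int)std::floor(qx), j0 = (int)std::floor(qy),
            k0 = (int)std::floor(qz);
        double fx = qx - i0, fy = qy - j0, fz = qz - k0;
        double m = 0.0;
        for (int dk = 0; dk < 2; ++dk)
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di)
              m += (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) *
                   (dk ? fz : 1 - fz) *
                   mv[(i0 + di) +
                      (R_xlen_t)mx * ((j0 + dj) + (R_xlen_t)my * (k0 + dk))];
        int jf = (int)std::floor(f);
        if (jf > nbins - 2) jf = nbins - 2;
        if (jf < 0) jf = 0;
        double wf = f - jf;
        int jm0 = (int)std::floor(m);
        for (int b = jm0 - 1; b <= jm0 + 2; ++b) {
          if (b < 0 || b >= nbins) continue;
          double bm = beta3(m - b);
          hist[(size_t)jf * nbins + b] += (1 - wf) * bm;
          hist[(size_t)(jf + 1) * nbins + b] += wf * bm;
        }
        count += 1.0;
      }
    }
  }

  if (count < 10.0)
    return List::create(_["value"] = NA_REAL, _["n"] = count,
                        _["grad"] = R_NilValue);

  std::vector<double> pf(nbins, 0.0), pm(nbins, 0.0);
  for (int a = 0; a < nbins; ++a)
    for (int b = 0; b < nbins; ++b) {
      double p = hist[(size_t)a * nbins + b] / count;
      hist[(size_t)a * nbins + b] = p;
      pf[a] += p;
      pm[b] += p;
    }
  double Hf = 0, Hm = 0, Hj = 0;
  for (int a = 0; a < nbins; ++a) if (pf[a] > 0) Hf -= pf[a] * std::log(pf[a]);
  for (int b = 0; b < nbins; ++b) if (pm[b] > 0) Hm -= pm[b] * std::log(pm[b]);
  for (size_t t = 0; t < hist.size(); ++t)
    if (hist[t] > 0) Hj -= hist[t] * std::log(hist[t]);
  double S = (Hf + Hm) / Hj;

  if (!want_grad)
    return List::create(_["value"] = S, _["n"] = count,
                        _["grad"] = R_NilValue);

  // dS/dp(a,b) table
  std::vector<double> dSdp((size_t)nbins * nbins, 0.0);
  for (int a = 0; a < nbins; ++a)
    for (int b = 0; b < nbins; ++b) {
      double pj = hist[(size_t)a * nbins + b];
      if (pj <= 0 || pf[a] <= 0 || pm[b] <= 0) continue;
      dSdp[(size_t)a * nbins + b] =
          (-(2.0 + std::log(pf[a]) + std::log(pm[b])) +
           S * (1.0 + std::log(pj))) / Hj;
    }

  NumericVector grad(coef.size());
  double *g = grad.begin();
  // pass 2: per-voxel alpha and scatter onto control points
  r = 0;
  for (int k = 0; k < nz; ++k) {
    double sz = k / cps; int kz = (int)std::floor(sz);
    bspline_w(sz - kz, wz);
    for (int j = 0; j < ny; ++j) {
      double sy = j / cps; int jy = (int)std::floor(sy);
      bspline_w(sy - jy, wy);
      for (int i = 0; i < nx; ++i, ++r) {
        double f = fv[r];
        if (!R_finite(f)) continue;
        double sx = i / cps; int ix = (int)std::floor(sx);
        bspline_w(sx - ix, wx);
        double u0 = 0, u1 = 0, u2 = 0;
        for (int c3 = 0; c3 < 4; ++c3) {
          int zz = kz + c3; if (zz < 0 || zz >= cz) continue;
          for (int c2 = 0; c2 < 4; ++c2) {
            int yy = jy + c2; if (yy < 0 || yy >= cy) continue;
            double wyz = wy[c2] * wz[c3];
            R_xlen_t base = (R_xlen_t)cx * (yy + (R_xlen_t)cy * zz);
            for (int c1 = 0; c1 < 4; ++c1) {
              int xx = ix + c1; if (xx < 0 || xx >= cx) continue;
              double w = wx[c1] * wyz;
              R_xlen_t idx = xx + base;
              u0 += w * cf[idx];
              u1 += w * cf[idx + comp];
              u2 += w * cf[idx + 2 * comp];
            }
          }
        }
        double X = Af(0, 0) * i + Af(0, 1) * j + Af(0, 2) * k + Af(0, 3) + u0;
        double Y = Af(1, 0) * i + Af(1, 1) * j + Af(1, 2) * k + Af(1, 3) + u1;
        double Z = Af(2, 0) * i + Af(2, 1) * j + Af(2, 2) * k + Af(2, 3) + u2;
        double qx = G(0, 0) * X + G(0, 1) * Y + G(0, 2) * Z + G(0, 3);
        double qy = G(1, 0) * X + G(1, 1) * Y + G(1, 2) * Z + G(1, 3);
        double qz = G(2, 0) * X + G(2, 1) * Y + G(2, 2) * Z + G(2, 3);
        if (qx < 0 || qy < 0 || qz < 0 || qx > mx - 1.000001 ||
            qy > my - 1.000001 || qz > mz - 1.000001)
          continue;
        int i0 = (int)std::floor(qx), j0 = (int)std::floor(qy),
            k0 = (int)std::floor(qz);
        double fx = qx - i0, fy = qy - j0, fz = qz - k0;
        double m = 0.0, gx = 0.0, gy = 0.0, gz = 0.0;
        for (int dk = 0; dk < 2; ++dk)
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              double val =
                  mv[(i0 + di) +
                     (R_xlen_t)mx * ((j0 + dj) + (R_xlen_t)my * (k0 + dk))];
              double wxi = di ? fx : 1 - fx, wyj = dj ? fy : 1 - fy,
                     wzk = dk ? fz : 1 - fz;
              m += wxi * wyj * wzk * val;
              gx += (di ? 1.0 : -1.0) * wyj * wzk * val;
              gy += (dj ? 1.0 : -1.0) * wxi * wzk * val;
              gz += (dk ? 1.0 : -1.0) * wxi * wyj * val;
            }
        int jf = (int)std::floor(f);
        if (jf > nbins - 2) jf = nbins - 2;
        if (jf < 0) jf = 0;
        double wf = f - jf;
        int jm0 = (int)std::floor(m);
        double alpha = 0.0;
        for (int b = jm0 - 1; b <= jm0 + 2; ++b) {
          if (b < 0 || b >= nbins) continue;
          double db = dbeta3(m - b);
          alpha += db * ((1 - wf) * dSdp[(size_t)jf * nbins + b] +
                         wf * dSdp[(size_t)(jf + 1) * nbins + b]);
        }
        alpha /= count;
        if (alpha == 0.0) continue;
        // dm/du_d = grad_q m . G[,d]
        double h0 = gx * G(0, 0) + gy * G(1, 0) + gz * G(2, 0);
        double h1 = gx * G(0, 1) + gy * G(1, 1) + gz * G(2, 1);
        double h2 = gx * G(0, 2) + gy * G(1, 2) + gz * G(2, 2);
        h0 *= alpha; h1 *= alpha; h2 *= alpha;
        for (int c3 = 0; c3 < 4; ++c3) {
          int zz = kz + c3; if (zz < 0 || zz >= cz) continue;
          for (int c2 = 0; c2 < 4; ++c2) {
            int yy = jy + c2; if (yy < 0 || yy >= cy) continue;
            double wyz = wy[c2] * wz[c3];
            R_xlen_t base = (R_xlen_t)cx * (yy + (R_xlen_t)cy * zz);
            for (int c1 = 0; c1 < 4; ++c1) {
              int xx = ix + c1; if (xx < 0 || xx >= cx) continue;
              double w = wx[c1] * wyz;
              R_xlen_t idx = xx + base;
              g[idx] += w * h0;
              g[idx + comp] += w * h1;
              g[idx + 2 * comp] += w * h2;
            }
          }
        }
      }
    }
  }
  return List::create(_["value"] = S, _["n"] = count, _["grad"] = grad);
}
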