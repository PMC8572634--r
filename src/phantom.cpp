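#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Voxel centre along axis a: origin[a] + i * spacing[a], i 0-based; a voxel
// spans +/- spacing/2 around its centre. Tubes are rasterised as the union of
// spheres placed at densely sampled centreline points (sample step below the
// sub-voxel pitch, so the union is an accurate capsule approximation).
//
// Returns, over the full grid:
//   occ  - fractional occupancy from ss^3 sub-voxel sampling (partial volume)
//   mask - exact voxel-centre-in-tube test (the binary ground truth)

// [[Rcpp::export]]
List rasterize_tube_cpp(NumericMatrix pts, NumericVector radii,
                        IntegerVector dim, NumericVector spacing,
                        NumericVector origin, int ss) {
  const int D0 = dim[0], D1 = dim[1], D2 = dim[2];
  const int n = pts.nrow();
  NumericVector occ((R_xlen_t)D0 * D1 * D2);
  LogicalVector mask((R_xlen_t)D0 * D1 * D2);
  if (n == 0) return List::create(_["occ"] = occ, _["mask"] = mask);

  double rmax = 0.0, pmin[3], pmax[3];
  for (int a = 0; a < 3; ++a) { pmin[a] = R_PosInf; pmax[a] = R_NegInf; }
  for (int t = 0; t < n; ++t) {
    if (radii[t] > rmax) rmax = radii[t];
    for (int a = 0; a < 3; ++a) {
      if (pts(t, a) < pmin[a]) pmin[a] = pts(t, a);
      if (pts(t, a) > pmax[a]) pmax[a] = pts(t, a);
    }
  }

  int lo[3], hi[3], nb[3];
  for (int a = 0; a < 3; ++a) {
    lo[a] = (int)std::floor((pmin[a] - rmax - origin[a]) / spacing[a]) - 1;
    hi[a] = (int)std::ceil((pmax[a] + rmax - origin[a]) / spacing[a]) + 1;
    if (lo[a] < 0) lo[a] = 0;
    if (hi[a] > dim[a] - 1) hi[a] = dim[a] - 1;
    nb[a] = hi[a] - lo[a] + 1;
    if (nb[a] <= 0) return List::create(_["occ"] = occ, _["mask"] = mask);
  }

  const int S0 = nb[0] * ss, S1 = nb[1] * ss, S2 = nb[2] * ss;
  std::vector<unsigned char> sub((size_t)S0 * S1 * S2, 0);
  double subsp[3], c0[3];
  for (int a = 0; a < 3; ++a) {
    subsp[a] = spacing[a] / ss;
    c0[a] = origin[a] + (lo[a] - 0.5) * spacing[a] + 0.5 * subsp[a];
  }

  // sub-voxel occupancy pass
  for (int t = 0; t < n; ++t) {
    const double r = radii[t], r2 = r * r;
    if (r <= 0) continue;
    int slo[3], shi[3];
    for (int a = 0; a < 3; ++a) {
      slo[a] = (int)std::ceil((pts(t, a) - r - c0[a]) / subsp[a]);
      shi[a] = (int)std::floor((pts(t, a) + r - c0[a]) / subsp[a]);
      if (slo[a] < 0) slo[a] = 0;
      int smax = nb[a] * ss - 1;
      if (shi[a] > smax) shi[a] = smax;
    }
    for (int sz = slo[2]; sz <= shi[2]; ++sz) {
      const double dz = c0[2] + sz * subsp[2] - pts(t, 2);
      for (int sy = slo[1]; sy <= shi[1]; ++sy) {
        const double dy = c0[1] + sy * subsp[1] - pts(t, 1);
        const double dyz = dy * dy + dz * dz;
        if (dyz > r2) continue;
        unsigned char* row = sub.data() + (size_t)S0 * (sy + (size_t)S1 * sz);
        for (int sx = slo[0]; sx <= shi[0]; ++sx) {
          const double dx = c0[0] + sx * subsp[0] - pts(t, 0);
          if (dx * dx + dyz <= r2) row[sx] = 1;
        }
      }
    }
  }

  // aggregate occupancy per voxel
  const double inv = 1.0 / ((double)ss * ss * ss);
  for (int k = 0; k < nb[2]; ++k)
    for (int j = 0; j < nb[1]; ++j)
      for (int i = 0; i < nb[0]; ++i) {
        int cnt = 0;
        for (int az = 0; az < ss; ++az)
          for (int ay = 0; ay < ss; ++ay) {
            const unsigned char* row = sub.data() +
              (size_t)S0 * ((j * ss + ay) + (size_t)S1 * (k * ss + az));
            for (int ax = 0; ax < ss; ++ax) cnt += row[i * ss + ax];
          }
        if (cnt)
          occ[(R_xlen_t)(lo[0] + i) + (R_xlen_t)D0 * (lo[1] + j) +
              (R_xlen_t)D0 * D1 * (lo[2] + k)] = cnt * inv;
      }

  // exact voxel-centre pass for the binary mask
  for (int t = 0; t < n; ++t) {
    const double r = radii[t], r2 = r * r;
    if (r <= 0) continue;
    int vlo[3], vhi[3];
    for (int a = 0; a < 3; ++a) {
      vlo[a] = (int)std::ceil((pts(t, a) - r - origin[a]) / spacing[a]);
      vhi[a] = (int)std::floor((pts(t, a) + r - origin[a]) / spacing[a]);
      if (vlo[a] < 0) vlo[a] = 0;
      if (vhi[a] > dim[a] - 1) vhi[a] = dim[a] - 1;
    }
    for (int k = vlo[2]; k <= vhi[2]; ++k) {
      const double dz = origin[2] + k * spacing[2] - pts(t, 2);
      for (int j = vlo[1]; j <= vhi[1]; ++j) {
        const double dy = origin[1] + j * spacing[1] - pts(t, 1);
        const double dyz = dy * dy + dz * dz;
        if (dyz > r2) continue;
        for (int i = vlo[0]; i <= vhi[0]; ++i) {
          const double dx = origin[0] + i * spacing[0] - pts(t, 0);
          if (dx * dx + dyz <= r2)
            mask[(R_xlen_t)i + (R_xlen_t)D0 * j + (R_xlen_t)D0 * D1 * k] = true;
        }
      }
    }
  }

  return List::create(_["occ"] = occ, _["mask"] = mask);
}

// Cross-sectional lumen area profile along a centreline: at each sample point
// count mask voxels inside a thin slab perpendicular to the local tangent and
// within window_r of the axis; area = voxel volume * count / slab thickness.

// [[Rcpp::export]]
NumericVector tube_profile_cpp(LogicalVector mask, IntegerVector dim,
                               NumericVector spacing, NumericVector origin,
                               NumericMatrix pts, NumericMatrix tangents,
                               double window_r, double slab_half) {
  const int D0 = dim[0], D1 = dim[1], D2 = dim[2];
  const int n = pts.nrow();
  NumericVector area(n);
  const double voxvol = spacing[0] * spacing[1] * spacing[2];
  const double reach = std::sqrt(window_r * window_r + slab_half * slab_half);
  for (int t = 0; t < n; ++t) {
    double tv[3];
    double nrm = 0;
    for (int a = 0; a < 3; ++a) { tv[a] = tangents(t, a); nrm += tv[a] * tv[a]; }
    nrm = std::sqrt(nrm);
    if (nrm <= 0) { area[t] = NA_REAL; continue; }
    for (int a = 0; a < 3; ++a) tv[a] /= nrm;
    int vlo[3], vhi[3];
    for (int a = 0; a < 3; ++a) {
      vlo[a] = (int)std::ceil((pts(t, a) - reach - origin[a]) / spacing[a]);
      vhi[a] = (int)std::floor((pts(t, a) + reach - origin[a]) / spacing[a]);
      if (vlo[a] < 0) vlo[a] = 0;
      if (vhi[a] > dim[a] - 1) vhi[a] = dim[a] - 1;
    }
    int cnt = 0;
    for (int k = vlo[2]; k <= vhi[2]; ++k) {
      const double dz = origin[2] + k * spacing[2] - pts(t, 2);
      for (int j = vlo[1]; j <= vhi[1]; ++j) {
        const double dy = origin[1] + j * spacing[1] - pts(t, 1);
        for (int i = vlo[0]; i <= vhi[0]; ++i) {
          if (!mask[(R_xlen_t)i + (R_xlen_t)D0 * j + (R_xlen_t)D0 * D1 * k])
            continue;
          const double dx = origin[0] + i * spacing[0] - pts(t, 0);
          const double ax = dx * tv[0] + dy * tv[1] + dz * tv[2];
          if (std::fabs(ax) > slab_half) continue;
          const double rad2 = dx * dx + dy * dy + dz * dz - ax * ax;
          if (rad2 <= window_r * window_r) ++cnt;
        }
      }
    }
    area[t] = voxvol * cnt / (2.0 * slab_half);
  }
  return area;
}

// Grid-to-grid resampling: trilinear for intensities, nearest for labels.
// Output voxel centres are mapped into the input's continuous index space
// and clamped at the edges.

// [[Rcpp::export]]
NumericVector resample3d_cpp(NumericVector x, IntegerVector dim,
                             NumericVector spacing, NumericVector origin,
                             IntegerVector newdim, NumericVector newspacing,
                             NumericVector neworigin, bool nearest) {
  const int D0 = dim[0], D1 = dim[1], D2 = dim[2];
  const int N0 = newdim[0], N1 = newdim[1], N2 = newdim[2];
  NumericVector out((R_xlen_t)N0 * N1 * N2);
  for (int k = 0; k < N2; ++k) {
    double fz = (neworigin[2] + k * newspacing[2] - origin[2]) / spacing[2];
    if (fz < 0) fz = 0; if (fz > D2 - 1) fz = D2 - 1;
    for (int j = 0; j < N1; ++j) {
      double fy = (neworigin[1] + j * newspacing[1] - origin[1]) / spacing[1];
      if (fy < 0) fy = 0; if (fy > D1 - 1) fy = D1 - 1;
      for (int i = 0; i < N0; ++i) {
        double fx = (neworigin[0] + i * newspacing[0] - origin[0]) / spacing[0];
        if (fx < 0) fx = 0; if (fx > D0 - 1) fx = D0 - 1;
        double v;
        if (nearest) {
          const int i0 = (int)std::lround(fx), j0 = (int)std::lround(fy),
                    k0 = (int)std::lround(fz);
          v = x[(R_xlen_t)i0 + (R_xlen_t)D0 * j0 + (R_xlen_t)D0 * D1 * k0];
        } else {
          const int i0 = (int)std::floor(fx), j0 = (int)std::floor(fy),
                    k0 = (int)std::floor(fz);
          const int i1 = i0 + 1 < D0 ? i0 + 1 : i0;
          const int j1 = j0 + 1 < D1 ? j0 + 1 : j0;
          const int k1 = k0 + 1 < D2 ? k0 + 1 : k0;
          const double wx = fx - i0, wy = fy - j0, wz = fz - k0;
          #define AT(ii, jj, kk) \
            x[(R_xlen_t)(ii) + (R_xlen_t)D0 * (jj) + (R_xlen_t)D0 * D1 * (kk)]
          v = (1 - wz) * ((1 - wy) * ((1 - wx) * AT(i0, j0, k0) + wx * AT(i1, j0, k0)) +
                          wy * ((1 - wx) * AT(i0, j1, k0) + wx * AT(i1, j1, k0))) +
              wz * ((1 - wy) * ((1 - wx) * AT(i0, j0, k1) + wx * AT(i1, j0, k1)) +
                    wy * ((1 - wx) * AT(i0, j1, k1) + wx * AT(i1, j1, k1)));
          #undef AT
        }
        out[(R_xlen_t)i + (R_xlen_t)N0 * j + (R_xlen_t)N0 * N1 * k] = v;
      }
    }
  }
  return out;
}
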