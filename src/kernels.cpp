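#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Offset {
  int di, dj, dk;
  double dist;
};

// All lattice offsets with physical length <= radius, given anisotropic
// voxel spacing. Optionally sorted by increasing physical distance.
std::vector<Offset> lattice_offsets(const double *sp, double radius,
                                    bool sorted) {
  const int mi = (int)std::floor(radius / sp[0]);
  const int mj = (int)std::floor(radius / sp[1]);
  const int mk = (int)std::floor(radius / sp[2]);
  std::vector<Offset> off;
  off.reserve((size_t)(2 * mi + 1) * (2 * mj + 1) * (2 * mk + 1) / 2 + 8);
  for (int dk = -mk; dk <= mk; ++dk) {
    const double z2 = dk * sp[2] * dk * sp[2];
    for (int dj = -mj; dj <= mj; ++dj) {
      const double yz2 = z2 + dj * sp[1] * dj * sp[1];
      for (int di = -mi; di <= mi; ++di) {
        const double d2 = yz2 + di * sp[0] * di * sp[0];
        if (d2 <= radius * radius) {
          Offset o;
          o.di = di; o.dj = dj; o.dk = dk; o.dist = std::sqrt(d2);
          off.push_back(o);
        }
      }
    }
  }
  if (sorted)
    std::sort(off.begin(), off.end(),
              [](const Offset &a, const Offset &b) { return a.dist < b.dist; });
  return off;
}

} // namespace

// Gamma index over masked reference voxels. Candidates are evaluated-volume
// voxel centres within cap*dta of the reference voxel, visited in order of
// increasing physical distance with early exit once the distance term alone
// reaches the current best gamma; exact for all gamma < cap.
// [[Rcpp::export]]
NumericVector gamma_map_cpp(NumericVector ref, NumericVector eval,
                            LogicalVector mask, IntegerVector dims,
                            NumericVector spacing, double dta, double dhu,
                            double cap) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double sp[3] = {spacing[0], spacing[1], spacing[2]};
  const double radius = cap * dta;
  std::vector<Offset> off = lattice_offsets(sp, radius, true);
  const size_t noff = off.size();

  NumericVector out(n, NA_REAL);
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      const R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t v = base + i;
        if (!mask[v]) continue;
        const double hr = ref[v];
        double best = cap;
        for (size_t t = 0; t < noff; ++t) {
          const double dterm = off[t].dist / dta;
          if (dterm >= best) break; // offsets sorted: no candidate can improve
          const int ii = i + off[t].di;
          if (ii < 0 || ii >= nx) continue;
          const int jj = j + off[t].dj;
          if (jj < 0 || jj >= ny) continue;
          const int kk = k + off[t].dk;
          if (kk < 0 || kk >= nz) continue;
          const double hd =
              (eval[(R_xlen_t)nx * (jj + (R_xlen_t)ny * kk) + ii] - hr) / dhu;
          const double g = std::sqrt(dterm * dterm + hd * hd);
          if (g < best) best = g;
        }
        out[v] = best;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Unpruned exhaustive minimisation over every candidate in the search
// sphere; verification oracle, independent of the sorted/early-exit path.
// [[Rcpp::export]]
NumericVector gamma_bruteforce_cpp(NumericVector ref, NumericVector eval,
                                   LogicalVector mask, IntegerVector dims,
                                   NumericVector spacing, double dta,
                                   double dhu, double cap) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double radius = cap * dta, r2 = radius * radius;
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const int mi = (int)std::floor(radius / sx);
  const int mj = (int)std::floor(radius / sy);
  const int mk = (int)std::floor(radius / sz);

  NumericVector out(n, NA_REAL);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t v = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (!mask[v]) continue;
        const double hr = ref[v];
        double best = cap;
        for (int dk = -mk; dk <= mk; ++dk) {
          const int kk = k + dk;
          if (kk < 0 || kk >= nz) continue;
          for (int dj = -mj; dj <= mj; ++dj) {
            const int jj = j + dj;
            if (jj < 0 || jj >= ny) continue;
            for (int di = -mi; di <= mi; ++di) {
              const int ii = i + di;
              if (ii < 0 || ii >= nx) continue;
              const double d2 = di * sx * di * sx + dj * sy * dj * sy +
                                dk * sz * dk * sz;
              if (d2 > r2) continue;
              const double hd =
                  (eval[(R_xlen_t)nx * (jj + (R_xlen_t)ny * kk) + ii] - hr) /
                  dhu;
              const double g = std::sqrt(d2 / (dta * dta) + hd * hd);
              if (g < best) best = g;
            }
          }
        }
        out[v] = best;
      }
  out.attr("dim") = dims;
  return out;
}

// Morphological dilation by physical (Euclidean) distance <= margin mm,
// anisotropic-spacing aware; expansion clipped at the array bounds.
// [[Rcpp::export]]
LogicalVector dilate_mask_cpp(LogicalVector mask, IntegerVector dims,
                              NumericVector spacing, double margin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sp[3] = {spacing[0], spacing[1], spacing[2]};
  std::vector<Offset> off = lattice_offsets(sp, margin, false);
  LogicalVector out((R_xlen_t)nx * ny * nz, FALSE);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t v = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (!mask[v]) continue;
        for (size_t t = 0; t < off.size(); ++t) {
          const int ii = i + off[t].di;
          if (ii < 0 || ii >= nx) continue;
          const int jj = j + off[t].dj;
          if (jj < 0 || jj >= ny) continue;
          const int kk = k + off[t].dk;
          if (kk < 0 || kk >= nz) continue;
          out[(R_xlen_t)nx * (jj + (R_xlen_t)ny * kk) + ii] = TRUE;
        }
      }
  out.attr("dim") = dims;
  return out;
}

// Trilinear interpolation of a source volume at the voxel centres of a
// target grid; target centres outside the source extent get `fill`.
// Physical position of index (i,j,k) is origin + index * spacing (0-based).
// [[Rcpp::export]]
NumericVector resample_trilinear_cpp(NumericVector src, IntegerVector sdims,
                                     NumericVector sspacing,
                                     NumericVector sorigin,
                                     IntegerVector tdims,
                                     NumericVector tspacing,
                                     NumericVector torigin, double fill) {
  const int snx = sdims[0], sny = sdims[1], snz = sdims[2];
  const int tnx = tdims[0], tny = tdims[1], tnz = tdims[2];
  NumericVector out((R_xlen_t)tnx * tny * tnz);
  for (int k = 0; k < tnz; ++k) {
    const double z = torigin[2] + k * tspacing[2];
    const double fz = (z - sorigin[2]) / sspacing[2];
    for (int j = 0; j < tny; ++j) {
      const double y = torigin[1] + j * tspacing[1];
      const double fy = (y - sorigin[1]) / sspacing[1];
      for (int i = 0; i < tnx; ++i) {
        const double x = torigin[0] + i * tspacing[0];
        const double fx = (x - sorigin[0]) / sspacing[0];
        const R_xlen_t v = i + (R_xlen_t)tnx * (j + (R_xlen_t)tny * k);
        if (fx < 0 || fx > snx - 1 || fy < 0 || fy > sny - 1 || fz < 0 ||
            fz > snz - 1) {
          out[v] = fill;
          continue;
        }
        int i0 = (int)std::floor(fx), j0 = (int)std::floor(fy),
            k0 = (int)std::floor(fz);
        if (i0 == snx - 1) i0--;
        if (j0 == sny - 1) j0--;
        if (k0 == snz - 1) k0--;
        const double ax = fx - i0, ay = fy - j0, az = fz - k0;
        double acc = 0.0;
        for (int c = 0; c < 8; ++c) {
          const int bi = c & 1, bj = (c >> 1) & 1, bk = (c >> 2) & 1;
          const double w = (bi ? ax : 1 - ax) * (bj ? ay : 1 - ay) *
                           (bk ? az : 1 - az);
          acc += w * src[(R_xlen_t)snx *
                             ((j0 + bj) + (R_xlen_t)sny * (k0 + bk)) +
                         (i0 + bi)];
        }
        out[v] = acc;
      }
    }
  }
  out.attr("dim") = tdims;
  return out;
}
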