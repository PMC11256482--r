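#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// Index helper: column-major, 0-based.
static inline R_xlen_t IDX(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// Trilinear interpolation at continuous 0-based voxel coordinates.
// Coordinates are clamped to the volume (replicate border).
// [[Rcpp::export(name = ".interp3_trilinear")]]
NumericVector interp3_trilinear(NumericVector arr, IntegerVector dim,
                                NumericVector xi, NumericVector yi,
                                NumericVector zi) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = xi.size();
  NumericVector out(n);
  for (R_xlen_t t = 0; t < n; ++t) {
    double x = xi[t], y = yi[t], z = zi[t];
    if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
    if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
    if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 > nx - 2) i0 = nx - 2; if (i0 < 0) i0 = 0;
    if (j0 > ny - 2) j0 = ny - 2; if (j0 < 0) j0 = 0;
    if (k0 > nz - 2) k0 = nz - 2; if (k0 < 0) k0 = 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    if (nx == 1) { i0 = 0; fx = 0; }
    if (ny == 1) { j0 = 0; fy = 0; }
    if (nz == 1) { k0 = 0; fz = 0; }
    int i1 = (nx == 1) ? 0 : i0 + 1, j1 = (ny == 1) ? 0 : j0 + 1,
        k1 = (nz == 1) ? 0 : k0 + 1;
    double c000 = arr[IDX(i0, j0, k0, nx, ny)], c100 = arr[IDX(i1, j0, k0, nx, ny)];
    double c010 = arr[IDX(i0, j1, k0, nx, ny)], c110 = arr[IDX(i1, j1, k0, nx, ny)];
    double c001 = arr[IDX(i0, j0, k1, nx, ny)], c101 = arr[IDX(i1, j0, k1, nx, ny)];
    double c011 = arr[IDX(i0, j1, k1, nx, ny)], c111 = arr[IDX(i1, j1, k1, nx, ny)];
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[t] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Nearest-neighbour interpolation (for label maps).
// [[Rcpp::export(name = ".interp3_nearest")]]
NumericVector interp3_nearest(NumericVector arr, IntegerVector dim,
                              NumericVector xi, NumericVector yi,
                              NumericVector zi) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = xi.size();
  NumericVector out(n);
  for (R_xlen_t t = 0; t < n; ++t) {
    int i = (int)std::lround(xi[t]), j = (int)std::lround(yi[t]),
        k = (int)std::lround(zi[t]);
    if (i < 0) i = 0; if (i > nx - 1) i = nx - 1;
    if (j < 0) j = 0; if (j > ny - 1) j = ny - 1;
    if (k < 0) k = 0; if (k > nz - 1) k = nz - 1;
    out[t] = arr[IDX(i, j, k, nx, ny)];
  }
  return out;
}

// Separable 1-D convolution along one axis (0,1,2), replicate boundary.
// [[Rcpp::export(name = ".conv_axis3")]]
NumericVector conv_axis3(NumericVector arr, IntegerVector dim,
                         NumericVector kernel, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int kn = kernel.size();
  const int half = kn / 2;
  NumericVector out(arr.size());
  const int len = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        double acc = 0;
        int pos = (axis == 0) ? i : (axis == 1) ? j : k;
        for (int m = 0; m < kn; ++m) {
          int p = pos + m - half;
          if (p < 0) p = 0;
          if (p > len - 1) p = len - 1;
          R_xlen_t id = (axis == 0) ? IDX(p, j, k, nx, ny)
                      : (axis == 1) ? IDX(i, p, k, nx, ny)
                                    : IDX(i, j, p, nx, ny);
          acc += arr[id] * kernel[m];
        }
        out[IDX(i, j, k, nx, ny)] = acc;
      }
    }
  }
  return out;
}

// Connected-component labelling of a binary mask, 6- or 26-connectivity.
// Returns integer labels 1..ncomp (0 = background), BFS flood fill.
// [[Rcpp::export(name = ".label_components3")]]
IntegerVector label_components3(IntegerVector mask, IntegerVector dim,
                                int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector labels(mask.size(), 0);
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && man > 1) continue;
        if (connectivity == 18 && man > 2) continue;
        offs.push_back({dx, dy, dz});
      }
  int next = 0;
  std::queue<std::array<int, 3>> q;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t id = IDX(i, j, k, nx, ny);
        if (mask[id] == 0 || labels[id] != 0) continue;
        ++next;
        labels[id] = next;
        q.push({i, j, k});
        while (!q.empty()) {
          auto v = q.front(); q.pop();
          for (auto &o : offs) {
            int ii = v[0] + o[0], jj = v[1] + o[1], kk = v[2] + o[2];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            R_xlen_t nid = IDX(ii, jj, kk, nx, ny);
            if (mask[nid] != 0 && labels[nid] == 0) {
              labels[nid] = next;
              q.push({ii, jj, kk});
            }
          }
        }
      }
  return labels;
}

// Binary dilation (op=1) or erosion (op=0) with a ball structuring element
// of the given radius in voxels.
// [[Rcpp::export(name = ".morph3_ball")]]
IntegerVector morph3_ball(IntegerVector mask, IntegerVector dim,
                          double radius, int op) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  int r = (int)std::floor(radius);
  std::vector<std::array<int, 3>> offs;
  for (int dz = -r; dz <= r; ++dz)
    for (int dy = -r; dy <= r; ++dy)
      for (int dx = -r; dx <= r; ++dx)
        if (dx * dx + dy * dy + dz * dz <= radius * radius + 1e-9)
          offs.push_back({dx, dy, dz});
  IntegerVector out(mask.size());
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int hit = (op == 1) ? 0 : 1;
        for (auto &o : offs) {
          int ii = i + o[0], jj = j + o[1], kk = k + o[2];
          int val;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            val = 0;  // outside counts as background
          else
            val = mask[IDX(ii, jj, kk, nx, ny)];
          if (op == 1) { if (val != 0) { hit = 1; break; } }
          else         { if (val == 0) { hit = 0; break; } }
        }
        out[IDX(i, j, k, nx, ny)] = hit;
      }
  return out;
}

// Local-correlation demons step for nonlinear registration.
// fixed F and warped-moving M share the grid. Both images are locally
// standardised (mean/SD over a box window of half-width `radius`,
// integral-image sums), which makes the match criterion a local
// normalised cross-correlation, then a Thirion-style demons update is
// computed on the standardised intensities:
//   delta = e * g / (|g|^2 + e^2 / cap^2),
// with e the residual, g the symmetric intensity gradient (mm^-1) and
// `cap` the maximum per-voxel step (mm); |delta| <= cap/2 and steps are
// proportional to the residual, so sub-voxel mismatches produce sub-voxel
// updates. Returns the 3 components of delta in mm.
// [[Rcpp::export(name = ".lcc_demons_step")]]
List lcc_demons_step(NumericVector F, NumericVector M, IntegerVector dim,
                     int radius, NumericVector spacing, double cap) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nv = F.size();
  // integral images with one layer of zero padding
  const int px = nx + 1, py = ny + 1, pz = nz + 1;
  auto PIDX = [&](int i, int j, int k) {
    return (R_xlen_t)i + (R_xlen_t)px * ((R_xlen_t)j + (R_xlen_t)py * (R_xlen_t)k);
  };
  std::vector<double> sF(px * (R_xlen_t)py * pz, 0.0), sM(sF), sFF(sF), sMM(sF),
      sFM(sF), sN(sF);
  for (int k = 1; k < pz; ++k)
    for (int j = 1; j < py; ++j)
      for (int i = 1; i < px; ++i) {
        R_xlen_t id = IDX(i - 1, j - 1, k - 1, nx, ny);
        double f = F[id], m = M[id];
        R_xlen_t c = PIDX(i, j, k);
        R_xlen_t a1 = PIDX(i - 1, j, k), a2 = PIDX(i, j - 1, k),
                 a3 = PIDX(i, j, k - 1), a12 = PIDX(i - 1, j - 1, k),
                 a13 = PIDX(i - 1, j, k - 1), a23 = PIDX(i, j - 1, k - 1),
                 a123 = PIDX(i - 1, j - 1, k - 1);
#define ACCUM(S, V)                                                   \
  S[c] = (V) + S[a1] + S[a2] + S[a3] - S[a12] - S[a13] - S[a23] + S[a123];
        ACCUM(sF, f) ACCUM(sM, m) ACCUM(sFF, f * f) ACCUM(sMM, m * m)
        ACCUM(sFM, f * m) ACCUM(sN, 1.0)
#undef ACCUM
      }
  auto boxsum = [&](std::vector<double> &S, int i0, int j0, int k0, int i1,
                    int j1, int k1) {
    // inclusive voxel box [i0..i1] etc., clipped
    if (i0 < 0) i0 = 0; if (j0 < 0) j0 = 0; if (k0 < 0) k0 = 0;
    if (i1 > nx - 1) i1 = nx - 1; if (j1 > ny - 1) j1 = ny - 1;
    if (k1 > nz - 1) k1 = nz - 1;
    return S[PIDX(i1 + 1, j1 + 1, k1 + 1)] - S[PIDX(i0, j1 + 1, k1 + 1)] -
           S[PIDX(i1 + 1, j0, k1 + 1)] - S[PIDX(i1 + 1, j1 + 1, k0)] +
           S[PIDX(i0, j0, k1 + 1)] + S[PIDX(i0, j1 + 1, k0)] +
           S[PIDX(i1 + 1, j0, k0)] - S[PIDX(i0, j0, k0)];
  };
  // locally standardised images, each by its own local SD (floored at a
  // fraction of the global SD): divides out smooth amplitude differences
  // (bias fields, interpolation blur) so the residual reflects pattern
  // shift only -- this is what makes the force correlation-like
  double gm = 0, gs = 0;
  for (R_xlen_t t = 0; t < nv; ++t) gm += F[t];
  gm /= nv;
  for (R_xlen_t t = 0; t < nv; ++t) gs += (F[t] - gm) * (F[t] - gm);
  gs = std::sqrt(gs / nv);
  const double floor_sd = 0.1 * gs + 1e-12;
  std::vector<double> Fn(nv), Mn(nv);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t id = IDX(i, j, k, nx, ny);
        double n = boxsum(sN, i - radius, j - radius, k - radius, i + radius,
                          j + radius, k + radius);
        double mF = boxsum(sF, i - radius, j - radius, k - radius, i + radius,
                           j + radius, k + radius) / n;
        double mM = boxsum(sM, i - radius, j - radius, k - radius, i + radius,
                           j + radius, k + radius) / n;
        double vF = boxsum(sFF, i - radius, j - radius, k - radius, i + radius,
                           j + radius, k + radius) / n - mF * mF;
        double vM = boxsum(sMM, i - radius, j - radius, k - radius, i + radius,
                           j + radius, k + radius) / n - mM * mM;
        double sdF = std::sqrt(vF > 0 ? vF : 0), sdM = std::sqrt(vM > 0 ? vM : 0);
        if (sdF < floor_sd) sdF = floor_sd;
        if (sdM < floor_sd) sdM = floor_sd;
        Fn[id] = (F[id] - mF) / sdF;
        Mn[id] = (M[id] - mM) / sdM;
      }
  NumericVector fx(nv), fy(nv), fz(nv);
  const double cap2 = cap * cap;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t id = IDX(i, j, k, nx, ny);
        double e = Fn[id] - Mn[id];
        if (e == 0) { fx[id] = fy[id] = fz[id] = 0; continue; }
        int im = (i > 0) ? i - 1 : i, ip = (i < nx - 1) ? i + 1 : i;
        int jm = (j > 0) ? j - 1 : j, jp = (j < ny - 1) ? j + 1 : j;
        int km = (k > 0) ? k - 1 : k, kp = (k < nz - 1) ? k + 1 : k;
        // symmetric gradient of the standardised images (mm^-1)
        double gx = 0.5 *
            ((Mn[IDX(ip, j, k, nx, ny)] - Mn[IDX(im, j, k, nx, ny)]) +
             (Fn[IDX(ip, j, k, nx, ny)] - Fn[IDX(im, j, k, nx, ny)])) /
            ((ip - im) * spacing[0]);
        double gy = 0.5 *
            ((Mn[IDX(i, jp, k, nx, ny)] - Mn[IDX(i, jm, k, nx, ny)]) +
             (Fn[IDX(i, jp, k, nx, ny)] - Fn[IDX(i, jm, k, nx, ny)])) /
            ((jp - jm) * spacing[1]);
        double gz = 0.5 *
            ((Mn[IDX(i, j, kp, nx, ny)] - Mn[IDX(i, j, km, nx, ny)]) +
             (Fn[IDX(i, j, kp, nx, ny)] - Fn[IDX(i, j, km, nx, ny)])) /
            ((kp - km) * spacing[2]);
        double g2 = gx * gx + gy * gy + gz * gz;
        double denom = g2 + e * e / cap2;
        if (denom <= 0) { fx[id] = fy[id] = fz[id] = 0; continue; }
        double w = e / denom;
        fx[id] = w * gx;
        fy[id] = w * gy;
        fz[id] = w * gz;
      }
  return List::create(_["x"] = fx, _["y"] = fy, _["z"] = fz);
}

// Joint histogram of two equal-length samples over nbins x nbins, with
// linear (partial-volume) binning. Values are assumed pre-scaled to
// [0, nbins-1].
// [[Rcpp::export(name = ".joint_hist")]]
NumericMatrix joint_hist(NumericVector a, NumericVector b, int nbins) {
  NumericMatrix H(nbins, nbins);
  const R_xlen_t n = a.size();
  for (R_xlen_t t = 0; t < n; ++t) {
    double x = a[t], y = b[t];
    if (x < 0) x = 0; if (x > nbins - 1) x = nbins - 1;
    if (y < 0) y = 0; if (y > nbins - 1) y = nbins - 1;
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y);
    if (i0 > nbins - 2) i0 = nbins - 2;
    if (j0 > nbins - 2) j0 = nbins - 2;
    double fx = x - i0, fy = y - j0;
    H(i0, j0)         += (1 - fx) * (1 - fy);
    H(i0 + 1, j0)     += fx * (1 - fy);
    H(i0, j0 + 1)     += (1 - fx) * fy;
    H(i0 + 1, j0 + 1) += fx * fy;
  }
  return H;
}

// Eigen-decomposition of symmetric 3x3 tensors (cyclic Jacobi sweeps).
// Input: n x 6 matrix of unique elements (xx, yy, zz, xy, xz, yz).
// Output: list(values = n x 3 descending, vector = n x 3 principal axis).
// [[Rcpp::export(name = ".eig3_sym")]]
List eig3_sym(NumericMatrix tens) {
  const int n = tens.nrow();
  NumericMatrix vals(n, 3), pvec(n, 3);
  for (int t = 0; t < n; ++t) {
    double a[3][3] = {{tens(t, 0), tens(t, 3), tens(t, 4)},
                      {tens(t, 3), tens(t, 1), tens(t, 5)},
                      {tens(t, 4), tens(t, 5), tens(t, 2)}};
    double v[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
    for (int sweep = 0; sweep < 30; ++sweep) {
      double off = std::fabs(a[0][1]) + std::fabs(a[0][2]) + std::fabs(a[1][2]);
      if (off < 1e-15) break;
      for (int p = 0; p < 2; ++p)
        for (int q = p + 1; q < 3; ++q) {
          if (std::fabs(a[p][q]) < 1e-30) continue;
          double theta = (a[q][q] - a[p][p]) / (2.0 * a[p][q]);
          double tt = (theta >= 0 ? 1.0 : -1.0) /
                      (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
          double c = 1.0 / std::sqrt(tt * tt + 1.0), s = tt * c;
          for (int r = 0; r < 3; ++r) {
            double arp = a[r][p], arq = a[r][q];
            a[r][p] = c * arp - s * arq;
            a[r][q] = s * arp + c * arq;
          }
          for (int r = 0; r < 3; ++r) {
            double apr = a[p][r], aqr = a[q][r];
            a[p][r] = c * apr - s * aqr;
            a[q][r] = s * apr + c * aqr;
          }
          for (int r = 0; r < 3; ++r) {
            double vrp = v[r][p], vrq = v[r][q];
            v[r][p] = c * vrp - s * vrq;
            v[r][q] = s * vrp + c * vrq;
          }
        }
    }
    int order[3] = {0, 1, 2};
    double d[3] = {a[0][0], a[1][1], a[2][2]};
    for (int x = 0; x < 2; ++x)
      for (int y = x + 1; y < 3; ++y)
        if (d[order[y]] > d[order[x]]) std::swap(order[x], order[y]);
    for (int x = 0; x < 3; ++x) vals(t, x) = d[order[x]];
    for (int r = 0; r < 3; ++r) pvec(t, r) = v[r][order[0]];
  }
  return List::create(_["values"] = vals, _["vector"] = pvec);
}
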