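#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Regularized probabilistic streamline propagation over a spherical-harmonic
// ODF field. Directions are drawn from a fixed sphere tessellation with
// probability proportional to odf^(1/T), restricted to the aperture cone
// around the previous direction; trajectories grow forward and backward from
// each seed and stop on leaving the propagation domain (or the grid) or when
// no candidate direction carries positive ODF mass. Uses R's RNG, so results
// are reproducible under set.seed().

struct Field {
  const double *coef;
  const double *odfMin; // voxelwise ODF minimum (min-max normalization)
  int nx, ny, nz, nc;
  const int *domain; // 0/1, nx*ny*nz
  // world -> continuous 0-based voxel coords (row-major 3x4 of inv affine)
  double inv[12];
};

static inline void worldToVox(const Field &f, const double *p, double *v) {
  for (int r = 0; r < 3; ++r)
    v[r] = f.inv[4 * r] * p[0] + f.inv[4 * r + 1] * p[1] +
           f.inv[4 * r + 2] * p[2] + f.inv[4 * r + 3];
}

static inline bool inGrid(const Field &f, const double *v) {
  return v[0] > -0.5 && v[0] < f.nx - 0.5 && v[1] > -0.5 &&
         v[1] < f.ny - 0.5 && v[2] > -0.5 && v[2] < f.nz - 0.5;
}

static inline bool inDomain(const Field &f, const double *v) {
  if (!inGrid(f, v)) return false;
  int i = (int)std::lround(v[0]), j = (int)std::lround(v[1]),
      k = (int)std::lround(v[2]);
  return f.domain[i + f.nx * (j + (long)f.ny * k)] != 0;
}

// Trilinear interpolation of all SH coefficients at voxel coords v.
static void interpCoefs(const Field &f, const double *v, double *out) {
  double x = v[0], y = v[1], z = v[2];
  if (x < 0) x = 0; if (x > f.nx - 1) x = f.nx - 1;
  if (y < 0) y = 0; if (y > f.ny - 1) y = f.ny - 1;
  if (z < 0) z = 0; if (z > f.nz - 1) z = f.nz - 1;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
      z0 = (int)std::floor(z);
  if (x0 > f.nx - 2) x0 = f.nx >= 2 ? f.nx - 2 : 0;
  if (y0 > f.ny - 2) y0 = f.ny >= 2 ? f.ny - 2 : 0;
  if (z0 > f.nz - 2) z0 = f.nz >= 2 ? f.nz - 2 : 0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  int x1 = x0 + 1 < f.nx ? x0 + 1 : x0;
  int y1 = y0 + 1 < f.ny ? y0 + 1 : y0;
  int z1 = z0 + 1 < f.nz ? z0 + 1 : z0;
  double w[8] = {(1 - fx) * (1 - fy) * (1 - fz), fx * (1 - fy) * (1 - fz),
                 (1 - fx) * fy * (1 - fz),       fx * fy * (1 - fz),
                 (1 - fx) * (1 - fy) * fz,       fx * (1 - fy) * fz,
                 (1 - fx) * fy * fz,             fx * fy * fz};
  long nxy = (long)f.nx * f.ny, nvox = nxy * f.nz;
  long base[8] = {x0 + f.nx * (y0 + (long)f.ny * z0),
                  x1 + f.nx * (y0 + (long)f.ny * z0),
                  x0 + f.nx * (y1 + (long)f.ny * z0),
                  x1 + f.nx * (y1 + (long)f.ny * z0),
                  x0 + f.nx * (y0 + (long)f.ny * z1),
                  x1 + f.nx * (y0 + (long)f.ny * z1),
                  x0 + f.nx * (y1 + (long)f.ny * z1),
                  x1 + f.nx * (y1 + (long)f.ny * z1)};
  for (int c = 0; c < f.nc; ++c) {
    double acc = 0;
    long off = (long)c * nvox;
    for (int q = 0; q < 8; ++q) acc += w[q] * f.coef[off + base[q]];
    out[c] = acc;
  }
}

// Trilinear interpolation of the voxelwise ODF-minimum volume.
static double interpMin(const Field &f, const double *v) {
  double x = v[0], y = v[1], z = v[2];
  if (x < 0) x = 0; if (x > f.nx - 1) x = f.nx - 1;
  if (y < 0) y = 0; if (y > f.ny - 1) y = f.ny - 1;
  if (z < 0) z = 0; if (z > f.nz - 1) z = f.nz - 1;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
      z0 = (int)std::floor(z);
  if (x0 > f.nx - 2) x0 = f.nx >= 2 ? f.nx - 2 : 0;
  if (y0 > f.ny - 2) y0 = f.ny >= 2 ? f.ny - 2 : 0;
  if (z0 > f.nz - 2) z0 = f.nz >= 2 ? f.nz - 2 : 0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  int x1 = x0 + 1 < f.nx ? x0 + 1 : x0;
  int y1 = y0 + 1 < f.ny ? y0 + 1 : y0;
  int z1 = z0 + 1 < f.nz ? z0 + 1 : z0;
  double acc = 0;
  double w[8] = {(1 - fx) * (1 - fy) * (1 - fz), fx * (1 - fy) * (1 - fz),
                 (1 - fx) * fy * (1 - fz),       fx * fy * (1 - fz),
                 (1 - fx) * (1 - fy) * fz,       fx * (1 - fy) * fz,
                 (1 - fx) * fy * fz,             fx * fy * fz};
  long base[8] = {x0 + f.nx * (y0 + (long)f.ny * z0),
                  x1 + f.nx * (y0 + (long)f.ny * z0),
                  x0 + f.nx * (y1 + (long)f.ny * z0),
                  x1 + f.nx * (y1 + (long)f.ny * z0),
                  x0 + f.nx * (y0 + (long)f.ny * z1),
                  x1 + f.nx * (y0 + (long)f.ny * z1),
                  x0 + f.nx * (y1 + (long)f.ny * z1),
                  x1 + f.nx * (y1 + (long)f.ny * z1)};
  for (int q = 0; q < 8; ++q) acc += w[q] * f.odfMin[base[q]];
  return acc;
}

// Draw a direction index with probability proportional to
// max(odf, 0)^(1/T) over candidates; returns -1 when no mass.
static int sampleDir(const std::vector<int> &cand,
                     const std::vector<double> &odf, double invT,
                     bool subtractFloor) {
  double tot = 0;
  double lo = 0;
  if (subtractFloor && !odf.empty()) {
    lo = odf[0];
    for (size_t c = 1; c < cand.size(); ++c)
      if (odf[c] < lo) lo = odf[c];
    if (lo < 0) lo = 0;
  }
  std::vector<double> p(cand.size());
  for (size_t c = 0; c < cand.size(); ++c) {
    double v = odf[c] - lo;
    p[c] = v > 0 ? std::pow(v, invT) : 0.0;
    tot += p[c];
  }
  if (tot <= 0) return -1;
  double u = unif_rand() * tot, acc = 0;
  for (size_t c = 0; c < cand.size(); ++c) {
    acc += p[c];
    if (u <= acc) return cand[c];
  }
  return cand.back();
}

// One-directional walk; appends stepped positions to pts (not the start).
static void walk(const Field &f, const NumericMatrix &dirs,
                 const NumericMatrix &basis, double *coefbuf,
                 const double *start, const double *dir0, double step,
                 double invT, double cosAper, int maxSteps,
                 std::vector<double> &pts) {
  int ndir = dirs.nrow(), nc = basis.ncol();
  double pos[3] = {start[0], start[1], start[2]};
  double prev[3] = {dir0[0], dir0[1], dir0[2]};
  std::vector<int> cand;
  std::vector<double> odf;
  cand.reserve(128);
  odf.reserve(128);
  for (int s = 0; s < maxSteps; ++s) {
    double v[3];
    worldToVox(f, pos, v);
    if (!inDomain(f, v)) break;
    interpCoefs(f, v, coefbuf);
    double floorv = interpMin(f, v);
    cand.clear();
    odf.clear();
    for (int dd = 0; dd < ndir; ++dd) {
      double dp = dirs(dd, 0) * prev[0] + dirs(dd, 1) * prev[1] +
                  dirs(dd, 2) * prev[2];
      if (dp < cosAper) continue;
      double val = -floorv;
      for (int c = 0; c < nc; ++c) val += basis(dd, c) * coefbuf[c];
      cand.push_back(dd);
      odf.push_back(val);
    }
    int pick = sampleDir(cand, odf, invT, true);
    if (pick < 0) break;
    prev[0] = dirs(pick, 0); prev[1] = dirs(pick, 1); prev[2] = dirs(pick, 2);
    pos[0] += step * prev[0]; pos[1] += step * prev[1];
    pos[2] += step * prev[2];
    double vn[3];
    worldToVox(f, pos, vn);
    if (!inGrid(f, vn)) break;
    pts.push_back(pos[0]); pts.push_back(pos[1]); pts.push_back(pos[2]);
  }
}

// [[Rcpp::export(name = ".trackStreamlines")]]
List trackStreamlines(NumericVector coefs, NumericVector odfMin,
                      IntegerVector dims,
                      IntegerVector domain, NumericMatrix invAffine,
                      NumericMatrix dirs, NumericMatrix basis,
                      NumericMatrix seeds, double step, double apertureDeg,
                      double temperature, double minLen, double maxLen,
                      double sharpening) {
  Field f;
  f.coef = coefs.begin();
  f.odfMin = odfMin.begin();
  f.nx = dims[0]; f.ny = dims[1]; f.nz = dims[2]; f.nc = dims[3];
  f.domain = domain.begin();
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 4; ++c) f.inv[4 * r + c] = invAffine(r, c);
  int ndir = dirs.nrow();
  double invT = sharpening / temperature;
  double cosAper = std::cos(apertureDeg * M_PI / 180.0);
  int maxSteps = (int)std::ceil(maxLen / step) + 2;
  std::vector<double> coefbuf(f.nc);

  RNGScope rng;
  List out;
  std::vector<int> kept;
  std::vector<int> candAll(ndir);
  for (int dd = 0; dd < ndir; ++dd) candAll[dd] = dd;
  std::vector<double> odfAll(ndir);

  for (int s = 0; s < seeds.nrow(); ++s) {
    double p0[3] = {seeds(s, 0), seeds(s, 1), seeds(s, 2)};
    double v[3];
    worldToVox(f, p0, v);
    if (!inDomain(f, v)) continue;
    interpCoefs(f, v, coefbuf.data());
    double floorv = interpMin(f, v);
    for (int dd = 0; dd < ndir; ++dd) {
      double val = -floorv;
      for (int c = 0; c < f.nc; ++c) val += basis(dd, c) * coefbuf[c];
      odfAll[dd] = val;
    }
    int d0 = sampleDir(candAll, odfAll, invT, false);
    if (d0 < 0) continue;
    double dir0[3] = {dirs(d0, 0), dirs(d0, 1), dirs(d0, 2)};
    double dir0n[3] = {-dir0[0], -dir0[1], -dir0[2]};
    std::vector<double> fwd, bwd;
    walk(f, dirs, basis, coefbuf.data(), p0, dir0, step, invT, cosAper,
         maxSteps, fwd);
    walk(f, dirs, basis, coefbuf.data(), p0, dir0n, step, invT, cosAper,
         maxSteps, bwd);
    int nb = bwd.size() / 3, nf = fwd.size() / 3;
    int npts = nb + 1 + nf;
    if (npts < 2) continue;
    double len = step * (npts - 1);
    if (len < minLen || len > maxLen) continue;
    NumericMatrix sl(npts, 3);
    for (int i = 0; i < nb; ++i) { // backward points, reversed
      int r = nb - 1 - i;
      sl(i, 0) = bwd[3 * r]; sl(i, 1) = bwd[3 * r + 1];
      sl(i, 2) = bwd[3 * r + 2];
    }
    sl(nb, 0) = p0[0]; sl(nb, 1) = p0[1]; sl(nb, 2) = p0[2];
    for (int i = 0; i < nf; ++i) {
      sl(nb + 1 + i, 0) = fwd[3 * i]; sl(nb + 1 + i, 1) = fwd[3 * i + 1];
      sl(nb + 1 + i, 2) = fwd[3 * i + 2];
    }
    out.push_back(sl);
    kept.push_back(s + 1);
  }
  return List::create(_["streamlines"] = out, _["seedIndex"] = wrap(kept));
}
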