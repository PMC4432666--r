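#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Deterministic FACT streamline propagation.
//
// Coordinates are "voxel-mm": world = (index + 0.5) * voxel_size, i.e. the
// centre of voxel (i,j,k) sits at ((i+0.5)*vx, (j+0.5)*vy, (k+0.5)*vz),
// matching the TrackVis convention. Directions are trilinearly interpolated
// from the principal-eigenvector field with per-corner sign alignment to the
// incoming direction (eigenvectors are line fields: v and -v are the same
// orientation). Propagation stops on leaving the volume, FA below fa_stop,
// turning angle above angle_stop, or a degenerate interpolated direction
// (includes the exact 90-degree flip, where the aligned dot product is 0).

struct Field {
  const double* evec;  // nx*ny*nz*3, principal eigenvector per voxel
  const double* fa;    // nx*ny*nz
  int nx, ny, nz;
  double vx, vy, vz;
  std::size_t nvox;

  inline std::size_t idx(int i, int j, int k) const {
    return (std::size_t)i + (std::size_t)nx * ((std::size_t)j + (std::size_t)ny * k);
  }
};

// Trilinear interpolation of direction (sign-aligned to ref) and FA at
// world point p. Returns false when p falls outside the interpolable region.
static bool interp_at(const Field& F, const double p[3], const double ref[3],
                      double dir_out[3], double* fa_out) {
  double f[3];
  f[0] = p[0] / F.vx - 0.5;
  f[1] = p[1] / F.vy - 0.5;
  f[2] = p[2] / F.vz - 0.5;
  const int dims[3] = {F.nx, F.ny, F.nz};
  int i0[3];
  double fr[3];
  for (int a = 0; a < 3; ++a) {
    if (f[a] < 0.0 || f[a] > dims[a] - 1.0) return false;
    i0[a] = (int)std::floor(f[a]);
    if (i0[a] > dims[a] - 2) i0[a] = dims[a] - 2;  // p exactly on the far face
    if (i0[a] < 0) i0[a] = 0;                      // degenerate single-slab axis
    fr[a] = f[a] - i0[a];
    if (dims[a] == 1) { i0[a] = 0; fr[a] = 0.0; }
  }
  double acc[3] = {0.0, 0.0, 0.0};
  double faacc = 0.0;
  for (int dz = 0; dz < 2; ++dz) {
    const int k = (F.nz == 1) ? 0 : i0[2] + dz;
    const double wz = dz ? fr[2] : 1.0 - fr[2];
    if (wz == 0.0) continue;
    for (int dy = 0; dy < 2; ++dy) {
      const int j = (F.ny == 1) ? 0 : i0[1] + dy;
      const double wy = dy ? fr[1] : 1.0 - fr[1];
      if (wy == 0.0) continue;
      for (int dx = 0; dx < 2; ++dx) {
        const int i = (F.nx == 1) ? 0 : i0[0] + dx;
        const double wx = dx ? fr[0] : 1.0 - fr[0];
        if (wx == 0.0) continue;
        const double w = wx * wy * wz;
        const std::size_t id = F.idx(i, j, k);
        double v0 = F.evec[id];
        double v1 = F.evec[id + F.nvox];
        double v2 = F.evec[id + 2 * F.nvox];
        if (!std::isfinite(v0) || !std::isfinite(v1) || !std::isfinite(v2)) {
          v0 = v1 = v2 = 0.0;
        }
        const double d = v0 * ref[0] + v1 * ref[1] + v2 * ref[2];
        double s;
        if (d < 0.0) s = -w;
        else if (d > 0.0) s = w;
        else {
          // exactly orthogonal: pick the vector's canonical orientation so
          // the blend is invariant to a global sign flip of the line field
          const double c = (v0 != 0.0) ? v0 : ((v1 != 0.0) ? v1 : v2);
          s = (c < 0.0) ? -w : w;
        }
        acc[0] += s * v0;
        acc[1] += s * v1;
        acc[2] += s * v2;
        double fav = F.fa[id];
        if (!std::isfinite(fav)) fav = 0.0;
        faacc += w * fav;
      }
    }
  }
  const double nrm = std::sqrt(acc[0] * acc[0] + acc[1] * acc[1] + acc[2] * acc[2]);
  if (nrm < 1e-12) return false;
  dir_out[0] = acc[0] / nrm;
  dir_out[1] = acc[1] / nrm;
  dir_out[2] = acc[2] / nrm;
  *fa_out = faacc;
  return true;
}

// Propagate one half-track from seed position p0 along d0; appends points
// (excluding the seed itself) to pts.
static void propagate(const Field& F, const double p0[3], const double d0[3],
                      double step, double fa_stop, double cos_stop,
                      int max_steps, std::vector<double>& pts) {
  double p[3] = {p0[0], p0[1], p0[2]};
  double d[3] = {d0[0], d0[1], d0[2]};
  for (int s = 0; s < max_steps; ++s) {
    double np[3] = {p[0] + step * d[0], p[1] + step * d[1], p[2] + step * d[2]};
    double nd[3], fav;
    if (!interp_at(F, np, d, nd, &fav)) break;
    if (fav < fa_stop) break;
    const double dot = nd[0] * d[0] + nd[1] * d[1] + nd[2] * d[2];
    if (dot < cos_stop) break;  // turning too sharply (dot<=0 at >=90 deg)
    pts.push_back(np[0]); pts.push_back(np[1]); pts.push_back(np[2]);
    p[0] = np[0]; p[1] = np[1]; p[2] = np[2];
    d[0] = nd[0]; d[1] = nd[1]; d[2] = nd[2];
  }
}

// [[Rcpp::export]]
List fact_track_cpp(NumericVector evec, NumericVector fa, IntegerVector dim,
                    NumericVector voxel_size, IntegerMatrix seeds,
                    double fa_stop, double angle_stop_deg, double step,
                    int max_steps) {
  Field F;
  F.nx = dim[0]; F.ny = dim[1]; F.nz = dim[2];
  F.vx = voxel_size[0]; F.vy = voxel_size[1]; F.vz = voxel_size[2];
  F.nvox = (std::size_t)F.nx * F.ny * F.nz;
  if ((std::size_t)evec.size() != 3 * F.nvox) stop("eigenvector field size mismatch");
  if ((std::size_t)fa.size() != F.nvox) stop("FA volume size mismatch");
  F.evec = evec.begin();
  F.fa = fa.begin();
  const double cos_stop = std::cos(angle_stop_deg * M_PI / 180.0);

  List out(seeds.nrow());
  std::vector<double> fwd, bwd;
  for (int s = 0; s < seeds.nrow(); ++s) {
    const int i = seeds(s, 0), j = seeds(s, 1), k = seeds(s, 2);
    const std::size_t id = F.idx(i, j, k);
    double d0[3] = {F.evec[id], F.evec[id + F.nvox], F.evec[id + 2 * F.nvox]};
    const double nrm = std::sqrt(d0[0] * d0[0] + d0[1] * d0[1] + d0[2] * d0[2]);
    if (!std::isfinite(nrm) || nrm < 1e-12) { out[s] = R_NilValue; continue; }
    d0[0] /= nrm; d0[1] /= nrm; d0[2] /= nrm;
    const double p0[3] = {(i + 0.5) * F.vx, (j + 0.5) * F.vy, (k + 0.5) * F.vz};
    const double d0n[3] = {-d0[0], -d0[1], -d0[2]};
    fwd.clear(); bwd.clear();
    propagate(F, p0, d0, step, fa_stop, cos_stop, max_steps, fwd);
    propagate(F, p0, d0n, step, fa_stop, cos_stop, max_steps, bwd);
    const std::size_t nb = bwd.size() / 3, nf = fwd.size() / 3;
    const std::size_t np = nb + 1 + nf;
    if (np < 2) { out[s] = R_NilValue; continue; }
    NumericMatrix m(np, 3);
    // backward half reversed, then seed, then forward half
    for (std::size_t q = 0; q < nb; ++q) {
      const std::size_t src = nb - 1 - q;
      m(q, 0) = bwd[3 * src]; m(q, 1) = bwd[3 * src + 1]; m(q, 2) = bwd[3 * src + 2];
    }
    m(nb, 0) = p0[0]; m(nb, 1) = p0[1]; m(nb, 2) = p0[2];
    for (std::size_t q = 0; q < nf; ++q) {
      m(nb + 1 + q, 0) = fwd[3 * q]; m(nb + 1 + q, 1) = fwd[3 * q + 1];
      m(nb + 1 + q, 2) = fwd[3 * q + 2];
    }
    out[s] = m;
  }
  return out;
}
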