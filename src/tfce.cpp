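#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Threshold-free cluster enhancement of a nonnegative 3D map.
// For each voxel v, sums extent(cluster of v at height h)^E * h^H * dh over
// h = dh, 2dh, ... <= x[v]. Cluster extent is counted over voxels >= h under
// the requested lattice connectivity (6 faces, 18 +edges, 26 +corners).
// [[Rcpp::export]]
NumericVector tfce_enhance_cpp(NumericVector x, IntegerVector dims,
                               double E, double H, double dh,
                               int connectivity = 6) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  if (x.size() != n) stop("value length does not match dims");
  if (dh <= 0) stop("dh must be > 0");

  // neighbour offsets
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        if (connectivity != 6 && connectivity != 18 && connectivity != 26)
          stop("connectivity must be 6, 18, or 26");
        offs.push_back({dx, dy, dz});
      }

  double mx = 0.0;
  for (int i = 0; i < n; ++i) {
    if (x[i] < 0) stop("tfce_enhance_cpp expects a nonnegative map");
    if (x[i] > mx) mx = x[i];
  }
  NumericVector out(n);
  if (mx <= 0) return out;

  std::vector<int> label(n);
  std::vector<int> csize;
  std::vector<int> stackv;
  for (double h = dh; h <= mx + 1e-12; h += dh) {
    std::fill(label.begin(), label.end(), 0);
    csize.clear();
    csize.push_back(0); // label 0 unused
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int idx = i + nx * (j + ny * k);
          if (x[idx] < h || label[idx] != 0) continue;
          int lab = (int)csize.size();
          csize.push_back(0);
          stackv.clear();
          stackv.push_back(idx);
          label[idx] = lab;
          while (!stackv.empty()) {
            int cur = stackv.back();
            stackv.pop_back();
            csize[lab]++;
            int ci = cur % nx, cj = (cur / nx) % ny, ck = cur / (nx * ny);
            for (auto &o : offs) {
              int ni = ci + o[0], nj = cj + o[1], nk = ck + o[2];
              if (ni < 0 || ni >= nx || nj < 0 || nj >= ny || nk < 0 || nk >= nz)
                continue;
              int nidx = ni + nx * (nj + ny * nk);
              if (x[nidx] >= h && label[nidx] == 0) {
                label[nidx] = lab;
                stackv.push_back(nidx);
              }
            }
          }
        }
    double hh = std::pow(h, H) * dh;
    for (int idx = 0; idx < n; ++idx) {
      if (label[idx] != 0)
        out[idx] += std::pow((double)csize[label[idx]], E) * hh;
    }
  }
  return out;
}
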