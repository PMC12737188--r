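#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Linear index convention matches R arrays dim = c(nz, ny, nx):
// idx = z + nz * (y + ny * x), all 0-based here.

static void neighbor_offsets(int connectivity,
                             std::vector<int> &dz,
                             std::vector<int> &dy,
                             std::vector<int> &dx) {
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int ord = std::abs(a) + std::abs(b) + std::abs(c);
        if (ord == 0) continue;
        if (connectivity == 6 && ord > 1) continue;
        if (connectivity == 18 && ord > 2) continue;
        dz.push_back(a); dy.push_back(b); dx.push_back(c);
      }
}

// [[Rcpp::export]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dims,
                           int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = mask.size();
  if (n != (R_xlen_t)nz * ny * nx) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  std::vector<int> dz, dy, dx;
  neighbor_offsets(connectivity, dz, dy, dx);
  const int nn = (int)dz.size();

  IntegerVector labels(n, 0);
  std::vector<int> stack;
  int next = 0;

  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++next;
    labels[s] = next;
    stack.clear();
    stack.push_back((int)s);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int z = cur % nz;
      int rest = cur / nz;
      int y = rest % ny;
      int x = rest / ny;
      for (int k = 0; k < nn; ++k) {
        int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        int idx = zz + nz * (yy + ny * xx);
        if (mask[idx] && labels[idx] == 0) {
          labels[idx] = next;
          stack.push_back(idx);
        }
      }
    }
  }
  return labels;
}

// Fill enclosed background: flood the complement from the volume border with
// 6-connectivity (the complement of 26-connected foreground); anything not
// reached is a hole and becomes foreground.
// [[Rcpp::export]]
LogicalVector fill_holes_cpp(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = mask.size();
  if (n != (R_xlen_t)nz * ny * nx) stop("mask length does not match dims");

  std::vector<char> outside(n, 0);
  std::vector<int> stack;

  // seed with all border background voxels
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        if (z != 0 && z != nz - 1 && y != 0 && y != ny - 1 &&
            x != 0 && x != nx - 1)
          continue;
        int idx = z + nz * (y + ny * x);
        if (!mask[idx] && !outside[idx]) {
          outside[idx] = 1;
          stack.push_back(idx);
        }
      }

  const int off_dz[6] = {1, -1, 0, 0, 0, 0};
  const int off_dy[6] = {0, 0, 1, -1, 0, 0};
  const int off_dx[6] = {0, 0, 0, 0, 1, -1};

  while (!stack.empty()) {
    int cur = stack.back(); stack.pop_back();
    int z = cur % nz;
    int rest = cur / nz;
    int y = rest % ny;
    int x = rest / ny;
    for (int k = 0; k < 6; ++k) {
      int zz = z + off_dz[k], yy = y + off_dy[k], xx = x + off_dx[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      int idx = zz + nz * (yy + ny * xx);
      if (!mask[idx] && !outside[idx]) {
        outside[idx] = 1;
        stack.push_back(idx);
      }
    }
  }

  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] || !outside[i];
  return out;
}
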