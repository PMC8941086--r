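// Hot loops of the ALE machinery: Gaussian kernel placement into the masked
// grid, connected-component labelling of suprathreshold voxels, and the
// foci-shuffling permutation null (max cluster size per permutation plus an
// optional pooled voxel-value histogram).  Everything uses R's RNG so that
// set.seed() in R makes permutation results reproducible.

#include <Rcpp.h>
#include <array>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Place one kernel per focus, combining across foci by voxel-wise maximum.
// foci: n x 3 (0-based voxel indices, may be out of volume); off: k x 3
// integer voxel offsets; mask_pos: length prod(dim), 1-based position of
// each volume voxel in the mask vector (0 = outside mask).
static void place_kernels_impl(const int* fx, const int* fy, const int* fz,
                               int n_foci, const int* ox, const int* oy,
                               const int* oz, const double* val, int k,
                               const int* dim, const int* mask_pos,
                               double* ma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  for (int f = 0; f < n_foci; ++f) {
    const int cx = fx[f], cy = fy[f], cz = fz[f];
    for (int j = 0; j < k; ++j) {
      const int x = cx + ox[j];
      if (x < 0 || x >= nx) continue;
      const int y = cy + oy[j];
      if (y < 0 || y >= ny) continue;
      const int z = cz + oz[j];
      if (z < 0 || z >= nz) continue;
      const int pos = mask_pos[x + (size_t)nx * (y + (size_t)ny * z)];
      if (pos > 0 && val[j] > ma[pos - 1]) ma[pos - 1] = val[j];
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_ma_map(IntegerMatrix foci, IntegerMatrix off,
                         NumericVector val, IntegerVector dim,
                         IntegerVector mask_pos, int n_mask) {
  NumericVector ma(n_mask);
  std::vector<int> fx(foci.nrow()), fy(foci.nrow()), fz(foci.nrow());
  for (int i = 0; i < foci.nrow(); ++i) {
    fx[i] = foci(i, 0); fy[i] = foci(i, 1); fz[i] = foci(i, 2);
  }
  std::vector<int> ox(off.nrow()), oy(off.nrow()), oz(off.nrow());
  for (int j = 0; j < off.nrow(); ++j) {
    ox[j] = off(j, 0); oy[j] = off(j, 1); oz[j] = off(j, 2);
  }
  place_kernels_impl(fx.data(), fy.data(), fz.data(), foci.nrow(),
                     ox.data(), oy.data(), oz.data(), REAL(val), off.nrow(),
                     INTEGER(dim), INTEGER(mask_pos), REAL(ma));
  return ma;
}

static std::vector<std::array<int, 3>> neighbour_offsets(int connectivity) {
  std::vector<std::array<int, 3>> out;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        const int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        out.push_back({dx, dy, dz});
      }
  return out;
}

// Label connected components of a voxel set given by 0-based linear volume
// indices.  Returns 1-based component labels parallel to `supra`.
static std::vector<int> label_components_impl(const std::vector<int>& supra,
                                              const int* dim,
                                              int connectivity) {
  const int nx = dim[0], ny = dim[1];
  std::unordered_map<int, int> where;
  where.reserve(supra.size() * 2);
  for (size_t i = 0; i < supra.size(); ++i) where[supra[i]] = (int)i;
  const auto nb = neighbour_offsets(connectivity);
  std::vector<int> labels(supra.size(), 0);
  std::vector<int> stack;
  int next = 0;
  for (size_t i = 0; i < supra.size(); ++i) {
    if (labels[i]) continue;
    ++next;
    labels[i] = next;
    stack.push_back((int)i);
    while (!stack.empty()) {
      const int cur = stack.back();
      stack.pop_back();
      const int lin = supra[cur];
      const int z = lin / (nx * ny);
      const int rem = lin - z * nx * ny;
      const int y = rem / nx;
      const int x = rem - y * nx;
      for (const auto& d : nb) {
        const int xx = x + d[0], yy = y + d[1], zz = z + d[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 ||
            zz >= dim[2])
          continue;
        const auto it = where.find(xx + nx * (yy + ny * zz));
        if (it == where.end() || labels[it->second]) continue;
        labels[it->second] = next;
        stack.push_back(it->second);
      }
    }
  }
  return labels;
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector supra_lin, IntegerVector dim,
                                   int connectivity) {
  std::vector<int> supra(supra_lin.begin(), supra_lin.end());
  std::vector<int> lab = label_components_impl(supra, INTEGER(dim),
                                               connectivity);
  return IntegerVector(lab.begin(), lab.end());
}

// Foci-shuffling permutation null.  Each pseudo-experiment keeps its focus
// count and kernel; focus locations are redrawn uniformly over in-mask
// voxel centres.  Records the max suprathreshold cluster size (voxels) per
// permutation at the fixed ALE cutoff and, if hist_nbins > 0, pools all
// in-mask ALE values into a histogram (bin = floor(ale / hist_bin), capped).
// [[Rcpp::export]]
List cpp_ale_permutation(int n_perm, IntegerVector n_foci, List kern_off,
                         List kern_val, IntegerVector dim,
                         IntegerVector mask_pos, IntegerVector mask_lin0,
                         double ale_cutoff, int connectivity, int hist_nbins,
                         double hist_bin) {
  const int n_exp = n_foci.size();
  const int n_mask = mask_lin0.size();
  const int nx = dim[0], ny = dim[1];

  // unpack kernels once
  std::vector<std::vector<int>> kox(n_exp), koy(n_exp), koz(n_exp);
  std::vector<std::vector<double>> kval(n_exp);
  for (int e = 0; e < n_exp; ++e) {
    IntegerMatrix off = kern_off[e];
    NumericVector val = kern_val[e];
    kox[e].resize(off.nrow()); koy[e].resize(off.nrow());
    koz[e].resize(off.nrow()); kval[e].assign(val.begin(), val.end());
    for (int j = 0; j < off.nrow(); ++j) {
      kox[e][j] = off(j, 0); koy[e][j] = off(j, 1); koz[e][j] = off(j, 2);
    }
  }

  IntegerVector max_size(n_perm);
  NumericVector hist(std::max(hist_nbins, 1));
  std::vector<double> ma(n_mask), one_minus(n_mask);
  std::vector<int> fx, fy, fz, supra;
  RNGScope scope;

  for (int p = 0; p < n_perm; ++p) {
    std::fill(one_minus.begin(), one_minus.end(), 1.0);
    for (int e = 0; e < n_exp; ++e) {
      std::fill(ma.begin(), ma.end(), 0.0);
      const int nf = n_foci[e];
      fx.assign(nf, 0); fy.assign(nf, 0); fz.assign(nf, 0);
      for (int f = 0; f < nf; ++f) {
        int u = (int)(unif_rand() * n_mask);
        if (u >= n_mask) u = n_mask - 1;
        const int lin = mask_lin0[u];
        const int z = lin / (nx * ny);
        const int rem = lin - z * nx * ny;
        fz[f] = z; fy[f] = rem / nx; fx[f] = rem - (rem / nx) * nx;
      }
      place_kernels_impl(fx.data(), fy.data(), fz.data(), nf, kox[e].data(),
                         koy[e].data(), koz[e].data(), kval[e].data(),
                         (int)kval[e].size(), INTEGER(dim), INTEGER(mask_pos),
                         ma.data());
      for (int i = 0; i < n_mask; ++i) one_minus[i] *= (1.0 - ma[i]);
    }
    supra.clear();
    for (int i = 0; i < n_mask; ++i) {
      const double ale = 1.0 - one_minus[i];
      if (hist_nbins > 0) {
        int b = (int)(ale / hist_bin);
        if (b >= hist_nbins) b = hist_nbins - 1;
        hist[b] += 1.0;
      }
      if (ale >= ale_cutoff) supra.push_back(mask_lin0[i]);
    }
    int best = 0;
    if (!supra.empty()) {
      std::vector<int> lab = label_components_impl(supra, INTEGER(dim),
                                                   connectivity);
      std::unordered_map<int, int> sizes;
      for (int l : lab) ++sizes[l];
      for (const auto& kv : sizes) best = std::max(best, kv.second);
    }
    max_size[p] = best;
  }
  return List::create(_["max_size"] = max_size, _["hist"] = hist);
}

// One union-convolution step of the analytic voxel null: combine a null
// support (nv, np) with an experiment MA histogram (ev, ep) under
// u = a + b - a*b, accumulating probability mass into bins of `bin_width`.
// Returns the occupied (value, prob) support, values at bin left edges.
// [[Rcpp::export]]
List cpp_union_convolve(NumericVector nv, NumericVector np, NumericVector ev,
                        NumericVector ep, double bin_width) {
  const int max_bins = (int)(1.0 / bin_width) + 2;
  std::vector<double> dense(max_bins, 0.0);
  for (int j = 0; j < ev.size(); ++j) {
    const double b = ev[j], pb = ep[j];
    for (int i = 0; i < nv.size(); ++i) {
      const double u = nv[i] + b - nv[i] * b;
      int idx = (int)(u / bin_width + 1e-9);
      if (idx >= max_bins) idx = max_bins - 1;
      dense[idx] += np[i] * pb;
    }
  }
  std::vector<double> v, p;
  for (int i = 0; i < max_bins; ++i)
    if (dense[i] > 0) {
      v.push_back(i * bin_width);
      p.push_back(dense[i]);
    }
  return List::create(_["v"] = NumericVector(v.begin(), v.end()),
                      _["p"] = NumericVector(p.begin(), p.end()));
}
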