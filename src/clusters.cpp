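// Connected-component labeling of supra-threshold voxels and the
// Freedman-Lane permutation null of maximum cluster extent. The inner
// permutation loop is C++ because building a 1000-draw max-extent null per
// contrast is the hot path of the group analysis.

#include <RcppArmadillo.h>
#include <vector>
#include <array>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static std::vector<std::array<int, 3>> neighbor_offsets(int connectivity) {
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        offs.push_back({dx, dy, dz});
      }
  return offs;
}

static void flood(const std::vector<char>& supra, std::vector<int>& labels,
                  int start, int lab, int nx, int ny, int nz,
                  const std::vector<std::array<int, 3>>& offs,
                  std::vector<int>& stack) {
  stack.clear();
  stack.push_back(start);
  labels[start] = lab;
  while (!stack.empty()) {
    int c = stack.back(); stack.pop_back();
    int x = c % nx, y = (c / nx) % ny, z = c / (nx * ny);
    for (const auto& o : offs) {
      int xx = x + o[0], yy = y + o[1], zz = z + o[2];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      int n = xx + nx * (yy + ny * zz);
      if (supra[n] && labels[n] == 0) {
        labels[n] = lab;
        stack.push_back(n);
      }
    }
  }
}

// [[Rcpp::export]]
IntegerVector label_clusters_cpp(LogicalVector mask, IntegerVector dims,
                                 int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nv = nx * ny * nz;
  if (mask.size() != nv) stop("mask length does not match dims");
  std::vector<char> supra(nv);
  for (int i = 0; i < nv; ++i) supra[i] = mask[i] == TRUE;
  std::vector<int> labels(nv, 0), stack;
  auto offs = neighbor_offsets(connectivity);
  int lab = 0;
  for (int i = 0; i < nv; ++i)
    if (supra[i] && labels[i] == 0) flood(supra, labels, i, ++lab, nx, ny, nz,
                                          offs, stack);
  return IntegerVector(labels.begin(), labels.end());
}

static int max_extent(const std::vector<char>& supra, int nx, int ny, int nz,
                      const std::vector<std::array<int, 3>>& offs,
                      std::vector<int>& labels, std::vector<int>& stack) {
  const int nv = nx * ny * nz;
  std::fill(labels.begin(), labels.end(), 0);
  int lab = 0, best = 0;
  for (int i = 0; i < nv; ++i) {
    if (!supra[i] || labels[i] != 0) continue;
    ++lab;
    int count = 0;
    stack.clear();
    stack.push_back(i);
    labels[i] = lab;
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      ++count;
      int x = c % nx, y = (c / nx) % ny, z = c / (nx * ny);
      for (const auto& o : offs) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int n = xx + nx * (yy + ny * zz);
        if (supra[n] && labels[n] == 0) {
          labels[n] = lab;
          stack.push_back(n);
        }
      }
    }
    if (count > best) best = count;
  }
  return best;
}

// Freedman-Lane permutation null of the maximum cluster extent.
// fit_red, res_red: n x V fitted values and residuals of the reduced model.
// Qfull, Qred: orthonormal column bases (n x p) of the full/reduced designs.
// For t statistics (is_F = false): avec is the pseudoinverse row giving the
// tested coefficient, c_xtx_c the corresponding diagonal of (X'X)^-1; the
// forming rule is t >= thresh (one-sided) or |t| >= thresh.
// For F statistics: q_diff extra columns, forming rule F >= thresh.
// perms: n x n_perm matrix of 0-based row permutations.
// [[Rcpp::export]]
IntegerVector perm_max_extent_cpp(const arma::mat& fit_red,
                                  const arma::mat& res_red,
                                  const arma::mat& Qfull,
                                  const arma::mat& Qred,
                                  const arma::rowvec& avec,
                                  double c_xtx_c, int df_full, int q_diff,
                                  double stat_thresh, bool is_F,
                                  bool one_sided, IntegerVector dims,
                                  int connectivity, const arma::umat& perms) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nv = nx * ny * nz;
  const arma::uword n = fit_red.n_rows;
  if ((int)fit_red.n_cols != nv) stop("data column count does not match dims");
  const int n_perm = perms.n_cols;
  auto offs = neighbor_offsets(connectivity);
  std::vector<int> labels(nv), stack;
  std::vector<char> supra(nv);
  IntegerVector out(n_perm);
  arma::mat Yp(n, nv);
  for (int j = 0; j < n_perm; ++j) {
    const arma::uvec idx = perms.col(j);
    Yp = fit_red + res_red.rows(idx);
    arma::rowvec tot = arma::sum(arma::square(Yp), 0);
    arma::mat Qy = Qfull.t() * Yp;
    arma::rowvec rss_full = tot - arma::sum(arma::square(Qy), 0);
    rss_full.transform([](double v) { return v > 0 ? v : 1e-300; });
    if (is_F) {
      arma::mat Qyr = Qred.t() * Yp;
      arma::rowvec rss_red = tot - arma::sum(arma::square(Qyr), 0);
      for (int v = 0; v < nv; ++v) {
        double num = (rss_red[v] - rss_full[v]) / q_diff;
        double den = rss_full[v] / df_full;
        supra[v] = (num / den) >= stat_thresh;
      }
    } else {
      arma::rowvec est = avec * Yp;
      for (int v = 0; v < nv; ++v) {
        double se = std::sqrt(rss_full[v] / df_full * c_xtx_c);
        double t = est[v] / se;
        supra[v] = one_sided ? (t >= stat_thresh)
                             : (std::fabs(t) >= stat_thresh);
      }
    }
    out[j] = max_extent(supra, nx, ny, nz, offs, labels, stack);
    if (j % 100 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
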