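#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Robust first-order moments of a value buffer: values deviating from the
// reference mean by more than outlier_sd * reference SD are dropped, then
// population moments are computed on the survivors. Degenerate survivor sets
// (n < 2 or zero variance) yield variance/skewness/kurtosis 0 by convention.
static inline void robust_moments(const std::vector<double>& buf,
                                  double outlier_sd,
                                  bool global_ref, double gmean, double gsd,
                                  double out[4]) {
  const int n = (int) buf.size();
  double m = gmean, s = gsd;
  if (!global_ref) {
    double sum = 0.0, ss = 0.0;
    for (int i = 0; i < n; ++i) sum += buf[i];
    m = sum / n;
    for (int i = 0; i < n; ++i) { double d = buf[i] - m; ss += d * d; }
    s = std::sqrt(ss / n);
  }
  const double thr = outlier_sd * s;
  // survivor pass 1: mean
  double sum_s = 0.0; int n_s = 0;
  const bool keep_all = !R_FINITE(thr) || s == 0.0;
  for (int i = 0; i < n; ++i) {
    if (keep_all || std::fabs(buf[i] - m) <= thr) { sum_s += buf[i]; ++n_s; }
  }
  if (n_s == 0) {
    // all excluded (possible when outlier_sd < 1): keep the value closest to
    // the reference mean so the bank stays dense
    double best = buf[0], bd = std::fabs(buf[0] - m);
    for (int i = 1; i < n; ++i) {
      double d = std::fabs(buf[i] - m);
      if (d < bd) { bd = d; best = buf[i]; }
    }
    out[0] = best; out[1] = 0.0; out[2] = 0.0; out[3] = 0.0;
    return;
  }
  const double mean_s = sum_s / n_s;
  double m2 = 0.0, m3 = 0.0, m4 = 0.0;
  for (int i = 0; i < n; ++i) {
    if (keep_all || std::fabs(buf[i] - m) <= thr) {
      double d = buf[i] - mean_s, d2 = d * d;
      m2 += d2; m3 += d2 * d; m4 += d2 * d2;
    }
  }
  m2 /= n_s; m3 /= n_s; m4 /= n_s;
  out[0] = mean_s;
  if (n_s < 2 || m2 <= 0.0) {
    out[1] = 0.0; out[2] = 0.0; out[3] = 0.0;
  } else {
    out[1] = m2;
    out[2] = m3 / std::pow(m2, 1.5);
    out[3] = m4 / (m2 * m2);
  }
}

// Multiscale windowed robust moments over all masked voxels.
// vox_lin: 1-based linear indices of masked voxels, in voxel-table order.
// Returns n_vox x (4 * n_radii) matrix, moment-major (all radii of the mean
// first, then variance, skewness, kurtosis); kernels are cubes of edge 2r+1
// clipped at the grid border (spherical option restricts to |d| <= r).
// [[Rcpp::export]]
NumericMatrix cpp_feature_bank(NumericVector data, LogicalVector mask,
                               IntegerVector dim, IntegerVector vox_lin,
                               IntegerVector radii, double outlier_sd,
                               bool spherical, bool global_ref,
                               double gmean, double gsd) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nv = vox_lin.size(), nr = radii.size();
  NumericMatrix out(nv, 4 * nr);
  std::vector<double> buf;
  double mom[4];
  for (int v = 0; v < nv; ++v) {
    const int lin = vox_lin[v] - 1;
    const int i = lin % nx, j = (lin / nx) % ny, k = lin / (nx * ny);
    for (int ri = 0; ri < nr; ++ri) {
      const int r = radii[ri];
      const int i0 = std::max(0, i - r), i1 = std::min(nx - 1, i + r);
      const int j0 = std::max(0, j - r), j1 = std::min(ny - 1, j + r);
      const int k0 = std::max(0, k - r), k1 = std::min(nz - 1, k + r);
      buf.clear();
      for (int kk = k0; kk <= k1; ++kk) {
        for (int jj = j0; jj <= j1; ++jj) {
          const int base = (kk * ny + jj) * nx;
          for (int ii = i0; ii <= i1; ++ii) {
            if (!mask[base + ii]) continue;
            if (spherical) {
              const int di = ii - i, dj = jj - j, dk = kk - k;
              if (di * di + dj * dj + dk * dk > r * r) continue;
            }
            buf.push_back(data[base + ii]);
          }
        }
      }
      robust_moments(buf, outlier_sd, global_ref, gmean, gsd, mom);
      for (int mci = 0; mci < 4; ++mci) out(v, mci * nr + ri) = mom[mci];
    }
  }
  return out;
}

// Masked intensities in the cubic (or spherical) window around one voxel.
// [[Rcpp::export]]
NumericVector cpp_neighborhood(NumericVector data, LogicalVector mask,
                               IntegerVector dim, int lin1, int r,
                               bool spherical) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int lin = lin1 - 1;
  const int i = lin % nx, j = (lin / nx) % ny, k = lin / (nx * ny);
  std::vector<double> buf;
  for (int kk = std::max(0, k - r); kk <= std::min(nz - 1, k + r); ++kk)
    for (int jj = std::max(0, j - r); jj <= std::min(ny - 1, j + r); ++jj) {
      const int base = (kk * ny + jj) * nx;
      for (int ii = std::max(0, i - r); ii <= std::min(nx - 1, i + r); ++ii) {
        if (!mask[base + ii]) continue;
        if (spherical) {
          const int di = ii - i, dj = jj - j, dk = kk - k;
          if (di * di + dj * dj + dk * dk > r * r) continue;
        }
        buf.push_back(data[base + ii]);
      }
    }
  return wrap(buf);
}

// k-th smallest entry of each row of a distance matrix, for several k at
// once (row includes the self-distance 0). Used to set per-voxel kernel
// truncation radii for the k-nearest-neighbour smoothers.
// [[Rcpp::export]]
NumericMatrix cpp_knn_threshold(NumericMatrix D, IntegerVector ks) {
  const int n = D.nrow(), nk = ks.size();
  NumericMatrix out(n, nk);
  std::vector<double> row((size_t) n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) row[j] = D(i, j);
    // ks is ascending: successive nth_element on the remaining tail
    int done = 0;
    for (int q = 0; q < nk; ++q) {
      int k = ks[q] - 1;  // 0-based order statistic
      if (k >= n) k = n - 1;
      std::nth_element(row.begin() + done, row.begin() + k, row.end());
      out(i, q) = row[k];
      done = k;
    }
  }
  return out;
}

// Binned semivariances for every column of a map matrix over one fixed pair
// sample: gamma[b, s] = mean over pairs in bin b of 0.5 * (y_i - y_j)^2.
// Empty bins give NaN.
// [[Rcpp::export]]
NumericMatrix cpp_batch_variogram(NumericMatrix Y, IntegerVector pi,
                                  IntegerVector pj, IntegerVector bin,
                                  int nbins) {
  const int m = pi.size(), S = Y.ncol();
  NumericMatrix out(nbins, S);
  std::vector<int> cnt(nbins, 0);
  for (int p = 0; p < m; ++p) cnt[bin[p] - 1]++;
  for (int s = 0; s < S; ++s) {
    const double* y = &Y(0, s);
    std::vector<double> acc(nbins, 0.0);
    for (int p = 0; p < m; ++p) {
      const double d = y[pi[p] - 1] - y[pj[p] - 1];
      acc[bin[p] - 1] += 0.5 * d * d;
    }
    for (int b = 0; b < nbins; ++b)
      out(b, s) = cnt[b] > 0 ? acc[b] / cnt[b] : R_NaN;
  }
  return out;
}

// dense kNN smoothing kernel: distance decay over the per-row truncation
// radius dk (k-th neighbour distance), zero beyond it, rows normalized.
// Single fused pass to keep large-n kernel construction cheap.
// [[Rcpp::export]]
NumericMatrix cpp_build_kernel(NumericMatrix D, NumericVector dk,
                               bool gaussian) {
  const int n = D.nrow();
  NumericMatrix W(n, n);
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < n; ++i) {
      const double dki = std::max(dk[i], 1e-300);
      const double d = D(i, j);
      if (d > dki) continue;
      const double u = d / dki;
      W(i, j) = gaussian ? std::exp(-u * u) : std::exp(-u);
    }
  }
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) s += W(i, j);
    if (s > 0) for (int j = 0; j < n; ++j) W(i, j) /= s;
  }
  return W;
}
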