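// Gray-level texture matrix builders for ROI-restricted 3D radiomics.
// All functions take an integer 3D label array (dim attribute set) with
// 0 marking voxels outside the ROI and labels 1..ng inside.

#include <Rcpp.h>
#include <vector>
#include <cstdlib>
using namespace Rcpp;

static inline int idx3(int i, int j, int k, const int* d) {
  return i + d[0] * (j + d[1] * k);
}

// the 13 unique direction offsets (half of the 26-neighbourhood)
static const int NDIR = 13;
static const int DIRS[13][3] = {
  {1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
  {0,1,1},{0,1,-1},{1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}};

// [[Rcpp::export]]
NumericMatrix glcm_counts(IntegerVector labels, int ng) {
  IntegerVector dim = labels.attr("dim");
  int d[3] = {dim[0], dim[1], dim[2]};
  NumericMatrix P(ng, ng);
  for (int dd = 0; dd < NDIR; ++dd) {
    int dx = DIRS[dd][0], dy = DIRS[dd][1], dz = DIRS[dd][2];
    for (int k = 0; k < d[2]; ++k)
      for (int j = 0; j < d[1]; ++j)
        for (int i = 0; i < d[0]; ++i) {
          int a = labels[idx3(i, j, k, d)];
          if (a == 0) continue;
          int i2 = i + dx, j2 = j + dy, k2 = k + dz;
          if (i2 < 0 || i2 >= d[0] || j2 < 0 || j2 >= d[1] ||
              k2 < 0 || k2 >= d[2]) continue;
          int b = labels[idx3(i2, j2, k2, d)];
          if (b == 0) continue;
          P(a - 1, b - 1) += 1.0;   // symmetric accumulation
          P(b - 1, a - 1) += 1.0;
        }
  }
  return P;
}

// [[Rcpp::export]]
NumericMatrix glrlm_counts(IntegerVector labels, int ng) {
  IntegerVector dim = labels.attr("dim");
  int d[3] = {dim[0], dim[1], dim[2]};
  int maxlen = std::max(std::max(d[0], d[1]), d[2]);
  NumericMatrix R(ng, maxlen);
  for (int dd = 0; dd < NDIR; ++dd) {
    int dx = DIRS[dd][0], dy = DIRS[dd][1], dz = DIRS[dd][2];
    for (int k = 0; k < d[2]; ++k)
      for (int j = 0; j < d[1]; ++j)
        for (int i = 0; i < d[0]; ++i) {
          int a = labels[idx3(i, j, k, d)];
          if (a == 0) continue;
          // run start: predecessor outside grid/ROI or different level
          int ip = i - dx, jp = j - dy, kp = k - dz;
          if (ip >= 0 && ip < d[0] && jp >= 0 && jp < d[1] &&
              kp >= 0 && kp < d[2] &&
              labels[idx3(ip, jp, kp, d)] == a) continue;
          int len = 1;
          int i2 = i + dx, j2 = j + dy, k2 = k + dz;
          while (i2 >= 0 && i2 < d[0] && j2 >= 0 && j2 < d[1] &&
                 k2 >= 0 && k2 < d[2] &&
                 labels[idx3(i2, j2, k2, d)] == a) {
            ++len; i2 += dx; j2 += dy; k2 += dz;
          }
          R(a - 1, len - 1) += 1.0;
        }
  }
  return R;
}

// zones: 26-connected components of constant gray level
// [[Rcpp::export]]
NumericMatrix glszm_counts(IntegerVector labels, int ng) {
  IntegerVector dim = labels.attr("dim");
  int d[3] = {dim[0], dim[1], dim[2]};
  int n = d[0] * d[1] * d[2];
  std::vector<char> seen(n, 0);
  std::vector<int> zone_sizes;
  std::vector<int> zone_levels;
  std::vector<int> stack;
  for (int v = 0; v < n; ++v) {
    if (seen[v] || labels[v] == 0) continue;
    int lev = labels[v];
    int size = 0;
    stack.clear(); stack.push_back(v); seen[v] = 1;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      ++size;
      int ci = cur % d[0], cj = (cur / d[0]) % d[1], ck = cur / (d[0] * d[1]);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int i2 = ci + dx, j2 = cj + dy, k2 = ck + dz;
            if (i2 < 0 || i2 >= d[0] || j2 < 0 || j2 >= d[1] ||
                k2 < 0 || k2 >= d[2]) continue;
            int w = idx3(i2, j2, k2, d);
            if (!seen[w] && labels[w] == lev) { seen[w] = 1; stack.push_back(w); }
          }
    }
    zone_sizes.push_back(size);
    zone_levels.push_back(lev);
  }
  int maxsz = 1;
  for (size_t z = 0; z < zone_sizes.size(); ++z)
    if (zone_sizes[z] > maxsz) maxsz = zone_sizes[z];
  NumericMatrix S(ng, maxsz);
  for (size_t z = 0; z < zone_sizes.size(); ++z)
    S(zone_levels[z] - 1, zone_sizes[z] - 1) += 1.0;
  return S;
}

// dependence: number of 26-neighbours (inside ROI) within alpha of the
// centre level; matrix column = dependence count + 1 (centre included)
// [[Rcpp::export]]
NumericMatrix gldm_counts(IntegerVector labels, int ng, int alpha) {
  IntegerVector dim = labels.attr("dim");
  int d[3] = {dim[0], dim[1], dim[2]};
  NumericMatrix P(ng, 27);
  for (int k = 0; k < d[2]; ++k)
    for (int j = 0; j < d[1]; ++j)
      for (int i = 0; i < d[0]; ++i) {
        int a = labels[idx3(i, j, k, d)];
        if (a == 0) continue;
        int dep = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int i2 = i + dx, j2 = j + dy, k2 = k + dz;
              if (i2 < 0 || i2 >= d[0] || j2 < 0 || j2 >= d[1] ||
                  k2 < 0 || k2 >= d[2]) continue;
              int b = labels[idx3(i2, j2, k2, d)];
              if (b == 0) continue;
              if (std::abs(b - a) <= alpha) ++dep;
            }
        P(a - 1, dep) += 1.0;   // column dep+1 in R indexing
      }
  return P;
}

// per-level counts n_i and absolute deviations s_i from the mean level of
// the valid 26-neighbourhood
// [[Rcpp::export]]
NumericMatrix ngtdm_counts(IntegerVector labels, int ng) {
  IntegerVector dim = labels.attr("dim");
  int d[3] = {dim[0], dim[1], dim[2]};
  NumericMatrix out(ng, 2);   // col 1: n_i, col 2: s_i
  for (int k = 0; k < d[2]; ++k)
    for (int j = 0; j < d[1]; ++j)
      for (int i = 0; i < d[0]; ++i) {
        int a = labels[idx3(i, j, k, d)];
        if (a == 0) continue;
        double sum = 0; int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int i2 = i + dx, j2 = j + dy, k2 = k + dz;
              if (i2 < 0 || i2 >= d[0] || j2 < 0 || j2 >= d[1] ||
                  k2 < 0 || k2 >= d[2]) continue;
              int b = labels[idx3(i2, j2, k2, d)];
              if (b == 0) continue;
              sum += b; ++cnt;
            }
        out(a - 1, 0) += 1.0;
        if (cnt > 0) out(a - 1, 1) += std::fabs(a - sum / cnt);
      }
  return out;
}
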