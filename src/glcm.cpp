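#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Moving-window GLCM Haralick features for one quantized band plane.
//
// levels: H x W integer plane, gray levels 0..n_levels-1, NA = masked.
// window: window side in pixels. Odd windows are centred; even windows
//   anchor the centre at the top-left pixel of the central 2 x 2.
// offsets: k x 2 matrix of (dx, dy) displacements at distance 1.
// symmetric: count each pair in both orders.
//
// Per window: pairs are counted per offset over pixel pairs lying fully
// inside the (border-truncated) window with both pixels unmasked; each
// offset's matrix is normalized to sum 1 and the normalized matrices are
// averaged over the offsets that produced at least one pair. The eight
// features (MEAN, VAR, HOM, CON, DIS, ENT, SEC, COR) are evaluated on the
// averaged matrix. Centres that are masked, or whose window yields no
// pair, get NA.
// [[Rcpp::export]]
NumericVector glcm_texture_map_cpp(IntegerMatrix levels, int n_levels,
                                   int window, IntegerMatrix offsets,
                                   bool symmetric) {
  const int H = levels.nrow(), W = levels.ncol();
  const int n_off = offsets.nrow();
  const int L = n_levels;
  NumericVector out(H * W * 8, NA_REAL);
  out.attr("dim") = IntegerVector::create(H, W, 8);

  int up, down;
  if (window % 2 == 1) {
    up = down = (window - 1) / 2;
  } else {
    up = window / 2 - 1;
    down = window / 2;
  }

  std::vector<double> buf(L * L, 0.0);
  std::vector<int> touched;
  std::vector<int> pair_idx;          // flattened per-offset pair cells
  std::vector<int> off_start, off_tot;
  touched.reserve(256);
  pair_idx.reserve(1024);

  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (levels(r, c) == NA_INTEGER) continue;
      const int r0 = std::max(0, r - up), r1 = std::min(H - 1, r + down);
      const int c0 = std::max(0, c - up), c1 = std::min(W - 1, c + down);

      pair_idx.clear();
      off_start.clear();
      off_tot.clear();
      int n_used = 0;
      for (int o = 0; o < n_off; ++o) {
        const int dx = offsets(o, 0), dy = offsets(o, 1);
        off_start.push_back((int)pair_idx.size());
        int tot = 0;
        for (int i = r0; i <= r1; ++i) {
          const int i2 = i + dy;
          if (i2 < r0 || i2 > r1) continue;
          for (int j = c0; j <= c1; ++j) {
            const int j2 = j + dx;
            if (j2 < c0 || j2 > c1) continue;
            const int a = levels(i, j), b = levels(i2, j2);
            if (a == NA_INTEGER || b == NA_INTEGER) continue;
            pair_idx.push_back(a + L * b);
            ++tot;
            if (symmetric) {
              pair_idx.push_back(b + L * a);
              ++tot;
            }
          }
        }
        off_tot.push_back(tot);
        if (tot > 0) ++n_used;
      }
      if (n_used == 0) continue;

      touched.clear();
      for (int o = 0; o < n_off; ++o) {
        if (off_tot[o] == 0) continue;
        const double w = 1.0 / ((double)off_tot[o] * n_used);
        const int s = off_start[o];
        const int e = (o + 1 < n_off) ? off_start[o + 1] : (int)pair_idx.size();
        for (int k = s; k < e; ++k) {
          const int idx = pair_idx[k];
          if (buf[idx] == 0.0) touched.push_back(idx);
          buf[idx] += w;
        }
      }

      // Marginal statistics over touched cells.
      double mu_i = 0, mu_j = 0;
      for (size_t k = 0; k < touched.size(); ++k) {
        const int idx = touched[k];
        const double p = buf[idx];
        const int i = idx % L, j = idx / L;
        mu_i += i * p;
        mu_j += j * p;
      }
      double var_i = 0, var_j = 0;
      double mean = 0, varf = 0, hom = 0, con = 0, dis = 0, ent = 0, sec = 0,
             cov = 0;
      mean = mu_i;
      for (size_t k = 0; k < touched.size(); ++k) {
        const int idx = touched[k];
        const double p = buf[idx];
        const int i = idx % L, j = idx / L;
        const double di = i - mu_i, dj = j - mu_j, dij = (double)(i - j);
        var_i += di * di * p;
        var_j += dj * dj * p;
        varf += di * di * p;
        hom += p / (1.0 + dij * dij);
        con += dij * dij * p;
        dis += std::fabs(dij) * p;
        if (p > 0) ent -= p * std::log(p);
        sec += p * p;
        cov += di * dj * p;
        buf[idx] = 0.0;  // reset for next window
      }
      const double denom = std::sqrt(var_i * var_j);
      const double corr = (denom == 0.0) ? 1.0 : cov / denom;

      const int base = r + H * c;
      const int HW = H * W;
      out[base + 0 * HW] = mean;
      out[base + 1 * HW] = varf;
      out[base + 2 * HW] = hom;
      out[base + 3 * HW] = con;
      out[base + 4 * HW] = dis;
      out[base + 5 * HW] = ent;
      out[base + 6 * HW] = sec;
      out[base + 7 * HW] = corr;
    }
  }
  return out;
}
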