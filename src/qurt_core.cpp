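// Compiled kernels: exact strip-area forward/back projector pair and the
// QU placement / erasure / intra-column refinement loops with incremental
// error-map updates.
//
// Geometry conventions (shared with the R layer):
//   - square n x n grid, image[row, col] with row = z index, col = x index;
//   - pixel centres at (i + 0.5 - n/2) in both axes, rotation centre = image
//     centre; detector bin t covers [t - n/2, t + 1 - n/2) on the x' axis;
//   - x' = x*cos(theta) + z*sin(theta); theta = 0 projects along z, positive
//     theta rotates counter-clockwise; theta in (-90, 90] degrees.
//
// The projector integrates each pixel's square footprint exactly: the shadow
// of a unit pixel at angle theta is the convolution of two boxes of widths
// |cos| and |sin| (a unit-area trapezoid), integrated per detector bin in
// closed form. The back projector is the exact transpose, divided by the
// number of angles.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <utility>
using namespace Rcpp;

static const double DEG = M_PI / 180.0;

struct Foot {
  double A;  // max(|cos|,|sin|)
  double B;  // min(|cos|,|sin|)
  double S;  // support half-width
  double P;  // plateau half-width
};

static inline Foot make_foot(double c, double s) {
  double ac = std::fabs(c), as = std::fabs(s);
  Foot f;
  f.A = ac > as ? ac : as;
  f.B = ac > as ? as : ac;
  f.S = 0.5 * (f.A + f.B);
  f.P = 0.5 * (f.A - f.B);
  return f;
}

// fraction of the unit-area trapezoid lying left of u (u relative to centre)
static inline double foot_cdf(const Foot& f, double u) {
  if (u <= -f.S) return 0.0;
  if (u >= f.S) return 1.0;
  if (f.B < 1e-12) return (u + f.S) / f.A;  // box profile (axis-aligned)
  if (u < -f.P) { double t = u + f.S; return t * t / (2.0 * f.A * f.B); }
  if (u <= f.P) return f.B / (2.0 * f.A) + (u + f.P) / f.A;
  double t = f.S - u;
  return 1.0 - t * t / (2.0 * f.A * f.B);
}

// detector bins (at most 3) receiving mass from pixel (ix, iz)
static inline int pixel_weights(int n, double cth, double sth, const Foot& f,
                                int ix, int iz, int* bins, double* w) {
  double h = 0.5 * n;
  double cc = (ix + 0.5 - h) * cth + (iz + 0.5 - h) * sth + h;
  int t0 = (int)std::floor(cc - f.S);
  int t1 = (int)std::floor(cc + f.S);
  int cnt = 0;
  for (int t = t0; t <= t1 && cnt < 4; ++t) {
    if (t < 0 || t >= n) continue;
    double wt = foot_cdf(f, t + 1 - cc) - foot_cdf(f, t - cc);
    if (wt > 0.0) { bins[cnt] = t; w[cnt] = wt; ++cnt; }
  }
  return cnt;
}

// [[Rcpp::export]]
NumericMatrix cpp_fp(NumericMatrix image, NumericVector angles) {
  int n = image.nrow();
  if (image.ncol() != n) stop("image must be square");
  int nA = angles.size();
  NumericMatrix out(n, nA);
  int bins[4]; double w[4];
  for (int a = 0; a < nA; ++a) {
    double cth = std::cos(angles[a] * DEG), sth = std::sin(angles[a] * DEG);
    Foot f = make_foot(cth, sth);
    for (int ix = 0; ix < n; ++ix) {
      for (int iz = 0; iz < n; ++iz) {
        double v = image(iz, ix);
        if (v == 0.0) continue;
        int c = pixel_weights(n, cth, sth, f, ix, iz, bins, w);
        for (int k = 0; k < c; ++k) out(bins[k], a) += v * w[k];
      }
    }
  }
  return out;
}

// unfiltered back projection (transpose of cpp_fp), divided by n_angles
// [[Rcpp::export]]
NumericMatrix cpp_bp(NumericMatrix resid, NumericVector angles) {
  int n = resid.nrow();
  int nA = angles.size();
  if (resid.ncol() != nA) stop("one residual column per angle required");
  NumericMatrix out(n, n);
  int bins[4]; double w[4];
  for (int a = 0; a < nA; ++a) {
    double cth = std::cos(angles[a] * DEG), sth = std::sin(angles[a] * DEG);
    Foot f = make_foot(cth, sth);
    for (int ix = 0; ix < n; ++ix) {
      for (int iz = 0; iz < n; ++iz) {
        int c = pixel_weights(n, cth, sth, f, ix, iz, bins, w);
        double acc = 0.0;
        for (int k = 0; k < c; ++k) acc += w[k] * resid(bins[k], a);
        out(iz, ix) += acc;
      }
    }
  }
  for (int i = 0; i < n * n; ++i) out[i] /= nA;
  return out;
}

// 0-based detector column of each pixel centre under rotation by theta
// [[Rcpp::export]]
IntegerMatrix cpp_colindex(int n, double theta) {
  IntegerMatrix out(n, n);
  double cth = std::cos(theta * DEG), sth = std::sin(theta * DEG);
  double h = 0.5 * n;
  for (int ix = 0; ix < n; ++ix) {
    for (int iz = 0; iz < n; ++iz) {
      double cc = (ix + 0.5 - h) * cth + (iz + 0.5 - h) * sth + h;
      int t = (int)std::floor(cc);
      if (t < 0) t = 0;
      if (t >= n) t = n - 1;
      out(iz, ix) = t;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// QURT solver state for one (level, base angle) sub-problem.
// Pixel linear index k = iz + ix*m (R column-major). g(x,z) = counts * q.
// ---------------------------------------------------------------------------

struct Solver {
  int m, nA;
  double q;
  std::vector<double> pexp;            // m*nA, [b + a*m]
  std::vector<double> cth, sth;
  std::vector<Foot> foot;
  std::vector<double> E;               // residual FP[g] - pexp
  std::vector<double> emap;            // BP[E], m*m
  std::vector<int> counts;             // QU pieces per pixel
  std::vector<int> col;                // base-angle column per pixel
  std::vector<int> ncol, placedc;      // budget / tally per column
  std::vector<std::vector<int>> colpix;
  std::vector<double> W2;              // per-pixel sum over angles/bins of w^2
  std::vector<int> pixpos;             // index of each pixel in its column list
  static const int NEIGH = 8;          // in-column neighbour span for moves
  double crossList[NEIGH + 1];         // weight overlap vs in-column distance
  // precomputed projector weights (both directions) when they fit in memory;
  // a pixel's footprint spans at most 3 detector bins
  bool cached = false;
  std::vector<double> fw_w;            // [ (a*m*m + k)*3 ]
  std::vector<int16_t> fw_bin;
  std::vector<int8_t> fw_cnt;          // [ a*m*m + k ]
  std::vector<int> rv_start;           // CSR rows per (a*m + b)
  std::vector<int> rv_pix;
  std::vector<double> rv_w;
  long long n_place = 0, n_move = 0, n_erase = 0, n_clamp = 0;
  int dropped_budget = 0;              // budget in columns holding no pixel

  Solver(const NumericMatrix& pexp_, const NumericVector& angles, double theta,
         double q_, const IntegerMatrix& init_counts,
         const IntegerVector& ncol_)
      : m(pexp_.nrow()), nA(angles.size()), q(q_) {
    if (pexp_.ncol() != nA) stop("projection/angle mismatch");
    if (init_counts.nrow() != m || init_counts.ncol() != m)
      stop("init_counts must match grid");
    if (ncol_.size() != m) stop("one column budget per detector bin required");
    pexp.assign(pexp_.begin(), pexp_.end());
    cth.resize(nA); sth.resize(nA); foot.resize(nA);
    for (int a = 0; a < nA; ++a) {
      cth[a] = std::cos(angles[a] * DEG);
      sth[a] = std::sin(angles[a] * DEG);
      foot[a] = make_foot(cth[a], sth[a]);
    }
    counts.assign(init_counts.begin(), init_counts.end());
    IntegerMatrix ci = cpp_colindex(m, theta);
    col.assign(ci.begin(), ci.end());
    colpix.assign(m, {});
    for (int k = 0; k < m * m; ++k) colpix[col[k]].push_back(k);
    ncol.assign(ncol_.begin(), ncol_.end());
    for (int j = 0; j < m; ++j) {
      if (colpix[j].empty() && ncol[j] > 0) {  // no pixel centre in this bin
        dropped_budget += ncol[j];
        ncol[j] = 0;
      }
    }
    placedc.assign(m, 0);
    for (int k = 0; k < m * m; ++k) placedc[col[k]] += counts[k];
    init_cache();
    precompute_overlaps();
    recompute();
  }

  // at most 3 bins per (pixel, angle); cache both directions if affordable
  void init_cache() {
    size_t cells = (size_t)m * m * nA;
    if (cells > 16000000) return;  // ~0.5 GB ceiling across all arrays
    fw_w.assign(cells * 3, 0.0);
    fw_bin.assign(cells * 3, 0);
    fw_cnt.assign(cells, 0);
    std::vector<int> rowcnt((size_t)nA * m, 0);
    int bins[4]; double w[4];
    for (int a = 0; a < nA; ++a) {
      for (int ix = 0; ix < m; ++ix) {
        for (int iz = 0; iz < m; ++iz) {
          int k = iz + ix * m;
          int c = pixel_weights(m, cth[a], sth[a], foot[a], ix, iz, bins, w);
          if (c > 3) c = 3;
          size_t cell = (size_t)a * m * m + k;
          fw_cnt[cell] = (int8_t)c;
          for (int i = 0; i < c; ++i) {
            fw_bin[cell * 3 + i] = (int16_t)bins[i];
            fw_w[cell * 3 + i] = w[i];
            ++rowcnt[(size_t)a * m + bins[i]];
          }
        }
      }
    }
    rv_start.assign((size_t)nA * m + 1, 0);
    for (size_t r = 0; r < (size_t)nA * m; ++r)
      rv_start[r + 1] = rv_start[r] + rowcnt[r];
    rv_pix.assign(rv_start.back(), 0);
    rv_w.assign(rv_start.back(), 0.0);
    std::vector<int> fill(rv_start.begin(), rv_start.end() - 1);
    for (int a = 0; a < nA; ++a) {
      for (int k = 0; k < m * m; ++k) {
        size_t cell = (size_t)a * m * m + k;
        for (int i = 0; i < fw_cnt[cell]; ++i) {
          size_t r = (size_t)a * m + fw_bin[cell * 3 + i];
          rv_pix[fill[r]] = k;
          rv_w[fill[r]] = fw_w[cell * 3 + i];
          ++fill[r];
        }
      }
    }
    cached = true;
  }

  inline int get_weights(int a, int k, int* bins, double* w) const {
    if (cached) {
      size_t cell = (size_t)a * m * m + k;
      int c = fw_cnt[cell];
      for (int i = 0; i < c; ++i) {
        bins[i] = fw_bin[cell * 3 + i];
        w[i] = fw_w[cell * 3 + i];
      }
      return c;
    }
    return pixel_weights(m, cth[a], sth[a], foot[a], k / m, k % m, bins, w);
  }

  // exact weight dot-product between two pixels' projector rows
  double cross_exact(int k1, int k2) const {
    int b1[4], b2[4]; double w1[4], w2v[4];
    double acc = 0.0;
    for (int a = 0; a < nA; ++a) {
      int c1 = get_weights(a, k1, b1, w1);
      int c2 = get_weights(a, k2, b2, w2v);
      for (int i = 0; i < c1; ++i)
        for (int jj = 0; jj < c2; ++jj)
          if (b1[i] == b2[jj]) acc += w1[i] * w2v[jj];
    }
    return acc;
  }

  // per-pixel squared weight norms, each pixel's index inside its column
  // list, and the (approximately translation-invariant, measured at the grid
  // centre) overlap profile between column neighbours, used to score moves
  // in O(1)
  void precompute_overlaps() {
    W2.assign((size_t)m * m, 0.0);
    int bins[4]; double w[4];
    for (int a = 0; a < nA; ++a) {
      for (int k = 0; k < m * m; ++k) {
        int c = get_weights(a, k, bins, w);
        double s = 0.0;
        for (int kk = 0; kk < c; ++kk) s += w[kk] * w[kk];
        W2[k] += s;
      }
    }
    pixpos.assign((size_t)m * m, 0);
    for (int j = 0; j < m; ++j)
      for (size_t i = 0; i < colpix[j].size(); ++i) pixpos[colpix[j][i]] = (int)i;
    // overlap profile along a central column
    for (int r = 0; r <= NEIGH; ++r) crossList[r] = 0.0;
    int j0 = m / 2;
    for (int tryj = 0; tryj < m; ++tryj) {
      int j = (j0 + tryj) % m;
      if ((int)colpix[j].size() >= 2 * NEIGH + 1) { j0 = j; break; }
    }
    const std::vector<int>& cp = colpix[j0];
    if ((int)cp.size() >= 2) {
      int i0 = (int)cp.size() / 2;
      for (int r = 0; r <= NEIGH && i0 + r < (int)cp.size(); ++r)
        crossList[r] = cross_exact(cp[i0], cp[i0 + r]);
    }
  }

  void recompute() {
    E.assign((size_t)m * nA, 0.0);
    int bins[4]; double w[4];
    for (int a = 0; a < nA; ++a) {
      for (int k = 0; k < m * m; ++k) {
        if (counts[k] == 0) continue;
        double v = counts[k] * q;
        int c = get_weights(a, k, bins, w);
        for (int kk = 0; kk < c; ++kk) E[bins[kk] + (size_t)a * m] += v * w[kk];
      }
    }
    for (size_t i = 0; i < E.size(); ++i) E[i] -= pexp[i];
    recompute_emap();
  }

  // spread a residual change db at (angle a, bin b) into the error map
  void scatter(int a, int b, double db) {
    if (cached) {
      double inc = db / nA;
      size_t r = (size_t)a * m + b;
      for (int i = rv_start[r]; i < rv_start[r + 1]; ++i)
        emap[rv_pix[i]] += inc * rv_w[i];
      return;
    }
    double h = 0.5 * m;
    const Foot& f = foot[a];
    double inc = db / nA;
    if (std::fabs(cth[a]) >= std::fabs(sth[a])) {
      // x-major: cos(theta) > 0 for |theta| <= 45
      double c = cth[a], s = sth[a];
      for (int iz = 0; iz < m; ++iz) {
        double zoff = (iz + 0.5 - h) * s;
        double u0 = (b - h - f.S - zoff) / c;
        double u1 = (b + 1 - h + f.S - zoff) / c;
        int lo = (int)std::floor(u0 + h - 0.5);
        int hi = (int)std::ceil(u1 + h - 0.5);
        if (lo < 0) lo = 0;
        if (hi > m - 1) hi = m - 1;
        for (int ix = lo; ix <= hi; ++ix) {
          double cc = (ix + 0.5 - h) * c + zoff + h;
          double wr = foot_cdf(f, b + 1 - cc) - foot_cdf(f, b - cc);
          if (wr > 0.0) emap[iz + (size_t)ix * m] += inc * wr;
        }
      }
    } else {
      double c = cth[a], s = sth[a];
      for (int ix = 0; ix < m; ++ix) {
        double xoff = (ix + 0.5 - h) * c;
        double b0 = (b - h - f.S - xoff), b1 = (b + 1 - h + f.S - xoff);
        double u0 = b0 / s, u1 = b1 / s;
        if (s < 0) std::swap(u0, u1);
        int lo = (int)std::floor(u0 + h - 0.5);
        int hi = (int)std::ceil(u1 + h - 0.5);
        if (lo < 0) lo = 0;
        if (hi > m - 1) hi = m - 1;
        for (int iz = lo; iz <= hi; ++iz) {
          double cc = xoff + (iz + 0.5 - h) * s + h;
          double wr = foot_cdf(f, b + 1 - cc) - foot_cdf(f, b - cc);
          if (wr > 0.0) emap[iz + (size_t)ix * m] += inc * wr;
        }
      }
    }
  }

  // add dc QU pieces at pixel k, updating residuals and error map in place
  void apply(int k, int dc) {
    counts[k] += dc;
    placedc[col[k]] += dc;
    double dq = dc * q;
    int bins[4]; double w[4];
    for (int a = 0; a < nA; ++a) {
      int c = get_weights(a, k, bins, w);
      for (int kk = 0; kk < c; ++kk) {
        double db = dq * w[kk];
        E[bins[kk] + (size_t)a * m] += db;
        scatter(a, bins[kk], db);
      }
    }
  }

  double rss() const {
    double s = 0.0;
    for (size_t i = 0; i < E.size(); ++i) s += E[i] * E[i];
    return s;
  }

  // counts/residual-only update (no error-map scatter); used by the batched
  // refinement which refreshes the map once per batch
  void apply_nomap(int k, int dc) {
    counts[k] += dc;
    placedc[col[k]] += dc;
    double dq = dc * q;
    int bins[4]; double w[4];
    for (int a = 0; a < nA; ++a) {
      int c = get_weights(a, k, bins, w);
      for (int kk = 0; kk < c; ++kk) E[bins[kk] + (size_t)a * m] += dq * w[kk];
    }
  }

  // emap = BP[E] from the (exactly maintained) residuals
  void recompute_emap() {
    emap.assign((size_t)m * m, 0.0);
    int bins[4]; double w[4];
    for (int a = 0; a < nA; ++a) {
      const double* Ea = E.data() + (size_t)a * m;
      for (int k = 0; k < m * m; ++k) {
        int c = get_weights(a, k, bins, w);
        double acc = 0.0;
        for (int kk = 0; kk < c; ++kk) acc += w[kk] * Ea[bins[kk]];
        emap[k] += acc;
      }
    }
    for (size_t i = 0; i < emap.size(); ++i) emap[i] /= nA;
  }

  // exact change of sum(E^2) if counts[ks] -= 1 and counts[kd] += 1
  double delta_move(int ks, int kd) const {
    int bs[4], bd[4]; double ws[4], wd[4];
    int bl[8]; double dl[8];
    double total = 0.0;
    for (int a = 0; a < nA; ++a) {
      int cs = get_weights(a, ks, bs, ws);
      int cd = get_weights(a, kd, bd, wd);
      int cnt = 0;
      for (int i = 0; i < cs; ++i) { bl[cnt] = bs[i]; dl[cnt] = -q * ws[i]; ++cnt; }
      for (int i = 0; i < cd; ++i) {
        double add = q * wd[i];
        bool merged = false;
        for (int jj = 0; jj < cnt; ++jj)
          if (bl[jj] == bd[i]) { dl[jj] += add; merged = true; break; }
        if (!merged) { bl[cnt] = bd[i]; dl[cnt] = add; ++cnt; }
      }
      for (int jj = 0; jj < cnt; ++jj) {
        double e = E[bl[jj] + (size_t)a * m];
        total += dl[jj] * (2.0 * e + dl[jj]);
      }
    }
    return total;
  }

  // exact change of sum(E^2) if counts[k] += dc
  double delta_put(int k, int dc) const {
    int bins[4]; double w[4];
    double total = 0.0;
    for (int a = 0; a < nA; ++a) {
      int c = get_weights(a, k, bins, w);
      for (int kk = 0; kk < c; ++kk) {
        double d = dc * q * w[kk];
        double e = E[bins[kk] + (size_t)a * m];
        total += d * (2.0 * e + d);
      }
    }
    return total;
  }

  // place QU pieces one-by-one at the most-negative error-map pixel among
  // columns with unmet budget; ties resolved by lowest linear index
  long long place_all(std::vector<int>* trace) {
    long long placed = 0;
    while (true) {
      int best = -1;
      double bv = R_PosInf;
      for (int k = 0; k < m * m; ++k) {
        int j = col[k];
        if (placedc[j] >= ncol[j]) continue;
        if (emap[k] < bv) { bv = emap[k]; best = k; }
      }
      if (best < 0) break;
      apply(best, +1);
      ++placed; ++n_place;
      if (trace) trace->push_back(best);
      if ((placed & 0x3FF) == 0) Rcpp::checkUserInterrupt();
    }
    return placed;
  }

  // remove pieces from columns whose tally exceeds the budget (warm starts),
  // always from the occupied pixel with the largest (most positive) error
  long long clamp_overfull() {
    long long removed = 0;
    for (int j = 0; j < m; ++j) {
      while (placedc[j] > ncol[j]) {
        int best = -1;
        double bv = R_NegInf;
        for (int k : colpix[j]) {
          if (counts[k] <= 0) continue;
          if (emap[k] > bv) { bv = emap[k]; best = k; }
        }
        if (best < 0) break;  // cannot happen: tally > 0 implies occupancy
        apply(best, -1);
        ++removed; ++n_clamp;
      }
    }
    return removed;
  }

  // erase pieces wherever the error map exceeds +margin (QU excess); a
  // negative margin selects the exact profitability rule: erase whenever
  // removal strictly decreases the squared residual (threshold q*W2/(2*nA))
  long long erase_sweep(double margin) {
    long long erased = 0;
    for (int k = 0; k < m * m; ++k) {
      double thr = margin >= 0 ? margin
                               : q * W2[k] / (2.0 * nA) + 1e-12;
      while (counts[k] > 0 && emap[k] > thr) {
        apply(k, -1);
        ++erased; ++n_erase;
      }
    }
    return erased;
  }

  bool best_move_exhaustive(int& src, int& dst, double& bestd,
                            double min_gain) const {
    bestd = -min_gain;
    bool found = false;
    for (int j = 0; j < m; ++j) {
      for (int ks : colpix[j]) {
        if (counts[ks] <= 0) continue;
        for (int kd : colpix[j]) {
          if (kd == ks) continue;
          double d = delta_move(ks, kd);
          if (d < bestd) { bestd = d; src = ks; dst = kd; found = true; }
        }
      }
    }
    return found;
  }

  // Candidate generation for the next refinement move. The exact change of
  // the squared residual for a move s -> d is
  //   2*q*nA*(emap[d] - emap[s]) + q^2*(W2[s] + W2[d] - 2*cross(s,d)),
  // so it is screened in O(1) by the proxy using the precomputed overlap
  // table (cross ~ 0 for distant pairs). Two candidate families: occupied
  // pixels moving to nearby in-column neighbours (large cross), and each
  // column's emap extremes (long-range moves); the shortlist is then
  // evaluated exactly.
  struct C2 { double proxy; int s, d; };

  // proxy-ranked shortlist of candidate moves (see best_move_heur)
  void build_shortlist(std::vector<C2>& shortlist, size_t keep) const {
    shortlist.clear();
    shortlist.reserve(512);
    const double lin = 2.0 * q * nA, q2 = q * q;
    // short-range: occupied pixels x neighbours along their column list
    // (spatially adjacent pixels of the same base-angle column)
    for (int j = 0; j < m; ++j) {
      const std::vector<int>& cp = colpix[j];
      int len = (int)cp.size();
      for (int i = 0; i < len; ++i) {
        int k = cp[i];
        if (counts[k] <= 0) continue;
        for (int r = -NEIGH; r <= NEIGH; ++r) {
          if (r == 0) continue;
          int i2 = i + r;
          if (i2 < 0 || i2 >= len) continue;
          int k2 = cp[i2];
          double proxy = lin * (emap[k2] - emap[k]) +
            q2 * (W2[k] + W2[k2] - 2.0 * crossList[r < 0 ? -r : r]);
          if (proxy < 0.0) shortlist.push_back({proxy, k, k2});
        }
      }
    }
    // long-range: per column, 3 best sources x 3 best destinations by the
    // cross-free parts of the proxy
    for (int j = 0; j < m; ++j) {
      if (colpix[j].empty()) continue;
      int ks[3] = {-1, -1, -1}, kd[3] = {-1, -1, -1};
      double bs[3] = {R_PosInf, R_PosInf, R_PosInf};
      double bd[3] = {R_PosInf, R_PosInf, R_PosInf};
      for (int k : colpix[j]) {
        if (counts[k] > 0) {
          double b = -lin * emap[k] + q2 * W2[k];
          if (b < bs[2]) {
            int i = 2;
            while (i > 0 && b < bs[i - 1]) { bs[i]=bs[i-1]; ks[i]=ks[i-1]; --i; }
            bs[i] = b; ks[i] = k;
          }
        }
        double a = lin * emap[k] + q2 * W2[k];
        if (a < bd[2]) {
          int i = 2;
          while (i > 0 && a < bd[i - 1]) { bd[i]=bd[i-1]; kd[i]=kd[i-1]; --i; }
          bd[i] = a; kd[i] = k;
        }
      }
      for (int is = 0; is < 3; ++is) {
        for (int id = 0; id < 3; ++id) {
          if (ks[is] < 0 || kd[id] < 0 || ks[is] == kd[id]) continue;
          shortlist.push_back({bs[is] + bd[id], ks[is], kd[id]});
        }
      }
    }
    if (shortlist.size() > keep) {
      std::partial_sort(shortlist.begin(), shortlist.begin() + keep,
                        shortlist.end(),
                        [](const C2& a, const C2& b) { return a.proxy < b.proxy; });
      // keep the tail too: the fallback pass may need it
      std::sort(shortlist.begin() + keep, shortlist.end(),
                [](const C2& a, const C2& b) { return a.proxy < b.proxy; });
    } else {
      std::sort(shortlist.begin(), shortlist.end(),
                [](const C2& a, const C2& b) { return a.proxy < b.proxy; });
    }
  }

  bool best_move_heur(int& src, int& dst, double& bestd, double min_gain) const {
    std::vector<C2> shortlist;
    build_shortlist(shortlist, 64);
    if (shortlist.empty()) return false;
    size_t keep = shortlist.size() < 64 ? shortlist.size() : 64;
    bestd = -min_gain;
    bool found = false;
    for (size_t i = 0; i < keep; ++i) {
      double d = delta_move(shortlist[i].s, shortlist[i].d);
      if (d < bestd) { bestd = d; src = shortlist[i].s; dst = shortlist[i].d; found = true; }
    }
    if (found) return true;
    for (size_t i = keep; i < shortlist.size(); ++i) {
      double d = delta_move(shortlist[i].s, shortlist[i].d);
      if (d < bestd) { bestd = d; src = shortlist[i].s; dst = shortlist[i].d; found = true; }
    }
    return found;
  }

  // intra-column rearrangement: repeat the move with the largest decrease of
  // sum(E^2); stops at the change-rate convergence test or when no move helps.
  // With batch > 1 (large grids) candidates are ranked against a map that is
  // refreshed once per batch, while every accepted move is still validated
  // against the exactly-maintained residuals, so the squared residual is
  // strictly decreasing in all modes.
  List refine(long long max_moves, double tol, int interval, int exh_limit,
              double min_gain, bool want_trace, int batch) {
    long long mv = 0, last_check = 0;
    bool conv = false;
    std::vector<int> gprev(counts);
    std::vector<int> tr_src, tr_dst;
    std::vector<double> tr_rss;
    auto check_conv = [&]() {
      double num = 0.0, den = 0.0;
      for (int k = 0; k < m * m; ++k) {
        num += std::fabs((double)(counts[k] - gprev[k]));
        den += counts[k];
      }
      if (den > 0 && num / den < tol) { conv = true; return true; }
      gprev = counts;
      return false;
    };
    if (batch > 1 && m > exh_limit) {
      std::vector<C2> shortlist;
      while (mv < max_moves && !conv) {
        Rcpp::checkUserInterrupt();
        build_shortlist(shortlist, (size_t)(4 * batch));
        int applied = 0;
        for (const C2& c : shortlist) {
          if (mv >= max_moves || applied >= batch) break;
          if (counts[c.s] <= 0) continue;
          double d = delta_move(c.s, c.d);
          if (d < -min_gain) {
            apply_nomap(c.s, -1);
            apply_nomap(c.d, +1);
            ++applied; ++mv; ++n_move;
            if (want_trace) {
              tr_src.push_back(c.s); tr_dst.push_back(c.d);
              tr_rss.push_back(rss());
            }
          }
        }
        recompute_emap();
        // endgame: when stale-ranked batches stop paying for their map
        // refresh, continue with exact one-by-one moves below
        if (applied < batch / 4) break;
        if (interval > 0 && mv - last_check >= interval) {
          last_check = mv;
          if (check_conv()) break;
        }
      }
    }
    if (!conv) {
      while (mv < max_moves) {
        int src = -1, dst = -1;
        double d = 0.0;
        bool ok = (m <= exh_limit) ? best_move_exhaustive(src, dst, d, min_gain)
                                   : best_move_heur(src, dst, d, min_gain);
        if (!ok) break;
        apply(src, -1);
        apply(dst, +1);
        ++mv; ++n_move;
        if (want_trace) {
          tr_src.push_back(src);
          tr_dst.push_back(dst);
          tr_rss.push_back(rss());
        }
        if (interval > 0 && mv % interval == 0) {
          Rcpp::checkUserInterrupt();
          if (check_conv()) break;
        }
      }
    }
    return List::create(_["moves"] = (double)mv, _["converged"] = conv,
                        _["src"] = tr_src, _["dst"] = tr_dst,
                        _["rss_trace"] = tr_rss);
  }

  List as_list() const {
    IntegerMatrix cm(m, m);
    std::copy(counts.begin(), counts.end(), cm.begin());
    NumericMatrix em(m, m);
    std::copy(emap.begin(), emap.end(), em.begin());
    NumericMatrix Em(m, nA);
    std::copy(E.begin(), E.end(), Em.begin());
    return List::create(
        _["counts"] = cm, _["emap"] = em, _["resid"] = Em,
        _["ncol"] = IntegerVector(ncol.begin(), ncol.end()),
        _["placed_col"] = IntegerVector(placedc.begin(), placedc.end()),
        _["n_place"] = (double)n_place, _["n_move"] = (double)n_move,
        _["n_erase"] = (double)n_erase, _["n_clamp"] = (double)n_clamp,
        _["dropped_budget"] = dropped_budget, _["rss"] = rss());
  }
};

static double opt_num(const List& opts, const char* nm, double def) {
  if (opts.containsElementNamed(nm)) return as<double>(opts[nm]);
  return def;
}

// Full solve for one (level, base angle): clamp warm-start overfull columns,
// place to budget, then alternate erase/re-place/refine until quiescent.
// [[Rcpp::export]]
List cpp_qurt_solve(NumericMatrix pexp, NumericVector angles, double theta,
                    double q, IntegerMatrix init_counts, IntegerVector ncol,
                    List opts) {
  Solver s(pexp, angles, theta, q, init_counts, ncol);
  double tol = opt_num(opts, "tol", 1e-6);
  int interval = (int)opt_num(opts, "interval", 100);
  double margin = opt_num(opts, "margin", q / 2.0);
  int exh_limit = (int)opt_num(opts, "exhaustive_limit", 12);
  int max_outer = (int)opt_num(opts, "max_outer", 40);
  double min_gain = opt_num(opts, "min_gain", 1e-10);
  double cap_mult = opt_num(opts, "move_cap", 50.0);
  int batch = (int)opt_num(opts, "batch", s.m > 48 ? 128 : 1);
  s.clamp_overfull();
  s.place_all(nullptr);
  long long N = 0;
  for (int j = 0; j < s.m; ++j) N += s.ncol[j];
  long long cap = (long long)(cap_mult * (double)N) + 1000;
  bool converged = false, capped = false;
  for (int outer = 0; outer < max_outer; ++outer) {
    long long er = s.erase_sweep(margin);
    if (er > 0) s.place_all(nullptr);
    List r = s.refine(cap - s.n_move, tol, interval, exh_limit, min_gain, false,
                      batch);
    bool conv = as<bool>(r["converged"]);
    double mv = as<double>(r["moves"]);
    if (conv) { converged = true; break; }
    if (s.n_move >= cap) { capped = true; break; }
    if (er == 0 && mv == 0) break;
  }
  List out = s.as_list();
  out["converged"] = converged;
  out["move_cap_hit"] = capped;
  out["N"] = (double)N;
  return out;
}

// placement phase only (with trace), for rule-replay tests
// [[Rcpp::export]]
List cpp_place_all(NumericMatrix pexp, NumericVector angles, double theta,
                   double q, IntegerMatrix init_counts, IntegerVector ncol) {
  Solver s(pexp, angles, theta, q, init_counts, ncol);
  std::vector<int> trace;
  s.place_all(&trace);
  List out = s.as_list();
  out["trace"] = IntegerVector(trace.begin(), trace.end());
  return out;
}

// refinement only (with trace), for move-oracle and monotonicity tests
// [[Rcpp::export]]
List cpp_refine(NumericMatrix pexp, NumericVector angles, double theta,
                double q, IntegerMatrix init_counts, IntegerVector ncol,
                double max_moves, double tol, int interval, int exh_limit,
                double min_gain, int batch = 1) {
  Solver s(pexp, angles, theta, q, init_counts, ncol);
  List r = s.refine((long long)max_moves, tol, interval, exh_limit, min_gain,
                    true, batch);
  List out = s.as_list();
  out["moves"] = r["moves"];
  out["converged"] = r["converged"];
  out["src"] = r["src"];
  out["dst"] = r["dst"];
  out["rss_trace"] = r["rss_trace"];
  return out;
}

// erasure sweep only
// [[Rcpp::export]]
List cpp_erase_sweep(NumericMatrix pexp, NumericVector angles, double theta,
                     double q, IntegerMatrix init_counts, IntegerVector ncol,
                     double margin) {
  Solver s(pexp, angles, theta, q, init_counts, ncol);
  long long er = s.erase_sweep(margin);
  List out = s.as_list();
  out["erased"] = (double)er;
  return out;
}

// exact sum(E^2) change for a single put/remove (test oracle plumbing)
// [[Rcpp::export]]
double cpp_delta_put(NumericMatrix pexp, NumericVector angles, double theta,
                     double q, IntegerMatrix init_counts, IntegerVector ncol,
                     int k0, int dc) {
  Solver s(pexp, angles, theta, q, init_counts, ncol);
  return s.delta_put(k0, dc);
}

// incremental error-map update: change g by `delta` over a square block,
// updating residuals and map in place (cost ~ angles x block ray footprint)
// [[Rcpp::export]]
List cpp_emap_update(NumericMatrix E, NumericMatrix emap, NumericVector angles,
                     int ix0, int iz0, int size, double delta) {
  int n = emap.nrow();
  if (emap.ncol() != n) stop("error map must be square");
  int nA = angles.size();
  if (E.nrow() != n || E.ncol() != nA) stop("residual/angle mismatch");
  if (ix0 < 0 || iz0 < 0 || ix0 + size > n || iz0 + size > n)
    stop("block out of bounds");
  // reuse Solver's scatter via a lightweight instance (zero data)
  NumericMatrix pz(n, nA);
  IntegerMatrix cz(n, n);
  IntegerVector nz(n);
  Solver s(pz, angles, 0.0, 1.0, cz, nz);
  std::copy(E.begin(), E.end(), s.E.begin());
  std::copy(emap.begin(), emap.end(), s.emap.begin());
  int bins[4]; double w[4];
  for (int ix = ix0; ix < ix0 + size; ++ix) {
    for (int iz = iz0; iz < iz0 + size; ++iz) {
      for (int a = 0; a < nA; ++a) {
        int c = pixel_weights(n, s.cth[a], s.sth[a], s.foot[a], ix, iz, bins, w);
        for (int kk = 0; kk < c; ++kk) {
          double db = delta * w[kk];
          s.E[bins[kk] + (size_t)a * n] += db;
          s.scatter(a, bins[kk], db);
        }
      }
    }
  }
  NumericMatrix Eo(n, nA), Mo(n, n);
  std::copy(s.E.begin(), s.E.end(), Eo.begin());
  std::copy(s.emap.begin(), s.emap.end(), Mo.begin());
  return List::create(_["resid"] = Eo, _["emap"] = Mo);
}
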