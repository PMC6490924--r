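#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include "rng.h"

using namespace Rcpp;

// metric codes: 0 = Euclidean, 1 = city-block
static inline double pair_stat(double w, double dc, double dm, int metric) {
  double a = w * dc, b = (1.0 - w) * dm;
  if (metric == 0) return a * a + b * b;  // squared distance; monotone in d
  return std::fabs(a) + std::fabs(b);
}

// Monte-Carlo choice probability for one (w, p1, p2) cell: target at the
// origin, unit Gaussian noise added independently to target and both tests
// on both dimensions, observer picks the test whose draw lies closer.
// [[Rcpp::export]]
double mc_choice_prob_cpp(double w, double p1c, double p1m, double p2c,
                          double p2m, int metric, int ntrials, double seed) {
  cmt::Rng rng(cmt::stream_seed((uint64_t)seed, 0));
  double q = 0.0;
  for (int t = 0; t < ntrials; ++t) {
    double tc = rng.normal(), tm = rng.normal();
    double d1 = pair_stat(w, tc - rng.normal() - p1c, tm - rng.normal() - p1m, metric);
    double d2 = pair_stat(w, tc - rng.normal() - p2c, tm - rng.normal() - p2m, metric);
    if (d1 < d2) q += 1.0;
    else if (d1 == d2) q += 0.5;
  }
  return q / ntrials;
}

// Build the 5-D choice-probability table over (w, p1C, p1M, p2C, p2M).
// Each cell owns an RNG stream derived from (seed, cell index). The same
// noise draws score both presentation orders, and the cell stores the
// average of the two orientation estimates, so the complement law
// P(p1,p2) + P(p2,p1) = 1 holds exactly. When the position grid is
// symmetric about zero, sign-flip symmetries of the model are used to
// simulate only one representative cell per symmetry orbit.
// [[Rcpp::export]]
NumericVector build_table_cpp(int metric, NumericVector wgrid,
                              NumericVector pgrid, int ntrials, double seed) {
  const int nw = wgrid.size(), np = pgrid.size();
  const int64_t np2 = (int64_t)np * np, np3 = np2 * np, np4 = np3 * np;
  const int64_t ncell = (int64_t)nw * np4;
  NumericVector out((R_xlen_t)ncell);

  bool sym = true;
  for (int i = 0; i < np; ++i)
    if (std::fabs(pgrid[i] + pgrid[np - 1 - i]) > 1e-9) { sym = false; break; }

  // transform table on (a,b,c,d) position indices; flag 1 = swap (complement)
  struct Tf { int64_t key; int flag; };
  std::vector<double> val(np4);

  for (int iw = 0; iw < nw; ++iw) {
    const double w = wgrid[iw];
    for (int64_t key = 0; key < np4; ++key) {
      int a = (int)(key / np3);
      int b = (int)((key / np2) % np);
      int c = (int)((key / np) % np);
      int d = (int)(key % np);
      int fa = np - 1 - a, fb = np - 1 - b, fc = np - 1 - c, fd = np - 1 - d;

      Tf tf[8];
      int ntf = 0;
      tf[ntf++] = { ((int64_t)a * np3 + (int64_t)b * np2 + (int64_t)c * np + d), 0 };
      tf[ntf++] = { ((int64_t)c * np3 + (int64_t)d * np2 + (int64_t)a * np + b), 1 };
      if (sym) {
        tf[ntf++] = { ((int64_t)fa * np3 + (int64_t)b * np2 + (int64_t)fc * np + d), 0 };
        tf[ntf++] = { ((int64_t)a * np3 + (int64_t)fb * np2 + (int64_t)c * np + fd), 0 };
        tf[ntf++] = { ((int64_t)fa * np3 + (int64_t)fb * np2 + (int64_t)fc * np + fd), 0 };
        tf[ntf++] = { ((int64_t)fc * np3 + (int64_t)d * np2 + (int64_t)fa * np + b), 1 };
        tf[ntf++] = { ((int64_t)c * np3 + (int64_t)fd * np2 + (int64_t)a * np + fb), 1 };
        tf[ntf++] = { ((int64_t)fc * np3 + (int64_t)fd * np2 + (int64_t)fa * np + fb), 1 };
      }
      int64_t kmin = tf[0].key;
      for (int i = 1; i < ntf; ++i) if (tf[i].key < kmin) kmin = tf[i].key;
      bool has0 = false, has1 = false;
      for (int i = 0; i < ntf; ++i)
        if (tf[i].key == kmin) { if (tf[i].flag) has1 = true; else has0 = true; }

      if (has0 && has1) {
        // orbit is fixed by a complementing transform: true value is 1/2
        val[key] = 0.5;
      } else if (key == kmin) {
        const double pc1 = pgrid[a], pm1 = pgrid[b];
        const double pc2 = pgrid[c], pm2 = pgrid[d];
        cmt::Rng rng(cmt::stream_seed((uint64_t)seed,
                                      (uint64_t)iw * (uint64_t)np4 + (uint64_t)key));
        double q1 = 0.0, q2 = 0.0;
        for (int t = 0; t < ntrials; ++t) {
          double tc = rng.normal(), tm = rng.normal();
          double n1c = rng.normal(), n1m = rng.normal();
          double n2c = rng.normal(), n2m = rng.normal();
          double ec1 = tc - n1c, em1 = tm - n1m;
          double ec2 = tc - n2c, em2 = tm - n2m;
          // orientation 1: p1 in slot 1
          double d1 = pair_stat(w, ec1 - pc1, em1 - pm1, metric);
          double d2 = pair_stat(w, ec2 - pc2, em2 - pm2, metric);
          if (d1 < d2) q1 += 1.0; else if (d1 == d2) q1 += 0.5;
          // orientation 2: same draws, positions swapped
          double e1 = pair_stat(w, ec1 - pc2, em1 - pm2, metric);
          double e2 = pair_stat(w, ec2 - pc1, em2 - pm1, metric);
          if (e1 < e2) q2 += 1.0; else if (e1 == e2) q2 += 0.5;
        }
        val[key] = (q1 + (ntrials - q2)) / (2.0 * ntrials);
      } else {
        // copy from the already-computed representative (kmin < key)
        int flag = -1;
        for (int i = 0; i < ntf; ++i)
          if (tf[i].key == kmin) { flag = tf[i].flag; break; }
        val[key] = flag ? 1.0 - val[kmin] : val[kmin];
      }
    }
    // write slice into the (w, p1C, p1M, p2C, p2M) column-major array
    const int64_t sA = nw, sB = (int64_t)nw * np, sC = (int64_t)nw * np2,
                  sD = (int64_t)nw * np3;
    for (int64_t key = 0; key < np4; ++key) {
      int a = (int)(key / np3);
      int b = (int)((key / np2) % np);
      int c = (int)((key / np) % np);
      int d = (int)(key % np);
      out[iw + sA * a + sB * b + sC * c + sD * d] = val[key];
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

static inline void axis_weights(double x, double g0, double step, int n,
                                int &s, double wts[4], int &nn) {
  double u = (x - g0) / step;
  if (u < -1e-8 || u > n - 1 + 1e-8)
    stop("interpolation query outside the grid range");
  if (u < 0) u = 0;
  if (u > n - 1) u = n - 1;
  if (n >= 4) {
    int i0 = (int)std::floor(u);
    if (i0 > n - 2) i0 = n - 2;
    s = i0 - 1;
    if (s < 0) s = 0;
    if (s > n - 4) s = n - 4;
    double t = u - s;
    wts[0] = -(t - 1) * (t - 2) * (t - 3) / 6.0;
    wts[1] = t * (t - 2) * (t - 3) / 2.0;
    wts[2] = -t * (t - 1) * (t - 3) / 2.0;
    wts[3] = t * (t - 1) * (t - 2) / 6.0;
    nn = 4;
  } else {
    int i0 = (int)std::floor(u);
    if (i0 > n - 2) i0 = n - 2;
    if (i0 < 0) i0 = 0;
    s = i0;
    double t = u - i0;
    wts[0] = 1 - t;
    wts[1] = t;
    nn = 2;
  }
}

// Separable local cubic (Lagrange) interpolation of the 5-D table at query
// points (w, p1C, p1M, p2C, p2M); exact at grid nodes.
// [[Rcpp::export]]
NumericVector interp5_cpp(NumericVector table, int nw, int np,
                          NumericVector wgrid, NumericVector pgrid,
                          NumericMatrix queries) {
  const int nq = queries.nrow();
  NumericVector out(nq);
  const double w0 = wgrid[0], wstep = (wgrid[nw - 1] - wgrid[0]) / (nw - 1);
  const double p0 = pgrid[0], pstep = (pgrid[np - 1] - pgrid[0]) / (np - 1);
  const int64_t sA = nw, sB = (int64_t)nw * np, sC = sB * np, sD = sC * np;
  const double *T = REAL(table);

  for (int q = 0; q < nq; ++q) {
    int s[5], nn[5];
    double wt[5][4];
    axis_weights(queries(q, 0), w0, wstep, nw, s[0], wt[0], nn[0]);
    for (int ax = 1; ax < 5; ++ax)
      axis_weights(queries(q, ax), p0, pstep, np, s[ax], wt[ax], nn[ax]);
    double acc = 0.0;
    for (int i0 = 0; i0 < nn[0]; ++i0) {
      const double v0 = wt[0][i0];
      const int64_t o0 = s[0] + i0;
      for (int i1 = 0; i1 < nn[1]; ++i1) {
        const double v1 = v0 * wt[1][i1];
        const int64_t o1 = o0 + sA * (s[1] + i1);
        for (int i2 = 0; i2 < nn[2]; ++i2) {
          const double v2 = v1 * wt[2][i2];
          const int64_t o2 = o1 + sB * (s[2] + i2);
          for (int i3 = 0; i3 < nn[3]; ++i3) {
            const double v3 = v2 * wt[3][i3];
            const int64_t o3 = o2 + sC * (s[3] + i3);
            const double *base = T + o3;
            for (int i4 = 0; i4 < nn[4]; ++i4)
              acc += v3 * wt[4][i4] * base[sD * (s[4] + i4)];
          }
        }
      }
    }
    out[q] = acc;
  }
  return out;
}

// Expected-information gains for candidate stimulus pairs under the current
// posterior: gain(pair) = H(pbar) + sum_i post_i * SL_i(pair), where
// SL = L*log(L) + (1-L)*log(1-L) is precomputed per (combo, pair).
// [[Rcpp::export]]
NumericVector quest_gain_cpp(NumericVector post, NumericMatrix L,
                             NumericMatrix SL, IntegerVector cols) {
  const int n = post.size(), m = cols.size();
  NumericVector out(m);
  const double *p = REAL(post);
  for (int j = 0; j < m; ++j) {
    const int col = cols[j] - 1;
    const double *lc = &L(0, col);
    const double *sc = &SL(0, col);
    double pbar = 0.0, s = 0.0;
    for (int i = 0; i < n; ++i) {
      pbar += p[i] * lc[i];
      s += p[i] * sc[i];
    }
    double h = 0.0;
    if (pbar > 0.0 && pbar < 1.0)
      h = -(pbar * std::log(pbar) + (1.0 - pbar) * std::log(1.0 - pbar));
    out[j] = h + s;
  }
  return out;
}

// FNV-1a over the byte representation, for table content hashes
// [[Rcpp::export]]
std::string hash_doubles_cpp(NumericVector x) {
  const unsigned char *bytes = (const unsigned char *)REAL(x);
  const R_xlen_t n = x.size() * (R_xlen_t)sizeof(double);
  uint64_t h = 1469598103934665603ULL;
  for (R_xlen_t i = 0; i < n; ++i) {
    h ^= bytes[i];
    h *= 1099511628211ULL;
  }
  char buf[17];
  snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
  return std::string(buf);
}
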