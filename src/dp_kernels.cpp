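// Dynamic-programming kernels for recombination-aware diploid alignment.
//
// Integer coding convention shared with the R side: alphabet symbols are
// coded 1..K, the gap '-' is 0, and `cm` is a (K+1)x(K+1) cost matrix
// indexed directly by code (row/column 0 = gap), so cm(a, b) is the cost
// of pairing symbol a with symbol b in one alignment column.

#include <Rcpp.h>
#include <cstdint>
#include <limits>
#include <vector>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// Classic pair-wise edit distance, full matrix
// ---------------------------------------------------------------------------

// Traceback tie-break: diagonal, then consume A (deletion), then consume B
// (insertion); implemented by strict '<' on candidates evaluated in order.
// [[Rcpp::export]]
List cpp_edit_full(IntegerVector a, IntegerVector b, NumericMatrix cm,
                   bool traceback) {
  const int n = a.size(), m = b.size();
  std::vector<double> D((size_t)(n + 1) * (m + 1));
  std::vector<uint8_t> bp;
  if (traceback) bp.assign((size_t)(n + 1) * (m + 1), 0);
  const size_t W = m + 1;

  D[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    D[(size_t)i * W] = D[(size_t)(i - 1) * W] + cm(a[i - 1], 0);
    if (traceback) bp[(size_t)i * W] = 2;
  }
  for (int j = 1; j <= m; ++j) {
    D[j] = D[j - 1] + cm(0, b[j - 1]);
    if (traceback) bp[j] = 3;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double best = D[(size_t)(i - 1) * W + (j - 1)] + cm(a[i - 1], b[j - 1]);
      uint8_t code = 1;
      double v = D[(size_t)(i - 1) * W + j] + cm(a[i - 1], 0);
      if (v < best) { best = v; code = 2; }
      v = D[(size_t)i * W + (j - 1)] + cm(0, b[j - 1]);
      if (v < best) { best = v; code = 3; }
      D[(size_t)i * W + j] = best;
      if (traceback) bp[(size_t)i * W + j] = code;
    }
  }

  List out = List::create(_["distance"] = D[(size_t)n * W + m]);
  if (traceback) {
    std::vector<int> top, bot;
    int i = n, j = m;
    while (i > 0 || j > 0) {
      uint8_t code = bp[(size_t)i * W + j];
      if (code == 1)      { top.push_back(a[i - 1]); bot.push_back(b[j - 1]); --i; --j; }
      else if (code == 2) { top.push_back(a[i - 1]); bot.push_back(0);        --i; }
      else                { top.push_back(0);        bot.push_back(b[j - 1]); --j; }
    }
    std::reverse(top.begin(), top.end());
    std::reverse(bot.begin(), bot.end());
    out["top"] = IntegerVector(top.begin(), top.end());
    out["bottom"] = IntegerVector(bot.begin(), bot.end());
  }
  return out;
}

// ---------------------------------------------------------------------------
// Banded edit distance with threshold doubling
// ---------------------------------------------------------------------------

// One banded pass for threshold t; returns D[n, m] restricted to the band
// (+Inf off-band cells). Band covers diagonals j - i in hull{0, m-n} +/- r.
static double edit_band_pass(const IntegerVector &a, const IntegerVector &b,
                             const NumericMatrix &cm, int r,
                             std::vector<double> &D, std::vector<uint8_t> &bp,
                             int &dlo_out, int &W_out, bool traceback) {
  const int n = a.size(), m = b.size();
  const int dlo = std::min(0, m - n) - r, dhi = std::max(0, m - n) + r;
  const int W = dhi - dlo + 1;
  dlo_out = dlo; W_out = W;
  D.assign((size_t)(n + 1) * W, INF);
  if (traceback) bp.assign((size_t)(n + 1) * W, 0);

  for (int i = 0; i <= n; ++i) {
    const int jlo = std::max(0, i + dlo), jhi = std::min(m, i + dhi);
    for (int j = jlo; j <= jhi; ++j) {
      const int off = j - i - dlo;
      const size_t idx = (size_t)i * W + off;
      if (i == 0 && j == 0) { D[idx] = 0.0; continue; }
      double best = INF; uint8_t code = 0;
      if (i > 0 && j > 0) {  // diagonal: same offset in previous row
        double v = D[(size_t)(i - 1) * W + off] + cm(a[i - 1], b[j - 1]);
        if (v < best) { best = v; code = 1; }
      }
      if (i > 0 && off + 1 < W) {  // consume A only
        double v = D[(size_t)(i - 1) * W + off + 1] + cm(a[i - 1], 0);
        if (v < best) { best = v; code = 2; }
      }
      if (j > 0 && off - 1 >= 0) {  // consume B only
        double v = D[(size_t)i * W + off - 1] + cm(0, b[j - 1]);
        if (v < best) { best = v; code = 3; }
      }
      D[idx] = best;
      if (traceback) bp[idx] = code;
    }
  }
  return D[(size_t)n * W + (m - n - dlo)];
}

// [[Rcpp::export]]
List cpp_edit_banded(IntegerVector a, IntegerVector b, NumericMatrix cm,
                     double t0, double cmin, bool traceback) {
  const int n = a.size(), m = b.size();
  double t = t0;
  std::vector<double> D;
  std::vector<uint8_t> bp;
  int dlo = 0, W = 0;
  double d = INF;
  for (;;) {
    int r = (int)std::ceil(t / (2.0 * cmin));
    bool full = (std::min(0, m - n) - r <= -n) && (std::max(0, m - n) + r >= m);
    d = edit_band_pass(a, b, cm, r, D, bp, dlo, W, traceback);
    if (d <= t || full) break;
    t *= 2.0;
  }
  List out = List::create(_["distance"] = d, _["threshold"] = t);
  if (traceback) {
    std::vector<int> top, bot;
    int i = n, j = m;
    while (i > 0 || j > 0) {
      uint8_t code = bp[(size_t)i * W + (j - i - dlo)];
      if (code == 1)      { top.push_back(a[i - 1]); bot.push_back(b[j - 1]); --i; --j; }
      else if (code == 2) { top.push_back(a[i - 1]); bot.push_back(0);        --i; }
      else                { top.push_back(0);        bot.push_back(b[j - 1]); --j; }
    }
    std::reverse(top.begin(), top.end());
    std::reverse(bot.begin(), bot.end());
    out["top"] = IntegerVector(top.begin(), top.end());
    out["bottom"] = IntegerVector(bot.begin(), bot.end());
  }
  return out;
}

// ---------------------------------------------------------------------------
// Cubic pair-of-haploids-to-diploid DP
// ---------------------------------------------------------------------------

// Cell (i, j, k): distance between X[1..i], Y[1..j] and the recombined
// length-k prefix of the diploid alignment. Ten guarded expressions; cases
// 1,3,4,5 keep the original row orientation, 2,6,7,8 swap it, 9/10 delete
// from X/Y without consuming a diploid column. First minimal case (in
// numeric order) wins, which prefers the original orientation on ties.
// [[Rcpp::export]]
List cpp_hap2dip(IntegerVector x, IntegerVector y, IntegerVector acol,
                 IntegerVector bcol, NumericMatrix cm, bool traceback) {
  const int n = x.size(), m = y.size(), L = acol.size();
  const size_t planeW = m + 1, plane = (size_t)(n + 1) * (m + 1);
  std::vector<double> prev(plane), cur(plane);
  std::vector<uint8_t> bp;
  if (traceback) {
    double cells = (double)plane * (L + 1);
    if (cells > 6e8)
      stop("traceback table would need %.0f cells; use traceback = FALSE", cells);
    bp.assign((size_t)plane * (L + 1), 0);
  }

  // k = 0 plane: delete all consumed prefixes of X and Y
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) {
      double v; uint8_t code = 0;
      if (i == 0 && j == 0) v = 0.0;
      else if (i > 0) { v = cur[(size_t)(i - 1) * planeW + j] + cm(x[i - 1], 0); code = 9; }
      else            { v = cur[(size_t)i * planeW + (j - 1)] + cm(0, y[j - 1]); code = 10; }
      cur[(size_t)i * planeW + j] = v;
      if (traceback) bp[(size_t)i * planeW + j] = code;
    }

  for (int k = 1; k <= L; ++k) {
    std::swap(prev, cur);
    const int a = acol[k - 1], b = bcol[k - 1];
    uint8_t *bpk = traceback ? &bp[(size_t)k * plane] : NULL;
    for (int i = 0; i <= n; ++i) {
      for (int j = 0; j <= m; ++j) {
        double best = INF; uint8_t code = 0;
        const double xa = i > 0 ? cm(x[i - 1], a) : 0.0;
        const double xb = i > 0 ? cm(x[i - 1], b) : 0.0;
        const double ya = j > 0 ? cm(y[j - 1], a) : 0.0;
        const double yb = j > 0 ? cm(y[j - 1], b) : 0.0;
        double v;
        if (i > 0 && j > 0) {
          v = xa + yb + prev[(size_t)(i - 1) * planeW + (j - 1)];
          if (v < best) { best = v; code = 1; }
          v = xb + ya + prev[(size_t)(i - 1) * planeW + (j - 1)];
          if (v < best) { best = v; code = 2; }
        }
        if (j > 0) {
          v = cm(0, a) + yb + prev[(size_t)i * planeW + (j - 1)];
          if (v < best) { best = v; code = 3; }
        }
        if (i > 0) {
          v = xa + cm(0, b) + prev[(size_t)(i - 1) * planeW + j];
          if (v < best) { best = v; code = 4; }
        }
        v = cm(0, a) + cm(0, b) + prev[(size_t)i * planeW + j];
        if (v < best) { best = v; code = 5; }
        if (j > 0) {
          v = cm(0, b) + ya + prev[(size_t)i * planeW + (j - 1)];
          if (v < best) { best = v; code = 6; }
        }
        if (i > 0) {
          v = xb + cm(0, a) + prev[(size_t)(i - 1) * planeW + j];
          if (v < best) { best = v; code = 7; }
        }
        v = cm(0, b) + cm(0, a) + prev[(size_t)i * planeW + j];
        if (v < best) { best = v; code = 8; }
        if (i > 0) {
          v = cm(x[i - 1], 0) + cur[(size_t)(i - 1) * planeW + j];
          if (v < best) { best = v; code = 9; }
        }
        if (j > 0) {
          v = cm(0, y[j - 1]) + cur[(size_t)i * planeW + (j - 1)];
          if (v < best) { best = v; code = 10; }
        }
        cur[(size_t)i * planeW + j] = best;
        if (traceback) bpk[(size_t)i * planeW + j] = code;
      }
    }
  }

  List out = List::create(_["distance"] = cur[(size_t)n * planeW + m]);
  if (traceback) {
    // mask[k-1]: 1 = keep original orientation, 0 = swap, -1 = free (a == b)
    std::vector<int> mask(L, -1);
    std::vector<int> a1t, a1b, a2t, a2b;
    int i = n, j = m, k = L;
    while (i > 0 || j > 0 || k > 0) {
      uint8_t code = bp[(size_t)k * plane + (size_t)i * planeW + j];
      const int a = k > 0 ? acol[k - 1] : 0, b = k > 0 ? bcol[k - 1] : 0;
      switch (code) {
      case 1:  a1t.push_back(a); a1b.push_back(x[i-1]); a2t.push_back(b); a2b.push_back(y[j-1]);
               mask[k-1] = (a == b) ? -1 : 1; --i; --j; --k; break;
      case 2:  a1t.push_back(b); a1b.push_back(x[i-1]); a2t.push_back(a); a2b.push_back(y[j-1]);
               mask[k-1] = 0; --i; --j; --k; break;
      case 3:  a1t.push_back(a); a1b.push_back(0); a2t.push_back(b); a2b.push_back(y[j-1]);
               mask[k-1] = (a == b) ? -1 : 1; --j; --k; break;
      case 4:  a1t.push_back(a); a1b.push_back(x[i-1]); a2t.push_back(b); a2b.push_back(0);
               mask[k-1] = (a == b) ? -1 : 1; --i; --k; break;
      case 5:  a1t.push_back(a); a1b.push_back(0); a2t.push_back(b); a2b.push_back(0);
               mask[k-1] = (a == b) ? -1 : 1; --k; break;
      case 6:  a1t.push_back(b); a1b.push_back(0); a2t.push_back(a); a2b.push_back(y[j-1]);
               mask[k-1] = 0; --j; --k; break;
      case 7:  a1t.push_back(b); a1b.push_back(x[i-1]); a2t.push_back(a); a2b.push_back(0);
               mask[k-1] = 0; --i; --k; break;
      case 8:  a1t.push_back(b); a1b.push_back(0); a2t.push_back(a); a2b.push_back(0);
               mask[k-1] = 0; --k; break;
      case 9:  a1t.push_back(0); a1b.push_back(x[i-1]); --i; break;
      default: a2t.push_back(0); a2b.push_back(y[j-1]); --j; break;
      }
    }
    // Resolve orientation-free columns (identical alignment symbols) by
    // carrying the nearest decided orientation from the left; leading free
    // columns take the first decided value (or 1 if none), minimizing
    // spurious switch points.
    int first = 1;
    for (int z = 0; z < L; ++z) if (mask[z] != -1) { first = mask[z]; break; }
    int carry = first;
    for (int z = 0; z < L; ++z) {
      if (mask[z] == -1) mask[z] = carry; else carry = mask[z];
    }
    std::reverse(a1t.begin(), a1t.end()); std::reverse(a1b.begin(), a1b.end());
    std::reverse(a2t.begin(), a2t.end()); std::reverse(a2b.begin(), a2b.end());
    out["mask"] = IntegerVector(mask.begin(), mask.end());
    out["aln1_top"] = IntegerVector(a1t.begin(), a1t.end());
    out["aln1_bottom"] = IntegerVector(a1b.begin(), a1b.end());
    out["aln2_top"] = IntegerVector(a2t.begin(), a2t.end());
    out["aln2_bottom"] = IntegerVector(a2b.begin(), a2b.end());
  }
  return out;
}

// ---------------------------------------------------------------------------
// Synchronized diploid-to-diploid DP (full table, two orientation layers)
// ---------------------------------------------------------------------------

// State: (z, k, o) where z indexes guide-alignment columns, k indexes
// diploid-alignment columns, and o is the orientation (1 = original rows,
// 0 = swapped) of the most recently consumed diploid column. A per-switch
// recombination penalty is charged when consecutive consumed diploid
// columns change orientation. With penalty 0 the two layers coincide and
// the recurrence reduces to the per-column orientation minimum.
// [[Rcpp::export]]
List cpp_sync_full(IntegerVector x, IntegerVector y, IntegerVector hi,
                   IntegerVector hj, IntegerVector acol, IntegerVector bcol,
                   NumericMatrix cm, double penalty, bool traceback,
                   bool keep_table) {
  const int L1 = hi.size() - 1, L2 = acol.size();
  const size_t W = (size_t)(L2 + 1) * 2;
  std::vector<double> D((size_t)(L1 + 1) * W, INF);
  std::vector<uint8_t> bp;
  if (traceback) bp.assign((size_t)(L1 + 1) * W, 0);
  // bp byte: low nibble = step (1 diag, 2 k-only, 3 z-only), bit 4 = o_prev

  for (int z = 0; z <= L1; ++z) {
    int dhi_ = 0, dhj_ = 0, xi = 0, yj = 0;
    double zonly = 0.0;
    if (z > 0) {
      dhi_ = hi[z] - hi[z - 1]; dhj_ = hj[z] - hj[z - 1];
      if (dhi_) xi = x[hi[z] - 1];
      if (dhj_) yj = y[hj[z] - 1];
      zonly = (dhi_ ? cm(xi, 0) : 0.0) + (dhj_ ? cm(0, yj) : 0.0);
    }
    for (int k = 0; k <= L2; ++k) {
      double diag_c[2] = {0.0, 0.0}, konly = 0.0;
      if (k > 0) {
        const int a = acol[k - 1], b = bcol[k - 1];
        diag_c[1] = (dhi_ ? cm(xi, a) : cm(0, a)) + (dhj_ ? cm(yj, b) : cm(0, b));
        diag_c[0] = (dhi_ ? cm(xi, b) : cm(0, b)) + (dhj_ ? cm(yj, a) : cm(0, a));
        konly = cm(0, a) + cm(0, b);
      }
      for (int o = 1; o >= 0; --o) {
        const size_t idx = (size_t)z * W + (size_t)k * 2 + o;
        if (z == 0 && k == 0) { D[idx] = 0.0; continue; }
        double best = INF; uint8_t code = 0; double v;
        if (z > 0 && k > 0) {
          v = D[(size_t)(z - 1) * W + (size_t)(k - 1) * 2 + o] + diag_c[o];
          if (v < best) { best = v; code = 1 | (o << 4); }
          if (k >= 2) {
            v = D[(size_t)(z - 1) * W + (size_t)(k - 1) * 2 + (1 - o)] +
                diag_c[o] + penalty;
            if (v < best) { best = v; code = 1 | ((1 - o) << 4); }
          }
        }
        if (k > 0) {
          v = D[(size_t)z * W + (size_t)(k - 1) * 2 + o] + konly;
          if (v < best) { best = v; code = 2 | (o << 4); }
          if (k >= 2) {
            v = D[(size_t)z * W + (size_t)(k - 1) * 2 + (1 - o)] + konly + penalty;
            if (v < best) { best = v; code = 2 | ((1 - o) << 4); }
          }
        }
        if (z > 0) {
          v = D[(size_t)(z - 1) * W + (size_t)k * 2 + o] + zonly;
          if (v < best) { best = v; code = 3 | (o << 4); }
        }
        D[idx] = best;
        if (traceback) bp[idx] = code;
      }
    }
  }

  const double d1 = D[(size_t)L1 * W + (size_t)L2 * 2 + 1];
  const double d0 = D[(size_t)L1 * W + (size_t)L2 * 2 + 0];
  List out = List::create(_["distance"] = std::min(d1, d0));

  if (keep_table) {
    NumericMatrix T(L1 + 1, L2 + 1);
    for (int z = 0; z <= L1; ++z)
      for (int k = 0; k <= L2; ++k)
        T(z, k) = std::min(D[(size_t)z * W + (size_t)k * 2 + 1],
                           D[(size_t)z * W + (size_t)k * 2 + 0]);
    out["table"] = T;
  }

  if (traceback) {
    std::vector<int> mask(L2, 1);
    std::vector<int> a1t, a1b, a2t, a2b;
    int z = L1, k = L2, o = (d1 <= d0) ? 1 : 0;
    while (z > 0 || k > 0) {
      uint8_t code = bp[(size_t)z * W + (size_t)k * 2 + o];
      const int step = code & 0x0F, oprev = (code >> 4) & 1;
      const int a = k > 0 ? acol[k - 1] : 0, b = k > 0 ? bcol[k - 1] : 0;
      int dhi_ = 0, dhj_ = 0;
      if (z > 0) { dhi_ = hi[z] - hi[z - 1]; dhj_ = hj[z] - hj[z - 1]; }
      if (step == 1) {
        mask[k - 1] = o;
        a1t.push_back(o ? a : b); a1b.push_back(dhi_ ? x[hi[z] - 1] : 0);
        a2t.push_back(o ? b : a); a2b.push_back(dhj_ ? y[hj[z] - 1] : 0);
        --z; --k; o = oprev;
      } else if (step == 2) {
        mask[k - 1] = o;
        a1t.push_back(o ? a : b); a1b.push_back(0);
        a2t.push_back(o ? b : a); a2b.push_back(0);
        --k; o = oprev;
      } else {
        if (dhi_) { a1t.push_back(0); a1b.push_back(x[hi[z] - 1]); }
        if (dhj_) { a2t.push_back(0); a2b.push_back(y[hj[z] - 1]); }
        --z;
      }
    }
    std::reverse(a1t.begin(), a1t.end()); std::reverse(a1b.begin(), a1b.end());
    std::reverse(a2t.begin(), a2t.end()); std::reverse(a2b.begin(), a2b.end());
    out["mask"] = IntegerVector(mask.begin(), mask.end());
    out["aln1_top"] = IntegerVector(a1t.begin(), a1t.end());
    out["aln1_bottom"] = IntegerVector(a1b.begin(), a1b.end());
    out["aln2_top"] = IntegerVector(a2t.begin(), a2t.end());
    out["aln2_bottom"] = IntegerVector(a2b.begin(), a2b.end());
  }
  return out;
}

// ---------------------------------------------------------------------------
// Banded synchronized DP with threshold doubling (distance only)
// ---------------------------------------------------------------------------

static double sync_band_pass(const IntegerVector &x, const IntegerVector &y,
                             const IntegerVector &hi, const IntegerVector &hj,
                             const IntegerVector &acol, const IntegerVector &bcol,
                             const NumericMatrix &cm, double penalty, int r) {
  const int L1 = hi.size() - 1, L2 = acol.size();
  const int dlo = std::min(0, L1 - L2) - r, dhi_band = std::max(0, L1 - L2) + r;
  const int W = dhi_band - dlo + 1;
  std::vector<double> D((size_t)(L1 + 1) * W * 2, INF);

  for (int z = 0; z <= L1; ++z) {
    int dhi_ = 0, dhj_ = 0, xi = 0, yj = 0;
    double zonly = 0.0;
    if (z > 0) {
      dhi_ = hi[z] - hi[z - 1]; dhj_ = hj[z] - hj[z - 1];
      if (dhi_) xi = x[hi[z] - 1];
      if (dhj_) yj = y[hj[z] - 1];
      zonly = (dhi_ ? cm(xi, 0) : 0.0) + (dhj_ ? cm(0, yj) : 0.0);
    }
    const int klo = std::max(0, z - dhi_band), khi = std::min(L2, z - dlo);
    for (int k = klo; k <= khi; ++k) {
      const int off = z - k - dlo;
      double diag_c[2] = {0.0, 0.0}, konly = 0.0;
      if (k > 0) {
        const int a = acol[k - 1], b = bcol[k - 1];
        diag_c[1] = (dhi_ ? cm(xi, a) : cm(0, a)) + (dhj_ ? cm(yj, b) : cm(0, b));
        diag_c[0] = (dhi_ ? cm(xi, b) : cm(0, b)) + (dhj_ ? cm(yj, a) : cm(0, a));
        konly = cm(0, a) + cm(0, b);
      }
      for (int o = 0; o < 2; ++o) {
        const size_t idx = ((size_t)z * W + off) * 2 + o;
        if (z == 0 && k == 0) { D[idx] = 0.0; continue; }
        double best = INF, v;
        if (z > 0 && k > 0) {  // diagonal: same offset
          v = D[((size_t)(z - 1) * W + off) * 2 + o] + diag_c[o];
          if (v < best) best = v;
          if (k >= 2) {
            v = D[((size_t)(z - 1) * W + off) * 2 + (1 - o)] + diag_c[o] + penalty;
            if (v < best) best = v;
          }
        }
        if (k > 0 && off + 1 < W) {  // k-only: offset + 1, same row
          v = D[((size_t)z * W + off + 1) * 2 + o] + konly;
          if (v < best) best = v;
          if (k >= 2) {
            v = D[((size_t)z * W + off + 1) * 2 + (1 - o)] + konly + penalty;
            if (v < best) best = v;
          }
        }
        if (z > 0 && off - 1 >= 0) {  // z-only: offset - 1, previous row
          v = D[((size_t)(z - 1) * W + off - 1) * 2 + o] + zonly;
          if (v < best) best = v;
        }
        D[idx] = best;
      }
    }
  }
  const int off_end = L1 - L2 - dlo;
  return std::min(D[((size_t)L1 * W + off_end) * 2 + 0],
                  D[((size_t)L1 * W + off_end) * 2 + 1]);
}

// [[Rcpp::export]]
List cpp_sync_banded(IntegerVector x, IntegerVector y, IntegerVector hi,
                     IntegerVector hj, IntegerVector acol, IntegerVector bcol,
                     NumericMatrix cm, double penalty, double t0, double cmin) {
  const int L1 = hi.size() - 1, L2 = acol.size();
  double t = t0, d = INF;
  for (;;) {
    int r = (int)std::ceil(t / (2.0 * cmin));
    bool full = (std::min(0, L1 - L2) - r <= -L2) &&
                (std::max(0, L1 - L2) + r >= L1);
    d = sync_band_pass(x, y, hi, hj, acol, bcol, cm, penalty, r);
    if (d <= t || full) break;
    t *= 2.0;
  }
  return List::create(_["distance"] = d, _["threshold"] = t);
}
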