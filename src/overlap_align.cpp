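// Ends-free (overlap) pairwise alignment with affine gaps, Gotoh-style.
// Scoring: match +1, mismatch -1, gap open 2, gap extension 0.5 per base
// (scaled by 2 internally so all scores are integers). Terminal gaps in
// either sequence are free and excluded from the reported alignment
// columns, which is what read-vs-consensus identity needs.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>

using namespace Rcpp;

static const int NEG = INT_MIN / 4;
static const int MATCH = 2;     // +1 scaled
static const int MISMATCH = -2; // -1 scaled
static const int GAP_FIRST = 5; // open (2) + one extension (0.5), scaled
static const int GAP_EXT = 1;   // 0.5 scaled

struct AlnResult {
  int score2;   // scaled score of the overlap region
  int matches;
  int cols;
  int p_start, p_end, s_start, s_end; // 1-based inclusive; 0 if empty
  std::string p_aln, s_aln;
};

// States: 0 = M (diagonal), 1 = Ix (gap in subject, consumes pattern),
// 2 = Iy (gap in pattern, consumes subject), 3 = alignment start.
static AlnResult overlap_align_one(const std::string& a, const std::string& b,
                                   bool want_strings) {
  const int n = (int)a.size(), m = (int)b.size();
  const size_t W = (size_t)m + 1;
  std::vector<int> M((size_t)(n + 1) * W, NEG), Ix(M), Iy(M);
  std::vector<unsigned char> tbM(M.size(), 0), tbX(M.size(), 0),
      tbY(M.size(), 0);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t k = (size_t)i * W + j;
      const int s = (a[(size_t)i - 1] == b[(size_t)j - 1]) ? MATCH : MISMATCH;
      // M from the best state at (i-1, j-1); borders start the alignment.
      if (i == 1 || j == 1) {
        M[k] = s;
        tbM[k] = 3;
      } else {
        const size_t kp = (size_t)(i - 1) * W + (j - 1);
        int best = M[kp];
        unsigned char st = 0;
        if (Ix[kp] > best) { best = Ix[kp]; st = 1; }
        if (Iy[kp] > best) { best = Iy[kp]; st = 2; }
        M[k] = best + s;
        tbM[k] = st;
      }
      // Ix: gap in subject (consumes pattern); never opens from a border.
      if (i >= 2) {
        const size_t ku = (size_t)(i - 1) * W + j;
        const int open = M[ku] - GAP_FIRST;
        const int ext = Ix[ku] - GAP_EXT;
        Ix[k] = open >= ext ? open : ext;
        tbX[k] = open >= ext ? 0 : 1;
      }
      // Iy: gap in pattern (consumes subject).
      if (j >= 2) {
        const size_t kl = (size_t)i * W + (j - 1);
        const int open = M[kl] - GAP_FIRST;
        const int ext = Iy[kl] - GAP_EXT;
        Iy[k] = open >= ext ? open : ext;
        tbY[k] = open >= ext ? 0 : 1;
      }
    }
  }
  // Overlap region ends at an M cell on the last row or last column
  // (trailing gaps are clipped, not scored).
  int best = NEG, bi = 0, bj = 0;
  for (int j = 1; j <= m; ++j) {
    if (M[(size_t)n * W + j] > best) {
      best = M[(size_t)n * W + j]; bi = n; bj = j;
    }
  }
  for (int i = 1; i <= n; ++i) {
    if (M[(size_t)i * W + m] > best) {
      best = M[(size_t)i * W + m]; bi = i; bj = m;
    }
  }
  AlnResult res;
  res.score2 = best;
  res.matches = 0; res.cols = 0;
  res.p_start = res.p_end = res.s_start = res.s_end = 0;
  if (n == 0 || m == 0 || bi == 0) return res;
  res.p_end = bi; res.s_end = bj;
  int i = bi, j = bj;
  unsigned char state = 0;
  std::string pa, sa;
  for (;;) {
    const size_t k = (size_t)i * W + j;
    if (state == 0) {
      res.cols += 1;
      if (a[(size_t)i - 1] == b[(size_t)j - 1]) res.matches += 1;
      if (want_strings) {
        pa.push_back(a[(size_t)i - 1]);
        sa.push_back(b[(size_t)j - 1]);
      }
      res.p_start = i; res.s_start = j;
      const unsigned char st = tbM[k];
      i -= 1; j -= 1;
      if (st == 3) break;
      state = st;
    } else if (state == 1) {
      res.cols += 1;
      if (want_strings) { pa.push_back(a[(size_t)i - 1]); sa.push_back('-'); }
      const unsigned char st = tbX[k];
      i -= 1;
      state = st == 0 ? 0 : 1;
    } else {
      res.cols += 1;
      if (want_strings) { pa.push_back('-'); sa.push_back(b[(size_t)j - 1]); }
      const unsigned char st = tbY[k];
      j -= 1;
      state = st == 0 ? 0 : 2;
    }
  }
  if (want_strings) {
    res.p_aln.assign(pa.rbegin(), pa.rend());
    res.s_aln.assign(sa.rbegin(), sa.rend());
  }
  return res;
}

// Identity with containment correction: alignment columns plus whatever
// part of the SHORTER sequence was left out of the overlap region. A short
// sequence fully contained in a long one is judged on its own length; a
// trivial short overlap between unrelated sequences scores near zero.
static double containment_identity(int n, int m, int matches, int cols,
                                   int p_cov, int s_cov) {
  if (cols <= 0) return 0.0;
  const int uncovered = (n <= m) ? (n - p_cov) : (m - s_cov);
  return (double)matches / (cols + (uncovered > 0 ? uncovered : 0));
}

// [[Rcpp::export(name = ".overlap_align")]]
List overlap_align_cpp(std::string pattern, std::string subject) {
  AlnResult r = overlap_align_one(pattern, subject, true);
  const int p_cov = r.p_end > 0 ? r.p_end - r.p_start + 1 : 0;
  const int s_cov = r.s_end > 0 ? r.s_end - r.s_start + 1 : 0;
  return List::create(
    _["score"] = r.score2 / 2.0,
    _["matches"] = r.matches,
    _["cols"] = r.cols,
    _["identity"] = containment_identity((int)pattern.size(),
                                         (int)subject.size(), r.matches,
                                         r.cols, p_cov, s_cov),
    _["p_start"] = r.p_start, _["p_end"] = r.p_end,
    _["s_start"] = r.s_start, _["s_end"] = r.s_end,
    _["p_aln"] = r.p_aln, _["s_aln"] = r.s_aln);
}

// Rolling two-row scoring-only variant: tracks (score, matches, cols) per
// state so identity needs no traceback and only O(m) memory.
struct Cell { int sc, ma, co; };

static double overlap_identity_fast(const std::string& a,
                                    const std::string& b) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) return 0.0;
  // Scores, matches, columns and region starts are packed per state into
  // parallel arrays; two rolling rows. Row layout: index j in [0, m].
  std::vector<int> buf(10 * 3 * (m + 1), NEG);
  int* Msc_p = buf.data();            int* Msc_c = Msc_p + (m + 1);
  int* Xsc_p = Msc_c + (m + 1);       int* Xsc_c = Xsc_p + (m + 1);
  int* Ysc_p = Xsc_c + (m + 1);       int* Ysc_c = Ysc_p + (m + 1);
  int* Mma_p = Ysc_c + (m + 1);       int* Mma_c = Mma_p + (m + 1);
  int* Xma_p = Mma_c + (m + 1);       int* Xma_c = Xma_p + (m + 1);
  int* Yma_p = Xma_c + (m + 1);       int* Yma_c = Yma_p + (m + 1);
  int* Mco_p = Yma_c + (m + 1);       int* Mco_c = Mco_p + (m + 1);
  int* Xco_p = Mco_c + (m + 1);       int* Xco_c = Xco_p + (m + 1);
  int* Yco_p = Xco_c + (m + 1);       int* Yco_c = Yco_p + (m + 1);
  int* Mps_p = Yco_c + (m + 1);       int* Mps_c = Mps_p + (m + 1);
  int* Xps_p = Mps_c + (m + 1);       int* Xps_c = Xps_p + (m + 1);
  int* Yps_p = Xps_c + (m + 1);       int* Yps_c = Yps_p + (m + 1);
  int* Mss_p = Yps_c + (m + 1);       int* Mss_c = Mss_p + (m + 1);
  int* Xss_p = Mss_c + (m + 1);       int* Xss_c = Xss_p + (m + 1);
  int* Yss_p = Xss_c + (m + 1);       int* Yss_c = Yss_p + (m + 1);
  int best_sc = NEG, best_ma = 0, best_co = 0;
  int best_pcov = 0, best_scov = 0;
  for (int i = 1; i <= n; ++i) {
    const char ai = a[(size_t)i - 1];
    Msc_c[0] = Xsc_c[0] = Ysc_c[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      const bool eq = ai == b[(size_t)j - 1];
      // M
      int fsc = 0, fma = 0, fco = 0, fps = i, fss = j;
      if (i > 1 && j > 1) {
        fsc = Msc_p[j - 1]; fma = Mma_p[j - 1]; fco = Mco_p[j - 1];
        fps = Mps_p[j - 1]; fss = Mss_p[j - 1];
        if (Xsc_p[j - 1] > fsc) {
          fsc = Xsc_p[j - 1]; fma = Xma_p[j - 1]; fco = Xco_p[j - 1];
          fps = Xps_p[j - 1]; fss = Xss_p[j - 1];
        }
        if (Ysc_p[j - 1] > fsc) {
          fsc = Ysc_p[j - 1]; fma = Yma_p[j - 1]; fco = Yco_p[j - 1];
          fps = Yps_p[j - 1]; fss = Yss_p[j - 1];
        }
      }
      const int msc = fsc + (eq ? MATCH : MISMATCH);
      const int mma = fma + (eq ? 1 : 0);
      const int mco = fco + 1;
      Msc_c[j] = msc; Mma_c[j] = mma; Mco_c[j] = mco;
      Mps_c[j] = fps; Mss_c[j] = fss;
      // Ix (gap in subject)
      if (i > 1) {
        if (Msc_p[j] - GAP_FIRST >= Xsc_p[j] - GAP_EXT) {
          Xsc_c[j] = Msc_p[j] - GAP_FIRST;
          Xma_c[j] = Mma_p[j]; Xco_c[j] = Mco_p[j] + 1;
          Xps_c[j] = Mps_p[j]; Xss_c[j] = Mss_p[j];
        } else {
          Xsc_c[j] = Xsc_p[j] - GAP_EXT;
          Xma_c[j] = Xma_p[j]; Xco_c[j] = Xco_p[j] + 1;
          Xps_c[j] = Xps_p[j]; Xss_c[j] = Xss_p[j];
        }
      } else {
        Xsc_c[j] = NEG;
      }
      // Iy (gap in pattern)
      if (j > 1) {
        if (Msc_c[j - 1] - GAP_FIRST >= Ysc_c[j - 1] - GAP_EXT) {
          Ysc_c[j] = Msc_c[j - 1] - GAP_FIRST;
          Yma_c[j] = Mma_c[j - 1]; Yco_c[j] = Mco_c[j - 1] + 1;
          Yps_c[j] = Mps_c[j - 1]; Yss_c[j] = Mss_c[j - 1];
        } else {
          Ysc_c[j] = Ysc_c[j - 1] - GAP_EXT;
          Yma_c[j] = Yma_c[j - 1]; Yco_c[j] = Yco_c[j - 1] + 1;
          Yps_c[j] = Yps_c[j - 1]; Yss_c[j] = Yss_c[j - 1];
        }
      } else {
        Ysc_c[j] = NEG;
      }
      if ((i == n || j == m) && msc > best_sc) {
        best_sc = msc; best_ma = mma; best_co = mco;
        best_pcov = i - fps + 1; best_scov = j - fss + 1;
      }
    }
    std::swap(Msc_p, Msc_c); std::swap(Xsc_p, Xsc_c); std::swap(Ysc_p, Ysc_c);
    std::swap(Mma_p, Mma_c); std::swap(Xma_p, Xma_c); std::swap(Yma_p, Yma_c);
    std::swap(Mco_p, Mco_c); std::swap(Xco_p, Xco_c); std::swap(Yco_p, Yco_c);
    std::swap(Mps_p, Mps_c); std::swap(Xps_p, Xps_c); std::swap(Yps_p, Yps_c);
    std::swap(Mss_p, Mss_c); std::swap(Xss_p, Xss_c); std::swap(Yss_p, Yss_c);
  }
  return containment_identity(n, m, best_ma, best_co, best_pcov, best_scov);
}

// [[Rcpp::export(name = ".overlap_identity_many")]]
NumericVector overlap_identity_many(CharacterVector patterns,
                                    std::string subject) {
  NumericVector out(patterns.size());
  for (R_xlen_t i = 0; i < patterns.size(); ++i) {
    out[i] = overlap_identity_fast(as<std::string>(patterns[i]), subject);
  }
  return out;
}
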