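#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Local (Smith-Waterman) alignment with affine gaps, Gotoh three-state DP.
//
// Among all alignments the DP optimizes lexicographically:
//   (1) score, (2) number of identical aligned residue pairs (matches),
//   (3) fewest alignment columns.
// This makes the reported identity well-defined (and swap-symmetric) even
// when several alignments share the optimal score. The aligned spans are
// propagated forward through the DP (no traceback); on exact value ties the
// predecessor priority is M > X > Y > restart, and the reported endpoint is
// the first best M cell in row-major order.
//
// Gap convention: a gap of length L costs gap_open + L * gap_ext.
// Gap states open from the match state only and extend from themselves;
// score-lossless as long as the most negative substitution score exceeds
// -2 * (gap_open + gap_ext) (true for BLOSUM62 with 11/1): an insertion
// column adjacent to a deletion column is then always beaten by a
// substitution column.

namespace {

const int NEG = -1000000000;

struct Cell {
  int score, matches, cols, qs, ts;
};

// strict lexicographic improvement of (s, m, c) over `cur`
inline bool improves(const Cell &cur, int s, int m, int c) {
  if (s != cur.score) return s > cur.score;
  if (m != cur.matches) return m > cur.matches;
  return c < cur.cols;
}

struct AlnResult {
  int score, matches, cols, qstart, qend, tstart, tend;
};

AlnResult align_core(const int *a, int la, const int *b, int lb,
                     const IntegerMatrix &sub, int gap_open, int gap_ext) {
  const int W = lb + 1;
  const Cell INVALID = { NEG, 0, 0, 0, 0 };
  std::vector<Cell> Mprev(W, INVALID), Mcur(W, INVALID);
  std::vector<Cell> Xprev(W, INVALID), Xcur(W, INVALID);
  std::vector<Cell> Yprev(W, INVALID), Ycur(W, INVALID);

  Cell best = { 0, 0, 0, 0, 0 };
  int bqend = 0, btend = 0;

  for (int i = 1; i <= la; ++i) {
    Mcur[0] = Xcur[0] = Ycur[0] = INVALID;
    for (int j = 1; j <= lb; ++j) {
      const int sc = sub(a[i - 1], b[j - 1]);
      const int eq = (a[i - 1] == b[j - 1]) ? 1 : 0;

      // M: substitution column; predecessor priority M > X > Y > restart
      Cell m = INVALID;
      const Cell &md = Mprev[j - 1], &xd = Xprev[j - 1], &yd = Yprev[j - 1];
      if (md.score > NEG) m = md;
      if (xd.score > NEG &&
          improves(m, xd.score, xd.matches, xd.cols)) m = xd;
      if (yd.score > NEG &&
          improves(m, yd.score, yd.matches, yd.cols)) m = yd;
      if (m.score > NEG) {
        m.score += sc; m.matches += eq; m.cols += 1;
      }
      // restart: a fresh alignment beginning at (i, j), lowest priority
      Cell r = { sc, eq, 1, i, j };
      if (m.score == NEG || improves(m, r.score, r.matches, r.cols)) m = r;
      Mcur[j] = m;

      // X: gap in target (consume a[i]); open from M, extend from X
      Cell x = INVALID;
      const Cell &mu = Mprev[j], &xu = Xprev[j];
      if (mu.score > NEG) {
        x = mu; x.score -= gap_open + gap_ext; x.cols += 1;
      }
      if (xu.score > NEG) {
        int s2 = xu.score - gap_ext, c2 = xu.cols + 1;
        if (x.score == NEG || improves(x, s2, xu.matches, c2)) {
          x = xu; x.score = s2; x.cols = c2;
        }
      }
      Xcur[j] = x;

      // Y: gap in query (consume b[j]); open from M, extend from Y
      Cell y = INVALID;
      const Cell &ml = Mcur[j - 1], &yl = Ycur[j - 1];
      if (ml.score > NEG) {
        y = ml; y.score -= gap_open + gap_ext; y.cols += 1;
      }
      if (yl.score > NEG) {
        int s2 = yl.score - gap_ext, c2 = yl.cols + 1;
        if (y.score == NEG || improves(y, s2, yl.matches, c2)) {
          y = yl; y.score = s2; y.cols = c2;
        }
      }
      Ycur[j] = y;

      if (m.score > NEG && improves(best, m.score, m.matches, m.cols)) {
        best = m; bqend = i; btend = j;
      }
    }
    std::swap(Mprev, Mcur);
    std::swap(Xprev, Xcur);
    std::swap(Yprev, Ycur);
  }

  AlnResult r;
  if (best.score <= 0) {
    r.score = 0; r.matches = 0; r.cols = 0;
    r.qstart = r.qend = r.tstart = r.tend = 0;
  } else {
    r.score = best.score; r.matches = best.matches; r.cols = best.cols;
    r.qstart = best.qs; r.qend = bqend;
    r.tstart = best.ts; r.tend = btend;
  }
  return r;
}

} // namespace

// Alignment of integer-encoded sequences a (query) and b (target).
// [[Rcpp::export(name = ".cpp_align")]]
List cpp_align(IntegerVector a, IntegerVector b, IntegerMatrix sub,
               int gap_open, int gap_ext) {
  AlnResult r = align_core(a.begin(), a.size(), b.begin(), b.size(), sub,
                           gap_open, gap_ext);
  return List::create(_["score"] = r.score, _["matches"] = r.matches,
                      _["cols"] = r.cols, _["qstart"] = r.qstart,
                      _["qend"] = r.qend, _["tstart"] = r.tstart,
                      _["tend"] = r.tend);
}

// Batch alignment of one query against many targets; one row per target.
// [[Rcpp::export(name = ".cpp_align_batch")]]
NumericMatrix cpp_align_batch(IntegerVector a, List bs, IntegerMatrix sub,
                              int gap_open, int gap_ext) {
  const int n = bs.size();
  NumericMatrix out(n, 7);
  colnames(out) = CharacterVector::create("score", "matches", "cols",
                                          "qstart", "qend", "tstart", "tend");
  for (int k = 0; k < n; ++k) {
    IntegerVector b = bs[k];
    AlnResult r = align_core(a.begin(), a.size(), b.begin(), b.size(), sub,
                             gap_open, gap_ext);
    out(k, 0) = r.score; out(k, 1) = r.matches; out(k, 2) = r.cols;
    out(k, 3) = r.qstart; out(k, 4) = r.qend;
    out(k, 5) = r.tstart; out(k, 6) = r.tend;
  }
  return out;
}
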