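#include <Rcpp.h>
#include <climits>
#include <string>
#include <vector>

using namespace Rcpp;

namespace {

const int NEG = INT_MIN / 4;

struct AlignResult {
  std::string a, b;
  int score;
};

inline int subScore(char x, char y, int match, int mismatch) {
  return x == y ? match : mismatch;
}

// Affine-gap global (Needleman-Wunsch) alignment.
// A gap of length k costs gapOpen + k * gapExtend (both negative).
// Traceback ties are broken diagonal > up (gap in b) > left (gap in a),
// applied through the state preference M > X > Y.
AlignResult nwAlign(const std::string& a, const std::string& b,
                    int match, int mismatch, int gapOpen, int gapExt) {
  const int n = (int)a.size(), m = (int)b.size();
  const int W = m + 1;
  std::vector<int> M((size_t)(n + 1) * W, NEG);
  std::vector<int> X((size_t)(n + 1) * W, NEG); // gap in b, consumes a ("up")
  std::vector<int> Y((size_t)(n + 1) * W, NEG); // gap in a, consumes b ("left")
  M[0] = 0;
  for (int i = 1; i <= n; ++i) X[(size_t)i * W] = gapOpen + i * gapExt;
  for (int j = 1; j <= m; ++j) Y[j] = gapOpen + j * gapExt;
  for (int i = 1; i <= n; ++i) {
    const size_t r = (size_t)i * W, p = (size_t)(i - 1) * W;
    for (int j = 1; j <= m; ++j) {
      int d = std::max(M[p + j - 1], std::max(X[p + j - 1], Y[p + j - 1]));
      M[r + j] = (d <= NEG) ? NEG : d + subScore(a[i - 1], b[j - 1], match, mismatch);
      X[r + j] = std::max(std::max(M[p + j] + gapOpen + gapExt, X[p + j] + gapExt),
                          Y[p + j] + gapOpen + gapExt);
      Y[r + j] = std::max(std::max(M[r + j - 1] + gapOpen + gapExt, Y[r + j - 1] + gapExt),
                          X[r + j - 1] + gapOpen + gapExt);
    }
  }
  const size_t rn = (size_t)n * W;
  int best = std::max(M[rn + m], std::max(X[rn + m], Y[rn + m]));
  int state = (M[rn + m] == best) ? 0 : (X[rn + m] == best ? 1 : 2);
  std::string ra, rb;
  ra.reserve(n + m);
  rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const size_t r = (size_t)i * W;
    if (state == 0) {
      ra.push_back(a[i - 1]);
      rb.push_back(b[j - 1]);
      int target = M[r + j] - subScore(a[i - 1], b[j - 1], match, mismatch);
      --i;
      --j;
      if (i == 0 && j == 0) break;
      const size_t q = (size_t)i * W;
      if (M[q + j] == target) state = 0;
      else if (X[q + j] == target) state = 1;
      else state = 2;
    } else if (state == 1) {
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      int v = X[r + j];
      --i;
      const size_t q = (size_t)i * W;
      if (M[q + j] + gapOpen + gapExt == v) state = 0;
      else if (X[q + j] + gapExt == v) state = 1;
      else state = 2;
    } else {
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      int v = Y[r + j];
      --j;
      if (M[r + j] + gapOpen + gapExt == v) state = 0;
      else if (Y[r + j] + gapExt == v) state = 2;
      else state = 1;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  AlignResult res;
  res.a = ra;
  res.b = rb;
  res.score = best;
  return res;
}

// Column counting for the uncorrected distance on an aligned pair.
// gapRunAsOne: each maximal gap run (within one sequence) contributes one
// difference and one comparable position; otherwise per-column.
// ignoreTerminal: columns in the leading/trailing region where either
// sequence is gapped are excluded.
void alignedCounts(const std::string& A, const std::string& B,
                   bool gapRunAsOne, bool ignoreTerminal,
                   double& diff, double& pos) {
  const int L = (int)A.size();
  int start = 0, end = L - 1;
  if (ignoreTerminal) {
    while (start < L && (A[start] == '-' || B[start] == '-')) ++start;
    while (end >= 0 && (A[end] == '-' || B[end] == '-')) --end;
  }
  diff = 0;
  pos = 0;
  int i = start;
  while (i <= end) {
    bool ga = A[i] == '-', gb = B[i] == '-';
    if (!ga && !gb) {
      pos += 1;
      if (A[i] != B[i]) diff += 1;
      ++i;
    } else if (gapRunAsOne) {
      bool inA = ga;
      int k = i;
      while (k <= end && ((inA ? A[k] : B[k]) == '-')) ++k;
      diff += 1;
      pos += 1;
      i = k;
    } else {
      diff += 1;
      pos += 1;
      ++i;
    }
  }
}

double pairDistance(const std::string& a, const std::string& b,
                    int match, int mismatch, int gapOpen, int gapExt,
                    bool gapRunAsOne, bool ignoreTerminal) {
  if (a == b) return 0.0;
  AlignResult al = nwAlign(a, b, match, mismatch, gapOpen, gapExt);
  double diff, pos;
  alignedCounts(al.a, al.b, gapRunAsOne, ignoreTerminal, diff, pos);
  if (pos == 0) return NA_REAL;
  return diff / pos;
}

} // namespace

// [[Rcpp::export]]
List cpp_nw_align(std::string a, std::string b, int match, int mismatch,
                  int gapOpen, int gapExt) {
  AlignResult res = nwAlign(a, b, match, mismatch, gapOpen, gapExt);
  return List::create(_["a"] = res.a, _["b"] = res.b, _["score"] = res.score);
}

// [[Rcpp::export]]
NumericVector cpp_aligned_counts(std::string a, std::string b, bool gapRunAsOne,
                                 bool ignoreTerminal) {
  double diff, pos;
  alignedCounts(a, b, gapRunAsOne, ignoreTerminal, diff, pos);
  return NumericVector::create(diff, pos);
}

// [[Rcpp::export]]
double cpp_pair_distance(std::string a, std::string b, int match, int mismatch,
                         int gapOpen, int gapExt, bool gapRunAsOne,
                         bool ignoreTerminal) {
  return pairDistance(a, b, match, mismatch, gapOpen, gapExt, gapRunAsOne,
                      ignoreTerminal);
}

// [[Rcpp::export]]
NumericMatrix cpp_distance_matrix(CharacterVector seqs, int match, int mismatch,
                                  int gapOpen, int gapExt, bool gapRunAsOne,
                                  bool ignoreTerminal) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = pairDistance(s[i], s[j], match, mismatch, gapOpen, gapExt,
                              gapRunAsOne, ignoreTerminal);
      out(i, j) = d;
      out(j, i) = d;
    }
    if (i % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Sliding-window (substitution-only) search for a 3'-anchored primer.
// A full-length occurrence anywhere, or a primer prefix overlapping the read
// end by at least minOverlap, is removed when its mismatch rate <= errorRate.
// Best match = lowest mismatch rate, then longest overlap, then leftmost.
// [[Rcpp::export]]
List cpp_trim_reverse(CharacterVector reads, std::string primer,
                      double errorRate, int minOverlap) {
  const int nr = reads.size();
  const int pl = (int)primer.size();
  CharacterVector trimmed(nr);
  LogicalVector flag(nr);
  for (int r = 0; r < nr; ++r) {
    std::string s = as<std::string>(reads[r]);
    const int L = (int)s.size();
    double bestRate = 2.0;
    int bestP = -1, bestOv = -1;
    for (int p = 0; p < L; ++p) {
      int ov = std::min(L - p, pl);
      if (ov < pl && ov < minOverlap) break; // overlaps only shrink from here
      int mism = 0;
      for (int k = 0; k < ov; ++k)
        if (s[p + k] != primer[k]) ++mism;
      double rate = (double)mism / ov;
      if (rate < bestRate - 1e-12 ||
          (std::abs(rate - bestRate) <= 1e-12 && ov > bestOv)) {
        bestRate = rate;
        bestP = p;
        bestOv = ov;
      }
    }
    if (bestP >= 0 && bestRate <= errorRate + 1e-12) {
      trimmed[r] = s.substr(0, bestP);
      flag[r] = true;
    } else {
      trimmed[r] = s;
      flag[r] = false;
    }
  }
  trimmed.names() = reads.names();
  return List::create(_["seq"] = trimmed, _["trimmed"] = flag);
}

namespace {

// Longest prefix of the overlap of a and b with at most maxMism mismatches.
int edgeLen(const std::string& a, const std::string& b, int maxMism, bool fromRight) {
  const int n = std::min(a.size(), b.size());
  int mism = 0;
  for (int k = 0; k < n; ++k) {
    char ca = fromRight ? a[a.size() - 1 - k] : a[k];
    char cb = fromRight ? b[b.size() - 1 - k] : b[k];
    if (ca != cb) {
      ++mism;
      if (mism > maxMism) return k;
    }
  }
  return n;
}

int singleParentMismatches(const std::string& a, const std::string& b) {
  const int n = std::min(a.size(), b.size());
  int mism = (int)(std::max(a.size(), b.size()) - n);
  for (int k = 0; k < n; ++k)
    if (a[k] != b[k]) ++mism;
  return mism;
}

} // namespace

// Simplified two-parent abundance-skew chimera test. A variant is flagged if
// some split yields a left segment within maxEdgeMism of one >= skew-fold
// more abundant variant and a right segment within maxEdgeMism of a different
// one, while no single parent matches with < minSingleMism mismatches.
// [[Rcpp::export]]
LogicalVector cpp_flag_chimeras(CharacterVector seqs, NumericVector totals,
                                double skew, int maxEdgeMism, int minSingleMism) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  LogicalVector flagged(n);
  for (int i = 0; i < n; ++i) {
    const int L = (int)s[i].size();
    int pl1 = -1, pl2 = -1, sl1 = -1, sl2 = -1; // top-2 prefix/suffix lengths
    int plIdx = -1, slIdx = -1;
    int minSingle = INT_MAX;
    for (int j = 0; j < n; ++j) {
      if (j == i || totals[j] < skew * totals[i]) continue;
      int pe = edgeLen(s[i], s[j], maxEdgeMism, false);
      int se = edgeLen(s[i], s[j], maxEdgeMism, true);
      if (pe > pl1) { pl2 = pl1; pl1 = pe; plIdx = j; }
      else if (pe > pl2) pl2 = pe;
      if (se > sl1) { sl2 = sl1; sl1 = se; slIdx = j; }
      else if (se > sl2) sl2 = se;
      int sm = singleParentMismatches(s[i], s[j]);
      if (sm < minSingle) minSingle = sm;
    }
    if (pl1 < 1 || sl1 < 1 || minSingle < minSingleMism) continue;
    int bestCross;
    if (plIdx != slIdx) bestCross = pl1 + sl1;
    else bestCross = std::max(pl1 + std::max(sl2, 0), std::max(pl2, 0) + sl1);
    // segments must be non-empty and jointly cover the variant
    if (bestCross >= L && pl1 >= 1 && sl1 >= 1) flagged[i] = true;
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return flagged;
}
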