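#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

// Global Needleman-Wunsch with linear gap costs.
//
// Terminal gaps are scored like internal gaps (fully ends-free scoring is
// degenerate for unrelated sequences of similar length: a chance handful of
// identical bases forms a tiny perfect "overlap" that outscores any
// spanning alignment and reports ~100% identity). Reported counts, however,
// exclude the leading and trailing terminal-gap runs of the optimal path,
// so matches + mismatches + insertions + deletions equals the alignment
// length used for percent identity over the terminal-trimmed region.
// "Insertion" = base present in the query but not the reference (gap in the
// reference); "deletion" = the reverse.

namespace {

struct AlnCounts {
  int score;
  int matches;
  int mismatches;
  int insertions;
  int deletions;
};

AlnCounts align_pair(const std::string &a, const std::string &b,
                     int match, int mismatch, int gap,
                     std::vector<int> &H) {
  const int n = static_cast<int>(a.size());
  const int m = static_cast<int>(b.size());
  const size_t w = static_cast<size_t>(m) + 1;
  H.resize((static_cast<size_t>(n) + 1) * w);
  for (int j = 0; j <= m; ++j) H[j] = j * gap;
  for (int i = 1; i <= n; ++i) {
    const char ai = a[static_cast<size_t>(i) - 1];
    const size_t row = static_cast<size_t>(i) * w;
    const size_t prev = row - w;
    H[row] = i * gap;
    for (int j = 1; j <= m; ++j) {
      const int diag = H[prev + j - 1] +
                       (ai == b[static_cast<size_t>(j) - 1] ? match : mismatch);
      const int up = H[prev + j] + gap;    // consumes query base: insertion
      const int left = H[row + j - 1] + gap;  // consumes ref base: deletion
      int v = diag >= up ? diag : up;
      if (left > v) v = left;
      H[row + j] = v;
    }
  }

  AlnCounts c;
  c.score = H[static_cast<size_t>(n) * w + m];
  c.matches = c.mismatches = c.insertions = c.deletions = 0;

  // Traceback from the corner. Tie preference is direction-dependent so
  // equally-scoring gap placements consolidate into terminal runs: gap
  // moves are preferred until the first aligned pair is traced (trailing
  // overhang), then diagonal moves are preferred (keeping the aligned
  // region contiguous; the leading overhang is the forced remainder).
  // Gap runs touching either end of the alignment are terminal: the
  // trailing run (seen first, before any diagonal step) is skipped, and
  // gaps are buffered until a later diagonal step proves them internal,
  // so the leading run left pending when the traceback ends is dropped.
  int i = n, j = m;
  bool seen_aligned = false;
  int pend_ins = 0, pend_del = 0;
  while (i > 0 || j > 0) {
    int move;  // 0 = diagonal, 1 = up/insertion, 2 = left/deletion
    if (i == 0) {
      move = 2;
    } else if (j == 0) {
      move = 1;
    } else {
      const size_t row = static_cast<size_t>(i) * w;
      const size_t prev = row - w;
      const int cur = H[row + j];
      const bool is_match = a[static_cast<size_t>(i) - 1] ==
                            b[static_cast<size_t>(j) - 1];
      const bool diag_ok =
          cur == H[prev + j - 1] + (is_match ? match : mismatch);
      const bool up_ok = cur == H[prev + j] + gap;
      const bool left_ok = cur == H[row + j - 1] + gap;
      if (seen_aligned) {
        move = diag_ok ? 0 : (up_ok ? 1 : 2);
      } else {
        move = up_ok ? 1 : (left_ok ? 2 : 0);
      }
    }
    if (move == 0) {
      if (seen_aligned) {
        c.insertions += pend_ins;
        c.deletions += pend_del;
      }
      pend_ins = pend_del = 0;
      seen_aligned = true;
      if (a[static_cast<size_t>(i) - 1] == b[static_cast<size_t>(j) - 1]) {
        ++c.matches;
      } else {
        ++c.mismatches;
      }
      --i; --j;
    } else if (move == 1) {
      ++pend_ins;
      --i;
    } else {
      ++pend_del;
      --j;
    }
  }
  return c;
}

IntegerVector counts_vector(const AlnCounts &c) {
  IntegerVector out = IntegerVector::create(
      _["score"] = c.score,
      _["matches"] = c.matches,
      _["mismatches"] = c.mismatches,
      _["insertions"] = c.insertions,
      _["deletions"] = c.deletions);
  return out;
}

inline double pct_identity(const AlnCounts &c) {
  const int len = c.matches + c.mismatches + c.insertions + c.deletions;
  return len > 0 ? 100.0 * c.matches / len : 0.0;
}

}  // namespace

// [[Rcpp::export]]
IntegerVector cpp_align_counts(std::string a, std::string b,
                               int match, int mismatch, int gap) {
  std::vector<int> H;
  return counts_vector(align_pair(a, b, match, mismatch, gap, H));
}

// [[Rcpp::export]]
List cpp_align_sets(CharacterVector query, CharacterVector ref,
                    int match, int mismatch, int gap) {
  const int nq = query.size(), nr = ref.size();
  IntegerMatrix score(nq, nr), matches(nq, nr), mismatches(nq, nr),
      insertions(nq, nr), deletions(nq, nr);
  NumericMatrix identity(nq, nr);
  std::vector<int> H;
  std::vector<std::string> refs(nr);
  for (int j = 0; j < nr; ++j) refs[j] = as<std::string>(ref[j]);
  for (int i = 0; i < nq; ++i) {
    const std::string q = as<std::string>(query[i]);
    for (int j = 0; j < nr; ++j) {
      const AlnCounts c = align_pair(q, refs[j], match, mismatch, gap, H);
      score(i, j) = c.score;
      matches(i, j) = c.matches;
      mismatches(i, j) = c.mismatches;
      insertions(i, j) = c.insertions;
      deletions(i, j) = c.deletions;
      identity(i, j) = pct_identity(c);
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["score"] = score, _["matches"] = matches,
                      _["mismatches"] = mismatches,
                      _["insertions"] = insertions,
                      _["deletions"] = deletions,
                      _["identity"] = identity);
}

// [[Rcpp::export]]
NumericMatrix cpp_identity_matrix(CharacterVector seqs,
                                  int match, int mismatch, int gap) {
  const int n = seqs.size();
  NumericMatrix identity(n, n);
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  std::vector<int> H;
  for (int i = 0; i < n; ++i) {
    identity(i, i) = 100.0;
    for (int j = i + 1; j < n; ++j) {
      const AlnCounts c = align_pair(s[i], s[j], match, mismatch, gap, H);
      const double id = pct_identity(c);
      identity(i, j) = id;
      identity(j, i) = id;
    }
    Rcpp::checkUserInterrupt();
  }
  return identity;
}
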