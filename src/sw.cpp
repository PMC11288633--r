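#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh). Gap of length L costs
// gap_open + (L - 1) * gap_extend: the first gapped base pays the opening
// cost, each additional base the extension cost. A query base aligned to a
// masked reference position ('N') scores n_score.

static inline int subst_score(char q, char r, int match, int mismatch,
                              int n_score) {
  if (r == 'N' || r == 'n') return n_score;
  return (q == r) ? match : mismatch;
}

// Score-only DP, two rolling rows. Used for the all-against-all pass where
// only the best score per transcript is needed.
static int sw_score_one(const std::string& q, const std::string& r,
                        int match, int mismatch, int n_score,
                        int gap_open, int gap_extend) {
  const int n = q.size(), m = r.size();
  std::vector<int> H0(m + 1, 0), H1(m + 1, 0), E0(m + 1, INT_MIN / 2),
      E1(m + 1, INT_MIN / 2);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    int F = INT_MIN / 2;  // gap in reference (insertion), within row i
    H1[0] = 0;
    E1[0] = INT_MIN / 2;
    for (int j = 1; j <= m; ++j) {
      E1[j] = std::max(H0[j] - gap_open, E0[j] - gap_extend);  // gap in query
      F = std::max(H1[j - 1] - gap_open, F - gap_extend);
      int diag =
          H0[j - 1] + subst_score(q[i - 1], r[j - 1], match, mismatch, n_score);
      int h = std::max(std::max(diag, E1[j]), std::max(F, 0));
      H1[j] = h;
      if (h > best) best = h;
    }
    std::swap(H0, H1);
    std::swap(E0, E1);
  }
  return best;
}

//' @useDynLib tRNAcharge, .registration = TRUE
//' @importFrom Rcpp sourceCpp
// [[Rcpp::export(name = ".sw_score_multi")]]
IntegerVector sw_score_multi(std::string query, CharacterVector refs,
                             int match, int mismatch, int n_score,
                             int gap_open, int gap_extend) {
  const int k = refs.size();
  IntegerVector out(k);
  for (int t = 0; t < k; ++t) {
    std::string r = as<std::string>(refs[t]);
    out[t] = sw_score_one(query, r, match, mismatch, n_score, gap_open,
                          gap_extend);
  }
  return out;
}

// Full DP with traceback. ref_masked drives the scoring; ref_orig (same
// length, original bases at masked positions) drives match/mismatch calls in
// the reported path so that misincorporation frequencies can be computed at
// originally-masked coordinates.
//
// Tie-breaking, in order: the end cell with the smallest reference index
// (then smallest query index); within the traceback, diagonal moves are
// preferred over deletions over insertions, so a mismatch is preferred over
// a gap among co-optimal paths.
// [[Rcpp::export(name = ".sw_align_full")]]
List sw_align_full(std::string query, std::string ref_masked,
                   std::string ref_orig, int match, int mismatch, int n_score,
                   int gap_open, int gap_extend) {
  const int n = query.size(), m = ref_masked.size();
  if (n == 0 || m == 0) stop("empty query or reference");
  if ((int)ref_orig.size() != m)
    stop("masked and original reference lengths differ");
  const int NEG = INT_MIN / 2;
  // full matrices: n, m <= a few hundred for tRNA work
  std::vector<int> H((n + 1) * (m + 1), 0), E((n + 1) * (m + 1), NEG),
      F((n + 1) * (m + 1), NEG);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      E[at(i, j)] = std::max(H[at(i - 1, j)] - gap_open,
                             E[at(i - 1, j)] - gap_extend);  // query gapped
      F[at(i, j)] = std::max(H[at(i, j - 1)] - gap_open,
                             F[at(i, j - 1)] - gap_extend);  // ref gapped
      int diag = H[at(i - 1, j - 1)] +
                 subst_score(query[i - 1], ref_masked[j - 1], match, mismatch,
                             n_score);
      int h = std::max(std::max(diag, E[at(i, j)]),
                       std::max(F[at(i, j)], 0));
      H[at(i, j)] = h;
      // strict > with j-major preference gives the smallest ref end index
      if (h > best || (h == best && (j < bj || (j == bj && i < bi)))) {
        if (h > 0) {
          best = h;
          bi = i;
          bj = j;
        }
      }
    }
  }
  std::string path;  // reversed during build: M/X per diagonal, D del, I ins
  std::vector<int> mm, del, ins;
  int i = bi, j = bj;
  char state = 'H';
  while (i > 0 && j > 0) {
    if (state == 'H') {
      if (H[at(i, j)] == 0) break;
      int diag = H[at(i - 1, j - 1)] +
                 subst_score(query[i - 1], ref_masked[j - 1], match, mismatch,
                             n_score);
      if (H[at(i, j)] == diag) {
        char q = query[i - 1], o = ref_orig[j - 1];
        if (q == o) {
          path.push_back('M');
        } else {
          path.push_back('X');
          mm.push_back(j - 1);
        }
        --i;
        --j;
      } else if (H[at(i, j)] == E[at(i, j)]) {
        state = 'E';
      } else if (H[at(i, j)] == F[at(i, j)]) {
        state = 'F';
      } else {
        break;  // local start
      }
    } else if (state == 'E') {
      // query base i-1 aligned to a gap: insertion relative to reference,
      // assigned to the 5'-adjacent reference position j-1 (0-based)
      path.push_back('I');
      ins.push_back(j - 1);
      if (E[at(i, j)] == H[at(i - 1, j)] - gap_open) state = 'H';
      --i;
    } else {  // 'F'
      path.push_back('D');
      del.push_back(j - 1);
      if (F[at(i, j)] == H[at(i, j - 1)] - gap_open) state = 'H';
      --j;
    }
  }
  std::reverse(path.begin(), path.end());
  std::reverse(mm.begin(), mm.end());
  std::reverse(del.begin(), del.end());
  std::reverse(ins.begin(), ins.end());
  return List::create(
      _["score"] = best, _["ref_start"] = j, _["ref_end"] = bj,
      _["read_start"] = i, _["read_end"] = bi,
      _["mismatch_pos"] = IntegerVector(mm.begin(), mm.end()),
      _["deletion_pos"] = IntegerVector(del.begin(), del.end()),
      _["insertion_pos"] = IntegerVector(ins.begin(), ins.end()),
      _["path"] = path);
}

// Hamming distance helper for barcode demultiplexing: best (lowest-distance,
// most 3') window of width |pattern| within the last `window` bases of each
// read. Returns a 2 x n matrix: row 1 distance, row 2 the 0-based start of
// the matched window within the read (-1 when the read is shorter than the
// pattern).
// [[Rcpp::export(name = ".barcode_scan")]]
IntegerMatrix barcode_scan(CharacterVector reads, std::string pattern,
                           int window) {
  const int n = reads.size(), w = pattern.size();
  IntegerMatrix out(2, n);
  for (int r = 0; r < n; ++r) {
    std::string s = as<std::string>(reads[r]);
    int L = s.size();
    if (L < w) {
      out(0, r) = w + 1;
      out(1, r) = -1;
      continue;
    }
    int lo = std::max(0, L - window);
    int bestd = w + 1, bestp = -1;
    for (int p = lo; p + w <= L; ++p) {  // ascending: later p wins ties (>=)
      int d = 0;
      for (int q = 0; q < w; ++q)
        if (s[p + q] != pattern[q]) ++d;
      if (d <= bestd) {
        bestd = d;
        bestp = p;
      }
    }
    out(0, r) = bestd;
    out(1, r) = bestp;
  }
  return out;
}
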