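#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh three-matrix
// recurrence).  A gap of length L costs gap_open + L * gap_extend.
//
//   E(i,j): best alignment of q[1..i]/s[1..j] ending with a gap in the
//           query (subject residue j aligned to '-')
//   F(i,j): best ending with a gap in the subject (query residue i vs '-')
//   H(i,j): best local alignment ending at (i,j), floored at 0
//
// Traceback is deterministic: at an H cell the preference order is
// diagonal > subject-gap (F) > query-gap (E); inside a gap matrix, a
// gap-open origin (H) is preferred over gap extension.  Among equal-score
// end cells the smallest query end, then the smallest subject end, wins.
//
// Sequences arrive as 0-based letter indices (A=0..Z=25); `sub` is a
// 26x26 integer substitution matrix.  Trace ops: 'M' consumes one residue
// on each side, 'I' consumes query only (gap in subject), 'D' consumes
// subject only (gap in query).

// [[Rcpp::export]]
List sw_align_cpp(IntegerVector q, IntegerVector s, IntegerMatrix sub,
                  int gap_open, int gap_extend) {
  const int n = q.size();
  const int m = s.size();
  const int NEG = INT_MIN / 4;
  const int W = m + 1;

  std::vector<int> H((size_t)(n + 1) * W, 0);
  std::vector<int> E((size_t)(n + 1) * W, NEG);
  std::vector<int> F((size_t)(n + 1) * W, NEG);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const int qi = q[i - 1];
    for (int j = 1; j <= m; ++j) {
      const size_t c = (size_t)i * W + j;
      const size_t up = c - W, left = c - 1, diag = c - W - 1;
      E[c] = std::max(E[left] - gap_extend, H[left] - gap_open - gap_extend);
      F[c] = std::max(F[up] - gap_extend, H[up] - gap_open - gap_extend);
      int h = H[diag] + sub(qi, s[j - 1]);
      h = std::max(h, F[c]);
      h = std::max(h, E[c]);
      h = std::max(h, 0);
      H[c] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  if (best <= 0) {
    return List::create(_["score"] = 0);
  }

  std::string trace;
  int i = bi, j = bj;
  char state = 'H';
  while (true) {
    const size_t c = (size_t)i * W + j;
    if (state == 'H') {
      if (H[c] == 0) break;
      if (i > 0 && j > 0 && H[c] == H[c - W - 1] + sub(q[i - 1], s[j - 1])) {
        trace.push_back('M'); --i; --j;
      } else if (H[c] == F[c]) {
        state = 'F';
      } else if (H[c] == E[c]) {
        state = 'E';
      } else {
        stop("internal error: inconsistent traceback at H");
      }
    } else if (state == 'F') {
      trace.push_back('I');
      if (F[c] == H[c - W] - gap_open - gap_extend) {
        --i; state = 'H';
      } else {
        --i; // extend
      }
    } else { // E
      trace.push_back('D');
      if (E[c] == H[c - 1] - gap_open - gap_extend) {
        --j; state = 'H';
      } else {
        --j;
      }
    }
  }
  std::reverse(trace.begin(), trace.end());

  return List::create(
    _["score"] = best,
    _["query_start"] = i + 1,
    _["query_end"] = bi,
    _["subject_start"] = j + 1,
    _["subject_end"] = bj,
    _["trace"] = trace
  );
}
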