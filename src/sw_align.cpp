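#include <Rcpp.h>
#include <climits>
#include <vector>
#include <string>
using namespace Rcpp;

// Local alignment with affine gaps (Gotoh). A gap of length k costs
// gap_open + k * gap_extend. 'N' never matches anything (scored as a
// mismatch), so ambiguous positions cannot fake identity. Traceback
// reports coordinates (1-based, inclusive) and per-column statistics.
//
// Matrices: H = best score of a local alignment ending at (i, j);
// E = ending with a gap in the query (consuming subject letters);
// F = ending with a gap in the subject (consuming query letters).

// [[Rcpp::export]]
IntegerVector sw_align_cpp(std::string q, std::string s,
                           int match, int mismatch,
                           int gap_open, int gap_extend) {
  const int m = (int) q.size(), n = (int) s.size();
  IntegerVector out = IntegerVector::create(
      _["score"] = 0, _["q_start"] = 0, _["q_end"] = 0,
      _["s_start"] = 0, _["s_end"] = 0, _["matches"] = 0,
      _["mismatches"] = 0, _["gap_opens"] = 0, _["gap_cols"] = 0,
      _["align_len"] = 0);
  if (m == 0 || n == 0) return out;

  const int NEG = INT_MIN / 4;
  const size_t W = (size_t) n + 1;
  std::vector<int> H((size_t)(m + 1) * W, 0);
  std::vector<int> E((size_t)(m + 1) * W, NEG);
  std::vector<int> F((size_t)(m + 1) * W, NEG);
  // tbH: 0 stop, 1 diagonal, 2 from E, 3 from F
  // tbE/tbF: 0 opened from H, 1 extended
  std::vector<unsigned char> tbH((size_t)(m + 1) * W, 0);
  std::vector<unsigned char> tbE((size_t)(m + 1) * W, 0);
  std::vector<unsigned char> tbF((size_t)(m + 1) * W, 0);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const char qc = q[(size_t) i - 1];
    for (int j = 1; j <= n; ++j) {
      const size_t k = (size_t) i * W + j;
      const size_t kl = k - 1;        // (i, j-1)
      const size_t ku = k - W;        // (i-1, j)
      const size_t kd = k - W - 1;    // (i-1, j-1)

      int e_open = H[kl] - gap_open - gap_extend;
      int e_ext  = E[kl] - gap_extend;
      if (e_open >= e_ext) { E[k] = e_open; tbE[k] = 0; }
      else                 { E[k] = e_ext;  tbE[k] = 1; }

      int f_open = H[ku] - gap_open - gap_extend;
      int f_ext  = F[ku] - gap_extend;
      if (f_open >= f_ext) { F[k] = f_open; tbF[k] = 0; }
      else                 { F[k] = f_ext;  tbF[k] = 1; }

      const char sc = s[(size_t) j - 1];
      const bool is_match = (qc == sc) && qc != 'N';
      int diag = H[kd] + (is_match ? match : mismatch);

      int h = 0; unsigned char tb = 0;
      if (diag > h) { h = diag; tb = 1; }
      if (E[k] > h) { h = E[k]; tb = 2; }
      if (F[k] > h) { h = F[k]; tb = 3; }
      H[k] = h; tbH[k] = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0) return out;

  // Traceback from the best cell to the first zero.
  int i = bi, j = bj;
  int matches = 0, mismatches = 0, gap_opens = 0, gap_cols = 0, cols = 0;
  int state = 0; // 0 = H, 1 = E, 2 = F
  while (true) {
    const size_t k = (size_t) i * W + j;
    if (state == 0) {
      if (H[k] == 0 || tbH[k] == 0) break;
      if (tbH[k] == 1) {
        const bool is_match = (q[(size_t) i - 1] == s[(size_t) j - 1]) &&
                              q[(size_t) i - 1] != 'N';
        if (is_match) ++matches; else ++mismatches;
        ++cols; --i; --j;
      } else if (tbH[k] == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {       // gap in query: consume subject letter
      ++cols; ++gap_cols;
      const unsigned char t = tbE[k];
      --j;
      if (t == 0) { ++gap_opens; state = 0; }
    } else {                       // gap in subject: consume query letter
      ++cols; ++gap_cols;
      const unsigned char t = tbF[k];
      --i;
      if (t == 0) { ++gap_opens; state = 0; }
    }
  }

  out["score"] = best;
  out["q_start"] = i + 1; out["q_end"] = bi;
  out["s_start"] = j + 1; out["s_end"] = bj;
  out["matches"] = matches; out["mismatches"] = mismatches;
  out["gap_opens"] = gap_opens; out["gap_cols"] = gap_cols;
  out["align_len"] = cols;
  return out;
}
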