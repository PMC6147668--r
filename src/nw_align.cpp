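#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Needleman-Wunsch global alignment, linear gap penalty.
// Traceback tie-break: diagonal > up (gap in b) > left (gap in a),
// enforced during the DP so the alignment is deterministic.
// Move codes: 0 = diagonal, 1 = up, 2 = left.

// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  std::vector<double> prev(m + 1), cur(m + 1);
  std::vector<unsigned char> move((n + 1) * (size_t)(m + 1));

  for (int j = 0; j <= m; ++j) {
    prev[j] = j * gap;
    if (j > 0) move[j] = 2;
  }
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * gap;
    move[i * (size_t)(m + 1)] = 1;
    for (int j = 1; j <= m; ++j) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double diag = prev[j - 1] + s;
      double up = prev[j] + gap;
      double left = cur[j - 1] + gap;
      double best = diag;
      unsigned char mv = 0;
      if (up > best) { best = up; mv = 1; }
      if (left > best) { best = left; mv = 2; }
      cur[j] = best;
      move[i * (size_t)(m + 1) + j] = mv;
    }
    std::swap(prev, cur);
  }
  double score = prev[m];

  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char mv = move[i * (size_t)(m + 1) + j];
    if (i > 0 && j > 0 && mv == 0) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j;
    } else if (i > 0 && (j == 0 || mv == 1)) {
      ra.push_back(a[i - 1]); rb.push_back('-'); --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]); --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = score);
}
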