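#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Gotoh global alignment with affine gaps. Gap cost convention: a run of k
// gap columns costs gap_open + (k - 1) * gap_extend (the first gap column
// pays the opening penalty, each further column the extension penalty).
// Traceback ties are broken deterministically: diagonal (match state), then
// up (gap in the second sequence), then left (gap in the first).

static const double NEG_INF = -1e30;

// state codes: 0 = M (diagonal), 1 = X (up, consumes a), 2 = Y (left, consumes b)

// [[Rcpp::export(name = ".gotoh_align_cpp")]]
List gotoh_align_cpp(std::string a, std::string b,
                     double match, double mismatch,
                     double gap_open, double gap_extend) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0)
    stop("both sequences must be non-empty");
  const size_t W = (size_t)(m + 1);
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  // predecessor state for each cell/state
  std::vector<unsigned char> pM((n + 1) * W, 0), pX((n + 1) * W, 0),
      pY((n + 1) * W, 0);

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = gap_open + (i - 1) * gap_extend;
    pX[i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = gap_open + (j - 1) * gap_extend;
    pY[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t cur = i * W + j, diag = (i - 1) * W + (j - 1),
                   up = (i - 1) * W + j, left = i * W + (j - 1);
      const double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      // M: ties prefer M, then X, then Y
      double best = M[diag];
      unsigned char arg = 0;
      if (X[diag] > best) { best = X[diag]; arg = 1; }
      if (Y[diag] > best) { best = Y[diag]; arg = 2; }
      M[cur] = best + s;
      pM[cur] = arg;
      // X: gap in b, consume a[i-1]
      best = M[up] + gap_open; arg = 0;
      if (X[up] + gap_extend > best) { best = X[up] + gap_extend; arg = 1; }
      if (Y[up] + gap_open > best) { best = Y[up] + gap_open; arg = 2; }
      X[cur] = best;
      pX[cur] = arg;
      // Y: gap in a, consume b[j-1]
      best = M[left] + gap_open; arg = 0;
      if (X[left] + gap_open > best) { best = X[left] + gap_open; arg = 1; }
      if (Y[left] + gap_extend > best) { best = Y[left] + gap_extend; arg = 2; }
      Y[cur] = best;
      pY[cur] = arg;
    }
  }

  const size_t end = (size_t)n * W + m;
  double score = M[end];
  unsigned char state = 0;
  if (X[end] > score) { score = X[end]; state = 1; }
  if (Y[end] > score) { score = Y[end]; state = 2; }

  std::string ga, gb;
  ga.reserve(n + m);
  gb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const size_t cur = (size_t)i * W + j;
    if (state == 0) {
      ga.push_back(a[i - 1]);
      gb.push_back(b[j - 1]);
      state = pM[cur];
      --i; --j;
    } else if (state == 1) {
      ga.push_back(a[i - 1]);
      gb.push_back('-');
      state = pX[cur];
      --i;
    } else {
      ga.push_back('-');
      gb.push_back(b[j - 1]);
      state = pY[cur];
      --j;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  return List::create(_["score"] = score, _["aligned1"] = ga,
                      _["aligned2"] = gb);
}
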