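#include <Rcpp.h>
#include <limits>
#include <vector>

using namespace Rcpp;

// Gotoh three-state global alignment over a position-specific similarity
// matrix S (rows = protein 1, columns = protein 2), maximising the total
// score under affine gaps. A gap of length k costs open + (k-1)*extend;
// switching gap sides re-opens. Terminal gaps are penalised (true global
// alignment). Ties are broken match > up (gap in protein 2) > left (gap in
// protein 1), which makes the traceback deterministic.
//
// Returns list(score, path): path is an integer matrix with columns (i, j),
// 1-based; NA marks the gapped side of a step.

// [[Rcpp::export(name = ".nw_affine")]]
List nw_affine(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow();
  const int m = S.ncol();
  if (n < 1 || m < 1)
    stop("substitution matrix must have at least one row and one column");
  const double NEG = -std::numeric_limits<double>::infinity();

  std::vector<std::vector<double> > M(n + 1, std::vector<double>(m + 1, NEG));
  std::vector<std::vector<double> > X(M);  // gap in protein 2 ("up")
  std::vector<std::vector<double> > Y(M);  // gap in protein 1 ("left")

  M[0][0] = 0.0;
  for (int i = 1; i <= n; ++i) X[i][0] = gap_open + (i - 1) * gap_extend;
  for (int j = 1; j <= m; ++j) Y[0][j] = gap_open + (j - 1) * gap_extend;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double d = M[i - 1][j - 1];
      if (X[i - 1][j - 1] > d) d = X[i - 1][j - 1];
      if (Y[i - 1][j - 1] > d) d = Y[i - 1][j - 1];
      M[i][j] = S(i - 1, j - 1) + d;

      double x = M[i - 1][j] + gap_open;
      if (X[i - 1][j] + gap_extend > x) x = X[i - 1][j] + gap_extend;
      if (Y[i - 1][j] + gap_open > x) x = Y[i - 1][j] + gap_open;
      X[i][j] = x;

      double y = M[i][j - 1] + gap_open;
      if (Y[i][j - 1] + gap_extend > y) y = Y[i][j - 1] + gap_extend;
      if (X[i][j - 1] + gap_open > y) y = X[i][j - 1] + gap_open;
      Y[i][j] = y;
    }
  }

  // End state: priority M > X > Y on exact ties.
  int state = 0;
  double best = M[n][m];
  if (X[n][m] > best) { best = X[n][m]; state = 1; }
  if (Y[n][m] > best) { best = Y[n][m]; state = 2; }

  std::vector<int> pi, pj;  // reversed path; NA_INTEGER for gaps
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      pi.push_back(i);
      pj.push_back(j);
      double a = M[i - 1][j - 1], b = X[i - 1][j - 1], c = Y[i - 1][j - 1];
      double d = a; if (b > d) d = b; if (c > d) d = c;
      state = (a == d) ? 0 : (b == d ? 1 : 2);
      --i; --j;
    } else if (state == 1) {
      pi.push_back(i);
      pj.push_back(NA_INTEGER);
      double a = M[i - 1][j] + gap_open;
      double b = X[i - 1][j] + gap_extend;
      double c = Y[i - 1][j] + gap_open;
      double d = a; if (b > d) d = b; if (c > d) d = c;
      state = (a == d) ? 0 : (b == d ? 1 : 2);
      --i;
    } else {
      pi.push_back(NA_INTEGER);
      pj.push_back(j);
      double a = M[i][j - 1] + gap_open;
      double b = X[i][j - 1] + gap_open;
      double c = Y[i][j - 1] + gap_extend;
      double d = a; if (b > d) d = b; if (c > d) d = c;
      state = (a == d) ? 0 : (b == d ? 1 : 2);
      --j;
    }
  }

  const int L = (int) pi.size();
  IntegerMatrix path(L, 2);
  for (int k = 0; k < L; ++k) {
    path(k, 0) = pi[L - 1 - k];
    path(k, 1) = pj[L - 1 - k];
  }
  colnames(path) = CharacterVector::create("i", "j");
  return List::create(_["score"] = best, _["path"] = path);
}
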