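#include <Rcpp.h>
using namespace Rcpp;

// Needleman-Wunsch with affine-free (linear) gap cost. Two modes:
//  - global: classic NW over the full matrix.
//  - overlap: end gaps free on both sequences (best score over last
//    row/column), suited to a query contained in a longer reference.
// Tie-breaking at traceback is fixed: diagonal > up (gap in b) > left
// (gap in a), so the alignment is deterministic for any input order.

// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch, double gap,
                  bool overlap) {
  const int n = a.size(), m = b.size();
  NumericMatrix S(n + 1, m + 1);
  for (int i = 1; i <= n; ++i) S(i, 0) = overlap ? 0.0 : i * gap;
  for (int j = 1; j <= m; ++j) S(0, j) = overlap ? 0.0 : j * gap;
  for (int i = 1; i <= n; ++i) {
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      double d = S(i - 1, j - 1) + (ai == b[j - 1] ? match : mismatch);
      double u = S(i - 1, j) + gap;
      double l = S(i, j - 1) + gap;
      double best = d;
      if (u > best) best = u;
      if (l > best) best = l;
      S(i, j) = best;
    }
  }

  int ei = n, ej = m;
  double score = S(n, m);
  if (overlap) {
    // best over last row and last column; ties prefer the cell
    // consuming more of both sequences, then more of a
    for (int j = 0; j <= m; ++j)
      if (S(n, j) > score ||
          (S(n, j) == score && (n + j > ei + ej || (n + j == ei + ej && n > ei)))) {
        score = S(n, j); ei = n; ej = j;
      }
    for (int i = 0; i <= n; ++i)
      if (S(i, m) > score ||
          (S(i, m) == score && (i + m > ei + ej || (i + m == ei + ej && i > ei)))) {
        score = S(i, m); ei = i; ej = m;
      }
  }

  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  // trailing free end gaps (overlap mode)
  for (int j = m; j > ej; --j) { ra.push_back('-'); rb.push_back(b[j - 1]); }
  for (int i = n; i > ei; --i) { ra.push_back(a[i - 1]); rb.push_back('-'); }

  int i = ei, j = ej;
  while (i > 0 && j > 0) {
    double s = S(i, j);
    double d = S(i - 1, j - 1) + (a[i - 1] == b[j - 1] ? match : mismatch);
    if (d == s) { ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j; continue; }
    if (S(i - 1, j) + gap == s) { ra.push_back(a[i - 1]); rb.push_back('-'); --i; continue; }
    ra.push_back('-'); rb.push_back(b[j - 1]); --j;
  }
  // leading gaps: in overlap mode these were free, emit them anyway so
  // the aligned strings always cover both inputs end to end
  while (i > 0) { ra.push_back(a[i - 1]); rb.push_back('-'); --i; }
  while (j > 0) { ra.push_back('-'); rb.push_back(b[j - 1]); --j; }

  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = score);
}

// Optimal string alignment (restricted Damerau-Levenshtein) distance:
// Levenshtein plus adjacent transposition, no substring edited twice.

static int osa_one(const std::string &a, const std::string &b) {
  const int n = a.size(), m = b.size();
  std::vector<std::vector<int>> D(n + 1, std::vector<int>(m + 1));
  for (int i = 0; i <= n; ++i) D[i][0] = i;
  for (int j = 0; j <= m; ++j) D[0][j] = j;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int cost = a[i - 1] == b[j - 1] ? 0 : 1;
      int v = std::min(std::min(D[i - 1][j] + 1, D[i][j - 1] + 1),
                       D[i - 1][j - 1] + cost);
      if (i > 1 && j > 1 && a[i - 1] == b[j - 2] && a[i - 2] == b[j - 1])
        v = std::min(v, D[i - 2][j - 2] + 1);
      D[i][j] = v;
    }
  }
  return D[n][m];
}

// [[Rcpp::export]]
IntegerMatrix osa_matrix_cpp(CharacterVector a, CharacterVector b) {
  IntegerMatrix out(a.size(), b.size());
  for (int i = 0; i < a.size(); ++i) {
    std::string ai = as<std::string>(a[i]);
    for (int j = 0; j < b.size(); ++j)
      out(i, j) = osa_one(ai, as<std::string>(b[j]));
  }
  return out;
}
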