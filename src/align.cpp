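#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment of two alignment profiles with linear
// gap penalty.  Profiles are 5 x L count matrices (rows A,C,G,T,gap).
// Column-column score is the average over all residue pairs of
// match/mismatch, with residue-vs-gap pairs scored at the gap cost and
// gap-gap pairs at zero.  Aligning a profile column against a newly
// inserted gap column costs gap * (ungapped fraction of the column).
//
// Returns a 2 x Lout integer matrix of 1-based column indices into each
// profile, 0 where a new gap column is inserted.
// [[Rcpp::export]]
IntegerMatrix align_profiles_cpp(NumericMatrix p1, NumericMatrix p2,
                                 double match, double mismatch, double gap) {
  const int L1 = p1.ncol(), L2 = p2.ncol();
  double n1 = 0, n2 = 0;
  for (int b = 0; b < 5; ++b) { n1 += p1(b, 0); n2 += p2(b, 0); }

  std::vector<double> r1(L1), r2(L2), g1cost(L1), g2cost(L2);
  for (int i = 0; i < L1; ++i) {
    double r = 0; for (int b = 0; b < 4; ++b) r += p1(b, i);
    r1[i] = r; g1cost[i] = gap * r / n1;
  }
  for (int j = 0; j < L2; ++j) {
    double r = 0; for (int b = 0; b < 4; ++b) r += p2(b, j);
    r2[j] = r; g2cost[j] = gap * r / n2;
  }

  // DP with full traceback (bytes): 0 = diag, 1 = up (gap in p2), 2 = left
  std::vector<double> prev(L2 + 1), cur(L2 + 1);
  std::vector<unsigned char> tb((size_t)(L1 + 1) * (L2 + 1));
  prev[0] = 0;
  for (int j = 1; j <= L2; ++j) { prev[j] = prev[j - 1] + g2cost[j - 1]; tb[j] = 2; }
  const double inv = 1.0 / (n1 * n2);
  for (int i = 1; i <= L1; ++i) {
    cur[0] = prev[0] + g1cost[i - 1];
    tb[(size_t)i * (L2 + 1)] = 1;
    for (int j = 1; j <= L2; ++j) {
      double mm = 0;
      for (int b = 0; b < 4; ++b) mm += p1(b, i - 1) * p2(b, j - 1);
      double s = match * mm + mismatch * (r1[i - 1] * r2[j - 1] - mm) +
                 gap * (r1[i - 1] * (n2 - r2[j - 1]) + (n1 - r1[i - 1]) * r2[j - 1]);
      double d = prev[j - 1] + s * inv;
      double u = prev[j] + g1cost[i - 1];
      double l = cur[j - 1] + g2cost[j - 1];
      unsigned char t = 0; double best = d;
      if (u > best) { best = u; t = 1; }
      if (l > best) { best = l; t = 2; }
      cur[j] = best;
      tb[(size_t)i * (L2 + 1) + j] = t;
    }
    std::swap(prev, cur);
  }

  std::vector<int> c1, c2;
  int i = L1, j = L2;
  while (i > 0 || j > 0) {
    unsigned char t = tb[(size_t)i * (L2 + 1) + j];
    if (i > 0 && j > 0 && t == 0) { c1.push_back(i); c2.push_back(j); --i; --j; }
    else if (i > 0 && (j == 0 || t == 1)) { c1.push_back(i); c2.push_back(0); --i; }
    else { c1.push_back(0); c2.push_back(j); --j; }
  }
  const int L = (int)c1.size();
  IntegerMatrix out(2, L);
  for (int k = 0; k < L; ++k) {
    out(0, k) = c1[L - 1 - k];
    out(1, k) = c2[L - 1 - k];
  }
  return out;
}

// Pairwise P (transition) and Q (transversion) difference proportions over
// the comparable (both-ungapped) sites of an encoded alignment matrix
// (rows = sequences, 1=A,2=C,3=G,4=T, 0=gap).  Returns a matrix with one
// row per unordered pair: i, j, n_sites, n_ts, n_tv.
// [[Rcpp::export]]
NumericMatrix pair_counts_cpp(IntegerMatrix aln) {
  const int n = aln.nrow(), L = aln.ncol();
  const int np = n * (n - 1) / 2;
  NumericMatrix out(np, 5);
  int r = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j, ++r) {
      int ns = 0, ts = 0, tv = 0;
      for (int s = 0; s < L; ++s) {
        int a = aln(i, s), b = aln(j, s);
        if (a == 0 || b == 0) continue;
        ++ns;
        if (a == b) continue;
        // purines: A(1), G(3); pyrimidines: C(2), T(4)
        bool pa = (a == 1 || a == 3), pb = (b == 1 || b == 3);
        if (pa == pb) ++ts; else ++tv;
      }
      out(r, 0) = i + 1; out(r, 1) = j + 1;
      out(r, 2) = ns; out(r, 3) = ts; out(r, 4) = tv;
    }
  }
  return out;
}

// Per-column pair indicators for the bootstrap: for every unordered pair,
// three logical rows over columns -- comparable, transition, transversion --
// stacked as an (3*np) x L integer matrix (pair-major: cmp, ts, tv blocks).
// [[Rcpp::export]]
IntegerMatrix pair_column_indicators_cpp(IntegerMatrix aln) {
  const int n = aln.nrow(), L = aln.ncol();
  const int np = n * (n - 1) / 2;
  IntegerMatrix out(3 * np, L);
  int r = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j, ++r) {
      for (int s = 0; s < L; ++s) {
        int a = aln(i, s), b = aln(j, s);
        if (a == 0 || b == 0) continue;
        out(r, s) = 1;
        if (a == b) continue;
        bool pa = (a == 1 || a == 3), pb = (b == 1 || b == 3);
        if (pa == pb) out(np + r, s) = 1; else out(2 * np + r, s) = 1;
      }
    }
  }
  return out;
}
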