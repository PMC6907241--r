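#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Free-ends dynamic-programming alignment of a read profile against a
// reference profile.  fmat and rmat are (positions x 4) probability
// matrices (columns A,C,G,T).  The distance between a reference vector f
// and a read vector r is |f[i] - r[i]| where i is the argmax of r (ties
// broken toward the lowest column index, i.e. alphabetical order).
//
// Recurrence (rows = reference prefix length x, cols = read prefix length y):
//   M(x,0) = 0          free start anywhere in the reference
//   M(0,y) = c*y        read prefix forced into insertions before the start
//   M(x,y) = min( M(x-1,y-1) + d(f_x, r_y),   match/substitution
//                 M(x-1,y)   + c,             deletion-from-read (ref advances)
//                 M(x,y-1)   + c )            insertion-from-read (read advances)
// The read is consumed in full: e = min over x of M(x, n).
//
// Path step codes: 1 = match/substitution, 2 = deletion-from-read,
// 3 = insertion-from-read.  Positions are 0-based; an insertion's ref
// coordinate is the locus *before which* the read base would be inserted.

// [[Rcpp::export]]
List dtw_align_cpp(NumericMatrix fmat, NumericMatrix rmat, double c,
                   bool keep_matrix) {
  const int L = fmat.nrow();
  const int n = rmat.nrow();
  if (L < 1 || n < 1) stop("empty reference or read profile");

  std::vector<int> iy(n);
  std::vector<double> rv(n);
  for (int y = 0; y < n; ++y) {
    int best = 0;
    double bv = rmat(y, 0);
    for (int j = 1; j < 4; ++j) {
      if (rmat(y, j) > bv) { bv = rmat(y, j); best = j; }
    }
    iy[y] = best;
    rv[y] = bv;
  }

  NumericMatrix M(L + 1, n + 1);
  for (int x = 0; x <= L; ++x) M(x, 0) = 0.0;
  for (int y = 1; y <= n; ++y) M(0, y) = c * y;
  for (int x = 1; x <= L; ++x) {
    for (int y = 1; y <= n; ++y) {
      double m = M(x - 1, y - 1) + std::fabs(fmat(x - 1, iy[y - 1]) - rv[y - 1]);
      double del = M(x - 1, y) + c;
      if (del < m) m = del;
      double ins = M(x, y - 1) + c;
      if (ins < m) m = ins;
      M(x, y) = m;
    }
  }

  // e = min over 1 <= x <= L of M(x, n); smallest row index wins on ties
  int end_row = 1;
  double e = M(1, n);
  for (int x = 2; x <= L; ++x) {
    if (M(x, n) < e) { e = M(x, n); end_row = x; }
  }

  // traceback; tie preference: match/substitution, then deletion, then insertion
  std::vector<int> op, refp, readp;
  int x = end_row, y = n;
  while (y > 0) {
    if (x > 0) {
      double diag = M(x - 1, y - 1) +
        std::fabs(fmat(x - 1, iy[y - 1]) - rv[y - 1]);
      if (M(x, y) == diag) {
        op.push_back(1); refp.push_back(x - 1); readp.push_back(y - 1);
        --x; --y;
        continue;
      }
      if (M(x, y) == M(x - 1, y) + c) {
        op.push_back(2); refp.push_back(x - 1); readp.push_back(NA_INTEGER);
        --x;
        continue;
      }
      op.push_back(3); refp.push_back(x); readp.push_back(y - 1);
      --y;
    } else {
      op.push_back(3); refp.push_back(0); readp.push_back(y - 1);
      --y;
    }
  }
  const int start_row = x;

  const int k = (int) op.size();
  IntegerMatrix path(k, 3);
  for (int i = 0; i < k; ++i) {  // reverse into forward walk order
    path(i, 0) = op[k - 1 - i];
    path(i, 1) = refp[k - 1 - i];
    path(i, 2) = readp[k - 1 - i];
  }
  colnames(path) = CharacterVector::create("op", "ref", "read");

  List out = List::create(
    _["edit_distance"] = e,
    _["ref_start"] = start_row,
    _["ref_end"] = end_row,
    _["path"] = path);
  if (keep_matrix) out["matrix"] = M;
  return out;
}
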