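#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh three-state DP).
// Gap of length L costs open + L * ext. Traceback tie-break is fixed:
// prefer the match state, then a gap in the subject (consume query, "up"),
// then a gap in the query ("left"), so results are bit-stable.

static const double NEG = -1e30;

// state codes
enum { SM = 0, SX = 1, SY = 2 };  // match, gap-in-b (up), gap-in-a (left)

// [[Rcpp::export]]
List cpp_pairwise_align(std::string a, std::string b,
                        NumericMatrix submat, std::string alpha,
                        double gap_open, double gap_ext, bool local) {
  int la = a.size(), lb = b.size();
  if (la == 0 || lb == 0) stop("empty sequence");
  // residue -> index lookup
  int lut[256];
  for (int i = 0; i < 256; ++i) lut[i] = -1;
  for (int i = 0; i < (int)alpha.size(); ++i)
    lut[(unsigned char)alpha[i]] = i;
  std::vector<int> ia(la), ib(lb);
  for (int i = 0; i < la; ++i) {
    ia[i] = lut[(unsigned char)a[i]];
    if (ia[i] < 0) stop("character not in scoring alphabet");
  }
  for (int j = 0; j < lb; ++j) {
    ib[j] = lut[(unsigned char)b[j]];
    if (ib[j] < 0) stop("character not in scoring alphabet");
  }
  double go = gap_open + gap_ext;  // cost of opening a length-1 gap

  int nr = la + 1, nc = lb + 1;
  std::vector<double> M(nr * nc, NEG), X(nr * nc, NEG), Y(nr * nc, NEG);
  // traceback: predecessor state for each cell/state
  std::vector<signed char> pM(nr * nc, -1), pX(nr * nc, -1), pY(nr * nc, -1);
  #define AT(i, j) ((i) * nc + (j))

  M[AT(0, 0)] = 0.0;
  for (int i = 1; i <= la; ++i) {
    if (!local) { X[AT(i, 0)] = -(gap_open + i * gap_ext); pX[AT(i, 0)] = SX; }
  }
  for (int j = 1; j <= lb; ++j) {
    if (!local) { Y[AT(0, j)] = -(gap_open + j * gap_ext); pY[AT(0, j)] = SY; }
  }
  if (local)
    for (int i = 0; i <= la; ++i)
      for (int j = 0; j <= lb; ++j)
        M[AT(i, j)] = 0.0;  // fresh start allowed anywhere

  double best = 0.0; int bi = 0, bj = 0, bs = SM;
  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      double s = submat(ia[i - 1], ib[j - 1]);
      // match state: tie-break M >= X >= Y
      double m0 = M[AT(i - 1, j - 1)], x0 = X[AT(i - 1, j - 1)], y0 = Y[AT(i - 1, j - 1)];
      double bestprev = m0; signed char ps = SM;
      if (x0 > bestprev) { bestprev = x0; ps = SX; }
      if (y0 > bestprev) { bestprev = y0; ps = SY; }
      double mval = bestprev + s;
      if (local && mval < 0) { mval = 0; ps = -1; }
      M[AT(i, j)] = mval; pM[AT(i, j)] = ps;
      // gap in b (consume a): from (i-1, j)
      double xo = M[AT(i - 1, j)] - go, xx = X[AT(i - 1, j)] - gap_ext,
             xy = Y[AT(i - 1, j)] - go;
      double xval = xo; signed char xs = SM;
      if (xx > xval) { xval = xx; xs = SX; }
      if (xy > xval) { xval = xy; xs = SY; }
      X[AT(i, j)] = xval; pX[AT(i, j)] = xs;
      // gap in a (consume b): from (i, j-1)
      double yo = M[AT(i, j - 1)] - go, yx = X[AT(i, j - 1)] - go,
             yy = Y[AT(i, j - 1)] - gap_ext;
      double yval = yo; signed char ys = SM;
      if (yx > yval) { yval = yx; ys = SX; }
      if (yy > yval) { yval = yy; ys = SY; }
      Y[AT(i, j)] = yval; pY[AT(i, j)] = ys;
      if (local && mval > best) { best = mval; bi = i; bj = j; bs = SM; }
    }
  }

  int ci, cj, cs;
  double score;
  if (local) {
    score = best; ci = bi; cj = bj; cs = SM;
    if (best <= 0.0)  // no positive-scoring local alignment: report no-hit
      return List::create(_["score"] = 0.0, _["aligned_a"] = "",
                          _["aligned_b"] = "", _["a_start"] = NA_INTEGER,
                          _["a_end"] = NA_INTEGER, _["b_start"] = NA_INTEGER,
                          _["b_end"] = NA_INTEGER);
  } else {
    ci = la; cj = lb;
    double m = M[AT(la, lb)], x = X[AT(la, lb)], y = Y[AT(la, lb)];
    score = m; cs = SM;
    if (x > score) { score = x; cs = SX; }
    if (y > score) { score = y; cs = SY; }
  }

  std::string ra, rb;
  int a_end = ci, b_end = cj;
  while (ci > 0 || cj > 0) {
    if (cs == SM) {
      signed char ps = pM[AT(ci, cj)];
      if (local && (ps == -1 || (ci == 0 && cj == 0))) break;
      if (ci == 0 && cj == 0) break;
      if (ps == -1) break;  // local fresh start
      ra.push_back(a[ci - 1]); rb.push_back(b[cj - 1]);
      --ci; --cj; cs = ps;
    } else if (cs == SX) {
      ra.push_back(a[ci - 1]); rb.push_back('-');
      signed char ps = pX[AT(ci, cj)];
      --ci; cs = ps;
    } else {
      ra.push_back('-'); rb.push_back(b[cj - 1]);
      signed char ps = pY[AT(ci, cj)];
      --cj; cs = ps;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  int a_start = ci + 1, b_start = cj + 1;
  if (!local) { a_start = 1; b_start = 1; a_end = la; b_end = lb; }

  return List::create(_["score"] = score, _["aligned_a"] = ra,
                      _["aligned_b"] = rb, _["a_start"] = a_start,
                      _["a_end"] = a_end, _["b_start"] = b_start,
                      _["b_end"] = b_end);
}

// Profile-profile global alignment with affine gaps and sum-of-pairs
// (expected substitution) column scores. Profiles are 20 x L frequency
// matrices; column sums may be < 1 when rows carry gaps, so gap-heavy
// columns contribute proportionally less.
// Returns 1-based column indices of each profile along the merged
// alignment, 0 marking a gap column.
// [[Rcpp::export]]
List cpp_profile_align(NumericMatrix p1, NumericMatrix p2,
                       NumericMatrix submat,
                       double gap_open, double gap_ext) {
  int l1 = p1.ncol(), l2 = p2.ncol(), na = submat.nrow();
  if (l1 == 0 || l2 == 0) stop("empty profile");
  // pre-compute B %*% p2 (na x l2)
  NumericMatrix bp2(na, l2);
  for (int j = 0; j < l2; ++j)
    for (int r = 0; r < na; ++r) {
      double acc = 0;
      for (int c = 0; c < na; ++c) acc += submat(r, c) * p2(c, j);
      bp2(r, j) = acc;
    }
  int nr = l1 + 1, nc = l2 + 1;
  std::vector<double> M(nr * nc, NEG), X(nr * nc, NEG), Y(nr * nc, NEG);
  std::vector<signed char> pM(nr * nc, -1), pX(nr * nc, -1), pY(nr * nc, -1);
  #define AT2(i, j) ((i) * nc + (j))
  M[AT2(0, 0)] = 0.0;
  for (int i = 1; i <= l1; ++i) { X[AT2(i, 0)] = -(gap_open + i * gap_ext); pX[AT2(i, 0)] = SX; }
  for (int j = 1; j <= l2; ++j) { Y[AT2(0, j)] = -(gap_open + j * gap_ext); pY[AT2(0, j)] = SY; }
  double go = gap_open + gap_ext;
  for (int i = 1; i <= l1; ++i) {
    for (int j = 1; j <= l2; ++j) {
      double s = 0;
      for (int r = 0; r < na; ++r) s += p1(r, i - 1) * bp2(r, j - 1);
      double m0 = M[AT2(i - 1, j - 1)], x0 = X[AT2(i - 1, j - 1)], y0 = Y[AT2(i - 1, j - 1)];
      double bp = m0; signed char ps = SM;
      if (x0 > bp) { bp = x0; ps = SX; }
      if (y0 > bp) { bp = y0; ps = SY; }
      M[AT2(i, j)] = bp + s; pM[AT2(i, j)] = ps;
      double xo = M[AT2(i - 1, j)] - go, xx = X[AT2(i - 1, j)] - gap_ext,
             xy = Y[AT2(i - 1, j)] - go;
      double xv = xo; signed char xs = SM;
      if (xx > xv) { xv = xx; xs = SX; }
      if (xy > xv) { xv = xy; xs = SY; }
      X[AT2(i, j)] = xv; pX[AT2(i, j)] = xs;
      double yo = M[AT2(i, j - 1)] - go, yx = X[AT2(i, j - 1)] - go,
             yy = Y[AT2(i, j - 1)] - gap_ext;
      double yv = yo; signed char ys = SM;
      if (yx > yv) { yv = yx; ys = SX; }
      if (yy > yv) { yv = yy; ys = SY; }
      Y[AT2(i, j)] = yv; pY[AT2(i, j)] = ys;
    }
  }
  int ci = l1, cj = l2, cs = SM;
  double m = M[AT2(l1, l2)], x = X[AT2(l1, l2)], y = Y[AT2(l1, l2)];
  double score = m;
  if (x > score) { score = x; cs = SX; }
  if (y > score) { score = y; cs = SY; }
  std::vector<int> o1, o2;
  while (ci > 0 || cj > 0) {
    if (cs == SM) {
      o1.push_back(ci); o2.push_back(cj);
      signed char ps = pM[AT2(ci, cj)];
      --ci; --cj; cs = ps;
    } else if (cs == SX) {
      o1.push_back(ci); o2.push_back(0);
      signed char ps = pX[AT2(ci, cj)];
      --ci; cs = ps;
    } else {
      o1.push_back(0); o2.push_back(cj);
      signed char ps = pY[AT2(ci, cj)];
      --cj; cs = ps;
    }
  }
  std::reverse(o1.begin(), o1.end());
  std::reverse(o2.begin(), o2.end());
  return List::create(_["score"] = score,
                      _["idx1"] = IntegerVector(o1.begin(), o1.end()),
                      _["idx2"] = IntegerVector(o2.begin(), o2.end()));
}
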