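#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap Smith-Waterman with traceback.
// Gap convention (BLAST-style): a gap of length L costs open + L * extend.
// States: M (match/mismatch), X (gap in template/subject, i advances),
// Y (gap in query, j advances). Local: all cells floored at 0 in M.
//
// qidx/tidx: 0-based indices into the scoring matrix rows/cols.
// Returns the optimal raw score, the aligned (match/mismatch) column pairs
// as 1-based positions, the number of identical columns, and the number of
// aligned columns.

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(IntegerVector qidx, IntegerVector tidx,
                  NumericMatrix smat, double gap_open, double gap_extend) {
  const int n = qidx.size(), m = tidx.size();
  const double NEG = -1e30;
  const double open_cost = gap_open + gap_extend;

  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  // traceback pointers: for M: 0 stop, 1 from M, 2 from X, 3 from Y
  IntegerMatrix pM(n + 1, m + 1), pX(n + 1, m + 1), pY(n + 1, m + 1);

  for (int j = 0; j <= m; ++j) { X(0, j) = NEG; Y(0, j) = NEG; }
  for (int i = 0; i <= n; ++i) { X(i, 0) = NEG; Y(i, 0) = NEG; }

  double best = 0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // X: gap in subject, query position i aligned to '-'
      double xo = M(i - 1, j) - open_cost;
      double xe = X(i - 1, j) - gap_extend;
      if (xo >= xe) { X(i, j) = xo; pX(i, j) = 1; }
      else          { X(i, j) = xe; pX(i, j) = 2; }
      // Y: gap in query
      double yo = M(i, j - 1) - open_cost;
      double ye = Y(i, j - 1) - gap_extend;
      if (yo >= ye) { Y(i, j) = yo; pY(i, j) = 1; }
      else          { Y(i, j) = ye; pY(i, j) = 3; }
      // M
      double s = smat(qidx[i - 1], tidx[j - 1]);
      double dM = M(i - 1, j - 1), dX = X(i - 1, j - 1), dY = Y(i - 1, j - 1);
      double d = dM; int p = 1;
      if (dX > d) { d = dX; p = 2; }
      if (dY > d) { d = dY; p = 3; }
      double v = d + s;
      if (v <= 0) { M(i, j) = 0; pM(i, j) = 0; }
      else        { M(i, j) = v; pM(i, j) = p; }
      if (M(i, j) > best) { best = M(i, j); bi = i; bj = j; }
    }
  }

  std::vector<int> qp, tp;
  int n_ident = 0;
  int i = bi, j = bj, state = 1;  // best always ends in M
  while (i > 0 && j > 0) {
    if (state == 1) {
      int p = pM(i, j);
      qp.push_back(i); tp.push_back(j);
      if (qidx[i - 1] == tidx[j - 1]) ++n_ident;
      --i; --j;
      if (p == 0) break;  // local start (the cell we just consumed)
      state = p;
      if (p == 1 && M(i, j) == 0 && pM(i, j) == 0) break;
    } else if (state == 2) {
      int p = pX(i, j); --i; state = p;
    } else {
      int p = pY(i, j); --j; state = p;
    }
  }
  std::reverse(qp.begin(), qp.end());
  std::reverse(tp.begin(), tp.end());

  return List::create(_["score"] = best,
                      _["qpos"] = wrap(qp), _["tpos"] = wrap(tp),
                      _["n_ident"] = n_ident,
                      _["n_aligned"] = (int)qp.size());
}
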