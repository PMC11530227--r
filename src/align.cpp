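#include <Rcpp.h>
using namespace Rcpp;

// Local affine-gap alignment (Smith-Waterman / Gotoh) of a query residue
// index vector against a "column score" matrix: colscore(i, a) is the gain
// of placing query residue a at target column i.  This one kernel serves
// sequence-vs-sequence search (colscore = substitution-matrix rows of the
// target residues) and query-vs-PSSM profile search.
//
// A gap of length k costs gap_open + k * gap_extend.
//
// Ties during the fill prefer diagonal over gap-in-query over gap-in-target
// and, for the end cell, the smallest query end then the smallest target
// end; together with the fixed traceback preference this makes the reported
// interval deterministic.
//
// t_res: residue index of each target column (consensus for profiles), used
// only for identity/mismatch counting.
//
// Returns 0-based half-open intervals.
// [[Rcpp::export(name = ".align_local_cpp")]]
List align_local_cpp(IntegerVector q, NumericMatrix colscore,
                     IntegerVector t_res,
                     double gap_open, double gap_extend) {
  const int m = q.size();          // query length
  const int n = colscore.nrow();   // target columns
  const double NEG = -1e30;
  const double gi = gap_open + gap_extend;  // cost of first gap position

  // DP matrices, (n+1) x (m+1), row-major via index r*(m+1)+c
  std::vector<double> H((n + 1) * (m + 1), 0.0);
  std::vector<double> E((n + 1) * (m + 1), NEG);  // gap in target (consumes query)
  std::vector<double> F((n + 1) * (m + 1), NEG);  // gap in query  (consumes target)
  // traceback pointers for H: 0 stop, 1 diag, 2 from E, 3 from F
  std::vector<unsigned char> PH((n + 1) * (m + 1), 0);
  // for E/F: 1 = opened from H, 0 = extended
  std::vector<unsigned char> PE((n + 1) * (m + 1), 0);
  std::vector<unsigned char> PF((n + 1) * (m + 1), 0);

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t c = (size_t)i * (m + 1) + j;
      const size_t up = c - (m + 1), left = c - 1, diag = up - 1;

      double e_open = H[left] - gi, e_ext = E[left] - gap_extend;
      if (e_open >= e_ext) { E[c] = e_open; PE[c] = 1; }
      else                 { E[c] = e_ext;  PE[c] = 0; }

      double f_open = H[up] - gi, f_ext = F[up] - gap_extend;
      if (f_open >= f_ext) { F[c] = f_open; PF[c] = 1; }
      else                 { F[c] = f_ext;  PF[c] = 0; }

      double d = H[diag] + colscore(i - 1, q[j - 1]);
      double h = 0.0; unsigned char ph = 0;
      if (d >= h) { h = d; ph = 1; }
      if (E[c] > h) { h = E[c]; ph = 2; }
      if (F[c] > h) { h = F[c]; ph = 3; }
      H[c] = h; PH[c] = ph;
      // end cell: strictly better score, or equal with smaller (j, i)
      if (h > best + 1e-12 ||
          (h > 0 && std::abs(h - best) <= 1e-12 &&
           (j < bj || (j == bj && i < bi)))) {
        best = h; bi = i; bj = j;
      }
    }
  }

  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["hit"] = false);
  }

  // traceback
  int i = bi, j = bj, state = 0;  // state 0 = in H
  int ncols = 0, nmatch = 0, nmismatch = 0, ngapopen = 0;
  int qi_end = bj, ti_end = bi;
  while (true) {
    const size_t c = (size_t)i * (m + 1) + j;
    if (state == 0) {
      unsigned char ph = PH[c];
      if (ph == 0) break;
      if (ph == 1) {
        ++ncols;
        if (t_res[i - 1] >= 0 && q[j - 1] == t_res[i - 1]) ++nmatch;
        else ++nmismatch;
        --i; --j;
      } else if (ph == 2) {
        state = 2;
      } else {
        state = 3;
      }
    } else if (state == 2) {      // E: gap in target, consume query residue
      ++ncols;
      unsigned char pe = PE[c];
      --j;
      if (pe == 1) { ++ngapopen; state = 0; }
    } else {                      // F: gap in query, consume target column
      ++ncols;
      unsigned char pf = PF[c];
      --i;
      if (pf == 1) { ++ngapopen; state = 0; }
    }
  }

  return List::create(
    _["score"] = best, _["hit"] = true,
    _["q_start"] = j, _["q_end"] = qi_end,     // 0-based half-open
    _["t_start"] = i, _["t_end"] = ti_end,
    _["n_cols"] = ncols, _["n_match"] = nmatch,
    _["n_mismatch"] = nmismatch, _["n_gapopen"] = ngapopen);
}
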