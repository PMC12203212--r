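#include <Rcpp.h>
using namespace Rcpp;

// Alignment kernels shared by the clustering and MSA layers.
//
// Sequences arrive as 0-based integer codes over a 21-letter alphabet
// (20 residue letters + code 20 for 'X'); the score matrices are 21x21 with
// the X row/column zeroed, already weighted and rounded to integers in R, so
// a column score is simply mat3(a3,b3) + mataa(aa,ba).
//
// Gap model: opening a gap of length 1 costs gap_open, each further gap
// character costs gap_extend.

static inline int score_at(const IntegerMatrix& m, int a, int b) {
  return m(a, b);
}

// Affine-gap local alignment (Gotoh) with full traceback.
// Returns raw score, 1-based aligned spans, alignment length (columns),
// number of identical AA matches, and number of match columns.
// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(IntegerVector q3, IntegerVector t3,
                  IntegerVector qa, IntegerVector ta,
                  IntegerMatrix mat3, IntegerMatrix mataa,
                  int gap_open, int gap_extend) {
  const int m = q3.size(), n = t3.size();
  const int NEG = -1000000000;

  // DP matrices (H best, E gap-in-query horizontal, F gap-in-target vertical)
  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0);
  std::vector<int> Eprev(n + 1, NEG), Ecur(n + 1, NEG);
  std::vector<int> Fcol(n + 1, NEG);
  // traceback: 0 stop, 1 diag, 2 left (gap in query), 3 up (gap in target)
  // plus gap-state continuation bits stored separately
  std::vector<unsigned char> tbH((m + 1) * (n + 1), 0);
  std::vector<unsigned char> tbE((m + 1) * (n + 1), 0); // 1 = extend from E
  std::vector<unsigned char> tbF((m + 1) * (n + 1), 0);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    Hcur[0] = 0; Ecur[0] = NEG;
    int Fprev_cell = NEG; // F[i][j] computed from H[i-1][j], F[i-1][j]
    for (int j = 1; j <= n; ++j) {
      // E: gap in query (consume target), move left
      int e_open = Hcur[j - 1] - gap_open;
      int e_ext  = Ecur[j - 1] - gap_extend;
      int E = (e_open >= e_ext) ? e_open : e_ext;
      tbE[i * (n + 1) + j] = (e_open >= e_ext) ? 0 : 1;
      Ecur[j] = E;
      // F: gap in target (consume query), move up
      int f_open = Hprev[j] - gap_open;
      int f_ext  = Fcol[j] - gap_extend;
      int F = (f_open >= f_ext) ? f_open : f_ext;
      tbF[i * (n + 1) + j] = (f_open >= f_ext) ? 0 : 1;
      Fcol[j] = F;
      (void)Fprev_cell;
      // H
      int s = score_at(mat3, q3[i - 1], t3[j - 1]) +
              score_at(mataa, qa[i - 1], ta[j - 1]);
      int diag = Hprev[j - 1] + s;
      int H = 0; unsigned char dir = 0;
      if (diag > H) { H = diag; dir = 1; }
      if (F > H)    { H = F;    dir = 3; }
      if (E > H)    { H = E;    dir = 2; }
      Hcur[j] = H;
      tbH[i * (n + 1) + j] = dir;
      if (H > best) { best = H; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }

  // traceback from (bi, bj)
  int i = bi, j = bj;
  int qend = bi, tend = bj;
  int ncols = 0, nmatch_cols = 0, nident = 0;
  int state = 0; // 0 = H, 1 = E, 2 = F
  while (i > 0 && j > 0) {
    if (state == 0) {
      unsigned char dir = tbH[i * (n + 1) + j];
      if (dir == 0) break;
      if (dir == 1) {
        ++ncols; ++nmatch_cols;
        if (qa[i - 1] == ta[j - 1] && qa[i - 1] != 20) ++nident;
        --i; --j;
      } else if (dir == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      ++ncols;
      unsigned char ext = tbE[i * (n + 1) + j];
      --j;
      if (!ext) state = 0;
    } else {
      ++ncols;
      unsigned char ext = tbF[i * (n + 1) + j];
      --i;
      if (!ext) state = 0;
    }
  }
  int qstart = i + 1, tstart = j + 1;
  if (best == 0) { qstart = qend = tstart = tend = 0; }

  return List::create(
    _["score"] = best,
    _["qstart"] = qstart, _["qend"] = qend,
    _["tstart"] = tstart, _["tend"] = tend,
    _["ncols"] = ncols, _["nmatch"] = nmatch_cols, _["nident"] = nident);
}

// Score-only local alignment: linear memory, no traceback.
// [[Rcpp::export(name = ".sw_score_cpp")]]
int sw_score_cpp(IntegerVector q3, IntegerVector t3,
                 IntegerVector qa, IntegerVector ta,
                 IntegerMatrix mat3, IntegerMatrix mataa,
                 int gap_open, int gap_extend) {
  const int m = q3.size(), n = t3.size();
  const int NEG = -1000000000;
  std::vector<int> H(n + 1, 0), E(n + 1, NEG), F(n + 1, NEG);
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    int Hdiag = 0; // H[i-1][j-1]
    H[0] = 0; E[0] = NEG;
    for (int j = 1; j <= n; ++j) {
      int e = std::max(H[j - 1] - gap_open, E[j - 1] - gap_extend);
      E[j] = e;
      int f = std::max(H[j] - gap_open, F[j] - gap_extend);
      F[j] = f;
      int s = score_at(mat3, q3[i - 1], t3[j - 1]) +
              score_at(mataa, qa[i - 1], ta[j - 1]);
      int h = Hdiag + s;
      if (h < 0) h = 0;
      if (e > h) h = e;
      if (f > h) h = f;
      Hdiag = H[j];
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// Batch score-only: one query vs many targets (used by member reassignment).
// [[Rcpp::export(name = ".sw_score_batch_cpp")]]
NumericVector sw_score_batch_cpp(IntegerVector q3, IntegerVector qa,
                                 List t3list, List talist,
                                 IntegerMatrix mat3, IntegerMatrix mataa,
                                 int gap_open, int gap_extend) {
  const int k = t3list.size();
  NumericVector out(k);
  for (int z = 0; z < k; ++z) {
    IntegerVector t3 = t3list[z], ta = talist[z];
    out[z] = sw_score_cpp(q3, t3, qa, ta, mat3, mataa, gap_open, gap_extend);
  }
  return out;
}

// Global affine-gap DP (Gotoh) over a precomputed column-score matrix
// (profile-profile scores), returning the edit path. Ties are broken
// "high road": diagonal preferred over up (gap in B) over left (gap in A).
// Path codes: 1 = diag, 2 = consume A only (gap in B), 3 = consume B only.
// [[Rcpp::export(name = ".nw_path_cpp")]]
IntegerVector nw_path_cpp(NumericMatrix S, double gap_open, double gap_extend) {
  const int m = S.nrow(), n = S.ncol();
  const double NEG = -1e300;
  NumericMatrix H(m + 1, n + 1), E(m + 1, n + 1), F(m + 1, n + 1);
  // tb codes for H: 1 diag, 2 from F (up), 3 from E (left)
  IntegerMatrix tbH(m + 1, n + 1), tbE(m + 1, n + 1), tbF(m + 1, n + 1);
  H(0, 0) = 0; E(0, 0) = NEG; F(0, 0) = NEG;
  for (int j = 1; j <= n; ++j) {
    E(0, j) = -gap_open - gap_extend * (j - 1);
    H(0, j) = E(0, j); F(0, j) = NEG;
    tbH(0, j) = 3; tbE(0, j) = (j > 1);
  }
  for (int i = 1; i <= m; ++i) {
    F(i, 0) = -gap_open - gap_extend * (i - 1);
    H(i, 0) = F(i, 0); E(i, 0) = NEG;
    tbH(i, 0) = 2; tbF(i, 0) = (i > 1);
  }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double e_open = H(i, j - 1) - gap_open;
      double e_ext = E(i, j - 1) - gap_extend;
      if (e_open >= e_ext) { E(i, j) = e_open; tbE(i, j) = 0; }
      else { E(i, j) = e_ext; tbE(i, j) = 1; }
      double f_open = H(i - 1, j) - gap_open;
      double f_ext = F(i - 1, j) - gap_extend;
      if (f_open >= f_ext) { F(i, j) = f_open; tbF(i, j) = 0; }
      else { F(i, j) = f_ext; tbF(i, j) = 1; }
      double diag = H(i - 1, j - 1) + S(i - 1, j - 1);
      double h = diag; int dir = 1;
      if (F(i, j) > h) { h = F(i, j); dir = 2; }
      if (E(i, j) > h) { h = E(i, j); dir = 3; }
      H(i, j) = h; tbH(i, j) = dir;
    }
  }
  std::vector<int> path;
  int i = m, j = n, state = 0;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int dir = tbH(i, j);
      if (dir == 1) { path.push_back(1); --i; --j; }
      else if (dir == 2) state = 2;
      else state = 1;
    } else if (state == 1) { // E, gap in A, consume B
      int ext = tbE(i, j);
      path.push_back(3); --j;
      if (!ext) state = 0;
    } else { // F, gap in B, consume A
      int ext = tbF(i, j);
      path.push_back(2); --i;
      if (!ext) state = 0;
    }
  }
  std::reverse(path.begin(), path.end());
  return wrap(path);
}
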