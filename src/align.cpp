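#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh three-state DP).
// Gap cost convention: a gap of length k costs gap_open + k * gap_extend
// (NCBI-style: the open penalty is charged once, on top of per-residue
// extension), so entering a gap state costs gap_open + gap_extend and
// staying in it costs gap_extend.

static const double NEG_INF = -1e30;

// a, b: 0-based indices into the substitution matrix; -1 = unknown residue
// (scores 0 against everything). Returns optimal local alignment with
// traceback-derived spans (1-based, inclusive) and identity bookkeeping.
// [[Rcpp::export]]
List sw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0)
    return List::create(_["score"] = 0.0, _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0,
                        _["aligned_cols"] = 0, _["identical"] = 0);

  const double open = gap_open + gap_extend, ext = gap_extend;
  // state 0 = M (diagonal), 1 = Ix (gap in b, consumes a), 2 = Iy (gap in a)
  std::vector<double> M((n + 1) * (m + 1), 0.0),
      Ix((n + 1) * (m + 1), NEG_INF), Iy((n + 1) * (m + 1), NEG_INF);
  // traceback: for M, 0=start-here, 1=from M, 2=from Ix, 3=from Iy;
  // for Ix/Iy, 0=opened from M, 1=extended
  std::vector<unsigned char> tbM((n + 1) * (m + 1), 0),
      tbX((n + 1) * (m + 1), 0), tbY((n + 1) * (m + 1), 0);

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int idx = i * (m + 1) + j;
      const int up = (i - 1) * (m + 1) + j, left = idx - 1,
                diag = up - 1;
      double s = (a[i - 1] < 0 || b[j - 1] < 0)
                     ? 0.0
                     : sub(a[i - 1], b[j - 1]);
      // Ix: gap in b
      double xo = M[up] - open, xe = Ix[up] - ext;
      if (xe > xo) { Ix[idx] = xe; tbX[idx] = 1; } else { Ix[idx] = xo; tbX[idx] = 0; }
      // Iy: gap in a
      double yo = M[left] - open, ye = Iy[left] - ext;
      if (ye > yo) { Iy[idx] = ye; tbY[idx] = 1; } else { Iy[idx] = yo; tbY[idx] = 0; }
      // M: continue the best incoming path, or start fresh at (i,j)
      double dm = M[diag], dx = Ix[diag], dy = Iy[diag];
      double dbest = dm; unsigned char from = 1;
      if (dx > dbest) { dbest = dx; from = 2; }
      if (dy > dbest) { dbest = dy; from = 3; }
      double cont = dbest + s, start_here = s;
      if (cont > start_here && cont > 0.0) { M[idx] = cont; tbM[idx] = from; }
      else if (start_here > 0.0) { M[idx] = start_here; tbM[idx] = 0; }
      else { M[idx] = 0.0; tbM[idx] = 0; }
      if (M[idx] > best) { best = M[idx]; bi = i; bj = j; }
    }
  }

  // traceback from (bi, bj) in state M
  int i = bi, j = bj, state = 0;
  int cols = 0, ident = 0;
  int a_end = bi, b_end = bj, a_start = bi, b_start = bj;
  while (i > 0 && j > 0) {
    const int idx = i * (m + 1) + j;
    if (state == 0) {
      ++cols;
      if (a[i - 1] >= 0 && a[i - 1] == b[j - 1]) ++ident;
      a_start = i; b_start = j;
      unsigned char t = tbM[idx];
      --i; --j;
      if (t == 0) break;
      state = (t == 1) ? 0 : (t == 2 ? 1 : 2);
    } else if (state == 1) { // Ix: consumes a
      ++cols;
      a_start = i;
      unsigned char t = tbX[idx];
      --i;
      state = (t == 1) ? 1 : 0;
    } else { // Iy: consumes b
      ++cols;
      b_start = j;
      unsigned char t = tbY[idx];
      --j;
      state = (t == 1) ? 2 : 0;
    }
  }
  if (best <= 0.0) { a_start = a_end = b_start = b_end = 0; cols = 0; ident = 0; }

  return List::create(_["score"] = best, _["a_start"] = a_start,
                      _["a_end"] = a_end, _["b_start"] = b_start,
                      _["b_end"] = b_end, _["aligned_cols"] = cols,
                      _["identical"] = ident);
}

// Local profile-sequence alignment: prof is L x A position-specific scores,
// seq holds 0-based column indices (-1 = unknown, scored 0). mask marks
// sequence positions that may not be aligned (already claimed by a
// higher-scoring hit). Same gap convention as sw_align_cpp.
// [[Rcpp::export]]
List profile_scan_cpp(NumericMatrix prof, IntegerVector seq,
                      double gap_open, double gap_extend,
                      LogicalVector mask) {
  const int n = prof.nrow(), m = seq.size();
  if (n == 0 || m == 0)
    return List::create(_["score"] = 0.0, _["q_start"] = 0, _["q_end"] = 0,
                        _["p_start"] = 0, _["p_end"] = 0);
  const double open = gap_open + gap_extend, ext = gap_extend;
  std::vector<double> M((n + 1) * (m + 1), 0.0),
      Ix((n + 1) * (m + 1), NEG_INF), Iy((n + 1) * (m + 1), NEG_INF);
  std::vector<unsigned char> tbM((n + 1) * (m + 1), 0),
      tbX((n + 1) * (m + 1), 0), tbY((n + 1) * (m + 1), 0);

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {       // profile position
    for (int j = 1; j <= m; ++j) {     // sequence position
      const int idx = i * (m + 1) + j;
      const int up = (i - 1) * (m + 1) + j, left = idx - 1, diag = up - 1;
      bool banned = mask.size() > 0 && mask[j - 1];
      double s;
      if (banned) s = NEG_INF;
      else s = (seq[j - 1] < 0) ? 0.0 : prof(i - 1, seq[j - 1]);
      double xo = M[up] - open, xe = Ix[up] - ext;
      if (xe > xo) { Ix[idx] = xe; tbX[idx] = 1; } else { Ix[idx] = xo; tbX[idx] = 0; }
      double yo = M[left] - open, ye = Iy[left] - ext;
      if (banned) { yo = NEG_INF; ye = NEG_INF; }
      if (ye > yo) { Iy[idx] = ye; tbY[idx] = 1; } else { Iy[idx] = yo; tbY[idx] = 0; }
      double dm = M[diag], dx = Ix[diag], dy = Iy[diag];
      double dbest = dm; unsigned char from = 1;
      if (dx > dbest) { dbest = dx; from = 2; }
      if (dy > dbest) { dbest = dy; from = 3; }
      double cont = dbest + s, start_here = s;
      if (cont > start_here && cont > 0.0) { M[idx] = cont; tbM[idx] = from; }
      else if (start_here > 0.0) { M[idx] = start_here; tbM[idx] = 0; }
      else { M[idx] = 0.0; tbM[idx] = 0; }
      if (M[idx] > best) { best = M[idx]; bi = i; bj = j; }
    }
  }

  int i = bi, j = bj, state = 0;
  int q_start = bj, q_end = bj, p_start = bi, p_end = bi;
  while (i > 0 && j > 0) {
    const int idx = i * (m + 1) + j;
    if (state == 0) {
      p_start = i; q_start = j;
      unsigned char t = tbM[idx];
      --i; --j;
      if (t == 0) break;
      state = (t == 1) ? 0 : (t == 2 ? 1 : 2);
    } else if (state == 1) {
      unsigned char t = tbX[idx];
      --i;
      state = (t == 1) ? 1 : 0;
    } else {
      unsigned char t = tbY[idx];
      --j;
      state = (t == 1) ? 2 : 0;
    }
  }
  if (best <= 0.0) { q_start = q_end = p_start = p_end = 0; }

  return List::create(_["score"] = best, _["q_start"] = q_start,
                      _["q_end"] = q_end, _["p_start"] = p_start,
                      _["p_end"] = p_end);
}
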