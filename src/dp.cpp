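#include <Rcpp.h>
using namespace Rcpp;

// Local (Smith-Waterman-style) affine-gap alignment of a position-specific
// scoring matrix against an integer-encoded sequence. `prof` is n_pos x
// n_alpha (scores, any units); `seq` holds 1-based alphabet indices.
// Returns the best score, its profile/target span (1-based, inclusive) and
// the per-column pairing of the best local alignment.
// [[Rcpp::export(name = ".pssm_local_scan")]]
List pssm_local_scan(NumericMatrix prof, IntegerVector seq,
                     double gap_open, double gap_ext) {
  const int n = prof.nrow();      // profile positions
  const int m = seq.size();       // target length
  if (n == 0 || m == 0) stop("empty profile or sequence");

  NumericMatrix M(n + 1, m + 1), Ix(n + 1, m + 1), Iy(n + 1, m + 1);
  IntegerMatrix ptr(n + 1, m + 1); // 0 stop, 1 diag, 2 up(Ix), 3 left(Iy)
  const double NEG = -1e30;
  for (int i = 0; i <= n; ++i) { Ix(i, 0) = NEG; Iy(i, 0) = NEG; }
  for (int j = 0; j <= m; ++j) { Ix(0, j) = NEG; Iy(0, j) = NEG; }

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double sc = prof(i - 1, seq[j - 1] - 1);
      double diag = std::max(std::max(M(i - 1, j - 1), Ix(i - 1, j - 1)),
                             Iy(i - 1, j - 1));
      double mval = sc + std::max(0.0, diag);
      Ix(i, j) = std::max(M(i - 1, j) - gap_open, Ix(i - 1, j) - gap_ext);
      Iy(i, j) = std::max(M(i, j - 1) - gap_open, Iy(i, j - 1) - gap_ext);
      M(i, j) = mval;
      double cell = std::max(std::max(mval, Ix(i, j)), Iy(i, j));
      if (cell <= 0.0) { ptr(i, j) = 0; }
      else if (cell == mval) ptr(i, j) = 1;
      else if (cell == Ix(i, j)) ptr(i, j) = 2;
      else ptr(i, j) = 3;
      if (cell > best) { best = cell; bi = i; bj = j; }
    }
  }
  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["prof_start"] = NA_INTEGER,
                        _["prof_end"] = NA_INTEGER,
                        _["t_start"] = NA_INTEGER, _["t_end"] = NA_INTEGER);
  }
  // traceback for the span
  int i = bi, j = bj;
  int state = ptr(i, j);
  int pi = bi, pj = bj;
  while (i > 0 && j > 0) {
    if (state == 1) {
      pi = i; pj = j;
      double diag = std::max(std::max(M(i - 1, j - 1), Ix(i - 1, j - 1)),
                             Iy(i - 1, j - 1));
      if (diag <= 0.0) break;
      if (diag == M(i - 1, j - 1)) state = 1;
      else if (diag == Ix(i - 1, j - 1)) state = 2;
      else state = 3;
      --i; --j;
    } else if (state == 2) {
      if (Ix(i, j) == M(i - 1, j) - gap_open) state = 1; else state = 2;
      --i;
    } else if (state == 3) {
      if (Iy(i, j) == M(i, j - 1) - gap_open) state = 1; else state = 3;
      --j;
    } else break;
  }
  return List::create(_["score"] = best, _["prof_start"] = pi,
                      _["prof_end"] = bi, _["t_start"] = pj,
                      _["t_end"] = bj);
}

// Global affine-gap alignment over a precomputed cell-score matrix
// (profile columns of A x profile columns of B). Returns the aligned index
// paths: 0 marks a gap. Used by the progressive multiple aligner.
// [[Rcpp::export(name = ".profile_global_align")]]
List profile_global_align(NumericMatrix cell, double gap_open,
                          double gap_ext) {
  const int n = cell.nrow(), m = cell.ncol();
  const double NEG = -1e30;
  NumericMatrix M(n + 1, m + 1), Ix(n + 1, m + 1), Iy(n + 1, m + 1);
  M(0, 0) = 0.0; Ix(0, 0) = NEG; Iy(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; Iy(i, 0) = NEG;
    Ix(i, 0) = -gap_open - gap_ext * (i - 1);
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; Ix(0, j) = NEG;
    Iy(0, j) = -gap_open - gap_ext * (j - 1);
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double prev = std::max(std::max(M(i - 1, j - 1), Ix(i - 1, j - 1)),
                             Iy(i - 1, j - 1));
      M(i, j) = cell(i - 1, j - 1) + prev;
      Ix(i, j) = std::max(M(i - 1, j) - gap_open, Ix(i - 1, j) - gap_ext);
      Iy(i, j) = std::max(M(i, j - 1) - gap_open, Iy(i, j - 1) - gap_ext);
    }
  }
  // traceback
  std::vector<int> pa, pb;
  int i = n, j = m;
  int state;
  double last = std::max(std::max(M(n, m), Ix(n, m)), Iy(n, m));
  if (last == M(n, m)) state = 1; else if (last == Ix(n, m)) state = 2;
  else state = 3;
  while (i > 0 || j > 0) {
    if (state == 1) {
      pa.push_back(i); pb.push_back(j);
      double prev = std::max(std::max(M(i - 1, j - 1), Ix(i - 1, j - 1)),
                             Iy(i - 1, j - 1));
      --i; --j;
      if (i == 0 && j == 0) break;
      if (prev == M(i, j)) state = 1;
      else if (prev == Ix(i, j)) state = 2;
      else state = 3;
    } else if (state == 2) {
      pa.push_back(i); pb.push_back(0);
      bool from_m = (Ix(i, j) == M(i - 1, j) - gap_open);
      --i;
      state = from_m ? 1 : 2;
      if (i == 0 && j == 0) break;
      if (i == 0) state = 3;
    } else {
      pa.push_back(0); pb.push_back(j);
      bool from_m = (Iy(i, j) == M(i, j - 1) - gap_open);
      --j;
      state = from_m ? 1 : 3;
      if (i == 0 && j == 0) break;
      if (j == 0) state = 2;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["score"] = last,
                      _["path_a"] = IntegerVector(pa.begin(), pa.end()),
                      _["path_b"] = IntegerVector(pb.begin(), pb.end()));
}
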