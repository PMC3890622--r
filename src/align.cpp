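#include <Rcpp.h>
#include <vector>
#include <limits>
#include <climits>
#include <cmath>
using namespace Rcpp;

// Affine gap convention throughout: a gap of length L costs
// gap_open + L * gap_extend (opening into a new column pays both).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// Score-only local alignment (Gotoh, linear memory in the subject).
// Integer arithmetic: the bulk all-vs-all path requires an
// integer-valued scoring scheme (BLOSUM + integer gap costs).
static int sw_score_one(const int* a, int m, const int* b, int n,
                        const int* mat, int k, int go, int ge) {
  const int NI = INT_MIN / 4;
  std::vector<int> H(n + 1, 0), E(n + 1, NI);
  int best = 0;
  const int goe = go + ge;
  int* Hp = H.data();
  int* Ep = E.data();
  for (int i = 1; i <= m; ++i) {
    int diag = 0;             // H[i-1][j-1]
    int F = NI;               // gap in subject, column-wise
    const int* row = mat + (size_t)a[i - 1] * k;
    for (int j = 1; j <= n; ++j) {
      int hup = Hp[j];
      int e = Ep[j] - ge;
      int eo = hup - goe;
      e = e > eo ? e : eo;
      Ep[j] = e;
      int fo = Hp[j - 1] - goe;
      F -= ge;
      F = F > fo ? F : fo;
      int h = diag + row[b[j - 1]];
      h = h > e ? h : e;
      h = h > F ? h : F;
      h = h > 0 ? h : 0;
      diag = hup;
      Hp[j] = h;
      best = h > best ? h : best;
    }
  }
  return best;
}

static std::vector<int> int_matrix(const NumericMatrix& mat) {
  std::vector<int> m(mat.size());
  for (R_xlen_t i = 0; i < mat.size(); ++i) {
    double v = mat[i];
    if (v != std::floor(v)) stop("bulk alignment requires an integer scoring matrix");
    m[i] = (int)v;
  }
  return m;
}

// [[Rcpp::export]]
NumericVector sw_scores_all_cpp(List seqs, NumericMatrix mat,
                                double gap_open, double gap_extend) {
  int n = seqs.size();
  int k = mat.nrow();
  std::vector<std::vector<int>> enc(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = seqs[i];
    enc[i].assign(v.begin(), v.end());
  }
  R_xlen_t npair = (R_xlen_t)n * (n - 1) / 2;
  NumericVector out(npair);
  std::vector<int> mi = int_matrix(mat);
  int go = (int)gap_open, ge = (int)gap_extend;
  if (gap_open != std::floor(gap_open) || gap_extend != std::floor(gap_extend))
    stop("bulk alignment requires integer gap penalties");
  R_xlen_t idx = 0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      out[idx++] = sw_score_one(enc[i].data(), (int)enc[i].size(),
                                enc[j].data(), (int)enc[j].size(),
                                mi.data(), k, go, ge);
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
NumericVector sw_scores_pairs_cpp(List seqs, IntegerVector ia, IntegerVector ib,
                                  NumericMatrix mat, double gap_open,
                                  double gap_extend) {
  int n = seqs.size();
  int k = mat.nrow();
  std::vector<std::vector<int>> enc(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = seqs[i];
    enc[i].assign(v.begin(), v.end());
  }
  std::vector<int> mi = int_matrix(mat);
  if (gap_open != std::floor(gap_open) || gap_extend != std::floor(gap_extend))
    stop("bulk alignment requires integer gap penalties");
  int go = (int)gap_open, ge = (int)gap_extend;
  R_xlen_t np = ia.size();
  NumericVector out(np);
  for (R_xlen_t p = 0; p < np; ++p) {
    int i = ia[p] - 1, j = ib[p] - 1;
    out[p] = sw_score_one(enc[i].data(), (int)enc[i].size(),
                          enc[j].data(), (int)enc[j].size(),
                          mi.data(), k, go, ge);
  }
  return out;
}

// Full-matrix alignment with traceback. local = true: Smith-Waterman;
// false: global with penalised end gaps (needle's true global mode).
// Returns aligned index vectors (1-based residue indices, 0 = gap).
// [[Rcpp::export]]
List align_pair_cpp(IntegerVector a, IntegerVector b, NumericMatrix mat,
                    double gap_open, double gap_extend, bool local) {
  int m = a.size(), n = b.size(), k = mat.nrow();
  const double* mp = REAL(mat);
  double goe = gap_open + gap_extend;

  std::vector<double> H((size_t)(m + 1) * (n + 1), NEG_INF);
  std::vector<double> E((size_t)(m + 1) * (n + 1), NEG_INF);
  std::vector<double> F((size_t)(m + 1) * (n + 1), NEG_INF);
  // traceback codes for H: 0 stop/reset, 1 diag, 2 left-gap (E), 3 up-gap (F)
  std::vector<unsigned char> TH((size_t)(m + 1) * (n + 1), 0);
  std::vector<unsigned char> TE((size_t)(m + 1) * (n + 1), 0); // 1 open, 2 extend
  std::vector<unsigned char> TF((size_t)(m + 1) * (n + 1), 0);
  auto at = [n](int i, int j) { return (size_t)i * (n + 1) + j; };

  H[at(0, 0)] = 0.0;
  for (int j = 1; j <= n; ++j) {
    if (local) {
      H[at(0, j)] = 0.0;
    } else {
      E[at(0, j)] = -(gap_open + gap_extend * j);
      H[at(0, j)] = E[at(0, j)];
      TE[at(0, j)] = (j == 1) ? 1 : 2;
      TH[at(0, j)] = 2;
    }
  }
  for (int i = 1; i <= m; ++i) {
    if (local) {
      H[at(i, 0)] = 0.0;
    } else {
      F[at(i, 0)] = -(gap_open + gap_extend * i);
      H[at(i, 0)] = F[at(i, 0)];
      TF[at(i, 0)] = (i == 1) ? 1 : 2;
      TH[at(i, 0)] = 3;
    }
  }

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const double* row = mp + (size_t)a[i - 1] * k;
    for (int j = 1; j <= n; ++j) {
      size_t c = at(i, j);
      // E: gap in query (move left, consume b)
      double eo = H[at(i, j - 1)] - goe;
      double ee = E[at(i, j - 1)] == NEG_INF ? NEG_INF : E[at(i, j - 1)] - gap_extend;
      if (eo >= ee) { E[c] = eo; TE[c] = 1; } else { E[c] = ee; TE[c] = 2; }
      // F: gap in subject (move up, consume a)
      double fo = H[at(i - 1, j)] - goe;
      double fe = F[at(i - 1, j)] == NEG_INF ? NEG_INF : F[at(i - 1, j)] - gap_extend;
      if (fo >= fe) { F[c] = fo; TF[c] = 1; } else { F[c] = fe; TF[c] = 2; }
      // H
      double dg = H[at(i - 1, j - 1)] == NEG_INF
                    ? NEG_INF
                    : H[at(i - 1, j - 1)] + row[b[j - 1]];
      double h = dg; unsigned char t = 1;
      if (E[c] > h) { h = E[c]; t = 2; }
      if (F[c] > h) { h = F[c]; t = 3; }
      if (local && h <= 0.0) { h = 0.0; t = 0; }
      H[c] = h; TH[c] = t;
      if (local && h > best) { best = h; bi = i; bj = j; }
    }
  }

  double score;
  int ei, ej;
  if (local) {
    score = best; ei = bi; ej = bj;
  } else {
    score = H[at(m, n)]; ei = m; ej = n;
  }

  std::vector<int> ai, bi_idx;
  int i = ei, j = ej;
  int state = 0; // 0 = H
  if (local && score <= 0.0) { i = 0; j = 0; }
  while (i > 0 || j > 0) {
    size_t c = at(i, j);
    if (state == 0) {
      unsigned char t = TH[c];
      if (t == 0) break; // local stop
      if (t == 1) {
        ai.push_back(i); bi_idx.push_back(j);
        --i; --j;
      } else if (t == 2) {
        state = 2;
      } else {
        state = 3;
      }
    } else if (state == 2) { // in E: gap in query, consume b
      ai.push_back(0); bi_idx.push_back(j);
      unsigned char t = TE[c];
      --j;
      if (t == 1) state = 0;
    } else { // in F: gap in subject, consume a
      ai.push_back(i); bi_idx.push_back(0);
      unsigned char t = TF[c];
      --i;
      if (t == 1) state = 0;
    }
    if (local && i == 0 && j == 0) break;
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi_idx.begin(), bi_idx.end());

  int qs = 0, qe = 0, ss = 0, se = 0;
  for (size_t p = 0; p < ai.size(); ++p) {
    if (ai[p] > 0) { if (qs == 0) qs = ai[p]; qe = ai[p]; }
    if (bi_idx[p] > 0) { if (ss == 0) ss = bi_idx[p]; se = bi_idx[p]; }
  }

  return List::create(_["score"] = score,
                      _["a_idx"] = IntegerVector(ai.begin(), ai.end()),
                      _["b_idx"] = IntegerVector(bi_idx.begin(), bi_idx.end()),
                      _["q_start"] = qs, _["q_end"] = qe,
                      _["s_start"] = ss, _["s_end"] = se);
}
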