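#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Batched global alignment with free end gaps (Gotoh affine-gap
// dynamic programming).  Scoring: +match / -mismatch on residues,
// N matches nothing; a gap of length k costs gap_open + k * gap_ext
// (so gap_open = 0 gives linear gaps).  End gaps are free on both
// sequences.  For every aligned pair the routine reports the score,
// identity over aligned columns (terminal overhangs excluded),
// coverage of the shorter sequence, and the substitution spectrum
// used by distance estimation: transition / transversion counts over
// comparable (gap- and N-free) columns.
//
// band <= 0 computes the full dynamic-programming matrix; band > 0
// restricts cells to a corridor of that width around the diagonal,
// widened by the length difference so end gaps stay reachable --
// exact for sequences without long indels, and much faster.  The
// three matrices are scratch buffers shared across a batch; per pair
// only the borders, the corridor and its one-cell guards are
// (re)initialised, keeping banded alignment O(length * band).

static const double NEG = -1e18;

struct AlnStats {
  double score;
  int columns, matches, mismatches, gapcols;
  int transitions, transversions, comparable;
  int span_p, span_s; // residues of pattern / subject inside the alignment
  int p_off, s_off;   // residues preceding the aligned region
  std::string a_aln, b_aln;
};

static inline bool is_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

static inline bool is_transition(char x, char y) {
  return (x == 'A' && y == 'G') || (x == 'G' && y == 'A') ||
         (x == 'C' && y == 'T') || (x == 'T' && y == 'C');
}

static AlnStats align_one(const std::string &a, const std::string &b,
                          double match, double mismatch,
                          double gap_open, double gap_ext,
                          bool want_strings, int band,
                          std::vector<double> &H, std::vector<double> &E,
                          std::vector<double> &F) {
  int m = (int)a.size(), n = (int)b.size();
  // H: best ending in match/mismatch or anything; E: gap in a
  // (consumes b); F: gap in b (consumes a)
  size_t need = (size_t)(m + 1) * (n + 1);
  if (H.size() < need) {
    H.resize(need);
    E.resize(need);
    F.resize(need);
  }
  auto at = [n](int i, int j) { return (size_t)i * (n + 1) + j; };
  int lo_off = band > 0 ? band + std::max(0, m - n) : m + n;
  int hi_off = band > 0 ? band + std::max(0, n - m) : m + n;
  auto jlo_of = [&](int i) { return std::max(1, i - lo_off); };
  auto jhi_of = [&](int i) { return std::min(n, i + hi_off); };
  for (int j = 0; j <= n; ++j) { // free leading gap in a
    H[at(0, j)] = 0;
    E[at(0, j)] = NEG;
    F[at(0, j)] = NEG;
  }
  for (int i = 0; i <= m; ++i) { // free leading gap in b
    H[at(i, 0)] = 0;
    E[at(i, 0)] = NEG;
    F[at(i, 0)] = NEG;
  }
  for (int i = 1; i <= m; ++i) {
    int jlo = jlo_of(i), jhi = jhi_of(i);
    if (jlo > 1) { // guard cell left of the corridor
      H[at(i, jlo - 1)] = NEG;
      E[at(i, jlo - 1)] = NEG;
      F[at(i, jlo - 1)] = NEG;
    }
    if (jhi < n) { // guard cell right of the corridor
      H[at(i, jhi + 1)] = NEG;
      E[at(i, jhi + 1)] = NEG;
      F[at(i, jhi + 1)] = NEG;
    }
    for (int j = jlo; j <= jhi; ++j) {
      double e = std::max(H[at(i, j - 1)] - gap_open - gap_ext,
                          E[at(i, j - 1)] - gap_ext);
      double f = std::max(H[at(i - 1, j)] - gap_open - gap_ext,
                          F[at(i - 1, j)] - gap_ext);
      bool eq = a[i - 1] == b[j - 1] && a[i - 1] != 'N';
      double diag = H[at(i - 1, j - 1)] + (eq ? match : -mismatch);
      E[at(i, j)] = e;
      F[at(i, j)] = f;
      H[at(i, j)] = std::max(diag, std::max(e, f));
    }
  }
  // free trailing gaps: best cell on the last row or column, looking
  // only at cells inside the corridor (or its borders/guards)
  int bi = m, bj = 0;
  double best = H[at(m, 0)];
  for (int j = std::max(0, jlo_of(m) - 1);
       j <= std::min(n, jhi_of(m) + 1); ++j)
    if (H[at(m, j)] > best) { best = H[at(m, j)]; bi = m; bj = j; }
  for (int i = 0; i <= m; ++i) {
    if (i > 0 && jhi_of(i) < n) continue; // (i, n) outside corridor
    if (H[at(i, n)] > best) { best = H[at(i, n)]; bi = i; bj = n; }
  }

  AlnStats st;
  st.score = best;
  st.columns = st.matches = st.mismatches = st.gapcols = 0;
  st.transitions = st.transversions = st.comparable = 0;
  st.span_p = st.span_s = 0;

  // traceback from (bi, bj) to the first row/column
  std::string ra, rb;
  int i = bi, j = bj;
  char state = 'H';
  while (i > 0 && j > 0) {
    if (state == 'H') {
      bool eq = a[i - 1] == b[j - 1] && a[i - 1] != 'N';
      double diag = H[at(i - 1, j - 1)] + (eq ? match : -mismatch);
      if (H[at(i, j)] == diag) {
        if (want_strings) { ra += a[i - 1]; rb += b[j - 1]; }
        char x = a[i - 1], y = b[j - 1];
        ++st.columns; ++st.span_p; ++st.span_s;
        if (eq) ++st.matches; else ++st.mismatches;
        if (is_base(x) && is_base(y)) {
          ++st.comparable;
          if (x != y) {
            if (is_transition(x, y)) ++st.transitions;
            else ++st.transversions;
          }
        }
        --i; --j;
      } else if (H[at(i, j)] == E[at(i, j)]) {
        state = 'E';
      } else {
        state = 'F';
      }
    } else if (state == 'E') { // gap in a, consume b[j-1]
      if (want_strings) { ra += '-'; rb += b[j - 1]; }
      ++st.columns; ++st.gapcols; ++st.span_s;
      if (E[at(i, j)] != E[at(i, j - 1)] - gap_ext) state = 'H';
      --j;
    } else { // gap in b, consume a[i-1]
      if (want_strings) { ra += a[i - 1]; rb += '-'; }
      ++st.columns; ++st.gapcols; ++st.span_p;
      if (F[at(i, j)] != F[at(i - 1, j)] - gap_ext) state = 'H';
      --i;
    }
  }
  st.p_off = i; // leading residues outside the aligned region
  st.s_off = j;
  if (want_strings) {
    std::reverse(ra.begin(), ra.end());
    std::reverse(rb.begin(), rb.end());
    st.a_aln = ra;
    st.b_aln = rb;
  }
  return st;
}

// [[Rcpp::export]]
List align_pairs_cpp(CharacterVector seqs, IntegerVector i_idx,
                     IntegerVector j_idx, double match, double mismatch,
                     double gap_open, double gap_ext,
                     bool want_strings, int band) {
  int np = i_idx.size();
  std::vector<std::string> sv(seqs.size());
  for (int k = 0; k < seqs.size(); ++k) sv[k] = as<std::string>(seqs[k]);
  NumericVector score(np), identity(np), coverage(np);
  IntegerVector comparable(np), transitions(np), transversions(np),
      columns(np), span_p(np), span_s(np);
  CharacterVector a_aln(np), b_aln(np);
  IntegerVector p_off(np), s_off(np);
  std::vector<double> H, E, F; // scratch, shared across the batch
  for (int k = 0; k < np; ++k) {
    const std::string &a = sv[i_idx[k] - 1];
    const std::string &b = sv[j_idx[k] - 1];
    AlnStats st = align_one(a, b, match, mismatch, gap_open, gap_ext,
                            want_strings, band, H, E, F);
    score[k] = st.score;
    identity[k] = st.columns > 0 ? (double)st.matches / st.columns : 0.0;
    int short_len = std::min((int)a.size(), (int)b.size());
    int short_span = a.size() <= b.size() ? st.span_p : st.span_s;
    coverage[k] = short_len > 0 ? (double)short_span / short_len : 0.0;
    comparable[k] = st.comparable;
    transitions[k] = st.transitions;
    transversions[k] = st.transversions;
    columns[k] = st.columns;
    span_p[k] = st.span_p;
    span_s[k] = st.span_s;
    p_off[k] = st.p_off;
    s_off[k] = st.s_off;
    if (want_strings) {
      a_aln[k] = st.a_aln;
      b_aln[k] = st.b_aln;
    }
  }
  List out = List::create(
      _["score"] = score, _["identity"] = identity,
      _["coverage"] = coverage, _["columns"] = columns,
      _["comparable"] = comparable, _["transitions"] = transitions,
      _["transversions"] = transversions,
      _["span_p"] = span_p, _["span_s"] = span_s,
      _["p_off"] = p_off, _["s_off"] = s_off);
  if (want_strings) {
    out["a_aln"] = a_aln;
    out["b_aln"] = b_aln;
  }
  return out;
}
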