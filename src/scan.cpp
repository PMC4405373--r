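#include <Rcpp.h>
#include <map>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Shared conventions for the structural scanners.
//
// Sequences are encoded A=0, C=1, G=2, T=3, N=4.  N never matches any
// residue, in direct-repeat (TSD) comparisons or in inverted-repeat
// (TIR) comparisons.  Complement pairs are exactly those whose codes
// sum to 3, which excludes N for free.
//
// A candidate is an element body [b, e) (0-based half-open, TSD
// excluded) such that
//   * some t in [tsd_min, tsd_max] gives identical flanking direct
//     repeats s[b-t, b) == s[e, e+t) (the TSD); the recorded TSD is
//     the longest such t;
//   * the body termini form an inverted repeat: the recorded TIR
//     length is the largest L in [tir_min, min(tir_max, (e-b)/2)]
//     such that the outermost and innermost aligned pairs are
//     Watson-Crick matches and the Hamming distance between
//     s[b, b+L) and the reverse complement of s[e-L, e) is
//     <= max_mm.  Requiring matched ends makes the recorded repeat a
//     maximal approximate inverted repeat rather than one padded by
//     terminal mismatches;
//   * 2*tir_min <= e - b < max_len.

static std::vector<int> encode(const std::string &s) {
  std::vector<int> x(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    switch (s[i]) {
    case 'A': x[i] = 0; break;
    case 'C': x[i] = 1; break;
    case 'G': x[i] = 2; break;
    case 'T': x[i] = 3; break;
    default:  x[i] = 4; break;
    }
  }
  return x;
}

static inline bool base_eq(int a, int b) { return a == b && a != 4; }

// Longest TIR at body [b, e): see the candidate definition above.
// Returns the length (0 if below tir_min) and writes the mismatch
// count at that length.
static int tir_at(const std::vector<int> &s, int b, int e,
                  int tir_min, int tir_max, int max_mm, int *mm_out) {
  int w = e - b;
  int lmax = std::min(tir_max, w / 2);
  int mm = 0, best = 0, best_mm = 0;
  for (int L = 1; L <= lmax; ++L) {
    bool pair = (s[b + L - 1] + s[e - L] == 3); // Watson-Crick, N excluded
    if (L == 1 && !pair) return 0;              // outermost pair must match
    if (!pair) {
      if (mm + 1 > max_mm) break;
      ++mm;
    } else {
      best = L;        // recorded length always ends on a match
      best_mm = mm;
    }
  }
  if (best < tir_min) return 0;
  *mm_out = best_mm;
  return best;
}

// Longest identical flanking direct repeat for body [b, e), scanning
// t downward so the first hit is maximal.  0 when none exists.
static int max_tsd_at(const std::vector<int> &s, int n, int b, int e,
                      int tsd_min, int tsd_max) {
  int tcap = std::min(tsd_max, std::min(b, n - e));
  for (int t = tcap; t >= tsd_min; --t) {
    bool ok = true;
    for (int j = 0; j < t; ++j) {
      if (!base_eq(s[b - t + j], s[e + j])) { ok = false; break; }
    }
    if (ok) return t;
  }
  return 0;
}

// Direct-repeat-first scanner.  For each start distance g between the
// two TSD copies it computes, in one pass, the length of the equality
// run starting at every position; every run of length >= tsd_min
// spawns (i, g, t) triples whose implied body is then tested for a
// TIR.  A body reachable through several TSD lengths is emitted once,
// at its maximal TSD.
// [[Rcpp::export]]
List scan_core_cpp(std::string seq, int tir_min, int tir_max,
                   int tsd_min, int tsd_max, int max_len, int max_mm) {
  std::vector<int> s = encode(seq);
  int n = (int)s.size();
  std::vector<int> vb, ve, vt, vl, vm;
  if (n == 0)
    return List::create(_["start"] = vb, _["end"] = ve, _["tsd_len"] = vt,
                        _["tir_len"] = vl, _["tir_mm"] = vm);
  int gmin = tsd_min + 2 * tir_min;
  int gmax = std::min(n - tsd_min, tsd_max + max_len - 1);
  std::vector<int> run(n, 0);
  for (int g = gmin; g <= gmax; ++g) {
    int last = n - g - 1; // last i with s[i + g] defined
    if (last < 0) break;
    for (int i = last; i >= 0; --i) {
      if (base_eq(s[i], s[i + g]))
        run[i] = (i == last) ? 1 : run[i + 1] + 1;
      else
        run[i] = 0;
    }
    for (int i = 0; i <= last; ++i) {
      int r = run[i];
      if (r < tsd_min) continue;
      int tcap = std::min(tsd_max, r);
      for (int t = tsd_min; t <= tcap; ++t) {
        int w = g - t;
        if (w < 2 * tir_min || w >= max_len) continue;
        int b = i + t, e = i + g;
        int mm = 0;
        int L = tir_at(s, b, e, tir_min, tir_max, max_mm, &mm);
        if (L == 0) continue;
        if (max_tsd_at(s, n, b, e, tsd_min, tsd_max) != t) continue;
        vb.push_back(b); ve.push_back(e); vt.push_back(t);
        vl.push_back(L); vm.push_back(mm);
      }
    }
  }
  return List::create(_["start"] = vb, _["end"] = ve, _["tsd_len"] = vt,
                      _["tir_len"] = vl, _["tir_mm"] = vm);
}

// ---------------------------------------------------------------------------
// Reference enumeration used as the independent oracle in the test
// suite.  It re-implements the candidate definition directly on the
// character sequence (no integer encoding, no run-length machinery)
// and shares no helper with the scanner above.

static inline char complement_of(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'T': return 'A';
  case 'C': return 'G';
  case 'G': return 'C';
  default:  return 'X'; // N and anything else match nothing
  }
}

// Mismatch profile of the aligned inverted-repeat positions (a match
// flag and a cumulative mismatch count per length), then a direct
// search for the longest length with matched ends and a mismatch
// total within budget.
static int naive_tir(const std::string &s, int b, int e,
                     int tir_min, int tir_max, int max_mm, int *mm_out,
                     std::vector<char> &is_match, std::vector<int> &mm_pre) {
  int lmax = std::min(tir_max, (e - b) / 2);
  if ((int)is_match.size() < lmax + 1) {
    is_match.resize(lmax + 1);
    mm_pre.resize(lmax + 1);
  }
  mm_pre[0] = 0;
  for (int L = 1; L <= lmax; ++L) {
    char left = s[b + L - 1];
    char right = s[e - L];
    is_match[L] = (left != 'N' && left == complement_of(right)) ? 1 : 0;
    mm_pre[L] = mm_pre[L - 1] + (is_match[L] ? 0 : 1);
  }
  for (int L = lmax; L >= tir_min; --L) {
    if (is_match[1] && is_match[L] && mm_pre[L] <= max_mm) {
      *mm_out = mm_pre[L];
      return L;
    }
  }
  *mm_out = 0;
  return 0;
}

static int naive_tsd(const std::string &s, int b, int e,
                     int tsd_min, int tsd_max) {
  int n = (int)s.size();
  for (int t = std::min({tsd_max, b, n - e}); t >= tsd_min; --t) {
    bool ok = true;
    for (int j = 0; j < t; ++j) {
      char left = s[b - t + j];
      if (left == 'N' || left != s[e + j]) { ok = false; break; }
    }
    if (ok) return t;
  }
  return 0;
}

// [[Rcpp::export]]
List scan_naive_cpp(std::string seq, int tir_min, int tir_max,
                    int tsd_min, int tsd_max, int max_len, int max_mm) {
  int n = (int)seq.size();
  std::vector<int> vb, ve, vt, vl, vm;
  std::vector<char> is_match;
  std::vector<int> mm_pre;
  for (int b = tsd_min; b < n; ++b) {
    int emax = std::min(n - tsd_min, b + max_len - 1);
    for (int e = b + 2 * tir_min; e <= emax; ++e) {
      int t = naive_tsd(seq, b, e, tsd_min, tsd_max);
      if (t == 0) continue;
      int mm = 0;
      int L = naive_tir(seq, b, e, tir_min, tir_max, max_mm, &mm,
                        is_match, mm_pre);
      if (L < tir_min) continue;
      vb.push_back(b); ve.push_back(e); vt.push_back(t);
      vl.push_back(L); vm.push_back(mm);
    }
  }
  return List::create(_["start"] = vb, _["end"] = ve, _["tsd_len"] = vt,
                      _["tir_len"] = vl, _["tir_mm"] = vm);
}

// Greedy overlap resolution.  Candidates are ranked by longer TIR,
// then fewer TIR mismatches, then longer TSD, then leftmost; a
// candidate is kept unless it shares more than half of the shorter
// span with an already kept candidate.
// [[Rcpp::export]]
LogicalVector resolve_overlaps_cpp(IntegerVector start, IntegerVector end,
                                   IntegerVector tsd_len, IntegerVector tir_len,
                                   IntegerVector tir_mm, int max_len) {
  int n = start.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (tir_len[a] != tir_len[b]) return tir_len[a] > tir_len[b];
    if (tir_mm[a] != tir_mm[b]) return tir_mm[a] < tir_mm[b];
    if (tsd_len[a] != tsd_len[b]) return tsd_len[a] > tsd_len[b];
    if (start[a] != start[b]) return start[a] < start[b];
    return end[a] < end[b];
  });
  LogicalVector keep(n, false);
  std::map<int, int> kept; // start -> end
  for (int k = 0; k < n; ++k) {
    int i = ord[k];
    int b = start[i], e = end[i], w = e - b;
    bool ok = true;
    auto it = kept.lower_bound(b - max_len);
    for (; it != kept.end() && it->first < e; ++it) {
      int kb = it->first, ke = it->second;
      int ov = std::min(e, ke) - std::max(b, kb);
      if (ov > 0 && 2 * ov > std::min(w, ke - kb)) { ok = false; break; }
    }
    if (ok) {
      keep[i] = true;
      kept[b] = e;
    }
  }
  return keep;
}
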