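#include <Rcpp.h>
using namespace Rcpp;

// Ungapped end-to-end alignment of short reads against consensus
// sequences, every offset, both strands.  N never matches.  All hits
// with at most max_mm mismatches are returned; restriction to
// equal-best loci per read happens at the R level.

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) {
    switch (c) {
    case 'A': c = 'T'; break;
    case 'C': c = 'G'; break;
    case 'G': c = 'C'; break;
    case 'T': c = 'A'; break;
    default:  c = 'N'; break;
    }
  }
  return r;
}

static inline bool match(char a, char b) {
  return a == b && a != 'N';
}

// [[Rcpp::export]]
List map_reads_cpp(CharacterVector reads, CharacterVector consensi,
                   int max_mm) {
  std::vector<int> ri, ci, pos, mm_out;
  std::vector<int> strand; // 1 = sense, -1 = antisense
  int nc = consensi.size();
  std::vector<std::string> cons(nc);
  for (int j = 0; j < nc; ++j) cons[j] = as<std::string>(consensi[j]);
  for (int i = 0; i < reads.size(); ++i) {
    std::string fwd = as<std::string>(reads[i]);
    std::string rev = revcomp(fwd);
    int len = (int)fwd.size();
    for (int str = 0; str < 2; ++str) {
      const std::string &rd = (str == 0) ? fwd : rev;
      for (int j = 0; j < nc; ++j) {
        const std::string &cs = cons[j];
        int lastp = (int)cs.size() - len;
        for (int p = 0; p <= lastp; ++p) {
          int mm = 0;
          for (int k = 0; k < len; ++k) {
            if (!match(rd[k], cs[p + k])) {
              if (++mm > max_mm) break;
            }
          }
          if (mm <= max_mm) {
            ri.push_back(i + 1);
            ci.push_back(j + 1);
            pos.push_back(p);
            strand.push_back(str == 0 ? 1 : -1);
            mm_out.push_back(mm);
          }
        }
      }
    }
  }
  return List::create(_["read"] = ri, _["consensus"] = ci, _["pos"] = pos,
                      _["strand"] = strand, _["mm"] = mm_out);
}
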