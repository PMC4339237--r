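#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Exhaustive k-mismatch scanning primitives for the toy mapper.
// Coordinates returned are 1-based inclusive, forward strand of `subject`.
// Orientation (read vs reverse complement) is handled by the R caller.

// All contiguous placements of each read in `subject` with <= max_mm
// substitutions. Early exit once the mismatch budget is blown keeps the
// expected cost per position O(1) on random sequence.
// [[Rcpp::export(name = ".cpp_scan_contiguous")]]
DataFrame cpp_scan_contiguous(std::string subject, CharacterVector reads,
                              int max_mm) {
  const int n = subject.size();
  const char *sp = subject.c_str();
  std::vector<int> out_read, out_pos, out_mm;
  for (int r = 0; r < reads.size(); ++r) {
    const char *rd = CHAR(STRING_ELT(reads, r));
    const int L = LENGTH(STRING_ELT(reads, r));
    if (L == 0 || L > n) continue;
    for (int i = 0; i + L <= n; ++i) {
      const char *s = sp + i;
      int mm = 0, k = 0;
      for (; k < L; ++k) {
        if (rd[k] != s[k] && ++mm > max_mm) break;
      }
      if (k == L && mm <= max_mm) {
        out_read.push_back(r + 1);
        out_pos.push_back(i + 1);
        out_mm.push_back(mm);
      }
    }
  }
  return DataFrame::create(_["read"] = out_read, _["pos"] = out_pos,
                           _["mm"] = out_mm);
}

// All two-segment spliced placements: read split into a prefix of length s
// and suffix of length L - s (both >= min_anchor), placed colinearly on the
// forward strand with a gap (intron) in [min_intron, max_intron], total
// substitutions <= max_mm. Prefix/suffix candidate lists stay tiny on random
// sequence because the mismatch budget is exhausted within a few bases.
// [[Rcpp::export(name = ".cpp_scan_spliced")]]
DataFrame cpp_scan_spliced(std::string subject, CharacterVector reads,
                           int max_mm, int min_anchor, int min_intron,
                           int max_intron) {
  const int n = subject.size();
  std::vector<int> out_read, out_pos1, out_len1, out_pos2, out_len2, out_mm;
  for (int r = 0; r < reads.size(); ++r) {
    const char *rd = CHAR(STRING_ELT(reads, r));
    const int L = LENGTH(STRING_ELT(reads, r));
    if (L < 2 * min_anchor || min_anchor > n) continue;

    // prefix hits: (start i, length s, mm), min_anchor <= s <= L - min_anchor
    std::vector<std::array<int, 3>> pref;
    const int smax = L - min_anchor;
    for (int i = 0; i < n; ++i) {
      int mm = 0;
      const int lim = std::min(smax, n - i);
      for (int k = 0; k < lim; ++k) {
        if (rd[k] != subject[i + k] && ++mm > max_mm) break;
        if (k + 1 >= min_anchor) pref.push_back({i, k + 1, mm});
      }
    }
    // suffix hits keyed by length t: (start j, mm); scanned by genome end e
    std::unordered_map<int, std::vector<std::pair<int, int>>> suf;
    for (int e = min_anchor - 1; e < n; ++e) {
      int mm = 0;
      const int tlim = std::min(smax, e + 1);
      for (int t = 1; t <= tlim; ++t) {
        if (rd[L - t] != subject[e - t + 1] && ++mm > max_mm) break;
        if (t >= min_anchor) suf[t].push_back({e - t + 1, mm});
      }
    }
    for (auto &p : pref) {
      const int i = p[0], s = p[1], mm1 = p[2], t = L - s;
      auto it = suf.find(t);
      if (it == suf.end()) continue;
      const int jlo = i + s + min_intron, jhi = i + s + max_intron;
      for (auto &q : it->second) {
        if (q.first < jlo || q.first > jhi) continue;
        if (mm1 + q.second > max_mm) continue;
        out_read.push_back(r + 1);
        out_pos1.push_back(i + 1);
        out_len1.push_back(s);
        out_pos2.push_back(q.first + 1);
        out_len2.push_back(t);
        out_mm.push_back(mm1 + q.second);
      }
    }
  }
  return DataFrame::create(_["read"] = out_read, _["pos1"] = out_pos1,
                           _["len1"] = out_len1, _["pos2"] = out_pos2,
                           _["len2"] = out_len2, _["mm"] = out_mm);
}

// Hamming distance helper used when rescoring candidate placements.
// [[Rcpp::export(name = ".cpp_hamming")]]
IntegerVector cpp_hamming(CharacterVector a, CharacterVector b) {
  const int n = a.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char *x = CHAR(STRING_ELT(a, i));
    const char *y = CHAR(STRING_ELT(b, i));
    int la = LENGTH(STRING_ELT(a, i));
    if (la != LENGTH(STRING_ELT(b, i)))
      stop("hamming: unequal lengths at element %d", i + 1);
    int mm = 0;
    for (int k = 0; k < la; ++k) mm += (x[k] != y[k]);
    out[i] = mm;
  }
  return out;
}
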