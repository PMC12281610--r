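#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

static inline bool base_ok2(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

static inline int ham_policy(const char *a, const char *b, int L, int budget) {
  int mm = 0;
  for (int k = 0; k < L; ++k) {
    char x = a[k], y = b[k];
    if (x != y || !base_ok2(x) || !base_ok2(y)) {
      if (++mm > budget) return mm;
    }
  }
  return mm;
}

// Greedy single-linkage collapse of spacer sequences already sorted by the
// caller (descending multiplicity, ties lexicographic). Each sequence joins
// the earliest retained representative of identical length within Hamming
// distance max_h, else founds a new cluster. Candidate representatives are
// located through (max_h + 1) disjoint piece hashes: any pair within the
// budget shares at least one literally identical piece (an ambiguous base
// counts as a mismatch, so a policy-clean piece is N-free and hashable).
// Returns, for each input sequence, the 1-based index of its representative.
// [[Rcpp::export]]
IntegerVector dedup_greedy_cpp(CharacterVector seqs, int max_h) {
  const int n = seqs.size();
  const int P = max_h + 1;
  IntegerVector repidx(n);
  std::unordered_map<std::string, std::vector<int>> pieces;
  pieces.reserve(n * P * 2);
  for (int i = 0; i < n; ++i) {
    SEXP el = STRING_ELT(seqs, i);
    const char *s = CHAR(el);
    const int L = LENGTH(el);
    int best = -1;
    std::vector<std::string> keys(P);
    for (int p = 0; p < P; ++p) {
      int a = (int)((long long)p * L / P);
      int b = (int)((long long)(p + 1) * L / P);
      keys[p] = std::to_string(L) + ":" + std::to_string(p) + ":" +
                std::string(s + a, s + b);
      auto it = pieces.find(keys[p]);
      if (it == pieces.end()) continue;
      for (int cand : it->second) {
        if (best >= 0 && cand >= best) continue;
        SEXP cel = STRING_ELT(seqs, cand);
        if (LENGTH(cel) != L) continue;
        if (ham_policy(s, CHAR(cel), L, max_h) <= max_h)
          best = (best < 0) ? cand : std::min(best, cand);
      }
    }
    if (best >= 0) {
      repidx[i] = best + 1;
    } else {
      repidx[i] = i + 1;
      for (int p = 0; p < P; ++p) pieces[keys[p]].push_back(i);
    }
  }
  return repidx;
}
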