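#include <Rcpp.h>
using namespace Rcpp;

static inline bool base_ok(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// Hamming count of pat against s[offset..]; an ambiguous base (anything
// outside ACGT) mismatches everything, including itself. Early exit once
// the budget is blown.
static inline int mm_at(const char *s, int offset, const std::string &pat,
                        int budget) {
  int mm = 0;
  for (size_t k = 0; k < pat.size(); ++k) {
    char c = s[offset + k];
    if (c != pat[k] || !base_ok(c)) {
      if (++mm > budget) return mm;
    }
  }
  return mm;
}

// Left-to-right non-overlapping cassette scan. A DR1 site is any offset
// within the mm budget; for each DR1 site the winning DR2 candidate
// minimises mm_dr2 (mm_dr1 is fixed), ties resolved towards the shorter
// spacer / smaller offset by scanning j upwards and only accepting strict
// improvements. After a cassette is emitted the scan resumes past its DR2;
// a DR1 site with no DR2 resumes one base further.
// [[Rcpp::export]]
DataFrame scan_cassettes_cpp(CharacterVector reads, std::string dr1,
                             std::string dr2, int max_mm1, int max_mm2,
                             bool restricted, int len_min, int len_max) {
  const int L1 = dr1.size(), L2 = dr2.size();
  std::vector<int> rid, d1, d2, m1v, m2v, cidx;
  for (int r = 0; r < reads.size(); ++r) {
    SEXP el = STRING_ELT(reads, r);
    const char *s = CHAR(el);
    const int L = LENGTH(el);
    int ci = 0, i = 0;
    while (i + L1 + 1 + L2 <= L) {
      int mm1 = mm_at(s, i, dr1, max_mm1);
      if (mm1 <= max_mm1) {
        int jlo = i + L1 + (restricted ? len_min : 1);
        int jhi = restricted ? i + L1 + len_max : L - L2;
        if (jhi > L - L2) jhi = L - L2;
        int best_j = -1, best_m2 = max_mm2 + 1;
        for (int j = jlo; j <= jhi; ++j) {
          int mm2 = mm_at(s, j, dr2, best_m2 - 1);
          if (mm2 < best_m2) {
            best_m2 = mm2;
            best_j = j;
            if (mm2 == 0) break;
          }
        }
        if (best_j >= 0) {
          rid.push_back(r + 1);
          d1.push_back(i + 1);
          d2.push_back(best_j + 1);
          m1v.push_back(mm1);
          m2v.push_back(best_m2);
          cidx.push_back(++ci);
          i = best_j + L2;
          continue;
        }
      }
      ++i;
    }
  }
  return DataFrame::create(
      _["read"] = rid, _["dr1_start"] = d1, _["dr2_start"] = d2,
      _["mm_dr1"] = m1v, _["mm_dr2"] = m2v, _["cassette_index"] = cidx,
      _["stringsAsFactors"] = false);
}

// Pairwise Hamming with the package N-policy; -1 signals unequal lengths.
// [[Rcpp::export]]
int hamming_cpp(std::string a, std::string b) {
  if (a.size() != b.size()) return -1;
  int mm = 0;
  for (size_t k = 0; k < a.size(); ++k) {
    char x = a[k], y = b[k];
    if (x != y || !base_ok(x) || !base_ok(y)) ++mm;
  }
  return mm;
}
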