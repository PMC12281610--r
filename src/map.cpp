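#include <Rcpp.h>
#include <map>
#include <unordered_map>
#include <unordered_set>
using namespace Rcpp;

static inline bool base_ok3(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

static inline int ham_pol(const char *a, const char *b, int L, int budget) {
  int mm = 0;
  for (int k = 0; k < L; ++k) {
    char x = a[k], y = b[k];
    if (x != y || !base_ok3(x) || !base_ok3(y)) {
      if (++mm > budget) return mm;
    }
  }
  return mm;
}

static inline int code2(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) {
    switch (c) {
      case 'A': c = 'T'; break;
      case 'C': c = 'G'; break;
      case 'G': c = 'C'; break;
      case 'T': c = 'A'; break;
      default: c = 'N';
    }
  }
  return r;
}

typedef std::unordered_map<uint64_t, std::vector<int64_t>> KmerIndex;

// positions are encoded contig*2^40 + offset (0-based, forward strand)
static void build_index(const std::vector<std::string> &refs, int k,
                        KmerIndex &idx) {
  for (size_t c = 0; c < refs.size(); ++c) {
    const std::string &r = refs[c];
    if ((int)r.size() < k) continue;
    for (size_t p = 0; p + k <= r.size(); ++p) {
      uint64_t code = 0;
      bool ok = true;
      for (int t = 0; t < k; ++t) {
        int b = code2(r[p + t]);
        if (b < 0) { ok = false; break; }
        code = (code << 2) | (uint64_t)b;
      }
      if (ok) idx[code].push_back(((int64_t)c << 40) | (int64_t)p);
    }
  }
}

struct Hit {
  int query, ref, start, mm;
  char strand;
};

static void scan_query(const std::string &q, int qi, char strand,
                       const std::vector<std::string> &refs, int max_mm,
                       std::map<int, KmerIndex> &indices,
                       std::vector<Hit> &out) {
  const int L = q.size();
  const int P = max_mm + 1;
  const int plen = L / P;
  const int k = std::min(12, plen);
  if (k >= 8) {
    auto iit = indices.find(k);
    if (iit == indices.end()) {
      build_index(refs, k, indices[k]);
      iit = indices.find(k);
    }
    KmerIndex &idx = iit->second;
    std::unordered_set<int64_t> seen;
    for (int p = 0; p < P; ++p) {
      int a = p * plen;  // seed = first k bases of piece p
      uint64_t code = 0;
      bool ok = true;
      for (int t = 0; t < k; ++t) {
        int b = code2(q[a + t]);
        if (b < 0) { ok = false; break; }
        code = (code << 2) | (uint64_t)b;
      }
      if (!ok) continue;
      auto hit = idx.find(code);
      if (hit == idx.end()) continue;
      for (int64_t packed : hit->second) {
        int c = (int)(packed >> 40);
        int64_t pos = packed & ((1LL << 40) - 1);
        int64_t start = pos - a;
        if (start < 0 || start + L > (int64_t)refs[c].size()) continue;
        int64_t key = ((int64_t)c << 40) | start;
        if (!seen.insert(key).second) continue;
        int mm = ham_pol(q.c_str(), refs[c].c_str() + start, L, max_mm);
        if (mm <= max_mm)
          out.push_back({qi, c, (int)start, mm, strand});
      }
    }
  } else {
    for (size_t c = 0; c < refs.size(); ++c) {
      const std::string &r = refs[c];
      if ((int)r.size() < L) continue;
      for (size_t s = 0; s + L <= r.size(); ++s) {
        int mm = ham_pol(q.c_str(), r.c_str() + s, L, max_mm);
        if (mm <= max_mm) out.push_back({qi, (int)c, (int)s, mm, strand});
      }
    }
  }
}

// All placements of every query (and its reverse complement) on the forward
// reference sequences with at most max_mm mismatches. A minus-strand hit is
// reported at the forward coordinates of the matched substring. Seeds follow
// the pigeonhole rule: max_mm + 1 disjoint pieces, any within-budget
// placement leaves one piece exact; queries too short to carry >= 8 nt
// seeds are full-scanned.
// [[Rcpp::export]]
DataFrame map_all_hits_cpp(CharacterVector queries, CharacterVector refseqs,
                           int max_mm) {
  std::vector<std::string> refs(refseqs.size());
  for (int i = 0; i < refseqs.size(); ++i)
    refs[i] = as<std::string>(refseqs[i]);
  std::map<int, KmerIndex> indices;
  std::vector<Hit> hits;
  for (int qi = 0; qi < queries.size(); ++qi) {
    std::string q = as<std::string>(queries[qi]);
    scan_query(q, qi, '+', refs, max_mm, indices, hits);
    scan_query(revcomp(q), qi, '-', refs, max_mm, indices, hits);
  }
  const int n = hits.size();
  IntegerVector query(n), ref(n), start(n), mm(n);
  CharacterVector strand(n);
  for (int i = 0; i < n; ++i) {
    query[i] = hits[i].query + 1;
    ref[i] = hits[i].ref + 1;
    start[i] = hits[i].start + 1;
    mm[i] = hits[i].mm;
    strand[i] = std::string(1, hits[i].strand);
  }
  return DataFrame::create(_["query"] = query, _["ref"] = ref,
                           _["start"] = start, _["strand"] = strand,
                           _["mm"] = mm, _["stringsAsFactors"] = false);
}
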