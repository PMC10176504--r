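#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <unordered_set>
#include <string>
using namespace Rcpp;

// 2-bit base codes; anything outside ACGT (upper case) is invalid and
// breaks the current k-mer window.
static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

static std::string decode_kmer(uint64_t code, int k) {
  static const char bases[] = "ACGT";
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = bases[code & 3ULL];
    code >>= 2;
  }
  return s;
}

static inline uint64_t revcomp_code(uint64_t code, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3ULL - (code & 3ULL));
    code >>= 2;
  }
  return rc;
}

// Rolling scan of one sequence; calls f(index) for each complete k-mer
// window free of non-ACGT letters. Index is the canonical (lexicographic
// minimum of strand and reverse complement) code when canonical is true.
template <typename F>
static void scan_kmers(const char* s, size_t n, int k, bool canonical, F f) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rc = 0;
  int valid = 0;
  for (size_t i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { valid = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - c) << shift);
    if (++valid >= k) {
      uint64_t idx = canonical ? std::min(fwd, rc) : fwd;
      f(i + 1 - (size_t)k, idx);
    }
  }
}

// Count all k-mers per scaffold, restricted to k-mers whose genome-wide
// total is at least min_total. Flat 4^k tables keep this exact and fast;
// k is capped at 13 (the default) so the tables stay within ~0.5 GB.
// [[Rcpp::export(name = ".count_kmers_cpp")]]
List count_kmers_cpp(CharacterVector seqs, int k, bool canonical,
                     double min_total) {
  if (k < 1 || k > 13) stop("k must be between 1 and 13");
  const size_t nk = 1ULL << (2 * k);
  const int nseq = seqs.size();

  std::vector<uint32_t> total(nk, 0u);
  for (int j = 0; j < nseq; ++j) {
    const char* s = CHAR(STRING_ELT(seqs, j));
    size_t n = strlen(s);
    scan_kmers(s, n, k, canonical, [&](size_t, uint64_t idx) {
      ++total[idx];
    });
  }

  std::vector<uint64_t> kept;
  for (size_t i = 0; i < nk; ++i)
    if ((double)total[i] >= min_total) kept.push_back(i);

  std::vector<int32_t> idmap(nk, -1);
  for (size_t r = 0; r < kept.size(); ++r) idmap[kept[r]] = (int32_t)r;

  IntegerMatrix counts((int)kept.size(), nseq);
  for (int j = 0; j < nseq; ++j) {
    const char* s = CHAR(STRING_ELT(seqs, j));
    size_t n = strlen(s);
    scan_kmers(s, n, k, canonical, [&](size_t, uint64_t idx) {
      int32_t r = idmap[idx];
      if (r >= 0) ++counts(r, j);
    });
  }

  CharacterVector kmers(kept.size());
  for (size_t r = 0; r < kept.size(); ++r)
    kmers[r] = decode_kmer(kept[r], k);

  return List::create(_["kmer"] = kmers, _["counts"] = counts);
}

// Per-window occurrence counts of two k-mer sets along one scaffold.
// A k-mer is attributed to the window containing its first base.
// [[Rcpp::export(name = ".window_hits_cpp")]]
IntegerMatrix window_hits_cpp(std::string seq, int k, bool canonical,
                              CharacterVector a_kmers,
                              CharacterVector b_kmers, double window) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  std::unordered_set<uint64_t> aset, bset;
  auto encode = [&](const char* s) -> int64_t {
    uint64_t code = 0;
    for (int i = 0; i < k; ++i) {
      int c = base_code(s[i]);
      if (c < 0) return -1;
      code = (code << 2) | (uint64_t)c;
    }
    return (int64_t)code;
  };
  for (int i = 0; i < a_kmers.size(); ++i) {
    int64_t c = encode(CHAR(STRING_ELT(a_kmers, i)));
    if (c >= 0) aset.insert((uint64_t)c);
  }
  for (int i = 0; i < b_kmers.size(); ++i) {
    int64_t c = encode(CHAR(STRING_ELT(b_kmers, i)));
    if (c >= 0) bset.insert((uint64_t)c);
  }

  size_t n = seq.size();
  size_t w = (size_t)window;
  size_t nwin = n == 0 ? 0 : (n + w - 1) / w;
  IntegerMatrix out((int)nwin, 2);
  scan_kmers(seq.c_str(), n, k, canonical, [&](size_t pos, uint64_t idx) {
    size_t win = pos / w;
    if (aset.count(idx)) ++out((int)win, 0);
    if (bset.count(idx)) ++out((int)win, 1);
  });
  return out;
}
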