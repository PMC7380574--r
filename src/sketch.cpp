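#include <Rcpp.h>
#include <cstdint>
#include <unordered_set>
#include <algorithm>
#include <vector>
#include <string>

using namespace Rcpp;

// 2-bit DNA codes; A<C<G<T matches lexicographic order so the numeric
// minimum of the packed k-mer and its reverse complement is the
// lexicographically smaller string.
static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1; // N or anything else: k-mers spanning it are skipped
  }
}

// splitmix64 finalizer: a fixed, documented 64-bit mix, identical on every
// platform. Seeded by XOR with a multiplied seed constant.
static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline uint64_t hash_kmer(uint64_t packed, uint64_t seed) {
  return mix64(packed ^ (seed * 0x9E3779B97F4A7C15ULL));
}

static std::string to_hex(uint64_t v) {
  static const char *digits = "0123456789abcdef";
  std::string s(16, '0');
  for (int i = 15; i >= 0; --i) { s[i] = digits[v & 0xF]; v >>= 4; }
  return s;
}

// Collect hashes of all distinct canonical k-mers across contigs.
static void canonical_hashes(const CharacterVector &contigs, int k,
                             uint64_t seed, std::unordered_set<uint64_t> &out) {
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  const int shift = 2 * (k - 1);
  for (R_xlen_t ci = 0; ci < contigs.size(); ++ci) {
    const char *s = CHAR(STRING_ELT(contigs, ci));
    int n = (int) LENGTH(STRING_ELT(contigs, ci));
    uint64_t fwd = 0, rev = 0;
    int valid = 0;
    for (int i = 0; i < n; ++i) {
      int c = base_code(s[i]);
      if (c < 0) { valid = 0; fwd = rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t) c) & mask;
      rev = (rev >> 2) | (((uint64_t)(3 - c)) << shift);
      if (++valid >= k) {
        uint64_t canon = fwd < rev ? fwd : rev;
        out.insert(hash_kmer(canon, seed));
      }
    }
  }
}

// [[Rcpp::export]]
CharacterVector sketch_hashes_cpp(CharacterVector contigs, int k, int s,
                                  double hash_seed) {
  std::unordered_set<uint64_t> hashes;
  canonical_hashes(contigs, k, (uint64_t) hash_seed, hashes);
  std::vector<uint64_t> v(hashes.begin(), hashes.end());
  size_t keep = std::min((size_t) s, v.size());
  std::partial_sort(v.begin(), v.begin() + keep, v.end());
  CharacterVector out(keep);
  for (size_t i = 0; i < keep; ++i) out[i] = to_hex(v[i]);
  return out;
}

// Exact Jaccard of full canonical k-mer sets (brute-force, for reports and
// diagnostics; sketches estimate this quantity).
// [[Rcpp::export]]
double exact_kmer_jaccard_cpp(CharacterVector contigs_a,
                              CharacterVector contigs_b, int k,
                              double hash_seed) {
  std::unordered_set<uint64_t> a, b;
  canonical_hashes(contigs_a, k, (uint64_t) hash_seed, a);
  canonical_hashes(contigs_b, k, (uint64_t) hash_seed, b);
  if (a.empty() && b.empty()) return 0.0;
  size_t inter = 0;
  const std::unordered_set<uint64_t> &small = a.size() < b.size() ? a : b;
  const std::unordered_set<uint64_t> &large = a.size() < b.size() ? b : a;
  for (uint64_t h : small) if (large.count(h)) ++inter;
  return (double) inter / (double) (a.size() + b.size() - inter);
}
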