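#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstring>

using namespace Rcpp;

// Seed-and-extend fragment alignment against a subject genome.
//
// Candidate loci are found by exact shared seed k-mers (both strands); each
// candidate diagonal is scored first by an ungapped comparison and, where
// that is not conclusive, by a banded overlap alignment (free end gaps on
// both sequences). Identity is matches / alignment columns with indel
// columns counted as mismatches — the denominator a fragment-based ANI
// expects.

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return 4; // N: never matches, never seeds
  }
}

static void encode(const char *s, int n, std::vector<int8_t> &out) {
  out.resize(n);
  for (int i = 0; i < n; ++i) out[i] = (int8_t) base_code(s[i]);
}

static void revcomp(const std::vector<int8_t> &in, std::vector<int8_t> &out) {
  int n = (int) in.size();
  out.resize(n);
  for (int i = 0; i < n; ++i) {
    int8_t c = in[n - 1 - i];
    out[i] = (c < 4) ? (int8_t)(3 - c) : (int8_t)4;
  }
}

struct SubjectIndex {
  std::vector<std::vector<int8_t>> contigs;
  // value packs strand (bit 62: subject k-mer stored reverse-complemented),
  // contig (bits 32..61) and position
  std::unordered_map<uint64_t, std::vector<uint64_t>> seeds;
  // presence bitmap over the low 24 k-mer bits: a cache-resident prefilter
  // that rejects almost every probe from unrelated sequence without touching
  // the (large, cache-cold) hash map
  std::vector<uint64_t> bloom;
  int k;
  size_t cap = 256; // positions kept per seed k-mer (repeat guard)

  inline void bloom_set(uint64_t key) {
    uint64_t b = key & 0xFFFFFFULL;
    bloom[b >> 6] |= (1ULL << (b & 63));
  }
  inline bool bloom_has(uint64_t key) const {
    uint64_t b = key & 0xFFFFFFULL;
    return (bloom[b >> 6] >> (b & 63)) & 1ULL;
  }

  void build(const CharacterVector &contig_seqs, int seed_k) {
    k = seed_k;
    const uint64_t mask = (1ULL << (2 * k)) - 1;
    const int shift = 2 * (k - 1);
    bloom.assign((1ULL << 24) / 64, 0);
    contigs.resize(contig_seqs.size());
    for (R_xlen_t ci = 0; ci < contig_seqs.size(); ++ci) {
      const char *s = CHAR(STRING_ELT(contig_seqs, ci));
      int n = (int) LENGTH(STRING_ELT(contig_seqs, ci));
      encode(s, n, contigs[ci]);
      uint64_t fwd = 0, rev = 0;
      int valid = 0;
      for (int i = 0; i < n; ++i) {
        int8_t c = contigs[ci][i];
        if (c >= 4) { valid = 0; fwd = rev = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t) c) & mask;
        rev = (rev >> 2) | (((uint64_t)(3 - c)) << shift);
        if (++valid >= k) {
          uint64_t pos = (uint64_t)(i - k + 1);
          auto &v = seeds[fwd];
          if (v.size() < cap) v.push_back(((uint64_t) ci << 32) | pos);
          bloom_set(fwd);
          auto &vr = seeds[rev];
          if (vr.size() < cap)
            vr.push_back((1ULL << 62) | ((uint64_t) ci << 32) | pos);
          bloom_set(rev);
        }
      }
    }
  }
};

struct Candidate {
  int contig;
  int strand;   // 0 = fragment as-is, 1 = reverse complement of fragment
  int diag;     // subject_pos - fragment_pos
  int votes;
  int minor;    // votes merged in from nearby secondary diagonals (indel sign)
  int diag2;    // strongest secondary diagonal
  int votes2;
};

// Optimal one-breakpoint (single indel) alignment across two diagonals,
// computed exactly with prefix/suffix match sums; a lower bound on the
// banded-DP optimum, exact when the fragment carries one indel.
static double two_piece_identity(const std::vector<int8_t> &q,
                                 const std::vector<int8_t> &w,
                                 int d1, int d2,
                                 std::vector<int> &pref, std::vector<int> &suff,
                                 bool &clean_ends) {
  const int m = (int) q.size(), clen = (int) w.size();
  clean_ends = false;
  if (std::min(d1, d2) < 0 || std::max(d1, d2) + m > clen) return -1.0;
  if (d1 == d2) return -1.0;
  double best = -1.0;
  int best_da = d1, best_db = d2, best_t = 0, best_skip = 0;
  pref.resize(m + 1); suff.resize(m + 1);
  for (int ori = 0; ori < 2; ++ori) {
    const int da = ori ? d2 : d1, db = ori ? d1 : d2;
    const int dd = db - da;
    const int gap = dd > 0 ? dd : 0;   // deletion in query: unaligned subject
    const int skip = dd < 0 ? -dd : 0; // insertion in query: skipped bases
    pref[0] = 0;
    for (int i = 0; i < m; ++i)
      pref[i + 1] = pref[i] + (q[i] == w[da + i] && q[i] < 4);
    suff[m] = 0;
    for (int i = m - 1; i >= 0; --i)
      suff[i] = suff[i + 1] + (q[i] == w[db + i] && q[i] < 4);
    int bm = -1, bt = 0;
    for (int t = 0; t + skip <= m; ++t) {
      int tot = pref[t] + suff[t + skip];
      if (tot > bm) { bm = tot; bt = t; }
    }
    double id = (double) bm / (double)(m + gap);
    if (id > best) {
      best = id; best_da = da; best_db = db; best_t = bt; best_skip = skip;
    }
  }
  // a third indel near a fragment end would leave that end mismatch-dense;
  // only report the ends as clean when the breakpoint is interior and both
  // terminal stretches look like substitution-level noise
  const int tail = std::min(25, m);
  if (best_t >= tail && best_t + best_skip <= m - tail) {
    int mm_head = 0, mm_tail = 0, mm_bl = 0, mm_br = 0;
    for (int i = 0; i < tail; ++i) {
      if (!(q[i] == w[best_da + i] && q[i] < 4)) ++mm_head;
      int jj = m - 1 - i;
      if (!(q[jj] == w[best_db + jj] && q[jj] < 4)) ++mm_tail;
      int bl = best_t - 1 - i; // breakpoint flanks: a second indel nearby
      if (!(q[bl] == w[best_da + bl] && q[bl] < 4)) ++mm_bl;
      int br = best_t + best_skip + i;
      if (!(q[br] == w[best_db + br] && q[br] < 4)) ++mm_br;
    }
    clean_ends = (mm_head <= 5 && mm_tail <= 5 && mm_bl <= 5 && mm_br <= 5);
  }
  return best;
}

struct Hit {
  double identity = -1.0;
  double frac = 0.0;
  bool found = false;
};

// Banded local (Smith-Waterman) alignment of query q against subject
// window w, restricted to diagonals within hb of offset0. Local semantics
// matter: when only part of the fragment has a homolog in the window (a
// contig break, an inserted segment), the alignment covers just that part
// and the fragment-length acceptance rule decides. Returns identity over
// aligned columns (indel columns count as mismatch) and the fraction of q
// inside the alignment.
static void banded_local(const std::vector<int8_t> &q,
                         const int8_t *w, int n,
                         int offset0, int hb,
                         double &identity, double &frac,
                         std::vector<int> &score_buf,
                         std::vector<int8_t> &ptr_buf) {
  const int m = (int) q.size();
  const int W = 2 * hb + 1;            // band width in j-offset terms
  const int GAP = -2, MATCH = 1, MISMATCH = -1;
  score_buf.assign((size_t)(m + 1) * W, 0);
  ptr_buf.assign((size_t)(m + 1) * W, 0); // 0 stop, 1 diag, 2 up(gap in w), 3 left(gap in q)

  // j(i, b) = i + offset0 - hb + b   for band slot b in [0, W)
  int best_i = -1, best_b = -1, best_score = 0;
  for (int i = 1; i <= m; ++i) {
    const int jbase = i + offset0 - hb;
    int *row = &score_buf[(size_t) i * W];
    const int *prev = &score_buf[(size_t)(i - 1) * W];
    int8_t *prow = &ptr_buf[(size_t) i * W];
    const int8_t qi = q[i - 1];
    int blo = jbase < 1 ? 1 - jbase : 0;
    int bhi = jbase + W - 1 > n ? n - jbase : W - 1;
    for (int b = blo; b <= bhi; ++b) {
      const int j = jbase + b;
      int best = 0;
      int8_t p = 0;
      int d = prev[b] + ((qi == w[j - 1] && qi < 4) ? MATCH : MISMATCH);
      if (d > best) { best = d; p = 1; }
      if (b + 1 < W) {
        int u = prev[b + 1] + GAP;
        if (u > best) { best = u; p = 2; }
      }
      if (b > 0) {
        int l = row[b - 1] + GAP;
        if (l > best) { best = l; p = 3; }
      }
      row[b] = best;
      prow[b] = p;
      if (best > best_score) { best_score = best; best_i = i; best_b = b; }
    }
  }
  if (best_i < 0) { identity = 0.0; frac = 0.0; return; }

  int i = best_i, b = best_b;
  long matches = 0, cols = 0;
  const int i_end = best_i;
  while (i > 0) {
    int8_t p = ptr_buf[(size_t) i * W + b];
    if (p == 0) break;
    int j = i + offset0 - hb + b;
    if (p == 1) {
      ++cols;
      if (q[i - 1] == w[j - 1] && q[i - 1] < 4) ++matches;
      i -= 1; // slot unchanged on diagonal moves
    } else if (p == 2) {
      ++cols; i -= 1; b += 1;
    } else {
      ++cols; b -= 1;
    }
  }
  identity = cols > 0 ? (double) matches / (double) cols : 0.0;
  frac = (double)(i_end - i) / (double) m;
}

// [[Rcpp::export]]
List one_way_ani_cpp(CharacterVector fragments, CharacterVector subject_contigs,
                     int seed_k, int band, double min_identity,
                     double min_fraction, int max_candidates = 4,
                     double fast_path_identity = 0.90) {
  SubjectIndex idx;
  idx.build(subject_contigs, seed_k);
  const uint64_t mask = (1ULL << (2 * seed_k)) - 1;
  const int hb = std::max(band / 2, 8);

  int nf = (int) fragments.size();
  NumericVector identity(nf), frac(nf);
  LogicalVector hit(nf);

  std::vector<int> score_buf, pref_buf, suff_buf;
  std::vector<int8_t> ptr_buf;
  std::vector<int8_t> fenc, renc;

  for (int fi = 0; fi < nf; ++fi) {
    const char *fs = CHAR(STRING_ELT(fragments, fi));
    int m = (int) LENGTH(STRING_ELT(fragments, fi));
    encode(fs, m, fenc);
    revcomp(fenc, renc);

    // seed voting: exact diagonal counts per (contig, strand); forward
    // fragment k-mers probe an index holding both subject strands
    std::unordered_map<uint64_t, int> votes;
    {
      uint64_t fwd = 0;
      int valid = 0;
      for (int i = 0; i < m; ++i) {
        int8_t c = fenc[i];
        if (c >= 4) { valid = 0; fwd = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t) c) & mask;
        if (++valid >= seed_k) {
          if (!idx.bloom_has(fwd)) continue;
          auto it = idx.seeds.find(fwd);
          if (it == idx.seeds.end()) continue;
          int qpos = i - seed_k + 1;
          for (uint64_t packed : it->second) {
            int strand = (int)(packed >> 62);
            int ci = (int)((packed >> 32) & 0x3FFFFFFFULL);
            int spos = (int)(packed & 0xFFFFFFFFULL);
            // a hit on the subject's reverse strand aligns the fragment's
            // reverse complement, whose k-mer start is m - k - qpos
            int diag = strand == 0 ? spos - qpos : spos - (m - seed_k - qpos);
            // key: contig (20 bits) | strand (1) | diag shifted to be >= 0
            uint64_t key = ((uint64_t) ci << 40) | ((uint64_t) strand << 36) |
                           (uint64_t)(diag + (1 << 30));
            votes[key] += 1;
          }
        }
      }
    }
    if (votes.empty()) { identity[fi] = NA_REAL; frac[fi] = 0; hit[fi] = false; continue; }

    // collapse diagonals within hb of a stronger one; keep top candidates
    std::vector<std::pair<uint64_t, int>> vv(votes.begin(), votes.end());
    std::sort(vv.begin(), vv.end(), [](const std::pair<uint64_t,int> &a,
                                       const std::pair<uint64_t,int> &b) {
      if (a.second != b.second) return a.second > b.second;
      return a.first < b.first;
    });
    std::vector<Candidate> cands;
    for (auto &kv : vv) {
      int ci = (int)(kv.first >> 40);
      int strand = (int)((kv.first >> 36) & 0xF);
      int diag = (int)(kv.first & 0xFFFFFFFFFULL) - (1 << 30);
      bool merged = false;
      for (auto &c : cands)
        if (c.contig == ci && c.strand == strand && std::abs(c.diag - diag) <= hb) {
          c.votes += kv.second; c.minor += kv.second;
          if (kv.second > c.votes2) { c.votes2 = kv.second; c.diag2 = diag; }
          merged = true; break;
        }
      if (!merged) cands.push_back({ci, strand, diag, kv.second, 0, 0, 0});
      if ((int) cands.size() >= max_candidates && kv.second <= 1) break;
    }
    if ((int) cands.size() > max_candidates) cands.resize(max_candidates);

    Hit best;
    int top_votes = cands.empty() ? 0 : cands[0].votes;
    for (auto &c : cands) {
      if (c.votes * 4 < top_votes) continue; // weak relative to the best locus
      // a single isolated seed is indistinguishable from a chance k-mer
      // collision; real homology detectable by 15-mer seeding leaves several
      if (c.votes < 2) continue;
      const std::vector<int8_t> &q = c.strand == 0 ? fenc : renc;
      const std::vector<int8_t> &contig = idx.contigs[c.contig];
      int clen = (int) contig.size();
      // ungapped fast path: only trusted when every seed sits on one
      // diagonal (no indel signal), the fragment lies wholly inside the
      // contig, identity is high, and both fragment ends look clean —
      // otherwise a gapped alignment could score better
      if (c.minor == 0 && c.diag >= 0 && c.diag + m <= clen) {
        int matches = 0;
        const int8_t *w = contig.data() + c.diag;
        for (int i = 0; i < m; ++i)
          if (q[i] == w[i] && q[i] < 4) ++matches;
        double id0 = (double) matches / (double) m;
        int tail = std::min(25, m);
        int mm_head = 0, mm_tail = 0;
        for (int i = 0; i < tail; ++i) {
          if (!(q[i] == w[i] && q[i] < 4)) ++mm_head;
          if (!(q[m - 1 - i] == w[m - 1 - i] && q[m - 1 - i] < 4)) ++mm_tail;
        }
        if (id0 >= fast_path_identity && mm_head <= 5 && mm_tail <= 5) {
          if (id0 > best.identity) { best.identity = id0; best.frac = 1.0; best.found = true; }
          continue;
        }
      }
      // two-diagonal fast path: a clear secondary diagonal means a single
      // indel, whose optimal alignment is computable without DP
      if (c.minor > 0 && c.votes2 >= 2) {
        bool clean_ends = false;
        double id2 = two_piece_identity(q, idx.contigs[c.contig], c.diag,
                                        c.diag2, pref_buf, suff_buf, clean_ends);
        if (id2 >= 0.95 && clean_ends) {
          if (id2 > best.identity) { best.identity = id2; best.frac = 1.0; best.found = true; }
          continue;
        }
      }
      // banded local alignment on a padded window
      int win_start = std::max(0, c.diag - hb);
      int win_end = std::min(clen, c.diag + m + hb);
      if (win_end <= win_start) continue;
      int n = win_end - win_start;
      int offset0 = c.diag - win_start;
      double id1, fr1;
      banded_local(q, contig.data() + win_start, n, offset0, hb,
                   id1, fr1, score_buf, ptr_buf);
      if (id1 > best.identity) { best.identity = id1; best.frac = fr1; best.found = true; }
    }

    if (!best.found) { identity[fi] = NA_REAL; frac[fi] = 0; hit[fi] = false; continue; }
    identity[fi] = best.identity;
    frac[fi] = best.frac;
    hit[fi] = (best.identity >= min_identity) && (best.frac >= min_fraction);
  }

  return List::create(_["identity"] = identity, _["frac_aligned"] = frac,
                      _["hit"] = hit);
}
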