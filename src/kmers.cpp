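#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <cstdint>
#include <cstring>
using namespace Rcpp;

// 64-bit k-mer hashing: FNV-1a over the canonical (lexicographically smaller
// of forward / reverse-complement) k-mer string, finalized with splitmix64.
// Returned to R as the top 53 bits in a double, since R lacks uint64.

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline uint64_t fnv1a(const char* s, int n) {
  uint64_t h = 1469598103934665603ULL;
  for (int i = 0; i < n; ++i) {
    h ^= (uint64_t)(unsigned char)s[i];
    h *= 1099511628211ULL;
  }
  return splitmix64(h);
}

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static inline bool valid_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// canonical hash of the k-mer starting at s+i, or return false if it holds N
static bool canon_hash(const char* s, int i, int k, std::string& rcbuf,
                       uint64_t& out) {
  const char* p = s + i;
  for (int j = 0; j < k; ++j) if (!valid_base(p[j])) return false;
  // reverse complement into rcbuf
  rcbuf.resize(k);
  for (int j = 0; j < k; ++j) rcbuf[j] = comp(p[k - 1 - j]);
  // lexicographic min of forward and rc
  int cmp = strncmp(p, rcbuf.data(), k);
  if (cmp <= 0) out = fnv1a(p, k);
  else out = fnv1a(rcbuf.data(), k);
  return true;
}

static void kmer_set(const std::string& seq, int k,
                     std::vector<uint64_t>& out) {
  out.clear();
  int n = (int)seq.size();
  if (n < k) return;
  std::string rcbuf;
  std::unordered_set<uint64_t> seen;
  seen.reserve((size_t)(n - k + 1));
  uint64_t h;
  for (int i = 0; i + k <= n; ++i) {
    if (canon_hash(seq.c_str(), i, k, rcbuf, h)) seen.insert(h);
  }
  out.assign(seen.begin(), seen.end());
  std::sort(out.begin(), out.end());
}

static inline double to_dbl(uint64_t h) { return (double)(h >> 11); }

// [[Rcpp::export]]
NumericVector cpp_kmer_hashes(std::string seq, int k) {
  std::vector<uint64_t> v;
  kmer_set(seq, k, v);
  NumericVector out(v.size());
  for (size_t i = 0; i < v.size(); ++i) out[i] = to_dbl(v[i]);
  return out;
}

// Pairwise max-containment over canonical k-mer sets, via an inverted index
// so the all-vs-all matrix is never materialized.
// [[Rcpp::export]]
DataFrame cpp_containment_edges(CharacterVector seqs, int k, double min_sim) {
  int n = seqs.size();
  std::vector<std::vector<uint64_t>> sets(n);
  std::unordered_map<uint64_t, std::vector<int>> index;
  for (int i = 0; i < n; ++i) {
    kmer_set(as<std::string>(seqs[i]), k, sets[i]);
    for (uint64_t h : sets[i]) index[h].push_back(i);
  }
  std::unordered_map<uint64_t, int> shared;
  for (auto& kv : index) {
    const std::vector<int>& post = kv.second;
    size_t m = post.size();
    if (m < 2) continue;
    for (size_t a = 0; a + 1 < m; ++a)
      for (size_t b = a + 1; b < m; ++b) {
        uint64_t key = ((uint64_t)post[a] << 32) | (uint64_t)post[b];
        shared[key]++;
      }
  }
  std::vector<int> vi, vj;
  std::vector<double> vw;
  for (auto& kv : shared) {
    int i = (int)(kv.first >> 32), j = (int)(kv.first & 0xFFFFFFFFULL);
    size_t denom = std::min(sets[i].size(), sets[j].size());
    if (denom == 0) continue;
    double w = (double)kv.second / (double)denom;
    if (w >= min_sim) {
      vi.push_back(i + 1); vj.push_back(j + 1); vw.push_back(w);
    }
  }
  // deterministic edge order: by (i, j)
  std::vector<size_t> ord(vi.size());
  for (size_t t = 0; t < ord.size(); ++t) ord[t] = t;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    if (vi[a] != vi[b]) return vi[a] < vi[b];
    return vj[a] < vj[b];
  });
  IntegerVector oi(ord.size()), oj(ord.size());
  NumericVector ow(ord.size());
  for (size_t t = 0; t < ord.size(); ++t) {
    oi[t] = vi[ord[t]]; oj[t] = vj[ord[t]]; ow[t] = vw[ord[t]];
  }
  return DataFrame::create(_["i"] = oi, _["j"] = oj, _["weight"] = ow);
}

// Bottom-s MinHash sketch over all sequences' canonical k-mers.
// [[Rcpp::export]]
NumericVector cpp_bottom_sketch(CharacterVector seqs, int k, int s) {
  std::unordered_set<uint64_t> all;
  std::string rcbuf;
  uint64_t h;
  for (int i = 0; i < seqs.size(); ++i) {
    std::string seq = as<std::string>(seqs[i]);
    int n = (int)seq.size();
    for (int p = 0; p + k <= n; ++p)
      if (canon_hash(seq.c_str(), p, k, rcbuf, h)) all.insert(h);
  }
  std::vector<uint64_t> v(all.begin(), all.end());
  size_t keep = std::min((size_t)s, v.size());
  std::partial_sort(v.begin(), v.begin() + keep, v.end());
  NumericVector out(keep);
  for (size_t i = 0; i < keep; ++i) out[i] = to_dbl(v[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Exact-seed ungapped mapper. Index: forward seed_k-mers of every contig.
// A read is tried in both orientations; each seed hit implies a diagonal
// placement which is scored by full-length mismatch count (read must lie
// entirely within the contig). Best tier = minimum mismatches; primary is
// the tie with the lexicographically smallest contig id, then smallest
// position, forward before reverse.
// ---------------------------------------------------------------------------

struct MapHit { int contig; int pos; bool rev; int nm; };

// [[Rcpp::export]]
List cpp_build_seed_index(CharacterVector seqs, int seed_k) {
  // opaque index rebuilt per call from R would be wasteful; instead mapping
  // is done in one call below. This export exists only for testing.
  return List::create(_["n"] = seqs.size(), _["k"] = seed_k);
}

static void revcomp_str(const std::string& s, std::string& out) {
  out.resize(s.size());
  for (size_t i = 0; i < s.size(); ++i) out[i] = comp(s[s.size() - 1 - i]);
}

static inline int count_mismatch(const char* a, const char* b, int n, int cap) {
  int nm = 0;
  for (int i = 0; i < n; ++i) {
    if (a[i] != b[i]) { if (++nm > cap) return nm; }
  }
  return nm;
}

// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, CharacterVector contig_seqs,
                        IntegerVector contig_rank, int seed_k, int seed_step,
                        int max_mismatch, int tie_mode) {
  int nc = contig_seqs.size();
  std::vector<std::string> contigs(nc);
  for (int i = 0; i < nc; ++i) contigs[i] = as<std::string>(contig_seqs[i]);

  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> index;
  {
    size_t total = 0;
    for (int c = 0; c < nc; ++c)
      if ((int)contigs[c].size() >= seed_k) total += contigs[c].size() - seed_k + 1;
    index.reserve(total);
    for (int c = 0; c < nc; ++c) {
      const std::string& s = contigs[c];
      for (int p = 0; p + seed_k <= (int)s.size(); ++p) {
        bool ok = true;
        for (int j = 0; j < seed_k; ++j)
          if (!valid_base(s[p + j])) { ok = false; break; }
        if (!ok) continue;
        index[fnv1a(s.c_str() + p, seed_k)].emplace_back(c, p);
      }
    }
  }

  std::vector<int> o_read, o_contig, o_pos, o_nm, o_ntie;
  std::vector<int> o_rev, o_primary;

  std::string rc;
  for (int r = 0; r < reads.size(); ++r) {
    std::string fwd = as<std::string>(reads[r]);
    int len = (int)fwd.size();
    if (len < seed_k) continue;
    revcomp_str(fwd, rc);
    std::vector<MapHit> hits;
    int best = max_mismatch + 1;
    std::unordered_set<uint64_t> tried;
    for (int orient = 0; orient < 2; ++orient) {
      const std::string& q = orient == 0 ? fwd : rc;
      for (int off = 0; off <= len - seed_k; off += seed_step) {
        int o = std::min(off, len - seed_k);
        auto it = index.find(fnv1a(q.c_str() + o, seed_k));
        if (it == index.end()) { if (off >= len - seed_k) break; continue; }
        for (auto& cp : it->second) {
          int c = cp.first, start = cp.second - o;
          if (start < 0 || start + len > (int)contigs[c].size()) continue;
          uint64_t key = ((uint64_t)c << 33) | ((uint64_t)(start) << 1) |
                         (uint64_t)orient;
          if (!tried.insert(key).second) continue;
          int nm = count_mismatch(contigs[c].c_str() + start, q.c_str(), len,
                                  best);
          if (nm <= best && nm <= max_mismatch) {
            if (nm < best) { best = nm; }
            hits.push_back({c, start, orient == 1, nm});
          }
        }
        if (off >= len - seed_k) break;
      }
    }
    if (best > max_mismatch) continue;
    // keep ties at the best tier, pick primary deterministically
    std::vector<MapHit> ties;
    for (auto& h : hits) if (h.nm == best) ties.push_back(h);
    std::sort(ties.begin(), ties.end(), [&](const MapHit& a, const MapHit& b) {
      if (contig_rank[a.contig] != contig_rank[b.contig])
        return contig_rank[a.contig] < contig_rank[b.contig];
      if (a.pos != b.pos) return a.pos < b.pos;
      return a.rev < b.rev;
    });
    // dedupe equal-contig ties: one record per contig (primary placement)
    std::vector<MapHit> uniq;
    std::unordered_set<int> seenc;
    for (auto& h : ties)
      if (seenc.insert(h.contig).second) uniq.push_back(h);
    if (tie_mode == 1 && uniq.size() > 1) {
      // pseudorandom but deterministic primary choice among equal-best
      // contigs, keyed by (read, contig): equal copies of a transcript then
      // share the read evidence instead of the lexicographically first copy
      // absorbing all of it. Both mates of a pair share the read index, so
      // they stick to the same copy.
      size_t pick = 0;
      uint64_t besth = UINT64_MAX;
      for (size_t t = 0; t < uniq.size(); ++t) {
        uint64_t h = splitmix64(((uint64_t)(r + 1) << 32) ^
                                (uint64_t)(uniq[t].contig + 1));
        if (h < besth) { besth = h; pick = t; }
      }
      if (pick != 0) std::swap(uniq[0], uniq[pick]);
    }
    for (size_t t = 0; t < uniq.size(); ++t) {
      o_read.push_back(r + 1);
      o_contig.push_back(uniq[t].contig + 1);
      o_pos.push_back(uniq[t].pos);
      o_rev.push_back(uniq[t].rev ? 1 : 0);
      o_nm.push_back(uniq[t].nm);
      o_primary.push_back(t == 0 ? 1 : 0);
      o_ntie.push_back((int)uniq.size());
    }
  }
  return DataFrame::create(
    _["read"] = o_read, _["contig"] = o_contig, _["pos"] = o_pos,
    _["is_rev"] = o_rev, _["nm"] = o_nm, _["is_primary"] = o_primary,
    _["n_tie"] = o_ntie);
}
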