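#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <cmath>
#include <unordered_map>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

// ---------- small helpers ----------

static inline int base2code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static const char CODE2BASE[4] = {'A', 'C', 'G', 'T'};

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp(c);
  return r;
}

static inline bool is_stop(char a, char b, char c) {
  // TAA, TAG, TGA
  if (a != 'T') return false;
  if (b == 'A' && (c == 'A' || c == 'G')) return true;
  if (b == 'G' && c == 'A') return true;
  return false;
}

// FNV-1a 64-bit; stable, platform independent
static inline uint64_t fnv1a(const std::string& s) {
  uint64_t h = 1469598103934665603ULL;
  for (unsigned char c : s) { h ^= c; h *= 1099511628211ULL; }
  return h;
}

// ---------- sequence evolution (Jukes-Cantor forward process) ----------

// frame: integer per site, 0 = neutral, 1/2/3 = codon position inside a
// plus-strand gene. Positions with frame 1 or 2 evolve at coding_factor*rate;
// frame 0 and 3 at the full rate. Substitutions that would create an
// in-frame stop codon are redrawn among the remaining bases.
// [[Rcpp::export(name = ".ph_evolve")]]
std::string ph_evolve(std::string seq, double years, double rate,
                      IntegerVector frame, double coding_factor) {
  size_t L = seq.size();
  if (frame.size() != (R_xlen_t)L) stop("frame vector length mismatch");
  std::vector<uint32_t> full_idx, part_idx;
  full_idx.reserve(L);
  for (size_t i = 0; i < L; ++i) {
    int f = frame[i];
    if (f == 1 || f == 2) part_idx.push_back((uint32_t)i);
    else full_idx.push_back((uint32_t)i);
  }
  double lam = years * rate *
    ((double)full_idx.size() + coding_factor * (double)part_idx.size());
  if (lam <= 0) return seq;
  int nev = (int)R::rpois(lam);
  double w_full = (double)full_idx.size();
  double w_part = coding_factor * (double)part_idx.size();
  double p_full = w_full / (w_full + w_part);
  for (int e = 0; e < nev; ++e) {
    uint32_t i;
    if (part_idx.empty() || unif_rand() < p_full) {
      i = full_idx[(size_t)(unif_rand() * full_idx.size())];
    } else {
      i = part_idx[(size_t)(unif_rand() * part_idx.size())];
    }
    int cur = base2code(seq[i]);
    if (cur < 0) continue;
    // the three alternative bases, in random rotation
    int alts[3]; int na = 0;
    for (int b = 0; b < 4; ++b) if (b != cur) alts[na++] = b;
    int start = (int)(unif_rand() * 3);
    int f = frame[i];
    bool placed = false;
    for (int t = 0; t < 3 && !placed; ++t) {
      int nb = alts[(start + t) % 3];
      if (f > 0) {
        size_t c0 = i - (size_t)(f - 1);
        char cdn[3] = {seq[c0], seq[c0 + 1], seq[c0 + 2]};
        cdn[f - 1] = CODE2BASE[nb];
        if (is_stop(cdn[0], cdn[1], cdn[2])) continue;
      }
      seq[i] = CODE2BASE[nb];
      placed = true;
    }
  }
  return seq;
}

// ---------- paired-end read simulation ----------

// Fragments uniform over the supplied sequences (weighted by length);
// R1 forward from the fragment start, R2 reverse-complement from the end.
// Errors are i.i.d. substitutions. Read names carry |origin=<chrom>| truth
// tags (a test-only convention ignored by the analysis modules).
// [[Rcpp::export(name = ".ph_sim_reads")]]
List ph_sim_reads(CharacterVector seqs, double depth, int read_len,
                  int insert_size, double error_rate, std::string prefix) {
  if (insert_size < read_len) stop("insert_size < read_length");
  int n = seqs.size();
  CharacterVector nm = seqs.names();
  std::vector<std::string> chroms(n);
  std::vector<double> cum(n + 1, 0.0);
  double total = 0;
  std::vector<const char*> ptr(n);
  std::vector<size_t> len(n);
  for (int i = 0; i < n; ++i) {
    ptr[i] = CHAR(STRING_ELT(seqs, i));
    len[i] = strlen(ptr[i]);
    chroms[i] = as<std::string>(nm[i]);
    double usable = (len[i] >= (size_t)insert_size) ? (double)len[i] : 0.0;
    total += (double)len[i];
    cum[i + 1] = cum[i] + usable;
  }
  if (cum[n] <= 0 && depth > 0) stop("no sequence long enough for insert_size");
  long n_pairs = (long)std::llround(depth * total / (2.0 * read_len));
  std::vector<std::string> r1(n_pairs), r2(n_pairs), n1(n_pairs), n2(n_pairs);
  for (long p = 0; p < n_pairs; ++p) {
    double u = unif_rand() * cum[n];
    int ci = (int)(std::upper_bound(cum.begin() + 1, cum.end(), u) -
                   (cum.begin() + 1));
    if (ci >= n) ci = n - 1;
    size_t maxs = len[ci] - insert_size;
    size_t start = (size_t)(unif_rand() * (double)(maxs + 1));
    if (start > maxs) start = maxs;
    std::string frag(ptr[ci] + start, (size_t)insert_size);
    std::string a = frag.substr(0, read_len);
    std::string b = revcomp(frag.substr(insert_size - read_len, read_len));
    if (error_rate > 0) {
      for (auto& c : a) if (unif_rand() < error_rate) {
        int cur = base2code(c);
        if (cur >= 0) c = CODE2BASE[(cur + 1 + (int)(unif_rand() * 3)) % 4];
      }
      for (auto& c : b) if (unif_rand() < error_rate) {
        int cur = base2code(c);
        if (cur >= 0) c = CODE2BASE[(cur + 1 + (int)(unif_rand() * 3)) % 4];
      }
    }
    std::string base = prefix + std::to_string(p + 1) + "|origin=" +
      chroms[ci] + "|pos=" + std::to_string(start);
    r1[p] = a; r2[p] = b;
    n1[p] = base + "/1";
    n2[p] = base + "/2";
  }
  return List::create(_["name1"] = n1, _["seq1"] = r1,
                      _["name2"] = n2, _["seq2"] = r2);
}

// ---------- exact k-mer index ----------

// k-mer table: (key, position) pairs sorted by key, with a bucket
// directory on the high key bits for near-O(1) range lookup
struct PhIndex {
  int k;
  int dir_bits;
  int shift;
  std::vector<std::string> names;
  std::vector<uint64_t> starts;  // offsets of each chrom in concat
  std::string seq;               // concatenated reference
  std::vector<uint64_t> keys;    // sorted
  std::vector<uint32_t> pos;     // co-sorted positions
  std::vector<uint32_t> dir;     // bucket -> first entry

  // range of entries for `key`: [lo, hi)
  inline std::pair<uint32_t, uint32_t> lookup(uint64_t key) const {
    uint32_t lo = dir[key >> shift], hi = dir[(key >> shift) + 1];
    while (lo < hi && keys[lo] < key) ++lo;
    uint32_t end = lo;
    while (end < hi && keys[end] == key) ++end;
    return {lo, end};
  }
};

// [[Rcpp::export(name = ".ph_build_index")]]
SEXP ph_build_index(CharacterVector seqs, int k) {
  if (k < 8 || k > 31) stop("k must be in [8, 31]");
  if (seqs.size() == 0) stop("empty genome");
  PhIndex* idx = new PhIndex();
  idx->k = k;
  CharacterVector nm = seqs.names();
  uint64_t off = 0;
  for (int i = 0; i < seqs.size(); ++i) {
    idx->names.push_back(as<std::string>(nm[i]));
    idx->starts.push_back(off);
    std::string s = as<std::string>(seqs[i]);
    if (s.empty()) stop("empty chromosome in genome");
    idx->seq += s;
    off += s.size();
  }
  idx->starts.push_back(off);
  const std::string& S = idx->seq;
  uint64_t mask = (1ULL << (2 * k)) - 1;
  std::vector<std::pair<uint64_t, uint32_t>> kv;
  kv.reserve(S.size());
  for (size_t ci = 0; ci + 1 < idx->starts.size(); ++ci) {
    uint64_t lo = idx->starts[ci], hi = idx->starts[ci + 1];
    if (hi - lo < (uint64_t)k) continue;
    uint64_t key = 0; int valid = 0;
    for (uint64_t i = lo; i < hi; ++i) {
      int c = base2code(S[i]);
      if (c < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++valid >= k) kv.emplace_back(key, (uint32_t)(i - k + 1));
    }
  }
  std::sort(kv.begin(), kv.end());
  idx->dir_bits = std::min(22, 2 * k);
  idx->shift = 2 * k - idx->dir_bits;
  size_t nb = ((size_t)1 << idx->dir_bits);
  idx->keys.resize(kv.size());
  idx->pos.resize(kv.size());
  for (size_t i = 0; i < kv.size(); ++i) {
    idx->keys[i] = kv[i].first;
    idx->pos[i] = kv[i].second;
  }
  idx->dir.assign(nb + 1, 0);
  for (auto& e : kv) idx->dir[(e.first >> idx->shift) + 1]++;
  for (size_t b = 1; b <= nb; ++b) idx->dir[b] += idx->dir[b - 1];
  XPtr<PhIndex> xp(idx, true);
  return xp;
}

// [[Rcpp::export(name = ".ph_index_info")]]
List ph_index_info(SEXP xp_) {
  XPtr<PhIndex> xp(xp_);
  return List::create(_["k"] = xp->k,
                      _["chroms"] = wrap(xp->names),
                      _["n_positions"] = (double)xp->pos.size());
}

// [[Rcpp::export(name = ".ph_lookup_kmer")]]
IntegerVector ph_lookup_kmer(SEXP xp_, std::string kmer) {
  XPtr<PhIndex> xp(xp_);
  if ((int)kmer.size() != xp->k) stop("k-mer length != index k");
  uint64_t key = 0;
  for (char c : kmer) {
    int b = base2code(c);
    if (b < 0) return IntegerVector(0);
    key = (key << 2) | (uint64_t)b;
  }
  auto rng = xp->lookup(key);
  IntegerVector out(rng.second - rng.first);
  for (uint32_t i = rng.first; i < rng.second; ++i)
    out[i - rng.first] = (int)xp->pos[i];
  return out;  // global 0-based positions in the concatenated reference
}

// ---------- mapping ----------

struct Cand { int64_t diag; uint32_t count; };

struct AlnHit {
  int chrom; int64_t pos;       // local 0-based start of retained interval
  int strand;                   // 0 = '+', 1 = '-'
  int score, nm, qstart, qend;  // retained query interval [qstart, qend)
};

// collect candidate diagonals for one oriented query
static void seed_diagonals(const PhIndex* idx, const std::string& q,
                           int stride, std::vector<int64_t>& diags) {
  int k = idx->k;
  int L = (int)q.size();
  uint64_t mask = (1ULL << (2 * k)) - 1;
  diags.clear();
  std::vector<int> offs;
  for (int i = 0; i + k <= L; i += stride) offs.push_back(i);
  if (!offs.empty() && offs.back() != L - k) offs.push_back(L - k);
  for (int i : offs) {
    uint64_t key = 0; bool ok = true;
    for (int j = 0; j < k; ++j) {
      int c = base2code(q[i + j]);
      if (c < 0) { ok = false; break; }
      key = ((key << 2) | (uint64_t)c) & mask;
    }
    if (!ok) continue;
    auto rng = idx->lookup(key);
    uint32_t n = rng.second - rng.first;
    if (n == 0 || n > 4096) continue;  // absent or hyper-repetitive
    for (uint32_t t = rng.first; t < rng.second; ++t)
      diags.push_back((int64_t)idx->pos[t] - i);
  }
}

// evaluate one oriented query at one diagonal: best ungapped sub-interval
// (match +1, mismatch -2, Kadane)
static bool eval_candidate(const PhIndex* idx, const std::string& q,
                           int64_t diag, AlnHit& out) {
  int L = (int)q.size();
  if (diag < 0 || diag + L > (int64_t)idx->seq.size()) return false;
  // must lie within a single chromosome
  size_t ci = (size_t)(std::upper_bound(idx->starts.begin(),
                idx->starts.end(), (uint64_t)diag) - idx->starts.begin()) - 1;
  if ((uint64_t)(diag + L) > idx->starts[ci + 1]) return false;
  int best = 0, besta = 0, bestb = 0;
  int cur = 0, cura = 0;
  for (int i = 0; i < L; ++i) {
    char r = idx->seq[diag + i];
    int m = (base2code(r) >= 0 && (q[i] == r)) ? 1 : -2;
    if (cur <= 0) { cur = m; cura = i; } else cur += m;
    if (cur > best) { best = cur; besta = cura; bestb = i + 1; }
  }
  if (best <= 0) return false;
  int nm = 0;
  for (int i = besta; i < bestb; ++i)
    if (q[i] != idx->seq[diag + i]) nm++;
  out.chrom = (int)ci;
  out.pos = diag + besta - (int64_t)idx->starts[ci];
  out.score = best;
  out.nm = nm;
  out.qstart = besta;
  out.qend = bestb;
  return true;
}

// map one oriented query; returns hits tied for best score
static int map_oriented(const PhIndex* idx, const std::string& q, int strand,
                        int stride, int min_chain, int max_cand,
                        std::vector<AlnHit>& best_hits, int& best_score) {
  std::vector<int64_t> diags;
  seed_diagonals(idx, q, stride, diags);
  if (diags.empty()) return 0;
  std::sort(diags.begin(), diags.end());
  std::vector<Cand> cands;
  for (size_t i = 0; i < diags.size();) {
    size_t j = i;
    while (j < diags.size() && diags[j] == diags[i]) ++j;
    if ((int)(j - i) >= min_chain)
      cands.push_back({diags[i], (uint32_t)(j - i)});
    i = j;
  }
  if (cands.empty()) return 0;
  std::stable_sort(cands.begin(), cands.end(),
                   [](const Cand& a, const Cand& b) {
                     if (a.count != b.count) return a.count > b.count;
                     return a.diag < b.diag;
                   });
  if ((int)cands.size() > max_cand) cands.resize(max_cand);
  int found = 0;
  for (auto& c : cands) {
    AlnHit h;
    if (!eval_candidate(idx, q, c.diag, h)) continue;
    h.strand = strand;
    ++found;
    if (h.score > best_score) {
      best_score = h.score;
      best_hits.clear();
      best_hits.push_back(h);
    } else if (h.score == best_score) {
      bool dup = false;
      for (auto& e : best_hits)
        if (e.chrom == h.chrom && e.pos == h.pos && e.strand == h.strand)
          { dup = true; break; }
      if (!dup) best_hits.push_back(h);
    }
  }
  return found;
}

// [[Rcpp::export(name = ".ph_map_reads")]]
DataFrame ph_map_reads(SEXP xp_, CharacterVector reads, CharacterVector names,
                       int stride, int min_chain, int max_candidates,
                       int min_score, int min_split) {
  XPtr<PhIndex> xp(xp_);
  const PhIndex* idx = xp.get();
  int n = reads.size();
  CharacterVector o_rname(n), o_strand(n), o_tierefs(n),
      o_prname(n), o_pside(n);
  IntegerVector o_pos(n), o_score(n), o_nm(n), o_alen(n), o_cl(n), o_cr(n),
      o_nbest(n), o_ppos(n), o_plen(n);
  LogicalVector o_amb(n), o_mapped(n);
  for (int r = 0; r < n; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    std::string qname = as<std::string>(names[r]);
    std::string rev = revcomp(fwd);
    std::vector<AlnHit> ties;
    int best = 0;
    map_oriented(idx, fwd, 0, stride, min_chain, max_candidates, ties, best);
    map_oriented(idx, rev, 1, stride, min_chain, max_candidates, ties, best);
    if (best < min_score || ties.empty()) {
      o_mapped[r] = false;
      o_rname[r] = NA_STRING; o_strand[r] = NA_STRING;
      o_pos[r] = NA_INTEGER; o_score[r] = NA_INTEGER; o_nm[r] = NA_INTEGER;
      o_alen[r] = NA_INTEGER; o_cl[r] = NA_INTEGER; o_cr[r] = NA_INTEGER;
      o_nbest[r] = 0; o_amb[r] = false; o_tierefs[r] = NA_STRING;
      o_prname[r] = NA_STRING; o_ppos[r] = NA_INTEGER;
      o_plen[r] = NA_INTEGER; o_pside[r] = NA_STRING;
      continue;
    }
    // deterministic, order-independent choice among score ties
    std::sort(ties.begin(), ties.end(), [&](const AlnHit& a, const AlnHit& b) {
      if (a.chrom != b.chrom) return idx->names[a.chrom] < idx->names[b.chrom];
      if (a.pos != b.pos) return a.pos < b.pos;
      return a.strand < b.strand;
    });
    size_t pick = (size_t)(fnv1a(qname) % (uint64_t)ties.size());
    const AlnHit& h = ties[pick];
    const std::string& q = (h.strand == 0) ? fwd : rev;
    int L = (int)q.size();
    o_mapped[r] = true;
    o_rname[r] = idx->names[h.chrom];
    o_strand[r] = (h.strand == 0) ? "+" : "-";
    o_pos[r] = (int)h.pos;
    o_score[r] = h.score;
    o_nm[r] = h.nm;
    o_alen[r] = h.qend - h.qstart;
    o_cl[r] = h.qstart;
    o_cr[r] = L - h.qend;
    o_nbest[r] = (int)ties.size();
    o_amb[r] = ties.size() > 1;
    std::string trefs;
    int shown = 0, last = -1;
    for (auto& t : ties) {
      if (t.chrom == last) continue;
      last = t.chrom;
      if (shown >= 8) { trefs += ",..."; break; }
      if (shown++) trefs += ",";
      trefs += idx->names[t.chrom];
    }
    o_tierefs[r] = trefs;
    // split-read: remap the larger soft-clipped portion
    o_prname[r] = NA_STRING; o_ppos[r] = NA_INTEGER;
    o_plen[r] = NA_INTEGER; o_pside[r] = NA_STRING;
    int cl = h.qstart, cr = L - h.qend;
    if (std::max(cl, cr) >= min_split) {
      bool left = cl >= cr;
      std::string sub = left ? q.substr(0, cl) : q.substr(h.qend);
      std::vector<AlnHit> pt;
      int pbest = 0;
      map_oriented(idx, sub, h.strand, std::max(2, stride / 2), 1,
                   max_candidates, pt, pbest);
      if (!pt.empty() && pbest >= (int)(0.5 * sub.size())) {
        std::sort(pt.begin(), pt.end(), [&](const AlnHit& a, const AlnHit& b) {
          if (a.chrom != b.chrom)
            return idx->names[a.chrom] < idx->names[b.chrom];
          return a.pos < b.pos;
        });
        const AlnHit& p = pt[(size_t)(fnv1a(qname + "#clip") % pt.size())];
        o_prname[r] = idx->names[p.chrom];
        o_ppos[r] = (int)p.pos;
        o_plen[r] = p.qend - p.qstart;
        o_pside[r] = left ? "L" : "R";
      }
    }
  }
  return DataFrame::create(
      _["qname"] = names, _["rname"] = o_rname, _["pos"] = o_pos,
      _["strand"] = o_strand, _["score"] = o_score, _["nm"] = o_nm,
      _["aln_len"] = o_alen, _["clip_left"] = o_cl, _["clip_right"] = o_cr,
      _["n_best"] = o_nbest, _["ambiguous_placement"] = o_amb,
      _["tie_refs"] = o_tierefs, _["partner_rname"] = o_prname,
      _["partner_pos"] = o_ppos, _["partner_len"] = o_plen,
      _["partner_side"] = o_pside, _["mapped"] = o_mapped,
      _["stringsAsFactors"] = false);
}
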