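// Split-read splice junction discovery core.
//
// A 2-bit-encoded k-mer hash index over the forward genome supports exact
// seed lookup; full-read placements are verified by Hamming distance.
// Junction candidates are enumerated between uniquely mapped read ends
// (or by extend-and-search when only one end maps), and each candidate
// carries its coordinate-shift equivalence class with a canonical
// (GT-AG > GC-AG > control > other, then leftmost) placement.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
  }
  return 'N';
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

struct SeedIndex {
  int k;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  // kmer code -> positions; position encoded as (chrom << 40) | pos
  std::unordered_map<uint64_t, std::vector<uint64_t>> map;
  size_t n_positions = 0;
};

static inline uint64_t enc_pos(int chrom, long long pos) {
  return (static_cast<uint64_t>(chrom) << 40) | static_cast<uint64_t>(pos);
}
static inline int pos_chrom(uint64_t e) { return static_cast<int>(e >> 40); }
static inline long long pos_off(uint64_t e) {
  return static_cast<long long>(e & ((1ULL << 40) - 1));
}

static bool encode_kmer(const std::string& s, size_t at, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bits(s[at + i]);
    if (b < 0) return false;
    v = (v << 2) | static_cast<uint64_t>(b);
  }
  out = v;
  return true;
}

// [[Rcpp::export]]
SEXP si_build(CharacterVector names, CharacterVector seqs, int k) {
  if (k < 12 || k > 31) stop("seed length k must be in [12, 31]");
  SeedIndex* si = new SeedIndex();
  si->k = k;
  for (int c = 0; c < seqs.size(); ++c) {
    si->names.push_back(as<std::string>(names[c]));
    si->seqs.push_back(as<std::string>(seqs[c]));
  }
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int c = 0; c < (int)si->seqs.size(); ++c) {
    const std::string& s = si->seqs[c];
    long long L = (long long)s.size();
    uint64_t v = 0;
    int valid = 0;
    for (long long i = 0; i < L; ++i) {
      int b = base2bits(s[i]);
      if (b < 0) { valid = 0; v = 0; continue; }
      v = ((v << 2) | (uint64_t)b) & mask;
      if (++valid >= k) {
        si->map[v].push_back(enc_pos(c, i - k + 1));
        si->n_positions++;
      }
    }
  }
  XPtr<SeedIndex> xp(si, true);
  return xp;
}

// [[Rcpp::export]]
List si_stats(SEXP xp_) {
  XPtr<SeedIndex> xp(xp_);
  return List::create(_["k"] = xp->k,
                      _["n_kmers"] = (double)xp->map.size(),
                      _["n_positions"] = (double)xp->n_positions,
                      _["chroms"] = wrap(xp->names));
}

// [[Rcpp::export]]
DataFrame si_query(SEXP xp_, std::string kmer) {
  XPtr<SeedIndex> xp(xp_);
  std::vector<int> chrom;
  std::vector<double> pos;
  uint64_t code;
  if ((int)kmer.size() == xp->k && encode_kmer(kmer, 0, xp->k, code)) {
    auto it = xp->map.find(code);
    if (it != xp->map.end()) {
      for (uint64_t e : it->second) {
        chrom.push_back(pos_chrom(e) + 1);
        pos.push_back((double)pos_off(e));
      }
    }
  }
  return DataFrame::create(_["chrom"] = chrom, _["pos"] = pos);
}

static inline const std::vector<uint64_t>* lookup(const SeedIndex* si,
                                                  const std::string& read,
                                                  size_t at) {
  uint64_t code;
  if (!encode_kmer(read, at, si->k, code)) return nullptr;
  auto it = si->map.find(code);
  if (it == si->map.end()) return nullptr;
  return &it->second;
}

// Hamming distance with early exit; returns cap+1 if exceeded or out of range.
static int hamming_at(const std::string& g, long long pos,
                      const std::string& r, size_t rfrom, size_t rlen, int cap) {
  if (pos < 0 || pos + (long long)rlen > (long long)g.size()) return cap + 1;
  int mm = 0;
  for (size_t i = 0; i < rlen; ++i) {
    if (g[pos + i] != r[rfrom + i] && ++mm > cap) return cap + 1;
  }
  return mm;
}

struct ContigHit { int chrom; long long pos; int strand; int mm; };

// Collect candidate contiguous placements of a read (both strands) seeded by
// its first-k and last-k k-mers, verify by full-read Hamming distance.
static void contig_candidates(const SeedIndex* si, const std::string& read,
                              int max_mm, std::vector<ContigHit>& out) {
  size_t L = read.size();
  const std::string strands[2] = { read, revcomp(read) };
  for (int st = 0; st < 2; ++st) {
    const std::string& r = strands[st];
    std::vector<long long> starts[2];
    const std::vector<uint64_t>* h1 = lookup(si, r, 0);
    const std::vector<uint64_t>* h2 = lookup(si, r, L - si->k);
    std::vector<std::pair<int, long long>> cands;
    if (h1) for (uint64_t e : *h1) cands.push_back({pos_chrom(e), pos_off(e)});
    if (h2) for (uint64_t e : *h2)
      cands.push_back({pos_chrom(e), pos_off(e) - (long long)(L - si->k)});
    for (auto& cp : cands) {
      bool dup = false;
      for (auto& o : out)
        if (o.chrom == cp.first && o.pos == cp.second && o.strand == st) { dup = true; break; }
      if (dup) continue;
      int mm = hamming_at(si->seqs[cp.first], cp.second, r, 0, L, max_mm);
      if (mm <= max_mm) out.push_back({cp.first, cp.second, st, mm});
    }
  }
}

// status: 0 = unique best, 1 = mapped but not unique, 2 = no placement
// Uniqueness: exactly one locus at the minimum mismatch count and no second
// locus within +1 mismatch.
static ContigHit map_contig_one(const SeedIndex* si, const std::string& read,
                                int max_mm, int& status) {
  std::vector<ContigHit> hits;
  contig_candidates(si, read, max_mm, hits);
  if (hits.empty()) { status = 2; return {0, 0, 0, 0}; }
  int best = max_mm + 1;
  for (auto& h : hits) best = std::min(best, h.mm);
  int n_best = 0, n_near = 0;
  ContigHit bh = hits[0];
  for (auto& h : hits) {
    if (h.mm == best) { n_best++; bh = h; }
    if (h.mm <= best + 1) n_near++;
  }
  status = (n_best == 1 && n_near == 1) ? 0 : 1;
  return bh;
}

// [[Rcpp::export]]
DataFrame cpp_map_contiguous(SEXP xp_, CharacterVector reads, int max_mm) {
  XPtr<SeedIndex> xp(xp_);
  int n = reads.size();
  IntegerVector status(n), chrom(n), mm(n);
  NumericVector pos(n);
  CharacterVector strand(n);
  for (int i = 0; i < n; ++i) {
    std::string r = as<std::string>(reads[i]);
    int st;
    ContigHit h = map_contig_one(xp, r, max_mm, st);
    status[i] = st;
    if (st == 0) {
      chrom[i] = h.chrom + 1; pos[i] = (double)h.pos;
      strand[i] = h.strand == 0 ? "+" : "-"; mm[i] = h.mm;
    } else {
      chrom[i] = NA_INTEGER; pos[i] = NA_REAL; strand[i] = NA_STRING; mm[i] = NA_INTEGER;
    }
  }
  return DataFrame::create(_["status"] = status, _["chrom"] = chrom,
                           _["pos"] = pos, _["strand"] = strand, _["mm"] = mm,
                           _["stringsAsFactors"] = false);
}

struct EndHit { int nhits; int chrom; long long pos; };

static EndHit end_map(const SeedIndex* si, const std::string& r, size_t at) {
  const std::vector<uint64_t>* h = lookup(si, r, at);
  if (!h || h->empty()) return {0, -1, -1};
  if (h->size() > 1) return {(int)h->size(), -1, -1};
  return {1, pos_chrom((*h)[0]), pos_off((*h)[0])};
}

// [[Rcpp::export]]
DataFrame cpp_split_map(SEXP xp_, CharacterVector reads) {
  XPtr<SeedIndex> xp(xp_);
  int n = reads.size();
  std::vector<int> read_i, f_n, f_chrom, l_n, l_chrom;
  std::vector<double> f_pos, l_pos;
  std::vector<std::string> orient;
  for (int i = 0; i < n; ++i) {
    std::string r0 = as<std::string>(reads[i]);
    for (int st = 0; st < 2; ++st) {
      std::string r = st == 0 ? r0 : revcomp(r0);
      if ((int)r.size() < xp->k) continue;
      EndHit f = end_map(xp, r, 0);
      EndHit l = end_map(xp, r, r.size() - xp->k);
      read_i.push_back(i + 1);
      orient.push_back(st == 0 ? "+" : "-");
      f_n.push_back(f.nhits); f_chrom.push_back(f.chrom + 1); f_pos.push_back((double)f.pos);
      l_n.push_back(l.nhits); l_chrom.push_back(l.chrom + 1); l_pos.push_back((double)l.pos);
    }
  }
  return DataFrame::create(_["read"] = read_i, _["orient"] = orient,
                           _["first_nhits"] = f_n, _["first_chrom"] = f_chrom, _["first_pos"] = f_pos,
                           _["last_nhits"] = l_n, _["last_chrom"] = l_chrom, _["last_pos"] = l_pos,
                           _["stringsAsFactors"] = false);
}

// Dinucleotide class of an intron placement, checking both strand readings.
// Returns class code 0 = GT-AG, 1 = GC-AG, 2 = control (GT-TC / GC-TC),
// 3 = other, and sets strand ('+' forward reading, '-' reverse reading).
static int place_class(const std::string& g, long long istart, long long iend,
                       char& strand) {
  if (istart < 0 || iend > (long long)g.size() || iend - istart < 4) {
    strand = '+'; return 3;
  }
  char a = g[istart], b = g[istart + 1], c = g[iend - 2], d = g[iend - 1];
  auto cls = [](char a, char b, char c, char d) {
    if (a == 'G' && b == 'T' && c == 'A' && d == 'G') return 0;
    if (a == 'G' && b == 'C' && c == 'A' && d == 'G') return 1;
    if (a == 'G' && b == 'T' && c == 'T' && d == 'C') return 2;
    if (a == 'G' && b == 'C' && c == 'T' && d == 'C') return 2;
    return 3;
  };
  int fwd = cls(a, b, c, d);
  // reverse-strand reading: intron on '-' runs from iend-1 down to istart
  int rev = cls(comp_base(d), comp_base(c), comp_base(b), comp_base(a));
  if (fwd <= rev) { strand = '+'; return fwd; }
  strand = '-'; return rev;
}

struct Cand {
  int chrom; long long istart, iend;  // placement as found
  int bp, mm, nplace;
  long long can_istart, can_iend;     // canonical placement
  int cls; char strand;
};

// Enumerate the shift-equivalence class of a placement and choose the
// canonical shift. shifts s must keep the breakpoint inside the read:
// bp + s in [1, L-1]; equivalence requires g[istart+t] == g[iend+t]
// (resp. backwards) so that the reconstructed sequence is unchanged.
static void shift_equiv(const std::string& g, long long istart, long long iend,
                        int bp, int L, Cand& out) {
  int vcap = (L - 1) - bp, ucap = bp - 1;
  int v = 0, u = 0;
  while (v < vcap && iend + v < (long long)g.size() &&
         g[istart + v] == g[iend + v]) ++v;
  while (u < ucap && istart - u - 1 >= 0 &&
         g[istart - u - 1] == g[iend - u - 1]) ++u;
  int best_cls = 99; char best_strand = '+'; long long bs = 0;
  for (int s = -u; s <= v; ++s) {
    char strand;
    int cl = place_class(g, istart + s, iend + s, strand);
    if (cl < best_cls) { best_cls = cl; best_strand = strand; bs = s; }
  }
  out.nplace = u + v + 1;
  out.cls = best_cls;
  out.strand = best_strand;
  out.can_istart = istart + bs;
  out.can_iend = iend + bs;
}

// Enumerate all splice junctions consistent with uniquely mapped first/last
// ends of an (oriented) read; keep the minimum-mismatch breakpoints.
static void enum_junctions(const SeedIndex* si, const std::string& r,
                           int chrom_f, long long p, int chrom_l, long long q,
                           int min_ov, int max_mm, int min_intron, int max_intron,
                           std::vector<Cand>& out) {
  int L = (int)r.size(), k = si->k;
  if (chrom_f != chrom_l) return;
  long long ilen = (q - p) - (long long)(L - k);
  if (ilen < min_intron || ilen > max_intron) return;
  const std::string& g = si->seqs[chrom_f];
  long long right_end = q + k;
  int best = max_mm + 1;
  std::vector<std::pair<int, int>> keep;  // (bp, mm)
  for (int b = min_ov; b <= L - min_ov; ++b) {
    long long rs = right_end - (long long)(L - b);
    int mm = hamming_at(g, p, r, 0, b, max_mm);
    if (mm > max_mm) continue;
    int mm2 = hamming_at(g, rs, r, b, L - b, max_mm - mm);
    if (mm + mm2 > max_mm) continue;
    int tot = mm + mm2;
    if (tot < best) { best = tot; keep.clear(); }
    if (tot == best) keep.push_back({b, tot});
  }
  for (auto& km : keep) {
    Cand c;
    c.chrom = chrom_f;
    c.istart = p + km.first;
    c.iend = right_end - (long long)(L - km.first);
    c.bp = km.first; c.mm = km.second;
    shift_equiv(g, c.istart, c.iend, c.bp, L, c);
    out.push_back(c);
  }
}

// Extend-and-search: one end mapped uniquely; extend without mismatches,
// then search for a unique perfect match to the remainder within the intron
// length window. which_end: 0 = first k bases mapped, 1 = last k bases.
static bool extend_search(const SeedIndex* si, const std::string& r,
                          int which_end, int chrom, long long pos,
                          int min_ov, int min_intron, int max_intron,
                          Cand& out) {
  const std::string& g = si->seqs[chrom];
  int L = (int)r.size(), k = si->k;
  long long gl = (long long)g.size();
  if (which_end == 0) {
    // verify seed then extend right
    if (hamming_at(g, pos, r, 0, k, 0) != 0) return false;
    int m = k;
    while (m < L && pos + m < gl && g[pos + m] == r[m]) ++m;
    int rem = L - m;
    if (rem < min_ov || m > L - min_ov) return false;
    long long a = pos + m;  // intron start
    long long lo = a + min_intron, hi = std::min(a + max_intron, gl - (long long)rem);
    long long hit = -1; int nhit = 0;
    for (long long rs = lo; rs <= hi; ++rs) {
      if (hamming_at(g, rs, r, m, rem, 0) == 0) {
        if (++nhit > 1) return false;
        hit = rs;
      }
    }
    if (nhit != 1) return false;
    out.chrom = chrom; out.istart = a; out.iend = hit; out.bp = m; out.mm = 0;
    shift_equiv(g, out.istart, out.iend, out.bp, L, out);
    return true;
  } else {
    if (hamming_at(g, pos, r, L - k, k, 0) != 0) return false;
    int m = k;  // matched suffix length
    while (m < L && pos + k - m - 1 >= 0 && g[pos + k - m - 1] == r[L - m - 1]) ++m;
    int rem = L - m;
    if (rem < min_ov || m > L - min_ov) return false;
    long long e = pos + k - m;  // intron end (exclusive)
    long long lo = std::max((long long)0, e - max_intron - rem);
    long long hi = e - min_intron - rem;
    long long hit = -1; int nhit = 0;
    for (long long ls = lo; ls <= hi; ++ls) {
      if (hamming_at(g, ls, r, 0, rem, 0) == 0) {
        if (++nhit > 1) return false;
        hit = ls;
      }
    }
    if (nhit != 1) return false;
    out.chrom = chrom; out.istart = hit + rem; out.iend = e; out.bp = rem; out.mm = 0;
    shift_equiv(g, out.istart, out.iend, out.bp, L, out);
    return true;
  }
}

// [[Rcpp::export]]
DataFrame cpp_enumerate_junctions(SEXP xp_, std::string read,
                                  int chrom_f, double pos_f,
                                  int chrom_l, double pos_l,
                                  int min_ov, int max_mm,
                                  int min_intron, int max_intron) {
  XPtr<SeedIndex> xp(xp_);
  std::vector<Cand> cands;
  enum_junctions(xp, read, chrom_f - 1, (long long)pos_f, chrom_l - 1,
                 (long long)pos_l, min_ov, max_mm, min_intron, max_intron, cands);
  int n = (int)cands.size();
  IntegerVector chrom(n), bp(n), mm(n), nplace(n), cls(n);
  NumericVector istart(n), iend(n), cistart(n), ciend(n);
  CharacterVector strand(n);
  for (int i = 0; i < n; ++i) {
    chrom[i] = cands[i].chrom + 1;
    istart[i] = (double)cands[i].istart; iend[i] = (double)cands[i].iend;
    cistart[i] = (double)cands[i].can_istart; ciend[i] = (double)cands[i].can_iend;
    bp[i] = cands[i].bp; mm[i] = cands[i].mm; nplace[i] = cands[i].nplace;
    cls[i] = cands[i].cls; strand[i] = std::string(1, cands[i].strand);
  }
  return DataFrame::create(_["chrom"] = chrom, _["istart"] = istart, _["iend"] = iend,
                           _["can_istart"] = cistart, _["can_iend"] = ciend,
                           _["breakpoint"] = bp, _["mm"] = mm,
                           _["n_placements"] = nplace, _["class_code"] = cls,
                           _["strand"] = strand, _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
DataFrame cpp_extend_search(SEXP xp_, std::string read, int which_end,
                            int chrom, double pos, int min_ov,
                            int min_intron, int max_intron) {
  XPtr<SeedIndex> xp(xp_);
  Cand c;
  bool ok = extend_search(xp, read, which_end, chrom - 1, (long long)pos,
                          min_ov, min_intron, max_intron, c);
  if (!ok) {
    return DataFrame::create(_["chrom"] = IntegerVector(0),
                             _["istart"] = NumericVector(0),
                             _["iend"] = NumericVector(0));
  }
  return DataFrame::create(_["chrom"] = c.chrom + 1,
                           _["istart"] = (double)c.istart, _["iend"] = (double)c.iend,
                           _["can_istart"] = (double)c.can_istart,
                           _["can_iend"] = (double)c.can_iend,
                           _["breakpoint"] = c.bp, _["mm"] = c.mm,
                           _["n_placements"] = c.nplace, _["class_code"] = c.cls,
                           _["strand"] = std::string(1, c.strand),
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
List cpp_shift_equivalence(SEXP xp_, int chrom, double istart, double iend,
                           int breakpoint, int read_length) {
  XPtr<SeedIndex> xp(xp_);
  const std::string& g = xp->seqs[chrom - 1];
  Cand c; c.istart = (long long)istart; c.iend = (long long)iend;
  shift_equiv(g, c.istart, c.iend, breakpoint, read_length, c);
  // recompute the raw shift bounds for reporting
  int vcap = (read_length - 1) - breakpoint, ucap = breakpoint - 1;
  int v = 0, u = 0;
  long long a = (long long)istart, e = (long long)iend;
  while (v < vcap && e + v < (long long)g.size() && g[a + v] == g[e + v]) ++v;
  while (u < ucap && a - u - 1 >= 0 && g[a - u - 1] == g[e - u - 1]) ++u;
  IntegerVector shifts(u + v + 1);
  CharacterVector dinuc(u + v + 1);
  for (int s = -u; s <= v; ++s) {
    shifts[s + u] = s;
    std::string d;
    d += g[a + s]; d += g[a + s + 1]; d += '-'; d += g[e + s - 2]; d += g[e + s - 1];
    dinuc[s + u] = d;
  }
  return List::create(_["shifts"] = shifts, _["dinucleotides"] = dinuc,
                      _["can_istart"] = (double)c.can_istart,
                      _["can_iend"] = (double)c.can_iend,
                      _["class_code"] = c.cls,
                      _["strand"] = std::string(1, c.strand),
                      _["n_placements"] = c.nplace);
}

// Full discovery driver. Returns per-read status and tables of contiguous
// alignments and junction candidates.
// status codes: 0 contiguous unique, 1 contiguous multi, 2 short-read
// both-ends-unique discard, 3 junction candidate(s), 4 no placement.
// [[Rcpp::export]]
List cpp_discover(SEXP xp_, CharacterVector reads, int max_mm, int min_ov,
                  int min_intron, int max_intron, bool discard_short_both) {
  XPtr<SeedIndex> xp(xp_);
  int n = reads.size(), k = xp->k;
  IntegerVector status(n);
  std::vector<int> c_read, c_chrom, c_mm; std::vector<double> c_pos;
  std::vector<std::string> c_strand;
  std::vector<int> j_read, j_chrom, j_bp, j_mm, j_np, j_cls;
  std::vector<double> j_istart, j_iend;
  std::vector<std::string> j_strand;
  for (int i = 0; i < n; ++i) {
    std::string r0 = as<std::string>(reads[i]);
    int L = (int)r0.size();
    if (L < k) { status[i] = 4; continue; }
    int st;
    ContigHit h = map_contig_one(xp, r0, max_mm, st);
    if (st == 0) {
      status[i] = 0;
      c_read.push_back(i + 1); c_chrom.push_back(h.chrom + 1);
      c_pos.push_back((double)h.pos);
      c_strand.push_back(h.strand == 0 ? "+" : "-"); c_mm.push_back(h.mm);
      continue;
    }
    if (st == 1) { status[i] = 1; continue; }
    // junction search, both read orientations
    std::vector<Cand> cands;
    bool short_discard = false;
    for (int ori = 0; ori < 2; ++ori) {
      std::string r = ori == 0 ? r0 : revcomp(r0);
      EndHit f = end_map(xp, r, 0);
      EndHit l = end_map(xp, r, L - k);
      if (f.nhits == 1 && l.nhits == 1) {
        if (L < 40) {
          if (discard_short_both) { short_discard = true; continue; }
          // alternative reading: discard only if consistent with a
          // contiguous alignment
          if (f.chrom == l.chrom && l.pos == f.pos + (long long)(L - k)) {
            short_discard = true; continue;
          }
        }
        enum_junctions(xp, r, f.chrom, f.pos, l.chrom, l.pos,
                       min_ov, max_mm, min_intron, max_intron, cands);
      } else if (f.nhits == 1 || l.nhits == 1) {
        Cand c;
        bool ok;
        if (f.nhits == 1)
          ok = extend_search(xp, r, 0, f.chrom, f.pos, min_ov, min_intron,
                             max_intron, c);
        else
          ok = extend_search(xp, r, 1, l.chrom, l.pos, min_ov, min_intron,
                             max_intron, c);
        if (ok) cands.push_back(c);
      }
    }
    if (cands.empty()) { status[i] = short_discard ? 2 : 4; continue; }
    // keep global minimum-mismatch candidates, dedupe by canonical interval
    int best = max_mm + 1;
    for (auto& c : cands) best = std::min(best, c.mm);
    status[i] = 3;
    std::vector<std::pair<long long, long long>> seen;
    for (auto& c : cands) {
      if (c.mm != best) continue;
      bool dup = false;
      for (auto& s : seen)
        if (s.first == ((long long)c.chrom << 42) + c.can_istart && s.second == c.can_iend) { dup = true; break; }
      if (dup) continue;
      seen.push_back({((long long)c.chrom << 42) + c.can_istart, c.can_iend});
      j_read.push_back(i + 1); j_chrom.push_back(c.chrom + 1);
      j_istart.push_back((double)c.can_istart); j_iend.push_back((double)c.can_iend);
      j_bp.push_back(c.bp); j_mm.push_back(c.mm); j_np.push_back(c.nplace);
      j_cls.push_back(c.cls); j_strand.push_back(std::string(1, c.strand));
    }
  }
  DataFrame contig = DataFrame::create(
      _["read"] = wrap(c_read), _["chrom"] = wrap(c_chrom), _["pos"] = wrap(c_pos),
      _["strand"] = wrap(c_strand), _["mm"] = wrap(c_mm),
      _["stringsAsFactors"] = false);
  DataFrame junc = DataFrame::create(
      _["read"] = wrap(j_read), _["chrom"] = wrap(j_chrom),
      _["istart"] = wrap(j_istart), _["iend"] = wrap(j_iend),
      _["breakpoint"] = wrap(j_bp), _["mm"] = wrap(j_mm),
      _["n_placements"] = wrap(j_np), _["class_code"] = wrap(j_cls),
      _["strand"] = wrap(j_strand), _["stringsAsFactors"] = false);
  return List::create(_["status"] = status, _["contiguous"] = contig,
                      _["candidates"] = junc);
}
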