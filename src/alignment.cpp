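// Seed-chain-extend local aligner: exact k-mer seeds on both subject strands,
// banded affine (Gotoh) gapped extension with an x-drop termination rule,
// identities recomputed from the traceback. Coordinates are 0-based half-open
// on the forward strand of each sequence.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static const int NEG_INF = INT_MIN / 4;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return 4; // ambiguous: never matches, including N vs N
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) {
    switch (r[i]) {
      case 'A': r[i] = 'T'; break;
      case 'C': r[i] = 'G'; break;
      case 'G': r[i] = 'C'; break;
      case 'T': r[i] = 'A'; break;
      default:  r[i] = 'N'; break;
    }
  }
  return r;
}

typedef std::unordered_map<uint64_t, std::vector<int> > kmer_map;

static void build_map(const std::string& s, int k, kmer_map& m) {
  const int n = (int) s.size();
  if (k > n) return;
  uint64_t code = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int run = 0; // valid-base run length
  for (int i = 0; i < n; ++i) {
    int b = base_code(s[i]);
    if (b > 3) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t) b) & mask;
    if (++run >= k) m[code].push_back(i - k + 1);
  }
}

struct KmerIndex {
  std::string fwd, rc;
  int k;
  kmer_map fwd_map, rc_map;
};

// [[Rcpp::export]]
SEXP cpp_index_build(std::string subject, int k) {
  KmerIndex* idx = new KmerIndex();
  idx->fwd = subject;
  idx->rc = revcomp(subject);
  idx->k = k;
  build_map(idx->fwd, k, idx->fwd_map);
  build_map(idx->rc, k, idx->rc_map);
  XPtr<KmerIndex> p(idx, true);
  return p;
}

// [[Rcpp::export]]
List cpp_index_lookup(SEXP ptr, std::string kmer) {
  XPtr<KmerIndex> idx(ptr);
  uint64_t code = 0;
  for (size_t i = 0; i < kmer.size(); ++i) {
    int b = base_code(kmer[i]);
    if (b > 3) return List::create(_["fwd"] = IntegerVector(0),
                                   _["rc"] = IntegerVector(0));
    code = (code << 2) | (uint64_t) b;
  }
  IntegerVector f, r;
  kmer_map::const_iterator it = idx->fwd_map.find(code);
  if (it != idx->fwd_map.end()) f = wrap(it->second);
  it = idx->rc_map.find(code);
  if (it != idx->rc_map.end()) r = wrap(it->second);
  return List::create(_["fwd"] = f, _["rc"] = r);
}

// [[Rcpp::export]]
int cpp_index_size(SEXP ptr) {
  XPtr<KmerIndex> idx(ptr);
  return (int) idx->fwd_map.size();
}

struct ExtResult {
  int score;      // best score gained beyond the anchor
  int dq, ds;     // query / subject characters consumed at the best cell
  int identities; // identical aligned columns in the extension
  int alnlen;     // alignment columns in the extension
};

struct Scheme {
  int match, mismatch, gap_open, gap_extend, x_drop;
};

// Banded Gotoh extension with x-drop. q/s point at the first character past
// the anchor (already reversed for leftward extension).
static ExtResult xdrop_extend(const char* q, int qn, const char* s, int sn,
                              const Scheme& sc) {
  ExtResult res; res.score = 0; res.dq = 0; res.ds = 0;
  res.identities = 0; res.alnlen = 0;
  if (qn <= 0 || sn <= 0) return res;
  const int W = sc.x_drop / std::max(1, -sc.gap_extend) + 2;
  const int BW = 2 * W + 1;
  const int go = sc.gap_open, ge = sc.gap_extend, xd = sc.x_drop;

  std::vector<int> Mprev(BW, NEG_INF), Xprev(BW, NEG_INF), Yprev(BW, NEG_INF);
  std::vector<int> Mcur(BW, NEG_INF), Xcur(BW, NEG_INF), Ycur(BW, NEG_INF);
  // traceback: bits 0-1 source of M (0 diagM,1 diagX,2 diagY),
  // bit 2 X from extend, bit 3 Y from extend
  std::vector<std::vector<uint8_t> > tb;

  // row 0: start cell at offset W plus leading subject-only gaps
  Mprev[W] = 0;
  tb.push_back(std::vector<uint8_t>(BW, 0));
  for (int c = W + 1; c < BW; ++c) {
    int b = c - W;
    if (b > sn) break;
    Yprev[c] = (c == W + 1) ? (Mprev[W] + go + ge) : (Yprev[c - 1] + ge);
    if (c > W + 1) tb[0][c] |= 8;
    if (Yprev[c] < -xd) { Yprev[c] = NEG_INF; break; }
  }

  int best = 0, best_a = 0, best_c = W;
  for (int a = 1; a <= qn; ++a) {
    std::fill(Mcur.begin(), Mcur.end(), NEG_INF);
    std::fill(Xcur.begin(), Xcur.end(), NEG_INF);
    std::fill(Ycur.begin(), Ycur.end(), NEG_INF);
    tb.push_back(std::vector<uint8_t>(BW, 0));
    std::vector<uint8_t>& tbr = tb[a];
    int row_best = NEG_INF;
    for (int c = 0; c < BW; ++c) {
      int b = a + c - W; // subject chars consumed
      if (b < 0 || b > sn) continue;
      if (b >= 1) {
        // diagonal move into M
        int m0 = Mprev[c], m1 = Xprev[c], m2 = Yprev[c];
        int src = 0, v = m0;
        if (m1 > v) { v = m1; src = 1; }
        if (m2 > v) { v = m2; src = 2; }
        if (v > NEG_INF) {
          int bq = base_code(q[a - 1]), bs = base_code(s[b - 1]);
          int subst = (bq == bs && bq < 4) ? sc.match : sc.mismatch;
          Mcur[c] = v + subst;
          tbr[c] |= (uint8_t) src;
        }
      }
      // gap in subject (consume query only): from (a-1, b) = prev row, c+1
      if (c + 1 < BW) {
        int vo = (Mprev[c + 1] > NEG_INF) ? Mprev[c + 1] + go + ge : NEG_INF;
        int vx = (Xprev[c + 1] > NEG_INF) ? Xprev[c + 1] + ge : NEG_INF;
        if (vx > vo) { Xcur[c] = vx; tbr[c] |= 4; }
        else Xcur[c] = vo;
      }
      // gap in query (consume subject only): from (a, b-1) = same row, c-1
      if (c >= 1 && b >= 1) {
        int vo = (Mcur[c - 1] > NEG_INF) ? Mcur[c - 1] + go + ge : NEG_INF;
        int vy = (Ycur[c - 1] > NEG_INF) ? Ycur[c - 1] + ge : NEG_INF;
        if (vy > vo) { Ycur[c] = vy; tbr[c] |= 8; }
        else Ycur[c] = vo;
      }
      if (Mcur[c] > row_best) row_best = Mcur[c];
      if (Mcur[c] > best) { best = Mcur[c]; best_a = a; best_c = c; }
    }
    if (row_best < best - xd) break; // x-drop termination
    // prune cells too far below the running best
    for (int c = 0; c < BW; ++c) {
      if (Mcur[c] < best - xd) Mcur[c] = NEG_INF;
      if (Xcur[c] < best - xd) Xcur[c] = NEG_INF;
      if (Ycur[c] < best - xd) Ycur[c] = NEG_INF;
    }
    Mprev.swap(Mcur); Xprev.swap(Xcur); Yprev.swap(Ycur);
  }

  if (best <= 0) return res;
  // traceback from (best_a, best_c) in M
  int a = best_a, c = best_c, state = 0; // 0=M,1=X,2=Y
  int ident = 0, alen = 0;
  while (!(a == 0 && c == W && state == 0)) {
    if (state == 0) {
      int src = tb[a][c] & 3;
      int b = a + c - W;
      int bq = base_code(q[a - 1]), bs = base_code(s[b - 1]);
      if (bq == bs && bq < 4) ++ident;
      ++alen;
      --a; state = src;
    } else if (state == 1) { // X: consumed query only
      int ext = tb[a][c] & 4;
      ++alen;
      --a; ++c;
      state = ext ? 1 : 0;
    } else { // Y: consumed subject only
      int ext = tb[a][c] & 8;
      ++alen;
      --c;
      state = ext ? 2 : 0;
    }
  }
  res.score = best;
  res.dq = best_a;
  res.ds = best_a + best_c - W;
  res.identities = ident;
  res.alnlen = alen;
  return res;
}

struct Hsp {
  int qs, qe, ss, se; // on the strand searched (rc coords for minus)
  bool minus;
  int ident, alen, raw;
};

static void find_on_strand(const std::string& q, const std::string& s,
                           const kmer_map& map, int k, const Scheme& sc,
                           bool minus, std::vector<Hsp>& out) {
  const int qn = (int) q.size(), sn = (int) s.size();
  if (k > qn || k > sn) return;
  const int W = sc.x_drop / std::max(1, -sc.gap_extend) + 2;
  uint64_t code = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int run = 0;
  std::string qrev(q.rbegin(), q.rend()); // for leftward extension
  std::string srev(s.rbegin(), s.rend());
  for (int i = 0; i < qn; ++i) {
    int bch = base_code(q[i]);
    if (bch > 3) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t) bch) & mask;
    if (++run < k) continue;
    kmer_map::const_iterator it = map.find(code);
    if (it == map.end()) continue;
    int qpos = i - k + 1;
    for (size_t h = 0; h < it->second.size(); ++h) {
      int spos = it->second[h];
      int diag = qpos - spos;
      bool covered = false;
      for (size_t e = 0; e < out.size(); ++e) {
        const Hsp& x = out[e];
        if (x.minus != minus) continue;
        if (qpos >= x.qs && qpos + k <= x.qe &&
            spos >= x.ss && spos + k <= x.se &&
            std::abs(diag - (x.qs - x.ss)) <= W) { covered = true; break; }
      }
      if (covered) continue;
      // rightward extension past the anchor
      ExtResult r = xdrop_extend(q.c_str() + qpos + k, qn - qpos - k,
                                 s.c_str() + spos + k, sn - spos - k, sc);
      // leftward extension on reversed prefixes
      ExtResult l = xdrop_extend(qrev.c_str() + (qn - qpos), qpos,
                                 srev.c_str() + (sn - spos), spos, sc);
      Hsp hd;
      hd.qs = qpos - l.dq; hd.qe = qpos + k + r.dq;
      hd.ss = spos - l.ds; hd.se = spos + k + r.ds;
      hd.minus = minus;
      hd.ident = k + l.identities + r.identities;
      hd.alen = k + l.alnlen + r.alnlen;
      hd.raw = k * sc.match + l.score + r.score;
      out.push_back(hd);
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_find_hsps(std::string query, SEXP ptr, List scheme) {
  XPtr<KmerIndex> idx(ptr);
  Scheme sc;
  sc.match = as<int>(scheme["match_reward"]);
  sc.mismatch = as<int>(scheme["mismatch_penalty"]);
  sc.gap_open = as<int>(scheme["gap_open"]);
  sc.gap_extend = as<int>(scheme["gap_extend"]);
  sc.x_drop = as<int>(scheme["x_drop"]);
  int k = idx->k;

  std::vector<Hsp> hs;
  find_on_strand(query, idx->fwd, idx->fwd_map, k, sc, false, hs);
  find_on_strand(query, idx->rc, idx->rc_map, k, sc, true, hs);

  const int sn = (int) idx->fwd.size();
  // convert minus-strand coords to forward-strand coords of the subject
  for (size_t i = 0; i < hs.size(); ++i) {
    if (hs[i].minus) {
      int ss = sn - hs[i].se, se = sn - hs[i].ss;
      hs[i].ss = ss; hs[i].se = se;
    }
  }
  // same-diagonal overlap rule: keep only the higher-scoring HSP when two
  // overlap on the same (strand, diagonal); also drops exact duplicates
  std::vector<int> ord(hs.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int) i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (hs[a].raw != hs[b].raw) return hs[a].raw > hs[b].raw;
    if (hs[a].qs != hs[b].qs) return hs[a].qs < hs[b].qs;
    return hs[a].ss < hs[b].ss;
  });
  std::vector<Hsp> kept;
  for (size_t oi = 0; oi < ord.size(); ++oi) {
    const Hsp& h = hs[ord[oi]];
    bool drop = false;
    for (size_t j = 0; j < kept.size(); ++j) {
      const Hsp& x = kept[j];
      if (x.minus != h.minus) continue;
      bool qov = h.qs < x.qe && x.qs < h.qe;
      bool sov = h.ss < x.se && x.ss < h.se;
      if (qov && sov && (h.qs - h.ss) == (x.qs - x.ss)) { drop = true; break; }
    }
    if (!drop) kept.push_back(h);
  }

  int n = (int) kept.size();
  IntegerVector qs(n), qe(n), ss(n), se(n), id(n), al(n), raw(n);
  CharacterVector strand(n);
  for (int i = 0; i < n; ++i) {
    qs[i] = kept[i].qs; qe[i] = kept[i].qe;
    ss[i] = kept[i].ss; se[i] = kept[i].se;
    id[i] = kept[i].ident; al[i] = kept[i].alen; raw[i] = kept[i].raw;
    strand[i] = kept[i].minus ? "-" : "+";
  }
  return DataFrame::create(
    _["query_start"] = qs, _["query_end"] = qe,
    _["subject_start"] = ss, _["subject_end"] = se,
    _["strand"] = strand,
    _["alignment_length"] = al, _["identities"] = id,
    _["raw_score"] = raw,
    _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return revcomp(s); }
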