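// Minimizer index and colinear anchor chaining for containment detection.
// Anchors are shared canonical minimizers; chains are built by a bounded
// longest-colinear-subsequence DP; identity is estimated from exact base
// matches inside chains (anchor bases plus direct comparison across the
// gaps between consecutive anchors along their local diagonal).

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <array>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

struct Posting {
  uint32_t seq;
  uint32_t pos;    // 0-based start of the k-mer on the forward strand
  uint8_t strand;  // 0: forward k-mer is canonical, 1: reverse complement is
};

struct MinimizerIndex {
  int k, w;
  std::unordered_map<uint64_t, std::vector<Posting>> idx;
  std::vector<std::string> ids;
  std::vector<std::string> seqs;
};

static inline int mcode(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

static inline char mcomp(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

// splitmix64 finalizer; decorrelates minimizer choice from base composition
static inline uint64_t hash64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

struct Mini {
  uint64_t code;
  uint32_t pos;
  uint8_t strand;
};

// Canonical minimizers of one sequence: per window of w consecutive k-mers
// the k-mer with the smallest hashed canonical code (leftmost on ties).
static std::vector<Mini> minimizers_of(const std::string &s, int k, int w) {
  std::vector<Mini> out;
  size_t n = s.size();
  if ((int)n < k) return out;
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int shift = 2 * (k - 1);
  std::vector<uint64_t> codes, hashes;
  std::vector<uint32_t> poss;
  std::vector<uint8_t> strands;
  uint64_t fwd = 0, rc = 0;
  int run = 0;
  auto flush = [&]() {
    size_t m = codes.size();
    if (m == 0) return;
    size_t nwin = m >= (size_t)w ? m - w + 1 : 1;
    size_t wlen = std::min<size_t>(w, m);
    long last = -1;
    for (size_t j = 0; j < nwin; ++j) {
      size_t best = j;
      for (size_t x = j + 1; x < j + wlen; ++x)
        if (hashes[x] < hashes[best]) best = x;
      if ((long)best != last) {
        out.push_back({codes[best], poss[best], strands[best]});
        last = (long)best;
      }
    }
    codes.clear(); hashes.clear(); poss.clear(); strands.clear();
  };
  for (size_t i = 0; i < n; ++i) {
    int c = mcode(s[i]);
    if (c < 0) { run = 0; fwd = 0; rc = 0; flush(); continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - c) << shift);
    if (++run >= k) {
      uint64_t canon = std::min(fwd, rc);
      codes.push_back(canon);
      hashes.push_back(hash64(canon));
      poss.push_back((uint32_t)(i + 1 - k));
      strands.push_back(fwd <= rc ? 0 : 1);
    }
  }
  flush();
  return out;
}

// [[Rcpp::export]]
SEXP mz_build(CharacterVector ids, CharacterVector seqs, int k, int w) {
  MinimizerIndex *mi = new MinimizerIndex();
  mi->k = k;
  mi->w = w;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    mi->ids.push_back(as<std::string>(ids[i]));
    mi->seqs.push_back(as<std::string>(seqs[i]));
    std::vector<Mini> ms = minimizers_of(mi->seqs.back(), k, w);
    for (const Mini &m : ms)
      mi->idx[m.code].push_back({(uint32_t)i, m.pos, m.strand});
  }
  XPtr<MinimizerIndex> ptr(mi, true);
  return ptr;
}

// [[Rcpp::export]]
List mz_params(SEXP mi_) {
  XPtr<MinimizerIndex> mi(mi_);
  NumericVector lens(mi->ids.size());
  for (size_t i = 0; i < mi->seqs.size(); ++i) lens[i] = (double)mi->seqs[i].size();
  return List::create(_["k"] = mi->k, _["w"] = mi->w,
                      _["ids"] = wrap(mi->ids), _["lengths"] = lens);
}

static std::string decode_mz(uint64_t code, int k) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) { s[i] = bases[code & 3ULL]; code >>= 2; }
  return s;
}

// [[Rcpp::export]]
DataFrame mz_export(SEXP mi_) {
  XPtr<MinimizerIndex> mi(mi_);
  std::vector<uint64_t> keys;
  for (const auto &kv : mi->idx) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  std::vector<std::string> kmer, id, strand;
  std::vector<int> pos;
  for (uint64_t key : keys) {
    for (const Posting &p : mi->idx.at(key)) {
      kmer.push_back(decode_mz(key, mi->k));
      id.push_back(mi->ids[p.seq]);
      pos.push_back((int)p.pos);
      strand.push_back(p.strand ? "-" : "+");
    }
  }
  return DataFrame::create(_["kmer"] = wrap(kmer), _["id"] = wrap(id),
                           _["pos"] = wrap(pos), _["strand"] = wrap(strand),
                           _["stringsAsFactors"] = false);
}

struct Anchor { uint32_t q, t; };

struct Chain {
  std::vector<Anchor> anchors; // sorted by query position
  uint32_t qs, qe, ts, te;     // half-open spans (qe/te include k)
};

// target base accessor on the strand the chain lives on; y is a coordinate
// on the reverse complement when rev is true
static inline char tgt_at(const std::string &t, size_t y, bool rev) {
  return rev ? mcomp(t[t.size() - 1 - y]) : t[y];
}

// [[Rcpp::export]]
DataFrame mz_find(SEXP mi_, std::string query_id, std::string query_seq,
                  int min_chain_anchors, bool only_longer, int max_occ,
                  int band, int max_chain_gap, int merge_gap) {
  XPtr<MinimizerIndex> mi(mi_);
  const int k = mi->k;
  const size_t qlen = query_seq.size();

  // anchors grouped by (target, relative strand)
  std::unordered_map<uint64_t, std::vector<Anchor>> groups;
  std::vector<Mini> qms = minimizers_of(query_seq, k, mi->w);
  for (const Mini &m : qms) {
    auto it = mi->idx.find(m.code);
    if (it == mi->idx.end()) continue;
    if ((int)it->second.size() > max_occ) continue;
    for (const Posting &p : it->second) {
      if (mi->ids[p.seq] == query_id) continue;
      size_t tlen = mi->seqs[p.seq].size();
      if (only_longer && tlen <= qlen) continue;
      uint8_t rel = m.strand ^ p.strand;
      // reverse-strand chains run on coordinates of the target's rev comp
      uint32_t tp = rel ? (uint32_t)(tlen - k - p.pos) : p.pos;
      groups[((uint64_t)p.seq << 1) | rel].push_back({m.pos, tp});
    }
  }

  struct Hit { int seq; double identity, qcov, score; int n_chains; };
  std::unordered_map<int, std::vector<Chain>> per_target;

  for (auto &g : groups) {
    int tseq = (int)(g.first >> 1);
    bool rev = (g.first & 1) != 0;
    std::vector<Anchor> &an = g.second;
    if ((int)an.size() < min_chain_anchors) continue;
    std::sort(an.begin(), an.end(), [](const Anchor &a, const Anchor &b) {
      return a.q != b.q ? a.q < b.q : a.t < b.t;
    });
    size_t n = an.size();
    std::vector<int> score(n, 1), parent(n, -1);
    const int lookback = 64;
    for (size_t i = 1; i < n; ++i) {
      size_t j0 = i > (size_t)lookback ? i - lookback : 0;
      for (size_t j = i; j-- > j0;) {
        if (an[j].q >= an[i].q || an[j].t >= an[i].t) continue;
        long dq = (long)an[i].q - (long)an[j].q;
        long dt = (long)an[i].t - (long)an[j].t;
        if (dq > max_chain_gap || dt > max_chain_gap) continue;
        if (std::labs(dq - dt) > band) continue;
        if (score[j] + 1 > score[i]) { score[i] = score[j] + 1; parent[i] = (int)j; }
      }
    }
    std::vector<size_t> order(n);
    for (size_t i = 0; i < n; ++i) order[i] = i;
    std::sort(order.begin(), order.end(), [&](size_t a, size_t b) {
      return score[a] != score[b] ? score[a] > score[b] : a < b;
    });
    std::vector<char> used(n, 0);
    std::vector<Chain> chains;
    for (size_t oi : order) {
      if (used[oi]) continue;
      std::vector<Anchor> ch;
      long cur = (long)oi;
      while (cur >= 0 && !used[cur]) {
        ch.push_back(an[cur]);
        used[cur] = 1;
        cur = parent[cur];
      }
      if ((int)ch.size() < min_chain_anchors) continue;
      std::reverse(ch.begin(), ch.end());
      Chain c;
      c.anchors = ch;
      c.qs = ch.front().q; c.qe = ch.back().q + k;
      c.ts = ch.front().t; c.te = ch.back().t + k;
      chains.push_back(c);
    }
    if (chains.empty()) continue;
    // merge chains separated by < merge_gap on both sequences
    std::sort(chains.begin(), chains.end(),
              [](const Chain &a, const Chain &b) { return a.qs < b.qs; });
    std::vector<Chain> merged;
    for (Chain &c : chains) {
      if (!merged.empty()) {
        Chain &p = merged.back();
        long gq = (long)c.qs - (long)p.qe;
        long gt = (long)c.ts - (long)p.te;
        if (gq > -k && gq < merge_gap && gt > -k && gt < merge_gap) {
          p.anchors.insert(p.anchors.end(), c.anchors.begin(), c.anchors.end());
          std::sort(p.anchors.begin(), p.anchors.end(),
                    [](const Anchor &a, const Anchor &b) { return a.q < b.q; });
          p.qe = std::max(p.qe, c.qe);
          p.te = std::max(p.te, c.te);
          continue;
        }
      }
      merged.push_back(c);
    }
    for (Chain &c : merged) c.ts = rev ? 1 : 0; // reuse field as strand flag
    auto &tv = per_target[tseq];
    tv.insert(tv.end(), merged.begin(), merged.end());
  }

  // score each target: identity over chained spans, union query coverage
  std::vector<Hit> hits;
  for (auto &kv : per_target) {
    int tseq = kv.first;
    const std::string &t = mi->seqs[tseq];
    double matched = 0.0, span = 0.0;
    std::vector<std::pair<uint32_t, uint32_t>> qiv;
    for (const Chain &c : kv.second) {
      bool rev = c.ts != 0;
      const std::vector<Anchor> &a = c.anchors;
      matched += k;
      for (size_t i = 1; i < a.size(); ++i) {
        long dq = (long)a[i].q - (long)a[i - 1].q;
        long dt = (long)a[i].t - (long)a[i - 1].t;
        if (dq <= 0 || dt <= 0) continue; // duplicate/crossing after merge
        if (dq >= k && dt >= k) {
          long gq = dq - k, gt = dt - k, g = std::min(gq, gt);
          long q0 = a[i - 1].q + k, t0 = a[i - 1].t + k;
          for (long x = 0; x < g; ++x)
            if (query_seq[q0 + x] == tgt_at(t, t0 + x, rev)) matched += 1.0;
          matched += k;
        } else {
          long add = std::min(dq, dt) - std::labs(dq - dt);
          matched += add > 0 ? (double)add : 0.0;
        }
      }
      span += (double)(c.qe - c.qs);
      qiv.push_back({c.qs, c.qe});
    }
    std::sort(qiv.begin(), qiv.end());
    double cov = 0.0;
    uint32_t lo = 0, hi = 0;
    bool open = false;
    for (auto &iv : qiv) {
      if (!open || iv.first > hi) {
        if (open) cov += (double)(hi - lo);
        lo = iv.first; hi = iv.second; open = true;
      } else hi = std::max(hi, iv.second);
    }
    if (open) cov += (double)(hi - lo);
    double identity = span > 0 ? std::min(1.0, matched / span) : 0.0;
    double qcov = qlen > 0 ? cov / (double)qlen : 0.0;
    hits.push_back({tseq, identity, qcov, identity * qcov,
                    (int)kv.second.size()});
  }
  std::sort(hits.begin(), hits.end(), [&](const Hit &a, const Hit &b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.identity != b.identity) return a.identity > b.identity;
    return mi->ids[a.seq] < mi->ids[b.seq];
  });
  CharacterVector target(hits.size());
  NumericVector identity(hits.size()), qcov(hits.size());
  IntegerVector nch(hits.size());
  for (size_t i = 0; i < hits.size(); ++i) {
    target[i] = mi->ids[hits[i].seq];
    identity[i] = hits[i].identity;
    qcov[i] = hits[i].qcov;
    nch[i] = hits[i].n_chains;
  }
  return DataFrame::create(_["target_id"] = target, _["identity"] = identity,
                           _["query_coverage"] = qcov, _["n_chains"] = nch,
                           _["stringsAsFactors"] = false);
}
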