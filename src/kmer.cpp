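// Canonical k-mer counting and spectra, the compiled core of the package.
// K-mers with k <= 31 are packed 2 bits/base into a uint64; the canonical
// form is the lexicographic min of a k-mer and its reverse complement
// (A<C<G<T maps to 0<1<2<3, so integer order == lexicographic order).

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

typedef std::unordered_map<uint64_t, uint32_t> KmerMap;

struct KmerTable {
  int k;
  KmerMap counts;
  double n_total; // total k-mer instances (sum of counts)
};

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1; // N or anything else: invalidates the window
  }
}

static std::string decode_kmer(uint64_t code, int k) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = bases[code & 3ULL];
    code >>= 2;
  }
  return s;
}

// Invoke fn(canonical_code) for every N-free window; fn2(is_valid) is
// called once per window position in order (used by the lookup routine).
template <typename F>
static void for_each_canonical(const char *s, size_t n, int k, F fn) {
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rc = 0;
  int run = 0;
  int shift = 2 * (k - 1);
  for (size_t i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - c) << shift);
    if (++run >= k) fn(std::min(fwd, rc));
  }
}

// [[Rcpp::export]]
SEXP kc_build(CharacterVector seqs, int k) {
  KmerTable *tab = new KmerTable();
  tab->k = k;
  tab->n_total = 0.0;
  tab->counts.reserve(1 << 16);
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    size_t n = LENGTH(STRING_ELT(seqs, i));
    for_each_canonical(s, n, k, [&](uint64_t code) {
      ++tab->counts[code];
      tab->n_total += 1.0;
    });
  }
  XPtr<KmerTable> ptr(tab, true);
  return ptr;
}

// [[Rcpp::export]]
List kc_stats(SEXP tab_) {
  XPtr<KmerTable> tab(tab_);
  return List::create(_["k"] = tab->k,
                      _["n_distinct"] = (double)tab->counts.size(),
                      _["n_total"] = tab->n_total);
}

// [[Rcpp::export]]
DataFrame kc_spectrum(SEXP tab_) {
  XPtr<KmerTable> tab(tab_);
  std::unordered_map<uint32_t, double> hist;
  for (const auto &kv : tab->counts) hist[kv.second] += 1.0;
  std::vector<uint32_t> ms;
  ms.reserve(hist.size());
  for (const auto &kv : hist) ms.push_back(kv.first);
  std::sort(ms.begin(), ms.end());
  IntegerVector mult(ms.size());
  NumericVector cnt(ms.size());
  for (size_t i = 0; i < ms.size(); ++i) {
    mult[i] = (int)ms[i];
    cnt[i] = hist[ms[i]];
  }
  return DataFrame::create(_["multiplicity"] = mult, _["count"] = cnt);
}

// Joint histogram of (assembly copy, read multiplicity) over distinct read
// k-mers, plus the count of k-mers present only in the assembly.
// [[Rcpp::export]]
List kc_spectra_cn(SEXP read_, SEXP asm_, int max_copy) {
  XPtr<KmerTable> rt(read_);
  XPtr<KmerTable> at(asm_);
  std::unordered_map<uint64_t, double> cells; // key = copy * 2^32 + mult
  for (const auto &kv : rt->counts) {
    uint32_t m = kv.second;
    uint32_t c = 0;
    auto it = at->counts.find(kv.first);
    if (it != at->counts.end())
      c = std::min<uint32_t>(it->second, (uint32_t)max_copy);
    cells[((uint64_t)c << 32) | (uint64_t)m] += 1.0;
  }
  double asm_only = 0.0;
  for (const auto &kv : at->counts)
    if (rt->counts.find(kv.first) == rt->counts.end()) asm_only += 1.0;
  std::vector<uint64_t> keys;
  keys.reserve(cells.size());
  for (const auto &kv : cells) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  IntegerVector copy(keys.size()), mult(keys.size());
  NumericVector cnt(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    copy[i] = (int)(keys[i] >> 32);
    mult[i] = (int)(keys[i] & 0xffffffffULL);
    cnt[i] = cells[keys[i]];
  }
  return List::create(
      _["cells"] = DataFrame::create(_["copy"] = copy, _["multiplicity"] = mult,
                                     _["count"] = cnt),
      _["assembly_only"] = asm_only);
}

// Per-window counts of one sequence looked up in a table; N-containing
// windows are skipped, so the result has one entry per valid window.
// [[Rcpp::export]]
IntegerVector kc_lookup(SEXP tab_, std::string seq) {
  XPtr<KmerTable> tab(tab_);
  std::vector<int> out;
  for_each_canonical(seq.c_str(), seq.size(), tab->k, [&](uint64_t code) {
    auto it = tab->counts.find(code);
    out.push_back(it == tab->counts.end() ? 0 : (int)it->second);
  });
  return wrap(out);
}

// Full table as (kmer, count), sorted lexicographically. Intended for small
// tables (tests, TSV export); materializes every key as a string.
// [[Rcpp::export]]
DataFrame kc_export(SEXP tab_) {
  XPtr<KmerTable> tab(tab_);
  std::vector<uint64_t> keys;
  keys.reserve(tab->counts.size());
  for (const auto &kv : tab->counts) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  CharacterVector kmer(keys.size());
  NumericVector cnt(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    kmer[i] = decode_kmer(keys[i], tab->k);
    cnt[i] = tab->counts[keys[i]];
  }
  return DataFrame::create(_["kmer"] = kmer, _["count"] = cnt,
                           _["stringsAsFactors"] = false);
}

// Rebuild a table from exported (kmer, count) pairs (TSV import path).
// [[Rcpp::export]]
SEXP kc_from_pairs(CharacterVector kmers, NumericVector counts, int k) {
  KmerTable *tab = new KmerTable();
  tab->k = k;
  tab->n_total = 0.0;
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    const char *s = CHAR(STRING_ELT(kmers, i));
    uint64_t fwd = 0, rc = 0;
    int shift = 2 * (k - 1);
    bool ok = (int)LENGTH(STRING_ELT(kmers, i)) == k;
    for (int j = 0; ok && j < k; ++j) {
      int c = base_code(s[j]);
      if (c < 0) { ok = false; break; }
      fwd = (fwd << 2) | (uint64_t)c;
      rc = (rc >> 2) | ((uint64_t)(3 - c) << shift);
    }
    if (!ok) { delete tab; stop("invalid k-mer at row %d", (int)(i + 1)); }
    tab->counts[std::min(fwd, rc)] += (uint32_t)counts[i];
    tab->n_total += counts[i];
  }
  XPtr<KmerTable> ptr(tab, true);
  return ptr;
}

// Base composition: rows A,C,G,T,other per sequence.
// [[Rcpp::export]]
IntegerMatrix seq_composition(CharacterVector seqs) {
  IntegerMatrix out(seqs.size(), 5);
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    size_t n = LENGTH(STRING_ELT(seqs, i));
    int cnt[5] = {0, 0, 0, 0, 0};
    for (size_t j = 0; j < n; ++j) {
      int c = base_code(s[j]);
      ++cnt[c < 0 ? 4 : c];
    }
    for (int j = 0; j < 5; ++j) out(i, j) = cnt[j];
  }
  colnames(out) = CharacterVector::create("A", "C", "G", "T", "other");
  return out;
}
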