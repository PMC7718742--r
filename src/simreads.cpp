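// Short-read simulator backend. Uses its own mt19937_64 stream with a
// hand-rolled uniform so that output is a pure, platform-stable function
// of the seed.

#include <Rcpp.h>
#include <random>
#include <cstdint>

using namespace Rcpp;

static inline double u01(std::mt19937_64 &rng) {
  return (double)(rng() >> 11) * (1.0 / 9007199254740992.0); // 2^-53
}

// [[Rcpp::export]]
List sim_reads_cpp(CharacterVector haps, CharacterVector hap_names,
                   IntegerVector n_reads, int read_length, double error_rate,
                   double seed) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  std::mt19937_64 rng((uint64_t)seed);
  R_xlen_t total = 0;
  for (R_xlen_t h = 0; h < haps.size(); ++h) total += n_reads[h];
  CharacterVector ids(total), seqs(total);
  R_xlen_t out = 0;
  std::string read;
  for (R_xlen_t h = 0; h < haps.size(); ++h) {
    std::string hap = as<std::string>(haps[h]);
    std::string hname = as<std::string>(hap_names[h]);
    size_t L = hap.size();
    if ((size_t)read_length > L)
      stop("read_length exceeds haplotype length");
    size_t nstart = L - (size_t)read_length + 1;
    for (int i = 0; i < n_reads[h]; ++i) {
      size_t start = (size_t)(u01(rng) * (double)nstart);
      if (start >= nstart) start = nstart - 1;
      read.assign(hap, start, (size_t)read_length);
      if (error_rate > 0) {
        for (int j = 0; j < read_length; ++j) {
          if (u01(rng) < error_rate) {
            int code;
            switch (read[j]) {
              case 'A': code = 0; break;
              case 'C': code = 1; break;
              case 'G': code = 2; break;
              case 'T': code = 3; break;
              default: continue;
            }
            int off = 1 + (int)(u01(rng) * 3.0);
            if (off > 3) off = 3;
            read[j] = bases[(code + off) & 3];
          }
        }
      }
      ids[out] = hname + "_r" + std::to_string(i + 1) + "_" +
                 std::to_string(start);
      seqs[out] = read;
      ++out;
    }
  }
  return List::create(_["id"] = ids, _["seq"] = seqs);
}
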