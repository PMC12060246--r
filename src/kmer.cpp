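#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// 2-bit base encoding; A<C<G<T so numeric order on packed k-mers equals
// lexicographic order on the strings.
static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// splitmix64 finalizer: fixed, platform-independent 64-bit mix
static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// Walk all k-mers of seq, calling f(code) with the (optionally canonical)
// packed encoding of each window that is free of non-ACGT characters.
template <typename F>
static void for_each_kmer(const std::string& seq, int k, bool canonical, F f) {
  const size_t n = seq.size();
  if (n < (size_t)k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rc = 0;
  int valid = 0;  // length of current run of valid bases ending here
  for (size_t i = 0; i < n; ++i) {
    int b = base2bits(seq[i]);
    if (b < 0) { valid = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
    if (++valid >= k) {
      uint64_t code = canonical ? std::min(fwd, rc) : fwd;
      f(code);
    }
  }
}

//' @noRd
// [[Rcpp::export(name = ".kmer_unique_fraction_cpp")]]
double kmer_unique_fraction_cpp(const std::string& seq, int k, bool canonical) {
  if (k < 1 || k > 32) stop("k must be between 1 and 32");
  std::unordered_map<uint64_t, int> counts;
  counts.reserve(seq.size());
  for_each_kmer(seq, k, canonical, [&](uint64_t code) {
    auto it = counts.find(code);
    if (it == counts.end()) counts.emplace(code, 1);
    else if (it->second == 1) it->second = 2;  // only need once vs more
  });
  if (counts.empty()) return NA_REAL;
  size_t once = 0;
  for (auto& kv : counts) if (kv.second == 1) ++once;
  return (double)once / (double)counts.size();
}

//' @noRd
// [[Rcpp::export(name = ".kmer_distinct_count_cpp")]]
double kmer_distinct_count_cpp(const std::string& seq, int k, bool canonical) {
  if (k < 1 || k > 32) stop("k must be between 1 and 32");
  std::unordered_set<uint64_t> seen;
  seen.reserve(seq.size());
  for_each_kmer(seq, k, canonical, [&](uint64_t code) { seen.insert(code); });
  return (double)seen.size();
}

// Hashes are truncated to 53 bits so every sketch value is exactly
// representable as an R double.
//' @noRd
// [[Rcpp::export(name = ".minhash_hashes_cpp")]]
NumericVector minhash_hashes_cpp(const std::string& seq, int k, int sketch_size) {
  if (k < 1 || k > 32) stop("k must be between 1 and 32");
  if (sketch_size < 1) stop("sketch_size must be >= 1");
  std::unordered_set<uint64_t> hashes;
  hashes.reserve(seq.size());
  for_each_kmer(seq, k, true, [&](uint64_t code) {
    hashes.insert(mix64(code) >> 11);
  });
  std::vector<uint64_t> v(hashes.begin(), hashes.end());
  size_t keep = std::min((size_t)sketch_size, v.size());
  std::partial_sort(v.begin(), v.begin() + keep, v.end());
  NumericVector out(keep);
  for (size_t i = 0; i < keep; ++i) out[i] = (double)v[i];
  return out;
}
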