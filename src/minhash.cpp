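#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>

// MinHash core. The hash contract is fully specified so that signatures are
// byte-identical across platforms and runs:
//
//   base(s)    = FNV-1a 64-bit over the UTF-8 bytes of the shingle string
//   salt(k, i) = splitmix64(k * 0x9E3779B97F4A7C15 + i)   (seed k, permutation i)
//   h_i(s)     = splitmix64(base(s) ^ salt(k, i)) >> 11   (top 53 bits)
//   signature[i] = min over shingles s of h_i(s)
//
// Only the top 53 bits are kept so each component is exactly representable as
// an R double; ordering (and hence the minimum) is taken on the truncated
// value, which is itself a well-defined 53-bit hash.

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline uint64_t fnv1a64(const char* s, size_t n) {
  uint64_t h = 0xCBF29CE484222325ULL;
  for (size_t i = 0; i < n; ++i) {
    h ^= static_cast<uint64_t>(static_cast<unsigned char>(s[i]));
    h *= 0x100000001B3ULL;
  }
  return h;
}

// [[Rcpp::export]]
Rcpp::NumericVector minhash_components(Rcpp::CharacterVector shingles,
                                       int signature_length,
                                       double seed) {
  const int n = shingles.size();
  if (n == 0) Rcpp::stop("cannot MinHash an empty shingle set");
  const uint64_t k = static_cast<uint64_t>(seed);

  std::vector<uint64_t> base(n);
  for (int j = 0; j < n; ++j) {
    const char* s = CHAR(STRING_ELT(shingles, j));
    base[j] = fnv1a64(s, std::strlen(s));
  }

  Rcpp::NumericVector out(signature_length);
  const uint64_t kmul = k * 0x9E3779B97F4A7C15ULL;
  for (int i = 0; i < signature_length; ++i) {
    const uint64_t salt = splitmix64(kmul + static_cast<uint64_t>(i));
    uint64_t best = UINT64_MAX;
    for (int j = 0; j < n; ++j) {
      const uint64_t h = splitmix64(base[j] ^ salt) >> 11;
      if (h < best) best = h;
    }
    out[i] = static_cast<double>(best);
  }
  return out;
}

// 64-bit string hash exposed for testing the hash contract itself.
// [[Rcpp::export]]
Rcpp::NumericVector hash_strings(Rcpp::CharacterVector x, double seed, int perm) {
  const uint64_t k = static_cast<uint64_t>(seed);
  const uint64_t salt = splitmix64(k * 0x9E3779B97F4A7C15ULL + static_cast<uint64_t>(perm));
  Rcpp::NumericVector out(x.size());
  for (int j = 0; j < x.size(); ++j) {
    const char* s = CHAR(STRING_ELT(x, j));
    out[j] = static_cast<double>(splitmix64(fnv1a64(s, std::strlen(s)) ^ salt) >> 11);
  }
  return out;
}
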