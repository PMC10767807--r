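// Bottom-s MinHash sketching of nucleotide sequences over canonical
// k-mers, hashed with MurmurHash3 x64 (128-bit finalization, lower 64
// bits kept). Hash values are returned to R as fixed-width lowercase hex
// strings so that lexicographic order equals numeric order and no
// precision is lost in R's doubles.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <cstring>
#include <string>
#include <unordered_set>
#include <vector>

static inline uint64_t rotl64(uint64_t x, int8_t r) {
  return (x << r) | (x >> (64 - r));
}

static inline uint64_t fmix64(uint64_t k) {
  k ^= k >> 33;
  k *= 0xff51afd7ed558ccdULL;
  k ^= k >> 33;
  k *= 0xc4ceb9fe1a85ec53ULL;
  k ^= k >> 33;
  return k;
}

// MurmurHash3_x64_128, lower 64 bits of the result.
static uint64_t murmur3_64(const char* key, int len, uint32_t seed) {
  const uint8_t* data = (const uint8_t*)key;
  const int nblocks = len / 16;
  uint64_t h1 = seed, h2 = seed;
  const uint64_t c1 = 0x87c37b91114253d5ULL;
  const uint64_t c2 = 0x4cf5ad432745937fULL;

  for (int i = 0; i < nblocks; i++) {
    uint64_t k1, k2;
    std::memcpy(&k1, data + i * 16, 8);
    std::memcpy(&k2, data + i * 16 + 8, 8);
    k1 *= c1; k1 = rotl64(k1, 31); k1 *= c2; h1 ^= k1;
    h1 = rotl64(h1, 27); h1 += h2; h1 = h1 * 5 + 0x52dce729;
    k2 *= c2; k2 = rotl64(k2, 33); k2 *= c1; h2 ^= k2;
    h2 = rotl64(h2, 31); h2 += h1; h2 = h2 * 5 + 0x38495ab5;
  }

  const uint8_t* tail = data + nblocks * 16;
  uint64_t k1 = 0, k2 = 0;
  switch (len & 15) {
    case 15: k2 ^= ((uint64_t)tail[14]) << 48; /* fallthrough */
    case 14: k2 ^= ((uint64_t)tail[13]) << 40; /* fallthrough */
    case 13: k2 ^= ((uint64_t)tail[12]) << 32; /* fallthrough */
    case 12: k2 ^= ((uint64_t)tail[11]) << 24; /* fallthrough */
    case 11: k2 ^= ((uint64_t)tail[10]) << 16; /* fallthrough */
    case 10: k2 ^= ((uint64_t)tail[9]) << 8;   /* fallthrough */
    case 9:  k2 ^= ((uint64_t)tail[8]);
             k2 *= c2; k2 = rotl64(k2, 33); k2 *= c1; h2 ^= k2;
             /* fallthrough */
    case 8:  k1 ^= ((uint64_t)tail[7]) << 56;  /* fallthrough */
    case 7:  k1 ^= ((uint64_t)tail[6]) << 48;  /* fallthrough */
    case 6:  k1 ^= ((uint64_t)tail[5]) << 40;  /* fallthrough */
    case 5:  k1 ^= ((uint64_t)tail[4]) << 32;  /* fallthrough */
    case 4:  k1 ^= ((uint64_t)tail[3]) << 24;  /* fallthrough */
    case 3:  k1 ^= ((uint64_t)tail[2]) << 16;  /* fallthrough */
    case 2:  k1 ^= ((uint64_t)tail[1]) << 8;   /* fallthrough */
    case 1:  k1 ^= ((uint64_t)tail[0]);
             k1 *= c1; k1 = rotl64(k1, 31); k1 *= c2; h1 ^= k1;
  }

  h1 ^= (uint64_t)len; h2 ^= (uint64_t)len;
  h1 += h2; h2 += h1;
  h1 = fmix64(h1); h2 = fmix64(h2);
  h1 += h2;
  return h1;
}

static inline char complement(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string to_hex(uint64_t v) {
  static const char* digits = "0123456789abcdef";
  std::string out(16, '0');
  for (int i = 15; i >= 0; --i) {
    out[i] = digits[v & 0xf];
    v >>= 4;
  }
  return out;
}

// [[Rcpp::export(name = ".sketch_hashes")]]
Rcpp::CharacterVector sketch_hashes(std::string seq, int k, int s,
                                    int seed) {
  int n = (int)seq.size();
  if (n < k) Rcpp::stop("sequence shorter than k");
  for (auto& c : seq) c = (char)std::toupper((unsigned char)c);

  std::unordered_set<uint64_t> seen;
  std::string kmer(k, 'N'), rc(k, 'N');
  for (int i = 0; i + k <= n; ++i) {
    bool valid = true;
    for (int j = 0; j < k; ++j) {
      char c = seq[i + j];
      if (c != 'A' && c != 'C' && c != 'G' && c != 'T') { valid = false; break; }
      kmer[j] = c;
      rc[k - 1 - j] = complement(c);
    }
    if (!valid) continue;
    const std::string& canon = (kmer <= rc) ? kmer : rc;
    seen.insert(murmur3_64(canon.data(), k, (uint32_t)seed));
  }
  std::vector<uint64_t> all(seen.begin(), seen.end());
  std::sort(all.begin(), all.end());
  size_t keep = std::min((size_t)s, all.size());
  Rcpp::CharacterVector out(keep);
  for (size_t i = 0; i < keep; ++i) out[i] = to_hex(all[i]);
  return out;
}
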