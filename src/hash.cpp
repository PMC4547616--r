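#include <Rcpp.h>
#include <cstdio>
using namespace Rcpp;

// 64-bit FNV-1a over the bytes of each string; returned as 16 uppercase
// hex digits.  Used for stable, registry-free node identifiers.
// [[Rcpp::export]]
CharacterVector fnv1a64_hex(CharacterVector x) {
  R_xlen_t n = x.size();
  CharacterVector out(n);
  char buf[17];
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t h = 14695981039346656037ULL;  // FNV offset basis
    const char *s = CHAR(STRING_ELT(x, i));
    for (const unsigned char *p = (const unsigned char *)s; *p; ++p) {
      h ^= (uint64_t)(*p);
      h *= 1099511628211ULL;              // FNV prime
    }
    std::snprintf(buf, sizeof(buf), "%016llX", (unsigned long long)h);
    out[i] = buf;
  }
  return out;
}
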