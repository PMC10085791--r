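#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// 2-bit packing A=0,C=1,G=2,T=3. Codes are returned as doubles, which is
// exact for k <= 25 (2k <= 50 bits < 53-bit mantissa).
static inline int baseCode(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

//' @noRd
// [[Rcpp::export(name = ".canonicalKmerCodes")]]
NumericVector canonical_kmer_codes(CharacterVector seqs, int k) {
  if (k < 1 || k > 25) stop("k must be between 1 and 25");
  std::vector<double> out;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  const int shift = 2 * (k - 1);
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    SEXP el = STRING_ELT(seqs, s);
    if (el == NA_STRING) continue;
    const char *str = CHAR(el);
    R_xlen_t n = LENGTH(el);
    if (n < k) continue;
    uint64_t fw = 0, rv = 0;
    R_xlen_t valid = 0;  // bases accumulated since last non-ACGT
    for (R_xlen_t i = 0; i < n; ++i) {
      int b = baseCode(str[i]);
      if (b < 0) { valid = 0; fw = 0; rv = 0; continue; }
      fw = ((fw << 2) | (uint64_t)b) & mask;
      rv = (rv >> 2) | ((uint64_t)(3 - b) << shift);
      if (++valid >= k) out.push_back((double)(fw < rv ? fw : rv));
    }
  }
  return wrap(out);
}

//' @noRd
// [[Rcpp::export(name = ".kmerCodeToString")]]
CharacterVector kmer_code_to_string(NumericVector codes, int k) {
  if (k < 1 || k > 25) stop("k must be between 1 and 25");
  static const char bases[] = "ACGT";
  CharacterVector out(codes.size());
  std::string buf(k, 'A');
  for (R_xlen_t i = 0; i < codes.size(); ++i) {
    uint64_t code = (uint64_t)codes[i];
    for (int j = k - 1; j >= 0; --j) {
      buf[j] = bases[code & 3ULL];
      code >>= 2;
    }
    out[i] = buf;
  }
  return out;
}

// Count mismatching positions between the length-n suffix of a and the
// length-n prefix of b; early exit once maxMismatch is exceeded.
//' @noRd
// [[Rcpp::export(name = ".suffixPrefixMismatches")]]
int suffix_prefix_mismatches(std::string a, std::string b, int n, int maxMismatch) {
  if (n > (int)a.size() || n > (int)b.size()) stop("overlap longer than sequence");
  int mm = 0;
  size_t offset = a.size() - (size_t)n;
  for (int i = 0; i < n; ++i) {
    if (a[offset + i] != b[i]) {
      if (++mm > maxMismatch) return mm;
    }
  }
  return mm;
}
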