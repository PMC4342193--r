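// GCTA-style genomic relationship matrix via partial-sum lookup.
//
// Twenty markers are processed per 64-bit word using 3-bit case codes.
// Per-sample words are built once per 20-marker block:
//   g' field: hom a1 -> 0, het -> 2, hom a2 -> 3 (missing remapped to 0)
//   mm field: 7 if the call is missing, else 0
// The pair word is then (g'_j + g'_k) | mm_j | mm_k, whose 3-bit fields take
// the seven case values
//   0 hom-a1/hom-a1, 2 hom-a1/het, 3 hom-a1/hom-a2, 4 het/het,
//   5 het/hom-a2, 6 hom-a2/hom-a2, 7 missing (value 1 unused)
// with no carry between fields (non-missing sums are at most 6).  Four
// 2^15-entry tables map five 3-bit codes at once to the sum of their five
// per-marker increments; a missing call contributes 0 and instead decrements
// the pair's denominator, which is counted from the mm words (three set bits
// per missing marker).

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>
using namespace Rcpp;

static const uint64_t M55g = 0x5555555555555555ULL;
static const uint64_t M33g = 0x3333333333333333ULL;
static const uint64_t M0Fg = 0x0F0F0F0F0F0F0F0FULL;
static const uint64_t M01g = 0x0101010101010101ULL;

static inline uint64_t popcount64g(uint64_t x) {
  x -= (x >> 1) & M55g;
  x = (x & M33g) + ((x >> 2) & M33g);
  x = (x + (x >> 4)) & M0Fg;
  return (x * M01g) >> 56;
}

// the six non-missing per-marker increments, indexed by case value;
// x, y are a1 (minor-allele) dosages and q is the a1 frequency
static void case_increments(double q, double f[8]) {
  double d = 2.0 * q * (1.0 - q);
  double v2 = 2.0 - 2.0 * q, v1 = 1.0 - 2.0 * q, v0 = 0.0 - 2.0 * q;
  f[0] = v2 * v2 / d; // hom a1 x hom a1 (x = y = 2)
  f[1] = 0.0;         // unused case value
  f[2] = v2 * v1 / d; // hom a1 x het
  f[3] = v2 * v0 / d; // hom a1 x hom a2
  f[4] = v1 * v1 / d; // het x het
  f[5] = v1 * v0 / d; // het x hom a2
  f[6] = v0 * v0 / d; // hom a2 x hom a2
  f[7] = 0.0;         // at least one call missing
}

// [[Rcpp::export(name = ".grm_case_increments_cpp")]]
NumericVector grm_case_increments_cpp(double q) {
  NumericVector out(8);
  double f[8];
  case_increments(q, f);
  for (int i = 0; i < 8; ++i) out[i] = f[i];
  return out;
}

// fill one 2^15-entry partial-sum table for a 5-marker group, by dynamic
// programming so every entry is the left-associated sum f0+f1+f2+f3+f4
static void fill_table(const double f[][8], int base, int nmark, double *tbl) {
  tbl[0] = 0.0;
  size_t sz = 1;
  for (int s = 0; s < 5; ++s) {
    double fs[8];
    if (base + s < nmark) std::memcpy(fs, f[base + s], sizeof(fs));
    else for (int c = 0; c < 8; ++c) fs[c] = 0.0; // padding markers
    // marker s occupies bits 3s..3s+2; c = 0 last so sources stay intact
    for (int c = 7; c >= 0; --c)
      for (size_t i = 0; i < sz; ++i)
        tbl[((size_t)c << (3 * s)) | i] = tbl[i] + fs[c];
    sz <<= 3;
  }
}

// [[Rcpp::export(name = ".grm_partial_sum_table_cpp")]]
NumericVector grm_partial_sum_table_cpp(NumericVector q5) {
  if (q5.size() < 1 || q5.size() > 5) stop("between 1 and 5 frequencies expected");
  double f[5][8];
  for (int s = 0; s < q5.size(); ++s) case_increments(q5[s], f[s]);
  NumericVector out(32768);
  fill_table(f, 0, q5.size(), REAL(out));
  return out;
}

// [[Rcpp::export(name = ".grm_cpp")]]
List grm_cpp(RawVector packed, int n, int m, NumericVector q,
             int row_start, int row_end, bool twenty_lookups) {
  if (q.size() != m) stop("one allele frequency per variant required");
  for (int j = 0; j < m; ++j)
    if (!(q[j] > 0.0 && q[j] < 1.0))
      stop("monomorphic variant reached the relationship kernel");
  int bpv = (n + 3) / 4;
  const unsigned char *p = RAW(packed);
  int nr = row_end - row_start;
  NumericMatrix acc(nr, n);
  NumericMatrix denom(nr, n);
  std::vector<uint64_t> gw(n), mw(n);
  std::vector<double> tables((size_t)4 * 32768);
  double f[20][8];
  // g' per bed code: hom a1(00)->0, missing(01)->0, het(10)->2, hom a2(11)->3
  static const uint64_t GMAP[4] = {0, 0, 2, 3};
  static const uint64_t MMAP[4] = {0, 7, 0, 0};
  for (int k0 = 0; k0 < m; k0 += 20) {
    int nb = m - k0 < 20 ? m - k0 : 20;
    std::fill(gw.begin(), gw.end(), 0);
    std::fill(mw.begin(), mw.end(), 0);
    for (int t = 0; t < nb; ++t) {
      const unsigned char *row = p + (size_t)(k0 + t) * bpv;
      case_increments(q[k0 + t], f[t]);
      for (int i = 0; i < n; ++i) {
        int code = (row[i / 4] >> (2 * (i % 4))) & 3;
        gw[i] |= GMAP[code] << (3 * t);
        mw[i] |= MMAP[code] << (3 * t);
      }
    }
    for (int t = nb; t < 20; ++t)
      for (int c = 0; c < 8; ++c) f[t][c] = 0.0;
    // padding markers beyond m are flagged missing so they add nothing and
    // are excluded from denominators
    if (nb < 20) {
      uint64_t padmm = 0;
      for (int t = nb; t < 20; ++t) padmm |= 7ULL << (3 * t);
      for (int i = 0; i < n; ++i) mw[i] |= padmm;
    }
    if (!twenty_lookups)
      for (int g = 0; g < 4; ++g)
        fill_table(f, 5 * g, 20, &tables[(size_t)g * 32768]);
    for (int r = 0; r < nr; ++r) {
      int i = row_start + r;
      for (int j = 0; j < n; ++j) {
        uint64_t w = (gw[i] + gw[j]) | mw[i] | mw[j];
        double add;
        if (!twenty_lookups) {
          add = acc(r, j);
          add += tables[w & 0x7fff];
          add += tables[32768 + ((w >> 15) & 0x7fff)];
          add += tables[2 * 32768 + ((w >> 30) & 0x7fff)];
          add += tables[3 * 32768 + ((w >> 45) & 0x7fff)];
        } else {
          // reference path: twenty single-case lookups, summed in the same
          // association order as the partial-sum tables
          add = acc(r, j);
          for (int g = 0; g < 4; ++g) {
            double s = 0.0;
            for (int t = 0; t < 5; ++t)
              s += f[5 * g + t][(w >> (3 * (5 * g + t))) & 7];
            add += s;
          }
        }
        acc(r, j) = add;
        denom(r, j) += (double)(popcount64g(mw[i] | mw[j]) / 3);
      }
    }
  }
  int mprime = 20 * ((m + 19) / 20);
  NumericMatrix values(nr, n);
  for (int r = 0; r < nr; ++r)
    for (int j = 0; j < n; ++j) {
      double dn = m - (denom(r, j) - (mprime - m));
      denom(r, j) = dn;
      values(r, j) = dn > 0 ? acc(r, j) / dn : NA_REAL;
    }
  return List::create(_["values"] = values, _["denominators"] = denom);
}
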