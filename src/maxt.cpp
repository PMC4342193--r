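// max(T) permutation association testing with bit-parallel counting.
//
// Genotypes are split once into per-variant bitplanes (hom a1 / het /
// hom a2 / non-missing, one bit per phenotyped sample); each permutation
// then needs only masked population counts per variant to rebuild the
// 2x3 genotype or 2x2 allele table.  Case labels are permuted by
// Fisher-Yates over the phenotyped samples with a self-contained 64-bit
// generator so reports are reproducible from the seed alone, independent
// of R's RNG state.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

double fisher22_p(int a, int b, int c, int d, double *midp_out); // exact.cpp

static const uint64_t M55m = 0x5555555555555555ULL;
static const uint64_t M33m = 0x3333333333333333ULL;
static const uint64_t M0Fm = 0x0F0F0F0F0F0F0F0FULL;
static const uint64_t M01m = 0x0101010101010101ULL;

static inline uint64_t popcount64m(uint64_t x) {
  x -= (x >> 1) & M55m;
  x = (x & M33m) + ((x >> 2) & M33m);
  x = (x + (x >> 4)) & M0Fm;
  return (x * M01m) >> 56;
}

// splitmix64: small, seedable, platform-independent
struct Splitmix {
  uint64_t s;
  explicit Splitmix(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // unbiased integer in [0, bound)
  uint64_t below(uint64_t bound) {
    uint64_t lim = UINT64_MAX - UINT64_MAX % bound;
    uint64_t v;
    do { v = next(); } while (v >= lim);
    return v % bound;
  }
};

struct VariantPlanes {
  std::vector<uint64_t> hom1, het, hom2, nonmiss;
  double th1, thet, th2, tn; // totals over phenotyped samples
};

// Cochran-Armitage trend chi-square with weights (0, 1, 2); the statistic
// is invariant to reversing the weights, so genotype orientation is moot
static double trend_chisq(double r0, double r1, double r2,
                          double n0, double n1, double n2) {
  double N = n0 + n1 + n2, R = r0 + r1 + r2;
  double swr = r1 + 2.0 * r2, swn = n1 + 2.0 * n2, sw2n = n1 + 4.0 * n2;
  double varpart = R * (N - R) * (N * sw2n - swn * swn);
  if (varpart <= 0.0 || N <= 1.0) return 0.0;
  double num = N * swr - R * swn;
  return N * num * num / varpart;
}

// allelic 1-df chi-square on the 2x2 allele-count table
static double allelic_chisq(double a, double b, double c, double d) {
  double N = a + b + c + d;
  double den = (a + b) * (c + d) * (a + c) * (b + d);
  if (den <= 0.0) return 0.0;
  double num = a * d - b * c;
  return N * num * num / den;
}

// statistic for one variant under a case mask; for fisher the returned
// value is the exact allelic p (smaller = more extreme)
static double variant_stat(const VariantPlanes &v, const std::vector<uint64_t> &mask,
                           int test) {
  uint64_t c1 = 0, ch = 0, c2 = 0, cn = 0;
  for (size_t w = 0; w < mask.size(); ++w) {
    c1 += popcount64m(v.hom1[w] & mask[w]);
    ch += popcount64m(v.het[w] & mask[w]);
    c2 += popcount64m(v.hom2[w] & mask[w]);
    cn += popcount64m(v.nonmiss[w] & mask[w]);
  }
  double r0 = (double)c1, r1 = (double)ch, r2 = (double)c2, R = (double)cn;
  double n0 = v.th1, n1 = v.thet, n2 = v.th2;
  if (test == 0) return trend_chisq(r0, r1, r2, n0, n1, n2);
  // allele counts: a1 = 2 hom1 + het
  double caseA = 2.0 * r0 + r1, caseB = 2.0 * R - caseA;
  double ctrlA = 2.0 * n0 + n1 - caseA, ctrlB = 2.0 * (v.tn - R) - ctrlA;
  if (test == 1) return allelic_chisq(caseA, caseB, ctrlA, ctrlB);
  return fisher22_p((int)caseA, (int)caseB, (int)ctrlA, (int)ctrlB, NULL);
}

// [[Rcpp::export(name = ".max_t_cpp")]]
List max_t_cpp(RawVector packed, int n, int m, IntegerVector status,
               int test, int R, double seed) {
  if (R < 1) stop("at least one permutation required");
  int bpv = (n + 3) / 4;
  const unsigned char *p = RAW(packed);
  // phenotyped samples only
  std::vector<int> idx;
  int ncase = 0;
  for (int i = 0; i < n; ++i)
    if (status[i] != NA_INTEGER) {
      idx.push_back(i);
      if (status[i] == 1) ++ncase;
    }
  int ns = (int)idx.size();
  if (ncase == 0 || ncase == ns) stop("phenotype is constant");
  size_t nw = (size_t)((ns + 63) / 64);
  std::vector<VariantPlanes> planes(m);
  for (int j = 0; j < m; ++j) {
    VariantPlanes &v = planes[j];
    v.hom1.assign(nw, 0); v.het.assign(nw, 0);
    v.hom2.assign(nw, 0); v.nonmiss.assign(nw, 0);
    const unsigned char *row = p + (size_t)j * bpv;
    for (int s = 0; s < ns; ++s) {
      int i = idx[s];
      int code = (row[i / 4] >> (2 * (i % 4))) & 3;
      uint64_t bit = 1ULL << (s % 64);
      size_t w = s / 64;
      switch (code) {
      case 0: v.hom1[w] |= bit; break;
      case 2: v.het[w] |= bit; break;
      case 3: v.hom2[w] |= bit; break;
      default: break;
      }
      if (code != 1) v.nonmiss[w] |= bit;
    }
    uint64_t h1 = 0, ht = 0, h2 = 0, tn = 0;
    for (size_t w = 0; w < nw; ++w) {
      h1 += popcount64m(v.hom1[w]); ht += popcount64m(v.het[w]);
      h2 += popcount64m(v.hom2[w]); tn += popcount64m(v.nonmiss[w]);
    }
    v.th1 = (double)h1; v.thet = (double)ht; v.th2 = (double)h2; v.tn = (double)tn;
  }
  // observed statistics
  std::vector<uint64_t> mask(nw, 0);
  for (int s = 0; s < ns; ++s)
    if (status[idx[s]] == 1) mask[s / 64] |= 1ULL << (s % 64);
  NumericVector obs(m);
  for (int j = 0; j < m; ++j) obs[j] = variant_stat(planes[j], mask, test);
  bool smaller_extreme = (test == 2);
  // permutations
  std::vector<int> perm(ns);
  for (int s = 0; s < ns; ++s) perm[s] = s;
  Splitmix rng((uint64_t)seed * 2654435761ULL + 0x1234ABCDULL);
  IntegerVector cnt_point(m), cnt_max(m);
  NumericVector maxima(R);
  const double rtol = 1e-9;
  for (int r = 0; r < R; ++r) {
    for (int s = ns - 1; s > 0; --s) { // Fisher-Yates
      int t = (int)rng.below((uint64_t)(s + 1));
      int tmp = perm[s]; perm[s] = perm[t]; perm[t] = tmp;
    }
    std::fill(mask.begin(), mask.end(), 0);
    for (int s = 0; s < ncase; ++s) mask[perm[s] / 64] |= 1ULL << (perm[s] % 64);
    double ext = smaller_extreme ? 2.0 : -1.0;
    for (int j = 0; j < m; ++j) {
      double st = variant_stat(planes[j], mask, test);
      if (smaller_extreme) {
        if (st < ext) ext = st;
        if (st <= obs[j] * (1.0 + rtol)) ++cnt_point[j];
      } else {
        if (st > ext) ext = st;
        if (st >= obs[j] - rtol) ++cnt_point[j];
      }
    }
    maxima[r] = ext;
    for (int j = 0; j < m; ++j) {
      if (smaller_extreme) { if (ext <= obs[j] * (1.0 + rtol)) ++cnt_max[j]; }
      else { if (ext >= obs[j] - rtol) ++cnt_max[j]; }
    }
  }
  return List::create(_["obs"] = obs, _["count_pointwise"] = cnt_point,
                      _["count_max"] = cnt_max, _["extrema"] = maxima,
                      _["n_perm"] = R, _["n_cases"] = ncase,
                      _["n_phenotyped"] = ns);
}

// 2x2 allele-count tables (a1/a2 x case/control) via masked popcounts on
// the per-variant bitplanes; missing genotypes and unphenotyped samples
// are excluded
// [[Rcpp::export(name = ".allelic_counts_cpp")]]
NumericMatrix allelic_counts_cpp(RawVector packed, int n, int m,
                                 IntegerVector status) {
  int bpv = (n + 3) / 4;
  const unsigned char *p = RAW(packed);
  size_t nw = (size_t)((n + 63) / 64);
  if (nw == 0) nw = 1;
  std::vector<uint64_t> casemask(nw, 0), phenomask(nw, 0);
  for (int i = 0; i < n; ++i) {
    if (status[i] == NA_INTEGER) continue;
    phenomask[i / 64] |= 1ULL << (i % 64);
    if (status[i] == 1) casemask[i / 64] |= 1ULL << (i % 64);
  }
  std::vector<uint64_t> hom1(nw), het(nw), hom2(nw);
  NumericMatrix out(4, m); // case a1, case a2, ctrl a1, ctrl a2
  for (int j = 0; j < m; ++j) {
    const unsigned char *row = p + (size_t)j * bpv;
    std::fill(hom1.begin(), hom1.end(), 0);
    std::fill(het.begin(), het.end(), 0);
    std::fill(hom2.begin(), hom2.end(), 0);
    for (int i = 0; i < n; ++i) {
      int code = (row[i / 4] >> (2 * (i % 4))) & 3;
      uint64_t bit = 1ULL << (i % 64);
      size_t w = i / 64;
      if (code == 0) hom1[w] |= bit;
      else if (code == 2) het[w] |= bit;
      else if (code == 3) hom2[w] |= bit;
    }
    uint64_t c1 = 0, ch = 0, c2 = 0, p1 = 0, ph = 0, p2 = 0;
    for (size_t w = 0; w < nw; ++w) {
      c1 += popcount64m(hom1[w] & casemask[w]);
      ch += popcount64m(het[w] & casemask[w]);
      c2 += popcount64m(hom2[w] & casemask[w]);
      p1 += popcount64m(hom1[w] & phenomask[w]);
      ph += popcount64m(het[w] & phenomask[w]);
      p2 += popcount64m(hom2[w] & phenomask[w]);
    }
    out(0, j) = 2.0 * c1 + ch;
    out(1, j) = 2.0 * c2 + ch;
    out(2, j) = 2.0 * (p1 - c1) + (ph - ch);
    out(3, j) = 2.0 * (p2 - c2) + (ph - ch);
  }
  return out;
}
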