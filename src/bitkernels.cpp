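// Word-level primitives shared by every other module: software population
// counts, the XOR/AND identity-by-state kernel on 960-call blocks, and the
// 2-bit dot-product kernel used for genotype correlations.
//
// Packed storage dialect (matches .bed): per call, 00 = hom a1,
// 01 = missing, 10 = het, 11 = hom a2; four calls per byte, first sample in
// the two lowest-order bits.  Unpacked genotypes are integer dosages of the
// a2 allele: hom a1 = 0, het = 1, hom a2 = 2, NA = missing.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>
using namespace Rcpp;

static const uint64_t M55 = 0x5555555555555555ULL;
static const uint64_t M33 = 0x3333333333333333ULL;
static const uint64_t M0F = 0x0F0F0F0F0F0F0F0FULL;
static const uint64_t M01 = 0x0101010101010101ULL;
static const uint64_t MAA = 0xAAAAAAAAAAAAAAAAULL;

// pure-integer SWAR popcount; no hardware intrinsic dependency
static inline uint64_t popcount64(uint64_t x) {
  x -= (x >> 1) & M55;
  x = (x & M33) + ((x >> 2) & M33);
  x = (x + (x >> 4)) & M0F;
  return (x * M01) >> 56;
}

// sum of the 32 2-bit fields of a word (each field in 0..3)
static inline uint64_t popcount2_64(uint64_t x) {
  x = (x & M33) + ((x >> 2) & M33);
  x = (x + (x >> 4)) & M0F;
  return (x * M01) >> 56;
}

static inline uint64_t load_word(const unsigned char *p, size_t nbytes_left) {
  uint64_t w = 0;
  size_t k = nbytes_left < 8 ? nbytes_left : 8;
  std::memcpy(&w, p, k); // little-endian byte order assumed (x86-64/ARM64)
  return w;
}

// [[Rcpp::export(name = ".popcount_raw")]]
double popcount_raw(RawVector bits) {
  const unsigned char *p = RAW(bits);
  size_t n = bits.size();
  uint64_t acc = 0;
  for (size_t i = 0; i < n; i += 8) acc += popcount64(load_word(p + i, n - i));
  return (double)acc;
}

// [[Rcpp::export(name = ".popcount2_raw")]]
double popcount2_raw(RawVector fields) {
  const unsigned char *p = RAW(fields);
  size_t n = fields.size();
  uint64_t acc = 0;
  for (size_t i = 0; i < n; i += 8) acc += popcount2_64(load_word(p + i, n - i));
  return (double)acc;
}

// ---- packing -------------------------------------------------------------

static inline int bed_code_from_dosage(int g) {
  // dosage 0/1/2/NA -> 2-bit bed code
  if (g == NA_INTEGER) return 1;
  switch (g) { case 0: return 0; case 1: return 2; case 2: return 3; }
  stop("genotype dosage must be 0, 1, 2 or NA");
  return -1;
}

static inline int dosage_from_bed_code(int c) {
  switch (c) { case 0: return 0; case 2: return 1; case 3: return 2; }
  return NA_INTEGER; // 01 = missing
}

// [[Rcpp::export(name = ".pack_genotypes_cpp")]]
RawVector pack_genotypes_cpp(IntegerMatrix geno) {
  int n = geno.nrow(), m = geno.ncol();
  int bpv = (n + 3) / 4;
  RawVector out((R_xlen_t)bpv * m);
  unsigned char *p = RAW(out);
  // pad calls beyond the last sample carry the fixed code 00; no kernel
  // ever reads them
  for (int j = 0; j < m; ++j) {
    unsigned char *row = p + (size_t)j * bpv;
    for (int b = 0; b < bpv; ++b) {
      unsigned byte = 0;
      for (int k = 0; k < 4; ++k) {
        int i = 4 * b + k;
        int code = (i < n) ? bed_code_from_dosage(geno(i, j)) : 0;
        byte |= (unsigned)code << (2 * k);
      }
      row[b] = (unsigned char)byte;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".unpack_genotypes_cpp")]]
IntegerMatrix unpack_genotypes_cpp(RawVector packed, int n, int m) {
  int bpv = (n + 3) / 4;
  if ((R_xlen_t)bpv * m != packed.size())
    stop("packed payload size does not match dimensions");
  IntegerMatrix out(n, m);
  const unsigned char *p = RAW(packed);
  for (int j = 0; j < m; ++j) {
    const unsigned char *row = p + (size_t)j * bpv;
    for (int i = 0; i < n; ++i) {
      int code = (row[i / 4] >> (2 * (i % 4))) & 3;
      out(i, j) = dosage_from_bed_code(code);
    }
  }
  return out;
}

// ---- IBS kernel ----------------------------------------------------------

// per-call encodings: A = {phi: 01, 0: 00, 1: 10, 2: 11}, mask = 00 if
// missing else 11; rows padded with missing calls to 960-call blocks
// (240 bytes, 30 words per block).

static void ibs_encode_fill(const int *g, int m, std::vector<uint64_t> &A,
                            std::vector<uint64_t> &C) {
  int mprime = 960 * ((m + 959) / 960);
  if (mprime == 0) mprime = 960;
  size_t nw = (size_t)mprime / 32;
  A.assign(nw, 0);
  C.assign(nw, 0);
  for (int i = 0; i < m; ++i) {
    uint64_t a, c;
    int gi = g[i];
    if (gi == NA_INTEGER) { a = 1; c = 0; }
    else { a = (gi == 0) ? 0 : (gi == 1 ? 2 : 3); c = 3; }
    A[i / 32] |= a << (2 * (i % 32));
    C[i / 32] |= c << (2 * (i % 32));
  }
  // pad calls already 00/00: A pad must be the missing code 01
  for (int i = m; i < mprime; ++i) A[i / 32] |= 1ULL << (2 * (i % 32));
}

// [[Rcpp::export(name = ".ibs_encode_cpp")]]
List ibs_encode_cpp(IntegerVector g) {
  std::vector<uint64_t> A, C;
  ibs_encode_fill(INTEGER(g), g.size(), A, C);
  RawVector a(A.size() * 8), c(C.size() * 8);
  std::memcpy(RAW(a), A.data(), a.size());
  std::memcpy(RAW(c), C.data(), c.size());
  return List::create(_["a_bits"] = a, _["mask_bits"] = c);
}

// diff/obs over 960-call blocks: E := A xor B, F := C and D,
// diff += popcount(E and F), obs += popcount(F)
static void ibs_core(const std::vector<uint64_t> &A, const std::vector<uint64_t> &C,
                     const std::vector<uint64_t> &B, const std::vector<uint64_t> &D,
                     double *diff, double *obs) {
  uint64_t d = 0, o = 0;
  size_t nw = A.size();
  for (size_t blk = 0; blk < nw; blk += 30) {
    size_t end = blk + 30 < nw ? blk + 30 : nw;
    for (size_t w = blk; w < end; ++w) {
      uint64_t E = A[w] ^ B[w];
      uint64_t F = C[w] & D[w];
      d += popcount64(E & F);
      o += popcount64(F);
    }
  }
  *diff = (double)d;
  *obs = (double)o;
}

// [[Rcpp::export(name = ".ibs_counts_cpp")]]
List ibs_counts_cpp(IntegerVector a, IntegerVector b) {
  if (a.size() != b.size()) stop("genotype vectors must have equal length");
  std::vector<uint64_t> A, C, B, D;
  ibs_encode_fill(INTEGER(a), a.size(), A, C);
  ibs_encode_fill(INTEGER(b), b.size(), B, D);
  double diff, obs;
  ibs_core(A, C, B, D, &diff, &obs);
  return List::create(_["diff"] = diff, _["obs"] = obs);
}

// ---- packed dot-product kernel ------------------------------------------

// encoding: hom minor 00 (v=-1), het or missing 01 (v=0), hom major 10 (v=+1)
static void dot_encode_fill(const int *g, int m, std::vector<uint64_t> &X) {
  size_t nw = (size_t)((m + 31) / 32);
  if (nw == 0) nw = 1;
  // pad fields must be 01 so they contribute 1 to popcount2, cancelling n'
  X.assign(nw, M55);
  for (int i = 0; i < m; ++i) {
    uint64_t x = (g[i] == NA_INTEGER) ? 1 : (g[i] == 0 ? 0 : (g[i] == 1 ? 1 : 2));
    X[i / 32] &= ~(3ULL << (2 * (i % 32)));
    X[i / 32] |= x << (2 * (i % 32));
  }
}

// sum over 2-bit fields of (1 - v_i w_i), via
// Z := (X or Y) and 0101...; popcount2(((X xor Y) and (1010... - Z)) or Z)
static uint64_t dot_core(const std::vector<uint64_t> &X, const std::vector<uint64_t> &Y) {
  uint64_t acc = 0;
  for (size_t w = 0; w < X.size(); ++w) {
    uint64_t Z = (X[w] | Y[w]) & M55;
    acc += popcount2_64(((X[w] ^ Y[w]) & (MAA - Z)) | Z);
  }
  return acc;
}

// [[Rcpp::export(name = ".dot_product_packed_cpp")]]
double dot_product_packed_cpp(IntegerVector x, IntegerVector y) {
  if (x.size() != y.size()) stop("genotype vectors must have equal length");
  std::vector<uint64_t> X, Y;
  dot_encode_fill(INTEGER(x), x.size(), X);
  dot_encode_fill(INTEGER(y), y.size(), Y);
  double nprime = (double)(X.size() * 32);
  return nprime - (double)dot_core(X, Y);
}

// dot product alone, for all-pairs scans where per-variant moments have
// been precomputed outside the pair loop
// [[Rcpp::export(name = ".ld_dot_cpp")]]
double ld_dot_cpp(RawVector packed, int n, int m, int vi, int vj) {
  if (vi < 0 || vi >= m || vj < 0 || vj >= m) stop("variant index out of range");
  int bpv = (n + 3) / 4;
  const unsigned char *p = RAW(packed);
  size_t nwords = (size_t)((n + 31) / 32);
  if (nwords == 0) nwords = 1;
  std::vector<uint64_t> X(nwords, M55), Y(nwords, M55);
  const unsigned char *rx = p + (size_t)vi * bpv;
  const unsigned char *ry = p + (size_t)vj * bpv;
  static const uint64_t DMAP[4] = {0, 1, 1, 2}; // hom a1, missing, het, hom a2
  for (int i = 0; i < n; ++i) {
    size_t w = i / 32;
    int sh = 2 * (i % 32);
    X[w] &= ~(3ULL << sh); X[w] |= DMAP[(rx[i / 4] >> (2 * (i % 4))) & 3] << sh;
    Y[w] &= ~(3ULL << sh); Y[w] |= DMAP[(ry[i / 4] >> (2 * (i % 4))) & 3] << sh;
  }
  double nprime = (double)(nwords * 32);
  return nprime - (double)dot_core(X, Y);
}

// ---- per-variant genotype tallies ---------------------------------------

// bitplane split of one packed variant row over n samples.
// planes: hom_a1 = !b1 & !b0, missing = !b1 & b0, het = b1 & !b0,
// hom_a2 = b1 & b0 where b0/b1 are the low/high bits of each call.
struct RowPlanes {
  std::vector<uint64_t> hom1, het, hom2, nonmiss;
};

static void row_planes(const unsigned char *row, int n, RowPlanes &pl) {
  size_t nw = (size_t)((n + 63) / 64);
  if (nw == 0) nw = 1;
  pl.hom1.assign(nw, 0); pl.het.assign(nw, 0);
  pl.hom2.assign(nw, 0); pl.nonmiss.assign(nw, 0);
  for (int i = 0; i < n; ++i) {
    int code = (row[i / 4] >> (2 * (i % 4))) & 3;
    uint64_t bit = 1ULL << (i % 64);
    size_t w = i / 64;
    switch (code) {
    case 0: pl.hom1[w] |= bit; pl.nonmiss[w] |= bit; break;
    case 2: pl.het[w] |= bit; pl.nonmiss[w] |= bit; break;
    case 3: pl.hom2[w] |= bit; pl.nonmiss[w] |= bit; break;
    default: break;
    }
  }
}

// [[Rcpp::export(name = ".genotype_count_matrix_cpp")]]
NumericMatrix genotype_count_matrix_cpp(RawVector packed, int n, int m) {
  int bpv = (n + 3) / 4;
  const unsigned char *p = RAW(packed);
  NumericMatrix out(4, m); // rows: hom_a1, het, hom_a2, missing
  RowPlanes pl;
  for (int j = 0; j < m; ++j) {
    row_planes(p + (size_t)j * bpv, n, pl);
    uint64_t h1 = 0, ht = 0, h2 = 0, nm = 0;
    for (size_t w = 0; w < pl.hom1.size(); ++w) {
      h1 += popcount64(pl.hom1[w]);
      ht += popcount64(pl.het[w]);
      h2 += popcount64(pl.hom2[w]);
      nm += popcount64(pl.nonmiss[w]);
    }
    out(0, j) = (double)h1; out(1, j) = (double)ht;
    out(2, j) = (double)h2; out(3, j) = (double)(n - (int)nm);
  }
  return out;
}

// ---- sample x sample IBS matrix ------------------------------------------

// [[Rcpp::export(name = ".ibs_matrix_cpp")]]
List ibs_matrix_cpp(RawVector packed, int n, int m, int row_start, int row_end) {
  int bpv = (n + 3) / 4;
  const unsigned char *p = RAW(packed);
  int mprime = m > 0 ? 960 * ((m + 959) / 960) : 960;
  size_t nw = (size_t)mprime / 32;
  // transpose to sample-major IBS encodings
  std::vector<std::vector<uint64_t> > A(n), C(n);
  for (int i = 0; i < n; ++i) {
    A[i].assign(nw, 0);
    C[i].assign(nw, 0);
  }
  for (int j = 0; j < m; ++j) {
    const unsigned char *row = p + (size_t)j * bpv;
    for (int i = 0; i < n; ++i) {
      int code = (row[i / 4] >> (2 * (i % 4))) & 3;
      uint64_t a, c;
      switch (code) {
      case 0: a = 0; c = 3; break;  // hom a1: 2 copies of a1 -> dosage 0
      case 2: a = 2; c = 3; break;  // het
      case 3: a = 3; c = 3; break;  // hom a2
      default: a = 1; c = 0; break; // missing
      }
      A[i][j / 32] |= a << (2 * (j % 32));
      C[i][j / 32] |= c << (2 * (j % 32));
    }
  }
  for (int i = 0; i < n; ++i)
    for (int j = m; j < mprime; ++j) A[i][j / 32] |= 1ULL << (2 * (j % 32));
  int nr = row_end - row_start;
  NumericMatrix diff(nr, n), obs(nr, n);
  for (int r = 0; r < nr; ++r) {
    int i = row_start + r;
    for (int j = 0; j < n; ++j) {
      double d, o;
      ibs_core(A[i], C[i], A[j], C[j], &d, &o);
      diff(r, j) = d;
      obs(r, j) = o;
    }
  }
  return List::create(_["diff"] = diff, _["obs"] = obs);
}

// ---- pairwise LD moment components ---------------------------------------

// integer moment components for the correlation between two variant rows,
// all derived from popcount/popcount2 on packed encodings.
// Returned sums use v+1 = a2 dosage in {0,1,2} so they are plain counts.
// [[Rcpp::export(name = ".ld_pair_components_cpp")]]
List ld_pair_components_cpp(RawVector packed, int n, int m, int vi, int vj) {
  if (vi < 0 || vi >= m || vj < 0 || vj >= m) stop("variant index out of range");
  int bpv = (n + 3) / 4;
  const unsigned char *p = RAW(packed);
  size_t nwords = (size_t)((n + 31) / 32);
  if (nwords == 0) nwords = 1;
  // 2-bit encodings per row: dosage (missing 00 + mask), het plane,
  // mask (11 if non-missing), dot encoding (missing -> 01)
  std::vector<uint64_t> Dx(nwords, 0), Dy(nwords, 0), Mx(nwords, 0), My(nwords, 0),
      Hx(nwords, 0), Hy(nwords, 0), X(nwords, M55), Y(nwords, M55);
  const unsigned char *rx = p + (size_t)vi * bpv;
  const unsigned char *ry = p + (size_t)vj * bpv;
  for (int i = 0; i < n; ++i) {
    int cx = (rx[i / 4] >> (2 * (i % 4))) & 3;
    int cy = (ry[i / 4] >> (2 * (i % 4))) & 3;
    size_t w = i / 32;
    int sh = 2 * (i % 32);
    uint64_t fx, fy, dotx, doty;
    switch (cx) {
    case 0: fx = 0; dotx = 0; break;
    case 2: fx = 1; dotx = 1; Hx[w] |= 1ULL << sh; break;
    case 3: fx = 2; dotx = 2; break;
    default: fx = 0; dotx = 1; break;
    }
    switch (cy) {
    case 0: fy = 0; doty = 0; break;
    case 2: fy = 1; doty = 1; Hy[w] |= 1ULL << sh; break;
    case 3: fy = 2; doty = 2; break;
    default: fy = 0; doty = 1; break;
    }
    if (cx != 1) Mx[w] |= 3ULL << sh;
    if (cy != 1) My[w] |= 3ULL << sh;
    Dx[w] |= fx << sh;
    Dy[w] |= fy << sh;
    X[w] &= ~(3ULL << sh); X[w] |= dotx << sh;
    Y[w] &= ~(3ULL << sh); Y[w] |= doty << sh;
  }
  uint64_t obs2 = 0, sx = 0, sy = 0, hx = 0, hy = 0, one_minus = 0;
  for (size_t w = 0; w < nwords; ++w) {
    uint64_t F = Mx[w] & My[w];
    obs2 += popcount64(F);
    sx += popcount2_64(Dx[w] & F);
    sy += popcount2_64(Dy[w] & F);
    hx += popcount64(Hx[w] & F & M55);
    hy += popcount64(Hy[w] & F & M55);
    uint64_t Z = (X[w] | Y[w]) & M55;
    one_minus += popcount2_64(((X[w] ^ Y[w]) & (MAA - Z)) | Z);
  }
  double n_obs = (double)(obs2 / 2);
  double nprime = (double)(nwords * 32);
  // sums of v+1 = dosage; convert: sum v = sum dosage - n_obs,
  // sum v^2 = n_obs - n_het (v^2 is 1 unless het)
  return List::create(
      _["n_obs"] = n_obs,
      _["sum_x"] = (double)sx - n_obs, _["sum_y"] = (double)sy - n_obs,
      _["sum_x2"] = n_obs - (double)hx, _["sum_y2"] = n_obs - (double)hy,
      _["dot"] = nprime - (double)one_minus);
}
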