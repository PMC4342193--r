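// Early-termination exact tests.
//
// All tests share one structure: likelihoods of the table family are
// computed as values relative to the most probable table via adjacent-table
// ratio recurrences (no factorials, no log-gamma), partial sums are tracked
// in constant space, and each tail sweep stops as soon as the newest term is
// too small to change any tracked IEEE-double partial sum.  "At least as
// extreme" means null likelihood <= observed likelihood, with a tiny
// relative tolerance so exactly-tied mirror tables reached along a different
// recurrence path still count as ties.
//
// The *_full_() variants are independent full-enumeration references in
// 80-bit extended precision (long double, lgammal-based absolute
// log-likelihoods); they exist so tests and the acceptance script can
// measure how many significant digits the fast path preserves.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double TIE_TOL = 1e-12;
static const double LOG2_53 = 53.0 * 0.693147180559945309; // -log(2^-53)

// ---- Hardy-Weinberg ------------------------------------------------------

// L(n12 = k + 2) / L(n12 = k) with fixed allele margins n1, n2
static inline double hwe_ratio_up(double k, double n1, double n2) {
  return (n1 - k) * (n2 - k) / ((k + 1.0) * (k + 2.0));
}

// [[Rcpp::export(name = ".hwe_exact_cpp")]]
List hwe_exact_cpp(int n_hom1, int n_het, int n_hom2) {
  double n1 = 2.0 * n_hom1 + n_het, n2 = 2.0 * n_hom2 + n_het;
  if (n_hom1 < 0 || n_het < 0 || n_hom2 < 0) stop("negative genotype count");
  if (n_hom1 + n_het + n_hom2 == 0) stop("empty genotype table");
  double n = n_hom1 + n_het + n_hom2;
  int kmin = ((int)n1 % 2 == 1) ? 1 : 0;
  int kmax = (int)(n1 < n2 ? n1 : n2);
  int kobs = n_het;
  long terms = 0;
  // locate the modal heterozygote count by hill-climbing on the ratio
  int kmode = (int)std::floor(n1 * n2 / (2.0 * n));
  kmode -= (kmode - kmin) % 2;
  if (kmode < kmin) kmode = kmin;
  if (kmode > kmax) kmode = kmax - ((kmax - kmin) % 2);
  while (kmode + 2 <= kmax && hwe_ratio_up(kmode, n1, n2) > 1.0) kmode += 2;
  while (kmode - 2 >= kmin && hwe_ratio_up(kmode - 2, n1, n2) < 1.0) kmode -= 2;
  // relative likelihood of the observed table, chained from the mode
  double obs_rel = 1.0;
  if (kobs > kmode)
    for (int k = kmode; k < kobs; k += 2) { obs_rel *= hwe_ratio_up(k, n1, n2); ++terms; }
  else
    for (int k = kmode; k > kobs; k -= 2) { obs_rel /= hwe_ratio_up(k - 2, n1, n2); ++terms; }
  double thr = obs_rel * (1.0 + TIE_TOL);
  double den = 1.0, num = (1.0 <= thr) ? 1.0 : 0.0; // mode term
  ++terms;
  // downward sweep; a tail may only stop once it has passed below the
  // observed likelihood, otherwise the numerator terms would be missed
  double cur = 1.0;
  for (int k = kmode - 2; k >= kmin; k -= 2) {
    cur /= hwe_ratio_up(k, n1, n2);
    ++terms;
    double den2 = den + cur, num2 = (cur <= thr) ? num + cur : num;
    if (den2 == den && num2 == num && (cur <= thr || cur == 0.0)) break;
    den = den2; num = num2;
  }
  // upward sweep
  cur = 1.0;
  for (int k = kmode + 2; k <= kmax; k += 2) {
    cur *= hwe_ratio_up(k - 2, n1, n2);
    ++terms;
    double den2 = den + cur, num2 = (cur <= thr) ? num + cur : num;
    if (den2 == den && num2 == num && (cur <= thr || cur == 0.0)) break;
    den = den2; num = num2;
  }
  double p = num / den;
  if (p > 1.0) p = 1.0;
  double obs_mass = obs_rel / den;
  return List::create(_["p"] = p, _["midp"] = p - obs_mass / 2.0,
                      _["obs_mass"] = obs_mass, _["n_terms"] = (double)terms);
}

// [[Rcpp::export(name = ".hwe_exact_full_cpp")]]
List hwe_exact_full_cpp(int n_hom1, int n_het, int n_hom2) {
  long double n1 = 2.0L * n_hom1 + n_het, n2 = 2.0L * n_hom2 + n_het;
  long double n = n_hom1 + n_het + n_hom2;
  if (n <= 0) stop("empty genotype table");
  int kmin = ((long)n1 % 2 == 1) ? 1 : 0;
  int kmax = (int)(n1 < n2 ? n1 : n2);
  int kobs = n_het;
  // absolute log-likelihood of k hets (up to the shared margin constant):
  // log L(k) = k log 2 + lgamma-based multinomial term
  std::vector<long double> ll;
  ll.reserve((kmax - kmin) / 2 + 1);
  long double lmax = -1e30L;
  for (int k = kmin; k <= kmax; k += 2) {
    long double l = k * 0.693147180559945309417232L
      - lgammal((n1 - k) / 2.0L + 1.0L) - lgammal((long double)k + 1.0L)
      - lgammal((n2 - k) / 2.0L + 1.0L);
    ll.push_back(l);
    if (l > lmax) lmax = l;
  }
  long double den = 0.0L, num = 0.0L, lobs = ll[(kobs - kmin) / 2];
  long double lthr = lobs + log1pl((long double)TIE_TOL);
  for (size_t i = 0; i < ll.size(); ++i) {
    long double t = expl(ll[i] - lmax);
    den += t;
    if (ll[i] <= lthr) num += t;
  }
  long double obs_mass = expl(lobs - lmax) / den;
  long double p = num / den;
  if (p > 1.0L) p = 1.0L;
  return List::create(_["p"] = (double)p, _["midp"] = (double)(p - obs_mass / 2.0L),
                      _["obs_mass"] = (double)obs_mass);
}

// ---- Fisher 2x2 ----------------------------------------------------------

// family over the upper-left cell x with margins (R1 rows, C1 cols, N total)
static inline double f22_ratio_up(double x, double R1, double C1, double N) {
  return (R1 - x) * (C1 - x) / ((x + 1.0) * (N - R1 - C1 + x + 1.0));
}

// shared by the R-facing wrapper and the max(T) permutation loop
double fisher22_p(int a, int b, int c, int d, double *midp_out) {
  double R1 = a + b, C1 = a + c, N = (double)a + b + c + d;
  if (N <= 0) stop("empty contingency table");
  int xmin = (int)std::fmax(0.0, R1 + C1 - N);
  int xmax = (int)std::fmin(R1, C1);
  if (xmin == xmax) { // single possible table
    if (midp_out) *midp_out = 0.5;
    return 1.0;
  }
  int xobs = a;
  int xmode = (int)std::floor((R1 + 1.0) * (C1 + 1.0) / (N + 2.0));
  if (xmode < xmin) xmode = xmin;
  if (xmode > xmax) xmode = xmax;
  while (xmode + 1 <= xmax && f22_ratio_up(xmode, R1, C1, N) > 1.0) ++xmode;
  while (xmode - 1 >= xmin && f22_ratio_up(xmode - 1, R1, C1, N) < 1.0) --xmode;
  double obs_rel = 1.0;
  if (xobs > xmode)
    for (int x = xmode; x < xobs; ++x) obs_rel *= f22_ratio_up(x, R1, C1, N);
  else
    for (int x = xmode; x > xobs; --x) obs_rel /= f22_ratio_up(x - 1, R1, C1, N);
  double thr = obs_rel * (1.0 + TIE_TOL);
  double den = 1.0, num = (1.0 <= thr) ? 1.0 : 0.0;
  // tails stop only after passing below the observed likelihood (see the
  // matching comment in the Hardy-Weinberg sweep)
  double cur = 1.0;
  for (int x = xmode - 1; x >= xmin; --x) {
    cur /= f22_ratio_up(x, R1, C1, N);
    double den2 = den + cur, num2 = (cur <= thr) ? num + cur : num;
    if (den2 == den && num2 == num && (cur <= thr || cur == 0.0)) break;
    den = den2; num = num2;
  }
  cur = 1.0;
  for (int x = xmode + 1; x <= xmax; ++x) {
    cur *= f22_ratio_up(x - 1, R1, C1, N);
    double den2 = den + cur, num2 = (cur <= thr) ? num + cur : num;
    if (den2 == den && num2 == num && (cur <= thr || cur == 0.0)) break;
    den = den2; num = num2;
  }
  double p = num / den;
  if (p > 1.0) p = 1.0;
  if (midp_out) *midp_out = p - obs_rel / den / 2.0;
  return p;
}

// [[Rcpp::export(name = ".fisher_2x2_cpp")]]
List fisher_2x2_cpp(int a, int b, int c, int d) {
  double midp;
  double p = fisher22_p(a, b, c, d, &midp);
  double R1 = a + b, C1 = a + c, N = (double)a + b + c + d;
  double obs_mass;
  if ((int)std::fmax(0.0, R1 + C1 - N) == (int)std::fmin(R1, C1)) obs_mass = 1.0;
  else obs_mass = 2.0 * (p - midp);
  return List::create(_["p"] = p, _["midp"] = midp, _["obs_mass"] = obs_mass);
}

// [[Rcpp::export(name = ".fisher_2x2_full_cpp")]]
List fisher_2x2_full_cpp(int a, int b, int c, int d) {
  long double R1 = a + b, C1 = a + c, N = (long double)a + b + c + d;
  if (N <= 0) stop("empty contingency table");
  int xmin = (int)fmaxl(0.0L, R1 + C1 - N);
  int xmax = (int)fminl(R1, C1);
  std::vector<long double> ll;
  long double lmax = -1e30L;
  for (int x = xmin; x <= xmax; ++x) {
    long double l = -lgammal(x + 1.0L) - lgammal(R1 - x + 1.0L)
      - lgammal(C1 - x + 1.0L) - lgammal(N - R1 - C1 + x + 1.0L);
    ll.push_back(l);
    if (l > lmax) lmax = l;
  }
  long double lobs = ll[a - xmin], lthr = lobs + log1pl((long double)TIE_TOL);
  long double den = 0.0L, num = 0.0L;
  for (size_t i = 0; i < ll.size(); ++i) {
    long double t = expl(ll[i] - lmax);
    den += t;
    if (ll[i] <= lthr) num += t;
  }
  long double obs_mass = expl(lobs - lmax) / den;
  long double p = num / den;
  if (p > 1.0L) p = 1.0L;
  return List::create(_["p"] = (double)p, _["midp"] = (double)(p - obs_mass / 2.0L),
                      _["obs_mass"] = (double)obs_mass);
}

// ---- Fisher 2x3 ----------------------------------------------------------

// Tables with margins (R1, R2 | C1, C2, C3) are parameterised by the first
// two top-row cells (a, b); the third is c = R1 - a - b.  Likelihood ratio
// recurrences for unit steps:
//   a -> a+1 (c -> c-1): r = c (C1 - a) / ((a + 1)(C3 - c + 1))
//   b -> b+1 (c -> c-1): r = c (C2 - b) / ((b + 1)(C3 - c + 1))
// The traversal visits the elliptical region of tables with relative
// likelihood >= 2^-53 l_max (denominator) and the annulus
// [2^-53 l_obs, l_obs] (numerator), scanning rows of constant `a` outward
// from the modal row and sweeping each row outward from its conditional
// mode.  Row reference likelihoods are chained in log space so no quantity
// ever under- or overflows.

struct F23 {
  double R1, C1, C2, C3, N;
  int bmin(int a) const {
    double lo = R1 - a - C3; // integer-valued
    return lo > 0 ? (int)lo : 0;
  }
  int bmax(int a) const {
    double hi = R1 - a;
    return (int)(hi < C2 ? hi : C2);
  }
  double ratio_b(int a, int b) const { // L(a, b+1) / L(a, b)
    double c = R1 - a - b;
    return c * (C2 - b) / ((b + 1.0) * (C3 - c + 1.0));
  }
  double ratio_a(int a, int b) const { // L(a+1, b) / L(a, b)
    double c = R1 - a - b;
    return c * (C1 - a) / ((a + 1.0) * (C3 - c + 1.0));
  }
};

// log relative likelihood of (a2,b2) given log rel of (a1,b1), chained along
// a monotone feasible path
static double f23_chain(const F23 &T, int a1, int b1, double l1, int a2, int b2) {
  int a = a1, b = b1;
  double l = l1;
  int guard = 0;
  while (a != a2 || b != b2) {
    if (++guard > 10000000) stop("chain failed to reach target table");
    bool moved = false;
    if (a < a2 && b >= T.bmin(a + 1) && b <= T.bmax(a + 1)) {
      l += std::log(T.ratio_a(a, b)); ++a; moved = true;
    } else if (a > a2 && b >= T.bmin(a - 1) && b <= T.bmax(a - 1)) {
      l -= std::log(T.ratio_a(a - 1, b)); --a; moved = true;
    }
    if (!moved) {
      // step b toward feasibility for the next row, or toward the target
      int btarget = b2;
      if (a != a2) {
        int anext = a < a2 ? a + 1 : a - 1;
        btarget = b < T.bmin(anext) ? T.bmin(anext) : T.bmax(anext);
      }
      if (b < btarget) { l += std::log(T.ratio_b(a, b)); ++b; }
      else if (b > btarget) { l -= std::log(T.ratio_b(a, b - 1)); --b; }
      else stop("chain stuck"); // unreachable on a convex feasible region
    }
  }
  return l;
}

// conditional mode of row a by hill-climb from b0 (clamped)
static int f23_row_mode(const F23 &T, int a, int b0, double *logrel) {
  int lo = T.bmin(a), hi = T.bmax(a);
  int b = b0 < lo ? lo : (b0 > hi ? hi : b0);
  double l = *logrel;
  while (b + 1 <= hi && T.ratio_b(a, b) > 1.0) { l += std::log(T.ratio_b(a, b)); ++b; }
  while (b - 1 >= lo && T.ratio_b(a, b - 1) < 1.0) { l -= std::log(T.ratio_b(a, b - 1)); --b; }
  *logrel = l;
  return b;
}

// sweep row a outward from its conditional mode; accumulates den (units of
// the global mode) and num (units of the observed likelihood)
static void f23_sweep_row(const F23 &T, int a, int bm, double logrel_m,
                          double lobs_rel, double *den, double *num) {
  int lo = T.bmin(a), hi = T.bmax(a);
  double scale_den = std::exp(logrel_m);           // row max over global mode
  double tro = std::exp(lobs_rel - logrel_m);       // L_obs in row-max units
  double thr_num_hi = tro * (1.0 + 1e-7);
  double thr_num_lo = tro * 1.1102230246251565e-16; // 2^-53
  double row_den = 0.0, row_num = 0.0;
  for (int dir = 0; dir < 2; ++dir) {
    double cur = 1.0;
    int b = bm;
    if (dir == 1) { // skip the mode term on the second pass
      if (1.0 <= thr_num_hi) row_num += 1.0;
      row_den += 1.0;
    }
    for (;;) {
      if (dir == 0) { if (b - 1 < lo) break; cur /= T.ratio_b(a, b - 1); --b; }
      else { if (b + 1 > hi) break; cur *= T.ratio_b(a, b); ++b; }
      double d2 = row_den + cur;
      bool in_num = (cur <= thr_num_hi && cur >= thr_num_lo);
      double n2 = in_num ? row_num + cur : row_num;
      if (d2 == row_den && n2 == row_num && (cur < thr_num_lo || cur == 0.0))
        break;
      row_den = d2; row_num = n2;
    }
  }
  *den += scale_den * row_den;
  // log-shifted so the intermediate exp() cannot overflow when the observed
  // likelihood is far below the row maximum
  if (row_num > 0.0)
    *num += std::exp((logrel_m - lobs_rel) + std::log(row_num));
}

// [[Rcpp::export(name = ".fisher_2x3_cpp")]]
List fisher_2x3_cpp(IntegerVector top, IntegerVector bottom) {
  if (top.size() != 3 || bottom.size() != 3) stop("rows must have 3 cells");
  F23 T;
  T.R1 = top[0] + top[1] + top[2];
  T.C1 = top[0] + bottom[0]; T.C2 = top[1] + bottom[1]; T.C3 = top[2] + bottom[2];
  T.N = T.R1 + bottom[0] + bottom[1] + bottom[2];
  if (T.N <= 0) stop("empty contingency table");
  int amin = (int)std::fmax(0.0, T.R1 - T.C2 - T.C3);
  int amax = (int)std::fmin(T.R1, T.C1);
  // modal table: rounded independence start, then greedy hill-climb
  int a = (int)std::floor(T.R1 * T.C1 / T.N + 0.5);
  if (a < amin) a = amin;
  if (a > amax) a = amax;
  double l0 = 0.0;
  int b = f23_row_mode(T, a, (int)std::floor(T.R1 * T.C2 / T.N + 0.5), &l0);
  for (;;) { // climb across rows until the row-mode likelihood stops rising
    bool up = false;
    if (a + 1 <= amax) {
      double l2 = l0; int b2 = b;
      int lo = T.bmin(a + 1), hi = T.bmax(a + 1);
      int bc = b2 < lo ? lo : (b2 > hi ? hi : b2);
      l2 = f23_chain(T, a, b, l0, a + 1, bc);
      b2 = f23_row_mode(T, a + 1, bc, &l2);
      if (l2 > l0) { a = a + 1; b = b2; l0 = l2; up = true; }
    }
    if (!up && a - 1 >= amin) {
      double l2 = l0; int b2 = b;
      int lo = T.bmin(a - 1), hi = T.bmax(a - 1);
      int bc = b2 < lo ? lo : (b2 > hi ? hi : b2);
      l2 = f23_chain(T, a, b, l0, a - 1, bc);
      b2 = f23_row_mode(T, a - 1, bc, &l2);
      if (l2 > l0) { a = a - 1; b = b2; l0 = l2; up = true; }
    }
    if (!up) break;
  }
  // renormalise so the mode has log relative likelihood 0
  int amode = a, bmode = b;
  double lobs_rel = f23_chain(T, amode, bmode, 0.0, top[0], top[1]);
  double den = 0.0, num = 0.0;
  double stop_log = (lobs_rel < 0.0 ? lobs_rel : 0.0) - LOG2_53 - 0.7;
  // scan rows outward from the modal row
  for (int dir = 0; dir < 2; ++dir) {
    int arow = amode;
    int brow = bmode;
    double lrow = 0.0;
    if (dir == 1) f23_sweep_row(T, amode, bmode, 0.0, lobs_rel, &den, &num);
    for (;;) {
      int anext = dir == 0 ? arow - 1 : arow + 1;
      if (anext < amin || anext > amax) break;
      int lo = T.bmin(anext), hi = T.bmax(anext);
      int bc = brow < lo ? lo : (brow > hi ? hi : brow);
      double lnext = f23_chain(T, arow, brow, lrow, anext, bc);
      int bnext = f23_row_mode(T, anext, bc, &lnext);
      arow = anext; brow = bnext; lrow = lnext;
      if (lrow < stop_log) break; // row maximum below every cutoff
      f23_sweep_row(T, arow, brow, lrow, lobs_rel, &den, &num);
    }
  }
  double p = std::exp(lobs_rel) * num / den;
  if (p > 1.0) p = 1.0;
  double obs_mass = std::exp(lobs_rel) / den;
  return List::create(_["p"] = p, _["midp"] = p - obs_mass / 2.0,
                      _["obs_mass"] = obs_mass);
}

// [[Rcpp::export(name = ".fisher_2x3_full_cpp")]]
List fisher_2x3_full_cpp(IntegerVector top, IntegerVector bottom) {
  if (top.size() != 3 || bottom.size() != 3) stop("rows must have 3 cells");
  long double R1 = top[0] + top[1] + top[2];
  long double C1 = top[0] + bottom[0], C2 = top[1] + bottom[1], C3 = top[2] + bottom[2];
  long double N = R1 + bottom[0] + bottom[1] + bottom[2];
  if (N <= 0) stop("empty contingency table");
  int amin = (int)fmaxl(0.0L, R1 - C2 - C3), amax = (int)fminl(R1, C1);
  long double lmax = -1e30L, lobs = 0.0L;
  // pass 1: locate the maximum and the observed table's log-likelihood
  for (int a = amin; a <= amax; ++a) {
    long double rem = R1 - a;
    int blo = (int)fmaxl(0.0L, rem - C3), bhi = (int)fminl(C2, rem);
    for (int b = blo; b <= bhi; ++b) {
      long double c = rem - b;
      long double l = -lgammal(a + 1.0L) - lgammal(b + 1.0L) - lgammal(c + 1.0L)
        - lgammal(C1 - a + 1.0L) - lgammal(C2 - b + 1.0L) - lgammal(C3 - c + 1.0L);
      if (l > lmax) lmax = l;
      if (a == top[0] && b == top[1]) lobs = l;
    }
  }
  long double lthr = lobs + log1pl(1e-7L);
  long double den = 0.0L, num = 0.0L, obs_t = 0.0L;
  for (int a = amin; a <= amax; ++a) {
    long double rem = R1 - a;
    int blo = (int)fmaxl(0.0L, rem - C3), bhi = (int)fminl(C2, rem);
    for (int b = blo; b <= bhi; ++b) {
      long double c = rem - b;
      long double l = -lgammal(a + 1.0L) - lgammal(b + 1.0L) - lgammal(c + 1.0L)
        - lgammal(C1 - a + 1.0L) - lgammal(C2 - b + 1.0L) - lgammal(C3 - c + 1.0L);
      long double t = expl(l - lmax);
      den += t;
      if (l <= lthr) num += t;
      if (a == top[0] && b == top[1]) obs_t = t;
    }
  }
  long double p = num / den;
  if (p > 1.0L) p = 1.0L;
  long double obs_mass = obs_t / den;
  return List::create(_["p"] = (double)p, _["midp"] = (double)(p - obs_mass / 2.0L),
                      _["obs_mass"] = (double)obs_mass);
}
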