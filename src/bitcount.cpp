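// Bitwise genotype counting: per SNP, 3 bitsets (one per genotype code) per
// phenotype class; a k-locus contingency cell is the popcount of the AND of
// the k bitsets selecting that genotype combination. Bitsets are stored as a
// raw array of dim (nbytes, 3, M) per class, nbytes a multiple of 8 so that
// words can be read as uint64.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>

using namespace Rcpp;

static inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0;
  while (x) { x &= x - 1; ++c; }
  return c;
#endif
}

struct BitView {
  const uint8_t *base;
  int nbytes;   // per bitset, multiple of 8
  int nsnp;
  const uint8_t *bitset(int snp0, int g) const {
    return base + ((size_t)snp0 * 3 + g) * (size_t)nbytes;
  }
};

static BitView view_of(const RawVector &x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3 || d[1] != 3)
    stop("bit array must have dim (nbytes, 3, M)");
  BitView v;
  v.base = (const uint8_t *)RAW(x);
  v.nbytes = d[0];
  v.nsnp = d[2];
  if (v.nbytes % 8 != 0) stop("bit array byte count must be a multiple of 8");
  return v;
}

// popcount of AND over k bitsets of one class for genotype combination g
static int cell_count(const BitView &v, const int *snps0, const int *g, int k) {
  int nw = v.nbytes / 8, cnt = 0;
  for (int w = 0; w < nw; ++w) {
    uint64_t acc = ~(uint64_t)0;
    for (int i = 0; i < k; ++i) {
      uint64_t word;
      std::memcpy(&word, v.bitset(snps0[i], g[i]) + 8 * w, 8);
      acc &= word;
    }
    cnt += popcount64(acc);
  }
  return cnt;
}

// decode row index u (0-based, first SNP most significant) into genotypes
static void decode_row(int u, int k, int *g) {
  for (int i = k - 1; i >= 0; --i) { g[i] = u % 3; u /= 3; }
}

// chi-squared statistic of independence on a r x 2 table, skipping rows with
// zero margin; returns NA if a column margin is zero
static double chi2_stat(const std::vector<int> &ca, const std::vector<int> &co) {
  double na = 0.0, nu = 0.0;
  size_t r = ca.size();
  for (size_t u = 0; u < r; ++u) { na += ca[u]; nu += co[u]; }
  double N = na + nu;
  if (na <= 0.0 || nu <= 0.0) return NA_REAL;
  double s = 0.0;
  for (size_t u = 0; u < r; ++u) {
    double rm = (double)ca[u] + (double)co[u];
    if (rm <= 0.0) continue;
    double ea = rm * na / N, eu = rm * nu / N;
    double da = ca[u] - ea, du = co[u] - eu;
    s += da * da / ea + du * du / eu;
  }
  return s;
}

// [[Rcpp::export]]
IntegerMatrix cpp_contingency(RawVector case_bits, RawVector ctrl_bits,
                              IntegerVector snps) {
  BitView vc = view_of(case_bits), vu = view_of(ctrl_bits);
  if (vc.nsnp != vu.nsnp) stop("case/control bit arrays disagree on SNP count");
  int k = snps.size();
  if (k < 1) stop("need at least one SNP");
  std::vector<int> s0(k);
  for (int i = 0; i < k; ++i) {
    if (snps[i] < 1 || snps[i] > vc.nsnp) stop("SNP index out of range");
    s0[i] = snps[i] - 1;
  }
  int nrows = 1;
  for (int i = 0; i < k; ++i) nrows *= 3;
  IntegerMatrix out(nrows, 2);
  std::vector<int> g(k);
  for (int u = 0; u < nrows; ++u) {
    decode_row(u, k, g.data());
    out(u, 0) = cell_count(vc, s0.data(), g.data(), k);
    out(u, 1) = cell_count(vu, s0.data(), g.data(), k);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_chi2_subsets(RawVector case_bits, RawVector ctrl_bits,
                               IntegerMatrix subsets) {
  BitView vc = view_of(case_bits), vu = view_of(ctrl_bits);
  int k = subsets.nrow(), n = subsets.ncol();
  int nrows = 1;
  for (int i = 0; i < k; ++i) nrows *= 3;
  NumericVector out(n);
  std::vector<int> s0(k), g(k);
  std::vector<int> ca(nrows), co(nrows);
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < k; ++i) {
      int s = subsets(i, j);
      if (s < 1 || s > vc.nsnp) stop("SNP index out of range");
      s0[i] = s - 1;
    }
    for (int u = 0; u < nrows; ++u) {
      decode_row(u, k, g.data());
      ca[u] = cell_count(vc, s0.data(), g.data(), k);
      co[u] = cell_count(vu, s0.data(), g.data(), k);
    }
    out[j] = chi2_stat(ca, co);
  }
  return out;
}

// All-pairs scan: returns (i, j, chi2) for pairs with chi2 > retain.
// [[Rcpp::export]]
NumericMatrix cpp_pair_scan(RawVector case_bits, RawVector ctrl_bits,
                            double retain) {
  BitView vc = view_of(case_bits), vu = view_of(ctrl_bits);
  int M = vc.nsnp;
  std::vector<double> keep;
  std::vector<int> ca(9), co(9);
  int s0[2], g[2];
  for (int i = 0; i < M - 1; ++i) {
    for (int j = i + 1; j < M; ++j) {
      s0[0] = i; s0[1] = j;
      for (int u = 0; u < 9; ++u) {
        g[0] = u / 3; g[1] = u % 3;
        ca[u] = cell_count(vc, s0, g, 2);
        co[u] = cell_count(vu, s0, g, 2);
      }
      double s = chi2_stat(ca, co);
      if (!ISNA(s) && s > retain) {
        keep.push_back(i + 1.0);
        keep.push_back(j + 1.0);
        keep.push_back(s);
      }
    }
    Rcpp::checkUserInterrupt();
  }
  int n = keep.size() / 3;
  NumericMatrix out(n, 3);
  for (int r = 0; r < n; ++r) {
    out(r, 0) = keep[3 * r];
    out(r, 1) = keep[3 * r + 1];
    out(r, 2) = keep[3 * r + 2];
  }
  return out;
}

// Per-SNP genotype counts in one class (popcounts of the 3 bitsets).
// [[Rcpp::export]]
IntegerMatrix cpp_genotype_counts(RawVector bits) {
  BitView v = view_of(bits);
  IntegerMatrix out(3, v.nsnp);
  int nw = v.nbytes / 8;
  for (int s = 0; s < v.nsnp; ++s) {
    for (int g = 0; g < 3; ++g) {
      const uint8_t *b = v.bitset(s, g);
      int cnt = 0;
      for (int w = 0; w < nw; ++w) {
        uint64_t word;
        std::memcpy(&word, b + 8 * w, 8);
        cnt += popcount64(word);
      }
      out(g, s) = cnt;
    }
  }
  return out;
}
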