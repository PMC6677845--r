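#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Base-2 digital-net machinery for Sobol' point sets with Matousek-style
// randomisation: a random linear matrix scramble (lower triangular, unit
// diagonal, applied to the digit vector of every point) followed by a random
// digital shift (XOR with a fixed random digit vector per dimension).
//
// All arithmetic uses 32 binary digits; a point value is digits / 2^32, so
// every coordinate lies in [0, 1 - 2^-32] and the half-open [0,1) contract
// holds without clamping.

static const int NBITS = 32;

// 32 random bits from R's RNG (two 16-bit draws; unif_rand granularity is
// far finer than 2^-16, so each draw is effectively uniform on 0..65535).
static inline uint32_t rand_bits32() {
  uint32_t hi = (uint32_t)(unif_rand() * 65536.0) & 0xFFFFu;
  uint32_t lo = (uint32_t)(unif_rand() * 65536.0) & 0xFFFFu;
  return (hi << 16) | lo;
}

static inline int parity32(uint32_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_parity(x);
#else
  x ^= x >> 16; x ^= x >> 8; x ^= x >> 4; x ^= x >> 2; x ^= x >> 1;
  return (int)(x & 1u);
#endif
}

// Direction numbers v[0..NBITS-1] for one dimension, digit 1 (MSB) in bit 31.
// dim_index is 1-based; dimension 1 is the van der Corput radical inverse.
static void direction_numbers(int dim_index, const IntegerVector& poly,
                              const IntegerMatrix& vinit, uint32_t* v) {
  if (dim_index == 1) {
    for (int i = 0; i < NBITS; ++i) v[i] = 1u << (31 - i);
    return;
  }
  int row = dim_index - 1;            // 0-based row in the tables
  uint32_t p = (uint32_t)poly[row];
  int deg = 0;
  for (uint32_t t = p; t > 1; t >>= 1) ++deg;   // degree = bit length - 1
  for (int i = 0; i < deg && i < NBITS; ++i)
    v[i] = ((uint32_t)vinit(row, i)) << (31 - i);
  for (int i = deg; i < NBITS; ++i) {
    uint32_t acc = v[i - deg] ^ (v[i - deg] >> deg);
    for (int k = 1; k < deg; ++k)
      if ((p >> (deg - k)) & 1u) acc ^= v[i - k];
    v[i] = acc;
  }
}

// Apply a random lower-triangular scramble matrix L (unit diagonal) to a
// digit vector: output digit i = parity(row_i & digits). Rows are drawn from
// R's RNG; the same L must act on every point of the dimension, so L is
// materialised as 32 row masks and applied to the direction numbers (the
// points are GF(2)-linear combinations of direction numbers, so scrambling
// the generators scrambles every point identically).
static void scramble_directions(uint32_t* v) {
  uint32_t rows[NBITS];
  for (int i = 0; i < NBITS; ++i) {
    uint32_t below = (i == 0) ? 0u : (rand_bits32() & (0xFFFFFFFFu << (32 - i)));
    rows[i] = below | (1u << (31 - i));
  }
  for (int k = 0; k < NBITS; ++k) {
    uint32_t y = 0;
    for (int i = 0; i < NBITS; ++i)
      if (parity32(rows[i] & v[k])) y |= 1u << (31 - i);
    v[k] = y;
  }
}

static inline int ctz32(uint32_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_ctz(x);
#else
  int c = 0; while (!(x & 1u)) { x >>= 1; ++c; } return c;
#endif
}

// [[Rcpp::export(name = ".sobol_points_cpp")]]
NumericMatrix sobol_points_cpp(int n, int s, IntegerVector poly,
                               IntegerMatrix vinit, bool scramble,
                               bool shift) {
  if (n < 1 || s < 1) stop("n and s must be positive");
  if (s > poly.size()) stop("dimension exceeds available direction numbers");
  NumericMatrix out(n, s);
  std::vector<uint32_t> v(NBITS);
  const double scale = 1.0 / 4294967296.0;  // 2^-32
  for (int j = 0; j < s; ++j) {
    direction_numbers(j + 1, poly, vinit, v.data());
    if (scramble) scramble_directions(v.data());
    uint32_t d = shift ? rand_bits32() : 0u;
    uint32_t x = 0;
    for (int i = 0; i < n; ++i) {
      out(i, j) = (double)(x ^ d) * scale;   // Gray-code enumeration
      x ^= v[ctz32((uint32_t)i + 1u)];
    }
  }
  return out;
}
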