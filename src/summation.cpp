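// Accumulation strategies for binary64 vectors: ordered naive and Kahan
// sums, a correctly rounded order-invariant sum through a Kulisch-style
// long accumulator, and an exact decimal-expansion oracle.

#include "summation.h"
#include "decimal.h"

#include <cmath>
#include <cstring>
#include <cstdio>
#include <cstdlib>
#include <stdexcept>
#include <string>

namespace hhsum {

double sum_naive(const double *x, size_t n) {
  if (n == 0) return 0.0;
  double s = x[0];
  for (size_t i = 1; i < n; ++i) s = s + x[i];
  return s;
}

double sum_kahan(const double *x, size_t n) {
  // classic Kahan: left-to-right, single compensation term starting at zero
  double s = 0.0, c = 0.0;
  for (size_t i = 0; i < n; ++i) {
    double y = x[i] - c;
    double t = s + y;
    c = (t - s) - y;
    s = t;
  }
  return s;
}

// --------------------------------------------------------------------------
// Kulisch accumulator: bit 0 of limb 0 represents 2^-1074

static const int KLIMBS = 40;

void KAcc::reset() {
  std::memset(pos, 0, sizeof(pos));
  std::memset(neg, 0, sizeof(neg));
}

void KAcc::add(double x) {
  if (x == 0.0) return;
  if (!std::isfinite(x)) throw std::runtime_error("non-finite value in reproducible sum");
  uint64_t bits;
  std::memcpy(&bits, &x, 8);
  uint64_t frac = bits & ((1ULL << 52) - 1);
  int bexp = (int)((bits >> 52) & 0x7ff);
  uint64_t m;
  int e;
  if (bexp == 0) { m = frac; e = -1074; }
  else { m = frac | (1ULL << 52); e = bexp - 1075; }
  uint64_t *acc = (bits >> 63) ? neg : pos;
  int b = e + 1074;
  int w = b >> 6, off = b & 63;
  unsigned __int128 v = ((unsigned __int128)m) << off;
  uint64_t lo = (uint64_t)v, hi = (uint64_t)(v >> 64);
  unsigned __int128 s = (unsigned __int128)acc[w] + lo;
  acc[w] = (uint64_t)s;
  uint64_t carry = (uint64_t)(s >> 64);
  int i = w + 1;
  s = (unsigned __int128)acc[i] + hi + carry;
  acc[i] = (uint64_t)s;
  carry = (uint64_t)(s >> 64);
  while (carry && ++i < KLIMBS) {
    s = (unsigned __int128)acc[i] + carry;
    acc[i] = (uint64_t)s;
    carry = (uint64_t)(s >> 64);
  }
}

double KAcc::result() const {
  // sign-magnitude difference pos - neg
  int cmp = 0;
  for (int i = KLIMBS - 1; i >= 0; --i)
    if (pos[i] != neg[i]) { cmp = pos[i] > neg[i] ? 1 : -1; break; }
  if (cmp == 0) return 0.0;
  const uint64_t *a = cmp > 0 ? pos : neg, *b = cmp > 0 ? neg : pos;
  uint64_t mag[KLIMBS];
  unsigned char brw = 0;
  for (int i = 0; i < KLIMBS; ++i) {
    uint64_t bi = b[i] + brw;
    brw = (bi < (uint64_t)brw) || (a[i] < bi);
    mag[i] = a[i] - bi;
  }
  int top = KLIMBS - 1;
  while (top > 0 && mag[top] == 0) top--;
  int p = top * 64 + (63 - __builtin_clzll(mag[top]));  // msb index
  double sgn = cmp > 0 ? 1.0 : -1.0;
  if (p <= 52) {
    return sgn * std::ldexp((double)mag[0], -1074);
  }
  int s = p - 52;
  int lo = s >> 6, off = s & 63;
  uint64_t mant = mag[lo] >> off;
  if (off > 11) mant |= mag[lo + 1] << (64 - off);
  mant &= (1ULL << 53) - 1;
  int gpos = s - 1;
  uint64_t guard = (mag[gpos >> 6] >> (gpos & 63)) & 1ULL;
  bool sticky = false;
  int glimb = gpos >> 6, goff = gpos & 63;
  if (goff > 0) sticky = (mag[glimb] & ((1ULL << goff) - 1)) != 0;
  for (int i = 0; i < glimb && !sticky; ++i) sticky = mag[i] != 0;
  if (guard && (sticky || (mant & 1))) {
    mant++;
    if (mant == (1ULL << 53)) { mant >>= 1; s++; }
  }
  return sgn * std::ldexp((double)mant, s - 1074);
}

double sum_repro(const double *x, size_t n) {
  KAcc acc;
  acc.reset();
  for (size_t i = 0; i < n; ++i) acc.add(x[i]);
  return acc.result();
}

// --------------------------------------------------------------------------
// exact decimal oracle

double sum_exact_decimal(const double *x, size_t n) {
  // fixed-point decimal accumulators: limb i covers 10^(BEXP + 18*i) ...,
  // spanning the full double range (lowest digit 10^-1074, top ~10^309)
  const int ALIMBS = 84;
  const long long BEXP = -1080;
  static uint64_t apos[ALIMBS], aneg[ALIMBS];  // single-threaded under R
  std::memset(apos, 0, sizeof(apos));
  std::memset(aneg, 0, sizeof(aneg));

  std::string digs;
  long long dexp;
  int sign;
  for (size_t ii = 0; ii < n; ++ii) {
    if (x[ii] == 0.0) continue;
    hhdec::double_exact_parts(x[ii], digs, dexp, sign);
    long long shift = dexp - BEXP;
    if (shift < 0) throw std::runtime_error("internal: oracle exponent range");
    int limb = (int)(shift / 18), r = (int)(shift % 18);
    digs.append((size_t)r, '0');
    uint64_t *acc = sign < 0 ? aneg : apos;
    int pos = (int)digs.size();
    int i = limb;
    while (pos > 0) {
      int lo = pos - 18; if (lo < 0) lo = 0;
      uint64_t v = 0;
      for (int k = lo; k < pos; ++k) v = v * 10 + (uint64_t)(digs[k] - '0');
      if (i >= ALIMBS) throw std::runtime_error("internal: oracle overflow");
      acc[i] += v;
      int j = i;
      while (acc[j] >= hhdec::LBASE) {  // immediate carry keeps limbs < 1e18
        acc[j] -= hhdec::LBASE;
        if (j + 1 >= ALIMBS) throw std::runtime_error("internal: oracle overflow");
        acc[j + 1] += 1;
        j++;
      }
      pos = lo;
      i++;
    }
  }

  int cmp = 0;
  for (int i = ALIMBS - 1; i >= 0; --i)
    if (apos[i] != aneg[i]) { cmp = apos[i] > aneg[i] ? 1 : -1; break; }
  if (cmp == 0) return 0.0;
  const uint64_t *a = cmp > 0 ? apos : aneg, *b = cmp > 0 ? aneg : apos;
  uint64_t mag[ALIMBS];
  int64_t brw = 0;
  for (int i = 0; i < ALIMBS; ++i) {
    int64_t d = (int64_t)a[i] - (int64_t)b[i] - brw;  // base-10^18 borrow
    brw = d < 0;
    if (d < 0) d += (int64_t)hhdec::LBASE;
    mag[i] = (uint64_t)d;
  }
  int top = ALIMBS - 1;
  while (top > 0 && mag[top] == 0) top--;

  // full exact decimal string, then one correctly rounded strtod
  char buf[32];
  std::string s;
  s.reserve(20 * (top + 2) + 16);
  if (cmp < 0) s.push_back('-');
  std::snprintf(buf, sizeof(buf), "%llu", (unsigned long long)mag[top]);
  s += buf;
  for (int i = top - 1; i >= 0; --i) {
    std::snprintf(buf, sizeof(buf), "%018llu", (unsigned long long)mag[i]);
    s += buf;
  }
  std::snprintf(buf, sizeof(buf), "e%lld", BEXP);
  s += buf;
  return std::strtod(s.c_str(), nullptr);
}

}  // namespace hhsum
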