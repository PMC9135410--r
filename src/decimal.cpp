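// Fixed-capacity decimal floating-point arithmetic with half-even rounding
// at a caller-supplied number of significant digits, plus exact binary64
// decimal-expansion utilities.  No third-party bignum is used: the decimal
// backend and its elementary functions are the point of the package, so the
// whole arithmetic path is in-repo and deterministic.

#include "decimal.h"

#include <cmath>
#include <cstdio>
#include <cstring>
#include <cstdlib>
#include <stdexcept>
#include <vector>

namespace hhdec {

typedef unsigned __int128 u128;

static const uint64_t POW10[19] = {
  1ULL, 10ULL, 100ULL, 1000ULL, 10000ULL, 100000ULL, 1000000ULL, 10000000ULL,
  100000000ULL, 1000000000ULL, 10000000000ULL, 100000000000ULL,
  1000000000000ULL, 10000000000000ULL, 100000000000000ULL,
  1000000000000000ULL, 10000000000000000ULL, 100000000000000000ULL,
  1000000000000000000ULL};

static inline int digcount_u64(uint64_t v) {
  if (v == 0) return 1;
  int bits = 64 - __builtin_clzll(v);
  int d = (bits * 1233) >> 12;           // floor(bits * log10(2)) approximation
  if (d > 18) d = 18;
  return d + (v >= POW10[d] ? 1 : 0);
}

// quotient/remainder of a 128-bit value by 10^18 without __udivti3:
// 10^18 = 2^18 * 5^18, and division by the 42-bit constant 5^18 is done with
// a Barrett reciprocal (one 128x128 high multiply plus a small correction).
static inline u128 divmod_L(u128 s, uint64_t &rem) {
  const uint64_t D5 = 3814697265625ULL;            // 5^18
  constexpr u128 M = (~(u128)0) / 3814697265625ULL; // floor(2^128 / 5^18)
  u128 t = s >> 18;
  uint64_t th = (uint64_t)(t >> 64), tl = (uint64_t)t;
  uint64_t Mh = (uint64_t)(M >> 64), Ml = (uint64_t)M;
  u128 lolo = (u128)tl * Ml;
  u128 mid1 = (u128)tl * Mh + (lolo >> 64);
  u128 mid2 = (u128)th * Ml;
  u128 midsum = mid1 + mid2;
  u128 carry128 = midsum < mid1 ? ((u128)1 << 64) : (u128)0;
  u128 q = (u128)th * Mh + (midsum >> 64) + carry128;
  u128 r = t - q * D5;
  while (r >= D5) { r -= D5; q += 1; }
  rem = (uint64_t)(((uint64_t)r << 18) | ((uint64_t)s & 0x3ffffULL));
  return q;
}

Dec dec_zero() {
  Dec z;
  z.exp = 0; z.n = 0; z.sign = 0;
  return z;
}

bool dec_is_zero(const Dec &a) { return a.n == 0; }

int dec_ndigits(const Dec &a) {
  if (a.n == 0) return 0;
  return LD * (a.n - 1) + digcount_u64(a.d[a.n - 1]);
}

int dec_top(const Dec &a) { return a.exp + dec_ndigits(a); }

Dec dec_neg(const Dec &a) {
  Dec r = a;
  r.sign = (int8_t)(-r.sign);
  return r;
}

static void normalize(Dec &a) {
  while (a.n > 0 && a.d[a.n - 1] == 0) a.n--;
  if (a.n == 0) { a.sign = 0; a.exp = 0; return; }
  int drop = 0;
  while (drop < a.n - 1 && a.d[drop] == 0) drop++;
  if (drop > 0) {
    for (int i = drop; i < a.n; ++i) a.d[i - drop] = a.d[i];
    a.n = (int16_t)(a.n - drop);
    a.exp += LD * drop;
  }
}

// ---------------------------------------------------------------------------
// rounding

static void coeff_increment(Dec &a) {
  for (int i = 0; i < a.n; ++i) {
    if (++a.d[i] < LBASE) return;
    a.d[i] = 0;
  }
  if (a.n >= LMAX) throw std::runtime_error("decimal coefficient overflow");
  a.d[a.n++] = 1;
}

// Per-limb Barrett division by 10^r (1 <= r <= 17), one pass over the
// coefficient.  10^r = 2^r * 5^r; t = cur >> r is divided by 5^r via a
// precomputed 128-bit reciprocal.
static const uint64_t POW5[18] = {
  1ULL, 5ULL, 25ULL, 125ULL, 625ULL, 3125ULL, 15625ULL, 78125ULL, 390625ULL,
  1953125ULL, 9765625ULL, 48828125ULL, 244140625ULL, 1220703125ULL,
  6103515625ULL, 30517578125ULL, 152587890625ULL, 762939453125ULL};

static inline uint64_t div_pow10_limb(u128 cur, int r, uint64_t &rem) {
  static u128 M5[18];
  static bool init = false;
  if (!init) {
    for (int i = 1; i < 18; ++i) M5[i] = (~(u128)0) / POW5[i];
    init = true;
  }
  const uint64_t D5 = POW5[r];
  u128 t = cur >> r;
  u128 M = M5[r];
  uint64_t th = (uint64_t)(t >> 64), tl = (uint64_t)t;
  uint64_t Mh = (uint64_t)(M >> 64), Ml = (uint64_t)M;
  u128 lolo = (u128)tl * Ml;
  u128 mid1 = (u128)tl * Mh + (lolo >> 64);
  u128 mid2 = (u128)th * Ml;
  u128 midsum = mid1 + mid2;
  u128 carry128 = midsum < mid1 ? ((u128)1 << 64) : (u128)0;
  u128 q = (u128)th * Mh + (midsum >> 64) + carry128;
  u128 r5 = t - q * D5;
  while (r5 >= D5) { r5 -= D5; q += 1; }
  rem = (uint64_t)(((uint64_t)r5 << r) | ((uint64_t)cur & ((1ULL << r) - 1)));
  return (uint64_t)q;
}

// divide coefficient by 10^r (0 < r < 18), returning the remainder
static uint64_t coeff_shift_down(Dec &a, int r) {
  uint64_t carry = 0;
  for (int i = a.n - 1; i >= 0; --i) {
    u128 cur = (u128)carry * LBASE + a.d[i];
    uint64_t rm;
    a.d[i] = div_pow10_limb(cur, r, rm);
    carry = rm;
  }
  a.exp += r;
  while (a.n > 0 && a.d[a.n - 1] == 0) a.n--;  // top limb may have emptied
  return carry;
}

void dec_round(Dec &a, int P, int mode, int sticky) {
  if (a.n == 0) return;
  if (P < PMIN) throw std::runtime_error("invalid precision");
  int D = dec_ndigits(a);
  int drop = D - P;
  if (drop <= 0) return;  // residue (if any) is far below the last kept digit

  int q = drop / LD, r = drop % LD;
  int dir = 0;  // -1 leave, +1 increment, 0 true tie
  bool low_nonzero = false;
  uint64_t top_dropped = 0;
  if (q > 0) {
    top_dropped = a.d[q - 1];
    for (int i = 0; i < q - 1; ++i) low_nonzero |= (a.d[i] != 0);
    for (int i = q; i < a.n; ++i) a.d[i - q] = a.d[i];
    a.n = (int16_t)(a.n - q);
    a.exp += LD * q;
  }
  if (r > 0) {
    // the whole dropped top limb (if any) ranks below the 10^r remainder
    low_nonzero |= (top_dropped != 0);
    uint64_t rm = coeff_shift_down(a, r);
    uint64_t half = 5 * POW10[r - 1];
    if (rm > half) dir = +1;
    else if (rm < half) { dir = -1; low_nonzero |= (rm != 0); }
    else dir = 0;
  } else {
    const uint64_t halfL = 5 * POW10[LD - 1];  // 5e17, half of one limb unit
    if (top_dropped > halfL) dir = +1;
    else if (top_dropped < halfL) dir = -1;
    else dir = 0;
  }
  if (mode == RND_TRUNC) {
    normalize(a);
    return;
  }
  if (dir == 0) {  // boundary: consult lower digits, then the sticky residue
    if (low_nonzero || sticky > 0) dir = +1;
    else if (sticky < 0) dir = -1;
  }
  if (dir == 0) {  // exact tie: half to even
    if (a.n > 0 && (a.d[0] % 10) & 1) dir = +1;
  }
  if (dir > 0) {
    coeff_increment(a);
    if (dec_ndigits(a) > P) coeff_shift_down(a, 1);  // 999.. -> 1000..: exact
  }
  normalize(a);
}

// ---------------------------------------------------------------------------
// addition / subtraction

// write the coefficient of x, scaled up by `s` decimal digits, into out[];
// returns the limb count
static int expand_into(const Dec &x, int s, uint64_t out[], int cap) {
  int q = s / LD, r = s % LD;
  for (int i = 0; i < q; ++i) out[i] = 0;
  int len = x.n + q;
  for (int i = 0; i < x.n; ++i) out[q + i] = x.d[i];
  if (r > 0) {
    uint64_t carry = 0, pw = POW10[r];
    for (int i = q; i < len; ++i) {
      u128 cur = (u128)out[i] * pw + carry;
      carry = (uint64_t)(cur / LBASE);
      out[i] = (uint64_t)(cur % LBASE);
    }
    if (carry) out[len++] = carry;
  }
  if (len > cap) throw std::runtime_error("decimal alignment overflow");
  return len;
}

// write the coefficient of x, scaled DOWN by k digits; sets dropped=true if
// nonzero digits were discarded
static int shrink_into(const Dec &x, int k, uint64_t out[], bool &dropped) {
  int q = k / LD, r = k % LD;
  dropped = false;
  for (int i = 0; i < q && i < x.n; ++i) dropped |= (x.d[i] != 0);
  int len = x.n - q;
  if (len <= 0) { dropped = dropped || (x.n > 0); return 0; }
  for (int i = 0; i < len; ++i) out[i] = x.d[q + i];
  if (r > 0) {
    uint64_t pw = POW10[r], carry = 0;
    for (int i = len - 1; i >= 0; --i) {
      u128 cur = (u128)carry * LBASE + out[i];
      out[i] = (uint64_t)(cur / pw);
      carry = (uint64_t)(cur % pw);
    }
    dropped |= (carry != 0);
    while (len > 0 && out[len - 1] == 0) len--;
  }
  return len;
}

static int cmp_arrays(const uint64_t *A, int la, const uint64_t *B, int lb) {
  if (la != lb) return la > lb ? 1 : -1;
  for (int i = la - 1; i >= 0; --i)
    if (A[i] != B[i]) return A[i] > B[i] ? 1 : -1;
  return 0;
}

Dec dec_add(const Dec &a, const Dec &b, int P) {
  if (a.n == 0) { Dec r = b; dec_round(r, P, RND_HALF_EVEN, 0); return r; }
  if (b.n == 0) { Dec r = a; dec_round(r, P, RND_HALF_EVEN, 0); return r; }

  int T = dec_top(a) > dec_top(b) ? dec_top(a) : dec_top(b);
  int emin = a.exp < b.exp ? a.exp : b.exp;
  int target = T - (P + 26);
  if (emin > target) target = emin;

  const int CAP = LMAX + 6;
  uint64_t A[CAP], B[CAP];
  int la, lb, res_a = 0, res_b = 0;  // residue sign (value-level) per operand
  if (a.exp >= target) la = expand_into(a, a.exp - target, A, CAP);
  else { bool dr; la = shrink_into(a, target - a.exp, A, dr); if (dr) res_a = a.sign; }
  if (b.exp >= target) lb = expand_into(b, b.exp - target, B, CAP);
  else { bool dr; lb = shrink_into(b, target - b.exp, B, dr); if (dr) res_b = b.sign; }

  Dec r;
  r.exp = target;
  int res_sign = res_a != 0 ? res_a : res_b;  // at most one operand truncated
  if ((la > lb ? la : lb) > LMAX) throw std::runtime_error("decimal add overflow");
  if (a.sign == b.sign) {
    int len = la > lb ? la : lb;
    uint64_t carry = 0;
    for (int i = 0; i < len; ++i) {
      uint64_t s = (i < la ? A[i] : 0) + carry;
      carry = 0;
      if (i < lb) s += B[i];
      if (s >= LBASE) { s -= LBASE; carry = 1; }
      r.d[i] = s;
    }
    if (carry) {
      if (len >= LMAX) throw std::runtime_error("decimal add overflow");
      r.d[len++] = 1;
    }
    if (len > LMAX) throw std::runtime_error("decimal add overflow");
    r.n = (int16_t)len;
    r.sign = a.sign;
  } else {
    int c = cmp_arrays(A, la, B, lb);
    if (c == 0) {
      r = dec_zero();
      return r;  // exact cancellation cannot coexist with a truncated residue
    }
    const uint64_t *X = c > 0 ? A : B, *Y = c > 0 ? B : A;
    int lx = c > 0 ? la : lb, ly = c > 0 ? lb : la;
    int64_t borrow = 0;
    for (int i = 0; i < lx; ++i) {
      int64_t s = (int64_t)X[i] - borrow - (i < ly ? (int64_t)Y[i] : 0);
      borrow = 0;
      if (s < 0) { s += (int64_t)LBASE; borrow = 1; }
      r.d[i] = (uint64_t)s;
    }
    r.n = (int16_t)lx;
    r.sign = c > 0 ? a.sign : b.sign;
  }
  normalize(r);
  int sticky = (res_sign == 0 || r.sign == 0) ? 0 : res_sign * r.sign;
  dec_round(r, P, RND_HALF_EVEN, sticky);
  return r;
}

Dec dec_sub(const Dec &a, const Dec &b, int P) { return dec_add(a, dec_neg(b), P); }

int dec_cmp(const Dec &a, const Dec &b) {
  // wide precision so that neither operand is ever truncated during alignment
  Dec d = dec_add(a, dec_neg(b), LD * (LMAX - 3));
  return d.sign;
}

static int dec_cmpmag(const Dec &a, const Dec &b) {
  Dec aa = a, bb = b;
  aa.sign = aa.n ? 1 : 0;
  bb.sign = bb.n ? 1 : 0;
  return dec_cmp(aa, bb);
}

// ---------------------------------------------------------------------------
// multiplication

Dec dec_mul(const Dec &a, const Dec &b, int P) {
  if (a.n == 0 || b.n == 0) return dec_zero();
  Dec r;
  int nr = a.n + b.n;
  if (nr > LMAX) throw std::runtime_error("decimal mul overflow");
  u128 carry = 0;
  int len = 0;
  for (int k = 0; k < nr; ++k) {
    u128 s = carry;
    int ilo = k - (b.n - 1); if (ilo < 0) ilo = 0;
    int ihi = k < a.n - 1 ? k : a.n - 1;
    for (int i = ilo; i <= ihi; ++i) s += (u128)a.d[i] * b.d[k - i];
    uint64_t rem;
    carry = divmod_L(s, rem);
    r.d[k] = rem;
    len = k + 1;
  }
  if (carry != 0) throw std::runtime_error("decimal mul overflow");
  r.n = (int16_t)len;
  r.exp = a.exp + b.exp;
  r.sign = (int8_t)(a.sign * b.sign);
  normalize(r);
  dec_round(r, P, RND_HALF_EVEN, 0);
  return r;
}

Dec dec_from_int(long long v) {
  Dec r = dec_zero();
  if (v == 0) return r;
  r.sign = v < 0 ? -1 : 1;
  unsigned long long m = v < 0 ? (unsigned long long)(-(v + 1)) + 1ULL
                               : (unsigned long long)v;
  r.exp = 0; r.n = 0;
  while (m) { r.d[r.n++] = m % LBASE; m /= LBASE; }
  return r;
}

// ---------------------------------------------------------------------------
// division

Dec dec_div_small(const Dec &a, uint64_t k, int P) {
  if (k == 0) throw std::runtime_error("division by zero");
  if (k >= (1ULL << 31)) throw std::runtime_error("small divisor too large");
  if (a.n == 0) return dec_zero();
  Dec r = a;
  int nd = dec_ndigits(r);
  int ext = P + 2 + digcount_u64(k) - nd;
  if (ext > 0) {
    const int CAP = LMAX + 6;
    uint64_t tmp[CAP];
    int len = expand_into(r, ext, tmp, CAP);
    if (len > LMAX) throw std::runtime_error("decimal div_small overflow");
    for (int i = 0; i < len; ++i) r.d[i] = tmp[i];
    r.n = (int16_t)len;
    r.exp -= ext;
  }
  // base-1e9 half-limb long division keeps everything in 64 bits
  uint64_t carry = 0;
  const uint64_t H = 1000000000ULL;
  for (int i = r.n - 1; i >= 0; --i) {
    uint64_t hi9 = r.d[i] / H, lo9 = r.d[i] % H;
    uint64_t cur1 = carry * H + hi9;
    uint64_t qh = cur1 / k; carry = cur1 % k;
    uint64_t cur2 = carry * H + lo9;
    uint64_t ql = cur2 / k; carry = cur2 % k;
    r.d[i] = qh * H + ql;
  }
  normalize(r);
  dec_round(r, P, RND_HALF_EVEN, carry != 0 ? +1 : 0);
  return r;
}

static Dec ulp_dec(int pos10, int sign) {  // sign * 10^pos10
  Dec u = dec_zero();
  u.sign = (int8_t)sign;
  u.n = 1; u.d[0] = 1; u.exp = pos10;
  return u;
}

Dec dec_div(const Dec &a, const Dec &b, int P) {
  if (b.n == 0) throw std::runtime_error("division by zero");
  if (a.n == 0) return dec_zero();
  if (b.n == 1 && b.d[0] == 1) {  // division by +-10^k is exact
    Dec r = a;
    r.sign = (int8_t)(r.sign * b.sign);
    r.exp -= b.exp;
    dec_round(r, P, RND_HALF_EVEN, 0);
    return r;
  }
  if (b.n == 1 && b.d[0] < (1ULL << 31)) {
    // coefficient 2^u * 5^v: division is an exact multiply by 5^u * 2^v and
    // a power-of-ten shift, so the rounded quotient is obtained exactly
    uint64_t t = b.d[0];
    int u2 = 0, v5 = 0;
    while ((t & 1) == 0) { t >>= 1; u2++; }
    while (t % 5 == 0) { t /= 5; v5++; }
    if (t == 1 && u2 + v5 <= 18) {
      uint64_t m = 1;
      for (int i = 0; i < u2; ++i) m *= 5;
      for (int i = 0; i < v5; ++i) m *= 2;
      Dec r = a;
      uint64_t carry = 0;
      for (int i = 0; i < r.n; ++i) {
        u128 cur = (u128)r.d[i] * m + carry;
        uint64_t rm;
        carry = (uint64_t)divmod_L(cur, rm);
        r.d[i] = rm;
      }
      while (carry) {
        if (r.n >= LMAX) throw std::runtime_error("decimal div overflow");
        uint64_t rm;
        carry = (uint64_t)divmod_L(carry, rm);
        r.d[r.n++] = rm;
      }
      r.exp -= b.exp + u2 + v5;
      r.sign = (int8_t)(r.sign * b.sign);
      normalize(r);
      dec_round(r, P, RND_HALF_EVEN, 0);
      return r;
    }
    // other short integer coefficients: exact long division with sticky
    // remainder gives the same correctly rounded quotient as Newton
    Dec r = dec_div_small(a, b.d[0], P);
    r.exp -= b.exp;
    r.sign = (int8_t)(r.sign * b.sign);
    return r;
  }
  int W = P + 6;

  // seed reciprocal from b's leading 19 digits: ~18.7 accurate digits
  int tb = dec_top(b);
  u128 B19;
  {
    uint64_t t = b.d[b.n - 1];
    int dt = digcount_u64(t);
    B19 = (u128)t * POW10[LD - dt] * 10;
    if (b.n > 1) B19 += b.d[b.n - 2] / (POW10[dt] / 10);
  }
  const u128 NUM38 = (u128)10000000000000000000ULL * 10000000000000000000ULL;  // 1e38
  u128 q0 = NUM38 / B19;  // 1e38 / B19 in (1e18, 1e19]
  Dec r = dec_zero();
  r.sign = b.sign;
  r.n = 0;
  {
    u128 m = q0;
    while (m) { uint64_t rm; m = divmod_L(m, rm); r.d[r.n++] = rm; }
  }
  r.exp = -38 + 19 - tb;

  // Newton-Raphson, precision roughly doubling per step
  int sched[8];
  int ns = 0, cur = 18;
  while (cur < W + 4) {
    int nxt = 2 * cur - 2;
    if (nxt > W + 4) nxt = W + 4;
    sched[ns++] = nxt;
    cur = nxt;
  }
  Dec two = dec_from_int(2);
  for (int i = 0; i < ns; ++i) {
    int pi = sched[i];
    Dec t = dec_mul(b, r, pi);
    t = dec_sub(two, t, pi);
    r = dec_mul(r, t, pi);
  }

  Dec q = dec_mul(a, r, W);

  // fast path: when the guard digits of q are far from a rounding boundary,
  // rounding q to P digits must equal the correctly rounded quotient
  int nd = dec_ndigits(q);
  int drop = nd - P;
  if (drop >= 6) {
    Dec qc = q;
    if (drop > 6) {
      int k = drop - 6, kq = k / LD, kr = k % LD;
      if (kq > 0) {
        for (int i = kq; i < qc.n; ++i) qc.d[i - kq] = qc.d[i];
        qc.n = (int16_t)(qc.n - kq);
        qc.exp += LD * kq;
      }
      if (kr > 0) coeff_shift_down(qc, kr);
    }
    uint64_t low6 = qc.n > 0 ? qc.d[0] % 1000000ULL : 0;
    const uint64_t m = 64;
    bool safe = (low6 > m && low6 < 500000ULL - m) ||
                (low6 > 500000ULL + m && low6 < 1000000ULL - m);
    if (safe) {
      dec_round(q, P, RND_HALF_EVEN, 0);
      return q;
    }
  }

  // exact verification: e = a - c*b decides whether c is the correctly
  // rounded quotient; adjust by one ulp if not, settle exact ties half-even
  Dec c = q;
  dec_round(c, P, RND_HALF_EVEN, 0);
  const int PB = LD * (LMAX - 3);
  Dec t = dec_mul(c, b, PB);
  Dec e = dec_add(a, dec_neg(t), PB);
  if (e.n != 0) {
    int upos = dec_top(c) - P;
    Dec e2 = dec_add(e, e, PB);
    Dec bu = b;  // |b| * 10^upos
    bu.exp += upos;
    int cm = dec_cmpmag(e2, bu);
    int dir = e.sign * b.sign;  // sign of the true correction e/b
    if (cm > 0) {
      c = dec_add(c, ulp_dec(upos, dir), P + 2);
      dec_round(c, P, RND_HALF_EVEN, 0);
    } else if (cm == 0) {
      int lastdig = (c.exp == upos) ? (int)(c.d[0] % 10) : 0;
      if (lastdig & 1) {
        c = dec_add(c, ulp_dec(upos, dir), P + 2);
        dec_round(c, P, RND_HALF_EVEN, 0);
      }
    }
  }
  return c;
}

// ---------------------------------------------------------------------------
// exponential

static double pow10_table(int e) {
  static double tbl[641];
  static bool init = false;
  if (!init) {
    for (int i = 0; i <= 640; ++i) tbl[i] = std::pow(10.0, (double)(i - 320));
    init = true;
  }
  if (e < -320) return 0.0;
  if (e > 320) return HUGE_VAL;
  return tbl[e + 320];
}

static double dec_to_double_approx(const Dec &a) {
  if (a.n == 0) return 0.0;
  double m = (double)a.d[a.n - 1];
  int e = a.exp + LD * (a.n - 1);
  if (a.n > 1) { m = m * 1e18 + (double)a.d[a.n - 2]; e -= LD; }
  return (double)a.sign * m * pow10_table(e);
}

// --- binary fixed-point kernel for exp's internals ------------------------
//
// Values in [0, 16) are held as FL 64-bit limbs scaled by 2^(64*FL-4).
// Argument halving is then a free bit shift, so the reduction e^r =
// (e^(r/2^K))^(2^K) can use a large K and a short Horner polynomial.
// Only the *internals* of exp live here; its argument and result are
// decimal and the final result is rounded half-even to the context digits.

namespace {

constexpr int FLMAX = 8;
constexpr int EXP_K = 20;       // halvings in the argument reduction
constexpr int TPMAX = 170;      // 10^-k table size

struct Fix {
  int sign;                     // +1 / -1 / 0
  uint64_t l[FLMAX];
};

struct ExpCache {
  int W = -1;                   // working digits the cache was built for
  int FL = 0;                   // fixed-point limbs
  int nterms = 0;               // Horner degree
  Dec e_const;                  // e at W+4 digits
  Dec epos[41], eneg[41];
  bool hpos[41] = {false}, hneg[41] = {false};
  uint64_t tpow_m[TPMAX][FLMAX];   // 10^-k = m * 2^-sh
  int tpow_sh[TPMAX];
  uint64_t tdig[FLMAX];            // 10^(W+2) as a binary integer
  int tdig_n = 0;
  Fix coef[40];                    // 1/i! in fixed point
};
static ExpCache EC;  // plain static: the package runs single-threaded under R



// compile-time-size product kernel for the Horner/squaring loop
template <int FLC>
static inline void fix_mul_t(const Fix &a, const Fix &b, Fix &r) {
  if (a.sign == 0 || b.sign == 0) {
    r.sign = 0;
    for (int i = 0; i < FLC; ++i) r.l[i] = 0;
    return;
  }
  uint64_t p[2 * FLC];
  u128 carry = 0;
  for (int k = 0; k < 2 * FLC; ++k) {
    u128 s = carry;
    u128 over = 0;
    int ilo = k - (FLC - 1); if (ilo < 0) ilo = 0;
    int ihi = k < FLC - 1 ? k : FLC - 1;
    for (int i = ilo; i <= ihi; ++i) {
      u128 prev = s;
      s += (u128)a.l[i] * b.l[k - i];
      if (s < prev) over += ((u128)1) << 64;
    }
    p[k] = (uint64_t)s;
    carry = (s >> 64) + over;
  }
  for (int i = 0; i < FLC; ++i)
    r.l[i] = (p[FLC - 1 + i] >> 60) | (p[FLC + i] << 4);
  r.sign = a.sign * b.sign;
}

static inline void fix_add(const Fix &a, const Fix &b, Fix &r, int FL) {
  if (a.sign == 0) { r = b; return; }
  if (b.sign == 0) { r = a; return; }
  if (a.sign == b.sign) {
    unsigned char c = 0;
    u128 s;
    for (int i = 0; i < FL; ++i) {
      s = (u128)a.l[i] + b.l[i] + c;
      r.l[i] = (uint64_t)s;
      c = (unsigned char)(s >> 64);
    }
    r.sign = a.sign;
    return;
  }
  int cmp = 0;
  for (int i = FL - 1; i >= 0; --i)
    if (a.l[i] != b.l[i]) { cmp = a.l[i] > b.l[i] ? 1 : -1; break; }
  if (cmp == 0) {
    r.sign = 0;
    for (int i = 0; i < FL; ++i) r.l[i] = 0;
    return;
  }
  const uint64_t *x = cmp > 0 ? a.l : b.l, *y = cmp > 0 ? b.l : a.l;
  unsigned char brw = 0;
  for (int i = 0; i < FL; ++i) {
    uint64_t yi = y[i] + brw;
    brw = (yi < (uint64_t)brw) || (x[i] < yi);
    r.l[i] = x[i] - yi;
  }
  r.sign = cmp > 0 ? a.sign : b.sign;
}

static inline void fix_shr(Fix &a, int bits, int FL) {
  int q = bits / 64, rb = bits % 64;
  for (int i = 0; i < FL; ++i) {
    uint64_t lo = (i + q < FL) ? a.l[i + q] : 0;
    uint64_t hi = (i + q + 1 < FL) ? a.l[i + q + 1] : 0;
    a.l[i] = rb ? ((lo >> rb) | (hi << (64 - rb))) : lo;
  }
  bool nz = false;
  for (int i = 0; i < FL; ++i) nz |= (a.l[i] != 0);
  if (!nz) a.sign = 0;
}

static inline void fix_div_small(Fix &a, uint64_t k, int FL) {
  const uint64_t H32 = 1ULL << 32;
  uint64_t carry = 0;
  for (int i = FL - 1; i >= 0; --i) {
    uint64_t hi = a.l[i] >> 32, lo = a.l[i] & (H32 - 1);
    uint64_t cur1 = (carry << 32) | hi;
    uint64_t q1 = cur1 / k; carry = cur1 % k;
    uint64_t cur2 = (carry << 32) | lo;
    uint64_t q2 = cur2 / k; carry = cur2 % k;
    a.l[i] = (q1 << 32) | q2;
  }
}

// divide a multiword binary integer by 10 (for the 10^-k table)
static inline uint64_t mp_div10(uint64_t *d, int n) {
  uint64_t carry = 0;
  for (int i = n - 1; i >= 0; --i) {
    uint64_t hi = d[i] >> 32, lo = d[i] & 0xffffffffULL;
    uint64_t cur1 = (carry << 32) | hi;
    uint64_t q1 = cur1 / 10; carry = cur1 % 10;
    uint64_t cur2 = (carry << 32) | lo;
    uint64_t q2 = cur2 / 10; carry = cur2 % 10;
    d[i] = (q1 << 32) | q2;
  }
  return carry;
}

}  // namespace

// squaring uses the symmetric half of the product matrix
template <int FLC>
static inline void fix_sq_t(const Fix &a, Fix &r) {
  if (a.sign == 0) { r = a; return; }
  uint64_t p[2 * FLC];
  u128 carry = 0;
  for (int k = 0; k < 2 * FLC; ++k) {
    u128 s = 0;
    u128 over = 0;
    int ilo = k - (FLC - 1); if (ilo < 0) ilo = 0;
    int ihi = k / 2;
    for (int i = ilo; i < ihi + (k & 1); ++i) {
      u128 prev = s;
      s += (u128)a.l[i] * a.l[k - i];
      if (s < prev) over += ((u128)1) << 64;
    }
    // double the off-diagonal part
    over <<= 1;
    if (s >> 127) over += ((u128)1) << 64;
    s <<= 1;
    if (!(k & 1)) {  // diagonal term
      u128 prev = s;
      s += (u128)a.l[k / 2] * a.l[k / 2];
      if (s < prev) over += ((u128)1) << 64;
    }
    u128 prev = s;
    s += carry;
    if (s < prev) over += ((u128)1) << 64;
    p[k] = (uint64_t)s;
    carry = (s >> 64) + over;
  }
  for (int i = 0; i < FLC; ++i)
    r.l[i] = (p[FLC - 1 + i] >> 60) | (p[FLC + i] << 4);
  r.sign = 1;
}

template <int FLC>
static void exp_core(Fix &F, Fix &h) {
  h = EC.coef[EC.nterms];
  Fix tmp;
  for (int i = EC.nterms - 1; i >= 0; --i) {
    fix_mul_t<FLC>(h, F, tmp);
    fix_add(tmp, EC.coef[i], h, FLC);
  }
  for (int i = 0; i < EXP_K; ++i) {
    fix_sq_t<FLC>(h, tmp);
    h = tmp;
  }
}


static void exp_cache_setup(int W) {
  if (EC.W == W) return;
  EC.W = W;
  for (int i = 0; i <= 40; ++i) { EC.hpos[i] = EC.hneg[i] = false; }

  // e = sum 1/i! in decimal (one-time)
  Dec one = dec_from_int(1);
  Dec t = one, s = one;
  for (int i = 1; i < 400; ++i) {
    t = dec_div_small(t, (uint64_t)i, W + 6);
    if (t.n == 0 || dec_top(t) < dec_top(s) - (W + 4)) break;
    s = dec_add(s, t, W + 6);
  }
  dec_round(s, W + 4, RND_HALF_EVEN, 0);
  EC.e_const = s;
  EC.epos[1] = EC.e_const; EC.hpos[1] = true;

  // fixed-point geometry: need ~3.33*(W+2) bits plus 2^K error amplification
  int bits_needed = (int)(3.3220 * (W + 2)) + EXP_K + 14;
  EC.FL = (bits_needed + 4 + 63) / 64;
  if (EC.FL > FLMAX) throw std::runtime_error("precision beyond exp kernel capacity");
  int FL = EC.FL;
  int S = 64 * FL - 4;

  // 10^-k = m_k * 2^-sh_k with m_k kept in a normalized band
  uint64_t m[FLMAX + 1];
  for (int i = 0; i <= FLMAX; ++i) m[i] = 0;
  m[FL - 1] = 1ULL << 60;  // 2^(64FL-4) / 2^0 => represents 1.0 with sh = S
  int sh = S;
  for (int i = 0; i < FL; ++i) EC.tpow_m[0][i] = m[i];
  EC.tpow_sh[0] = sh;
  for (int k = 1; k < TPMAX; ++k) {
    // multiply by 2^j/10 with j chosen to keep the top limb in [2^59, 2^61)
    int j = (m[FL - 1] >= (1ULL << 60)) ? 3 : 4;
    uint64_t carry = 0;
    for (int i = 0; i < FL; ++i) {
      uint64_t nv = (m[i] << j) | carry;
      carry = m[i] >> (64 - j);
      m[i] = nv;
    }
    if (carry) throw std::runtime_error("internal: tpow normalization");
    mp_div10(m, FL);
    sh += j;
    for (int i = 0; i < FL; ++i) EC.tpow_m[k][i] = m[i];
    EC.tpow_sh[k] = sh;
  }

  // 10^(W+2) as a plain binary integer
  {
    uint64_t t10[FLMAX];
    for (int i = 0; i < FLMAX; ++i) t10[i] = 0;
    t10[0] = 1;
    int n10 = 1;
    for (int k = 0; k < W + 2; ++k) {
      u128 c = 0;
      for (int i = 0; i < n10; ++i) {
        u128 cur = (u128)t10[i] * 10 + c;
        t10[i] = (uint64_t)cur;
        c = cur >> 64;
      }
      if (c) {
        if (n10 >= FLMAX) throw std::runtime_error("exp kernel 10^W overflow");
        t10[n10++] = (uint64_t)c;
      }
    }
    for (int i = 0; i < FLMAX; ++i) EC.tdig[i] = t10[i];
    EC.tdig_n = n10;
  }

  // Horner coefficients 1/i!
  EC.nterms = (S - 12) / (EXP_K + 1) + 2;
  if (EC.nterms > 39) EC.nterms = 39;
  Fix c;
  c.sign = 1;
  for (int i = 0; i < FLMAX; ++i) c.l[i] = 0;
  c.l[FL - 1] = 1ULL << 60;  // 1.0
  EC.coef[0] = c;
  for (int i = 1; i <= EC.nterms; ++i) {
    fix_div_small(c, (uint64_t)i, FL);
    EC.coef[i] = c;
  }
}

static Dec e_int_power(long long n, int W) {  // e^n for n != 0
  exp_cache_setup(W);
  bool negp = n < 0;
  unsigned long long m = negp ? (unsigned long long)(-n) : (unsigned long long)n;
  Dec p;
  if (m <= 40 && !negp && EC.hpos[m]) return EC.epos[m];
  if (m <= 40 && negp && EC.hneg[m]) return EC.eneg[m];
  // binary power on e
  Dec base = EC.e_const, acc = dec_from_int(1);
  unsigned long long mm = m;
  bool first = true;
  while (mm) {
    if (mm & 1) {
      acc = first ? base : dec_mul(acc, base, W + 4);
      first = false;
    }
    mm >>= 1;
    if (mm) base = dec_mul(base, base, W + 4);
  }
  p = acc;
  if (negp) p = dec_div(dec_from_int(1), p, W + 4);
  if (m <= 40) {
    if (negp) { EC.eneg[m] = p; EC.hneg[m] = true; }
    else { EC.epos[m] = p; EC.hpos[m] = true; }
  }
  return p;
}

// argument reduction core at compile-time limb count: r (|r| <= 0.55, r != 0)
// -> e^r at W+2 digits
template <int FLC>
static Dec exp_reduce_core(const Dec &r, int W) {
  const int S = 64 * FLC - 4;
  if (r.exp >= 0) throw std::runtime_error("internal: exp reduction");
  int k = -r.exp;
  if (k >= TPMAX) throw std::runtime_error("internal: exp scale table");

  // binary integer I = decimal coefficient of r
  uint64_t I[FLC + 1];
  int ni = 1;
  I[0] = 0;
  for (int i = r.n - 1; i >= 0; --i) {
    u128 c = r.d[i];
    for (int j = 0; j < ni; ++j) {
      u128 cur = (u128)I[j] * LBASE + c;
      I[j] = (uint64_t)cur;
      c = cur >> 64;
    }
    while (c) {
      if (ni > FLC) throw std::runtime_error("internal: exp coefficient");
      I[ni++] = (uint64_t)c;
      c >>= 64;
    }
  }
  for (int i = ni; i <= FLC; ++i) I[i] = 0;

  // F = |r| * 2^S = (I * m_k) >> (sh_k - S)
  uint64_t p[2 * FLC + 2];
  {
    u128 carry = 0;
    for (int kk = 0; kk < 2 * FLC + 1; ++kk) {
      u128 s = carry;
      u128 over = 0;
      int ilo = kk - (FLC - 1); if (ilo < 0) ilo = 0;
      int ihi = kk <= FLC ? kk : FLC;
      for (int i = ilo; i <= ihi && i <= FLC; ++i) {
        if (kk - i >= FLC) continue;
        u128 prev = s;
        s += (u128)I[i] * EC.tpow_m[k][kk - i];
        if (s < prev) over += ((u128)1) << 64;
      }
      p[kk] = (uint64_t)s;
      carry = (s >> 64) + over;
    }
    p[2 * FLC + 1] = (uint64_t)carry;
  }
  int shift = EC.tpow_sh[k] - S;
  int q = shift / 64, rb = shift % 64;
  Fix F;
  F.sign = r.sign;
  for (int i = 0; i < FLC; ++i) {
    uint64_t lo = (q + i < 2 * FLC + 2) ? p[q + i] : 0;
    uint64_t hi = (q + i + 1 < 2 * FLC + 2) ? p[q + i + 1] : 0;
    F.l[i] = rb ? ((lo >> rb) | (hi << (64 - rb))) : lo;
  }

  fix_shr(F, EXP_K, FLC);  // s = r / 2^K
  Fix h;
  exp_core<FLC>(F, h);

  // J = e^r * 10^(W+2), then binary -> decimal limbs
  {
    u128 carry = 0;
    int tn = EC.tdig_n;
    for (int kk = 0; kk < FLC + tn; ++kk) {
      u128 s = carry;
      u128 over = 0;
      int ilo = kk - (tn - 1); if (ilo < 0) ilo = 0;
      int ihi = kk < FLC - 1 ? kk : FLC - 1;
      for (int i = ilo; i <= ihi; ++i) {
        u128 prev = s;
        s += (u128)h.l[i] * EC.tdig[kk - i];
        if (s < prev) over += ((u128)1) << 64;
      }
      if (kk < 2 * FLC + 2) p[kk] = (uint64_t)s;
      carry = (s >> 64) + over;
    }
    for (int kk = FLC + EC.tdig_n; kk < 2 * FLC + 2; ++kk) p[kk] = 0;
  }
  q = S / 64; rb = S % 64;
  uint64_t J[FLC + 2];
  int nj = 0;
  for (int i = 0; i < FLC + 2; ++i) {
    uint64_t lo = (q + i < 2 * FLC + 2) ? p[q + i] : 0;
    uint64_t hi = (q + i + 1 < 2 * FLC + 2) ? p[q + i + 1] : 0;
    J[i] = rb ? ((lo >> rb) | (hi << (64 - rb))) : lo;
    if (J[i]) nj = i + 1;
  }
  Dec result = dec_zero();
  result.sign = 1;
  result.exp = -(W + 2);
  int nd = 0;
  while (nj > 0) {
    uint64_t carry = 0;
    for (int i = nj - 1; i >= 0; --i) {
      u128 cur = ((u128)carry << 64) | J[i];
      uint64_t rem;
      u128 qq = divmod_L(cur, rem);
      J[i] = (uint64_t)qq;
      carry = rem;
    }
    while (nj > 0 && J[nj - 1] == 0) nj--;
    if (nd >= LMAX) throw std::runtime_error("internal: exp conversion");
    result.d[nd++] = carry;
  }
  result.n = (int16_t)nd;
  normalize(result);
  return result;
}

Dec dec_exp(const Dec &x, int P) {
  int W = P + 10;
  exp_cache_setup(W);
  if (x.n == 0) return dec_from_int(1);
  double approx = dec_to_double_approx(x);
  if (std::fabs(approx) > 1e8) throw std::runtime_error("exp overflow");
  long long n = (long long)std::llround(approx);
  Dec r = dec_sub(x, dec_from_int(n), W + 4);

  Dec result;
  if (r.n == 0) {
    result = dec_from_int(1);
  } else if (dec_top(r) < -(W + 4)) {
    result = dec_add(dec_from_int(1), r, W + 2);  // e^r = 1 + r to working precision
  } else {
    switch (EC.FL) {
      case 2: result = exp_reduce_core<2>(r, W); break;
      case 3: result = exp_reduce_core<3>(r, W); break;
      case 4: result = exp_reduce_core<4>(r, W); break;
      case 5: result = exp_reduce_core<5>(r, W); break;
      case 6: result = exp_reduce_core<6>(r, W); break;
      case 7: result = exp_reduce_core<7>(r, W); break;
      case 8: result = exp_reduce_core<8>(r, W); break;
      default: throw std::runtime_error("internal: exp kernel size");
    }
  }

  if (n != 0) {
    result = dec_mul(result, e_int_power(n, W), P);  // single final rounding
  } else {
    dec_round(result, P, RND_HALF_EVEN, 0);
  }
  return result;
}

Dec dec_pow_chain(const Dec &x, int k, int P) {
  if (k < 1 || k > 4) throw std::runtime_error("pow chain exponent must be 1..4");
  if (k == 1) { Dec r = x; dec_round(r, P, RND_HALF_EVEN, 0); return r; }
  Dec p = dec_mul(x, x, P);
  if (k >= 3) p = dec_mul(p, x, P);
  if (k == 4) p = dec_mul(p, x, P);
  return p;
}

// ---------------------------------------------------------------------------
// parsing

bool dec_parse(const std::string &lit, int P, Dec &out, std::string &err) {
  const char *s = lit.c_str();
  size_t i = 0, L = lit.size();
  out = dec_zero();
  err.clear();
  int sign = 1;
  if (i < L && (s[i] == '+' || s[i] == '-')) { if (s[i] == '-') sign = -1; ++i; }
  std::string digs;
  digs.reserve(L);
  long long dexp = 0;
  bool seen_digit = false, seen_dot = false;
  for (; i < L; ++i) {
    char c = s[i];
    if (c >= '0' && c <= '9') {
      seen_digit = true;
      digs.push_back(c);
      if (seen_dot) dexp--;
    } else if (c == '.' && !seen_dot) {
      seen_dot = true;
    } else if ((c == 'e' || c == 'E') && seen_digit) {
      ++i;
      int es = 1;
      if (i < L && (s[i] == '+' || s[i] == '-')) { if (s[i] == '-') es = -1; ++i; }
      if (i >= L) { err = "malformed decimal literal: '" + lit + "'"; return false; }
      long long ev = 0;
      for (; i < L; ++i) {
        if (s[i] < '0' || s[i] > '9') { err = "malformed decimal literal: '" + lit + "'"; return false; }
        ev = ev * 10 + (s[i] - '0');
        if (ev > 100000000LL) { err = "exponent out of range in '" + lit + "'"; return false; }
      }
      dexp += es * ev;
      break;
    } else {
      err = "malformed decimal literal: '" + lit + "'";
      return false;
    }
  }
  if (!seen_digit) { err = "malformed decimal literal: '" + lit + "'"; return false; }

  // canonical significant digits
  size_t lead = 0;
  while (lead < digs.size() && digs[lead] == '0') ++lead;
  digs.erase(0, lead);
  while (!digs.empty() && digs.back() == '0') { digs.pop_back(); ++dexp; }
  if (digs.empty()) return true;  // zero

  int sticky = 0;
  const size_t CAPD = (size_t)(LD * (LMAX - 2));
  if (digs.size() > CAPD) {
    for (size_t k = CAPD; k < digs.size(); ++k) if (digs[k] != '0') { sticky = 1; break; }
    dexp += (long long)(digs.size() - CAPD);
    digs.resize(CAPD);
  }
  if (dexp > 1000000 || dexp + (long long)digs.size() < -1000000) {
    err = "exponent out of range in '" + lit + "'";
    return false;
  }
  out.sign = (int8_t)sign;
  out.exp = (int32_t)dexp;
  int nd = (int)digs.size();
  out.n = (int16_t)((nd + LD - 1) / LD);
  int pos = nd;
  for (int limb = 0; limb < out.n; ++limb) {
    int lo = pos - LD; if (lo < 0) lo = 0;
    uint64_t v = 0;
    for (int k = lo; k < pos; ++k) v = v * 10 + (uint64_t)(digs[k] - '0');
    out.d[limb] = v;
    pos = lo;
  }
  normalize(out);
  if (P > 0) dec_round(out, P, RND_HALF_EVEN, sticky);
  return out.n >= 0;
}

// ---------------------------------------------------------------------------
// formatting

// Round a digit string (value = 0.d1 d2 ... * 10^T, digits given as the
// significand with the top digit first) to `sig` digits, returning the laid
// out number.  Used by both the Dec formatter and the exact binary64
// expansion.
static std::string format_digits(int sign, std::string digs, long long T,
                                 int sig, int mode) {
  if (sig < 1) throw std::runtime_error("sig_digits must be >= 1");
  if (digs.empty()) return "0";
  if ((long long)digs.size() > (long long)sig) {
    bool up = false;
    if (mode == RND_HALF_EVEN) {
      char g = digs[sig];
      bool rest = false;
      for (size_t k = sig + 1; k < digs.size(); ++k)
        if (digs[k] != '0') { rest = true; break; }
      if (g > '5') up = true;
      else if (g == '5') up = rest ? true : ((digs[sig - 1] - '0') & 1);
    }
    digs.resize(sig);
    if (up) {
      int k = sig - 1;
      while (k >= 0) {
        if (digs[k] == '9') { digs[k] = '0'; --k; }
        else { digs[k]++; break; }
      }
      if (k < 0) { digs.insert(digs.begin(), '1'); digs.resize(sig); T++; }
    }
  }
  while ((int)digs.size() < sig) digs.push_back('0');

  std::string out;
  if (sign < 0) out.push_back('-');
  if (T > -6 && T <= 21) {
    if (T <= 0) {
      out += "0.";
      for (long long k = 0; k < -T; ++k) out.push_back('0');
      out += digs;
    } else if ((long long)digs.size() > T) {
      out += digs.substr(0, (size_t)T);
      out.push_back('.');
      out += digs.substr((size_t)T);
    } else {
      out += digs;
      for (long long k = digs.size(); k < T; ++k) out.push_back('0');
    }
  } else {
    out.push_back(digs[0]);
    if (digs.size() > 1) { out.push_back('.'); out += digs.substr(1); }
    char buf[24];
    std::snprintf(buf, sizeof(buf), "e%+lld", T - 1);
    out += buf;
  }
  return out;
}

static std::string coeff_digits(const Dec &a) {
  char buf[24];
  std::string s;
  std::snprintf(buf, sizeof(buf), "%llu", (unsigned long long)a.d[a.n - 1]);
  s = buf;
  for (int i = a.n - 2; i >= 0; --i) {
    std::snprintf(buf, sizeof(buf), "%018llu", (unsigned long long)a.d[i]);
    s += buf;
  }
  return s;
}

std::string dec_format(const Dec &a, int sig, int mode) {
  if (a.n == 0) return "0";
  return format_digits(a.sign, coeff_digits(a), dec_top(a), sig, mode);
}

std::string dec_format_full(const Dec &a) {
  if (a.n == 0) return "0";
  std::string digs = coeff_digits(a);
  size_t last = digs.find_last_not_of('0');
  int sig = (int)last + 1;
  return format_digits(a.sign, digs, dec_top(a), sig, RND_TRUNC);
}

double dec_to_double(const Dec &a) {
  if (a.n == 0) return 0.0;
  std::string s = dec_format(a, dec_ndigits(a) < 30 ? dec_ndigits(a) : 30,
                             RND_HALF_EVEN);
  return std::strtod(s.c_str(), nullptr);
}

// ---------------------------------------------------------------------------
// exact binary64 expansion (dynamic big-integer, conversion paths only)

static void vec_mul_small(std::vector<uint64_t> &v, uint64_t m) {
  u128 carry = 0;
  for (size_t i = 0; i < v.size(); ++i) {
    u128 cur = (u128)v[i] * m + carry;
    uint64_t rem;
    carry = divmod_L(cur, rem);
    v[i] = rem;
  }
  while (carry) {
    uint64_t rem;
    carry = divmod_L(carry, rem);
    v.push_back(rem);
  }
}

// exact decimal digits of |x| = digs * 10^dexp (digits top-first)
void double_exact_parts(double x, std::string &digs, long long &dexp,
                        int &sign) {
  if (!std::isfinite(x)) throw std::runtime_error("non-finite value");
  uint64_t bits;
  std::memcpy(&bits, &x, 8);
  sign = (bits >> 63) ? -1 : 1;
  uint64_t frac = bits & ((1ULL << 52) - 1);
  int bexp = (int)((bits >> 52) & 0x7ff);
  uint64_t m;
  int e2;
  if (bexp == 0) { m = frac; e2 = -1074; }
  else { m = frac | (1ULL << 52); e2 = bexp - 1075; }
  if (m == 0) { digs.clear(); dexp = 0; return; }

  std::vector<uint64_t> v;
  v.push_back(m % LBASE);
  if (m / LBASE) v.push_back(m / LBASE);
  dexp = 0;
  if (e2 >= 0) {
    int e = e2;
    while (e >= 60) { vec_mul_small(v, 1ULL << 60); e -= 60; }
    if (e > 0) vec_mul_small(v, 1ULL << e);
  } else {
    int e = -e2;
    const uint64_t P5_25 = 298023223876953125ULL;  // 5^25
    while (e >= 25) { vec_mul_small(v, P5_25); e -= 25; }
    if (e > 0) { uint64_t p5 = 1; for (int k = 0; k < e; ++k) p5 *= 5; vec_mul_small(v, p5); }
    dexp = e2;
  }
  char buf[24];
  std::snprintf(buf, sizeof(buf), "%llu", (unsigned long long)v.back());
  digs = buf;
  for (int i = (int)v.size() - 2; i >= 0; --i) {
    std::snprintf(buf, sizeof(buf), "%018llu", (unsigned long long)v[i]);
    digs += buf;
  }
  // strip trailing zeros into the exponent
  size_t last = digs.find_last_not_of('0');
  dexp += (long long)(digs.size() - 1 - last);
  digs.resize(last + 1);
}

std::string double_exact_string(double x, int sig, int mode) {
  if (x == 0.0) return "0";
  std::string digs;
  long long dexp;
  int sign;
  double_exact_parts(x, digs, dexp, sign);
  long long T = dexp + (long long)digs.size();
  return format_digits(sign, digs, T, sig, mode);
}

Dec dec_from_double(double x, int P) {
  if (x == 0.0) return dec_zero();
  std::string digs;
  long long dexp;
  int sign;
  double_exact_parts(x, digs, dexp, sign);
  char buf[24];
  std::snprintf(buf, sizeof(buf), "e%lld", dexp);
  std::string lit = (sign < 0 ? "-" : "") + digs + buf;
  Dec out;
  std::string err;
  if (!dec_parse(lit, P, out, err)) throw std::runtime_error(err);
  return out;
}

}  // namespace hhdec
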