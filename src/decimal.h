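#ifndef HHREPRO_DECIMAL_H
#define HHREPRO_DECIMAL_H

#include <cstdint>
#include <string>

// Decimal floating point with a fixed-capacity coefficient.
//
// value = sign * (d[0] + d[1]*1e18 + ... + d[n-1]*1e18^(n-1)) * 10^exp
//
// Working precision (significant decimal digits) is supplied per operation;
// every user-visible arithmetic operation rounds half-to-even to that
// precision.  Capacity is sized so that the exact product of two operands at
// the maximum supported precision (plus guard digits) still fits, which keeps
// add/sub/mul exact before the final rounding.

namespace hhdec {

constexpr int      LD    = 18;                       // decimal digits per limb
constexpr uint64_t LBASE = 1000000000000000000ULL;   // 10^18
constexpr int      LMAX  = 16;                       // coefficient capacity (limbs)
constexpr int      PMIN  = 1;                        // smallest rounding precision
constexpr int      PMAX  = 120;                      // largest context precision

struct Dec {
  int32_t  exp;       // power of ten of the unit of d[0]
  int16_t  n;         // limbs in use (0 => value is zero)
  int8_t   sign;      // +1 / -1 (0 when n == 0)
  uint64_t d[LMAX];
};

enum RoundMode { RND_HALF_EVEN = 0, RND_TRUNC = 1 };

Dec dec_zero();
bool dec_is_zero(const Dec &a);
int  dec_ndigits(const Dec &a);          // significant digits of the coefficient
int  dec_top(const Dec &a);              // value in [10^(top-1), 10^top)
Dec  dec_neg(const Dec &a);
int  dec_cmp(const Dec &a, const Dec &b);        // -1 / 0 / +1, exact

// Rounding of |a| to P significant digits.  `sticky` is the sign of
// (|true value| - |stored value|) for a previously discarded residue
// (0 when the stored value is exact).
void dec_round(Dec &a, int P, int mode, int sticky);

Dec dec_add(const Dec &a, const Dec &b, int P);
Dec dec_sub(const Dec &a, const Dec &b, int P);
Dec dec_mul(const Dec &a, const Dec &b, int P);
Dec dec_div(const Dec &a, const Dec &b, int P);      // correctly rounded
Dec dec_div_small(const Dec &a, uint64_t k, int P);  // divisor < 10^18
Dec dec_exp(const Dec &x, int P);                    // exp, accurate to ~P digits
Dec dec_pow_chain(const Dec &x, int k, int P);       // (((x*x)*x)*x), k in 2..4

Dec dec_from_int(long long v);
// Parse a decimal literal.  P <= 0 keeps the literal exactly (error if it
// exceeds capacity); P > 0 rounds half-to-even to P significant digits.
// Returns false and fills `err` on malformed input.
bool dec_parse(const std::string &lit, int P, Dec &out, std::string &err);

// Exactly convert a finite binary64 value (dynamic big-integer path).
Dec dec_from_double(double x, int P);

// Decimal string with exactly `sig` significant digits (fixed notation for
// moderate exponents, scientific otherwise).  Zero prints as "0".
std::string dec_format(const Dec &a, int sig, int mode);
// Shortest-ish full form: all stored digits.
std::string dec_format_full(const Dec &a);

double dec_to_double(const Dec &a);      // correctly rounded via strtod

// Exact decimal expansion of a binary64, rounded/truncated to `sig`
// significant digits (this is the exact value of the bit pattern, not a
// shortest round-trip form).
std::string double_exact_string(double x, int sig, int mode);

// Exact decimal digits of |x| (top digit first) with |x| = digs * 10^dexp.
void double_exact_parts(double x, std::string &digs, long long &dexp, int &sign);

}  // namespace hhdec

#endif
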