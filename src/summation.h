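#ifndef HHREPRO_SUMMATION_H
#define HHREPRO_SUMMATION_H

#include <cstdint>
#include <cstddef>

namespace hhsum {

double sum_naive(const double *x, size_t n);
double sum_kahan(const double *x, size_t n);

// Correctly rounded sum of binary64 values via a Kulisch-style long
// accumulator: the result is the double nearest (ties to even) the exact
// real sum, identical under any permutation of the inputs.
struct KAcc {
  uint64_t pos[40];
  uint64_t neg[40];
  void reset();
  void add(double x);
  double result() const;
};

double sum_repro(const double *x, size_t n);

// Independent oracle: exact fixed-point *decimal* accumulation of the exact
// decimal expansions of the inputs, rounded once at the end through strtod.
double sum_exact_decimal(const double *x, size_t n);

}  // namespace hhsum

#endif
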