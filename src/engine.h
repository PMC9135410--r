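#ifndef HHREPRO_ENGINE_H
#define HHREPRO_ENGINE_H

#include <map>
#include <string>
#include <vector>

namespace hheng {

// 0 naive, 1 kahan, 2 reproducible (binary64 only)
enum SumKind { SUM_NAIVE = 0, SUM_KAHAN = 1, SUM_REPRO = 2 };

struct EngineConfig {
  int N = 0;
  std::vector<std::string> iapp;               // decimal literals, one per neuron
  std::vector<char> is_exc;                    // pool membership per neuron
  std::map<std::string, std::string> params;   // parameter literals
  std::string dt_lit = "0.01";
  long nsteps = 0;
  int stride = 1;
  int sum_kind = SUM_NAIVE;
  bool unified = false;                        // single-pool accumulation (requires V_exc == V_inh)
  int singularity = 0;                         // 0 error, 1 analytic limit
  int hfpp_digits = 0;                         // 0 => binary64 backend
  std::vector<std::string> init_V, init_n, init_a, init_s;  // length 1 or N
};

struct RunResult {
  std::vector<double> times, A, S;
  std::vector<std::string> A_str, S_str;       // full-precision (HFPP only)
};

RunResult run_network(const EngineConfig &cfg);

// single derivative evaluation (binary64), for cross-checks against the
// reference implementation: inputs are the state blocks, outputs the
// derivative blocks
void deriv_f64(const EngineConfig &cfg, const std::vector<double> &V,
               const std::vector<double> &n, const std::vector<double> &a,
               const std::vector<double> &s, std::vector<double> &dV,
               std::vector<double> &dn, std::vector<double> &da,
               std::vector<double> &ds);

}  // namespace hheng

#endif
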