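// Deterministic network integration: Hodgkin-Huxley-type neurons with
// synaptic depression, all-to-all coupling, fixed-step RK4 with a pinned
// operation order, templated over the binary64 (DFPP) and decimal (HFPP)
// backends so both execute the same operation sequence.

#include "engine.h"
#include "decimal.h"
#include "summation.h"

#include <cmath>
#include <cstdio>
#include <cstdlib>
#include <stdexcept>
#include <type_traits>

namespace hheng {

using hhdec::Dec;

// ---------------------------------------------------------------------------
// numeric backends

struct BkF64 {
  typedef double num;
  static double add(double a, double b) { return a + b; }
  static double sub(double a, double b) { return a - b; }
  static double mul(double a, double b) { return a * b; }
  static double div(double a, double b) { return a / b; }
  static double neg(double a) { return -a; }
  static double exp_(double a) { return std::exp(a); }
  static bool eq(double a, double b) { return a == b; }
  static double zero() { return 0.0; }
  static double from_int(long v) { return (double)v; }
  static double from_lit(const std::string &s) {
    Dec d;
    std::string err;
    if (!hhdec::dec_parse(s, 0, d, err)) throw std::runtime_error(err);
    return std::strtod(s.c_str(), nullptr);
  }
  static bool bad(double x) { return !std::isfinite(x); }
  static double to_double(double x) { return x; }
};

struct BkDec {
  int P;
  typedef Dec num;
  Dec add(const Dec &a, const Dec &b) const { return hhdec::dec_add(a, b, P); }
  Dec sub(const Dec &a, const Dec &b) const { return hhdec::dec_sub(a, b, P); }
  Dec mul(const Dec &a, const Dec &b) const { return hhdec::dec_mul(a, b, P); }
  Dec div(const Dec &a, const Dec &b) const { return hhdec::dec_div(a, b, P); }
  Dec neg(const Dec &a) const { return hhdec::dec_neg(a); }
  Dec exp_(const Dec &a) const { return hhdec::dec_exp(a, P); }
  bool eq(const Dec &a, const Dec &b) const {
    if (a.sign != b.sign) return false;
    if (a.n == 0) return b.n == 0;
    if (hhdec::dec_top(a) != hhdec::dec_top(b)) return false;  // cheap prefilter
    return hhdec::dec_cmp(a, b) == 0;
  }
  Dec zero() const { return hhdec::dec_zero(); }
  Dec from_int(long v) const { return hhdec::dec_from_int(v); }
  Dec from_lit(const std::string &s) const {
    Dec d;
    std::string err;
    if (!hhdec::dec_parse(s, P, d, err)) throw std::runtime_error(err);
    return d;
  }
  bool bad(const Dec &x) const { return x.n != 0 && hhdec::dec_top(x) > 350; }
  double to_double(const Dec &x) const { return hhdec::dec_to_double(x); }
};

// ---------------------------------------------------------------------------

template <class BK>
class Net {
 public:
  typedef typename BK::num num;
  BK bk;
  const EngineConfig &cfg;
  int N;
  std::vector<char> is_exc;
  std::vector<num> Iapp;
  // model parameters and literal constants
  num C, g_l, V_l, g_Na, V_Na, g_K, V_K, gbar_syn, V_exc, V_inh;
  num alpha_a, beta_a, alpha_s, beta_s, V_th, k_v;
  num gsyn_over_N, dt;
  num c1, c2, c4, c6, c10, c25, c001, c01, c0125, c08, c80, c18;
  bool all_exc_pooling;  // single-pool arithmetic path
  // scratch
  std::vector<num> as;
  long cur_step = 0;

  Net(const BK &bk_, const EngineConfig &c) : bk(bk_), cfg(c) {
    N = c.N;
    is_exc = c.is_exc;
    auto par = [&](const char *k) -> num {
      auto it = c.params.find(k);
      if (it == c.params.end())
        throw std::runtime_error(std::string("missing parameter: ") + k);
      return bk.from_lit(it->second);
    };
    C = par("C"); g_l = par("g_l"); V_l = par("V_l");
    g_Na = par("g_Na"); V_Na = par("V_Na"); g_K = par("g_K"); V_K = par("V_K");
    gbar_syn = par("gbar_syn"); V_exc = par("V_exc"); V_inh = par("V_inh");
    alpha_a = par("alpha_a"); beta_a = par("beta_a");
    alpha_s = par("alpha_s"); beta_s = par("beta_s");
    V_th = par("V_th"); k_v = par("k_v");
    gsyn_over_N = bk.div(gbar_syn, bk.from_int(N));
    dt = bk.from_lit(c.dt_lit);
    c1 = bk.from_int(1); c2 = bk.from_int(2); c4 = bk.from_int(4);
    c6 = bk.from_int(6); c10 = bk.from_lit("10.0"); c25 = bk.from_lit("25.0");
    c001 = bk.from_lit("0.01"); c01 = bk.from_lit("0.1");
    c0125 = bk.from_lit("0.125"); c08 = bk.from_lit("0.8");
    c80 = bk.from_lit("80"); c18 = bk.from_lit("18");
    for (const auto &lit : c.iapp) Iapp.push_back(bk.from_lit(lit));
    bool any_inh = false;
    for (char e : is_exc) any_inh |= !e;
    all_exc_pooling = !any_inh || c.unified;
    if (c.unified && !bk.eq(V_exc, V_inh))
      throw std::runtime_error("unified accumulation requires V_exc == V_inh");
    as.resize(N, bk.zero());
  }

  // pool: 0 = excitatory members, 1 = inhibitory members, 2 = all neurons
  num pool_sum(int pool) {
    if (cfg.sum_kind == SUM_REPRO) {
      if constexpr (std::is_same<num, double>::value) {
        hhsum::KAcc acc;
        acc.reset();
        for (int j = 0; j < N; ++j)
          if (pool == 2 || (pool == 0) == (bool)is_exc[j]) acc.add(as[j]);
        return acc.result();
      } else {
        throw std::runtime_error(
            "reproducible summation is defined for the binary64 backend only");
      }
    }
    if (cfg.sum_kind == SUM_KAHAN) {
      num s = bk.zero(), comp = bk.zero();
      for (int j = 0; j < N; ++j) {
        if (!(pool == 2 || (pool == 0) == (bool)is_exc[j])) continue;
        num y = bk.sub(as[j], comp);
        num t = bk.add(s, y);
        comp = bk.sub(bk.sub(t, s), y);
        s = t;
      }
      return s;
    }
    // strict left-to-right naive accumulation
    num s = bk.zero();
    bool first = true;
    for (int j = 0; j < N; ++j) {
      if (!(pool == 2 || (pool == 0) == (bool)is_exc[j])) continue;
      if (first) { s = as[j]; first = false; }
      else s = bk.add(s, as[j]);
    }
    return s;
  }

  void singular(const char *fn, double vval, int k) {
    char buf[160];
    std::snprintf(buf, sizeof(buf),
                  "removable singularity in %s at V=%g (neuron %d, step %ld); "
                  "set singularity=\"limit\" to substitute the analytic limit",
                  fn, vval, k + 1, cur_step);
    throw std::runtime_error(buf);
  }

  // state layout: V[0..N), n[0..N), a[0..N), s[0..N)
  void deriv(const std::vector<num> &y, std::vector<num> &dy) {
    const num *V = &y[0], *nn = &y[N], *aa = &y[2 * N], *ss = &y[3 * N];
    num *dV = &dy[0], *dn = &dy[N], *da = &dy[2 * N], *ds = &dy[3 * N];
    for (int j = 0; j < N; ++j) as[j] = bk.mul(aa[j], ss[j]);
    num Se, Si;
    if (all_exc_pooling) {
      Se = pool_sum(2);
      Si = bk.zero();
    } else {
      Se = pool_sum(0);
      Si = pool_sum(1);
    }
    for (int k = 0; k < N; ++k) {
      // alpha_n(V) = 0.01 (10 - V) / (e^{0.1 (10 - V)} - 1)
      num t1 = bk.sub(c10, V[k]);
      num an;
      if (bk.eq(V[k], c10)) {
        if (cfg.singularity != 1) singular("alpha_n", 10.0, k);
        an = c01;  // analytic limit 0.01/0.1
      } else {
        num E = bk.exp_(bk.mul(c01, t1));
        an = bk.div(bk.mul(c001, t1), bk.sub(E, c1));
      }
      // beta_n(V) = 0.125 e^{-V/80}
      num bn = bk.mul(c0125, bk.exp_(bk.div(bk.neg(V[k]), c80)));
      // m_inf(V) = alpha_m / (alpha_m + beta_m), classic squid-axon rates
      num t2 = bk.sub(c25, V[k]);
      num am;
      if (bk.eq(V[k], c25)) {
        if (cfg.singularity != 1) singular("alpha_m", 25.0, k);
        am = c1;  // analytic limit 0.1/0.1
      } else {
        num E2 = bk.exp_(bk.mul(c01, t2));
        am = bk.div(bk.mul(c01, t2), bk.sub(E2, c1));
      }
      num bm = bk.mul(c4, bk.exp_(bk.div(bk.neg(V[k]), c18)));
      num minf = bk.div(am, bk.add(am, bm));
      // ionic currents
      num m2 = bk.mul(minf, minf);
      num m3 = bk.mul(m2, minf);
      num INa = bk.mul(bk.mul(bk.mul(g_Na, m3), bk.sub(c08, nn[k])),
                       bk.sub(V[k], V_Na));
      num n2 = bk.mul(nn[k], nn[k]);
      num n3 = bk.mul(n2, nn[k]);
      num n4 = bk.mul(n3, nn[k]);
      num IK = bk.mul(bk.mul(g_K, n4), bk.sub(V[k], V_K));
      num Il = bk.mul(g_l, bk.sub(V[k], V_l));
      // synaptic conductances: pool sum minus own term for the home pool
      num ge, gi;
      if (all_exc_pooling) {
        ge = bk.mul(gsyn_over_N, bk.sub(Se, as[k]));
        gi = bk.mul(gsyn_over_N, Si);  // Si is exactly zero
      } else if (is_exc[k]) {
        ge = bk.mul(gsyn_over_N, bk.sub(Se, as[k]));
        gi = bk.mul(gsyn_over_N, Si);
      } else {
        ge = bk.mul(gsyn_over_N, Se);
        gi = bk.mul(gsyn_over_N, bk.sub(Si, as[k]));
      }
      num Isyne = bk.mul(ge, bk.sub(V[k], V_exc));
      num Isyni = bk.mul(gi, bk.sub(V[k], V_inh));
      // C dV/dt = -[INa + IK + Il + Isyn_e + Isyn_i - Iapp]
      num acc = bk.add(bk.add(bk.add(bk.add(INa, IK), Il), Isyne), Isyni);
      acc = bk.sub(acc, Iapp[k]);
      dV[k] = bk.div(bk.neg(acc), C);
      dn[k] = bk.sub(bk.mul(an, bk.sub(c1, nn[k])), bk.mul(bn, nn[k]));
      // synaptic release gate
      num Pi = bk.div(c1, bk.add(c1, bk.exp_(bk.div(bk.sub(V_th, V[k]), k_v))));
      da[k] = bk.sub(bk.mul(bk.mul(Pi, alpha_a), bk.sub(c1, aa[k])),
                     bk.mul(beta_a, aa[k]));
      ds[k] = bk.sub(bk.mul(alpha_s, bk.sub(c1, ss[k])),
                     bk.mul(bk.mul(Pi, beta_s), ss[k]));
    }
  }

  // one fixed-step RK4 update with the pinned evaluation order
  void rk4_step(std::vector<num> &y, std::vector<num> &k1, std::vector<num> &k2,
                std::vector<num> &k3, std::vector<num> &k4,
                std::vector<num> &u) {
    int M = 4 * N;
    deriv(y, k1);
    for (int i = 0; i < M; ++i)
      u[i] = bk.add(y[i], bk.div(bk.mul(dt, k1[i]), c2));
    deriv(u, k2);
    for (int i = 0; i < M; ++i)
      u[i] = bk.add(y[i], bk.div(bk.mul(dt, k2[i]), c2));
    deriv(u, k3);
    for (int i = 0; i < M; ++i)
      u[i] = bk.add(y[i], bk.mul(dt, k3[i]));
    deriv(u, k4);
    for (int i = 0; i < M; ++i) {
      num s = bk.add(bk.add(bk.add(k1[i], bk.mul(c2, k2[i])),
                            bk.mul(c2, k3[i])), k4[i]);
      y[i] = bk.add(y[i], bk.div(bk.mul(dt, s), c6));
    }
  }

  RunResult run() {
    int M = 4 * N;
    std::vector<num> y(M, bk.zero()), k1(M, bk.zero()), k2(M, bk.zero()),
        k3(M, bk.zero()), k4(M, bk.zero()), u(M, bk.zero());
    auto init_block = [&](const std::vector<std::string> &lits, int block) {
      for (int j = 0; j < N; ++j) {
        const std::string &lit = lits.size() == 1 ? lits[0] : lits[j];
        y[block * N + j] = bk.from_lit(lit);
      }
    };
    init_block(cfg.init_V, 0);
    init_block(cfg.init_n, 1);
    init_block(cfg.init_a, 2);
    init_block(cfg.init_s, 3);

    const bool dec_backend = !std::is_same<num, double>::value;
    RunResult out;
    auto record = [&](long step) {
      num t = bk.mul(dt, bk.from_int(step));  // fresh product, never accumulated
      num sa = pool_sum_block(&y[2 * N]);
      num sb = pool_sum_block(&y[3 * N]);
      num A = bk.div(sa, bk.from_int(N));
      num S = bk.div(sb, bk.from_int(N));
      out.times.push_back(bk.to_double(t));
      out.A.push_back(bk.to_double(A));
      out.S.push_back(bk.to_double(S));
      if (dec_backend) {
        out.A_str.push_back(fmt_full(A));
        out.S_str.push_back(fmt_full(S));
      }
    };
    record(0);
    for (long step = 1; step <= cfg.nsteps; ++step) {
      cur_step = step;
      rk4_step(y, k1, k2, k3, k4, u);
      for (int i = 0; i < M; ++i) {
        if (bk.bad(y[i])) {
          char buf[160];
          std::snprintf(buf, sizeof(buf),
                        "non-finite state at step %ld (neuron %d, variable %s)",
                        step, (i % N) + 1,
                        i < N ? "V" : i < 2 * N ? "n" : i < 3 * N ? "a" : "s");
          throw std::runtime_error(buf);
        }
      }
      if (step % cfg.stride == 0) record(step);
    }
    return out;
  }

 private:
  // population average numerator over the full network with the configured
  // strategy (ascending neuron index)
  num pool_sum_block(const num *block) {
    if (cfg.sum_kind == SUM_REPRO) {
      if constexpr (std::is_same<num, double>::value) {
        hhsum::KAcc acc;
        acc.reset();
        for (int j = 0; j < N; ++j) acc.add(block[j]);
        return acc.result();
      } else {
        throw std::runtime_error(
            "reproducible summation is defined for the binary64 backend only");
      }
    }
    if (cfg.sum_kind == SUM_KAHAN) {
      num s = bk.zero(), comp = bk.zero();
      for (int j = 0; j < N; ++j) {
        num yv = bk.sub(block[j], comp);
        num t = bk.add(s, yv);
        comp = bk.sub(bk.sub(t, s), yv);
        s = t;
      }
      return s;
    }
    num s = bk.zero();
    for (int j = 0; j < N; ++j) s = (j == 0) ? block[j] : bk.add(s, block[j]);
    return s;
  }

  static std::string fmt_full(const num &x) {
    if constexpr (std::is_same<num, double>::value) return std::string();
    else return hhdec::dec_format_full(x);
  }
};

// ---------------------------------------------------------------------------

static void validate_cfg(const EngineConfig &cfg) {
  if (cfg.N < 1) throw std::runtime_error("N must be >= 1");
  if ((int)cfg.iapp.size() != cfg.N)
    throw std::runtime_error("Iapp length must equal N");
  if ((int)cfg.is_exc.size() != cfg.N)
    throw std::runtime_error("pool membership length must equal N");
  if (cfg.nsteps < 0) throw std::runtime_error("negative step count");
  if (cfg.stride < 1) throw std::runtime_error("record_stride must be >= 1");
  auto chklen = [&](const std::vector<std::string> &v, const char *nm) {
    if (v.size() != 1 && (int)v.size() != cfg.N)
      throw std::runtime_error(std::string("initial condition '") + nm +
                               "' must have length 1 or N");
  };
  chklen(cfg.init_V, "V"); chklen(cfg.init_n, "n");
  chklen(cfg.init_a, "a"); chklen(cfg.init_s, "s");
  if (cfg.hfpp_digits != 0 &&
      (cfg.hfpp_digits < 16 || cfg.hfpp_digits > hhdec::PMAX))
    throw std::runtime_error("HFPP digits must be in [16, 120]");
  if (cfg.hfpp_digits != 0 && cfg.sum_kind == SUM_REPRO)
    throw std::runtime_error(
        "reproducible summation is defined for the binary64 backend only; "
        "high-precision runs use plain accumulation");
}

RunResult run_network(const EngineConfig &cfg) {
  validate_cfg(cfg);
  if (cfg.hfpp_digits == 0) {
    Net<BkF64> net(BkF64(), cfg);
    return net.run();
  }
  BkDec bk;
  bk.P = cfg.hfpp_digits;
  Net<BkDec> net(bk, cfg);
  return net.run();
}

void deriv_f64(const EngineConfig &cfg, const std::vector<double> &V,
               const std::vector<double> &n, const std::vector<double> &a,
               const std::vector<double> &s, std::vector<double> &dV,
               std::vector<double> &dn, std::vector<double> &da,
               std::vector<double> &ds) {
  EngineConfig c2 = cfg;
  c2.nsteps = 0;
  validate_cfg(c2);
  Net<BkF64> net(BkF64(), c2);
  int N = cfg.N;
  std::vector<double> y(4 * N), dy(4 * N);
  for (int j = 0; j < N; ++j) {
    y[j] = V[j]; y[N + j] = n[j]; y[2 * N + j] = a[j]; y[3 * N + j] = s[j];
  }
  net.deriv(y, dy);
  dV.assign(dy.begin(), dy.begin() + N);
  dn.assign(dy.begin() + N, dy.begin() + 2 * N);
  da.assign(dy.begin() + 2 * N, dy.begin() + 3 * N);
  ds.assign(dy.begin() + 3 * N, dy.begin() + 4 * N);
}

}  // namespace hheng
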