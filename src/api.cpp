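// R-facing interface: decimal scalar operations, summation strategies,
// the portable applied-current generator, and the network integrator.

#include <Rcpp.h>

#include "decimal.h"
#include "engine.h"
#include "summation.h"

using namespace Rcpp;
using hhdec::Dec;

static Dec parse_or_stop(const std::string &lit, int digits) {
  Dec d;
  std::string err;
  if (!hhdec::dec_parse(lit, digits, d, err)) stop(err);
  return d;
}

static int mode_code(const std::string &mode) {
  if (mode == "round") return hhdec::RND_HALF_EVEN;
  if (mode == "truncate") return hhdec::RND_TRUNC;
  stop("rounding mode must be 'round' or 'truncate'");
}

// ---------------------------------------------------------------------------
// numerics

// [[Rcpp::export]]
std::string cpp_parse_literal(std::string literal, int digits) {
  Dec d = parse_or_stop(literal, digits);
  return hhdec::dec_format_full(d);
}

// [[Rcpp::export]]
double cpp_strtod_strict(std::string literal) {
  parse_or_stop(literal, 0);
  return std::strtod(literal.c_str(), nullptr);
}

// [[Rcpp::export]]
double cpp_nearest_binary32(std::string literal) {
  parse_or_stop(literal, 0);
  errno = 0;
  float f = std::strtof(literal.c_str(), nullptr);
  if (!std::isfinite((double)f))
    stop("value overflows the binary32 range: '%s'", literal.c_str());
  return (double)f;
}

// [[Rcpp::export]]
std::string cpp_dec_arith(std::string op, std::string a, std::string b,
                          int digits) {
  Dec da = parse_or_stop(a, digits), db = parse_or_stop(b, digits);
  Dec r;
  if (op == "+") r = hhdec::dec_add(da, db, digits);
  else if (op == "-") r = hhdec::dec_sub(da, db, digits);
  else if (op == "*") r = hhdec::dec_mul(da, db, digits);
  else if (op == "/") r = hhdec::dec_div(da, db, digits);
  else stop("unsupported operation '%s'", op.c_str());
  return hhdec::dec_format_full(r);
}

// [[Rcpp::export]]
int cpp_dec_cmp(std::string a, std::string b) {
  return hhdec::dec_cmp(parse_or_stop(a, 0), parse_or_stop(b, 0));
}

// [[Rcpp::export]]
std::string cpp_dec_exp(std::string x, int digits) {
  return hhdec::dec_format_full(hhdec::dec_exp(parse_or_stop(x, digits), digits));
}

// [[Rcpp::export]]
std::string cpp_dec_pow_chain(std::string x, int k, int digits) {
  return hhdec::dec_format_full(
      hhdec::dec_pow_chain(parse_or_stop(x, digits), k, digits));
}

// [[Rcpp::export]]
std::string cpp_dec_format(std::string x, int sig_digits, std::string mode) {
  return hhdec::dec_format(parse_or_stop(x, 0), sig_digits, mode_code(mode));
}

// [[Rcpp::export]]
double cpp_dec_to_double(std::string x) {
  return hhdec::dec_to_double(parse_or_stop(x, 0));
}

// [[Rcpp::export]]
std::string cpp_double_exact_string(double x, int sig_digits, std::string mode) {
  if (!R_finite(x)) stop("exact decimal expansion requires a finite value");
  return hhdec::double_exact_string(x, sig_digits, mode_code(mode));
}

// ---------------------------------------------------------------------------
// summation

// [[Rcpp::export]]
double cpp_sum_ordered_f64(NumericVector x, std::string kind) {
  if (kind == "NAIVE") return hhsum::sum_naive(x.begin(), x.size());
  if (kind == "KAHAN") return hhsum::sum_kahan(x.begin(), x.size());
  stop("ordered summation kind must be NAIVE or KAHAN");
}

// [[Rcpp::export]]
double cpp_sum_reproducible(NumericVector x) {
  return hhsum::sum_repro(x.begin(), x.size());
}

// [[Rcpp::export]]
double cpp_sum_exact_oracle(NumericVector x) {
  return hhsum::sum_exact_decimal(x.begin(), x.size());
}

// [[Rcpp::export]]
std::string cpp_sum_ordered_dec(CharacterVector x, std::string kind,
                                int digits) {
  std::vector<Dec> v;
  v.reserve(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    v.push_back(parse_or_stop(as<std::string>(x[i]), digits));
  Dec s = hhdec::dec_zero();
  if (kind == "NAIVE") {
    for (size_t i = 0; i < v.size(); ++i)
      s = (i == 0) ? v[0] : hhdec::dec_add(s, v[i], digits);
  } else if (kind == "KAHAN") {
    Dec comp = hhdec::dec_zero();
    for (size_t i = 0; i < v.size(); ++i) {
      Dec y = hhdec::dec_sub(v[i], comp, digits);
      Dec t = hhdec::dec_add(s, y, digits);
      comp = hhdec::dec_sub(hhdec::dec_sub(t, s, digits), y, digits);
      s = t;
    }
  } else {
    stop("ordered summation kind must be NAIVE or KAHAN");
  }
  return hhdec::dec_format_full(s);
}

// difference |a - b| of decimal strings, returned as binary64 magnitudes
// (used to compare high-precision traces far below binary64 resolution)
// [[Rcpp::export]]
NumericVector cpp_dec_abs_diff(CharacterVector a, CharacterVector b) {
  if (a.size() != b.size()) stop("length mismatch");
  NumericVector out(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    Dec da = parse_or_stop(as<std::string>(a[i]), 0);
    Dec db = parse_or_stop(as<std::string>(b[i]), 0);
    Dec d = hhdec::dec_sub(da, db, 40);
    d.sign = (int8_t)(d.n == 0 ? 0 : 1);
    out[i] = hhdec::dec_to_double(d);
  }
  return out;
}

// ---------------------------------------------------------------------------
// applied-current generator: splitmix64, uniform on [-10, 5]

static inline uint64_t splitmix64_next(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// [[Rcpp::export]]
CharacterVector cpp_generate_iapp(double seed, int n) {
  if (n < 1) stop("N must be >= 1");
  if (!R_finite(seed) || seed != std::floor(seed))
    stop("seed must be an integer value");
  uint64_t state = (uint64_t)(int64_t)seed;
  CharacterVector out(n);
  char buf[40];
  for (int i = 0; i < n; ++i) {
    uint64_t z = splitmix64_next(state);
    double u = (double)(z >> 11) * 0x1.0p-53;  // [0, 1)
    double val = -10.0 + 15.0 * u;
    std::snprintf(buf, sizeof(buf), "%.16e", val);  // 17 significant digits
    out[i] = buf;
  }
  return out;
}

// ---------------------------------------------------------------------------
// network integration

static hheng::EngineConfig build_cfg(List params, CharacterVector iapp,
                                     LogicalVector is_exc, std::string dt,
                                     double nsteps, int stride, int sum_kind,
                                     bool unified, int singularity,
                                     int hfpp_digits, List inits) {
  hheng::EngineConfig cfg;
  cfg.N = (int)iapp.size();
  for (R_xlen_t i = 0; i < iapp.size(); ++i)
    cfg.iapp.push_back(as<std::string>(iapp[i]));
  for (R_xlen_t i = 0; i < is_exc.size(); ++i)
    cfg.is_exc.push_back(is_exc[i] ? 1 : 0);
  CharacterVector nm = params.names();
  for (R_xlen_t i = 0; i < params.size(); ++i)
    cfg.params[as<std::string>(nm[i])] = as<std::string>(params[i]);
  cfg.dt_lit = dt;
  cfg.nsteps = (long)nsteps;
  cfg.stride = stride;
  cfg.sum_kind = sum_kind;
  cfg.unified = unified;
  cfg.singularity = singularity;
  cfg.hfpp_digits = hfpp_digits;
  auto getv = [&](const char *k) {
    CharacterVector v = inits[k];
    std::vector<std::string> r;
    for (R_xlen_t i = 0; i < v.size(); ++i) r.push_back(as<std::string>(v[i]));
    return r;
  };
  cfg.init_V = getv("V"); cfg.init_n = getv("n");
  cfg.init_a = getv("a"); cfg.init_s = getv("s");
  return cfg;
}

// [[Rcpp::export]]
List cpp_run_network(List params, CharacterVector iapp, LogicalVector is_exc,
                     std::string dt, double nsteps, int stride, int sum_kind,
                     bool unified, int singularity, int hfpp_digits,
                     List inits) {
  hheng::EngineConfig cfg =
      build_cfg(params, iapp, is_exc, dt, nsteps, stride, sum_kind, unified,
                singularity, hfpp_digits, inits);
  hheng::RunResult res = hheng::run_network(cfg);
  List out = List::create(
      _["times"] = NumericVector(res.times.begin(), res.times.end()),
      _["A"] = NumericVector(res.A.begin(), res.A.end()),
      _["S"] = NumericVector(res.S.begin(), res.S.end()));
  if (!res.A_str.empty()) {
    out["A_str"] = CharacterVector(res.A_str.begin(), res.A_str.end());
    out["S_str"] = CharacterVector(res.S_str.begin(), res.S_str.end());
  }
  return out;
}

// [[Rcpp::export]]
List cpp_deriv_f64(List params, CharacterVector iapp, LogicalVector is_exc,
                   int sum_kind, bool unified, int singularity,
                   NumericVector V, NumericVector n, NumericVector a,
                   NumericVector s) {
  List inits = List::create(_["V"] = CharacterVector::create("0"),
                            _["n"] = CharacterVector::create("0"),
                            _["a"] = CharacterVector::create("0"),
                            _["s"] = CharacterVector::create("0"));
  hheng::EngineConfig cfg = build_cfg(params, iapp, is_exc, "0.01", 0, 1,
                                      sum_kind, unified, singularity, 0, inits);
  std::vector<double> Vv(V.begin(), V.end()), nv(n.begin(), n.end()),
      av(a.begin(), a.end()), sv(s.begin(), s.end()), dV, dn, da, ds;
  hheng::deriv_f64(cfg, Vv, nv, av, sv, dV, dn, da, ds);
  return List::create(_["dV"] = NumericVector(dV.begin(), dV.end()),
                      _["dn"] = NumericVector(dn.begin(), dn.end()),
                      _["da"] = NumericVector(da.begin(), da.end()),
                      _["ds"] = NumericVector(ds.begin(), ds.end()));
}
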