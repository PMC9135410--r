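# hhrepro

Replicability-controlled simulation of a small all-to-all network of
Hodgkin-Huxley-type neurons with activity-dependent synaptic depression —
the classic model of episodic population activity in developing circuits.
Deterministic simulations of this model are notoriously hard to *replicate
numerically*: floating-point addition is neither commutative nor
associative, literals silently round to the nearest representable value,
and math libraries differ in their last bit. `hhrepro` makes each of these
effects an explicit, testable configuration axis instead of an accident.

## The model

Each neuron carries membrane potential `V`, delayed-rectifier gate `n`,
synaptic activity `a`, and synaptic efficacy `s`:

    C dV/dt = -[ I_Na + I_K + I_l + g_e (V - V_exc) + g_i (V - V_inh) - I_app ]
    dn/dt   = alpha_n(V) (1 - n) - beta_n(V) n
    da/dt   = Pi(V) alpha_a (1 - a) - beta_a a
    ds/dt   = alpha_s (1 - s) - Pi(V) beta_s s

with instantaneous sodium activation (`I_Na = g_Na m_inf^3 (0.8 - n)(V - V_Na)`),
a sigmoidal release gate `Pi(V) = 1/(1 + exp((V_th - V)/k_v))`, and
per-neuron synaptic conductances built from population sums
`g_e,k = (gbar_syn / N) (sum_{j in exc} a_j s_j - a_k s_k)`. Fast synaptic
depression during episodes and slow recovery during silence generate the
rhythm: bursts of elevated mean activity `<A>` separated by quiescence
while `<S>` recovers.

The experiment matrix crosses two axes that are algebraically irrelevant
but floating-point relevant: the excitatory/inhibitory **split** (how the
conductance sum is associated into partial sums; the "inhibitory" pool has
the same reversal potential, so only the arithmetic changes) and the
**ordering** of the applied-current vector (how the sum's terms commute).

What the package controls:

* **Initialization** — every constant is a decimal literal string,
  materialized per backend with no intermediate conversion.
* **Precision backend** — IEEE binary64 (`DFPP`), or an in-package decimal
  floating-point arithmetic (`HFPP`) with 16–120 significant digits in
  which every operation rounds half-to-even, including an in-package `exp`
  so no platform math library is involved.
* **Summation strategy** — naive left-to-right, Kahan-compensated, or a
  correctly rounded order-invariant sum (Kulisch-style long accumulator)
  for every cross-neuron reduction.
* **Operation order** — the fixed-step RK4 integrator and all model
  formulas evaluate in a pinned order, bit-identical between the compiled
  engine and the plain-R reference implementation.

An analysis toolkit compares runs: pairwise absolute-error series
`eps(t) = |A_i(t) - A_j(t)|`, first-crossing times, all-to-all divergence
matrices, episode detection with hysteresis, and bit-exact CSV trace I/O
(including traces produced by other implementations).

## Worked example

```r
library(hhrepro)

# why ordering matters at all: the same four numbers, summed three ways
sum_ordered(c(0.1, 0.1, 0.1, -0.3), "NAIVE")   # 5.5511151231257827e-17
sum_reproducible(c(0.1, 0.1, 0.1, -0.3))       # 2.7755575615628914e-17 (exact sum, rounded)
to_decimal_string(make_scalar("0.1"), 20)      # "0.10000000000000000555"

# one scenario cell: 100 neurons, binary64, naive summation, 3 s
spec <- scenario_spec("ALL_EXC", "RND", seed = 1, N = 100,
                      settings = simulation_settings("0.01", 3000, 10))
tr <- run_scenario(spec)
tr
#> <hh_trace> N=100 ALL_EXC DFPP NAIVE, dt=0.01 ms, 30001 samples over 3000 ms
#>   <A> in [0, 0.73], <S> in [0.1603, 1]

detect_episodes(tr)
#>   start_ms end_ms
#> 1      6.2  169.2
#> 2    890.7 1026.2
#> 3   1799.4 1944.6
#> 4   2690.6 2824.5

# reorder the applied currents (same multiset!) and watch the runs diverge
tr_rnd <- run_scenario(scenario_spec("SPLIT_80_20", "RND", seed = 1, N = 100,
                                     settings = simulation_settings("0.01", 3000, 10)))
tr_asd <- run_scenario(scenario_spec("SPLIT_80_20", "ASD", seed = 1, N = 100,
                                     settings = simulation_settings("0.01", 3000, 10)))
first_divergence_time(absolute_error_series(tr_rnd, tr_asd), 1e-6)
#> [1] 2689.8    # ms: the rounding differences have de-phased an episode

# the mitigation: order-invariant sums make the orderings bitwise identical
spec_r <- scenario_spec("ALL_EXC", "RND", seed = 1, N = 100, summation = "REPRODUCIBLE",
                        settings = simulation_settings("0.01", 3000, 10))
spec_a <- scenario_spec("ALL_EXC", "ASD", seed = 1, N = 100, summation = "REPRODUCIBLE",
                        settings = simulation_settings("0.01", 3000, 10))
identical(run_scenario(spec_r)$A, run_scenario(spec_a)$A)
#> [1] TRUE
```

Interpretation: the four detected episodes are the developing-network
rhythm (episode onsets near 0, 0.9, 1.8, 2.7 s; quiescent gaps between).
Reordering the applied-current vector changes only the rounding of the
conductance sums — a perturbation of order 1e-17 — yet by 2.69 s the
absolute error between the two runs exceeds 1e-6 because an episode onset
has shifted. With the correctly rounded order-invariant sum the orderings
are bitwise indistinguishable over the full run; a high-precision backend
(e.g. `precision_spec("HFPP", 50)`) achieves the same replicability while
keeping the naive accumulation order.

A command-line front end is installed with the package
(`inst/scripts/hhrepro.R`): `run <scenario.yaml>`, `sweep --all-cells`,
`compare A.csv B.csv --threshold 1e-6`, and `matrix <dir> --report out.csv`,
with exit codes 0 / 2 (validation) / 3 (numeric abort).

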