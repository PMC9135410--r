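---
title: "Numerical replicability in a depressing Hodgkin-Huxley network: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Numerical replicability in a depressing Hodgkin-Huxley network: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hhrepro)
```

## The scientific problem

Two runs of the same deterministic simulation "should" produce the same
numbers. In floating-point arithmetic they often do not: summation is
neither commutative nor associative, literals are silently converted to the
nearest representable value, and elementary functions differ in their last
bit across math libraries. In a recurrent network model these
last-bit discrepancies are amplified by the dynamics until trajectories
visibly disagree.

`hhrepro` simulates a small, all-to-all coupled network of
Hodgkin-Huxley-type neurons with activity-dependent synaptic depression --
the classic model of episodic population activity in developing circuits
(spinal cord, retina, cortex) -- and turns every known source of
floating-point non-replicability into an explicit, testable configuration
axis:

* **initialization**: every constant is materialized from a decimal literal
  string, never through an intermediate representation;
* **precision backend**: IEEE binary64 ("DFPP") or an in-package decimal
  floating-point arithmetic with a configurable number of significant
  digits ("HFPP");
* **accumulation strategy**: presynaptic conductance sums and population
  averages can be accumulated naively, with Kahan compensation, or with a
  correctly rounded order-invariant sum;
* **operation order**: the fixed-step RK4 integrator and every model
  formula evaluate in a pinned order and association.

## The model

Each neuron $j$ carries four state variables: membrane potential $V_j$
(mV), delayed-rectifier activation $n_j$, synaptic activity $a_j$, and
synaptic efficacy $s_j$:

$$C \frac{dV_j}{dt} = -\left[ I_{Na,j} + I_{K,j} + I_{l,j} + I_{syn,e,j} + I_{syn,i,j} - I_{app,j} \right]$$

$$\frac{dn_j}{dt} = \alpha_n(V_j)(1 - n_j) - \beta_n(V_j)\, n_j$$

with $\alpha_n(V) = 0.01(10 - V)/(e^{0.1(10-V)} - 1)$ and
$\beta_n(V) = 0.125\, e^{-V/80}$ (rest-at-0-mV convention). The sodium
current assumes instantaneous activation and the Rinzel reduction
$h \approx 0.8 - n$:

$$I_{Na} = g_{Na}\, m_\infty^3(V)\,(0.8 - n)\,(V - V_{Na}), \qquad
  I_K = g_K\, n^4 (V - V_K), \qquad I_l = g_l (V - V_l).$$

Synaptic currents are conductance-based, $I_{syn,e} = g_{syn,e}(V - V_{exc})$
and $I_{syn,i} = g_{syn,i}(V - V_{inh})$, with per-neuron conductances built
from the population:

$$g_{syn,e,k} = \frac{\bar g_{syn}}{N}\left( \sum_{j \in exc} a_j s_j - [a_k s_k] \right),$$

the own term subtracted only from the pool containing neuron $k$
(all-to-all coupling, no autapse), and analogously for the inhibitory pool.
The activity and efficacy variables follow

$$\frac{da_j}{dt} = \Pi(V_j)\, \alpha_a (1 - a_j) - \beta_a a_j, \qquad
  \frac{ds_j}{dt} = \alpha_s (1 - s_j) - \Pi(V_j)\, \beta_s s_j,$$

with the sigmoidal release gate $\Pi(V) = 1/(1 + e^{(V_{th} - V)/k_v})$.
Fast depression ($\beta_s$) during activity and slow recovery ($\alpha_s$)
during silence generate the rhythm: episodes of elevated network activity
$\langle A \rangle = \frac1N \sum_j a_j$ separated by quiescent periods
during which $\langle S \rangle = \frac1N \sum_j s_j$ recovers.

Applied currents $I_{app,j}$ are drawn once, uniformly from $[-10, 5]$
uA/cm^2, and reused (as 17-digit decimal strings) by every scenario.
Because $V_{exc} = V_{inh} = 70$ mV, neurons labelled "inhibitory" still act
excitatorily: the 80/20 split changes only how the conductance sum is
*associated* into two partial sums, while reordering the applied-current
vector changes how its terms *commute* -- together the $2 \times 3$
scenario matrix probes exactly the two algebraic properties that
floating-point addition lacks.

## Parameters and under-specified constants

The published parameter set: $g_l = 0.1$, $V_l = -10.6$, $g_{Na} = 36$,
$V_{Na} = 115$, $g_K = 12$, $V_K = -12$, $\bar g_{syn} = 3.6$ (all mS/cm^2
and mV), $V_{exc} = V_{inh} = 70$ mV, $\alpha_a = 1$, $\beta_a = 0.1$,
$\alpha_s = 0.0015$, $\beta_s = 0.12$ ms$^{-1}$, $V_{th} = 40$ mV. (The
printed unit of $g_l$, S/cm^2 amid mS/cm^2 entries, is treated as a typo
for mS/cm^2.)

Three ingredients are not fixed by the published description and are
package choices, each made once and documented here:

* **$m_\infty$**: the functional form is not printed; the classic
  squid-axon rates in the rest-at-0 convention are adopted,
  $\alpha_m = 0.1(25-V)/(e^{0.1(25-V)}-1)$, $\beta_m = 4e^{-V/18}$,
  consistent with the convention of the printed $\alpha_n, \beta_n$.
* **$C$**: absent from the table; the standard squid-axon value 1 uF/cm^2.
* **$k_v$**: the release slope appears in $\Pi$ with no value. This
  constant controls the recurrent gain at quiescence and therefore whether
  the network has an episodic rhythm at all. A one-dimensional sweep shows:
  below about 6.2 mV the quiescent state is globally stable (no episodes
  ever recur); above about 7.5 mV activity becomes nearly continuous; in
  between the model produces the described rhythm. The default
  **$k_v = 6.5$ mV** was selected inside this window as the value whose
  rhythm matches the published description (episodes of order 100 ms,
  inter-episode intervals of order 1 s, two to three spontaneous episodes
  in the first 3 s, efficacy cycling between roughly 0.16 and 0.68). It was
  identified against the model's described dynamics, once, and is exposed
  as an ordinary parameter.
* **initial conditions**: unknown; defaults $V(0)=0$, $n(0)=0.3$, $a(0)=0$,
  $s(0)=1$ -- a near-rest start with fully recovered synapses, every value
  exactly representable in both backends. With recovered synapses the run
  begins with a startup episode; scenario files may pin any other start.

## Precision backends

**DFPP** is IEEE binary64 with round-to-nearest, ties-to-even. The
`exp` function delegates to the platform math library, and consequently
*cross-platform bit equality of DFPP runs is explicitly not promised*:
last-bit differences between math libraries are one of the documented
sources of non-replicability this package exists to study. Within one
environment DFPP runs are bitwise deterministic; fused multiply-add
contraction is disabled in the compiled code so the engine executes the
same binary64 operation sequence as the interpreted reference
implementation (`state_derivatives()`), a property the test suite asserts
bit for bit.

**HFPP** is a decimal floating-point arithmetic implemented in the package:
a sign, a base-10 coefficient, and a power-of-ten exponent, with every
arithmetic operation rounded half-to-even to the context's significant
digits (16 to 120; default 100). Addition, subtraction, and multiplication
compute the exact result before the single rounding; division is correctly
rounded (a Newton-Raphson reciprocal with guard digits, plus an exact
residual check near rounding boundaries, with exact single-pass paths for
short integer divisors). A scalar constructed from a literal with at most
`digits` significant digits is exact, and scalars never convert silently
between backends -- assigning a binary64 intermediate to a high-precision
variable is precisely the initialization mistake the literal-string
discipline prevents.

`exp` for HFPP is implemented in-package rather than delegated, because
platform math libraries are a known divergence source. The algorithm:
split $x = n + r$ with integer $n$ and $|r| \le 0.5$; convert $r$ to a
binary fixed-point representation with roughly $3.3 \times$ (working
digits) + 34 bits; halve 20 times (bit shifts); evaluate the Taylor
polynomial by Horner with precomputed reciprocal-factorial coefficients;
square 20 times; convert back to decimal and multiply by the cached
$e^n$. About ten guard digits are carried, so results are accurate to the
working precision (and in practice correctly rounded except within
$\sim 10^{-8}$ ulp of a rounding boundary). Integer powers use the explicit
chain $(((x \cdot x) \cdot x) \cdot x)$ in both backends.

The removable rate singularities ($V = 10$ in $\alpha_n$, $V = 25$ in
$\alpha_m$) raise an error on exact equality by default -- the hazard stays
visible -- with `singularity = "limit"` substituting the analytic limits
(0.1 and 1).

## Summation strategies

`sum_ordered(x, "NAIVE")` is strict left-to-right binary accumulation;
`"KAHAN"` is classic compensated summation (single correction term,
initialized to zero, left-to-right). Both are order-sensitive by contract.
`sum_reproducible()` returns the binary64 value nearest the *exact* real
sum, via a Kulisch-style long accumulator (a 2560-bit fixed-point register
aligned at $2^{-1074}$) -- order-invariant by construction, because the
exact sum has no order. Its independent oracle, `sum_exact_decimal()`,
accumulates the exact finite decimal expansions of the inputs in a wide
decimal fixed-point register and rounds once through `strtod`; the two
routes share no arithmetic and agree bitwise on randomized mixed-magnitude
vectors (a standing property test).

The engine uses the configured strategy for every cross-neuron reduction --
the two conductance pools and both population averages -- always over
ascending neuron index. Reproducible summation is defined for the binary64
backend only; a high-precision run is its own mitigation and uses plain
ordered accumulation.

As the strongest mitigation, `unified_accumulation = TRUE` (valid when
$V_{exc} = V_{inh}$) accumulates both pools as one order-invariant sum
before the split is applied, which makes the six scenario cells bitwise
identical. It is off by default because it changes the model's arithmetic
path: the point of the scenario matrix is to *expose* the association of
the sum, and the unified mode deliberately erases it.

## Integration

The classical RK4 scheme with fixed step (default $dt = 0.01$ ms) and a
pinned operation order: $u_1 = y + (dt \cdot k_1)/2$ componentwise,
$u_2 = y + (dt \cdot k_2)/2$, $u_3 = y + dt \cdot k_3$, and
$y' = y + (dt \cdot (((k_1 + 2k_2) + 2k_3) + k_4))/6$, components in
ascending neuron index with variable blocks ordered $(V, n, a, s)$. The
step count is `round(duration/dt)` computed once from the literals, and
each sample time is the fresh product $i \cdot dt$, never an accumulated
time variable. Closed-form identities (the degree-4 Taylor polynomial for
linear decay; Simpson-exactness for time-only cubics) are asserted to one
ulp in the tests.

## What the generated inputs emulate -- and what they do not

The synthetic applied-current vector is the study's only random input. It
emulates the heterogeneous constant drive of the original experiments
(uniform on $[-10, 5]$ uA/cm^2, drawn once, identical multiset across all
six cells); it is generated by splitmix64 -- chosen over R's own RNG
because the algorithm is four lines long and exactly portable to any
language -- and frozen as 17-digit decimal strings so every backend
materializes identical binary64 values. What it does not emulate: the
original study's actual current vector (its seed was never published), so
episode times here are statistically similar but not numerically identical
to the published figures, and all timing-sensitive checks use tolerances at
the level of "episodes occur, in this window" rather than exact onsets.

One consequence deserves emphasis. With this package's reconstructed
constants the network's attractor is, for most current realizations, a
*stable* limit cycle: between episodes, perturbations contract, and the
binary64 ordering experiment de-phases an episode onset within 3 s for
roughly two-thirds of seeds (for the others the six cells still replicate
each other after 3 s -- reported as "never diverged"). The original
system appears to sit deeper in the chaotic regime, since its published
divergence was robust. The divergence analysis therefore reports the
all-to-all matrix over the six cells, with the full duration standing in
for "never" (the dark-red convention of divergence reports).

## Problem sizes in the tests and acceptance script

At the model's full scale (8 s, 100 neurons, 100 decimal digits) a
high-precision run is a day-scale computation in any implementation; the
package's standing checks use desk-scale versions chosen as the smallest
sizes at which each phenomenon is unambiguous:

* high-precision replicability: the six cells at $N = 20$, 1000 ms, 50
  digits, compared sample-by-sample on the full decimal strings (agreement
  is typically below $10^{-40}$; the acceptance bound is $10^{-30}$);
* binary64 divergence, mitigation, and episodes: $N = 100$, 3000 ms,
  $dt = 0.01$ ms;
* reproducible-sum contract: $10^4$ random vectors (length $\le 200$,
  magnitudes $10^{\pm 10}$) times 10 permutations against the decimal
  oracle.

The canonical scenario seed throughout is 1; the acceptance script accepts
any seed and regenerates everything from it.

## Known limitations

* Cross-platform bit equality of DFPP runs is not promised (platform
  `exp`); HFPP runs are bit-identical wherever the package builds.
* The decimal backend caps the context at 120 significant digits
  (coefficient capacity is sized for exact products at that precision);
  the published 100-digit setting fits, with margin for guard digits.
* HFPP division is correctly rounded; HFPP `exp` is guaranteed accurate to
  the working precision but not formally correctly rounded at exact
  rounding-boundary ties.
* The under-specified constants ($k_v$, $C$, $m_\infty$, initial
  conditions) were identified against the published description of the
  dynamics, not against the original source code; quantitative episode
  timings are therefore reconstruction-specific.

## A worked example

```{r example, eval = FALSE}
library(hhrepro)

# one scenario cell: binary64, naive summation
spec <- scenario_spec("ALL_EXC", "RND", seed = 1, N = 100,
                      settings = simulation_settings("0.01", 3000, 10))
tr <- run_scenario(spec)
detect_episodes(tr)

# the same cell with the applied currents sorted ascending
tr2 <- run_scenario(scenario_spec("ALL_EXC", "ASD", seed = 1, N = 100,
                                  settings = simulation_settings("0.01", 3000, 10)))
err <- absolute_error_series(tr, tr2)
first_divergence_time(err, 1e-6)

# order-invariant accumulation makes the orderings bitwise identical
spec_r <- scenario_spec("ALL_EXC", "RND", seed = 1, N = 100,
                        summation = "REPRODUCIBLE",
                        settings = simulation_settings("0.01", 3000, 10))
spec_a <- scenario_spec("ALL_EXC", "ASD", seed = 1, N = 100,
                        summation = "REPRODUCIBLE",
                        settings = simulation_settings("0.01", 3000, 10))
identical(run_scenario(spec_r)$A, run_scenario(spec_a)$A)  # TRUE
```
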