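---
title: "Binary threshold assemblies: model, statistical laws and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binary threshold assemblies: model, statistical laws and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`neuroassembly` simulates *assemblies*: networks of McCulloch–Pitts binary
threshold neurons in discrete time, wired by a square connection matrix
$M$ whose entries are unitized synapses, $m_{ij} \in \{-1, 0, 1\}$
($m_{ij}$ is the synapse from neuron $i$ to neuron $j$).  The state at
time $t$ is a binary vector $Y^t$; the synchronous update is

$$X^t = Y^{t-1} M + S^t, \qquad
  Y_j^t = \begin{cases} 1 & X_j^t > 0 \\ 0 & X_j^t \le 0, \end{cases}$$

where $S^t$ is an optional external drive.  The tie rule is part of the
model: an accumulation of exactly zero leaves the neuron silent, and it is
deliberately not configurable.  Stimulation comes in two forms, because
both are natural experimental manipulations: *clamping* (forcing selected
neurons to 1 or 0 after the threshold is applied, so that clamped neurons
still feed everyone else) and *additive input* (a term added to $X$ before
thresholding).  Time is 0-based, row $t$ of a raster is $Y^t$, and
protocol windows are half-open $[\mathrm{start}, \mathrm{end})$.

Because the state space is finite ($2^n$ states) and the dynamics are
deterministic, every trajectory under a time-invariant drive ends in a
fixed point or a loop of period $T$.  `detect_cycle()` finds the smallest
(transient, period) pair by state-revisit hashing, capped at a horizon and
reporting `found = FALSE` beyond it rather than searching without bound.
The interesting observable is not any single state but the *spike
probability* $P_i$, the long-run fraction of steps on which neuron $i$
fires, together with the *mean accumulation* $\bar X_i$.

## Exact statistics over one attractor period

With `burn_in = "auto-cycle"`, `spike_probabilities()` measures $P$ and
$\bar X$ over exactly one attractor period, making both exact rationals
with denominator $T$.  One subtlety is worth recording: the window must
start one step *inside* the attractor.  The accumulation at the re-entry
step is produced by the last transient state, so a window starting at the
transient itself would mix one out-of-attractor input into $\bar X$.  With
the window $[\tau + 1, \tau + T)$ the conservation identity

$$\bar X = P \, M$$

holds *exactly* (integer counting, no tolerance): every input integrated
during a cycle is a spike some neuron emitted during that same cycle.
`accumulation_residual()` verifies this and the test suite asserts literal
zero over random matrices up to $n = 50$.

## The logistic law and the nonlinear fixed-point system

Across the neurons of a stationary assembly, spike probability follows a
logistic function of mean accumulation,

$$P_i = \frac{1}{1 + e^{A \bar X_i + C}}, \qquad A < 0,$$

which can be motivated by a Bayes argument: conditioning on firing versus
silence, the accumulations are approximately normal with a common
variance, and the log posterior odds are then linear in $\bar X$.  The
intermediate quantities of that argument (the two conditional means and
the shared variance) appear only inside the derivation; they are never
estimated separately, and $(A, C)$ are the only fitted parameters.
`fit_logistic()` estimates them by least squares on the logit scale
(probabilities clipped to $[\varepsilon, 1-\varepsilon]$,
$\varepsilon = 10^{-6}$ by default), with an optional `nls` refinement on
the probability scale; on data generated exactly from the law both routes
recover $(A, C)$ to numerical precision, which the tests assert.

Substituting $\bar X = P M$ into the law yields the nonlinear system

$$(P M)_j + S_j \;=\; \frac{1}{A}\left(\log\frac{1 - P_j}{P_j} - C\right),$$

whose solution the simulated probabilities meet.  The printed closed-form
has no stimulation term; the interpretation adopted here (documented, not
derived) is that the external sum $S$ enters additively next to $P M$,
which reduces to the closed form when $S = 0$.  `solve_fixed_point()`
solves the system by damped iteration on the equivalent logistic form,
$P \leftarrow (1-\lambda) P + \lambda\, \sigma(-(A (P M + S) + C))$
($\lambda = 0.5$, `tol` $= 10^{-8}$, at most $10^4$ iterations), with a
BFGS minimization of the squared residual as fallback, and reports rather
than asserts uniqueness (multi-start comparison is available through
`init`).  Two double-precision caveats near saturation are handled
explicitly and matter in practice at $n = 400$: coordinates pinned at the
clipping boundary whose residual points outward are counted as saturated
(their exact probability is not representable inside the band), and for
$P$ within about $10^{-8}$ of 0 or 1 one representable step of $P$ moves
the logit by more than `tol`, so the convergence test grants each
coordinate that representational floor.

Where do $(A, C)$ come from when solving?  They are properties of the
operating network, not free constants, so the package's default
(`estimate_ac_from_pilot()`) measures them from a pilot run of the same
matrix; both `solve_fixed_point()` and the comparison wrapper accept
externally supplied values instead.
`compare_with_simulation()` chains simulate → fit → solve → correlate; at
$n = 400$, equal excitatory/inhibitory proportions and full density, the
Pearson correlation between solved and simulated probabilities is
typically 0.97–0.99 (median ≈ 0.98 over seeds), and the package's
acceptance script recomputes exactly this quantity.

Three negative controls (`linear_predictor_checks()`) make the point that
no *linear* summary of $M$ predicts $P$: column weight sums correlate only
weakly with $P$; graded persistent inputs correlate weakly with the
probability shifts they cause; and permuting the columns of $M$ does not
preserve $P$.  For the last control the package permutes *all* columns:
swapping just two of several hundred leaves the dynamics nearly unchanged
and would be an uninformative test.  If the permuted matrix happens to
equal the original the control correctly reports agreement.

## Entropy and polarization — including a negative result

Two entropies are computed for an attractor: the Boltzmann entropy
$S_T = k \ln T$ of a uniformly visited cycle, and a Shannon entropy of the
spike probabilities.  The latter exists in two variants:

* `"as-printed"`: $S_P = -\sum_i P_i \ln P_i$ — the form the polarization
  argument manipulates, kept as the default;
* `"bernoulli"`: $-\sum_i [P_i \ln P_i + (1-P_i)\ln(1-P_i)]$ — the full
  per-neuron marginal entropy.

The claimed bound $S_T \le S_P$ is *provable for the Bernoulli variant*:
the attractor is a uniform distribution over $T$ joint states, and the
joint entropy is at most the sum of marginal entropies (subadditivity).
The as-printed form, however, drops the $(1-P)\ln(1-P)$ terms and is
strictly smaller whenever any neuron is polarized, and it does **not**
bound $\ln T$ in general: on random attractors ($n$ = 5–30, balanced
synapses) the package finds violations in a few to twenty percent of
instances, depending on density.  The acceptance suite therefore carries
one deliberately failing expectation — the as-printed bound asserted on
every detected attractor — as an honest record of this, alongside the
passing Bernoulli bound.  Nothing else in the package depends on the
as-printed inequality.

Polarization itself is robust.  `polarization_experiment()` drives an
assembly with a nested, growing set of clamped (persistently active)
neurons and reports, per stage, the as-printed entropy of the *observed*
(non-clamped) neurons and their mean active count.  At $n = 500$ with a
0.53 excitatory fraction and clamp stages of 50/100/150 neurons (the
stage sizes are configuration; 50-neuron increments are the package's
default stimulation unit), mean entropy over ten seeds falls
monotonically and the observed active count falls with it — more
stimulation, more polarized probabilities, a sharper "decision".

## Stability: the binomial/normal activity theory

With $n$ active neurons and excitatory fraction $E_1$, a neuron's summed
input is distributed like a signed binomial sample, and the probability
that it is positive (more $+1$ than $-1$ among the sampled synapses) has
the truncated-normal form

$$\Phi\!\left(\frac{n - nE_1}{\sqrt{n E_1 E_{-1}}}\right) -
  \Phi\!\left(\frac{n/2 - nE_1}{\sqrt{n E_1 E_{-1}}}\right),$$

implemented by `firing_probability()`.  The plain form above is the
default and gives the theory's analytic limits (at $E_1 = 0.5$,
$N = 500$: equilibrium activity $N^* = 250$).  It is worth knowing that
near $E_1 = 0.5$ it overshoots the exact binomial tail by up to
$\approx 0.4/\sqrt n$ (0.056 at $n = 50$), because the tied outcome
$X = 0$ — silent under the threshold rule — carries the single largest
probability mass there.  The half-unit continuity correction
(`continuity = TRUE`) tracks the exact tail to better than 0.002 over
$n \ge 50$, $E_1 \in [0.3, 0.7]$, and also explains why simulated
balanced assemblies equilibrate slightly below $N/2$ (about 237–245 of
500 rather than 250).

`solve_equilibrium()` finds the fixed points of
$n \mapsto N \cdot p_{\mathrm{fire}}(n, E_1)$ by a sign scan plus
root refinement, classifies each root by the local map slope (zero is
always a fixed point; small positive roots at low $E_1$ exist but are
dynamically unstable), and returns the largest stable root: `extinct`
(no stable positive root — over-inhibition kills activity), `saturated`
(root at ≥ 95% of $N$), or `stable`.  `phase_diagram()` pairs these
predictions with seeded simulations; over $E_1 \in [0.5, 0.6]$ at
$N = 500$ the prediction matches Monte-Carlo mean activity within a few
percent, and sweeping density at fixed $(N, E_1)$ confirms that in a
closed assembly the proportion of zeros in $M$ does not move the
equilibrium — density only matters once external input breaks closure.

## Reducing a raw network to the unit matrix

A biologically parameterized network — Dale-typed neurons, real weights,
real thresholds, integer conduction delays — is reduced to a
behavior-equivalent unit matrix in four stages, each implemented as its
own operation so intermediate networks remain inspectable:

1. **Type equivalence** (`eliminate_inhibitory_neurons()`): every
   dedicated inhibitory neuron is rewritten into relay chains
   $i \to r \to k$, one per (incoming, outgoing) synapse pair, the final
   edge carrying the negative weight and the chain preserving total delay;
   the relay inherits the eliminated neuron's threshold.  This is exact
   precisely when the inhibitory neuron is a pass-through (at most one
   input).  Convergent inhibitory neurons have a genuinely nonlinear role
   that no per-pair rewrite preserves; they are rewritten anyway and
   recorded as approximate, with a warning.  An input-less inhibitory
   neuron with negative threshold (a spontaneous firer) is kept as an
   untyped unit instead, which is exact.
2. **Threshold equivalence** (`normalize_thresholds()`): one always-on
   bias unit (+1 self-loop, seeded active) supplies a weight $-\theta$
   synapse to every neuron with threshold $\theta \ne 0$, after which all
   thresholds are zero: $X > \theta \iff X - \theta > 0$.  Non-integer
   thresholds are **floored**, not ceiled: for integer-valued
   accumulations $X > \theta$ and $X > \lfloor\theta\rfloor$ are the same
   event, so flooring is exact where ceiling would not be.
3. **Weight discretization** (`discretize_weights()`): non-integer weights
   are mapped to their sign outside a configurable zero band (lossy,
   recorded).  An integer weight of magnitude $m$ becomes $m$ parallel
   unit synapses — but parallel edges collapse in a matrix, and routing
   them through relay units cannot preserve a delay-1 edge (a relay hop
   costs a step).  The package instead *replicates the source neuron*:
   replicas receive the same inputs, fire in lockstep, and each carries
   one unit synapse at the original delay.  Exact and delay-preserving,
   at the cost of $\max_e |w_e|$ copies per neuron.
4. **Delay unitization** (`unitize_delays()`): a delay-$d$ synapse becomes
   a chain of $d - 1$ unit relays, so a spike takes exactly $d$ steps end
   to end; the final \{-1, 0, 1\} matrix is emitted with an index map
   (original / bias / clone / relay, origin, seeded-active).

For integer parameters and pass-through inhibition the projection of the
simplified matrix's trajectory onto the surviving original neurons equals
the raw trajectory *step for step*; the test suite checks this with a
dual simulator (`simulate_raw()` versus `simulate_simplified()`) over
random instances.  The random raw-network generator deliberately creates
its inhibitory interneurons as pass-throughs (single input, threshold 0,
a feed-forward inhibition motif) so that generated instances sit in the
exact regime; the approximate paths are exercised separately.  No attempt
is made to minimize the emitted matrix.

## Phase coupling and the memory framework

Spike trains of "homogeneous probability" are deterministic periodic
patterns (`spike_train()`), because phase coupling is a relation between
reproducible phases.  `couple_trains()` computes the train seen by a
downstream neuron that fires at $t+1$ iff $a_t + b_{t+\mathrm{offset}} >
\mathrm{threshold}$: with the canonical 0.25 and 0.5 trains, threshold 1
selects the phase intersection (probability 0.25 in phase, 0 out of
phase) and threshold 0 the union (0.5) — the same two inputs yield many
output rates depending on relative phase and threshold.  Note that a
plain threshold gate on these two trains can never exceed the union
probability 0.75; output rates beyond that would require coupling
machinery richer than the gate modeled here, and the package does not
target them.

The memory framework (`build_memory_framework()`) wires two input units
and four mutually unconnected coupling units (each a closed random
assembly) with unidirectional excitatory links, all coupling units feeding
one output neuron under a step-up threshold modulator — implemented, in
keeping with the threshold rule, as an additive external input of
$-\mathrm{threshold}$ on the output neuron.  Unit sizes, link counts,
internal excitatory fractions and the three input modes are genuinely
open design parameters; the defaults — units of 50 neurons at
$E_1 = 0.5$ (self-sustaining but not saturated), 10 links per inter-unit
pair, modes = the 0.25/0.5 train pair at three distinct relative phases —
are one concrete configuration, chosen once and kept.  A presented mode
entrains the coupling units; after the input is removed each coupling
unit continues on the attractor the drive left it on, and that retained
phase relationship *is* the stored trace: activity-silent in the sense
that no persistent external drive maintains it, and overwritten by the
next presentation.  `recall()` steps the output threshold upward and
records the output spike probability per level; distinct modes leave
pairwise-distinct recall profiles (all pairwise distances positive in
five of five tested seeds at the default configuration), quantified by
`distinguishability()`.

## What the synthetic generator does and does not emulate

All experiments run on matrices from `random_connection_matrix()`:
i.i.d. entries, nonzero with probability `density`, $+1$ with probability
`e1` given nonzero, no self-connections by default.  The standard study
configurations used throughout the tests are: $n = 1000$ at
$E_1 = 0.5$ (logistic law), $n = 400$ at $E_1 = 0.5$, full density
(fixed-point comparison), $n = 500$ at $E_1 = 0.53$ (polarization),
$N = 500$ sweeps (stability).  The generator emulates unstructured random
wiring only: no distance-dependent connectivity, no degree structure, no
clustering, no plasticity.  Passing tests therefore show that the
statistical laws hold for homogeneous random assemblies; they say nothing
about structured biological circuits, where the mean-field sampling
argument behind both the logistic law and the stability theory can break.

## Problem sizes and numerical defaults

The test suite runs the full configurations where the claims are stated
($n = 400$ over 5 seeds and 5000 steps; $n = 1000$ for the logistic law;
$n = 500$ over 10 seeds for polarization and 5 seeds per grid cell for
stability) and smaller instances everywhere a property is exact rather
than statistical (conservation on $n \le 50$, brute-force oracle
agreement on $n \le 10$ over the full $2^n$ horizon, transform
equivalence on $n \le 8$).  Cycle-search horizons default to the recorded
run; periods for $n \le 50$ balanced assemblies are typically tens to
hundreds of steps, so 4000-step runs contain the attractor in practice.
Runs that never revisit a state (large $n$) fall back to trailing-half
statistics with a warning — for $n \ge 100$ this is the expected path,
and all large-$n$ laws are stated over that quasi-steady window.

Known limitations, beyond those noted above: the fixed-point system's
solution set is not characterized (the solver reports, and multi-start
probes, uniqueness only empirically); burn-in lengths for the large-$n$
experiments are package defaults with no deeper justification than the
quasi-steady behavior they demonstrably reach; and the equivalence
claims of the transform are exact only
for integer parameters — fractional weights pass through a documented,
flagged lossy mapping.
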