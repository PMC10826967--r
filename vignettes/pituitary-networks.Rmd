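---
title: "Methods: coupled spiking and bursting pituitary cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled spiking and bursting pituitary cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pitnet` simulates small networks of anterior-pituitary endocrine cells
(lactotroph-type) coupled by gap junctions, and analyzes when and why
electrically bursting cells convert tonically spiking neighbors into bursters,
and how the placement of bursters in a network shapes hormone secretion. This
vignette documents the model, the algorithmic choices, the tunable parameters,
and the known limitations — it is the package's methods reference.

## The single-cell model

Each cell carries four state variables: membrane potential $V$ (mV),
delayed-rectifier K$^+$ activation $n$, cytosolic free Ca$^{2+}$ concentration
$c$ (µM), and BK-channel activation $b$:

$$C_m \frac{dV}{dt} = -(I_{Kdr} + I_{Ca} + I_{BK} + I_{SK} + I_L + I_c),$$
$$\tau_n \frac{dn}{dt} = n_\infty(V) - n, \qquad
  \tau_b \frac{db}{dt} = b_\infty(V) - b, \qquad
  \frac{dc}{dt} = -f_c(\alpha I_{Ca} + k_c c),$$

with currents $I_{Kdr} = g_{Kdr}\, n (V - V_K)$,
$I_{Ca} = g_{Ca}\, m_\infty(V)(V - V_{Ca})$ (the fast Ca$^{2+}$ activation $m$
is at quasi-equilibrium), $I_{BK} = g_{BK}\, b (V - V_K)$,
$I_{SK} = g_{SK}\, d_\infty(c) (V - V_K)$ with
$d_\infty(c) = c^2/(c^2 + k_{SK}^2)$, and leak $I_L = g_L (V - V_L)$. Voltage
activations are Boltzmann sigmoids
$x_\infty(V) = 1/(1 + \exp((\nu_x - V)/l_x))$.

`cell_params()` returns the reference parameter set (capacitance 5 pF,
$g_{Kdr} = 2.5$, $g_{Ca} = 2.1$, $g_{SK} = 2$, $g_L = 0.2$ nS, reversal
potentials 60/−75/−50 mV, $\tau_n = 30$ ms, $\tau_b = 5$ ms,
$\alpha = 0.0015$ µM/fC, $f_c = 0.005$, $k_c = 0.12$ ms$^{-1}$,
$k_{SK} = 0.4$ µM). One parameter switches the phenotype: with
$g_{BK} = 1$ nS the cell produces pseudo-plateau bursting (small spikes riding
on a depolarized plateau); with $g_{BK} = 0$ it spikes tonically
(`burster_params()` / `spiker_params()`). $b$ is integrated for every cell and
is simply inert when $g_{BK} = 0$, keeping the state shape uniform across a
mixed network.

One unit note: the Ca$^{2+}$ removal rate $k_c$ multiplies $c$ in the calcium
balance, so it is a rate; we use $k_c = 0.12\ \mathrm{ms}^{-1}$.

Secretion is summarized by a dimensionless sigmoid readout of calcium,

$$s(c) = \frac{1}{1 + \exp\!\big({-5}\,\big(\tfrac{c - 0.27}{0.082} - 0.6\big)\big)},$$

whose midpoint $c^\ast = 0.3192$ µM sits between the calcium ranges of spiking
and bursting cells, so $s$ swings strongly when a cell bursts. The grouping of
constants in this expression is a package decision (the composition
`(c - 0.27)/0.082 - 0.6` inside the exponential); it places the midpoint where
the readout separates the two phenotypes.

## Coupling and integration

Gap junctions are ohmic and bidirectional: the current into cell $i$ is
$I_c = \sum_{j \in N_i} g_c (V_i - V_j)$ over its structural neighbors, so
coupling currents cancel pairwise over the network (asserted to round-off in
the tests). All cells on an edge share one conductance $g_c$; per-edge
heterogeneity is out of scope.

The network ODEs are integrated with the classic fixed-step 4th-order
Runge–Kutta method at $\Delta t = 0.5$ ms (`run_network()`). The stepper is
compiled (Rcpp) for the placement sweeps; a pure-R reference RK4
(`integrate_rk4()`) is kept and the two are cross-checked against each other
in the tests to $10^{-9}$ on a coupled pair, alongside a closed-form
exponential test verifying 4th-order convergence. Fixed-step RK4 at this
resolution is the protocol of record, so adaptive or implicit solvers are
deliberately not the default.

Initial conditions are not dictated by the biology, so the package default is
$V = -60$ mV, $n = 0.1$, $c = 0.1$ µM, $b = 0.1$ with small seeded jitter
(±1 mV on $V$, ±5% on $c$) to break artificial symmetry between identical
cells; both the states and the jitter are overridable (`sim_config(init = )`).
Runs discard a transient (default 10 s; 20 s for the 60-s two-cell protocols)
and analyze the following window — with `sim_config(t_end = 20000,
t_transient = 10000)` that is a 10-s analysis span, the span used for all
secretion averages. Identical configuration and seed reproduce trajectories
bit-identically.

## Structural networks and placement strategies

Networks are grown by the random-walk rule (`random_walk_network()`): start
from two connected nodes; repeatedly pick a uniform random existing node and,
with probability $p$, attach a new node to it, otherwise connect it to another
uniform random existing node. Duplicate edges are resampled up to a bounded
retry count, which biases the expected edge count $1 + (n-2)/p$ slightly low
(the tests quantify this). The growth probability is not a biologically
measured quantity; the package default $p = 0.7$ gives 20-cell networks with
roughly 27 edges (mean degree ≈ 2.7). Density matters for the strategy
results below, so $p$ is exposed everywhere.

`assign_types()` labels `round(fraction * n)` nodes as intrinsic bursters:
uniformly at random, by a greedy *defensive* rule (grow a connected burster
cluster, maximizing burster homophily; on a path graph it provably attains the
exhaustive-search maximum), by a greedy *offensive* rule (scatter bursters,
minimizing homophily, preferring high-degree nodes), or from an explicit id
list. Homophily statistics (`homophily()`): $\gamma_b$ of a burster is the
fraction of its neighbors that are bursters and $\Gamma_b$ is the mean over
bursters; $\gamma_s, \Gamma_s$ are the spiker-side analogues (the fraction of
a spiker's neighbors that are bursters). Means over empty populations are
flagged `NA`, never silently zero.

## Event detection and synchrony

Voltage traces are segmented with a hysteresis detector
(`detect_events()`): an event opens at an upward crossing of $V_{on} = -35$ mV
and closes at a downward crossing of $V_{off} = -45$ mV — between the model's
silent phase (≈ −60 mV) and plateau (≈ −20 mV) — and local maxima with
prominence ≥ 2 mV are counted inside each event. All three thresholds are
arguments. Classification (`classify_events()`): one peak → spike; two
single-peak events separated by < 40 ms of sub-threshold voltage → doublet
(the voltage re-polarizes between the peaks); $k \ge 2$ peaks within one
envelope → $k$-spike burst; a burst longer than 1.5× the train's median burst
duration → long burst. The doublet/2-spike-burst distinction follows from the
hysteresis envelope, which is also why it is stable under sub-threshold noise
(tested at ±0.25 mV). A cell is *converted* when at least half of its events
are bursts (`is_converted_burster()`); doublets do not count as bursts.
`minimal_period()` reports the smallest exact repeat length of a label
sequence (requiring two full repeats in the window); fuzzy periodicity is out
of scope.

Synchrony (`synchrony_index()`) is the mean over cell pairs of the maximum
normalized cross-correlation of voltage within ±50 ms of lag. The lag window
is the package's design choice: a converted spiker phase-locks to its partner
with a short constant delay (≈ 20 ms at $g_c = 0.05$ nS) and with different
spike amplitudes, which caps the zero-lag Pearson correlation near 0.78 even
though the cells are locked one-to-one; the lagged index reports ≈ 0.97 for
that pair and stays below 0.1 for the drifting weakly coupled pair, so a 0.9
threshold cleanly separates the regimes. `max_lag_ms = 0` recovers the plain
zero-lag definition. Pairs with a constant trace are excluded with a warning.

## Fast/slow analysis: why a burster converts a spiker

The spiker ($g_{BK} = 0$) has one fast variable ($V$) and two slow ones
($n$, $c$). Its critical manifold $F(V, n, c) = 0$ (the $V$-nullcline with
$m = m_\infty(V)$) is solved for $n$, which enters linearly
(`critical_manifold_n()`). Both fold conditions ($F = 0$, $\partial F/\partial
V = 0$) depend on $n$ and $c$ only through $g_{Kdr} n + g_{SK} d_\infty(c)$,
so the fold lies along lines of constant voltage found by a scalar solve
(`fold_voltages()`); for the reference spiker the two folds sit near −55 and
−13.5 mV. The slow flow is projected to the $(V, c)$ chart by total
differentiation of the constraint and rescaled by $-\partial F/\partial V$
(`desingularized_rhs()`), making the field regular across the fold; its
equilibria on the fold are folded singularities (`find_folded_node()`, solved
by bracketed scalar root-finding plus Newton polish to residuals < $10^{-8}$;
deterministic, no randomness). The upper fold carries a stable folded node —
both eigenvalues of the desingularized Jacobian real and negative — whose
eigenvalue ratio $\mu = \lambda_w/\lambda_s$ bounds the number of secondary
canards by the sector rule $2k+1 < 1/\mu < 2k+3$
(`secondary_canard_count()`; an odd-integer $1/\mu$ is flagged as resonance).

A partner held at a depolarized voltage adds $g_c (V - V_{fix})$ to the fast
equation. This shifts the folded node — and with it the canard funnel — to
higher calcium, monotonically in $g_c$, while leaving $\mu$ (hence the canard
bound) essentially unchanged over $g_c \in [0, 0.05]$ nS. That is the
conversion mechanism: the driven spiker's trajectory, which passes on the
non-oscillatory side of the primary canard when uncoupled, lands inside the
funnel once the structure is shifted, and executes small plateau oscillations
— a pseudo-plateau burst. The package verifies this on trajectories: windows
of elevated-voltage input (taken from a reference burster's detected active
phases, clamp level = the plateau mean; `clamp_protocol_from_burster()` and
`run_with_clamped_partner()`) make the spiker emit multi-spike bursts in a
majority of windows, with per-burst small-oscillation counts within the
canard-sector bound.

Two deliberate boundaries of this module: computing the attracting/repelling
slow-manifold *surfaces* and explicit canard orbits requires boundary-value
continuation, which is out of scope — the algebraic folded-node quantities
plus trajectory diagnostics replace it. And the asymptotic sector rule counts
the canards of the $\varepsilon \to 0$ limit: for the reference spiker
$1/\mu \approx 21.5$, so the rule admits up to $k = 10$ secondary canards,
while the time-scale separation of the actual model is moderate
($\tau_V : \tau_n \approx 1 : 30$), and the bursts the trajectories actually
produce carry far fewer small oscillations (typically one, a 2-spike burst).
Geometric computations at finite $\varepsilon$ resolve only the first few
secondary canards; the eigenvalue-ratio count should therefore be read as an
upper bound, not as the number of oscillations a simulated burst will show.

## Placement sweeps and the strategy question

`sweep_placements()` distributes a fixed number of intrinsic bursters across a
fixed structural network in distinct random ways (canonical-set deduplication,
fully seeded: placement $i$ simulates with seed $\mathrm{seed} + i$, fresh
initial jitter per placement), simulates each placement (default 20 s, 10-s
analysis window), and records $\Gamma_b$, $\Gamma_s$, the network- and
time-averaged secretion $\langle s \rangle$ (`average_secretion()`), and the
number of converted spikers. `bin_average()` summarizes
$\langle s \rangle$ in ten equal-width $\Gamma_b$ bins (right-open except the
last; empty bins flagged). The package default scale — 300 placements at 50%
bursters, 200 at 25% — is a deliberate scaled-down version of the full
$10^4$/$10^3$-placement experiments; the full scale is reachable by arguments
but takes proportionally longer.

At 50% bursters the sweep reproduces the offensive advantage: Spearman
correlation between $\Gamma_b$ and $\langle s \rangle$ is clearly negative
(≈ −0.3 on the default network) — dispersed bursters contact and convert many
spikers, raising network secretion. At 25% bursters the expected reversal
(clustered bursters protecting each other and out-secreting dispersed ones) is
**density-dependent in this implementation**: on the default $p = 0.7$
networks (mean degree ≈ 2.7) conversion cascades through essentially every
placement, $\langle s \rangle$ is nearly flat in $\Gamma_b$, and the
correlation stays weakly negative; on denser networks ($p = 0.4$, mean degree
≈ 4.5) the correlation at 25% turns positive and the defensive strategy wins.
`analysis/04_strategy_sweep.R` runs both densities side by side. Because the
reference 20-cell topology behind the original strategy experiments is not
available as data, the package keeps $p = 0.7$ as the generator default and
reports the low-fraction strategy ordering as connectivity-dependent rather
than universal. For the same reason, the "more conversions → more secretion"
trend across placements carries no signal at $g_c = 0.05$ nS on the default
network: conversion is near-total in almost every placement, so the rank
correlation between converted count and $\langle s \rangle$ is dominated by
noise.

For the secretion-spread question, `matched_secretion_split()` selects the
most populous cell of a $(\Gamma_b, \Gamma_s)$ grid (default width 0.1,
minimum 15 placements — a scaled-down analogue of pooling same-homophily
networks out of thousands) and splits it at the median $\langle s \rangle$;
`gamma_s_histogram()` then pools per-spiker $\gamma_s$ values in each half.
The hypothesis is that low-secreting placements spread burster exposure less
evenly over their spikers (wider $\gamma_s$ distribution); at the package's
sweep scale the direction is reported per seed and required in two of three
seeds rather than asserted universally.

## What the synthetic conditions do and do not show

All inputs are synthetic by design: the study object is the model itself.
The generator emulates the stated experimental conditions — random-walk
topologies of 2–20 cells, burster fractions 25–50%, coupling 0.005–0.05 nS,
RK4 at 0.5 ms — and the tests verify behavior under exactly those conditions.
They do not establish anything about real pituitary tissue beyond the model's
scope: no channel noise, no cell-to-cell parameter heterogeneity beyond
$g_{BK} \in \{0, 1\}$ nS, uniform coupling strength, no spatial structure, and
a secretion readout that is a static function of calcium. Conclusions that
depend on network density (notably the low-fraction placement strategy) should
be read as regime statements, not point predictions.

## Numerical choices, degenerate inputs, limitations

- Fold/folded-node solves: grid scan + `uniroot` at tolerance $10^{-13}$ with
  Newton polish; residuals of all three defining equations are checked against
  $10^{-8}$. The search box is the physiological range $V \in [-75, 60]$ mV,
  $c \in [0, 2]$ µM; a model with no real solution there reports "no folded
  singularity" rather than erroring.
- The desingularized Jacobian uses Richardson-extrapolated central
  differences; tests compare it against plain central differences at a
  different step.
- `detect_events()` drops events cut by the window edges; an all-silent trace
  returns an empty frame, and an empty train yields an `NA` conversion flag.
- `minimal_period()` uses exact symbol matching and needs at least two full
  repeats; otherwise `NA`.
- Networks must be connected, simple and fully labelled before simulation;
  the generator asserts this, and `cell_network()` rejects self-loops,
  duplicate edges and out-of-range ids.
- The non-finite-state guard inside the integrator names the failing step, so
  blow-ups in experimental parameter regimes are diagnosable.
- RK4 at 0.5 ms is accurate for this stiffness regime (step-halving leaves
  event classifications unchanged in the tests) but is not error-controlled;
  very different parameter sets may need a smaller step.
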