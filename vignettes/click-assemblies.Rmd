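---
title: "Click assemblies: intransitive kill cycles of immune cell populations"
author: "clickassembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Click assemblies: intransitive kill cycles of immune cell populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clickassembly)
```

## The model

A *click* is a receptor–ligand pairing between two immune cell types that
triggers the contextual death of exactly one of them. Two rules constrain
how clicks wire a set of populations into an assembly: each unordered pair
of populations carries at most one click (exclusivity), and every click has
a fixed killer and victim (directionality). Under these rules any
self-sustaining assembly is a directed cycle in the kill graph, and
selective fratricide prunes larger tangles down to the smallest directed
cycle — the same intransitive ("rock–paper–scissors") logic that makes a
set of Efron dice have no globally best die.

The canonical assembly spans two lineages, each with a young and a mature
stage: naive cytotoxic T cells (`Tc`) maturing into NK-receptor-bearing
cells (`Tnk`), and type-1 helper cells (`Th`) maturing into regulatory
cells (`Tr1`). Young cells regulate the mature generation of their own
lineage and mature cells regulate the young generation of the other
lineage, giving the 4-cycle `Tc ⊣ Tnk ⊣ Th ⊣ Tr1 ⊣ Tc`. Bystander help
(cytokines, tissue factors) enters as a control parameter `h` that scales
the growth of help-sensitive populations — the helper compartment in the
canonical wiring — without touching the kill cycle.

The deterministic backend is a generalized Lotka–Volterra system on a
normalized response scale. For population $i$ with growth rate $r_i$,
death rate $d_i$, help sensitivity $\beta_i$, and maturation outflow $m_i$:

$$\frac{dP_i}{dt} = P_i\!\left[r_i(1+\beta_i h)\Bigl(1-\tfrac{\sum_j P_j}{K}\Bigr)
  - d_i - \sum_{j \dashv i}\kappa_{ji}P_j\right]
  + \sum_{l \to i} m_l P_l - m_i P_i$$

Self-limitation is shared through total abundance over the carrying
capacity $K$ (default 1), killing is mass-action along click edges with
rates $\kappa$, and maturation is a linear flow. This is the simplest
closed form that reproduces the qualitative repertoire the four-population
cycle is known for: stable coexistence, alternative stable states, and
sensitive switching. Nothing is fitted to experimental data; time units
are arbitrary.

The stochastic backend is a toroidal lattice automaton with von Neumann
neighborhoods: one sweep performs width × height random-sequential contact
updates (kill if a click connects focal and neighbor, else reproduce into
an empty neighbor), followed by an independent per-site demographic pass
(maturation, then spontaneous death). Exactly one cell changes in a kill
resolution. `map_ode_rates_to_ca()` converts ODE rates to per-sweep
probabilities as `rate × dt`, with `dt` chosen so the largest probability
is 0.5; in the well-mixed limit the automaton's expected dynamics match
the ODE with time measured in sweeps of length `dt`.

## The calibrated canonical parameterization

The shipped rate table (`inst/extdata/fig1_4click.json`) is data, not
code. It was calibrated by inverse design: a target resting composition
was chosen, the balance equations solved for the remaining rates, and
candidates screened numerically for a stable, reachable equilibrium with
the regime structure described below. Three deliberate choices shape it:

* **The resting state is Tr1-dominant coexistence.** At the default help
  level `h = 0.2` the system has a stable interior equilibrium
  (Tc 0.016, Tnk 0.027, Th 0.012, Tr1 0.857); from the shipped initial
  abundances the Tr1 response rises from 0.3 to a maximum near 0.87
  before settling. All four populations persist: Tnk polices Th, Tr1
  suppresses Tc, and the maturation flows keep the small populations
  supplied. The balance is genuinely delicate — that fragility *is* the
  biology being modeled, a resting state maintained by active mutual
  regulation rather than by wide stability margins.
* **Reducing Tnk releases the cytotoxic response.** Depleting Tnk and
  slowing its resupply (the `fig2b` preset: Tnk initial abundance 0,
  Tc maturation rate reduced to 0.0055) removes the brake on Th; Th then
  prunes Tr1, Tr1's suppression of Tc lapses, and the system converges to
  a Tc-dominant state (Tc ≈ 0.95).
* **The switch is controlled by bystander help.** Scanning `h` with
  everything else fixed: below ≈ 0.14 the helper compartment cannot
  sustain itself against Tnk and the cytotoxic state wins; in a band
  around 0.2 the Tr1-dominant resting state is reached; at very high
  help (h ≳ 0.9) unrestrained Th takes over. Near the boundary
  (`transition_help = 0.146` in the `fig2c` preset) trajectories wander
  aperiodically for thousands of time units — recurrent Th flare-ups that
  nearly, but not quite, tip the system — before committing. In this
  window the twin-trajectory Lyapunov estimate is positive while it is
  negative in both stable regimes, and the joint return-map path does not
  retrace itself, the signatures of a chaotic, initial-condition-sensitive
  transition. Both the cytotoxic and the suppressive states coexist as
  attractors at the same help level (`detect_bistability()` finds both
  basins), so which response wins is decided by context, not by the
  parameters alone.

The direction of the switch deserves a note. Help feeds Th, and the
cytotoxic response is the *low*-help (or Tnk-depleted) outcome; the causal
chain "help expands Th and ultimately Tc" plays out transiently in the
transition window, where Th flare-ups suppress Tr1 and let Tc surge, but
with help sustained the cycle closes — Tc matures into Tnk, Tnk kills Th,
Tr1 recovers — and suppression is restored. The regime map is thus:
cytotoxic state at low help, actively-maintained suppressive rest in a
mid-range band, helper overgrowth at extreme help. The last regime is
outside the shipped scan range and should be read as a model limit, not a
biological prediction.

## Diagnostics

`classify_attractor()` labels a trajectory from its time-averaged tail:
`extinct` when every tail mean is below the extinction threshold
(10⁻⁸), `non_stationary` when any non-negligible population's tail
coefficient of variation exceeds 0.1, `<id>_dominant` when the leader
exceeds the runner-up at least 2-fold, and `coexistence` otherwise. The
margin and CV threshold are fixed conventions; for the canonical assembly
the constructed labels are `Tr1_dominant` and `Tc_dominant`.

`lyapunov_estimate()` integrates twin trajectories separated by
`eps = 10⁻⁶` and fits log separation against time by least squares over
the pre-saturation window (separation below 1% of the state norm),
discarding the leading 30% of that window so the initial alignment
transient does not bias the slope. The window conventions matter at desk
scale: at a stable equilibrium the informative signal is the asymptotic
decay, at a basin boundary it is the exponential escape, and the same
rule captures both. The estimator reproduces the analytic eigenvalue −r
of a one-dimensional logistic model within 10%, and the dominant Jacobian
eigenvalue of the canonical resting equilibrium within 20%.

`return_map()` builds the "time + 1 versus time" delay plot at an
adjustable lag (default one output-grid step). Its overlap statistic is
the minimum distance between non-adjacent segments of the *joint* delay
path through all populations at once, normalized by the data range:
periodic trajectories retrace this path exactly (statistic 0), chaotic
transients never do (statistic > 0). Per-population planar statistics are
also reported, but planar projections of four-dimensional dynamics cross
transversally, so only the joint statistic discriminates.

## Numerical choices

Integration uses `deSolve::ode` (lsoda, stiff-capable) at absolute and
relative tolerances 10⁻⁹ and 10⁻⁷; halving the tolerances moves the
canonical final state by less than 10⁻⁵. Negative undershoot is clamped
to zero at output steps and the largest clamp recorded in the trajectory
metadata. A run is flagged converged when max |dP/dt| < 10⁻⁶ at the final
time; the resting approach has a slow spiral mode (dominant eigenvalue
real part ≈ −0.003), so the `fig2a` preset integrates to t = 6000.
Equilibria are refined by damped Newton iteration to residual 10⁻¹⁰ with
central-difference Jacobians (`pracma::jacobian`), and stability read off
the Jacobian spectrum. Lattice runs draw all randomness from R's seeded
generator; identical (assembly, rates, lattice, seed) reproduce runs
bit-for-bit, and the compiled sweep is cross-checked draw-for-draw
against an R reference stepper in the test suite. Dice probabilities are
exact integer counts over the 36 ordered face pairs; no floating point
enters them.

Problem sizes in the shipped presets — output grids of 2 501–3 001
points, a 200 × 200 lattice for the mean-field comparison, 200 random
graphs for the reduction cross-check, 10⁵ dice rolls — were chosen so the
full suite and the acceptance script complete in well under a minute on a
single core.

## What the synthetic conditions do and do not show

Everything here is simulation of an idealized model: well-mixed (or
nearest-neighbor) interactions, fixed rates, a single shared resource,
and abundances on a normalized 0–1 scale. Passing tests demonstrate that
the click rules generate the claimed dynamical repertoire — reduction to
the smallest cycle, bistable suppressive/cytotoxic outcomes, a
help-controlled sensitive switch, exact intransitivity — not that any
specific parameter value matches a measured immune system. Real
lymphocyte populations have structured antigen dependence, trafficking,
and cell-intrinsic programs that this model deliberately omits.

Two observed limitations are worth recording. First, the resting
equilibrium's basin of attraction is small: most random initial
conditions fall to the cytotoxic state, which is why resting-state runs
start from the calibrated initial abundances. Second, the spatial
automaton departs from the mean-field picture precisely at that fragile
resting state — local Th patches escape Tnk policing and the lattice
drifts to a four-species mosaic — while in the robust cytotoxic regime
lattice means match the ODE equilibrium to better than 0.01. The
mean-field consistency check therefore runs in the cytotoxic regime; the
divergence at the resting state is a real property of locally-interacting
click assemblies, not a numerical artifact.

## A worked example

```{r example, eval = FALSE}
a <- build_canonical_4click()
validate_assembly(a, strict = TRUE)$valid
smallest_directed_cycle(a)

cfg <- canonical_preset("fig2a")
traj <- simulate_ode(cfg$assembly, cfg$params)
classify_attractor(traj)
max(traj$abundances[, "Tr1"])

ef <- efron_dice()
verify_intransitive_cycle(ef)$intransitive
best_response(ef$A, ef)$die
```
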