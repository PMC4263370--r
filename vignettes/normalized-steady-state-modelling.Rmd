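---
title: "Normalized steady-state modelling of regulated metabolic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalized steady-state modelling of regulated metabolic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nssnet)
```

## The modelling idea

Large multi-tissue metabolic models fail classically at parameter
estimation: there are hundreds of enzymes and almost no trustworthy in-vivo
kinetic constants. `nssnet` instead *defines* the model at a reference
steady state in which every concentration is 1 by construction, and derives
all rate constants from a small set of interpretable, independent
parameters. The price is that predictions are relative (fold-changes), and
semi-quantitative rather than precise; the gain is that a network with
hundreds of states needs no fitted constants at all.

### Reaction mechanism

Each enzymatic reaction is the reversible two-step mechanism

$$S + E \;\underset{k_{CR}}{\overset{k_C}{\rightleftharpoons}}\; C
  \;\underset{k_{PR}}{\overset{k_P}{\rightleftharpoons}}\; E + P$$

with substrate influx, product demand, and constant-enzyme turnover
($\varphi_{EI} = k_{dE}$ at baseline). In normalized coordinates
($S_N = E_N = P_N = 1$, $C_N = w$, where $w$ is the bound/free enzyme
ratio), requiring (i) net flux $\Phi$ through both elementary steps and
(ii) reverse/forward flux ratio $r$ on each step yields uniquely

$$k_C = \frac{\Phi}{1-r},\qquad
  k_{CR} = \frac{r\,\Phi}{(1-r)\,w},\qquad
  k_P = \frac{\Phi}{(1-r)\,w},\qquad
  k_{PR} = \frac{r\,\Phi}{1-r}.$$

`derive_rate_constants()` implements exactly this. The reaction throughput
$\Phi$ is not free: it is the branch fraction $f$ times the parent
metabolite's total steady-state efflux, so the whole network's constants
follow from sources $\varphi$, fractions $f$, reversibilities $r$ and
ratios $w$ by solving one linear flux-balance system (`build_network()`).
The assembled derivative of any valid network therefore vanishes *exactly*
(to floating-point) at the initialized state — the core correctness oracle,
tested on every fixture and on hundreds of randomly generated networks.

For a single reaction fed by fraction $f$ of a unit source, with influx
fold $u$ and product-demand fold $d$, the new steady state has the closed
form (with $A = 1 - r^2 + r^2/d$, $J = uf/(f + (1-f)A)$):

$$S^\* = \frac{uA}{f+(1-f)A},\quad E^\* = 1,\quad
  C^\* = w\frac{J}{f}\Bigl((1-r)+\frac{r}{d}\Bigr),\quad
  P^\* = \frac{J}{fd},\quad f^\* = \frac{f}{f+(1-f)A}.$$

Note the squared $r$: reversibility enters the relative concentrations only
at second order, while $f$ enters at first order — which is why the flux
distribution, not reversibility, dominates model behaviour. The relations
contain no absolute flux scale. `predict_single_reaction_steady_state()`
is the package's independent oracle: the test suite checks the numerically
integrated network against it to $10^{-6}$ relative, and checks the closed
form itself against a separately hand-written mechanistic ODE.

### Flux bookkeeping conventions

* A reaction's throughput is pinned to its **first-listed substrate**;
  draws on further substrates are debited against those metabolites'
  balances. A definition whose secondary draws exceed a metabolite's influx
  is rejected at build time ("overdrawn").
* Branch fractions split the parent's efflux *remaining after secondary
  draws* and must sum to 1; a reserved `sink` child models export/terminal
  demand. Metabolites without consumers get an automatic first-order sink,
  closing the network.
* Carrier-free transport steps are first-order in the source metabolite
  with rate chosen so the baseline flux matches the branch fraction;
  enzymatic transport just uses the ordinary mechanism with a carrier
  enzyme.
* Multi-substrate reactions multiply the normalized substrate
  concentrations in the binding term. Every factor is 1 at baseline, so
  parameter initialization is unchanged.

### Regulation layer

Transcription, translation and post-translational switching are normalized
the same way — with every driver at 1, each regulatory node contributes
zero net rate, so adding regulation never disturbs the baseline.

* **Negative control**: production $= k_d\,Q_{max}/(1 + (Q_{max}-1)Q_C^h)$
  — a decreasing sigmoid from $Q_{max}$ (no repressor) to 0.
* **Positive control**: a clamped Hill sigmoid with a basal floor that
  passes 1 at $Q_C = 1$ and reaches $Q_{max}$ *exactly* at the saturating
  regulator level $\hat{Q}_C$ (constant beyond). Feasibility requires
  $(1-b)/(Q_{max}-b) > \hat{Q}_C^{-h}$; infeasible combinations are
  rejected ("no dynamic range") rather than silently distorted.
* **Translation** is linear: $k_t Q_{mRNA} - k_d Q_P$.
* **Switches** (insulin, glucagon, PPARα) keep an active and an inactive
  pool with mass transferred at $k_a Q_M Q_{CI}$ and back at
  $k_i Q_M' Q_{CA}$, plus synthesis/degradation. Baseline neutrality forces
  $k_i = k_a - k_d$ and total pool 2, so the active pool's dose–response is
  $Q_{CA} = 2q/(1+q)$ for an activating driver $q$ — bounded in $(0, 2)$.
  $k_a$ sets response speed only. Positive transcription edges driven by
  switch pools must therefore use $\hat{Q}_C \le 2$ and a steeper Hill
  coefficient (a Hill curve of slope $h$ can span at most a $2^h$-fold rise
  over $q \in [1, 2]$).
* Factors from several regulators of one gene multiply (each is 1 at
  baseline), capped at the largest $Q_{max}$ so mRNA stays in
  $[0, Q_{max}]$.

Defaults: $w = 1$ (affects transients only), enzyme turnover
$k_{dE} = 0.01$ per time unit, mRNA/protein degradation $0.01$,
$Q_{max} = 10$, $\hat{Q}_C = 10$, $h = 2$, basal floor $0.05$ — all
overridable per entity in the model-definition format. Magnitudes of the
turnover constants set how fast expression responds relative to metabolism;
they do not move any steady state.

## Simulation and steady-state detection

The assembled system is stiff (metabolite dynamics vs. slow gene
expression), so trajectories use `deSolve::lsoda` at relative tolerance
$10^{-9}$. Perturbations (influx folds, degradation folds, knockouts
— degradation × 1000 —, constant activation of a switch pool, demand folds)
are piecewise-constant multipliers; integration restarts at each start time
so discontinuities are handled exactly. A steady state is accepted when the
derivative max-norm falls below $\varepsilon_{ss} = 10^{-7}$ *and* the
maximum relative state change over the trailing 10% of elapsed time is
below $\varepsilon_{ss}$; divergence (any state beyond $10^6$), negativity
(below $-10^{-9}$) and solver failure are returned as flagged
non-convergence results, never raised — the tolerance analysis consumes
them. Default horizon $10^6$ time units; the test and acceptance runs use
$10^5$–$3\times10^5$, which the fixtures' slowest modes (turnover 0.01 per
time unit, i.e. relaxation times of order $10^2$–$10^3$) settle well
within.

## Sensitivity analysis

`set_branch_fraction()` perturbs one branch child's fraction with
proportional sibling renormalization (the unique rule symmetric in the
siblings) and re-derives **only that branch's** rate constants, holding
every other parameter at its initialized value. This matters: rebuilding
the whole network would re-normalize downstream demand and erase the
disturbance. The control coefficient then compares the converged steady
states of the reference and modified networks under the same background
(e.g. a high-calorie diet), using the *realized* post-perturbation fraction
$f^\*$ in the denominator (falling back to the imposed fraction when the
two coincide to machine precision, flagged in the record). Scans default to
the standard ±10% interval; one-sided forward differences, with δ-halving
consistency checked in the tests. Classification uses absolute values:
high $>1$, moderate $0.1$–$0.99$, low $<0.1$; the printed-bound gap
$(0.99, 1]$ classifies as high, the conservative screening call.
`tolerance_range()` walks a fraction grid and reports the maximal
contiguous stable interval around the baseline with the instability mode at
each boundary; an `infeasible` mode marks fractions the flux balance cannot
realize at all (e.g. overdrawing a co-substrate).

## Fixtures: what they emulate and what they don't

`make_toy_networks()` provides analytic anchors: a linear chain (exact
closed-form scaling), a two-branch split (control coefficients $1$ and
$-f_1/(1-f_1)$ exactly), a negative-feedback loop (sub-linear response) and
a capacity-limited branch whose co-substrate supply caps the carried flux —
raising the fraction or the influx past the cap makes the intermediate grow
without bound, reproducing the low-tolerance phenomenology.

`make_mini_steatonet()` is a ~110-state reduced liver–adipose–blood network
(glycolysis, glycogen, gluconeogenesis, lipogenesis ACC1→FAS→SCD1→GPAT,
β-oxidation, ketogenesis, cholesterol/lipoprotein cycling, adipose
storage/lipolysis; insulin, glucagon and PPARα switches; SREBP-1c,
adiponectin, TNFα). Design choices worth stating:

* Dietary and serum fatty acids enter the hepatic **saturated** pool and
  must pass the SCD1 desaturation step before esterification by GPAT, so an
  SCD1 knockout starves triglyceride synthesis on any diet — the mechanism
  behind its protective phenotype.
* PPARα is driven by the saturated FA pool and induces CPT1 (β-oxidation),
  ATGL (hepatic lipolysis) and CYP7A1 (cholesterol catabolism); glucagon
  additionally induces CPT1, HMGCS (ketogenesis), HSL and PEPCK; insulin
  induces SREBP-1c and the FA-uptake transporters and represses the
  catabolic genes; adiponectin induces adipose β-oxidation and ceramidase
  and represses SREBP-1c and TNFα. Edge strengths ($Q_{max}$, floors) were
  chosen, iteratively against the qualitative physiology the scenarios
  encode, exactly as one builds such regulatory layers in practice —
  structure first, then adjust until known biology is reproduced.
* HDL is fed by a constant source loop independent of the perturbed
  pathways, so interventions that should leave HDL unchanged do so by
  structure.
* Knockout expectations are judged against a **diet-matched control run**
  (the wild-type protocol without the knockout), the comparison the
  underlying experiments actually make; diet and hormone responses are
  judged against the initial baseline, and phase-switch expectations
  against the previous phase's steady state.

What passing the validation matrix does *not* show: quantitative transient
shapes (they depend on $w$ and turnover magnitudes, deliberately
unconstrained), absolute concentrations (normalized away), and any row
whose variables the reduced network lacks (urea cycle — reported as
uncovered). The random-network generator exercises the parameterization
(fixed point, invariances) but draws tree-like topologies only; cycles are
covered by the curated fixtures.

## Numerical choices and degenerate inputs

* Fractions must lie in $(0, 1]$ and sum to 1 within $10^{-12}$; the
  residual is reported on violation.
* Flux balance is solved exactly (`solve()`); non-positive throughputs,
  singular systems and overdrawn metabolites are build errors naming the
  entity. Zero-flux isolated metabolites are warnings.
* State clamping at 0 inside the rate evaluation protects against tiny
  negative excursions of the stiff solver; genuine negativity beyond
  $-10^{-9}$ flags the run.
* Perturbation composition is multiplicative (fold-change semantics);
  `constant_activation` holds a state at a target level via a fast
  first-order relaxation (rate 1 per time unit, ~100× faster than the
  regulation layer).
* Direction verdicts use a 5% margin on fold-changes: outside
  $[0.95, 1.05]$ counts as changed.

## Limitations

Single-compartment kinetics per species (no spatial gradients); no
stochasticity or delays; the Modelica importer covers only the
systems-biology object classes and `connect` wiring (declarations outside
that subset are reported, not executed); reported coefficients are local
sensitivities at the investigated steady state, not global measures.
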