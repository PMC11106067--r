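---
title: "Epoch-stratified range evolution: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epoch-stratified range evolution: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleorange)
```

This vignette is the package's own account of the science it implements:
the model, every tunable that matters, the conventions adopted where the
underlying methods literature leaves choices open, and what the synthetic
validation does and does not establish about real data.

## The anagenetic process

A range is a non-empty subset of a small, fixed set of biogeographic
areas (six in the canonical configuration: WNA, ENA, JP, EU, EA, CA),
encoded internally as a bitmask.  Along a branch the range evolves as a
continuous-time Markov chain on the `1 + Σ_k C(n, k)` states of
`state_space()`:

* **gain** of area `b ∉ R` at rate `d · Σ_{a∈R} m[a, b]`, where `m` is the
  dispersal-multiplier matrix of the current epoch,
* **loss** of any occupied area at rate `e`,
* the empty range is absorbing: a lineage that loses its last area is
  dead and can never be observed at a tip.

Both model families share this process; they differ only at cladogenesis.
`d` and `e` have units events/Ma; with all multipliers 1 the expected
number of gains on a branch of length `t` from a single-area range with
one available neighbour is `d·t` (this is tested directly against
`1 − exp(−d·t)` by simulation).

**Epochs.** Connectivity history enters as piecewise-constant multiplier
matrices over age slices (`epoch_schedule()`).  Ages increase into the
past; boundaries are given oldest-first; an age exactly on a boundary
belongs to the *older* epoch.  Branch transition probabilities cut the
branch at every boundary it crosses and compose the per-segment matrix
exponentials old-to-young.  `fraxinus_epochs()` encodes the canonical
three-slice schedule: all pairs open before 30 Ma; EU–WNA reduced to 0.5
between 30 and 5 Ma; ENA–EU at 0.25 and WNA–EA at 0.5 after 5 Ma.  Pairs
not named in a slice stay at 1, and the bundled YAML configuration spells
out every pair explicitly — the config loader refuses a slice with a
missing pair rather than defaulting silently.

## Cladogenesis

At each node the parental range `R` is inherited as an ordered daughter
pair drawn from `cladogenesis_distribution()`:

* **DEC**, `|R| = 1`: both daughters copy `R`.
* **DEC**, `|R| ≥ 2`: for every single area `a ⊂ R`, one subset-sympatry
  outcome `(R, {a})` and one vicariance outcome `({a}, R∖{a})`, each with
  unit weight.  Vicariance is restricted to single-area splits (wide
  splits excluded).
* **BAYAREALIKE**: both daughters copy `R`, whatever its size.
* **+J**: additionally, for every area `b ∉ R` whose incoming multiplier
  from some occupied area is positive *in the node's epoch*, a founder
  outcome `(R, {b})` with weight `j`.  Weights are normalised per parent
  state, so `j` is a relative weight on a per-outcome basis, bounded
  `[0, 100]` in the optimiser; `j = 0` reproduces the base family to the
  last bit (identical code path, not merely a numerical limit).

Two conventions deserve emphasis.  First, the enumeration above pairs each
subset-sympatry scenario with one vicariance scenario per contained area,
so a two-area parent has four outcomes at probability 1/4 — vicariance
carries more weight than under the historical six-outcome enumeration
(1/6 each).  This is the package's fixed convention; it is applied
identically in the likelihood, the reconstruction and the simulator, so
all internal consistency checks are exact.  Second, daughter order is
*symmetrised*: every ordered outcome is averaged over the two child
assignments during pruning (and sampled with a fair coin in the
simulator), so likelihoods and reconstructions cannot depend on which
child a Newick file happens to list first.

**Root prior.** Uniform over all non-empty states within the range-size
cap (the empty range is excluded).  It is configurable; conditioning the
root on any particular range is a one-line change via `root_prior`.

**Range-size cap.** `max_range_size` defaults to the number of areas (no
restriction), since wide ancestral ranges are a legitimate outcome; a cap
shrinks the state space quadratically and is worth setting for analyses
with many areas.

## Likelihood, fitting, model choice

Tip conditional likelihoods are indicators at the observed ranges, placed
at the tips' own ages, so fossil tips enter exactly like extant ones.
Pruning proceeds post-order with per-node rescaling (log-scale
accumulation) to avoid underflow on large trees.  Matrix exponentials use
a per-epoch eigendecomposition when it reconstructs `Q` to `1e-9`
(the generic case), with `Matrix::expm` (scaling-and-squaring) as the
fallback for ill-conditioned decompositions; propagation of a conditional
vector then costs `O(S²)` per branch segment.  All state spaces here are
dense and small (≤ 64 states for six areas); no sparsity machinery is
warranted.

`fit_biogeo()` maximises the likelihood over `log d`, `log e` (and
`log j`) with L-BFGS-B, bounds `d, e ∈ [1e-9, 10]` events/Ma, from
`n_starts` start points: one fixed heuristic start at `(0.01, 0.01)` and
the rest drawn uniformly on the log scale from a generator seeded by
`seed`, so every fit is exactly reproducible.  Non-convergence of every
start is flagged on the returned object, never silently ignored.  Models
are ranked by AICc with `n` = number of tips; exact ties go to the model
with fewer parameters.  `compare_models()` refuses to rank fits whose
data fingerprints differ.

## Ancestral ranges and event extraction

`ancestral_ranges()` computes, for every node, `P(state | all data)` by
the standard inside–outside construction, reusing the same branch
propagators and symmetrised cladogenetic tables as the likelihood; corner
marginals (the daughter lineage's state immediately after its parent's
cladogenesis) fall out of the same pass.  MAP states break exact ties
toward the smallest state index, i.e. fewest areas then lexically first
bitmask — deterministic by construction.

`extract_events()` reads events off the MAP (or, for simulated histories,
the true) node and corner states:

* corners disjoint and uniting to the parent → one **vicariance** at the
  node age;
* a corner outside the parent (necessarily a single area) → one founder
  **dispersal** at the node age;
* per branch, each area gained between corner and child node → one
  **dispersal**, each area lost → one **extinction**, all at the branch
  *midpoint* age, gains applied before losses in area order with the
  source range growing as gains apply.

The midpoint rule is a deliberate, deterministic stand-in for the unknown
true timing of an anagenetic change; a stochastic-mapping draw would be
the natural extension point but is not the default because every
downstream number should be reproducible from the MAP reconstruction
alone.  Consequently the extracted list is a *lower bound* on the true
history: two changes on one branch that cancel (gain then loss of the same
area) are invisible to any net-change reader.  The extraction-consistency
experiment in the test suite therefore runs in a low-rate regime
(expected changes per branch ≪ 1) where the net reading and the true log
coincide; this validates the extraction semantics, not the behaviour
under saturation.

Event scopes come from the area-pair table: dispersal is `adjacent` iff
at least one source area is adjacent to the gained area (so an event is
counted once, by its nearest corridor), vicariance is `intercontinental`
iff any cross-partition pair is intercontinental.  The six-region
adjacency default (WNA–ENA, EA–JP, EA–CA, JP–CA, EU–CA adjacent, the rest
intercontinental) reflects within-landmass contact; EU–CA and JP–CA are
judgment calls and deliberately sit in configuration, not code.

## The climate statistic

`fit_temperature()` is loess with degree 1 and tricube weights — a local
linear smoother reproduces a globally linear series exactly, which is the
anchor test.  The span default 0.25 is a smoothing choice, exposed in
configuration; evaluation outside the data range is refused rather than
extrapolated.  `slope_at()` is a central finite difference with half-step
`delta` (default 0.1 Ma; one-sided at the range ends), signed so that
*positive means warming toward the present*; intensity is its absolute
value.  `event_density()` is a Gaussian KDE over event ages, reflected at
age 0 so no mass leaks into the future, and scaled to integrate to the
event count — an events-per-Ma intensity whose integral is checked to
within 2% in the tests.  Bandwidth (default 1 Ma in code, 1.5 Ma in the
bundled config) trades resolution against stability and is pure
configuration.  `correlate_events_climate()` regresses density on
intensity by OLS with each event as one degree of freedom, per event
type; fewer than 3 events yields an `insufficient` flag and a
zero-variance predictor a `degenerate` flag instead of a division by
zero.  Warm/cold period boundaries are *user configuration* read off the
curve, never inferred — changepoint detection is explicitly out of scope.

## The synthetic-data generator

`simulate_chronogram()` wraps `ape::rphylo` (birth–death conditioned on
the number of extant tips); extinct lineages are retained as fossil tips
with probability `1 − exp(−ψ·L)` for terminal branch length `L` — a
Poisson fossil-recovery model applied to the terminal branch.
`simulate_history()` is an exact Gillespie simulation of the anagenetic
process (waiting times redrawn at epoch boundaries, which is exact for
piecewise-constant rates) with cladogenetic outcomes drawn from the same
distribution the likelihood uses, and every jump, vicariance and founder
event logged with its exact time, source and scope.  Copy and
subset-sympatry outcomes are not events; they are recorded through the
corner states, and `replay_history()` verifies that corners plus logged
events reproduce every tip range exactly.  Dead lineages stay in the tree
as unobservable null ranges; `prune_dead_tips()` removes them before
fitting, mirroring the fact that real datasets contain no extinct,
unsampled lineages.

What the generator does *not* emulate: diversification–range feedback
(extinction of the range process does not remove the lineage from the
tree, and speciation is range-independent); spatial autocorrelation or
dating error in the temperature series (noise is iid Gaussian around a
piecewise-linear trend, where real deep-sea compilations have serially
correlated, heteroscedastic errors); and incomplete or biased geographic
sampling of tips.  Green synthetic tests therefore certify the
*computational* chain — likelihood, reconstruction, extraction,
statistics — under the model's own assumptions, not the adequacy of those
assumptions for any particular clade.

## Validation design and problem sizes

The test suite validates the likelihood against exhaustive enumeration
over all internal-state and cladogenetic-outcome assignments (50 random
instances of up to 4 tips, 3 areas, 3 epochs, tolerance 1e-8), marginals
against brute-force posteriors, epoch-stratified propagation against a
1000-slice piecewise product, and runs designed power experiments:
parameter recovery on 20 replicate 150-tip pure-birth trees
(`d = 0.02`, `e = 0.01`), founder-event model selection on 10+10
40-tip fixtures, extraction consistency on 100 12-tip histories, a
closed-corridor conservation check on 1000 histories, a climate-power
experiment with 40 events per replicate over 100 replicates, and a
10,000-branch gain-law check.  These sizes were chosen to give each
experiment clear statistical resolution while keeping the whole suite
comfortably runnable on a laptop.

## Known limitations

* **Extinction-rate estimation.** On extant-dominated data the maximum
  likelihood estimate of `e` is strongly biased toward zero, and in our
  recovery experiments it typically sits at the lower bound even when the
  generating `e` is substantial.  Two mechanisms compound: lineages whose
  range dies are unobservable, so surviving data under-represent loss;
  and singleton tip ranges — the common case, since every DEC
  cladogenesis produces a singleton daughter — are explained free of
  charge by cladogenetic resets, leaving losses with almost no likelihood
  signal.  Profiling the likelihood in `e` at the true `d` shows it
  monotonically decreasing from the boundary in replicate after
  replicate: this is a property of the estimator on such data, consistent
  with long-standing reports for this model family, not an optimiser
  artefact.  Treat fitted `e` as qualitative; `d` (and `j`) recover well.
* **BAYAREALIKE is a likelihood analogue.** The family implemented here
  keeps the copy-only cladogenesis that defines BAYAREALIKE but uses the
  same gain/loss generator as DEC for anagenesis inside a maximum
  likelihood framework; it is not the original Bayesian implementation,
  and numbers should not be expected to match one.
* **Event lists are reinterpretations.** Published event counts from GUI
  pipelines depend on extraction conventions those tools do not document.
  The rules here are deterministic and fully specified above; they will
  not numerically reproduce another tool's counts, by design.
* **The climate regression is descriptive.** Density and intensity are
  both smooth functions evaluated at the same time points; the OLS slope
  quantifies association under "each event is one degree of freedom" and
  inherits that assumption's optimism.  The package reports the CI and p
  value of that stated model, nothing stronger.
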