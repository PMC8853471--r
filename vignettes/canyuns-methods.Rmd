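---
title: "Evidence-weighted reconstruction with canyuns: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence-weighted reconstruction with canyuns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canyuns)
```

## The reconstruction problem

A genome-scale metabolic network reconstruction (GENRE) is a set of
stoichiometrically balanced reactions believed to be catalyzed by an
organism. Automated reconstruction pipelines usually proceed in two
passes: annotate the genome against a reference sequence-to-reaction
dataset, keep reactions above an alignment-score threshold, then gapfill
whatever else is needed to reproduce observed growth phenotypes. The
hard threshold discards information (a bitscore of 480 and a bitscore of
5 are both "below 500"), and gapfilled reactions lose their connection
to the evidence that justified them.

`canyuns` takes a different route. It starts from a curated *universal*
biochemical network and treats reconstruction as contextualization:
every reaction keeps a continuous weight derived from its alignment
evidence, and each experimentally growth-positive condition is simulated
separately on the full universal network. The reactions that carry flux
in those per-condition solutions — tracked per direction — accumulate
into *certainty values* (CVs) that decide inclusion in the final model.
The three data inputs (universal network, reaction bitscores, binary
growth phenotypes) are integrated simultaneously rather than
sequentially, and every included reaction carries a quantitative record
of why it is there.

## From bitscores to weights

Gene-level alignment bitscores are aggregated to reaction bitscores
(`reaction_bitscores()`): per reference sequence the best query hit is
kept, and a reaction's score aggregates over its reference sequences.
The default aggregation is the **maximum** of best hits. The upstream
method that popularized sequence-to-reaction scoring normalizes scores;
we deliberately do not, and the exact gene-to-reaction rule (including
any subunit structure) is not restated in the source material for this
method, so the maximum was chosen as the conservative, order-preserving
rule; `aggregate = "mean"` is available as the alternative.

The step-wise linear transform (`weight_transform()`) maps bitscores to
weights in $[-1, 1]$:

$$
w(b) \;=\;
\begin{cases}
b/b_0 - 1 & 0 \le b \le b_0\\[2pt]
(b - b_0)/(b_{\mathrm{sat}} - b_0) & b_0 \le b \le b_{\mathrm{sat}}\\[2pt]
1 & b \ge b_{\mathrm{sat}}
\end{cases}
$$

with $b_0 = 500$ (the functional-annotation threshold; accuracy is
insensitive to choices in 200–500) and $b_{\mathrm{sat}} = 1000$ by
default. Three anchors are normative: $w(0) = -1$ (no evidence),
$w(b_0) = 0$, and saturation at $w = 1$ for high-bitscore reactions.
The saturation knot is not printed anywhere authoritative; 1000 is this
package's default, chosen so that the sub- and supra-threshold segments
have equal slope-scale (each spans one unit of weight over 500 bitscore
units), and it is a visible, configurable parameter of
`weight_config()`. Reactions absent from the evidence table — including
every exchange and biomass pseudo-reaction, which have no gene — default
to $w = -1$.

```{r transform}
weight_transform(c(0, 250, 500, 750, 1000, 2500))
```

## Data-guided FBA

All linear programs operate on the *split network*
(`split_reversible()`): each reversible reaction becomes two opposing
irreversible components, so every flux variable is non-negative and the
net flux of a base reaction is forward minus reverse. dgFBA is the LP

$$
\max_v \; \sum_r w_r v_r
\quad \text{s.t.} \quad
S v = 0,\; 0 \le v \le \mathrm{ub},\; v_{\mathrm{biomass}} \ge v_{\min},
$$

where both components of a reversible reaction inherit the base
reaction's weight. Reactions with substantial evidence are maximized,
reactions with little or none are minimized, each in proportion to the
weight; with all weights at $-1$ the objective is exactly minus the
total flux and the program reduces to parsimonious FBA, which is how the
pFBA comparison mode (`evidence = NULL`) is implemented. The problem is
a plain LP, not a MILP.

Choices the formulation leaves open, and what this package does:

* **Biomass requirement.** Flux through biomass is required during
  training, but no value is stated. We use a lower bound
  `biomass_min = 0.1`, aligning the training constraint with the
  growth-call threshold ("growth" means FBA biomass flux strictly
  greater than 0.1). A lower bound, not an equality: evidence
  maximization may push growth higher.
* **Bound-capped pumping.** A reversible reaction with positive weight
  improves the objective by running both components simultaneously up to
  their caps (default 1000). This is expected: net flux is zero, so the
  net-flux rule keeps such pairs out of the flux-carrying set, and
  `loop_report()` lists them for inspection. Bounds are always finite,
  so the objective is never unbounded; networks should nevertheless be
  cleared of free-mass defects first (below), since a mass-generating
  loop with positive weights inflates flux-carrying sets.
* **Degeneracy.** Alternate optima make the flux-carrying set
  solver-dependent in principle. The built-in simplex uses Bland's rule,
  so the returned vertex is a deterministic function of the input; an
  optional canonicalization pass (`canonical = TRUE` in `dgfba()`)
  re-minimizes total unweighted flux at the pinned optimal objective. It
  is off by default, matching the single-solve training description.
* **Activity tolerance.** A reaction "carries flux" when its net flux
  exceeds `eps = 1e-6` in magnitude — comfortably above simplex
  arithmetic noise at these problem sizes and far below any meaningful
  flux (uptake caps are 10, bounds 1000).

### The LP solver

No functional linear-programming package is available in this
environment, so the package ships a dense two-phase bounded-variable
primal simplex (`solve_lp()`). Bland's rule makes it cycle-free and
fully deterministic. This is practical because every program in scope is
small (tens to a few hundred variables); the implementation is validated
in the test suite against brute-force vertex enumeration on tiny
programs and against an independent LP implementation (scipy's HiGHS,
through the system `python`) at working sizes.

## Media, growth calls and conventions

Exchange reactions are written `1 metabolite <-> nothing` with negative
flux meaning uptake; after splitting, the uptake direction is the
reverse component. A media condition lists maximum uptake magnitudes
per exchange; `apply_media()` closes the uptake component of every
unlisted exchange and never touches secretion or internal bounds —
only what may *enter* the system is constrained. Uptake magnitudes for
minimal-media simulations are not stated anywhere authoritative; the
synthetic scenarios default to 10 mmol/gDW/h, the community convention
for a limiting carbon source, and the value is configurable and logged.
Default reaction bounds are $0$ and $\pm 1000$.

A condition *grows* when FBA biomass flux exceeds 0.1 strictly; a flux
of exactly 0.1 is a no-growth call. Observed `inconclusive` phenotype
calls are mapped conservatively to `no_growth` on read.

## Free-mass curation

Before training, the universal network is screened for thermodynamically
infeasible mass creation (`free_mass_scan()`): close every exchange in
both directions ($0 \le v_{ex} \le 0$), add a sink (metabolite →
nothing, bounds $[0, 1000]$) for every non-extracellular metabolite, and
maximize the summed sink flux subject to $S v = 0$. Any strictly
positive optimum certifies mass generation — a single imbalanced
reaction or an amplifying cycle — and the reactions carrying flux in the
optimal solution are reported as culprits. This is strictly stronger
than per-reaction formula balancing (`mass_balance_check()`): it needs
no formula annotations and it catches multi-reaction loops whose members
are individually uncheckable. The objective value is unique; the culprit
support is one deterministic optimal solution among possibly many.
Curation is report-then-remove: the scan never deletes anything itself
(`remove_reactions()` is the explicit user action), mirroring the manual
curation workflow the method is built around.

## Certainty values and model assembly

For each experimentally growth-positive condition, the flux-carrying
reactions (FCRs) of the dgFBA solution are recorded with the direction
of their net flux. The certainty value of reaction $r$ in direction $d$
is

$$\mathrm{CV}(r, d) = \frac{\#\{\text{training growth conditions where } r \text{ carries net flux in } d\}}{\#\{\text{training growth conditions}\}}.$$

Because one solution assigns a reaction at most one net direction,
$\mathrm{CV}_{\mathrm{fwd}} + \mathrm{CV}_{\mathrm{rev}} \le 1$ always —
a structural guarantee the test suite asserts across every synthetic
run. Two denominator readings are possible (all phenotyped conditions,
or growth-positive ones only); this package divides by the number of
experimentally growth-positive conditions used for training, since only
those are simulated, and conditions whose dgFBA solve is infeasible
still count in the denominator while contributing no FCRs.

`assemble_model()` keeps exactly the reactions with CV $> 0$, restricted
to their certain directions: one-sided CVs make a reversible reaction
irreversible; CVs in both directions keep it reversible. Reactions with
genetic evidence but CV $= 0$ are excluded — evidence alone never adds a
reaction. Exchange reactions and the biomass pseudo-reaction are
structural necessities retained regardless of CV (their "CVs" would
anyway be artifacts of the media design, not of biology).

## Evaluation, conditional essentiality and pruning

Training accuracy is the standard confusion matrix of FBA growth calls
against observed phenotypes, with the Matthews correlation coefficient
(MCC); when any marginal of the confusion matrix is zero the MCC is
reported as 0 and flagged degenerate, the common convention.

To steer remaining error, `conditional_essentiality()` screens every
predicted-growth condition (true and false positives alike): a reaction
is conditionally essential where closing it drops the biomass optimum to
at or below the threshold. Exchanges and biomass are excluded from the
screen — removing the condition's carbon exchange would trivially "fix"
every false positive. `net_benefit_ranking()` then scores each
candidate as (false positives corrected) − (true positives lost), ties
broken toward the least annotation evidence, and `prune_model()` applies
a chosen removal. Pruning is deliberately interactive-by-default — the
ranking is a report, like the free-mass scan — with `--auto-prune N` in
the command-line interface for unattended greedy removal of the top
positive-net-benefit records.

## Rarefaction and discovery metrics

`rarefaction()` measures how the cumulative unique-FCR count grows with
the number of training conditions: for each subset size $k$ it draws
`n_samples` (default 10000) independent subsets of $k$ distinct
conditions and records min/mean/max of the union size. The sampling
scheme beyond the sample count is unstated upstream; independent
equal-probability subsets per $k$ is this package's choice, seeded and
reproducible.

`discovery_metrics()` compares a model against a trusted reference
reconstruction, partitioning internal reactions by (evidence ≥ 500?, in
reference?) into confirmed / true discovered / likely additions / false
discovered. Discovery accuracy — among reactions included *without*
sufficient evidence, the fraction vindicated by the reference — is the
method's headline validation and is reported as `NA` when no such
reactions exist. A CV-stratified overlap table supports the companion
claim that inclusion accuracy rises with CV.

## The synthetic scenario generator

Desk-scale validation needs ground truth, so `generate_scenario()`
builds miniature worlds with a known organism inside a larger universal
network:

* **Topology.** `n_pathways` linear catabolic routes (default 3), each
  from its own extracellular source through a transporter and
  `pathway_length` conversions (default 3) into a shared biomass
  precursor; decoy shortcuts and dead ends (default 3); `n_orphans`
  sources (default 2) whose transporter and precursor feeder exist only
  in the universal network. The planted truth is pathways + exchanges +
  biomass. Defaults stay at or under 60 reactions and 12 conditions so
  exhaustive oracles (vertex enumeration, single-knockout screens)
  remain sub-second.
* **Chemistry.** Every metabolite has the pseudo-formula `X`, making
  all internal reactions balanced by construction; an un-injected
  network always scans free-mass clean, and `inject_mass_loop()` plants
  either an imbalanced reaction or an amplifying two-reaction cycle for
  curation tests.
* **Evidence.** Truth reactions draw bitscores from a high class
  (normal around 750, truncated above 500), decoys from a low class
  (around 250, truncated below 500); with probability `noise_fraction` a
  reaction draws from the other class. Noise 0.2 reproduces, in
  miniature, the discovered/false-discovered structure of real
  annotation data.
* **Phenotypes.** Binary calls are FBA on the planted truth at the 0.1
  threshold: single-source conditions per pathway (growth) and orphan
  (no growth), then pathway+orphan pairs. The pairs are what make the
  generator interesting: with noisy evidence, a high-scoring orphan
  feeder can carry flux in a pair condition, enter the model, and turn
  the orphan-only condition into a false positive — the exact error mode
  net-benefit pruning exists to correct.

What the generator does *not* emulate: realistic network breadth
(thousands of reactions, multiple compartments beyond two), cofactor
coupling and realistic stoichiometric ratios, genuine biomass
compositions, or noisy growth-curve thresholds. Passing tests
demonstrate the algorithmic machinery — LP correctness, bookkeeping,
the CV calculus, pruning logic — not organism-scale predictive accuracy,
which requires the real universal network, alignment data and phenotype
panels.

## Problem sizes and determinism

The shipped test and acceptance workloads use scenarios of roughly 25
reactions and 8 conditions (50 seeds for the stochastic suites, 100 for
the free-mass screen), sizes at which every result can be re-derived by
an independent oracle. All randomness flows through explicit seeds:
generators snapshot and restore the global RNG state, the simplex has no
random component, and repeated command-line runs are byte-identical.

## Known limitations

* The flux distributions of dgFBA solutions are selection devices, not
  biological flux predictions; only the binary carries-flux signal is
  used downstream.
* A model assembled from CV $> 0$ reactions is contextualized to its
  training conditions; it is not designed to extrapolate to unseen
  media, and honest evaluation of that ability needs held-out
  phenotypes.
* The sub-threshold weight segment treats "no evidence" and "strong
  evidence against" identically ($w = -1$); distinguishing them would
  need alignment coverage information the bitscore alone does not carry.
* The dense simplex is adequate for desk-scale networks; an
  organism-scale universal network (thousands of reactions) would want a
  sparse LP backend behind the same `solve_lp()` contract.
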