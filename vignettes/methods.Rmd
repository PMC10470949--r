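---
title: "Methods: sex-biased subsystem scoring and context-specific flux models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-biased subsystem scoring and context-specific flux models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepaflux)
```

`hepaflux` asks two related questions of a tissue transcriptome in the
context of a genome-scale metabolic model (GEM): *which metabolic
subsystems* carry a sex-biased expression signal once gene–protein–
reaction (GPR) structure is taken into account, and *which individual
reactions* survive in transcript-consistent context-specific models of
each sex. A third, independent component quantifies the clinical
signal the modelling is meant to explain: sex differences in quarterly
liver-related adverse-event report proportions.

This vignette records the model assumptions, the parameter choices and
their rationale, the numerical design of the optimisation and sampling
layers, what the synthetic-data generator does and does not emulate,
and known limitations.

## Subsystem scoring

Gene weights are log2 fold changes thresholded at FDR < 0.1 (genes at
or above the threshold get *exactly* 0, not a shrunken value). Each
reaction with a GPR receives the rule-resolved weight of its genes:
`or` nodes (isozymes) take the maximum child value, `and` nodes
(complexes) the minimum, and genes absent from the data are skipped —
an absent gene never forces a reaction value, it simply does not
contribute. A subsystem's score is the arithmetic mean of its member
reactions' weights, and its null distribution is built by drawing the
same number of weights uniformly *with replacement* from reactions
outside the subsystem, 1000 times by default.

Choices worth recording:

* **With-replacement null.** The resampling pool can be small once a
  model is reduced; with-replacement draws stay well defined for any
  pool size and have clean closed-form moments (mean = pool mean,
  variance = pool variance / k), which the test suite verifies at
  10^5 draws.
* **Empirical p with add-one correction.** One-tail p =
  (1 + #{null ≥ score})/(n + 1), ties counting toward the extreme
  tail; two-sided p = 2·min(tails), capped at 1. P-values are never
  exactly zero, and the test is conservative at ties.
* **Significance at p < 0.05 two-sided** (0.025 per tail), no
  multiplicity correction by default; a Benjamini–Hochberg option
  (`adjust = "BH"`) is available.
* **`min_reactions = 3`.** A "subsystem" represented by one or two
  weighted reactions is a reaction test, not a subsystem test; such
  subsystems are reported as skipped rather than silently dropped.
* **Orientation.** Positive score = biased toward group A of the
  contrast (male, in the default sex contrast). Note an intrinsic
  asymmetry: because `or` takes a maximum, reversing the contrast
  negates gene weights but does *not* simply negate multi-gene
  reaction weights (max(−x) = −min(x)). Single-gene rules are exactly
  antisymmetric; multi-gene rules are not. The property suite tests
  exact antisymmetry on single-gene models only.
* **Rule-composition sensitivity.** A subsystem dominated by `or`
  rules has positively shifted weights relative to a mixed pool (the
  maximum of several noisy genes is biased upward), and an `and`-heavy
  subsystem the reverse. The permutation null draws from *other*
  subsystems, so a strongly unbalanced rule composition inflates the
  two-sided rejection rate. This is a property of the scoring scheme
  itself, worth checking on any real GEM before interpreting marginal
  calls; the synthetic model keeps rule composition roughly balanced
  across subsystems so that its null calibration is measurable.

## Context-specific model extraction

Transcript abundances are resolved to reactions through the same GPR
max/min convention and mapped linearly to weights in [0, 1]: the
reaction with the highest resolved abundance gets weight 0, the lowest
gets 1, and reactions with no resolvable abundance get a neutral 0.5
(a maximal-penalty policy is selectable). Extraction then proceeds:

1. minimise `sum w_r |v_r|` subject to `S v = 0`, the flux bounds, and
   biomass ≥ `biomass_fraction` × the *base* model's maximum
   (default 0.4);
2. prune reactions with |flux| ≤ 1e-6 in that optimum, dropping
   orphaned metabolites and genes, and re-verify the kept model still
   reaches the floor;
3. re-weight inversely (`w' = 1 − w`), maximise the weighted flux sum,
   and sample the polytope constrained to retain at least
   `objective_fraction` (default 0.8) of that maximum, 110 samples per
   model by default.

Design decisions:

* **Split variables.** `sum w |v|` is linearised by the standard
  parsimonious-FBA split `v = v⁺ − v⁻`, `v⁺, v⁻ ≥ 0`; net fluxes are
  reported.
* **Orthant-fixed maximisation before sampling.** Maximising
  `sum w'|v|` is a non-convex problem: in the split encoding the
  optimiser can inflate `v⁺` and `v⁻` simultaneously, so the split
  maximum can exceed the true maximum of `sum w'|v|` and a constraint
  derived from it could be unsatisfiable on net fluxes. We therefore
  fix each kept reaction's flux direction to its sign in the pruning
  optimum (every kept reaction has |flux| > 1e-6 there, so the sign is
  well defined), which makes `sum w'|v|` linear, the maximisation
  exact within that orthant, and the retention constraint exactly
  verifiable on every sample. The sampled polytope is thus the
  transcript-consistent flux cone around the parsimonious state — a
  deliberate interpretation choice, recorded here.
* **Biomass floor against the base maximum.** When a sample's
  zero-abundance reactions are closed before pruning
  (`close_zero = TRUE`), the floor still refers to the *unmodified*
  model's maximum. This is what makes the retention filter meaningful:
  a sample whose absent transcripts disable an essential reaction
  becomes infeasible at the floor and is excluded and reported, rather
  than silently producing a crippled model. With the floor referred to
  the modified model, exclusion could never trigger.
* **Per-sample seeds** are derived deterministically from the master
  seed and the sample index, so cohorts rebuild bitwise identically.
* **`objective_fraction = 0.8`** balances constraint strength against
  sampling freedom; at 1.0 the polytope collapses to (near) a point,
  at 0 the weighted-flux constraint is inert. The value is a package
  default, exposed in every relevant function.

## Flux sampling

Sampling is a seeded hit-and-run walk (ACHR-style) run in the null
space of the equality system, so every iterate satisfies `S v = 0` to
machine precision by construction; inequality constraints (bounds and
any extra rows) bound each chord. The chain starts from the average of
boundary probe points (LP optima along coordinate directions), uses
100 warm-up steps and thinning 10, and recomputes its constraint
residuals every 50 steps to keep floating-point drift at bay. Fully
determined polytopes (zero-dimensional null space, or zero-width
chords) return the unique feasible point. Identical seeds give
bitwise-identical sample matrices; tests verify |S v|∞ ≤ 1e-6 and
bound/constraint satisfaction to the same tolerance on every sample.

## The LP core

All optimisation reduces to one standard form solved by a dense
two-phase primal simplex written for this package (Dantzig pivoting
with a Bland's-rule fallback for anti-cycling, tolerance 1e-9).
FBA-style LPs are heavily degenerate — every mass-balance right-hand
side is zero and many capacity rows are zero-width — and the
general-purpose simplex routines available in the R ecosystem
installed here fail on exactly that structure (NaN pivots or singular
bases). The implementation is verified against scipy's HiGHS solver
on identical formulations (relative agreement ≤ 1e-6 across jittered
fixtures) and against closed-form optima on tiny networks.
Mass-balance and bound tolerances are 1e-6 throughout, matching the
pruning tolerance, i.e. typical LP solver precision.

## Expression and adverse-event statistics

* Sex inference: samples at or above the 1 − q empirical quantile
  (type 7, linear interpolation) of a male-specific marker are called
  male, at or below the q quantile female, q = 0.16 by default; a
  mean ± 1 SD variant is selectable. A zero-spread marker assigns
  nobody, and boundary samples satisfying both cutoffs stay
  unassigned, keeping the calls disjoint.
* Differential expression: log2(x + 1) transform (handles zeros;
  standard for nonnegative abundance matrices), Welch two-sample *t*
  per gene, Benjamini–Hochberg adjustment. The contract is the
  (log2fc, FDR) table; precomputed tables (e.g. treated-vs-untreated
  hepatocyte contrasts) can be supplied instead and are completed by
  BH when the FDR column is absent.
* Mann–Whitney U (flux contrasts and quarterly series): exact null
  when both samples are untied and the smaller has ≤ 20 observations,
  tie-corrected normal approximation otherwise; all-identical input
  returns p = 1. Exactness is verified against full enumeration of
  every layout with group sizes ≤ 6. Quarterly proportions are treated
  as independent observations in the test — their serial correlation
  is a recognised simplification, inherent to applying a rank test to
  a time series.
* The per-drug filter keeps drugs with strictly more than 100,000
  combined reports before computing female report fractions.

## What the synthetic data emulates — and what it does not

`make_toy_model()` builds a deterministic ~50-reaction liver-like
network: a glycolysis backbone, an oxidative pentose-phosphate branch,
nucleotide synthesis that releases free ribose (so any growth *must*
dispose of ribose), and two disposal routes — direct ATP-coupled
ribose export, or reduction to ribitol (regenerating NAD+) followed by
ribitol export — plus lumped TCA, oxidative phosphorylation,
fatty-acid, amino-acid and xenobiotic modules, exchanges, ATP
maintenance and a biomass reaction. The export route costs 2 ATP so
that the two branches are energetically comparable and transcript
weights, not stoichiometric accidents, decide which one a context
model keeps. Either branch alone supports full growth; closing both
stops it. GPR rules cover ~75% of reactions and are balanced within
each subsystem between single-gene, isozyme and complex forms (see the
rule-composition note above).

`simulate_expression()` draws per-gene log2 baselines (Normal(8, 1),
floored at 5), shifts the genes of planted subsystems by the effect
size in the favoured sex, shifts the branch genes (female: ribitol
route; male: direct export) by ±4 log2 units, gives males a
high-abundance marker gene, adds Normal noise (sd 0.3 by default) and
exponentiates. Defaults — 20 + 20 samples, log2 effect 2, noise 0.3 —
are the conditions under which the pipeline's power and calibration
are measured in the acceptance suite. `simulate_aers()` draws
quarterly totals around 10^5 (Poisson) and liver-related counts as
Binomial with a 0.05 male baseline and +0.02 female excess over 71
quarters (2004Q1–2021Q3).

The generator does *not* emulate: human-genome scale (thousands of
genes, 13k reactions), probe-level microarray artefacts,
normalisation and batch effects, correlated gene expression within
pathways beyond the planted mean shifts, missing sex metadata beyond
the marker mechanism, or reporting biases in adverse-event data
(prescription trends, voluntary reporting). Passing tests therefore
demonstrate that the algorithms recover planted truth under clean,
favourable conditions at desk scale — not that the pipeline's calls on
real cohorts carry the same error rates.

## Problem sizes in the test suite

The acceptance checks run at: 1000 random GPR trees; 21 LP fixtures;
500 null-cohort and 200 planted-cohort replicates for the permutation
test's size and power (permutation depth 1000); 10^5 null draws for
the moment check; 120 per-sample and 40 averaged context-model
replicates for branch recovery; 2 × 110 flux samples for polytope
validity; the full Mann–Whitney enumeration sweep (3418 layouts) plus
200 power and 500 null adverse-event replicates; and 100 random
cohorts for the uniqueness logic. These sizes are the package's
choice of a thorough-but-quick regression suite; all are
parameterised, and nothing prevents running larger designs.

## Known limitations

* The subsystem test's calibration depends on GPR rule composition
  (above); on real GEMs with strongly unbalanced subsystems the
  two-sided rate at the nominal threshold can drift.
* Uniqueness uses strict absence (fraction exactly 0 in the other
  sex); with small cohorts a single stray model removes a reaction
  from the unique set. A softer threshold is configurable.
* The orthant restriction during sampling deliberately excludes flux
  states whose directions differ from the parsimonious optimum;
  reversible-reaction sign flips are therefore not explored at the
  sampling stage.
* SBML support is read-only and covers Level 3 + FBC v2 with
  `groups`-based (or notes-based) subsystem labels — the subset needed
  to ingest curated human GEM releases — not the full SBML feature
  set.
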