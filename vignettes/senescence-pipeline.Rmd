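---
title: "Models and methods behind senescape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind senescape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

senescape analyzes multiomic time courses of replicative senescence: a
primary fibroblast line passaged toward proliferative arrest, sampled at
increasing population doubling levels (PDL), and profiled alongside a
telomerase-immortalized (hTERT) control line collected at temporally
paired timepoints. This vignette explains the models the package fits,
the parameters that matter, what the synthetic-data module does and does
not emulate, and the design decisions taken where the methodology was
genuinely open.

## The PDL axis

PDL is the cumulative number of population doublings. One passage
contributes `log2(harvested / seeded)` doublings — `pdl_increment()` —
which is additive over serial passages. We deliberately implement the
doubling count rather than a ratio of logarithms: the latter is
dimensionally inconsistent with "number of doublings" (it is not additive
and returns 1 when harvested equals seeded only by accident of the
counts). All trend models treat the timepoint covariate `T_t` exactly as
supplied — typically the passage vector itself — and leave any rescaling
(for example, fraction of time course complete) to the caller.

## Per-feature linear trends

For each feature (metabolite, protein, peak, FRiP value) the model is

$$y_{it} = \beta_0 + \beta_1 T_t + \varepsilon_{it},$$

fit by ordinary least squares with a two-sided t-test on $\beta_1$
(`n − 2` degrees of freedom) and Benjamini–Hochberg FDR across features.
No moderation or shrinkage is applied across features: with only a few
timepoints the model is deliberately simple, and its calibration is
checked directly (null p-values are uniform by a Kolmogorov–Smirnov test
at 1,000 features in the test suite). The covariate must take at least
three distinct values; a constant covariate is an error, not an NA.

## Metabolite normalization and paired batch correction

Raw metabolite values are first scaled by a protein-concentration factor:
each (line, timepoint) group's median protein concentration divided by the
median across all samples of that line, multiplied onto the group's
values. The printed convention multiplies (scaling high-protein groups
up); because the opposite convention is equally defensible and the choice
is not recoverable from the procedure's description, `invert = TRUE`
divides instead.

Batch correction exploits the paired design: each WT value is divided by
the same-timepoint control value (replicates matched by index; if the
replicate counts differ, by the control's per-timepoint mean — the
minimal-variance choice when one-to-one pairing is impossible). A batch
factor shared by both members of a pair cancels exactly in this division;
the test suite asserts the cancellation to 1e-10. Ratios are then
expressed as log2 fold changes against the reference timepoint's mean
ratio (arithmetic mean across reference replicates, matching the
"average of the first timepoint" convention used elsewhere in the
pipeline), and the identically zero reference columns are dropped before
trend testing. Zero or missing control values are hard errors; no
pseudocount or imputation is ever applied silently.

## Chromatin-state accounting

Peaks are assigned to a 25-state segmentation by containment: `inside`
when the peak lies entirely within one state instance, `inside_feature`
when it fully contains instances of a single state and touches no base
pair of any other state, `discarded` otherwise. Coordinates are uniformly
0-based half-open, so contact at a shared boundary is not overlap — this
removes every off-by-one ambiguity and is asserted against a brute-force
per-basepair labeling oracle in the tests.

Signal fractions per state (or per broad category) sum counts over all
instances of a state before normalizing per sample. Quantile
normalization (`quantile_normalize()`, backed by limma) forces every
sample onto the per-rank mean distribution; it is idempotent and makes
per-column value multisets identical.

One numerical caveat is documented rather than hidden: when accessibility
changes are asymmetric — planted gains concentrated in NAD/LAD domains
with no compensating losses — any normalization that forces equal totals
or equal distributions (library-size scaling, quantile normalization)
compresses all fold changes by the net gain. For recovery of absolute
effect sizes the package therefore provides `size_factors()`, a
median-of-ratios estimator with an optional `control_features` argument;
anchoring the medians on peaks outside the responsive domains is the
standard control-feature normalization and leaves planted medians
unbiased. `state_fc_summary()` accepts any normalized matrix, computes
each significant peak's log2 fold change against the mean of the
reference-timepoint replicates with a +1 pseudocount, and reports
per-state medians; states with no qualifying peak are `NA`, never 0.
Fold changes are computed after normalization (the pre-normalization
alternative would reintroduce library-size effects into the reference).

Two statistical properties of this summary are worth knowing. First,
restricting to significant peaks inflates their estimated fold changes
relative to their own true values (winner's curse), so truth-recovery
checks run with the cutoff at 1. Second, a per-state median over ~100
peaks has order-statistic noise of roughly 0.05 log2 units under the
default simulation, plus a small (~−0.03) concavity bias from the log2(+1)
transform; recovery tests hold individual states to three sigma and the
well-populated undefined state, and per-domain medians (n ≥ 500), to 0.1.

## Domain-overlap statistics

The permutation overlap test asks whether target genes intersect domains
(≥ 1 bp of gene body; no promoter extension) more than expression-matched
chance. Nulls are drawn without replacement within expression deciles of
the universe so each draw reproduces the target's per-decile counts —
deciles being the coarsest standard binning that still preserves the
distribution. The Z-score is `(obs − mean(null)) / sd(null)` (0, flagged,
when the null is degenerate) and the empirical p-value uses the add-one
rule so it is never 0. With matching disabled on an exhaustively
enumerable universe the test reduces exactly to the hypergeometric tail,
which the suite verifies by enumerating all subsets. The default 1,000
permutations balance Monte Carlo error (~0.01 on p near 0.05) against
runtime. Domains are held fixed and genes resampled — never the reverse —
because domain coordinates are few, long and autocorrelated.

The domain shift test is a Wilcoxon rank-sum comparison of peak log2 fold
changes inside vs. outside a domain class: exact when both groups have at
most 25 tie-free observations, tie-corrected normal approximation with
continuity correction otherwise. Enrichment tests default to one-sided
greater; the shift test to two-sided. The motif-by-domain interaction is
a one-sided OLS t-test on the `motif:domain` coefficient — a declared
modeling choice for "greater-than-additive"; other parameterizations
(e.g. rank-based) would be defensible and need not produce the same
p-values.

## Motif regression

Per-motif enrichment uses an inclusive upper-tail binomial test with the
background presence frequency as `p0`, handling degenerate motifs
(`p0 ∈ {0, 1}`) exactly. The predictive model is L2-penalized logistic
regression on raw binary motif indicators — no standardization, so
coefficients read as per-motif log-odds — with an unpenalized intercept.
The held-out AUC comes from a stratified two-thirds/one-third split and a
rank statistic (equal to the probability a random positive outscores a
random negative, with half credit for ties). "Several independent models
on all the data" is realized as bootstrap resamples: refitting identical
data would produce identical coefficients, so the bootstrap is the only
reading under which averaging ten fits adds information; a configuration
with a fixed penalty and seed makes any run reproducible. The penalty
defaults to 5-fold cross-validated deviance over a small grid when not
supplied; tests and the acceptance script fix it (0.05) for determinism
and speed. Expression filtering of the motif universe is data
preparation, not model logic, and stays outside the module.

## Single-cell scoring and pseudobulk

Counts are scaled to the median library size and log1p-transformed — a
monotone normalized scale sufficient for scoring, deliberately not a
variance-stabilizing transform. A module score is the mean normalized
expression of the program genes minus the mean of a control pool drawn
per program gene from the same average-expression bin (24 equal-count
bins, 100 controls per gene, without replacement within a bin; a bin
smaller than the request contributes all its genes). The score is
invariant to per-cell additive shifts. Two artifacts of this standard
scoring scheme are surfaced by the tests rather than hidden: a program
expressed in many cells raises its genes' average expression and drags
control selection toward the program itself, and controls drawn from a
large program's bins partially contain program genes — both shrink the
score toward zero.

Phase assignment: both scores ≤ 0 is G1, otherwise the larger of the S
and G2M scores wins, with exact positive ties going to S (logged).
Pseudobulk sums counts within (PDL, phase), keeps groups with strictly
more than 15 cells, retains the 8,000 highest-expressed genes (total
summed counts, lexical tie-break), and expresses CPM+1 log2 fold changes
within phase against that phase's earliest PDL.

## Pseudotime trajectories

Cells are binned into 60 equal-width bins over the observed pseudotime
range (equal-width rather than equal-count, so bins have a fixed
pseudotime meaning; empty bins are omitted from the fit, not imputed).
Per-bin means feed a cubic smoothing spline whose stiffness is chosen by
generalized cross-validation (overridable via `spar`), evaluated at all
60 bin centers, then min-max scaled to [0, 1]. Constant trajectories
cannot be scaled and are returned as all-zero with a flag.

K-median clustering under cosine similarity alternates assignment to the
most similar cluster median and coordinate-wise median updates computed
on unit-normalized rows — normalizing before the median is what makes
the procedure genuinely scale-invariant, matching the cosine geometry.
Because a coordinate-wise median is not guaranteed to reduce a cosine
objective, any update that would increase the objective is rolled back
and iteration stops; the objective is therefore non-increasing by
construction. Initialization is k-means++-style under cosine distance
from a seeded RNG; empty clusters are re-seeded from the worst-fit row.
Clusters are labeled early/transition/late by the argmax bin of their
median profile (bins 1–20, 21–40, 41–60), ties resolving to the earliest
bin.

## The synthetic study

The generators are pure functions of a `simulation_spec()` — identical
spec, identical bytes — with per-generator sub-streams derived from one
master seed. Defaults are the study conditions, chosen once:

* **Genome**: 2 chromosomes × 5 Mb tiled by 25 states; the undefined
  state forms 50–200 kb blocks (heterochromatic domains are long) and
  holds roughly half the genome; 20 NADs and 20 LADs are placed inside
  undefined blocks with bias 0.9 (enforced as a hard bp-fraction
  guarantee); 400 genes avoid NADs at 10:1, with log-normal expression
  scores so expression matching is exercisable.
* **ATAC**: 5,000 peaks of 500 bp; PDL 20–50 with 3 replicates; counts
  NB(μ, α) with Var = μ + αμ², α = 0.1, and
  μ = L_s · b_p · 2^(f_p x_s) for the scaled PDL covariate x; planted
  f_p centred at 0.98 (NAD), 0.24 (LAD-only), 0 elsewhere with sd 0.25 —
  the medians are anchored to the reported domain effects, the spread is
  a synthetic convention since effect-size distributions beyond medians
  are not published.
* **Motifs**: 100 motifs at presence frequency 0.15; one planted
  coefficient of +8 with intercept −4. A single binary feature caps the
  achievable AUC well below 1 unless the off-motif class is nearly pure,
  so a strong coefficient with a negative intercept is the configuration
  under which "one predictive motif" is actually learnable (held-out AUC
  ≈ 0.95); weaker settings exist but would test noise, not recovery.
* **Cells**: 500 cells at each of six PDLs, 2,000 genes, a 200-gene
  senescence program whose log2 intensity rises linearly (slope 1 over
  the course) in every phase, G1 fraction growing 0.6 → 0.9, 50 S and 50
  G2M marker genes boosted 4× in their phase, NB dispersion 0.3.
* **Metabolites**: 100 metabolites over 5 timepoints × 3 replicates;
  half null, half with |slope| uniform on [0.5, 2] (natural-log units
  per scaled course); per-timepoint batch factors (sd 0.5) shared
  exactly within WT/control pairs; log-noise sd 0.1.
* **Pseudotime**: 3,000 cells uniform on [0, 1]; 300 genes split over
  three logistic-bump archetypes peaking in the early/middle/late third;
  additive noise sd 0.1.

What passing on these fixtures shows — and what it does not. The
generators reproduce the statistical *structure* the analyses assume:
domain-concentrated accessibility gains, motif-driven labels, a program
ramping within every phase, exactly shared batch factors, smooth
archetypal trajectories. They do not emulate read-level artifacts
(fragment-size structure, GC bias, peak-calling uncertainty), mappability
or copy-number structure, doublets and ambient RNA, mean–variance trends
beyond a constant NB dispersion, or pseudotime inference error (the
pseudotime covariate is an input by design). Recovery on the fixtures
validates the estimators and their implementation, not robustness to
those upstream artifacts.

## Problem sizes and runtime

The test suite runs the full default fixtures: 5,000-peak ATAC courses,
50-seed motif-recovery and null-AUC experiments, 500-draw permutation
calibration on a 250-gene universe, 3,000-cell single-cell fixtures and
300-gene trajectory sets — sizes chosen so each statistical claim is
tested at meaningful power while the whole suite completes in a few
minutes on one core. `scripts/acceptance.R` re-runs the pipeline
end-to-end on the defaults in well under a minute.

## Known limitations

* The trend model is unmoderated OLS; with very few replicates,
  empirical-Bayes approaches will be better calibrated per feature.
* The permutation overlap p-value is discrete (add-one over n_perm
  draws); extremely small p-values require raising `n_perm`.
* Module scores inherit the control-matching artifacts described above
  when programs are large or broadly active.
* K-median cosine clustering is a local optimizer; different seeds can
  yield different partitions on weakly separated data (the objective is
  reported so runs can be compared).
* `protein_normalize()` implements the multiplicative convention as
  printed; use `invert` if your study intended division.
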