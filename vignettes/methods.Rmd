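---
title: "Models and methods behind agingproteome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind agingproteome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agingproteome)
```

This vignette is the package's own account of its statistical machinery: the
models, their assumptions, the tunable parameters and why their defaults are
what they are, what the synthetic-data generators do and do not emulate, and
the numerical conventions adopted where more than one defensible choice
existed.

## Differential abundance by rank products

### The model

The input is a protein × replicate table of log2(heavy/light) abundance
ratios from paired isotope-labeled samples (old over young), with missing
values where a protein was not quantified in a replicate. Proteins present
in fewer than `min_replicates` replicates (default 2, matching a
two-of-three replicate design) are filtered on construction.

Each replicate column is first **median-centered**: labeled samples are
mixed nominally 1:1, but the true mixing ratio is inexact, which shifts an
entire replicate's log-ratio distribution by a constant. Subtracting the
per-replicate median absorbs this, at the cost that all calls are *relative
to the bulk proteome* rather than absolute per-animal changes. Centering
changes no within-replicate ordering, so the rank-based statistic downstream
is unaffected except through interpretability.

The **rank product** of protein *i* is the geometric mean of its
within-replicate ranks (rank 1 = strongest change in the tested direction),
with each rank divided by the number of proteins quantified in that
replicate and the result rescaled by the universe size *N*:

$$ RP_i = N \prod_{j \in \text{obs}(i)} \left(\frac{r_{ij}}{n_j}\right)^{1/k_i}. $$

The depth scaling is this package's treatment of missingness: the classical
statistic assumes complete data, and dividing by the replicate depth keeps
rank fractions comparable across proteins with different missingness
patterns while preserving the attainable minimum of 1 (top-ranked
everywhere). Ties receive average ranks — symmetric and deterministic. The
statistic depends only on within-replicate orderings, so it is invariant to
any strictly increasing transform of a replicate's values (a property the
test suite asserts directly).

### The permutation PFP

Significance uses the proportion-of-false-predictions (PFP) estimate, a
permutation FDR analogue. Each permutation independently shuffles the ranks
within every replicate while holding each protein's missingness pattern
fixed, so each replicate's depth is respected, and recomputes all rank
products. For a protein at position *r* of the ascending observed-RP list:

* expected false positives `E = #(permuted RP <= observed RP) / n_perm`,
  pooled over all proteins in all permutations;
* `PFP = E / r`.

Two conventions are ours because the procedure leaves them open. First,
**monotonization**: raw PFP need not be monotone in *r*; we replace it by
the cumulative minimum from the bottom of the sorted list (the step-up
convention also used by Benjamini–Hochberg), so that loosening the cutoff
never removes a call. Second, PFP values above 1 are reported clipped to 1,
with the raw value retained in the `pfp_raw` diagnostic column. The up and
down directions are tested **separately** (two one-directional tests rather
than one two-sided test), matching how such experiments report separate
up/down counts; in the pathological case where a protein passes in both
directions, the smaller PFP wins and a warning is emitted.

The permutation scheme shuffles ranks *within replicates independently*
rather than permuting protein labels jointly across replicates. With three
paired replicates there are too few samples for sample-label permutation;
independent within-replicate shuffling is the literal null of "no consistent
ordering across replicates".

Defaults: `n_perm = 10000`, `fdr = 0.10`. A warning is raised below
`n_perm = 100`, where the E estimate is unstable. On universes small enough
to enumerate, the test suite checks the permutation estimate against an
exhaustive enumeration of all joint rank assignments, with tolerances scaled
by the exact per-permutation standard deviation.

## Set-level statistics

**Fisher fold enrichment** reports `fold = (a/n_hits)/(K/N)` — observed over
expected hits in an annotation set — with the exact hypergeometric upper
tail as the primary p value. Sidedness is a deliberate choice: every
enrichment claim this pipeline makes is about over-representation, so the
upper tail is primary and the two-sided Fisher probability is reported
alongside. `overlap_enrichment` applies the same test to the intersection of
two sets. When multiple sets are tested in one run, Benjamini–Hochberg
adjustment across sets is applied (`adjust_across_sets`); single-set p
values are reported unadjusted.

**KS shift tests** compare a subset's fold-change distribution against a
reference with the asymptotic two-sample Kolmogorov–Smirnov test. The
reference may *contain* the subset — the primary comparison of a class
against the full background — and the caller can instead pass an
already-filtered subset and set `exclude_overlap` to record that reading.
The direction is the sign of the median difference.

**GSEA** is the weighted running-sum family: walking down the
score-sorted list, the sum rises by `|score|^w` (normalized over members,
`w` ∈ {0, 1}, default 1) at a member and falls by `1/(N−K)` otherwise; the
enrichment score is the maximum deviation from zero. The null permutes
*gene labels* — with three paired replicates, sample permutation is
infeasible — and the permutation p uses the add-one estimator, so
`p >= 1/(n_perm+1)`. NES divides ES by the mean |ES| of same-sign permuted
scores, and the permutation FDR pools null NES across sets. Sets outside
[5, 500] members after restriction are skipped. For small `choose(N, K)` an
`exhaustive = TRUE` mode enumerates all placements and returns an exact p.

**Direction concordance** between two studies counts shared proteins whose
fold changes agree in sign; an exactly-zero fold change counts as
*discordant* (the conservative reading), a binomial test compares the
fraction against 0.5, and the squared Pearson correlation summarizes
magnitude agreement.

## Developmental-stage clustering

Stage matrices hold per-stage transcript abundance (RPKM, non-negative) for
the proteins of an experiment, ordered early-embryo → young-adult. Because
the question is *shape* (when is a gene expressed?) rather than level, rows
are normalized before clustering. Two normalizations serve two purposes:
**z-score** rows (mean 0, SD 1) feed the clustering, the convention of
clustergram-style tools; **sum** normalization (rows as stage proportions)
scores cluster specificity, because a sum-normalized row reads directly as
"fraction of this gene's expression in stage s". Both are recorded in the
object's metadata.

Clustering is agglomerative with distance `1 − Pearson correlation` between
normalized rows (range [0, 2]) and average linkage by default — the cited
tools' default; complete and single linkage are available. Constant rows
have undefined correlation and are dropped with a message. Merge
tie-breaking follows `stats::hclust`, which is deterministic for a fixed
input ordering.

The adult-specific cluster is extracted by cutting the tree at *k* clusters
and returning the cluster with the highest mean target-stage proportion; *k*
may be a vector, in which case the scan keeps the best (cluster, *k*) pair.
Selecting by maximal specificity automates what is otherwise an by-eye
choice from a heatmap; it is a design decision, and `k` remains fully
configurable. A caveat the simulations make explicit: under correlation
distance, background genes whose noise happens to peak in the adult stage
correlate strongly with a genuine adult-specific profile, so the extracted
cluster reliably *contains* the planted adult-specific genes (recall ≈ 1 in
the test suite's recovery simulations) while its *purity* is substantially
lower (~0.6 under the default noise level). Interpreting cluster membership
as evidence of adult specificity for any individual gene therefore
overstates certainty; the package's own tests freeze the simulated levels.

## Protein turnover from photoconversion timecourses

A photoconvertible (green→red) reporter is converted at time 0; the red pool
then decays as pre-existing protein is removed, while green tracks total
protein. Unconverted animals of the same group, imaged at the same
timepoints, provide the red background. Normalization is per animal:

$$ rel(t) = \frac{R(t) - B(t)}{R(0) - B(0)}, $$

with `B(t)` the mean red signal of unconverted animals at the *same
timepoint* (not a global constant — illumination and autofluorescence drift
with time). `rel(0) = 1` by construction; `rel = 0` means indistinguishable
from background (complete removal). Noise can push `rel` below zero; values
are retained and flagged, never clipped, so group means stay unbiased.
Animals whose time-0 signal does not exceed background have an undefined
normalization and are excluded with a message, as are animals that died
mid-course.

Two half-life estimators are provided because bound-style statements
("less than 4 h", "greater than 36 h") and point estimates need different
machinery:

* **interpolation** (default): the first linear-interpolated crossing of 0.5
  on the group-mean curve. If the mean curve never reaches 0.5 inside the
  observation window, the estimate is right-censored and reported as
  `> t_max` — never a point value. This mirrors how slow turnover can only
  be bounded by the experiment's window.
* **loglinear**: least squares of `ln(rel)` on time over animal-level points
  with `rel > 0`; `t½ = ln 2 / |slope|`. Rejected when no decay is
  detectable (non-negative slope), rather than returning a negative
  half-life.

On noiseless exponential data sampled on a grid containing the half-life,
both estimators agree exactly (asserted to 1e-9). Bootstrap confidence
intervals resample animals (default 1000 draws, seeded).

The **synthesis rate** comes from the linear production–decay model
`dT/dt = s − kT`, closed form `T(t) = s/k + (T(0) − s/k)e^{−kt}` (limit
`st + T(0)` at `k = 0`), fitted by least squares to the group-mean total
(green) trajectory with `k` supplied from the decay fit. With `k` fixed the
model is linear in `(s, T(0))`, so the fit is exact arithmetic. This is
explicitly model-based: the reported `s` is the production needed to explain
the observed total-level trajectory *given* the measured removal rate, and
the model-implied fold change at `t_max` is reported with it.

`summarize_reporter` is the generic two-group readout: background-subtracted
means scaled to a reference group, SEMs, and a two-sample test. Welch's
unequal-variance test is the default (the safer choice when variances are
unknown); the classic pooled-variance test is available by flag.

## Lifespan analysis

Kaplan–Meier product-limit curves with right-censoring; animals censored for
death modes unrelated to aging (internal hatching, bursting, loss) leave the
risk set at their censoring time. The **median convention** is the first
observed event time with `S(t) ≤ 0.5` — the step-function convention —
flagged undefined when the curve never reaches 0.5 rather than guessed.
Group comparison uses the standard observed-minus-expected chi-squared
log-rank test (1 df) over pooled event times, tied events contributing
jointly; the statistic is symmetric in group order and exactly zero for
identical groups. `median_extension` reports
`100 · (median_g − median_ref)/median_ref`. Only pairwise tests are exposed:
the experimental design compares one treatment against its control plate.

## The synthetic-data generators

Every generator is a pure function of its arguments including the seed
(asserted by the test suite), runs its randomness in an isolated RNG scope
so callers' streams are undisturbed, and returns the planted truth alongside
the data. One practical consequence of seeded purity: two generators called
with the *same* seed replay the same RNG stream, so downstream draws can
coincide with upstream ones — use distinct seeds for independent inputs.

Noise models are the simplest ones consistent with each quantity's support,
and are assumptions of this package, not measurements:

* **Ratio tables**: planted effect ± `effect_log2` (default 2) on a fraction
  of proteins, Normal noise (`noise_sd`, default 0.5 log2 units), a
  per-replicate additive offset uniform in ±0.5 emulating inexact mixing
  (this is what makes median-centering non-trivial; the magnitude is a
  construction, and configurable), and missing-completely-at-random dropout
  (`missing_rate` < 1/3) capped so every protein keeps ≥ 2 replicates.
  Replicate-to-replicate correlation beyond the planted effect is *not*
  modeled.
* **Stage matrices**: background rows flat at `base_rpkm` (default 50),
  planted rows multiplied by `specificity` (default 20) in the adult stage,
  multiplicative lognormal noise with coefficient of variation `noise_cv`
  (default 0.3), mean-corrected so stated expectations hold exactly.
* **Decay traces**: `red(t) = background + init_red·2^(−t/t½) + N(0, σ)`
  for converted animals, background plus noise for unconverted; green
  follows the production–decay model with `G(0)` chosen so the noiseless
  12-hour total change matches the growth scenario (+50% by default) when
  synthesis is on, or pure decay when it is off. Negative post-noise
  signals are clipped at 0 and counted.
* **Lifespans**: Weibull event times (shape default 4, a realistic aging
  hazard steepness) with scale solving the requested median exactly;
  censoring is independent and uniform over each animal's pre-death
  interval — real censoring (bagging, bursting) is correlated with
  physiology and is not modeled mechanistically.

What passing tests on these generators shows is that the *statistical
machinery* behaves as designed under its stated assumptions — calibrated
nulls, recovery of planted effects at the designed sizes. What it cannot
show is robustness to structure the generators omit: correlated replicates,
intensity-dependent missingness, batch structure in stage data, non-Normal
imaging noise, or informative censoring.

## Problem sizes and reproducibility

The test and acceptance simulations run at the study's own scales — 1796 × 3
ratio tables, 249- and 95-member annotation classes, turnover groups of ~15
animals, lifespan arms of 100 — with permutation depth 2000 for simulation
sweeps and 10000 for single headline runs, and 10–50 seeds per calibration,
sizes chosen to keep each sweep in seconds-to-minutes while leaving
Monte-Carlo error well inside the asserted tolerances. Every stochastic stage
takes an explicit integer seed, records it in its result (and in the run
manifest written by the `run_*` orchestrators, along with input checksums and
parameter values), and reproduces byte-identical output when re-run with the
same seed.

## Known limitations

* The pipeline starts from ratio tables; spectral search, PSM filtering, and
  peptide-to-protein rollup are upstream and out of scope.
* PFP is an FDR *analogue*; its monotonized, clipped form is conservative at
  the top of the list and can exceed nominal accuracy claims at the bottom.
* Gene-label GSEA treats genes as exchangeable under the null, which
  understates correlation between co-regulated genes.
* The adult-specific cluster's membership is high-recall but impure under
  realistic noise (see above); treat per-gene membership as a screen, not a
  verdict.
* Interpolation half-lives depend on the sampling grid between the two
  bracketing timepoints; the log-linear estimator uses all points but
  assumes a single-exponential pool.
* Synthesis rates are model-implied, not directly measured.
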