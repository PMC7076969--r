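---
title: "Models and methods: grain water content QTL mapping and fine-mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: grain water content QTL mapping and fine-mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwcqtl)
```

## The problem

Grain water content (GWC) at harvest determines whether maize can be
machine-harvested without breaking kernels; it depends on GWC at
physiological maturity (PM, ~45 days after pollination) and on the grain
dehydration rate (GDR) afterwards.  Both are quantitative traits:
moderate heritability, many small-effect loci, strong environmental
sensitivity.  `gwcqtl` implements the full computational chain used to
dissect such traits in a biparental cross — trait computation from
kernel weights, linkage-map quality control, genome scanning with
permutation thresholds, variance components and BLUP across trials,
and, centrally, sequential fine-mapping of one QTL by
recombinant-derived progeny tests — together with a synthetic-population
generator that provides data with a known truth model.

Genotype codes throughout are `"A"` (homozygous for the low-GWC parent
allele), `"B"` (homozygous for the high-GWC parent), `"H"`
(heterozygous), and `NA` (missing).

## Trait definitions

GWC (%) is `100 * (fresh - dry) / fresh` from the fresh and oven-dry
weight of a kernel sample; GDR (percentage points) is the drop in GWC
between two successive samplings, five days apart in the default
designs.  Negative GDR (apparent re-wetting) is retained but flagged
with a warning — real dry-down series occasionally show it, and
silently clamping would bias trial means.  Correlations in
`correlation_table()` are Pearson r with two-sided t-based stars at
0.05/0.01/0.001; a correlation on fewer than three complete pairs or
against a constant column is reported as missing.

## The synthetic population generator

The generator is first-class, tested code; it defines the study
conditions the rest of the package is validated against.

* **Meiosis** (`simulate_gametes()`): crossovers are a Poisson process
  on the cM scale with no interference (count ~ Poisson(L/100),
  positions uniform), so the recombinant fraction over d cM is
  `(1 - exp(-d/50)) / 2`.  The no-interference model is used for
  *simulation*; the Kosambi function — the standard choice for maize
  linkage maps — is used on the *estimation* side
  (`kosambi_distance()`, genotype probabilities).  The two are
  deliberately different: estimation should not be validated against a
  generator that shares its own map function.
* **Populations**: `derive_ril_population()` advances an F1 by
  single-seed descent; the number of selfing generations defaults to 8
  (a typical advanced RIL generation; the exact generation of a given
  real population is usually not critical because heterozygosity has
  decayed to (1/2)^g by then) and is configurable.
  `derive_progeny()` selfs or backcrosses a recombinant plant.
* **Default map**: 10 chromosomes x 78 equally spaced markers,
  1522.48 cM total at 1.4 Mb/cM — the scale of a dense maize SNP map.
* **Phenotypes** (`simulate_phenotypes()`): GWC for line i, trial j,
  DAP t is `baseline_j(t) + x_i a + z_i d + G_i + (GxE)_ij + e`, with
  x = +1/0/-1 for QTL genotype A/H/B and z = 1 for heterozygotes.  The
  baseline trajectory is piecewise-linear through per-trial (DAP, GWC)
  anchors; the three default trials fall from ~38-39% at 45 DAP to
  ~23% at 60 DAP (one winter-nursery trial is drier throughout).
  Default effects a = 1.655, d = 0.075 reproduce a semi-dominant QTL
  whose homozygotes differ by 3.31 GWC points; default variances
  (sigma2_G = 4.5, sigma2_GxE = 3, sigma2_e = 3) give broad-sense
  heritability 0.75 in a three-trial design.  Fresh weights are fixed
  at 30 g and dry weights derived so that the GWC formula recovers the
  simulated value exactly (a round-trip identity the tests assert).
* **Coupled dry-down mode** (off by default): successive GWC values are
  generated sequentially and the per-interval drop both carries its own
  noise and pulls lines above the baseline back towards it.  Because
  the same noise term raises GDR and lowers GWC at the later sampling,
  this induces the strong negative GDR-GWC(later) correlation (~ -0.6
  at the defaults) seen in real dry-down tables.  The mode exists to
  exercise the correlation machinery qualitatively, not to model kernel
  physiology.

What the generator does **not** emulate: crossover interference,
segregation distortion from selection, genotyping error structure
beyond a uniform rate, husk/cob water, planting-density or weather
covariates.  Passing tests therefore demonstrate the correctness of the
estimators under the stated genetic model, not robustness to every
field artefact.

## Linkage-map QC and distances

Markers are filtered in a fixed order with one primary reason each:
non-polymorphic between the parents first, then missing rate > 20%,
then heterozygous rate > 20% (both strict: exactly 20% is kept), then
segregation distortion by Pearson chi-square against the Mendelian
ratio for the population type (RIL homozygotes 1:1, F2 1:2:1, BC 1:1)
at alpha = 0.05 with an optional Bonferroni correction — the
distortion alpha and its correction are design choices here, since
standard practice varies.  QC precedes distance estimation.

Marker *ordering* is taken from the input map; only distances are
recomputed.  For selfing-derived RILs the observed homozygote
recombinant fraction R is corrected to the meiotic fraction via
r = R / (2(1 - R)) before the Kosambi transform
d = 25 log((1+2r)/(1-2r)); estimates cap at r = 0.4999 because the map
function diverges at 0.5.

## Genome scan

`genotype_probabilities()` computes, at every marker and on a step grid
(default 1 cM), the genotype-class probabilities conditional on the
nearest flanking non-missing markers under a Markov chain along the
chromosome; RIL transitions use the two-state fixed-line matrix with
between-line recombinant fraction R = 2r/(1+2r), F2 uses the product
of two independent gamete chains, and missing flanks fall back to the
class priors.  `interval_mapping_scan()` is Haley-Knott regression on
the expected genotype score: LOD = (n/2) log10(RSS0/RSS1), the
additive effect is half the fitted homozygote difference (positive when
the low-GWC parent allele increases the trait), and R2 is reported in
percent.  `cim_scan()` adds forward-selected marker cofactors (<= 5 by
default, entry p < 0.05) to both models, excluding cofactors within a
10 cM window of the evaluated position; with zero cofactors it reduces
exactly to plain interval mapping, which the tests assert to 1e-9.
The cofactor count, entry threshold and window are package defaults —
composite interval mapping is standard for this design but its control
parameters are rarely published.

`permutation_threshold()` permutes the phenotype (1000 times by
default) and returns the empirical 95th percentile of the genome-wide
maximum LOD.  The declared calling threshold in the pipeline is
`max(2.5, permutation threshold)`: the fixed 2.5 floor and the
permutation device are both standard, and taking the maximum applies
whichever is stricter.  `call_qtl()` merges contiguous supra-threshold
runs, reports a 1.5-LOD support interval extended one scan position
past the drop so the flanking markers bracket it, and flags calls with
R2 > 10% as major.

## Variance components, heritability, BLUP

`anova_components()` fits the all-random model
Y_ijk = mu + G_i + E_j + S_k + (GxE)_ij + e_ijk on one observation per
(line, environment, unit) cell and solves the expected mean squares:
sigma2_e = MS_res, sigma2_GxE = (MS_GxE - MS_res)/r,
sigma2_G = (MS_G - MS_GxE)/(lr).  Negative moment estimates are
truncated to zero and flagged.  When more than 10% of cells are empty
the design is treated as unbalanced and components come from REML
(`lme4::lmer`) instead.  Broad-sense heritability is
h2 = sigma2_G / (sigma2_G + sigma2_GxE/l + sigma2_e/(lr)); for GWC the
unit stratum r is the number of sampling times, for GDR the number of
replicates (`anova_records()` reshapes accordingly).  `blup_predict()`
fits the all-random model y = mu + g + l + r(l) + (g x l) + e per
sampling time and predicts each line as grand mean + BLUP; terms
confounded with the residual (e.g. the line-by-trial interaction in
single-replicate data) are dropped automatically.  The predicted GDR is
exactly the difference of the two predicted GWC values.

## Sequential fine-mapping

The engine's unit of evidence is the **recombination type**: a distinct
multi-marker genotype pattern over the region, with a contiguous
heterozygous segment.  The segment is tracked twice: the *certain*
segment spans the outermost markers typed H; the *possible* segment
extends one marker further on each side, because the true boundary lies
somewhere in the flanking uncertainty gap.  A progeny test compares
mean GWC between the two homozygote classes (selfed families) or
heterozygote vs recurrent homozygote (backcross families) with a
two-sided Welch t-test; verdict "S" when P <= 0.05.  The published
wording for this comparison is a paired t-test, but the two genotype
classes are unpaired samples of unequal size, so Welch is the
defensible reading; a pooled-variance option is provided.

`narrow_interval()` computes

> candidate = interval ∩ (∩ possible segments of S types) −
> (∪ certain segments of NS types)

with boundaries snapped outward to marker positions.  Using *possible*
segments for S and *certain* segments for NS is the conservative
combination: it can never exclude the true location because of boundary
uncertainty.  Removing a single excluded marker point does not count as
disconnecting the candidate.  If the candidate is empty or genuinely
disconnected, the verdict set is inconsistent: the smallest set of
verdicts whose removal restores a single positive-length segment is
dropped and reported, exploring the most *borderline* verdicts first
(|log(p/0.05)| smallest) — a verdict with p near the threshold is the
least reliable on either side.  The search is bounded (drop sets up to
size 4 over the 12 most borderline verdicts), which keeps the cost
polynomial; an instance that cannot be resolved within the bound is
returned flagged rather than guessed.

`run_sequential_finemap()` drives the whole procedure on a simulated
region (default: 26 markers named by their Mb position over a ~27 Mb
target, QTL hidden at 76.6 Mb).  Design choices that matter:

* **Verdicts accumulate across rounds** and each round re-narrows from
  the full region using every verdict observed so far.  This mirrors
  drawing the inference by comparison of *all* recombination types and
  gives the procedure self-correction: a borderline false "S" that
  mis-narrows one round is contradicted by later families and removed
  by the conflict resolution, instead of being locked in forever.
* **A control family** — a plant heterozygous across the whole current
  candidate — is tested in every round after the first.  When the
  candidate is right it simply confirms segregation; when it is wrong
  its NS verdict blankets the candidate and triggers the resolution.
  Growing a heterozygote-derived control alongside the recombinant
  families is part of the real workflow.
* **Marginal S verdicts are confirmed**: when a family segregates with
  p above 0.005, a second independent family of the same recombinant is
  grown and the verdict must replicate.  At the per-family 5% level a
  borderline false positive is otherwise the dominant failure mode of
  the whole procedure; replicated progeny tests across seasons are how
  the field handles it, and the confirmation keeps the per-family
  verdict rule (P <= 0.05) intact.
* **Round sizes**: 11/9/18/11 recombinants and family sizes
  80/80/150/200 per round — early screening families are small, while
  advanced-generation segregating progenies are larger.
* The test marker for each family is the heterozygous-run marker
  nearest the segment midpoint; which marker was used when several were
  available is typically not published, and the midpoint choice
  maximises the distance to both uncertain boundaries.

Under the default effect sizes the four rounds take the ~27 Mb region
to a median final interval of ~2 Mb with the true position inside in
>= 90% of seeded replicates (the acceptance suite runs this experiment
at a = 1.5, residual sd = 2.5).  With a zero-effect QTL no round
produces a segregating majority and the interval is returned unchanged
and flagged.  `finemap_example_round1()` ships a synthetic encoding of
a first-round panel — 11 recombinants, 10 types, published-style S/NS
verdicts — whose narrowing delimits the SSR-75.1/SSR-80.1 interval; the
genotype patterns are synthetic reconstructions because only verdicts
and the resulting interval are published, and marker "positions" are
taken from the Mb suffix of the marker names.

`estimate_genetic_effect()` reduces per-genotype class means to the
homozygote difference Delta, a = Delta/2 (signed), d = mean(H) −
midpoint, and a gene-action class from |d/a| (< 0.2 additive, 0.2-0.8
semi-dominant, > 0.8 dominant; configurable).  The `intermediate` flag
records the operational sense of semi-dominance — the heterozygote mean
strictly between the homozygote means — which holds in all four
worked-example generations even when d/a itself is small.

## Numerical and degenerate-input choices

* Zero-variance progeny classes: the t-test is replaced by an exact
  rule (p = 0 if the class means differ, 1 otherwise) so noise-free
  simulations behave.
* Positions with zero genotype-score variance scan to LOD 0 rather
  than NaN; permutation maxima clamp r^2 away from 1 by 1e-12.
* The heritability denominator below 1e-12 reports NA (undefined)
  rather than 0/0.
* Recombination-fraction estimates cap at 0.4999; fewer than 20
  informative joint calls is an error, not a guess.
* Ties in type ordering and conflict resolution are broken
  canonically (segment bounds, then pattern) so results do not depend
  on input order.

## Problem sizes used in the validation suite

The shipped experiments are sized for routine re-running: calibration
uses 1000 null families and 400 null RIL datasets of 120 lines on a
2-chromosome map with 200 permutations each; parameter recovery uses
100 datasets of 200 RILs on a 3-chromosome map, 100 heritability
round trips, and 50 seeded fine-mapping runs.  These sizes give
binomial standard errors comfortably inside the asserted bands; larger
genomes or replicate counts change nothing structurally.

## Known limitations

* No multiple-QTL model or epistasis scan; the CIM cofactor policy is
  the only multi-locus device.
* The RIL recombination-fraction correction assumes selfing-derived
  lines; sib-mated RILs would need a different correction.
* The EMS path assumes the balanced classical ANOVA; heavily
  unbalanced data silently lose the sampling-stratum interpretation
  when REML takes over.
* Fine-mapping assumes a single QTL in the target region; two linked
  QTL inside the region would produce systematically conflicting
  verdicts (which the engine reports, but cannot resolve into two
  intervals).
* The no-interference meiosis model slightly overstates double
  crossovers relative to real maize; map-length recovery tests allow
  for this.
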