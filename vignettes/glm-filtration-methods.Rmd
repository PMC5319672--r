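---
title: "Platform-calibrated GLM filtration of variant calls: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Platform-calibrated GLM filtration of variant calls: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glmvc)
library(dplyr)
```

## The problem

Amplicon-based targeted sequencing panels report variant calls with high
sensitivity but, depending on the platform, a substantial false positive
burden — especially for indels, where pyrosequencing and semiconductor
chemistries systematically miscall homopolymer run lengths. Fixed
one-size-fits-all filters (e.g. "drop everything with QD < 2.5") transfer
poorly between assays: thresholds tuned on one dataset can remove a majority
of *true* variants on another (the `qd_varw_filter()` comparator exists to
demonstrate exactly this failure mode).

glmvc instead calibrates a logistic regression per platform and per variant
type on a labeled training set, then derives a retention threshold that, by
construction, sacrifices no training sensitivity. The assumption is that
true mutations and artifacts differ in distribution over a panel of
call-level characteristics, and that the informative characteristics differ
by platform — so the model, not the analyst, should pick them.

## The parameter panel

Each call is scored on up to 23 parameters (`glm_params()`), grouped by what
they measure: quality and depth (`Q`, `DP`, `QD`), coverage (`Cov_total`,
`Cov_ref`, `Cov_vcf`), allele frequency (`AF_total`, `AF_ref`, `AF_vcf`),
strand bias (`SB`, `SB_vcf`, `SOR`), variant position in the read (`VP`,
`VP_vcf`), base quality (`BQ`, `BQ_vcf`), mapping quality (`MQ`, `MQRank`),
homopolymer context (`HP`, `HP_AT`, `HP_CG`) and indel width (`VARW`,
`DevGT`). The `_vcf`-suffixed parameters are copied from GATK annotations;
the rest are calculated from the read pileup and the reference. 18 apply to
SNVs (the homopolymer and indel-width parameters do not), 22 to indels
(`BQ` does not).

Several calculated parameters have no universally fixed definition, so the
package states its own and keeps them bounded and interpretable:

* **`SB`** — absolute difference of forward-strand fractions between
  ALT- and REF-supporting reads, in [0, 1]. Undefined when either class is
  empty. Chosen over odds-ratio forms because it is bounded and distinct
  from the VCF's `FS` and `SOR`, which are consumed as-is.
* **`VP`** — per ALT read, the distance of the variant site to the nearer
  read end divided by read length; the median over ALT reads, in [0, 0.5].
  Values near 0 flag end-of-read artifacts; this mirrors the intent of
  `ReadPosRankSum` on a bounded scale.
* **`HP`** — length of the maximal reference run of the indel's first
  inserted/deleted base that contains or is adjacent (±1 base) to the
  position following the VCF anchor; runs are counted on the reference
  only. An insertion of a base absent from its context yields `HP = 1`.
  `HP` is reported as a length; an indicator variant ("is the indel in an
  A/T run at all") is available via the `indicator` argument, since either
  reading is defensible.
* **`VARW` / `DevGT`** — over indel-bearing reads at the site, the number
  of distinct observed indel alleles minus one, and the fraction whose
  indel differs from the called allele. Heterogeneous indel support is the
  signature of homopolymer length noise rather than a real variant.
* **`Cov_total` vs `Cov_ref`** — all reads at the site versus only
  REF/ALT-supporting reads; with `AF_total`/`AF_ref` as the alt fraction
  over each denominator this yields three distinct allele-frequency
  estimates alongside the AD-derived `AF_vcf`.

### Missing values

Absent VCF annotations are stored as `NA` at I/O time, never as zero.
Modeling applies one fixed policy (`impute_features()`): the rank-sum
statistics (`VP_vcf`, `BQ_vcf`, `MQRank`) and the Phred-scaled bias scores
(`SB_vcf`, `SOR`) impute 0 — their null, "no evidence of bias" value, which
GATK omits precisely when it cannot be computed (e.g. homozygous-alt
sites). Any other missing covariate has no defensible default: such rows
are dropped from training, while at application time the call is **kept**
and flagged — when the model cannot score a call honestly, the package
fails toward sensitivity.

## Relative variable importance

To characterize which parameters separate true from false calls on a given
platform, the package computes Akaike-weight relative variable importance
over an enumerated space of logistic models. Models containing a correlated
parameter pair (|Pearson r| ≥ 0.7 on pairwise-complete rows; the
quality/quality-by-depth pair always) are excluded, because collinearity
biases AIC; non-converging fits are excluded too, with convergence defined
as IRLS termination within 25 iterations *and* all |coefficients| ≤ 15 —
the coefficient bound is a quasi-separation proxy, since a perfectly
separating covariate drives its coefficient toward infinity while the
likelihood still "improves". Both controls are arguments (`corr_threshold`,
`coef_limit`); the bound matters when covariates live on small scales,
where legitimate coefficients above 15 exist.

Each admissible model *m* gets an Akaike weight
$w_m = \exp(-\Delta_m/2) / \sum_k \exp(-\Delta_k/2)$,
$\Delta_m = \mathrm{AIC}_m - \min \mathrm{AIC}$, and the raw RVI of a
parameter is the sum of weights of the models containing it.

Exclusions leave parameters present in unequal numbers of models, which
distorts raw RVI: a parameter admitted to few models cannot accumulate
weight. `normalize_rvi()` offers two corrections. The default,
`"mean_inverse"`, divides by the parameter's own model count and rescales
by the mean count, `raw(p) · (Σᵢ#models(i)/n) / #models(p)` — it up-weights
under-represented parameters and can exceed 1. The alternative,
`"as_printed"`, multiplies by `#models(p)/Σᵢ#models(i)` and is a pure
down-scaling, never exceeding the raw value. The default was chosen
because the correction's purpose is to *compensate* under-representation,
which only the inverse scaling does; the other form is retained for
comparability with reports that use it.

Enumeration is exhaustive over all subset sizes while the admissible count
stays within `full_limit` (50,000); beyond that the subset size is capped
(`max_size`, default 4). Full enumeration of 2²² subsets is not a
computation anyone should run.

## Training: forward selection and the threshold rule

`train_pipeline()` composes three steps.

1. **Correlation screen** as above.
2. **Forward selection by AIC**: starting from the intercept-only model,
   repeatedly add the candidate that yields the lowest AIC among additions
   that converge and introduce no forbidden pair; stop when no addition
   strictly lowers AIC. Ties break lexicographically so the procedure is
   deterministic. There is no extra stopping penalty: AIC's implicit cost
   of 2 per parameter is the whole rule, which means a pure-noise covariate
   still enters with probability ≈ 0.16 per candidate (the chance its
   deviance improvement exceeds 2). Consumers should expect an occasional
   hitchhiker covariate; the planted signal itself is recovered essentially
   always at reasonable n.
3. **Threshold estimation**: with predicted probabilities in hand, let *m*
   be the minimum over true positives and *E* the set of false positive
   probabilities below *m*; the threshold is `max(E)` (0 if *E* is empty),
   and the decision rule is KEEP iff `p̂ > t` — strictly. This is the
   literal minimum threshold satisfying three conditions: no training true
   positive is filtered, every false positive that *can* be excluded
   without violating that is excluded, and no smaller threshold does both.
   A call landing exactly on the threshold is filtered; the strict
   inequality is what makes `t = max(E)` optimal.

The guarantee is a training-set identity, not a generalization claim: on
held-out data a true positive may well score below the trained threshold.
For triage workflows, `triage_calls()` implements a two-threshold variant —
filter below the trained threshold, keep above the smallest training-TP
probability, and route the band in between to review.

## Synthetic data: what it emulates and what it does not

`generate_profile_table()` draws labeled feature tables from six built-in
platform profiles. Class counts default to the training compositions of the
amplicon benchmark the package is modeled on (36 TP SNVs for the
pyrosequencing profile, 7 TP vs 644 FP indels for the semiconductor one,
etc.), and the *direction* of each informative effect follows the known
error structure: false positive indels sit in long homopolymers (FP run
floor 4 vs TP runs of 1–3), artifact quality-by-depth is depressed,
artifact strand-bias odds ratios are elevated, artifact alt support sits
near read ends. All distribution families and numeric settings are package
inventions, fixed once; they are not estimates from any real dataset.

Two construction details matter for interpretation:

* Each FP class contains a 2% contaminant drawn from the TP distributions.
  Without it, the classes quasi-separate and every informative fit is
  rejected by the coefficient bound; with too much of it (5% was tried
  during design), the TP-clone artifacts suppress the informative slopes
  and single-covariate models win selection. 2% keeps fits convergent
  while leaving the separated bulk removable.
* The profiles are constructed so that the trained filter achieves zero
  training TP loss (which the threshold rule guarantees on any input) and
  ≥ 90% FP removal on the generating sample; this was verified over 48
  profile × seed combinations (worst observed removal 93.5%).

Consequently, passing tests on these profiles demonstrates the machinery —
extraction, screening, selection, thresholding — not performance on real
reads: real feature distributions are uglier, correlated, and
platform-version dependent. The generators draw every parameter
independently within a class, which no real dataset does.

`generate_logistic()` is the recovery-test harness: covariates from stated
distributions, labels Bernoulli with probability `plogis(η*)` from stated
coefficients. `build_fixture()` emits mutually consistent FASTA, pileup,
VCF and truth files from a declarative spec, so feature extraction can be
checked against intended values exactly.

All generators take an explicit integer seed, use R's default
Mersenne-Twister stream, and restore the caller's RNG state on exit.

## Numerical and representational choices

* **Coordinates** are 1-based VCF convention everywhere, including the
  pileup table; a single convention removes a whole class of off-by-one
  errors.
* **Indel identity** for truth matching is `(chrom, pos, ref, alt)` after
  suffix/prefix trimming and (when a reference is supplied) left-alignment
  (`normalize_calls()`); representation differences otherwise manufacture
  spurious FP/FN pairs.
* **Multi-allelic records** are decomposed to one call per alt allele;
  AD-derived features use the ref and the focal alt depths only.
* **Coverage for the unspecific filter** uses INFO `DP`, falling back to
  the AD sum; a call with neither fails the coverage rule (depth unknown
  is treated as depth insufficient).
* **No covariate standardization**: raw scales enter the GLM so that
  coefficients are directly comparable with published linear predictors.
* **Report rounding** is half away from zero at 2 decimals, display-only;
  undefined ratios print as `/`. A summary with an empty truth set reports
  both sensitivity and PPV as undefined — with no true variants to find,
  precision against the panel is not a meaningful number.
* **AIC** is `2(k+1) − 2·logLik`, counting the intercept.

## Worked example

```{r example}
tbl <- generate_profile_table(platform_profile("iontorrent-indel", seed = 7))
model <- train_pipeline(tbl, platform = "IonTorrent")
glance(model)
tidy(model)

scored <- apply_model(model, tbl)
scored |>
  count(label, decision) |>
  tidyr::pivot_wider(names_from = decision, values_from = n, values_fill = 0)
```

The trained filter keeps every true positive (the threshold rule's
guarantee) and removes the overwhelming majority of artifacts. The
importance analysis on the same table ranks the strand-bias odds ratio
first, with homopolymer context among the leaders — the artifact axes built
into the profile:

```{r rvi}
importance <- rvi(tbl, candidates = c("HP", "SOR", "QD", "MQ", "VP_vcf", "DP"),
                  max_size = 3)
importance |> arrange(desc(normalized_rvi))
```

Six ready-made filters from the amplicon benchmark ship as
`amplicon_models()`; applied to a feature vector they reproduce the
published linear predictors exactly:

```{r published}
m <- amplicon_models()$snv_iontorrent
tidy(m)
apply_model(m, tibble::tibble(VP_vcf = c(0, 0.4)))[, c("p_hat", "decision")]
```

## Problem sizes used in the test suite

The suite fits its recovery simulations at n = 2000 (forward selection,
100 replicates), n = 5000 (coefficient recovery) and n = 250–400 (oracle
comparisons over 15-model spaces); the six profile tables range from 43 to
651 rows. These sizes make every statistical check decisive — recovery
rates sit at 100/100, oracle agreement at 1e-11 — while the whole suite
runs in well under a minute per file.

## Known limitations

* The calculated `SB`, `VP` and `HP` definitions are package policies;
  other tools' synonymous annotations will differ in detail.
* The coefficient-bound convergence proxy can reject legitimate fits on
  small-scale covariates (a published semiconductor SNV filter has a
  rank-sum coefficient of 20.6); raise `coef_limit` when covariates are
  bounded and genuinely strong.
* Truth matching is exact after normalization; complex substitutions that
  are neither trimmable nor left-alignable (e.g. `AT→GC`) must match
  verbatim.
* The pileup adapter classifies reads by exact ref/alt support at the
  anchored position; it does not realign, so alignment ambiguity around
  tandem repeats lands in the OTHER class.
* Training on very few true positives (the semiconductor indel profile has
  7) makes the threshold hostage to the single weakest TP; the two-threshold
  triage mode exists for exactly that situation.
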