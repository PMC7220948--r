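---
title: "Selecting minimal low-collinearity gene signatures with vifsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting minimal low-collinearity gene signatures with vifsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Expression-based outcome predictors (the motivating case is 5-year distant
metastasis in breast cancer) are often built from tens of genes chosen
purely for univariate association. Microarray and RNA-seq data are heavily
multicollinear — co-regulated genes carry nearly identical information — so
such signatures are larger than they need to be, their coefficients are
unstable, and they generalise poorly to independent cohorts. `vifsig`
implements a selection pipeline whose explicit goal is a *minimal* gene set
whose members are *mutually near-independent*, together with the repeated
random-split machinery needed to judge such a signature honestly.

## The pipeline

`fit_signature()` runs four stages on a genes × samples matrix of
normalised log-scale intensities with a binary outcome:

1. **Univariate screen.** Genes whose median intensity is below 5 (log2-like
   scale) in *both* outcome groups are discarded as unexpressed; the
   remaining genes are tested with a two-sided pooled-variance (Student's)
   t-test and kept at P ≤ 0.005. The "both groups" reading of the intensity
   filter is deliberate: a gene expressed in only one group is potentially
   the most informative kind, and removing it because one group's median is
   low would discard signal. A strict "either group" switch
   (`intensity_rule = "any"`) is provided. No multiplicity correction is
   applied — the 0.005 cut is a screening device, not an inference.

2. **SVM-RFE ranking.** The survivors are ranked by recursive feature
   elimination under a linear soft-margin SVM (cost C = 1): fit, remove the
   gene with the smallest squared weight, repeat. Genes are standardised to
   training mean 0 / sd 1 before fitting; without this the weight magnitudes
   of genes on different intensity scales are incomparable and the
   elimination order becomes an artefact of scale. Ties in w² are broken
   toward keeping the better screening p-value, and the linear solver is
   deterministic, so the ranking is exactly reproducible. The ranking is
   truncated to the top `rfe_count` (default 102) candidates, further capped
   below the sample count so the next stage's regressions stay well-posed.

3. **VIF-constrained forward selection.** Walking down the ranking, each
   candidate is tentatively added and the variance inflation factor
   VIF_j = 1/(1 − R²_j) of *every* member of the tentative set is
   recomputed; the candidate stays only if all VIFs remain below the
   threshold (default 10, the conventional multicollinearity alarm level).
   Re-checking the whole set on every addition is the only greedy variant
   that guarantees the final set satisfies its own bound, which is the
   property the report advertises; rejecting only on the candidate's own
   VIF does not. Exact collinearity (R² = 1 within 1e-12) is reported as an
   infinite VIF rather than a large number. Candidate sets approaching the
   sample count are refused (n ≤ p error) rather than silently regularised.
   A backward mode (drop the worst VIF until all pass) exists for
   comparison.

4. **Gene-count optimisation.** For every prefix of the decorrelated
   ranking, the k-fold (default k = 10, outcome-stratified)
   cross-validated AUC is computed with the working classifier. The first
   differences of this curve are sorted; the value at the top 25% boundary
   (rank ⌈0.25·n⌉ of the descending sort) is the threshold, and the chosen
   count is the **largest** count whose incoming difference still meets the
   threshold — the last point at which the curve is still gaining at a
   top-quartile rate. Two resolutions were needed to make this rule
   operational: the "differential values" are taken as plain first
   differences of CV-AUC over increasing counts, and a count must show a
   strictly positive gain to qualify, so that long flat plateaus (whose
   zero differences can fall inside the top quartile by rank alone) never
   drag the choice outward. When several differences tie at the threshold
   the largest qualifying count wins; when no difference is positive the
   curve never improves and the smallest count is returned.

The final model — multiple logistic regression by default, linear SVM and
random forest as comparators — is refit on all training samples with the
chosen genes. Unpenalised maximum likelihood can diverge under complete
separation; in that case the fit falls back to a vanishingly small ridge
penalty (λ = 1e-6) with a warning, which leaves non-degenerate problems
untouched to numerical precision but keeps separable ones finite.

## Validation protocols

`evaluate_signatures()` repeats (default 200×) a stratified random split —
approximately 2:1 train:validation, jointly stratified on outcome and the
ER-status-like stratum when present — refits each signature's model on the
training portion and collects validation AUCs. AUC is computed by the
Mann-Whitney identity (ties ½), arms share identical splits (pairing
reduces comparison variance), distributions are summarised by median,
quartiles and a percentile 2.5–97.5% interval, and arms are compared by a
two-sided Mann-Whitney test (which treats the lists as unpaired, matching
the convention in this literature).

Two external-validation designs are provided by `external_validate()`:

* **exp1** — only the gene list transfers: the external cohort is itself
  repeatedly split and the model refit there. This isolates the
  generalisability of the *selection*.
* **exp2** — the fitted model transfers: both datasets are first Z-scored
  per gene on all of their own samples, the discovery cohort is repeatedly
  split, and each fitted model is scored on the entire external cohort.
  Z-scoring is computed on the full dataset rather than per split: no
  outcome labels are involved, so this leaks nothing into selection, and it
  matches how a fixed signature would be deployed on a new cohort.

One property worth knowing when interpreting exp2: for a *linear* scorer
(logistic regression, linear SVM) the AUC is mathematically invariant to
any per-gene additive shift of the external data, because each gene's shift
adds the same constant to every sample's score. Pure location batch effects
therefore cannot hurt a linear signature's external AUC, with or without
Z-scoring; what Z-scoring protects against is scale distortion and, far
more importantly, location sensitivity in nonlinear models such as random
forests, whose split thresholds are calibrated on the training scale. The
package's batch-effect tests accordingly use the random-forest comparator,
where the phenomenon is visible.

## The synthetic study conditions

`generate_expression()` emulates the data structure this method assumes,
with defaults fixed once as the package's reference study: 150 samples at
35% outcome prevalence (matching the relapse fraction of typical breast
cancer discovery cohorts), 5 informative genes whose group means differ by
1.0 baseline sd (a strong-marker effect: two-sample t power ≈ 1 at
α = 0.005 at this n), 10 equicorrelated decoy blocks of 5 genes at
ρ = 0.9 built from a shared latent factor (x = √ρ·f + √(1−ρ)·ε, exact
target correlation in expectation), 2000 independent null genes of which
10% are centred at intensity 3 to exercise the "< 5" filter, all on a
log2-like scale centred at 8, and an ER-like stratum drawn independently of
outcome so stratification is testable without confounding.
`generate_pair()` adds a cross-study batch effect to a second, independent
draw: a per-gene location shift N(0, `batch_shift_sd`²) plus a mild
log-normal scale jitter (sd 0.1).

What this generator does *not* emulate — and what green tests on it
therefore do not demonstrate — includes probe-level noise, heavy-tailed and
skewed intensity distributions, gene–gene correlation beyond block
equicorrelation, outcome-correlated strata, and censoring of the 5-year
endpoint. Results on real cohorts depend on all of these.

## Numerical and design notes

* Z-scores and all standardisations use the unbiased (n−1) sd; the choice
  cancels in rank- and VIF-based computations.
* Per-repeat and per-fold seeds are derived from the master seed by a
  Lehmer-style mixing map, so every run is bit-reproducible end to end and
  seeds stay valid 32-bit integers.
* Ties: screening p-value ties keep matrix row order; RFE w² ties keep the
  better-screened gene; count-rule ties resolve to the largest qualifying
  count. All three make the pipeline deterministic.
* The RFE truncation count feeding the VIF stage is an explicit,
  documented parameter (`rfe_count`, default 102) rather than a hard-coded
  constant, because the right value is data-dependent.
* Degenerate inputs fail loudly by design: zero-variance genes, single
  strata, single-class folds, candidates ≥ samples, and signature genes
  missing from external data are all named errors, never silent repairs.

Problem sizes in the test-suite simulations (e.g. 25 replicates of the
150 × 2055 reference study for recovery; 20 replicates for batch-effect
transfer) were chosen as the smallest sizes at which the properties under
test are statistically resolvable.

## Known limitations

* With ~15–20 screened candidates at n = 150, null genes that survive a
  P ≤ 0.005 screen have selection-inflated effect sizes and can interleave
  with genuinely informative genes in the RFE ranking; the top-quartile
  count rule is deliberately parsimonious, so a planted 5-gene truth is
  typically recovered only in part. This is a property of the method under
  these conditions, not an implementation artefact.
* The count rule's behaviour depends on how many candidates survive VIF
  selection (more candidates → more differences → a lower top-quartile
  threshold → larger chosen counts).
* Univariate screening before multivariate ranking can discard genes that
  are informative only in combination.
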