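---
title: "Methods: deconvolution-based differentiation indexing of methylomes"
author: "methyldecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deconvolution-based differentiation indexing of methylomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methyldecon)
```

## The problem

Bulk DNA methylation of a purified tumor cell population carries the imprint
of the normal differentiation program the tumor arose from. In B-cell
malignancies such as chronic lymphocytic leukemia, tumors resemble either
naive or memory B cells to varying degrees, and the clinically used binary
subtyping (by *IGHV* germline identity) discards the continuum in between.
This package treats reference-based cell-type deconvolution — built to
quantify *mixtures* of discrete cell types — as a read-out of *intermediate
differentiation state* in a purified population, and provides the
surrounding statistical machinery to validate and interpret that read-out.

## Constrained projection and the B-Index

Given a reference library of mean beta values $\beta^{ref}_{i,k}$ (CpG $i$,
cell type $k$) and a sample profile $y$, the projection step solves

$$\hat p = \arg\min_{p \ge 0} \lVert y - X p \rVert^2$$

with $X$ the CpG-by-cell-type reference matrix. `nnls_fit()` implements the
Lawson–Hanson active-set algorithm: deterministic, no random
initialization, exact at convergence. We deliberately impose only
non-negativity inside the solver; proportions are normalized to sum to one
*afterwards* (`deconvolve()`), which makes an in-solver sum constraint
immaterial to the reported proportions.

The B-Index restricts the library to the two endpoint types (memory-like
and naive-like B cells), ranks CpGs by the absolute reference difference
$|\beta^{ref}_{mem} - \beta^{ref}_{nv}|$ (ties broken by CpG identifier so
the ranking is total and reproducible), projects each sample onto the top
$n$ CpGs, and rescales:

$$B = \frac{\max(0, \hat p_{mem})}{\max(0, \hat p_{mem}) + \max(0, \hat p_{nv})}$$

so 0 is fully naive-like and 1 fully memory-like. The clamp at zero is
redundant with a non-negative solver but kept so the formula, not the
solver, defines the estimator. The default $n = 400$ is where per-sample
index trajectories stabilize as CpGs are added in decreasing order of
reference difference; `stabilization_curve()` recomputes the index over a
grid of nested prefixes of one fixed ranking, so successive grid points
differ only by the CpGs appended — this nesting is a design choice that
makes the curve interpretable as "information added", rather than
re-ranking per grid size. A sample whose two raw coefficients are both zero
has an undefined index and is reported as `NA`, never silently 0.

On noiseless two-reference mixtures the index equals the mixing weight
exactly for any weight in $[0, 1]$; on per-CpG bimodal intermediate-state
samples it estimates the fraction of informative CpGs in the memory state.
Both properties are asserted in the test suite.

## Mixture or intermediate state?

A bulk profile with $\hat p_{mem} = 0.6$ could be (a) a physical mixture of
two populations, or (b) a single population whose individual CpGs each sit
in one of the two pure states. The diagnostic (`run_mixture_diagnostic()`)
separates these: for the tertile of samples with the lowest memory
proportion (size $\lceil n/3 \rceil$, ties at the boundary broken by sample
identifier), it builds each sample's *expected mixture profile*

$$\tilde\beta_i = \sum_{k=1}^{K} p_k\, \beta^{ref}_{i,k}$$

from the sample's full $K$-type proportion vector (all reference types, not
just the two B-cell columns, since non-B contamination also contributes to
a true mixture), and at the top 100 most differential CpGs tallies each CpG
to whichever of {expected mixture, pure memory, pure naive} is closest in
absolute difference. Under hypothesis (a) betas concentrate at
$\tilde\beta_i$; under (b) they concentrate at the pure values, which at
informative CpGs are far from $\tilde\beta_i$. The summary statistic is the
pure fraction per sample.

Exact ties between the three distances have no stated convention anywhere;
we assign them with precedence mixture > pure-memory > pure-naive — i.e.
conservatively *in favor of* the mixture interpretation — and expose the
order as an argument. Ties occur with probability zero under continuous
noise, so the choice only matters for constructed inputs.

## The EWAS engine

Association studies are run on M-values, $M = \log_2(\beta / (1 - \beta))$,
whose variance is far more homogeneous across the $[0,1]$ beta range.
Betas are clipped to $[\varepsilon, 1 - \varepsilon]$ with
$\varepsilon = 10^{-6}$ before the transform so boundary values stay
finite; the inverse transform is exact away from the clip boundary.

`build_design()` produces the fixed design: intercept, variable of
interest, mean-centered age, sex coded 0/1 against the first sorted level
(recorded in an attribute). Zero-variance adjusters are dropped with a
warning; residual collinearity is an error naming the columns. Every CpG
is then fit by one shared QR decomposition (`fit_linear_models()`).

Residual variances are moderated empirically (`ebayes_moderate()`). With
$d$ residual degrees of freedom and $e_g = \log s^2_g - \psi(d/2) +
\log(d/2)$, the scaled inverse-chi-square prior $(d_0, s_0^2)$ is fit by
moment matching:

$$\psi'(d_0/2) = \mathrm{var}(e) - \psi'(d/2), \qquad
  s_0^2 = \exp\{\bar e + \psi(d_0/2) - \log(d_0/2)\},$$

inverting the trigamma by Newton iteration (monotone, so the solution is
unique). When $\mathrm{var}(e) \le \psi'(d/2)$ — no more dispersion among
log-variances than a common variance would produce — the prior is
degenerate: $d_0 = \infty$ and every posterior variance equals
$\exp(\bar e)$. Otherwise

$$\tilde s^2_g = \frac{d_0 s_0^2 + d\, s^2_g}{d_0 + d},$$

the moderated $t$ uses $\tilde s_g$ with $d_0 + d$ degrees of freedom, and
two-sided p-values follow. Setting `d0 = 0` disables moderation and
reproduces ordinary per-CpG OLS t-tests exactly (a tested identity).
Exact-fit rows ($s^2 = 0$) would break the log-variance moments; they are
replaced by the smallest positive $s^2$ times $10^{-6}$ and flagged.
Parameter recovery under the prior's own generative model (5,000 CpGs,
$n = 20$) is part of the acceptance suite.

FDR is always Benjamini–Hochberg over *all* CpGs entering the model, never
within the hyper/hypomethylated subsets; the subsets are formed afterwards
by the sign of $\Delta M$, optionally intersected with a beta-scale effect
threshold. The beta-scale effect is

$$\Delta\beta = \frac{2^{\beta_0+\Delta M}}{1+2^{\beta_0+\Delta M}} -
  \frac{2^{\beta_0}}{1+2^{\beta_0}},$$

the change in methylation fraction implied by moving from the model
intercept by the fitted effect — bounded in $(-1, 1)$ and strictly
increasing in $\Delta M$.

## Equivalence testing

Similarity claims need more than a failure to reject difference;
`tost_two_sample()` implements the two-one-sided-tests procedure with a
beta-scale margin ($\varepsilon = 0.1$ by default, i.e. a tolerated
$\pm 0.1$ difference). We use the Welch (unequal-variance) construction by
default since case and reference groups differ in size and dispersion; a
pooled-variance mode is available. The TOST p-value is the larger of the
two one-sided p-values, so at a true difference exactly on the margin one
statistic is 0 and $p \ge 0.5$: equivalence can never be concluded at the
boundary, and never at all as $\varepsilon \to 0$. When both groups are
constant and the difference lies strictly inside the margin the limiting
p-value is 0; it is returned as 0 with a `degenerate` flag rather than
`NaN`.

The screen (`run_tost_screen()`) applies BH-FDR separately per reference
over all CpGs entering the screen — the prefilter (differentially
methylated CpGs between the two references at FDR < 0.05 and
$|\Delta\beta| > 0.2$) defines the family. The contingency summary of
equivalent CpGs needs a per-CpG methylation "state" for the cases; no
convention exists for this, so we call a CpG hypomethylated when the case
mean is below the midpoint of the two reference means at that CpG. CpGs
equivalent to both references are excluded from the table and counted
separately. `manhattan_similarity()` provides the prefilter-free
complement: whole-profile L1 distance to each reference mean.

## Enrichment tests

Chromosome enrichment uses two-sided Fisher's exact tests, with the
two-sided p defined as the sum of hypergeometric outcome probabilities no
larger than the observed one (the convention of `fisher.test`; other
two-sided definitions exist, hence the explicit statement). TFBS
enrichment is one-sided (`greater`). Island-context enrichment is a
Cochran–Mantel–Haenszel test stratified by Illumina probe type; genomic
context is CMH stratified by island context — in both cases the stratifier
is a known confounder of the feature's marginal distribution. No
continuity correction is applied (a flag exists). The CMH statistic uses
the hypergeometric mean and variance per stratum; in the single-stratum
case this is the Mantel–Haenszel chi-square of that table, which carries
the finite-population $(n-1)/n$ factor relative to the Pearson statistic —
the tests pin down both identities.

Odds ratios are the sample cross-product $(ad)/(bc)$ with the
Haldane–Anscombe 0.5 added to every cell only when a cell is zero (the
exact p is unaffected); a table with a zero *margin* has no defined odds
ratio and is flagged `NA`. CIs are Woolf (single table) and
Robins–Breslow–Greenland (Mantel–Haenszel). FDR is computed across the
features tested within one axis run. Forest-plot columns are exported in
log2 space.

Genomic context is collapsed to one label per CpG by the precedence
Promoter > 5'UTR > 3'UTR > Exon > Intron, with CpGs mapping to nothing
labeled Intergenic. Promoter windows span 1,500 bases upstream to 200
downstream of the strand-aware TSS.

## Classification metrics

`roc_auc()` computes AUC from the rank statistic with ties counted one
half, so it is invariant to strictly increasing transforms of the score.
Cutoff conventions are not standardized across implementations, so the
package fixes them: candidate cutoffs are the observed score values plus
$-\infty$; a sample is predicted positive strictly above the cutoff; the
Youden cutoff is the *smallest* maximizer of TPR − FPR. The Wilcoxon
rank-sum test is two-sided without continuity correction, exact (full
permutation null) when both groups have at most 50 observations and no
ties, and the tie-corrected normal approximation otherwise.

## What the synthetic generator emulates — and what it does not

All fixtures are generated in code (`synth_config()` and the `make_*`
functions), fully deterministic per seed with no global RNG state
leakage. The generators realize exactly the structures the methods assume:

* **Reference pairs** with informative CpGs whose absolute difference is
  drawn around the target gap (sd 0.05) with random direction about a
  midpoint in $[0.4, 0.6]$, and a shared bimodal background elsewhere
  (mixtures of Beta(2,10) and Beta(10,2), mimicking the usual
  near-0/near-1 methylation landscape). Default gap 0.5: large enough to
  be informative, small enough that noise matters.
* **Intermediate cohorts**: each informative CpG independently in the
  memory state with probability $w$; **mixture cohorts**: per-CpG weighted
  averages. Per-sample weights default to a bimodal mixture of normals at
  0.45 and 0.9 (sd 0.08, truncated to $[0,1]$), echoing the two clinical
  subtype modes without copying any cohort's values.
* **Noise** is normal on the beta scale, clipped to $[0, 1]$ (default sd
  0.02, a typical array replicate error); an M-scale (logit-normal) route
  exists implicitly via `beta_to_m()` for EWAS cohorts, which are
  generated directly on the M scale with scaled inverse-chi-square
  variances — the moderation prior's own model.
* **Donor groups and cases** for the equivalence screen, with a planted
  fraction of CpGs tracking one reference; **annotation tables** with
  independent categorical marginals and one TFBS feature planted at a
  configurable membership fold.

Deliberately *not* emulated: probe-type-specific beta-distribution shifts,
batch and dye effects, spatial correlation along the genome, SNP-affected
probes, and cell-type label noise in the reference. Passing tests
therefore show the estimators are correct under their assumed generative
structure, not that real arrays satisfy those assumptions — the upstream
normalization steps that justify them are out of scope here.

## Numerical choices and problem sizes

* `clip_eps = 1e-6` for the beta–M transform (nothing in the field fixes
  how exact 0/1 betas are handled; clipping keeps M finite and the
  transform invertible on the interior).
* NNLS dual-feasibility tolerance scales with the matrix magnitude;
  coefficient ties cannot occur (the active-set path is deterministic).
* File output at 10 significant digits; comma vs tab inferred from the
  extension.
* Degenerate results are `NA` + flag, never a silent 0: undefined
  proportions, undefined B-Index, zero-margin odds ratios, all-degenerate
  CMH strata.
* Test and acceptance simulations use cohorts of 600–700 CpGs, 2–40
  samples, and 20–200 seed replicates per property, with 5,000-CpG
  simulations for the moderation-prior recovery — sizes chosen so each
  property's sampling error is well below its asserted tolerance while the
  whole suite remains quick to run on one core.

## Known limitations

* The index presumes the two endpoint references bracket the biology; a
  sample resembling a third, absent cell type loads arbitrarily on the two
  columns. Running the full multi-type deconvolution first (as the
  diagnostic module does) is the guard.
* Equal-gap ranking by $|\Delta\beta|$ uses reference means only; a
  variance-aware ranking would need per-cell-type dispersions, which mean
  reference libraries do not carry.
* The EWAS engine fits one variable of interest plus adjusters; contrast
  systems, surrogate variables, and array weights are out of scope.
* The 0.60 classification cutoff shipped as a default is a convention
  inherited from the index's original clinical application, not a
  recommendation; `youden_cutoff()` rederives a cutoff from any labeled
  cohort.
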