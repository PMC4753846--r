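---
title: "Methods: activity calling and differential expression in tissue-resolved root RNA-Seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activity calling and differential expression in tissue-resolved root RNA-Seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery:
the generative model behind the synthetic data, the hierarchical activity
model and its approximations, the differential-expression pipeline, and the
design decisions taken where more than one reasonable construction existed.

## The experimental design

The workflow targets a 4-tissue (meristematic zone, elongation zone,
cortex, stele) by 2-treatment (control, water deficit) design with `R`
biological replicates per combination, whose `8 R` sequencing libraries are
pooled onto flow-cell lanes of `libraries_per_lane` libraries each. Each
lane is an incomplete block: it cannot carry all 8 tissue–treatment
combinations of all replicates, so lane-level artifacts partially confound
biological contrasts and must be modelled, not ignored. `generate_design()`
uses a deterministic cyclic construction (seed-derived rotations within
each replicate) so that, whenever a lane fits inside a replicate, no lane
carries two replicates of the same combination.

## The generative model

`simulate_counts()` draws, for gene $g$ and sample $s$,

$$ y_{gs} \sim \mathrm{NB}\big(\mu_{gs},\ \phi_g\big), \qquad
   \log \mu_{gs} = o_{gs} + \beta_{g,\mathrm{cell}(s)} + u_{\mathrm{lane}(s)}
   + e_{g,\mathrm{rep}(s)}, $$

with $\mathrm{Var}(y) = \mu + \phi\mu^2$. The pieces:

* **Fixed effects** $\beta_{gk}$, one per tissue–treatment cell, on the
  natural-log reads-per-million scale. Control-cell effects are iid
  $N(m_k, v_k)$ draws. Deficit-cell effects are *tied* to their control
  counterparts: $\beta_{g,k+4} = \beta_{g,k} + (m_{k+4}-m_k) +
  \log(2)\,\mathrm{lfc}_{g,t}$. The tie is deliberate: it makes every gene
  without a planted effect an exact null for the treatment contrast, which
  the differential-expression calibration checks require. The cost is that
  the deficit-cell population variances equal the control-cell ones (the
  configured deficit variances are ignored); the moment-recovery tests
  assert accordingly.
* **Dispersion** $\log \phi_g \sim N(\mu_\phi, \sigma^2_\phi)$, constant
  within a gene. Default $\mu_\phi = \log 0.1$, a typical bulk RNA-Seq
  biological coefficient of variation of about 0.3.
* **Lane effects** $u_\ell$: one draw per lane, shared by every gene —
  a sequencing artifact, not biology. Their precision is drawn from a
  gamma. The configuration default is Gamma(50, 0.5) (mean precision 100,
  lane sd about 0.1): a *realistic* lane artifact. A vague gamma such as
  Gamma(0.01, 0.01) is the right *prior* for inference, but drawing a
  generative precision from it produces absurd data (the implied
  lane-effect variance has no finite mean), so the generator and the model
  prior intentionally use different gammas.
* **Replicate effects** $e_{gr}$: per gene and replicate id, shared across
  the 8 cells within a gene, with per-gene precision
  $\tau_g \sim \Gamma(a, b)$ (default mean variance $b/(a-1) \approx
  0.011$). Making them gene-specific is the reading under which the gamma
  hyperparameters of the replicate precision are estimable by empirical
  Bayes across genes.
* **Offsets** $o_{gs}$ combine the recorded library size (log-normal around
  `mean_library_size`, default $10^6$ — all downstream statistics are scale
  free), a centred length/GC trend (default: slope 1 in log length, a mild
  concave quadratic in GC), and a **read-competition** term: sequencing
  depth is fixed, so a sample whose transcript mass grows (say, by induced
  genes under deficit) yields proportionally fewer reads per transcript.
  The per-sample fixed-effect mass is renormalised, centred at its
  geometric mean so that the reads-per-million interpretation of $\beta$ is
  preserved. Without this term there is no composition effect in the data
  and TMM normalization would *introduce* a fold-change bias rather than
  remove one. Lane and replicate effects stay outside the renormalisation:
  they act as depth errors relative to the recorded library size, which is
  exactly what makes them estimable downstream.

Ground truth records `truly_active` ($\beta$ above the activity threshold,
default $\log 2$) and the planted per-tissue log2 fold changes. A
`min_separation` option reflects effects out of a dead zone around the
threshold for recovery studies whose truth must be unambiguous.

**What the generator does not emulate:** read-level error, positional
coverage, isoforms, PCR duplicates, genuinely correlated fixed effects
across cells, outlier samples, and annotation errors. Passing tests
therefore demonstrate correctness of the statistical machinery under the
model's own assumptions, not robustness to every artifact of real
libraries.

## Normalization

`tmm_factors()` implements trimmed-mean-of-M-values scaling: pairwise
against an automatically chosen reference (the sample whose
75th-percentile count fraction is closest to the across-sample mean),
excluding zero-count genes pairwise, trimming 30% two-sided on M and 5% on
A, and averaging with inverse delta-method variances. The reference's
factor is exactly 1. `fit_covariate_smoother()` is a two-dimensional local
*linear* regression (tri-cube weights, `stats::loess`, default span 0.5) of
log mean raw count on GC fraction and log length; local linear was chosen
as the weakest assumption matching a "smoother", and the span is
configurable because a strongly curved GC effect is slightly underfit at
0.5. `compose_offsets()` adds the per-sample term (log effective library
size, centred at its geometric mean) to the per-gene fitted value. The
smoother is fit on the across-sample mean, so the covariate term is
sample-independent by construction.

## The activity model

Hyperparameters are estimated by empirical Bayes in `estimate_hyperparameters()`:

1. **Lane absorption.** Realized lane effects are shared by all genes, so
   cell-centred log residuals averaged across genes estimate them almost
   exactly; they are absorbed into the offsets before any per-gene fit.
   The inverse variance of the absorbed effects is kept as a plug-in lane
   precision; the model-side lane prior stays vague (Gamma(0.01, 0.01)).
2. **Fixed-effect moments.** Per-gene ML cell means (vectorized Newton with
   a Cox–Reid-adjusted dispersion profile) are pooled per cell by maximum
   likelihood under $\hat\beta \sim N(m, v + \mathrm{se}^2)$, which
   downweights the enormous sampling variances of near-zero-count cells
   instead of letting them corrupt raw moments.
3. **Dispersion population.** A profile log-likelihood of $\log\phi$ on a
   grid (−7 to 3, step 0.25) is computed for every gene, and the normal
   population $(\mu_\phi, \sigma^2_\phi)$ maximises the sum of log marginal
   likelihoods through that grid. A Gaussian summary of the per-gene MLE is
   not good enough here: the estimation error correlates with the true
   value, which breaks naive deconvolution. Because the per-gene replicate
   effect inflates apparent dispersion by roughly its variance, the fitted
   population is mapped back through $x \mapsto \log(e^x + s)$ by
   Gauss–Hermite moment matching, with $s$ the estimated mean replicate
   variance.
4. **Replicate precision.** Per-gene variance components from
   expected-mean-square equations on log residuals of well-measured genes
   (every cell mean ≥ 5 reads, where the log-linear approximation holds;
   the replicate-precision population is gene-independent, so the subset is
   unbiased), fit to an inverse-gamma by moments with a sampling-noise
   correction. With 4 replicates per gene the gamma *shape* is weakly
   identified; the mean variance is the reliably recoverable quantity.

`gene_posterior()` approximates each cell's marginal posterior by the
nested-Laplace construction: a joint Newton mode over (8 fixed effects,
lane effects, replicate effects) with the replicate precision updated at
its conditional posterior mode, then — for any cell whose plain Gaussian
exceedance is not already decisive (|z| < 5) — a profile
(Tierney–Kadane) marginal: the fixed effect walks a grid of ±6 posterior
sd in steps of 0.5 sd, nuisance parameters are re-maximised at each point
(warm-started reduced Newton), the Laplace log-determinant correction is
applied, and the one-dimensional density is integrated numerically. A
single mode/curvature Gaussian is *not* sufficient: at low counts the
posterior is visibly skewed, and its plain-Laplace exceedance errs by up to
0.06 (third-order Edgeworth corrections make it worse); the profile
marginal brings the worst error against dense quadrature below 0.02, the
tolerance the test suite enforces. Dispersion is plugged in at its
empirical-Bayes shrunken value rather than integrated; the quadrature
oracle bounds the damage.

`calibrate_threshold()` root-finds T so that a pseudo-gene with average
covariates in an average library sits exactly at exceedance probability 0.5
when its expected coverage equals `target_rpm` (default 2) reads per
million. `activity_boundary()` inverts any T back to an expected-count
boundary, which also yields per-gene effective thresholds (higher for
longer genes when the length trend is positive). Calls use the strict rule:
exceedance exactly 0.5 is inactive.

## Activity patterns

`classify_pattern()` is pure set algebra on the per-condition active-tissue
sets; the number of activity-status changes is the symmetric difference
(0–4). Genes active in no cell form their own `never_active` category and
are excluded from active-gene denominators. The category system is an exact
partition, verified exhaustively over all 256 set pairs.

## Differential expression

After the minimum-count filter (≥ `min_count` = 5 in *every* replicate of
at least one tissue × treatment group — the stricter group-level reading,
configurable), counts are transformed to
$\log_2((y + 0.5)/\tilde N_s \times 10^6)$ with $\tilde N_s$ the
TMM-scaled library size. Observation weights are the inverse fourth power
of a lowess trend of $\sqrt{\mathrm{sd}}$ on average log expression,
evaluated at each observation's fitted value.

Before the per-gene model, the cross-gene estimate of the realized lane
effects is removed from the logged matrix (default `adjust_lanes = TRUE`).
With thousands of genes those effects are estimable almost exactly, and
leaving them in imposes a common shift on an entire contrast family — a
shared bias no per-gene model can remove. The residual within-lane
correlation (driven by replicate pairing and any unremoved lane variation)
is then estimated by quadratic-form moment equations that target the
*same-lane covariance* directly: with lanes nested inside replicates, a
naive lane-variance decomposition double-counts the replicate contribution.
Per-gene correlations are combined on the Fisher-z scale.

Contrasts (deficit − control per tissue) come from per-gene weighted
generalized least squares under the common correlation; residual variances
(24 df at 4 replicates) are moderated by a scaled inverse-chi-square prior
fit by moments of log variances (the trigamma-inversion construction);
moderated t statistics use $d_0 + d_g$ degrees of freedom, two-sided
p-values, and Benjamini–Hochberg q-values within each tissue's contrast
family (the correction is applied per contrast). `select_responsive()`
applies q < 0.01 and |log2FC| ≥ 1 and summarises per-tissue counts,
direction, multi-tissue overlap and direction consistency.

Two calibration caveats, both visible in the test suite's constructions:
the $\log_2(y + 0.5)$ transform attenuates fold changes at low counts
(unbiasedness is asserted in the regime where all group means are ≥ 64
reads, averaged over three independent experiments, because a single
experiment's contrast mean carries shared normalization noise of about
0.05 log2 units); and the lane-only random-block structure deliberately
ignores replicate pairing, which leaves a mild conservative tilt in the
middle of the null p-value distribution — the same tilt the established
precision-weighted moderated-t implementation shows on identical data.

## Enrichment

`fisher_enrichment()` computes one-sided hypergeometric upper tails per
category against the expressed-gene background (unannotated genes count in
the totals), with BH adjustment by default and a Benjamini–Yekutieli
switch. Annotation is taken as already propagated; no ontology closure is
performed. `chisq_distribution_test()` compares observed responsive-gene
counts over a fixed partition with expectations from background
proportions; per-category flags use standardized residuals with a
one-sided normal reference at 0.05, and zero-expectation categories are
merged into `other`.

## Diagnostics and pipeline

`sample_distances()` computes pairwise root-mean-square distances over the
top-k (default 500) largest squared log2 differences — the leading fold
change — then average-linkage clustering (Newick export via `ape`) and
classical MDS. `run_pipeline()` chains the stages, validates inputs
strictly (duplicated ids, missing design cells, negative counts all error
with locations), writes deterministic TSVs plus a manifest of input MD5s
and the seed, and reproduces byte-identical outputs under an identical
configuration.

## Numerical choices

* Newton iterations clamp steps (±3 on cell means, ±2 in profile inner
  loops) and use step halving against the exact objective; convergence at
  step < 1e−9 (joint mode) / 1e−7 (profile); bounded jittered restarts, and
  a flagged prior-tail fallback for genes that still fail.
* $\log(1/\phi)$ is bounded in [−12, 7]; dispersion grids span
  $\log\phi \in [-7, 3]$.
* Root finders (`uniroot`) run at tolerance 1e−10 on brackets of ±10
  posterior sd (threshold) and $[10^{-6}, 10^8]$ on the count scale
  (boundary inversion).
* Marginal grids: ±6 sd, step 0.5 sd (profile); ±10 sd, step 0.1 sd
  (one-cell calibration posterior); trapezoid integration with linear CDF
  interpolation.
* Ties in BH ranking are handled by `stats::p.adjust`; p-values at exactly
  the boundary of a selection rule are excluded by strict inequalities.
* Degenerate inputs error early and by name: all-zero samples in TMM,
  constant covariates in the smoother, empty DE sets, multi-assigned
  partition genes, rank-deficient designs.

## Problem sizes used by the test suite

Monte-Carlo checks run at the sizes the methods were designed for: 10,000
parameter draws for moment checks, 5,000-gene simulations for
hyperparameter recovery and activity sensitivity/specificity, 2,000-gene
simulations for differential-expression calibration, 100 random instances
for the posterior quadrature oracle, and exhaustive enumeration (256 set
pairs; hypergeometric margins to 200) where the space is finite.

## Known limitations

* The posterior machinery is approximate; its error bound (0.02 on
  exceedance probabilities) is enforced only on the no-random-effect
  instances the oracle can integrate exactly.
* Dispersion and random-effect precisions are plugged in, not integrated;
  extremely low-count genes inherit prior-driven calls.
* The gamma shape of the replicate-precision hyperprior is weakly
  identified at 4 replicates; treat it as a nuisance, not an estimate.
* TMM assumes most genes are not differentially expressed; at planted DE
  fractions approaching one half the composition correction itself becomes
  the dominant error source.
* Activity truth in the generator is a threshold on the fixed effect; real
  "presence" of a transcript is a biological notion this cannot capture.
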