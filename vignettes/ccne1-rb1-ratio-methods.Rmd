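---
title: "Models and methods behind the CCNE1/RB1 ratio analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the CCNE1/RB1 ratio analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbratio)
```

## The scientific problem

CDK4/6 inhibitors such as palbociclib arrest hormone receptor-positive
breast cancer cells by preventing Rb phosphorylation, which keeps E2F
transcription factors repressed. Acquired resistance is near-universal, and
in conditioned-resistant cell-line models two lesions recur together:
up-regulation of cyclin E1 (*CCNE1*), which reactivates CDK2 downstream of
the blocked kinase, and loss of Rb (*RB1*). `rbratio` packages the
computational analyses used to characterise that phenotype and to evaluate
the *CCNE1*/*RB1* expression ratio as a resistance and prognosis biomarker:

1. intra-cell-line log2 fold-change (FC) normalization of expression
   profiles, with detection filtering and signal-to-noise probe collapse;
2. the RBsig loss-of-Rb-function signature score;
3. a pre-ranked, weighted Kolmogorov–Smirnov enrichment score for E2F
   targets with gene-permutation FDR;
4. 4-parameter logistic (4PL) dose–response fitting and IC50 inversion;
5. droplet digital PCR (ddPCR) copy-number calling via Poisson occupancy;
6. biomarker evaluation: correlation screens against drug IC50 panels,
   ROC/AUC discrimination of resistant patients, and Kaplan–Meier /
   log-rank / hazard-ratio survival stratification.

Every stage runs on synthetic data with known ground truth, generated by
the package itself, so the full pipeline is testable offline.

## Fold-change normalization and gene selection

Cell-line identity dominates expression profiles: hierarchical clustering
groups samples by line, not by treatment state. The remedy is to express
each treated or resistant sample as a log2 ratio to the matched untreated
parental (PDS) sample of the same line,

$$\mathrm{FC}(g, s) = \log_2 x_{g,s} - \log_2 x_{g,\mathrm{PDS}(s)},$$

which removes any per-line additive offset on the log scale exactly (a
property the test suite asserts). Detection filtering keeps genes with a
detection p-value < 0.05 in at least one sample (strict inequality);
multiple probes per gene are collapsed to the probe with the highest
signal-to-noise ratio, defined here as mean/SD across all samples, with a
zero SD treated as infinite SNR and ties broken by input order — the SNR
definition is ours, since bead-array software does not document one.
"Top variable" genes are the top quantile by SD of FC across treated and
resistant columns (``ceiling(q * n)`` genes), intersected with genes whose
|mean FC| across resistant columns exceeds a threshold (default 0.2 log2
units). Whether the quantile cut precedes or follows the effect filter is
ambiguous in the source procedure; we implement the intersection, which is
order-independent.

## RBsig score

For each signature gene $i$, the median $\bar g_{i}$ and raw median
absolute deviation $\mathrm{mad}(g_i)$ of expression are estimated over the
untreated reference samples; a sample $j$ then scores

$$\mathrm{RBsig}_j = \frac{1}{N}\sum_i
  \frac{g_{ij} - \bar g_{i}}{\mathrm{mad}(g_{i})}.$$

The MAD is deliberately unscaled (no 1.4826 consistency constant): the
formula is a literal median of absolute deviations. A `mad_constant`
argument allows the conventional scaling as a sensitivity check. Genes with
zero reference MAD are excluded with a warning rather than epsilon-floored,
keeping the formula literal. Whether scores are computed on log2 or linear
expression is a documented caller choice (`expr_mat` carries a scale flag);
the qualitative treated < resistant < untreated ordering holds on either
scale in the simulations.

## Enrichment score and permutation FDR

The pre-ranked GSEA statistic on a ranking of $N$ genes by averaged FC:
walking down the list, set genes increment the running sum by
$|r_g|^p / N_R$ (with $N_R$ the sum over set genes), non-set genes
decrement by $1/(N-m)$; the enrichment score (ES) is the signed maximum
deviation. $p = 1$ is the classic weighting, $p = 0$ the unweighted KS
statistic; a metric of exactly 0 contributes zero hit weight under $p = 1$.
Because the ranking is a single averaged-FC vector, there are no sample
labels to permute, so significance uses gene-set permutation: `n_perm`
random same-size sets drawn without replacement. The permutation p-value is
one-sided within the observed ES sign with the add-one convention
$(r+1)/(n_{\mathrm{perm}}+1)$ — under the null it is approximately uniform
on $(0, \tfrac12]$, which the calibration test checks on the doubled
p-value. NES divides ES by the mean |null ES| of the same sign, and the FDR
is the same-sign null-NES tail fraction truncated to $[0,1]$. Ties in the
metric are broken by input order, deterministically, and a fixed seed makes
the whole computation reproducible.

On the default synthetic panel the treated-state ranking gives a strongly
negative E2F-target ES with FDR < 0.05, and *CCNE1* is the top up-regulated
E2F-set gene on the resistant ranking — the package's qualitative
reproduction of the biology it models.

## Dose–response model

Raw viability signals are anchored between time-zero and vehicle controls,
$y_p = (y - T_0)/(\mathrm{vehicle} - T_0)$, and fitted with

$$f(x) = B + \frac{T - B}{1 + 10^{\,s\,(\log_{10} x - \log_{10} x_{mid})}}$$

by Levenberg–Marquardt least squares, with data-driven starts and up to
five seeded jittered restarts. The vehicle (dose 0) never enters the fit —
log dose is undefined there — and only anchors the transform. The IC50 is
the dose where $y_p$ crosses 0.5, obtained by closed-form inversion; note
this is *not* the curve's inflection unless $B = 0,\ T = 1$. Levels outside
$(B, T)$ return a censored bound relative to the tested dose range.
`weighting = "residual"` is a two-stage fit with weights
$w_i = 1/\max(r_i^2, 10^{-6})$ from first-stage residuals; the reported
weighted SE is $\sqrt{\sum w_i r_i^2/(n-4)}$ and the weighted
goodness-of-fit is $1 - \mathrm{wRSS}/\mathrm{wTSS}$ — the latter formula
is our choice, as "weighted goodness-of-fit" has no canonical definition.

The recovery simulation uses the doubling-dilution ladder from 64 µM down
to about 1 nM (17 doses) with Gaussian noise of SD 0.05 on the proportion
scale: 200 replicate curves give a median relative IC50 error around 7%,
and noise-free curves return the generating parameters to better than
1e-6.

## ddPCR copy-number calling

Droplet partitioning makes template counts Poisson per droplet, so the
fraction of negative droplets estimates $e^{-\lambda}$ and
$\hat\lambda = -\ln(n_-/(n_+ + n_-))$ is the maximum-likelihood
concentration (verified against brute-force likelihood maximization in the
tests). Replicate wells are merged by averaging $\hat\lambda$ — wells can
differ in accepted-droplet totals — with a raw-droplet pooling mode for
sensitivity analysis. The target/reference ratio cancels the droplet
volume. A resistant-vs-parental log2 ratio $r$ converts to acquired copies
as $2 \cdot 2^{r} - 2$ under the assumption that the parental line is
diploid at both loci; the conversion is asymmetric in $r$, and it is
mis-scaled if the parental line is aneuploid at the reference locus (noted,
not corrected). The two printed worked examples — $r = 4.4$ giving ≈ 40
acquired copies (> 30) and $r = 3.08$ giving ≈ 14.9 (> 10) — are recomputed
by `scripts/acceptance.R`. Saturated wells (no negatives) are rejected, and
any positive droplets in a no-template control raise a contamination
warning.

## Survival and biomarker evaluation

Kaplan–Meier curves, the two-group log-rank test and the single-covariate
proportional-hazards fit (Breslow tie handling, Wald CI) are delegated to
the `survival` package behind the module surface; the tests pin them to
hand-tabulated risk-table oracles and to the classical score-test/log-rank
equivalence. Patients are stratified at a *CCNE1*/*RB1* ratio cutoff of 1
(equality assigned to the high group) or at the cohort median. The reported
hazard ratio is for the **low-ratio group relative to high**
(`hr_low_vs_high` < 1 means a high ratio is adverse), matching the clinical
reporting direction; ratios are always formed on the linear expression
scale (log2 input is exponentiated first — the cutoff of 1 means equal
expression on either scale).

For neoadjuvant-style discrimination, each of ratio/*CCNE1*/*RB1* gets a
two-sided Wilcoxon–Mann–Whitney p-value and a ROC AUC per biopsy
timepoint. All markers are oriented "higher score ⇒ predicted resistant",
so *RB1* is negated before the AUC; the orientation is recorded in the
output. AUC uses the rank (Mann–Whitney) formula with half credit for
ties and is cross-checked against $U/(n_1 n_2)$.

The correlation screen computes Pearson r of marker versus IC50 across
shared cell lines for every (marker, compound) pair, BH-FDR across the
compound axis per marker, and the per-marker rank of |r| across compounds.
IC50 values are correlated as provided — whether a dataset stores log
IC50s is a convention of the dataset, not of this package.

## The synthetic-data generators

The generators define the study-like conditions under which the pipeline
is exercised; their defaults were chosen once, on the following grounds,
and are not tuned against test outcomes.

* **Cell-line panel** (`generate_panel()`): 7 cell lines (the number of
  models that acquired resistance), 1000 genes of which 100 are simulated
  E2F targets, three samples per line (PDS, treated, resistant).
  Expression is simulated on the log2 scale: per-gene global means
  $\mathcal N(8, 1.5)$, per-line baseline offsets with SD 2 (large enough
  that samples cluster by line), and i.i.d. Gaussian noise with SD 0.25 —
  the additive-on-log2 (lognormal on linear) noise model standard for
  microarray intensities. Treatment suppresses E2F targets by 1 log2 unit;
  resistance restores half of that; *CCNE1* rises 1.5 and *RB1* falls 1
  log2 unit at resistance only. Effect magnitudes are free parameters (the
  source analyses report directions, not sizes); these values make the
  downstream qualitative results reproducible without being trivial. 10%
  of genes are flagged undetected in all samples. The exported E2F gene
  set includes *CCNE1* — cyclin E1 is itself an E2F target, which is what
  makes "the only up-regulated E2F-set gene at resistance" a meaningful
  statement — while *CCNE1* and *RB1* keep their dedicated resistance
  effects. A truth object (target genes, effect sizes, undetected genes)
  is returned alongside so tests never re-infer parameters.
* **Dose–response** (`generate_dose_response()`): 4PL on the proportion
  scale, doubling dilutions 64 µM → ~1 nM, noise on the proportion scale,
  fixed T0/vehicle anchors.
* **ddPCR** (`generate_ddpcr()`): binomial droplet counts with
  $P(+) = 1 - e^{-\lambda}$, target $\lambda$ scaled by the copy-number
  ratio. High-copy samples should be generated dilute (smaller reference
  $\lambda$) to keep the target assay off saturation, as at the bench.
* **Survival cohorts** (`generate_survival_cohort()`): exponential event
  times; the high-ratio group's hazard is multiplied by
  $1/\mathrm{HR}_{\mathrm{true}}$ so the low-vs-high HR equals
  `true_group_hr` (default 0.63, the prognostic effect size in large ER+
  cohorts). Censoring is independent uniform on $[0, \tau]$ with $\tau$
  solved numerically against the mixture of group hazards to hit the
  requested censoring fraction — standard non-informative censoring. With
  `er_positive_fraction` set, the hazard effect applies in the ER+ stratum
  only, emulating a prognostic effect confined to ER+ disease.
* **Neoadjuvant cohorts** (`generate_neoadjuvant_cohort()`): resistant
  patients' log2 ratio is shifted by 2.6 (default), realised as half up on
  *CCNE1* and half down on *RB1* with unit marker SD — so the ratio pools
  two weaker single-marker signals and its AUC (~0.90) exceeds either
  single marker's (~0.83), the qualitative structure of the clinical
  discrimination result. 30% of patients are resistant.

What the generators deliberately do *not* emulate: bead-level raw
intensities, probe sequences, droplet fluorescence amplitudes,
non-proportional hazards, informative censoring, or correlated gene-gene
structure beyond the line baselines. Passing tests therefore demonstrate
correctness of the computations under these idealised conditions, not
robustness to every artefact of real data.

## Numerical choices and edge cases

* Strict inequalities where stated: detection p < alpha; |avg FC| >
  threshold; ratio ≥ cutoff goes to the high group.
* WMW p-values are exact for tie-free samples with both n ≤ 10, otherwise
  the normal approximation with tie and continuity correction; the
  threshold is configurable.
* The 4PL optimizer flags non-convergence honestly (`converged = FALSE`
  with the optimizer message) instead of raising; degenerate constant
  responses never crash.
* Pipeline outputs are serialized with 10 significant digits so
  byte-identity checks are meaningful without bit-level brittleness;
  every stochastic stage derives its seed from the single master seed.
* Problem sizes used by the verification suites — 200 dose–response
  replicates, 1000 null survival cohorts of n = 100, 200 coverage cohorts
  of n = 1445, 100 neoadjuvant replicates, 500 small enrichment-oracle
  instances — are the package's chosen balance between Monte-Carlo
  precision and a test suite that runs in well under a minute per module.

## Known limitations

* The RBsig gene list itself is an input; the package ships no copy of it
  and does not re-derive it. The pipeline demonstration uses the simulated
  E2F-target set as a stand-in signature.
* No multivariable or time-varying survival models; one binary marker at a
  time.
* The ddPCR caller consumes droplet counts, not fluorescence; thresholding
  is upstream.
* Single-gene-set enrichment only; no batch database screening, no
  phenotype-permutation mode.
* Public cohort and drug-screen datasets are consumed as user-supplied
  TSVs in the documented shapes; the package contains no download clients.
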