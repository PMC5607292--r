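---
title: "Methods: methylation-tag diversity as a readout of crypt stem cell dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylation-tag diversity as a readout of crypt stem cell dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crypttags)
```

## The assay and its readouts

Colonic crypts are maintained by a small niche of stem cells. Because no
stem-cell marker is usable in routine human material, crypt dynamics are
read indirectly from somatic methylation patterns in the CpG island of an
unexpressed gene (here a CSX-style amplicon with 8 genotyped CpGs):
methylation at an unregulated locus changes only by random per-division
error and is inherited clonally, so the set of distinct patterns in one
crypt acts as a lineage tracer.

Two crypt-level summaries drive everything downstream:

* **Tag diversity** — the number of distinct 8-site methylation patterns
  among a crypt's reads after error filtering. Fewer patterns mean the
  stem cells shared a common ancestor recently (a recent *niche
  succession*); more patterns mean a protracted clonal history.
* **Percent methylation** — methylated CpG site-calls divided by all CpG
  site-calls, a proxy for mitotic age (cumulative divisions since the
  zygote).

Each sequencing read is one molecule, so each read yields one complete
pattern: bisulfite treatment converts unmethylated C to T while methylated
C is protected, and the read's C/T states at the CpG positions are its
pattern.

## Read processing

`call_reads()` turns raw barcoded reads into per-read pattern calls:

1. **Demultiplexing.** Barcodes are anchored at the 5' end. The default
   tolerance is 0 mismatches (exact); ties at equal distance are never
   guessed and go to `unassigned`.
2. **Alignment.** A bespoke bisulfite-aware Needleman–Wunsch global
   aligner (C++ core) aligns each distinct read sequence to the
   *in-silico converted reference* — the amplicon with every non-CpG C
   replaced by T, i.e. a fully methylated, fully converted molecule. At
   CpG reference positions read C and T both score as matches, so both
   epialleles align equally well. Defaults: match +1, mismatch −1, linear
   gap −2; these are a documented choice, as is the score floor of 0.6 ×
   the maximum attainable score, below which a read is discarded. Both
   orientations are tried and the better one kept. Alignment is memoized
   over identical read sequences, which dominate amplicon data.
3. **Coverage filter.** Only reads that fully cover the amplicon are
   kept. The default `"strict"` policy requires every reference position
   to be read-covered (no deletions at all); `"sites-only"` relaxes this
   to the CpG and control positions, tolerating indels away from any
   genotyped site. How indels at sites were handled historically is not
   documented anywhere we know of, so both policies are explicit options.
4. **Conversion controls.** Non-CpG cytosines must read T; a C there
   marks incomplete bisulfite conversion and invalidates the read (any
   other base does too). The shipped synthetic assay has controls at
   positions 14 and 20; the published site list prints a third control
   position that duplicates the first, which the reader deduplicates with
   a warning since the true third coordinate is unrecoverable.
5. **Genotyping.** At each CpG, C calls M and T calls U; anything else
   (or a gap) is ambiguous, and a read with any ambiguous CpG is
   discarded. Base qualities are read but unused, matching the assay's
   published workflow; a minimum-quality hook exists in the config.

Every read is accounted for in a `filter_ledger`; conservation
(passed + discards = input) is tested property-style.

## Tag analysis

Per crypt, passed reads are tabulated into exact pattern counts. The
**frequency cutoff** (default 1%) then removes patterns whose count is
below `cutoff × depth`, where depth is the crypt's total passed reads
(not the retained subset). Rare patterns at amplicon depth are
overwhelmingly PCR/sequencing artifacts or residual conversion failures;
1% follows diagnostic practice for amplicon NGS of FFPE material. The
boundary is inclusive — a pattern at exactly 1% is retained — because the
filtering rule omits patterns *below* the threshold. Diversity is the
count of retained patterns.

Percent methylation is reported read-weighted over the post-cutoff
patterns by default, with pattern-weighted and pre-cutoff variants
computed alongside: the historical wording is ambiguous between read- and
pattern-level averaging, and the 10-clone Sanger workflow is inherently
read-weighted, so read weighting is the comparable default.

Crypts with zero passed reads, or with nothing surviving the cutoff, are
flagged and excluded from regression input rather than recorded as
diversity 0: a sampled crypt always contains at least one true lineage,
so an empty profile marks assay failure, not biology.

`depth_sensitivity_filter()` (default ≥ 1000 reads) supports the
high-coverage sensitivity re-analysis, and `clone_subsample()` emulates
the Sanger workflow (10 random reads, no cutoff).

Timepoints are encoded both categorically (`t0`, `t4m`, `t2y`) and
continuously in years (4 months = 1/3), the latter for all "per year"
quantities.

## The crypt simulator

The synthetic-data generator exists so that every downstream stage is
testable against known truth. It has three layers.

**Niche dynamics.** Each crypt is a Moran-type niche of `n_stem` stem
cells. Replacement events (rate `replacement_rate` per stem cell per
year) kill a random cell and copy another into its place; run to
fixation this is niche succession. Methylation errors accrue
*continuously per cell* as a two-state Markov process per CpG site (gain
`mu_gain`, loss `mu_loss`, per site per year), using exact finite-time
transition probabilities between events. We deliberately decoupled error
accrual from replacement events: stem cells divide continuously whether
or not lineages replace one another, so a higher replacement rate prunes
diversity faster *without* generating errors faster. Coupling errors to
replacement events (the obvious alternative) makes diversity a function
of event count alone, so a faster-replacing arm merely runs the same
trajectory faster and can never stay flat while the slow arm rises —
grid simulation confirmed this — whereas the decoupled model yields the
qualitative structure the assay is used to detect: an untreated arm
drifting up in diversity while an arm with accelerated replacement
(modeled as a multiplier, default 4) stays flat or declines.

The niche starts from a single ancestor whose pattern is methylated per
site with probability `ancestor_meth` (the patient's accumulated mitotic
age at the last succession) and drifts `t_burnin` years before study
start. Defaults (`n_stem = 6`, `replacement_rate = 1`/cell/yr,
`mu_gain = 0.07`, `mu_loss = 0.28`/site/yr, `t_burnin = 0.3` y,
`ancestor_meth = 0.22`) were calibrated once, at truth level, so that
baseline crypts show roughly 2–3 retained patterns and ~20–25%
methylation with the untreated arm rising by roughly 1.3×/yr — the
magnitudes such assays report — and are documented as calibration
choices, not measured biology.

**Assay noise.** Per crypt, read depth is lognormal (default
`meanlog = log(5000)`, `sdlog = 1.4`, clipped to [1, 50000]), emulating
the very wide depth variation of amplicon runs (reported ranges span
roughly 4–50,000 reads per crypt). Each read samples a stem cell
uniformly and renders its pattern onto the converted reference. Bisulfite
conversion failure is modeled **per molecule**: with probability
`p_conversion_failure` (default 1%) a read derives from an incompletely
converted molecule in which each unmethylated cytosine — control sites
and unmethylated CpGs alike — independently escapes conversion with
probability `conv_retention` (default 0.5). Conversion failure is
molecule-level chemistry; modeling it per site independently would (a)
let single-site artifact patterns approach the 1% cutoff at realistic
rates, and (b) decouple control-site failures from CpG failures, making
the control filter uninformative. The correlated model is what makes
control sites work: most poorly converted molecules betray themselves at
a control and are filtered. Per-site inappropriate conversion of
methylated CpGs (default 0.2%) and uniform per-base substitution error
(default 0.1%) complete the layer.

**Cohort layout.** Two arms (placebo, sulindac) × 4 patients × 3
timepoints (0, 4 months, 2 years) × 10 crypts, mirroring the
longitudinal two-arm design. A crypt sampled at time *t* drifts
`t_burnin` at the baseline rate and then *t* years at its arm's rate.
Per-patient polyp burdens are Poisson with a linear-in-time mean whose
per-patient slope is Gamma-distributed around the arm mean (placebo
7/yr, treated 0.4/yr — the scale of the published counts); everyone
starts polyp-free. Patient ages default to the published baseline ages.
All randomness derives from one master seed through a fixed per-crypt
counter scheme, so any crypt is reproducible in isolation and a dataset
is byte-identical across reruns.

What the simulator does *not* emulate: FFPE deamination damage, PCR
chimeras and indel errors, primer-site variation, spatial crypt
structure, selection (e.g. *APC*-driven advantage), or between-patient
heterogeneity in niche size and rates. Passing the end-to-end tests
therefore shows the pipeline's bookkeeping and statistics are sound under
a plausible generative model — not that the biology of real crypts is
captured.

## Trend models

Crypt-level outcomes are analyzed with the crypt as the unit and a
Gaussian random intercept per patient to absorb within-patient
clustering; fixed effects are treatment, time and their interaction.

* **Pattern counts** (right-skewed): NB2 negative binomial with log link
  (variance μ + μ²/θ). The marginal likelihood integrates the patient
  intercept by adaptive Gauss–Hermite quadrature (default 25 nodes;
  estimates shift by < 10⁻³ going to 51 on our fixtures) centered at
  each patient's posterior mode, and is maximized by BFGS over
  (β, log θ, log σ) from Poisson-GLM starting values — deterministic
  given the data. With categorical time the fit reports per-group
  *conditional* means per timepoint (random intercept 0; the usual
  software convention — whether published means are conditional or
  marginal is typically unstated, and the choice is documented here);
  with continuous time it reports exp(slope), the multiplicative rate
  per year. If the variance estimate collapses (σ < 10⁻⁴) the model is
  refitted as a plain NB GLM with a warning.
* **Percent methylation** (approximately Gaussian): the analogous linear
  random-intercept model. β and the residual variance profile out in
  closed form per variance ratio, leaving a 1-D maximum-likelihood
  search; at the boundary the fit is exactly OLS.

Inference is by Wald z tests and 95% CIs on the link scale (no
small-sample df correction); the interaction is tested by Wald on the
interaction coefficients, with a likelihood-ratio test against the
reduced (additive) fit reported alongside. No multiplicity adjustment is
applied and α = 0.05, matching the reporting conventions of the analyses
this package mirrors. `project_rate()` implements the reporting
convention for multiplicative rates (iterated yearly multiplication,
rounded to 2 decimals per step for whole years).

`per_patient_trends()` estimates per-patient rates (patient-level NB
regression, Poisson fallback when dispersion is inestimable), percent
and polyp slopes (OLS), and their pairwise Pearson correlations across
all patients pooled. `adjust_for_age()` refits the mixed models with
baseline age as a fixed covariate, refusing (with a notice) when ages
are missing and dropping the covariate (with a warning) when constant.

## Numerical and degenerate-input choices

* Alignment traceback ties resolve deterministically diagonal → deletion
  → insertion; scores with the default integer parameters are exact in
  double precision, so the optimality tests against the exhaustive DP
  oracle compare equality.
* Newton mode-finding for the quadrature exploits log-concavity of the
  integrand; steps are capped and non-finite regions return −∞ so the
  optimizer simply avoids them.
* Empty crypts, all-zero count patients, constant covariates, orphan
  barcodes and non-nested model comparisons each have a defined refusal
  path (error, warning, or exclusion with a logged reason) rather than a
  silent answer.

## Problem sizes used by the test suite

The shipped tests run the full battery at the sizes the methods are
meant for: the aligner oracle on 500 random ≤ 25 bp instances; the
cutoff oracle on 1000 random tables; one 240-crypt zero-error cohort
processed read-by-read end to end; 100 crypts at ~8000× depth for error
suppression; 200 simulated cohorts for parameter recovery of the NB
mixed model (true rates 1.3 vs 1.0 per year) plus 200 for the size of
the interaction test. Recovery and calibration work at the count level —
the generative model of the fitted regression — so they measure the
estimator, not the read simulator.

## Known limitations

* The synthetic reference sequence honors the published site geometry
  (CpGs at 1-based positions 2, 4, 6, 18, 22, 37, 40, 51; controls at 14
  and 20) but is otherwise invented; results on it exercise the code, not
  the real amplicon.
* Whether the printed site coordinates are 0- or 1-based, and relative
  to what, is not documented; the coordinate convention is therefore a
  config knob (`coordinate_base`, default: as printed, 1-based).
* The NB mixed model uses Wald inference; with 4 patients per arm the
  random-intercept variance is weakly identified and small-sample
  coverage is approximate (the recovery tests bound it empirically).
* Paired-end merging, quality recalibration, genome mapping and indel
  genotyping are out of scope by design.
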