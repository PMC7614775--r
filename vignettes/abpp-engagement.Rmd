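---
title: "Quantifying covalent cysteine engagement from TMT-ABPP competition data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying covalent cysteine engagement from TMT-ABPP competition data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abppquant)
```

## The measurement

Activity-based protein profiling (ABPP) with a cysteine-reactive probe
(iodoacetamide-desthiobiotin, IA-DTB) measures how much of each proteomic
cysteine remains free after treatment with an electrophilic compound. In the
multiplexed (TMT 10-plex) competition format, replicate DMSO-treated and
compound-treated samples occupy different reporter-ion channels of the same
run. For every peptide-spectrum match (PSM), each channel's reporter
intensity is divided by the mean intensity of the DMSO channels:

$$f_c = \frac{I_c}{\operatorname{mean}(I_{\mathrm{DMSO}})}$$

A site's *competition ratio* is $R = 1/f$ (DMSO over compound signal) and
its *engagement* is $100\,(1 - f)$ percent. The two are tied by the identity
$\mathrm{engagement} = 100\,(1 - 1/R)$, which the package audits on every
emitted row: a ratio of 4 is exactly a 75% loss of probe-accessible signal,
and that ratio is the default call threshold for "significantly engaged".

## QC filtering

PSMs are excluded when (rule order fixed for report attribution):

1. the peptide is a reversed-database match;
2. the peptide is not fully tryptic;
3. the peptide is shorter than 6 residues;
4. the summed DMSO-channel intensity is strictly below 10,000;
5. the DMSO coefficient of variation is strictly above 0.5.

Boundary values (sum exactly 10,000, CV exactly 0.5) are retained, because
the exclusion rules are strict inequalities. The CV uses the sample
standard deviation ($n-1$ denominator) over the DMSO channels divided by
their mean; for duplicate DMSO channels this is
$\sqrt{2}\,|I_1 - I_2| / (I_1 + I_2)$. The definition matters at the
boundary and is stated because the population-SD convention would shift
it. Each excluded record is attributed to
its *first* failing rule so that exclusion counts always sum to the input
size. Filtering is idempotent.

## From PSMs to sites

PSMs are grouped by (protein, cysteine residue). Within each PSM the
fractions of the replicate channels of a condition are averaged first; the
site-level fraction is then the **median** of those per-PSM values. The
median is the default because single-PSM outliers (co-isolated precursors,
poorly integrated reporters) otherwise propagate directly into the site
value; the mean is available via `aggregate_sites(..., agg = "mean")`.
Whether replicate averaging happens before or after cross-PSM aggregation
is a genuinely open choice; replicates-first is used because it keeps each
PSM's contribution a single number, and with duplicate channels and the
two-point median the alternative ordering differs only in higher moments.

Peptides that carry more than one labeled cysteine cannot be resolved to a
single site by reporter ions; they contribute an identical row to *every*
listed residue with `ambiguous = TRUE` (the JAK1 tryptic peptide carrying
both C810 and C817 is the canonical example). Resolution requires
orthogonal evidence (e.g. mutagenesis) and is out of scope here.

Ratios are capped at 20 before thresholding (zero compound signal would
otherwise be infinite); the cap is an ABPP reporting convention, and
`fraction`/`engagement_pct` are recomputed from the capped ratio so the
engagement identity survives capping.

## The planted-truth generator

Synthetic data make every stage testable against known ground truth.
Liganded sites follow the standard two-step covalent kinetics,

$$occ(C, t) = occ_{\max}\left(1 - e^{-k_{\mathrm{inact}}\, t\, C / (K_I + C)}\right),$$

chosen over an empirical logistic because it yields a closed-form
half-engagement concentration,
$TE_{50}(t) = K_I \ln 2 / (k_{\mathrm{inact}} t - \ln 2)$, that serves as
an independent oracle and makes the hallmark time-dependent potency of
covalent ligands emerge mechanistically rather than by construction.

Generator conventions (defaults, with rationale):

* **Reporter noise** — multiplicative log-normal per channel with unit mean,
  CV 0.10. Reporter-ion intensities are positive and right-skewed with
  roughly constant CV, which the log-normal reproduces; the magnitude is a
  free parameter of the generator (`noise_cv`) since instrument-level
  dispersion varies between set-ups.
* **PSMs per site** — $1 + \mathrm{Poisson}(\lambda)$, $\lambda = 2$:
  most sites are seen a handful of times, a long tail is seen often, none
  is seen zero times.
* **Channel layout** — duplicate DMSO channels plus duplicate compound
  channels per concentration (up to four concentrations per 10-plex),
  matching the duplicate-treatment convention of competition experiments.
  Experiments needing seven concentrations span two plexes.
* **Injected QC violations** — at rates set in the design, each violating
  record gets exactly one defect (DMSO sum forced to 5,000; DMSO channels
  split 4:1/4 giving CV ≈ 1.25; reverse flag; C-terminal residue mutated
  off K/R). Exclusive defects make the generator ledger exactly
  comparable, count for count, with the QC report.
* **Determinism** — all randomness flows from the design's single integer
  seed through one RNG stream with a documented draw order; the caller's
  RNG state is restored afterwards.

The generator does **not** emulate spectrum-level physics: co-isolation
interference, TMT isotopic impurity spillover, missing channels,
chromatographic drift, or identification error. Passing tests therefore
demonstrate the correctness of the *quantification arithmetic and calling
logic* under a realistic noise magnitude — not robustness to every failure
mode of real LC-MS/MS data.

For plate assays, `generate_htrf_plate()` plants a logistic
concentration-response on the HTRF ratio scale between a basal ratio
(default 2,000) and a stimulation window (default 8,000, i.e. a 5-fold
assay window), with two unstimulated and five stimulated DMSO control
wells per plate and a seven-point half-log dilution in duplicate. Raw
665/620 nm counts are emitted (620 nm fixed at 50,000 counts) so the full
normalization path — ratio, basal subtraction, percent-of-stimulated
control — is exercised, not just the final numbers. Basal subtraction is
applied uniformly to all wells, including the stimulated controls
themselves; this is required for the percent-of-control formula to return
exactly 100 at the controls.

## Dose-response fitting

TE50/IC50 values come from the four-parameter logistic

$$y = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}{1 + (x/\mathrm{midpoint})^{\mathrm{hill}}}$$

fitted in log10-concentration space by bounded Levenberg-Marquardt least
squares (`minpack.lm::nls.lm`). Numerical choices:

* **Constraints** (overridable): bottom in [0, 20], top in [80, 120],
  Hill-slope magnitude in [0.3, 5], log-midpoint within the tested range
  ± 2 decades. These stabilize seven-point percent-scale fits where the
  asymptotes are only partly observed.
* **Direction** is detected from the response/log-dose correlation and
  carried as the sign of the fitted Hill slope, so decreasing
  (percent-of-control) and increasing (engagement) readouts share one code
  path; the reported bottom is always the lower asymptote.
* **Starting values** follow the usual heuristics (asymptotes from extreme
  responses, midpoint from the half-maximal crossing, slope 1) but a small
  deterministic grid of starting slopes (0.5, 1, 2) and midpoints (the
  heuristic and the dose-range center) is tried and the lowest-RSS
  converged fit kept. Seven-point logistic surfaces have genuine local
  minima; a fixed grid removes the dependence on any single heuristic
  while staying fully deterministic. A later candidate must beat the
  incumbent by a real margin — when resampling leaves only four distinct
  doses the fit is exactly determined and any interpolant has residual
  zero, so near-ties must not switch solutions.
* **Confidence intervals** are percentile intervals from case-resampling
  bootstrap over the series' points, refit with the full-data estimate as
  one warm-start candidate alongside the grid. Resamples with fewer than
  four distinct concentrations cannot support the model and are skipped
  (counted, warned). The method was chosen because the assay reports no
  analytic error model.
* Fits whose midpoint falls outside the tested concentration span are
  flagged `extrapolated`, mirroring the reporting of ">" potency bounds.

## Validation problem sizes

The test suite exercises: exactness of noise-free recovery (engagement
equals planted occupancy to numerical precision); median-absolute
engagement error under 10% reporter CV over 250 liganded sites (< 5
percentage points); exact agreement of QC exclusion counts with the
injected-violation ledger on a ~10,000-PSM table; TE50 recovery within
2-fold at planted potencies of 2.1 and 45 µM from two-plex seven-point
experiments at 10% CV; IC50 recovery within 2-fold at 1.4 µM through the
full HTRF plate path; first-and-second ranking of a potent and a
10-fold-weaker planted site among 1,000 sites; and 95%-nominal bootstrap
coverage ≥ 90% over 100 simulated series (300 resamples each, planted
midpoint at the geometric center of the dose range, where a well-designed
assay places its expected potency). The closed-form $TE_{50}(t)$ is checked
against numeric root-finding of the occupancy model at relative tolerance
1e-6, and fitted midpoints decrease strictly across 10/30/60-minute
pre-incubations, the kinetic signature that distinguishes covalent from
reversible binding.

In kinetic test fixtures the exposure is set so that
$k_{\mathrm{inact}} t = 8 \ln 2$, which makes the occupancy ceiling ~99.6%
(so the logistic top is observable) and places $TE_{50}$ at exactly
$K_I / 7$; planting a desired $TE_{50}$ is then a one-line choice of
$K_I$.

## Known limitations

* Site-level aggregation assumes reporter intensities are comparable
  across PSMs after the within-PSM DMSO normalization; no
  isotopic-impurity correction or co-isolation filtering is applied.
* The ratio cap (20) bounds reportable engagement at 95%; stronger
  engagement is indistinguishable from the cap by design.
* The 4PL midpoint equals the absolute-50% crossing only when the fitted
  asymptotes sit at 0/100; with partially observed asymptotes the fitted
  midpoint is the model's inflection point, which is what dose-response
  software conventionally reports.
* Bootstrap intervals on seven-point duplicate designs are mildly
  anti-conservative (coverage ~90% at nominal 95%), a known small-sample
  property of the percentile method.
* `occ_max < 1` (incomplete maximal occupancy) is supported by the
  generator but the closed-form $TE_{50}$ assumes $occ_{\max} = 1$ and
  refuses configurations that never reach 50%.
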