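# abppquant

Quantification of covalent-inhibitor engagement of proteomic cysteines from
multiplexed activity-based protein profiling (ABPP) competition experiments,
plus the dose–response and functional-assay arithmetic that surrounds a
covalent-probe discovery campaign.

The package is written for chemoproteomics practitioners who have PSM-level
TMT reporter-ion tables (or targeted PRM / targeted-TMT quantification
tables, or raw HTRF plate reads) and need the downstream numbers: per-site
competition ratios and engagement calls, TE50/IC50 estimates with bootstrap
confidence intervals, selectivity rankings, and the standard plate/blot/qPCR
normalizations. A synthetic-data generator with planted covalent kinetics
provides ground truth for every stage, so the whole pipeline is testable
end to end.

## The quantities

For each peptide-spectrum match, every TMT channel's reporter intensity is
divided by the mean intensity of the DMSO (vehicle) channels:
*f* = *I*<sub>channel</sub> / mean(*I*<sub>DMSO</sub>). After QC filtering
(DMSO intensity sum ≥ 10,000, DMSO CV ≤ 0.5, fully tryptic, not a reversed
match, ≥ 6 residues), PSMs are grouped by protein cysteine; the site-level
fraction is the median across PSMs of the replicate-channel means. The
competition ratio is *R* = 1/*f* (DMSO over compound), engagement is
100·(1 − *f*) %, and sites with capped *R* ≥ 4 — i.e. ≥ 75 % loss of
probe-accessible signal — are called engaged.

Concentration–response series are fitted with the four-parameter logistic
*y* = bottom + (top − bottom)/(1 + (*x*/midpoint)^hill) in log₁₀ dose, the
midpoint being the TE50 (engagement readout) or IC50 (percent-of-control
inhibition readout). The synthetic generator drives liganded sites with the
two-step covalent model occ(*C*, *t*) = occ·(1 − e^(−k_inact·t·C/(K_I+C))),
whose closed-form TE50(t) = K_I·ln2/(k_inact·t − ln2) provides an
independent oracle and reproduces the time-dependent potency gain that
distinguishes covalent from reversible binders.

## Worked example

Simulate a 502-site proteome in which JAK1_C817 is potently liganded
(K_I = 1 µM) and TYK2_C838 is 10-fold weaker, profiled at 1 µM compound in
a TMT 10-plex with duplicate DMSO and compound channels and 10 % reporter
noise, then quantify and rank:

```r
library(abppquant)
set.seed(1)
truths <- dplyr::bind_rows(
  site_truth("JAK1", 817, liganded = TRUE, k_inact = 8 * log(2) / 60,
             K_I = 1, n_psms = 3),
  site_truth("TYK2", 838, liganded = TRUE, k_inact = 8 * log(2) / 60,
             K_I = 10, n_psms = 3),
  sample_site_truths(500))
design <- tmt10_design(1, compound = "cmpd", noise_cv = 0.1, seed = 2)
g <- generate_psm_table(truths, design)
q <- quantify_sites(g$psms, design_layout(design))
rank_sites(q$sites, targets = c("JAK1_C817", "TYK2_C838"))
#> Selectivity report for cmpd@1uM
#>   sites quantified: 502 | engaged: 1 | off-target calls: 0
#> # A tibble: 10 × 4
#>    site_id       ratio engagement_pct engaged
#>    <chr>         <dbl>          <dbl> <lgl>
#>  1 JAK1_C817     17.7            94.4 TRUE
#>  2 TYK2_C838      1.53           34.8 FALSE
#>  3 PROT0033_C573  1.29           22.4 FALSE
#>  ...
```

The potent site is the only engagement call (ratio 17.7 ≥ 4, i.e. 94 %
engagement); the weaker secondary site ranks second but stays below the
call threshold at this concentration, and the 500 decoys scatter around
ratio 1.

Recovering a planted IC50 through the full HTRF plate path (raw 665/620 nm
counts → ratio → basal subtraction → percent-of-stimulated-control → 4PL):

```r
plate <- generate_htrf_plate(plate_design(seed = 4), ic50 = 1.4)
cw <- subset(htrf_normalize_plate(plate), condition == "stim_compound")
s <- dose_response_series(cw$conc_uM, cw$pct_of_control)
bootstrap_ci(s, fit_4pl(s), n_boot = 500, seed = 5)
#> 4PL fit: midpoint 1.385 uM (hill 0.954, bottom 0, top 99.7)
#>   95% CI [0.9195, 1.524] uM
```

A thin command-line wrapper over the same functions lives at
`inst/cli/abppquant.R` (subcommands `simulate`, `quantify`, `plate`,
`run`).

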