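# Synthetic TMT-ABPP and HTRF data with planted ground truth.
#
# All randomness in a generator call flows from the single `seed` carried by
# the design object, through one base-R RNG stream. Stream order is fixed and
# documented per generator so fixtures are stable across sessions.

TMT10_CHANNELS <- c("126", "127N", "127C", "128N", "128C",
                    "129N", "129C", "130N", "130C", "131")

#' Ground truth for one cysteine site
#'
#' Describes a protein cysteine and, if liganded, the covalent kinetics that
#' drive its concentration/time-dependent occupancy in the generator.
#'
#' @param protein Protein identifier, e.g. `"JAK1"`.
#' @param residue Cysteine residue number (positive integer).
#' @param liganded Does the compound engage this site at all?
#' @param k_inact Inactivation rate constant, per minute.
#' @param K_I Reversible binding constant, uM.
#' @param occ_max Maximal attainable occupancy, fraction in `[0, 1]`.
#' @param n_psms Number of peptide-spectrum matches observed for the site.
#' @param base_intensity Reporter-ion intensity scale of the DMSO channels
#'   (arbitrary units).
#' @return A one-row tibble with a derived `site_id` (`"PROTEIN_C<residue>"`).
#' @examples
#' site_truth("JAK1", 817, liganded = TRUE, k_inact = 0.09, K_I = 15)
#' @export
site_truth <- function(protein, residue, liganded = FALSE,
                       k_inact = 0, K_I = 1, occ_max = 1,
                       n_psms = 3, base_intensity = 1e5) {
  stopifnot(residue >= 1, K_I > 0, k_inact >= 0,
            occ_max >= 0, occ_max <= 1, n_psms >= 1, base_intensity > 0)
  tibble::tibble(
    site_id = sprintf("%s_C%d", protein, as.integer(residue)),
    protein = protein, residue = as.integer(residue),
    liganded = liganded, k_inact = k_inact, K_I = K_I,
    occ_max = occ_max, n_psms = as.integer(n_psms),
    base_intensity = base_intensity
  )
}

#' Sample a synthetic proteome of (mostly unliganded) cysteine sites
#'
#' Decoy sites carry no compound engagement; PSM counts are drawn as
#' `1 + Poisson(lambda_psms)` and base intensities log-uniformly over
#' `intensity_range`. Draws come from the caller's RNG stream (set a seed
#' before calling for reproducibility).
#'
#' @param n Number of sites.
#' @param lambda_psms Poisson rate for extra PSMs per site (default 2).
#' @param intensity_range Range of per-site DMSO-channel intensity scales.
#' @return A tibble of site truths, proteins named `PROT0001`, ...
#' @export
sample_site_truths <- function(n, lambda_psms = 2,
                               intensity_range = c(3e4, 3e5)) {
  stopifnot(n >= 1, intensity_range[1] >= 1)
  tibble::tibble(
    protein = sprintf("PROT%04d", seq_len(n)),
    residue = sample(20:900, n, replace = TRUE),
    liganded = FALSE, k_inact = 0, K_I = 1, occ_max = 1,
    n_psms = 1L + stats::rpois(n, lambda_psms),
    base_intensity = exp(stats::runif(n, log(intensity_range[1]),
                                      log(intensity_range[2])))
  ) |>
    dplyr::mutate(site_id = sprintf("%s_C%d", .data$protein, .data$residue),
                  .before = 1)
}

#' TMT experiment design: channel-to-condition map plus noise model
#'
#' @param condition_map Tibble with columns `channel`, `treatment` (`"DMSO"`
#'   or a compound id), `conc_uM`, `replicate`. Every channel label must be
#'   unique and at least two channels must be DMSO (the quantification
#'   denominator is the mean of replicate DMSO channels).
#' @param preincubation_time Compound/lysate pre-incubation, minutes.
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   reporter noise (0 = noise-free).
#' @param seed Integer seed owning all randomness of [generate_psm_table()].
#' @param qc_violation_rates Named numeric rates for injected QC-violating
#'   records: `low_intensity`, `high_cv`, `reverse`, `nontryptic`. At most one
#'   violation type is assigned per record.
#' @return An object of class `abpp_design`.
#' @export
experiment_design <- function(condition_map, preincubation_time = 60,
                              noise_cv = 0.1, seed = 1L,
                              qc_violation_rates = c(low_intensity = 0,
                                                     high_cv = 0,
                                                     reverse = 0,
                                                     nontryptic = 0)) {
  condition_map <- tibble::as_tibble(condition_map)
  stopifnot(all(c("channel", "treatment", "conc_uM", "replicate") %in%
                  names(condition_map)))
  if (anyDuplicated(condition_map$channel)) {
    stop("each channel label may appear only once in `condition_map`",
         call. = FALSE)
  }
  if (sum(condition_map$treatment == "DMSO") < 2) {
    stop("at least two DMSO channels are required", call. = FALSE)
  }
  rates <- c(low_intensity = 0, high_cv = 0, reverse = 0, nontryptic = 0)
  rates[names(qc_violation_rates)] <- qc_violation_rates
  stopifnot(all(rates >= 0), sum(rates) <= 1)
  structure(
    list(condition_map = condition_map,
         preincubation_time = preincubation_time,
         noise_cv = noise_cv, seed = as.integer(seed),
         qc_violation_rates = rates),
    class = "abpp_design"
  )
}

#' Standard TMT 10-plex competition design
#'
#' Duplicate DMSO channels (126, 127N) followed by duplicate compound
#' channels per concentration, mirroring the duplicate-DMSO /
#' duplicate-compound layout of multiplexed competition experiments.
#'
#' @param concs Up to four compound concentrations, uM.
#' @param compound Compound identifier used in condition labels.
#' @inheritParams experiment_design
#' @export
tmt10_design <- function(concs, compound = "compound",
                         preincubation_time = 60, noise_cv = 0.1, seed = 1L,
                         qc_violation_rates = c(low_intensity = 0, high_cv = 0,
                                                reverse = 0, nontryptic = 0)) {
  stopifnot(length(concs) >= 1, length(concs) <= 4, all(concs > 0))
  cmap <- tibble::tibble(
    channel = TMT10_CHANNELS[seq_len(2 + 2 * length(concs))],
    treatment = c("DMSO", "DMSO", rep(compound, 2 * length(concs))),
    conc_uM = c(0, 0, rep(concs, each = 2)),
    replicate = c(1L, 2L, rep(1:2, length(concs)))
  )
  experiment_design(cmap, preincubation_time, noise_cv, seed,
                    qc_violation_rates)
}

#' Channel layout implied by an experiment design
#'
#' Conditions are labelled `"<compound>@<conc>uM"`; DMSO channels form the
#' normalization denominator.
#'
#' @param design An [experiment_design()].
#' @return An `abpp_layout`: `dmso_channels`, `treatment_channels` (named
#'   list), `condition_meta` tibble (`condition`, `compound`, `conc_uM`,
#'   `time`).
#' @export
design_layout <- function(design) {
  cm <- design$condition_map
  trt <- cm[cm$treatment != "DMSO", ]
  cond <- sprintf("%s@%guM", trt$treatment, trt$conc_uM)
  meta <- unique(tibble::tibble(condition = cond, compound = trt$treatment,
                                conc_uM = trt$conc_uM,
                                time = design$preincubation_time))
  channel_layout(
    dmso_channels = cm$channel[cm$treatment == "DMSO"],
    treatment_channels = split(trt$channel, cond)[meta$condition],
    condition_meta = meta
  )
}

#' Construct a channel layout directly
#'
#' @param dmso_channels Channel labels of the vehicle (DMSO) replicates.
#' @param treatment_channels Named list: condition id -> channel labels.
#' @param condition_meta Optional tibble (`condition`, `compound`, `conc_uM`,
#'   `time`).
#' @export
channel_layout <- function(dmso_channels, treatment_channels,
                           condition_meta = NULL) {
  stopifnot(length(dmso_channels) >= 2)
  if (length(intersect(dmso_channels, unlist(treatment_channels))) > 0) {
    stop("DMSO and treatment channels must be disjoint", call. = FALSE)
  }
  structure(list(dmso_channels = dmso_channels,
                 treatment_channels = treatment_channels,
                 condition_meta = condition_meta),
            class = "abpp_layout")
}

# log-normal multiplicative noise factor with unit mean and given CV
lnoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

random_tryptic_peptide <- function(residue) {
  aa <- strsplit("ADEFGHILMNPQSTVWY", "")[[1]] # no C/K/R in the core
  len <- sample(8:18, 1)
  cpos <- sample(2:(len - 1), 1)
  core <- sample(aa, len - 1, replace = TRUE)
  core[cpos] <- "C"
  paste0(paste(core, collapse = ""), sample(c("K", "R"), 1))
}

#' Generate a PSM-level TMT quantification table with known truth
#'
#' Emits `n_psms` peptide-spectrum-match records per site. DMSO-channel
#' intensities are `base_intensity` times unit-mean log-normal noise;
#' compound channels at concentration C are
#' `base_intensity * (1 - occupancy(C, preincubation_time))` times noise, so
#' with `noise_cv = 0` the downstream competition machinery recovers planted
#' occupancy exactly. QC-violating records are injected at the design's
#' `qc_violation_rates` (at most one violation per record) and recorded in
#' the returned truth ledger:
#' * `low_intensity` - all channels rescaled so the DMSO sum is 5,000 (half
#'   the conventional 10,000 gate);
#' * `high_cv` - DMSO channels multiplied by alternating factors 4 and 1/4
#'   (CV about 1.25 for duplicates);
#' * `reverse` - record flagged as a reversed-database match;
#' * `nontryptic` - C-terminal residue mutated to alanine and the tryptic
#'   flag cleared.
#'
#' RNG stream order (from `design$seed`): one peptide draw per site in input
#' order, then one violation-category uniform per PSM, then the noise matrix
#' (PSM by channel, column-major). Identical seed implies a byte-identical
#' table.
#'
#' @param truths Tibble of site truths ([site_truth()] rows).
#' @param design An [experiment_design()].
#' @return List with `psms` (one row per PSM; intensity columns named by
#'   channel label) and `ledger` (tibble `psm_id`, `site_id`, `violation`).
#' @export
generate_psm_table <- function(truths, design) {
  stopifnot(inherits(design, "abpp_design"), nrow(truths) >= 1)
  cm <- design$condition_map
  if (nrow(cm) == 0) stop("empty channel map", call. = FALSE)
  rates <- design$qc_violation_rates
  cuts <- cumsum(rates)

  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(design$seed)

  dmso_idx <- cm$treatment == "DMSO"
  n_chan <- nrow(cm)
  n_sites <- nrow(truths)

  peptides <- vapply(truths$residue, random_tryptic_peptide, "")

  # expected noise-free intensity, site x channel
  expected <- matrix(truths$base_intensity, n_sites, n_chan)
  for (j in seq_len(n_chan)) {
    if (dmso_idx[j]) next
    occ <- ifelse(
      truths$liganded,
      truths$occ_max * (1 - exp(-truths$k_inact * design$preincubation_time *
                                  cm$conc_uM[j] /
                                  (truths$K_I + cm$conc_uM[j]))),
      0)
    expected[, j] <- truths$base_intensity * (1 - occ)
  }

  site_of <- rep(seq_len(n_sites), truths$n_psms)
  n_psm <- length(site_of)
  u <- stats::runif(n_psm)
  violation <- rep("none", n_psm)
  if (sum(rates) > 0) {
    hit <- u < cuts[length(cuts)]
    violation[hit] <- names(cuts)[
      vapply(u[hit], function(v) which(v < cuts)[1], 1L)]
  }
  intens <- expected[site_of, , drop = FALSE] *
    matrix(lnoise(n_psm * n_chan, design$noise_cv), n_psm, n_chan)

  low <- violation == "low_intensity"
  if (any(low)) {
    intens[low, ] <- intens[low, , drop = FALSE] *
      (5000 / rowSums(intens[low, dmso_idx, drop = FALSE]))
  }
  hcv <- violation == "high_cv"
  if (any(hcv)) {
    intens[hcv, dmso_idx] <- intens[hcv, dmso_idx, drop = FALSE] *
      rep(rep_len(c(4, 0.25), sum(dmso_idx)), each = sum(hcv))
  }
  pep <- peptides[site_of]
  ntr <- violation == "nontryptic"
  pep[ntr] <- paste0(substr(pep[ntr], 1, nchar(pep[ntr]) - 1), "A")

  psms <- tibble::tibble(
    psm_id = sprintf("PSM%06d", seq_len(n_psm)),
    site_id = truths$site_id[site_of],
    protein = truths$protein[site_of],
    peptide = pep,
    modified_residues = as.character(truths$residue[site_of]),
    charge = 2L,
    is_tryptic = !ntr,
    is_reverse = violation == "reverse"
  )
  intens_df <- tibble::as_tibble(as.data.frame(intens))
  names(intens_df) <- cm$channel
  psms <- dplyr::bind_cols(psms, intens_df)
  list(psms = psms,
       ledger = tibble::tibble(psm_id = psms$psm_id,
                               site_id = psms$site_id,
                               violation = violation))
}

#' HTRF plate design
#'
#' Defaults mirror a 384-well phospho-STAT dose-response layout: a
#' seven-point half-log serial dilution in duplicate, two unstimulated and
#' five cytokine-stimulated DMSO control wells per plate.
#'
#' @param n_doses Number of compound concentrations.
#' @param dilution Fold step of the serial dilution.
#' @param top_dose Highest concentration, uM.
#' @param replicates_per_dose Wells per concentration.
#' @param basal_ratio HTRF ratio of unstimulated controls.
#' @param window Stimulated-minus-basal ratio window.
#' @param n_unstim_controls,n_stim_controls Control wells per plate.
#' @param noise_cv CV of multiplicative log-normal well noise.
#' @param seed Integer seed for [generate_htrf_plate()].
#' @export
plate_design <- function(n_doses = 7, dilution = sqrt(10), top_dose = 10,
                         replicates_per_dose = 2, basal_ratio = 2000,
                         window = 8000, n_unstim_controls = 2,
                         n_stim_controls = 5, noise_cv = 0.05, seed = 1L) {
  stopifnot(n_doses >= 1, dilution > 1, top_dose > 0, window > 0,
            n_unstim_controls >= 2, n_stim_controls >= 5)
  structure(list(n_doses = n_doses, dilution = dilution, top_dose = top_dose,
                 replicates_per_dose = replicates_per_dose,
                 basal_ratio = basal_ratio, window = window,
                 n_unstim_controls = n_unstim_controls,
                 n_stim_controls = n_stim_controls,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "htrf_design")
}

#' Generate a raw two-wavelength HTRF plate with a planted IC50
#'
#' Well-level intended HTRF ratios are `basal_ratio + window` for stimulated
#' DMSO controls, `basal_ratio` for unstimulated controls, and
#' `basal_ratio + window / (1 + (conc/ic50)^hill)` for compound wells;
#' multiplicative log-normal noise acts on the stimulation window. Raw 665 nm
#' and 620 nm counts are emitted such that
#' [htrf_ratio()] (`665/620 * 1e4`) reconstructs the intended ratio exactly.
#'
#' RNG stream order (from `design$seed`): one noise draw per well in output
#' row order (unstimulated controls, stimulated controls, then doses from the
#' top concentration down, replicates within dose).
#'
#' @param design A [plate_design()].
#' @param ic50 Planted midpoint, uM.
#' @param hill Planted Hill slope.
#' @param compound Compound id recorded for treated wells.
#' @return Tibble: `well`, `row`, `col`, `condition`, `compound`, `conc_uM`,
#'   `signal_665`, `signal_620`.
#' @export
generate_htrf_plate <- function(design, ic50, hill = 1,
                                compound = "compound") {
  stopifnot(inherits(design, "htrf_design"), ic50 > 0)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(design$seed)

  concs <- design$top_dose / design$dilution^(0:(design$n_doses - 1))
  wells <- tibble::tibble(
    condition = c(rep("unstim_dmso", design$n_unstim_controls),
                  rep("stim_dmso", design$n_stim_controls),
                  rep("stim_compound",
                      design$n_doses * design$replicates_per_dose)),
    compound = ifelse(condition == "stim_compound", compound, NA_character_),
    conc_uM = c(rep(0, design$n_unstim_controls + design$n_stim_controls),
                rep(concs, each = design$replicates_per_dose))
  )
  frac <- ifelse(wells$condition == "unstim_dmso", 0,
          ifelse(wells$condition == "stim_dmso", 1,
                 1 / (1 + (wells$conc_uM / ic50)^hill)))
  ratio <- design$basal_ratio +
    design$window * frac * lnoise(nrow(wells), design$noise_cv)
  n <- nrow(wells)
  wells$well <- sprintf("%s%d", LETTERS[(seq_len(n) - 1) %/% 24 + 1],
                        (seq_len(n) - 1) %% 24 + 1)
  wells$row <- substr(wells$well, 1, 1)
  wells$col <- (seq_len(n) - 1) %% 24 + 1
  wells$signal_620 <- 50000
  wells$signal_665 <- ratio * wells$signal_620 / 1e4
  wells[, c("well", "row", "col", "condition", "compound", "conc_uM",
            "signal_665", "signal_620")]
}
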