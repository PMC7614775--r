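# Functional-assay arithmetic: HTRF plate normalization, western-blot
# densitometry, delta-delta-Ct expression, trans-phosphorylation efficiency.

#' HTRF ratio from raw two-wavelength signals
#'
#' `(signal 665 nm / signal 620 nm) * 1e4`. The 620 nm donor signal acts as
#' an internal reference that cancels well-to-well dispensing variation.
#'
#' @param signal_665,signal_620 Fluorescence counts; vectorized.
#' @return HTRF ratio units.
#' @examples
#' htrf_ratio(2000, 1000) # 20000
#' @export
htrf_ratio <- function(signal_665, signal_620) {
  if (any(signal_620 <= 0)) {
    stop("signal_620 must be positive", call. = FALSE)
  }
  (signal_665 / signal_620) * 1e4
}

#' Normalize an HTRF plate to percent-of-stimulated-control
#'
#' The basal ratio (mean of the unstimulated DMSO wells) is subtracted from
#' every well, and stimulated wells are expressed as a percentage of the
#' basal-subtracted mean of the cytokine-stimulated DMSO control wells:
#' `100 * (ratio - basal) / (mean(stim DMSO ratio) - basal)`. A plate whose
#' stimulation window is not positive reflects assay failure and is
#' rejected. Values below basal come out negative and are reported as-is.
#'
#' @param wells Tibble with `condition` (`"unstim_dmso"`, `"stim_dmso"`,
#'   `"stim_compound"`), `signal_665`, `signal_620` and (for compound wells)
#'   `conc_uM`.
#' @return The wells with `ratio` and, for stimulated wells,
#'   `pct_of_control` columns added.
#' @export
htrf_normalize_plate <- function(wells) {
  stopifnot(all(c("condition", "signal_665", "signal_620") %in% names(wells)))
  if (!any(wells$condition == "unstim_dmso") ||
      !any(wells$condition == "stim_dmso")) {
    stop("plate needs at least one unstim_dmso and one stim_dmso well",
         call. = FALSE)
  }
  wells$ratio <- htrf_ratio(wells$signal_665, wells$signal_620)
  basal <- mean(wells$ratio[wells$condition == "unstim_dmso"])
  stim <- mean(wells$ratio[wells$condition == "stim_dmso"])
  window <- stim - basal
  if (window <= 0) {
    stop("stimulation window <= 0: plate rejected (assay failure)",
         call. = FALSE)
  }
  wells$pct_of_control <- ifelse(
    wells$condition == "unstim_dmso", NA_real_,
    100 * (wells$ratio - basal) / window
  )
  wells
}

#' Background-subtract and normalize densitometry lanes
#'
#' Each lane's background-corrected intensity is expressed as a percentage
#' of the mean background-corrected intensity of that experiment's control
#' lanes.
#'
#' @param records Tibble: `lane`, `target`, `raw`, `background`, `group`.
#' @param control_label The `group` value identifying control lanes.
#' @return The records with `corrected` and `pct_of_control` added.
#' @export
densitometry_normalize <- function(records, control_label) {
  stopifnot(all(records$raw >= records$background),
            all(records$background >= 0))
  records$corrected <- records$raw - records$background
  ctrl <- mean(records$corrected[records$group == control_label])
  if (!is.finite(ctrl) || ctrl <= 0) {
    stop("control lanes have non-positive corrected mean: ",
         "experiment rejected", call. = FALSE)
  }
  records$pct_of_control <- 100 * records$corrected / ctrl
  records
}

#' Relative expression by the 2^-ddCt method
#'
#' `dCt = Ct_gene - Ct_reference` per record; `ddCt = dCt_sample -
#' dCt_control`; fold-change `= 2^-ddCt`. Satisfies the reciprocity
#' `fold(a, b) * fold(b, a) == 1`.
#'
#' @param sample_ct,sample_ref_ct Target-gene and reference-gene Ct of the
#'   sample.
#' @param control_ct,control_ref_ct Same for the control (e.g. stimulated
#'   DMSO-treated).
#' @return Fold-change relative to the control; vectorized.
#' @examples
#' ddct_fold_change(25, 20, 24, 20) # one cycle later = 0.5
#' @export
ddct_fold_change <- function(sample_ct, sample_ref_ct,
                             control_ct, control_ref_ct) {
  cts <- c(sample_ct, sample_ref_ct, control_ct, control_ref_ct)
  if (any(!is.finite(cts)) || any(cts <= 0) || any(cts >= 45)) {
    stop("Ct values must be finite and in (0, 45)", call. = FALSE)
  }
  ddct <- (sample_ct - sample_ref_ct) - (control_ct - control_ref_ct)
  2^(-ddct)
}

#' Trans-phosphorylation efficiency and compound effect per construct pair
#'
#' For co-transfections of a catalytically active JAK1 donor (WT or C817A)
#' with a kinase-dead recipient (K908E or K908E/C817A), the DMSO
#' trans-phosphorylation efficiency of each pair is its phospho-JAK1 signal
#' as a percentage of the DMSO signal of the reference pair (both constructs
#' carrying native C817, i.e. donor WT / recipient K908E). Because that
#' efficiency differs between pairs, compound effects are normalized within
#' pair: compound-treated signal as a percentage of the same pair's DMSO
#' signal.
#'
#' @param records Tibble: `donor` (`"WT"` or `"C817A"`), `recipient`
#'   (`"K908E"` or `"K908E/C817A"`), `treatment` (`"DMSO"` or a compound
#'   id), `pjak1` (recipient-immunoprecipitate phospho-JAK1 intensity).
#' @param reference `c(donor, recipient)` of the reference pair.
#' @return Tibble per (pair, treatment): `donor`, `recipient`, `treatment`,
#'   `pjak1`, `dmso_efficiency_pct` (DMSO rows), `pct_of_pair_dmso`
#'   (compound rows). Pairs lacking a DMSO baseline are skipped with a
#'   warning.
#' @export
transphos_efficiency <- function(records,
                                 reference = c("WT", "K908E")) {
  stopifnot(all(records$pjak1 >= 0))
  pair_dmso <- records |>
    dplyr::filter(.data$treatment == "DMSO") |>
    dplyr::summarise(dmso_pjak1 = mean(.data$pjak1),
                     .by = c("donor", "recipient"))
  ref <- pair_dmso$dmso_pjak1[pair_dmso$donor == reference[1] &
                                pair_dmso$recipient == reference[2]]
  if (length(ref) != 1 || ref <= 0) {
    stop("DMSO baseline for the reference pair (", reference[1], "/",
         reference[2], ") is required", call. = FALSE)
  }
  pairs_all <- unique(records[, c("donor", "recipient")])
  skipped <- dplyr::anti_join(pairs_all, pair_dmso,
                              by = c("donor", "recipient"))
  if (nrow(skipped) > 0) {
    warning(nrow(skipped), " construct pair(s) without DMSO baseline skipped",
            call. = FALSE)
  }
  records |>
    dplyr::inner_join(pair_dmso, by = c("donor", "recipient")) |>
    dplyr::mutate(
      dmso_efficiency_pct = ifelse(.data$treatment == "DMSO",
                                   100 * .data$pjak1 / ref, NA_real_),
      pct_of_pair_dmso = ifelse(.data$treatment == "DMSO", NA_real_,
                                100 * .data$pjak1 / .data$dmso_pjak1)
    ) |>
    dplyr::select("donor", "recipient", "treatment", "pjak1",
                  "dmso_efficiency_pct", "pct_of_pair_dmso")
}
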