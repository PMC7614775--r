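# PSM-level TMT competition quantification: per-channel fractions of DMSO,
# QC filtering, grouping to protein-cysteine sites, and engagement calls.

#' Default QC thresholds for PSM filtering
#'
#' Records are excluded when the summed DMSO reporter intensity is strictly
#' below `min_dmso_sum`, the DMSO coefficient of variation (sample sd / mean)
#' is strictly above `max_dmso_cv`, the peptide is shorter than
#' `min_peptide_length`, non-tryptic, or a reversed-database match. Boundary
#' values (sum exactly 10,000; CV exactly 0.5) are retained.
#'
#' @param min_dmso_sum Minimum summed DMSO-channel intensity.
#' @param max_dmso_cv Maximum DMSO-channel coefficient of variation.
#' @param min_peptide_length Minimum peptide length, residues.
#' @export
qc_thresholds <- function(min_dmso_sum = 10000, max_dmso_cv = 0.5,
                          min_peptide_length = 6) {
  list(min_dmso_sum = min_dmso_sum, max_dmso_cv = max_dmso_cv,
       min_peptide_length = min_peptide_length)
}

intensity_matrix <- function(psms, channels) {
  missing <- setdiff(channels, names(psms))
  if (length(missing) > 0) {
    stop("PSM table lacks intensity columns for channel(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(psms[, channels, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Per-channel fractions of the mean DMSO intensity
#'
#' Engagement quantification starts by dividing each reporter-ion intensity
#' by the mean intensity of the DMSO (vehicle) channels of the same PSM.
#' A PSM whose DMSO mean is zero or absent is flagged `quantifiable = FALSE`
#' (its fractions are `NA`) rather than erroring.
#'
#' @param psms PSM tibble with one intensity column per channel label.
#' @param layout A [channel_layout()] (or [design_layout()] result).
#' @return Long tibble: `psm_id`, `channel`, `fraction`, `quantifiable`.
#' @examples
#' psms <- tibble::tibble(psm_id = "p1", `126` = 1e5, `127N` = 1e5,
#'                        `127C` = 2.5e4)
#' lay <- channel_layout(c("126", "127N"), list(trt = "127C"))
#' compute_psm_fractions(psms, lay)
#' @export
compute_psm_fractions <- function(psms, layout) {
  channels <- c(layout$dmso_channels, unlist(layout$treatment_channels))
  m <- intensity_matrix(psms, channels)
  dmean <- rowMeans(m[, layout$dmso_channels, drop = FALSE])
  ok <- is.finite(dmean) & dmean > 0
  frac <- m / ifelse(ok, dmean, NA_real_)
  tibble::tibble(
    psm_id = rep(psms$psm_id, times = length(channels)),
    channel = rep(channels, each = nrow(psms)),
    fraction = as.vector(frac),
    quantifiable = rep(ok, times = length(channels))
  )
}

dmso_stats <- function(psms, layout) {
  m <- intensity_matrix(psms, layout$dmso_channels)
  mu <- rowMeans(m)
  k <- ncol(m)
  sdev <- sqrt(rowSums((m - mu)^2) / (k - 1)) # sample sd, n-1 denominator
  list(sum = rowSums(m), cv = sdev / mu)
}

#' Filter PSMs on the standard competition-experiment QC rules
#'
#' Exclusion rules (each record attributed to its first failing rule, in
#' this fixed order): reversed-database match, non-tryptic peptide, peptide
#' shorter than the minimum length, summed DMSO intensity strictly below the
#' gate, DMSO coefficient of variation strictly above the gate. Filtering is
#' idempotent: re-applying it to its own output removes nothing.
#'
#' @inheritParams compute_psm_fractions
#' @param thresholds See [qc_thresholds()].
#' @return List: `psms` (retained records) and `report`, a `qc_report` with
#'   per-rule exclusion counts. Counts always satisfy
#'   `sum(excluded) + retained == total`.
#' @export
apply_qc_filters <- function(psms, layout, thresholds = qc_thresholds()) {
  ds <- dmso_stats(psms, layout)
  fails <- cbind(
    reverse      = psms$is_reverse,
    nontryptic   = !psms$is_tryptic,
    short_peptide = nchar(psms$peptide) < thresholds$min_peptide_length,
    low_dmso_sum = ds$sum < thresholds$min_dmso_sum,
    high_dmso_cv = ds$cv > thresholds$max_dmso_cv
  )
  first_fail <- apply(fails, 1, function(f) {
    w <- which(f)
    if (length(w) == 0) NA_integer_ else w[1]
  })
  rule_names <- colnames(fails)
  counts <- vapply(seq_along(rule_names),
                   function(j) sum(first_fail == j, na.rm = TRUE), 0L)
  names(counts) <- rule_names
  report <- structure(
    list(excluded = counts, retained = sum(is.na(first_fail)),
         total = nrow(psms)),
    class = "qc_report"
  )
  list(psms = psms[is.na(first_fail), , drop = FALSE], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("PSM QC report:", x$total, "records,", x$retained, "retained\n")
  for (r in names(x$excluded)) {
    cat(sprintf("  excluded (%s): %d\n", r, x$excluded[[r]]))
  }
  invisible(x)
}

#' Group filtered PSMs into per-cysteine engagement values
#'
#' For each PSM the per-channel fractions of DMSO are averaged over the
#' replicate channels of each condition; the site-level fraction is then the
#' median (default; configurable to the mean) of those per-PSM values over
#' all PSMs mapping to the same (protein, residue). Peptides carrying more
#' than one labeled cysteine contribute an identical row to every listed
#' residue, flagged `ambiguous` -- the site assignment cannot be resolved
#' from the reporter ions alone.
#'
#' @param psms Filtered PSM tibble (see [apply_qc_filters()]).
#' @param layout A [channel_layout()].
#' @param agg `"median"` (default) or `"mean"` aggregation across PSMs.
#' @return Site table: `site_id`, `protein`, `residue`, `condition`,
#'   `conc_uM`, `fraction`, `ratio` (DMSO/compound), `engagement_pct`
#'   (`100 * (1 - fraction)`), `n_psms`, `ambiguous`. Sites with no
#'   quantifiable PSM are absent, never imputed.
#' @export
aggregate_sites <- function(psms, layout, agg = c("median", "mean")) {
  agg_fun <- match.arg(agg)
  agg_fun <- if (agg_fun == "median") stats::median else mean
  if (nrow(psms) == 0) {
    return(tibble::tibble(site_id = character(), protein = character(),
                          residue = integer(), condition = character(),
                          conc_uM = double(), fraction = double(),
                          ratio = double(), engagement_pct = double(),
                          n_psms = integer(), ambiguous = logical()))
  }
  fr <- compute_psm_fractions(psms, layout)
  fr <- fr[fr$quantifiable, ]
  cond_of <- tibble::tibble(
    channel = unlist(layout$treatment_channels, use.names = FALSE),
    condition = rep(names(layout$treatment_channels),
                    lengths(layout$treatment_channels))
  )
  per_psm <- fr |>
    dplyr::inner_join(cond_of, by = "channel") |>
    dplyr::summarise(fraction = mean(.data$fraction),
                     .by = c("psm_id", "condition"))
  sites <- psms[, c("psm_id", "protein", "modified_residues")] |>
    dplyr::mutate(residues = strsplit(as.character(.data$modified_residues),
                                      "[,;]"),
                  ambiguous = lengths(.data$residues) > 1) |>
    tidyr::unnest(cols = "residues") |>
    dplyr::mutate(residue = as.integer(.data$residues)) |>
    dplyr::inner_join(per_psm, by = "psm_id",
                      relationship = "many-to-many") |>
    dplyr::summarise(fraction = agg_fun(.data$fraction),
                     n_psms = dplyr::n_distinct(.data$psm_id),
                     ambiguous = any(.data$ambiguous),
                     .by = c("protein", "residue", "condition"))
  sites <- sites |>
    dplyr::mutate(site_id = sprintf("%s_C%d", .data$protein, .data$residue),
                  ratio = 1 / .data$fraction,
                  engagement_pct = 100 * (1 - .data$fraction))
  meta <- layout$condition_meta
  if (!is.null(meta)) {
    sites <- dplyr::left_join(sites, meta[, c("condition", "conc_uM")],
                              by = "condition")
  } else {
    sites$conc_uM <- NA_real_
  }
  sites[, c("site_id", "protein", "residue", "condition", "conc_uM",
            "fraction", "ratio", "engagement_pct", "n_psms", "ambiguous")]
}

#' Call significantly engaged sites from competition ratios
#'
#' Competition ratios (DMSO/compound signal) at or above `ratio_threshold`
#' are called engaged; a ratio of 4 corresponds to a 75% loss of peptide
#' signal relative to DMSO. Ratios above `ratio_cap` -- including infinite
#' ratios from a zero compound signal -- are reported at the cap, and the
#' cap is applied before thresholding. `fraction` and `engagement_pct` are
#' kept consistent with the capped ratio so the identity
#' `engagement_pct == 100 * (1 - 1/ratio)` holds on every output row.
#'
#' @param sites Site table from [aggregate_sites()].
#' @param ratio_threshold Call threshold on the capped ratio (default 4).
#' @param ratio_cap Reporting cap for large ratios (default 20).
#' @return The site table with `ratio` capped and an `engaged` flag.
#' @export
call_engagement <- function(sites, ratio_threshold = 4, ratio_cap = 20) {
  stopifnot(ratio_threshold > 0, ratio_cap >= ratio_threshold)
  capped <- pmin(sites$ratio, ratio_cap)
  sites$ratio <- capped
  sites$fraction <- 1 / capped
  sites$engagement_pct <- 100 * (1 - 1 / capped)
  sites$engaged <- capped >= ratio_threshold
  sites
}

#' One-call site quantification: QC, aggregation and engagement calls
#'
#' @inheritParams apply_qc_filters
#' @inheritParams aggregate_sites
#' @inheritParams call_engagement
#' @return List: `sites` (called site table) and `qc` (the `qc_report`).
#' @export
quantify_sites <- function(psms, layout, thresholds = qc_thresholds(),
                           agg = "median", ratio_threshold = 4,
                           ratio_cap = 20) {
  filtered <- apply_qc_filters(psms, layout, thresholds)
  sites <- aggregate_sites(filtered$psms, layout, agg)
  list(sites = call_engagement(sites, ratio_threshold, ratio_cap),
       qc = filtered$report)
}
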