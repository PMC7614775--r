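# Readers and writers for the tabular interchange formats.

#' @importFrom rlang .data %||%
#' @importFrom utils head tail
NULL

#' Write / read a PSM quantification table (TSV)
#'
#' Columns: `psm_id`, `site_id`, `protein`, `peptide`, `modified_residues`
#' (comma-separated residue numbers), `charge`, `is_tryptic`, `is_reverse`,
#' then one intensity column per TMT channel label.
#'
#' @param psms PSM tibble.
#' @param path File path.
#' @export
write_psm_table <- function(psms, path) {
  readr::write_tsv(psms, path)
  invisible(path)
}

#' @rdname write_psm_table
#' @export
read_psm_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    modified_residues = readr::col_character(),
                    .default = readr::col_guess()))
}

#' Write / read a site engagement table (TSV)
#'
#' Columns: `site_id, protein, residue, condition, conc_uM, fraction, ratio,
#' engagement_pct, n_psms, ambiguous` and, after [call_engagement()],
#' `engaged`.
#'
#' @param sites Site tibble.
#' @param path File path.
#' @export
write_site_table <- function(sites, path) {
  readr::write_tsv(sites, path)
  invisible(path)
}

#' @rdname write_site_table
#' @export
read_site_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write / read an HTRF plate table (CSV)
#'
#' Columns: `well, row, col, condition, compound, conc_uM, signal_665,
#' signal_620`.
#'
#' @param wells Plate tibble.
#' @param path File path.
#' @export
write_plate <- function(wells, path) {
  readr::write_csv(wells, path)
  invisible(path)
}

#' @rdname write_plate
#' @export
read_plate <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write / read an experiment design (JSON)
#'
#' Serializes the channel-to-condition map together with the
#' pre-incubation time, noise level, seed and injected-violation rates, so
#' a simulation can be re-run or its PSM table re-quantified elsewhere.
#'
#' @param design An [experiment_design()].
#' @param path File path.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "abpp_design"))
  jsonlite::write_json(
    list(condition_map = design$condition_map,
         preincubation_time = design$preincubation_time,
         noise_cv = design$noise_cv, seed = design$seed,
         qc_violation_rates = as.list(design$qc_violation_rates)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  experiment_design(
    condition_map = tibble::as_tibble(x$condition_map),
    preincubation_time = x$preincubation_time,
    noise_cv = x$noise_cv, seed = x$seed,
    qc_violation_rates = unlist(x$qc_violation_rates)
  )
}

#' Read a PRM quantification table (CSV)
#'
#' Columns: `site_id, sample, condition, conc_uM, frag1..frag6`.
#'
#' @param path File path.
#' @export
read_prm_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
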