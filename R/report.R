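# Selectivity ranking and end-to-end pipeline orchestration.

#' Rank quantified sites by competition ratio
#'
#' Produces the selectivity profile for one condition: sites ordered by
#' capped competition ratio, descending, ties broken by `site_id`
#' lexicographically (fixed rule for determinism). Declared targets split
#' the engaged set into on- and off-target calls.
#'
#' @param sites Called site table ([call_engagement()] output).
#' @param condition Condition id to report; `NULL` if the table holds one.
#' @param targets Character vector of declared target `site_id`s.
#' @return A `selectivity_report`: `condition`, `ranking` (tibble `site_id`,
#'   `ratio`, `engagement_pct`, `engaged`), `engaged_site_count`,
#'   `top_site`, `off_targets`.
#' @export
rank_sites <- function(sites, condition = NULL, targets = character()) {
  if (!is.null(condition)) {
    sites <- sites[sites$condition == condition, , drop = FALSE]
  } else if (length(unique(sites$condition)) > 1) {
    stop("site table spans several conditions; pass `condition`",
         call. = FALSE)
  } else {
    condition <- unique(sites$condition)
  }
  ranking <- sites[order(-sites$ratio, sites$site_id),
                   c("site_id", "ratio", "engagement_pct", "engaged")]
  engaged_ids <- ranking$site_id[ranking$engaged]
  structure(
    list(condition = if (length(condition)) condition else NA_character_,
         ranking = tibble::as_tibble(ranking),
         engaged_site_count = length(engaged_ids),
         top_site = if (nrow(ranking)) ranking$site_id[1] else NA_character_,
         off_targets = setdiff(engaged_ids, targets),
         targets = targets),
    class = "selectivity_report"
  )
}

#' @export
print.selectivity_report <- function(x, ...) {
  cat("Selectivity report for", x$condition, "\n")
  cat("  sites quantified:", nrow(x$ranking),
      "| engaged:", x$engaged_site_count,
      "| off-target calls:", length(x$off_targets), "\n")
  print(utils::head(x$ranking, 10))
  invisible(x)
}

#' Run the full competition pipeline
#'
#' Simulation (or ingestion) -> QC filtering -> site aggregation ->
#' engagement calls -> selectivity report, with all artifacts and a
#' provenance manifest written to `out_dir` when given. Identical config
#' and seed give identical outputs.
#'
#' @param config A list with either `truths` (site-truth tibble) plus
#'   `design` ([experiment_design()]) to simulate, or `psm_file` (TSV) plus
#'   `layout`; optional `thresholds`, `agg`, `ratio_threshold`, `ratio_cap`,
#'   `targets`, `report_condition`.
#' @param out_dir Output directory (created); `NULL` to skip writing.
#' @return List: `psms`, `ledger` (simulated runs), `sites`, `qc`, `report`,
#'   `provenance`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  simulated <- !is.null(config$truths)
  if (simulated) {
    stopifnot(inherits(config$design, "abpp_design"))
    gen <- generate_psm_table(config$truths, config$design)
    psms <- gen$psms
    ledger <- gen$ledger
    layout <- design_layout(config$design)
  } else {
    stopifnot(!is.null(config$psm_file), !is.null(config$layout))
    psms <- read_psm_table(config$psm_file)
    ledger <- NULL
    layout <- config$layout
  }
  thresholds <- config$thresholds %||% qc_thresholds()
  quant <- quantify_sites(psms, layout, thresholds,
                          agg = config$agg %||% "median",
                          ratio_threshold = config$ratio_threshold %||% 4,
                          ratio_cap = config$ratio_cap %||% 20)
  cond <- config$report_condition %||%
    utils::tail(unique(quant$sites$condition), 1)
  report <- rank_sites(quant$sites, cond,
                       targets = config$targets %||% character())
  provenance <- list(
    package_version = as.character(utils::packageVersion("abppquant")),
    config_hash = rlang::hash(config),
    seed = if (simulated) config$design$seed else NA_integer_,
    n_psms_in = nrow(psms),
    n_psms_retained = quant$qc$retained,
    input_digest = if (!simulated) {
      unname(tools::md5sum(config$psm_file))
    } else NA_character_
  )
  out <- list(psms = psms, ledger = ledger, sites = quant$sites,
              qc = quant$qc, report = report, provenance = provenance)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ok <- FALSE
    on.exit(if (!ok) unlink(file.path(out_dir,
                                      c("psms.tsv", "sites.tsv", "qc.json",
                                        "report.json", "truth_ledger.json",
                                        "provenance.json"))))
    if (simulated) {
      write_psm_table(psms, file.path(out_dir, "psms.tsv"))
      jsonlite::write_json(ledger, file.path(out_dir, "truth_ledger.json"))
    }
    write_site_table(quant$sites, file.path(out_dir, "sites.tsv"))
    jsonlite::write_json(unclass(quant$qc), file.path(out_dir, "qc.json"),
                         auto_unbox = TRUE)
    jsonlite::write_json(
      list(condition = report$condition,
           engaged_site_count = report$engaged_site_count,
           top_site = report$top_site, off_targets = report$off_targets,
           ranking = report$ranking),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE)
    ok <- TRUE
  }
  out
}
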