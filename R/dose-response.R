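# Four-parameter logistic (4PL) dose-response fitting for TE50/IC50
# estimation, with case-resampling bootstrap confidence intervals and the
# closed-form kinetic TE50 of the covalent-occupancy model.

#' Assemble a dose-response series
#'
#' @param conc Concentrations, uM (strictly positive).
#' @param response Responses (e.g. engagement_pct or percent-of-control).
#' @param replicate Replicate index per point.
#' @param compound,readout,time Optional annotations carried along.
#' @return Tibble with columns `conc`, `response`, `replicate` and the
#'   annotations as attributes.
#' @export
dose_response_series <- function(conc, response, replicate = 1L,
                                 compound = NA_character_,
                                 readout = NA_character_, time = NA_real_) {
  stopifnot(length(conc) == length(response), all(conc > 0),
            all(is.finite(response)))
  out <- tibble::tibble(conc = conc, response = response,
                        replicate = rep_len(replicate, length(conc)))
  attr(out, "compound") <- compound
  attr(out, "readout") <- readout
  attr(out, "time") <- time
  out
}

#' Box constraints for 4PL fitting
#'
#' Defaults suit percent-scale readouts from seven-point plate designs: the
#' lower asymptote free in `[0, 20]`, the upper in `[80, 120]`, the Hill
#' slope magnitude in `[0.3, 5]`. All overridable per fit.
#'
#' @param bottom,top,hill Length-2 numeric `c(lower, upper)` bounds.
#' @export
pl4_constraints <- function(bottom = c(0, 20), top = c(80, 120),
                            hill = c(0.3, 5)) {
  stopifnot(bottom[1] <= bottom[2], top[1] <= top[2],
            hill[1] > 0, hill[1] <= hill[2])
  list(bottom = bottom, top = top, hill = hill)
}

#' Evaluate a four-parameter logistic curve
#'
#' `y = bottom + (top - bottom) / (1 + (x / midpoint)^hill)`. With
#' `hill > 0` the curve decreases with concentration (inhibition readouts);
#' a negative `hill` gives the increasing form (engagement readouts).
#'
#' @param x Concentrations.
#' @param bottom,top Lower/upper asymptotes.
#' @param hill Hill slope (signed; see above).
#' @param midpoint Half-maximal concentration.
#' @export
pl4 <- function(x, bottom, top, hill, midpoint) {
  bottom + (top - bottom) / (1 + (x / midpoint)^hill)
}

#' Fit a four-parameter logistic dose-response model
#'
#' Fits `y = bottom + (top - bottom)/(1 + (x/midpoint)^hill)` by bounded
#' Levenberg-Marquardt least squares in log10-concentration space. The
#' direction of the curve (increasing engagement vs decreasing
#' percent-of-control) is detected from the sign of the response/log-dose
#' correlation and carried in the sign of the fitted `hill`; the reported
#' `bottom` is always the lower asymptote. Starting values: asymptotes from
#' the extreme responses, midpoint from the concentration bracketing the
#' half-maximal response, Hill slope 1. The fit is deterministic for
#' identical inputs.
#'
#' @param series A [dose_response_series()] or tibble with `conc`,
#'   `response` columns.
#' @param constraints See [pl4_constraints()].
#' @param start Optional additional starting values (list with `bottom`,
#'   `top`, `hill`, `logmid`), tried before the default deterministic grid
#'   of starting slopes and midpoints; the lowest-RSS converged fit is
#'   kept.
#' @param direction Optional direction override (+1 decreasing, -1
#'   increasing); detected from the data when `NULL`.
#' @return An object of class `pl4_fit`: `bottom`, `top`, `hill`,
#'   `midpoint` (uM), `ci95` (filled by [bootstrap_ci()]), `rss`,
#'   `converged`, `extrapolated` (midpoint outside the tested span).
#' @export
fit_4pl <- function(series, constraints = pl4_constraints(), start = NULL,
                    direction = NULL) {
  x <- series$conc
  y <- series$response
  if (length(unique(x)) < 4) {
    stop("4PL fit requires at least 4 distinct concentrations",
         call. = FALSE)
  }
  if (any(!is.finite(y))) stop("non-finite responses", call. = FALSE)
  lx <- log10(x)
  if (is.null(direction)) {
    direction <- if (stats::cor(lx, y) <= 0) 1 else -1 # +1: decreasing
  }
  clamp <- function(v, b) min(max(v, b[1]), b[2])
  residual_fun <- function(p) {
    y - (p[1] + (p[2] - p[1]) / (1 + 10^(direction * p[3] * (lx - p[4]))))
  }
  lower <- c(constraints$bottom[1], constraints$top[1],
             constraints$hill[1], min(lx) - 2)
  upper <- c(constraints$bottom[2], constraints$top[2],
             constraints$hill[2], max(lx) + 2)
  b0 <- clamp(min(y), constraints$bottom)
  t0 <- clamp(max(y), constraints$top)
  m0 <- clamp(lx[which.min(abs(y - (b0 + t0) / 2))], range(lx) + c(-1, 1))
  grid <- expand.grid(hill = c(0.5, 1, 2),
                      logmid = unique(c(m0, mean(range(lx)))))
  starts <- lapply(seq_len(nrow(grid)), function(i) {
    c(bottom = b0, top = t0, hill = clamp(grid$hill[i], constraints$hill),
      logmid = grid$logmid[i])
  })
  if (!is.null(start)) {
    starts <- c(list(c(bottom = start$bottom, top = start$top,
                       hill = start$hill, logmid = start$logmid)), starts)
  }
  fit <- NULL
  for (par0 in starts) {
    cand <- tryCatch(
      minpack.lm::nls.lm(
        par = par0, lower = lower, upper = upper, fn = residual_fun,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                             ptol = 1e-15)),
      error = function(e) NULL
    )
    # nls.lm info codes 1-3 indicate convergence in f, p, or both and
    # 4 convergence of the gradient (e.g. an exact zero-residual fit);
    # a later start must beat the incumbent by a real margin (near-zero
    # deviance ties arise when few distinct doses make the fit
    # exactly determined, where any interpolant is as good)
    if (!is.null(cand) && cand$info %in% 1:4 &&
        (is.null(fit) ||
           cand$deviance < fit$deviance - max(1e-12, 1e-9 * fit$deviance))) {
      fit <- cand
    }
  }
  if (is.null(fit)) {
    return(structure(list(bottom = NA_real_, top = NA_real_,
                          hill = NA_real_, midpoint = NA_real_,
                          ci95 = c(NA_real_, NA_real_), rss = NA_real_,
                          converged = FALSE, extrapolated = NA,
                          direction = direction, series = series),
                     class = "pl4_fit"))
  }
  p <- fit$par
  midpoint <- 10^p[["logmid"]]
  structure(
    list(bottom = p[["bottom"]], top = p[["top"]],
         hill = direction * p[["hill"]], midpoint = midpoint,
         ci95 = c(NA_real_, NA_real_),
         rss = fit$deviance, converged = TRUE,
         extrapolated = midpoint < min(x) || midpoint > max(x),
         direction = direction, series = series),
    class = "pl4_fit"
  )
}

#' @export
print.pl4_fit <- function(x, ...) {
  if (!x$converged) {
    cat("4PL fit: did not converge\n")
    return(invisible(x))
  }
  cat(sprintf(
    "4PL fit: midpoint %.4g uM (hill %.3g, bottom %.3g, top %.3g)%s\n",
    x$midpoint, x$hill, x$bottom, x$top,
    if (isTRUE(x$extrapolated)) " [midpoint outside tested range]" else ""))
  if (all(is.finite(x$ci95))) {
    cat(sprintf("  95%% CI [%.4g, %.4g] uM\n", x$ci95[1], x$ci95[2]))
  }
  invisible(x)
}

#' @export
predict.pl4_fit <- function(object, conc, ...) {
  pl4(conc, object$bottom, object$top, object$hill, object$midpoint)
}

#' Bootstrap confidence interval for the 4PL midpoint
#'
#' Percentile 95% interval of the midpoint from case-resampling of the
#' series' points (rows), refitting with the same constraints and the
#' full-data estimate as the starting point (the standard warm start for
#' bootstrap refits). Resamples with fewer than four distinct
#' concentrations cannot support a 4PL and are skipped; their count is
#' returned. Seeded and reproducible.
#'
#' @param series The fitted series.
#' @param fit The [fit_4pl()] result (provides constraints context).
#' @param n_boot Number of bootstrap resamples (>= 200).
#' @param seed Integer seed.
#' @param constraints Constraints used for refits.
#' @return The `pl4_fit` with `ci95` filled and attributes
#'   `n_boot_used`/`n_boot_skipped`.
#' @export
bootstrap_ci <- function(series, fit, n_boot = 500, seed = 1L,
                         constraints = pl4_constraints()) {
  stopifnot(n_boot >= 200, fit$converged)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  n <- nrow(series)
  mids <- rep(NA_real_, n_boot)
  skipped <- 0L
  warm <- list(bottom = fit$bottom, top = fit$top, hill = abs(fit$hill),
               logmid = log10(fit$midpoint))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    res <- series[idx, ]
    if (length(unique(res$conc)) < 4) {
      skipped <- skipped + 1L
      next
    }
    bf <- tryCatch(fit_4pl(res, constraints, start = warm,
                           direction = fit$direction),
                   error = function(e) NULL)
    if (!is.null(bf) && bf$converged) mids[b] <- bf$midpoint
  }
  if (skipped > 0) {
    warning(sprintf("%d degenerate bootstrap resamples skipped", skipped),
            call. = FALSE)
  }
  fit$ci95 <- unname(stats::quantile(mids, c(0.025, 0.975), na.rm = TRUE))
  attr(fit, "n_boot_used") <- sum(is.finite(mids))
  attr(fit, "n_boot_skipped") <- skipped
  fit
}

#' Fit TE50s across pre-incubation times
#'
#' Convenience wrapper fitting one 4PL per pre-incubation time; covalent
#' ligands show strictly decreasing midpoints with longer exposure.
#'
#' @param series_list Named list of series, names = time in minutes.
#' @param constraints See [pl4_constraints()].
#' @return Tibble `time`, `midpoint`, `converged` plus the fits as a
#'   list-column, times sorted increasing.
#' @export
te50_time_series <- function(series_list, constraints = pl4_constraints()) {
  times <- as.numeric(names(series_list))
  stopifnot(!anyNA(times), !is.unsorted(times, strictly = TRUE))
  fits <- lapply(series_list, fit_4pl, constraints = constraints)
  tibble::tibble(
    time = times,
    midpoint = vapply(fits, function(f) f$midpoint, 0),
    converged = vapply(fits, function(f) f$converged, TRUE),
    fit = fits
  )
}
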