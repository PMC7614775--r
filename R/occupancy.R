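#' Covalent site occupancy under two-step irreversible kinetics
#'
#' Fractional occupancy of a cysteine site by a covalent ligand after
#' pre-incubation, under the standard two-step model (reversible binding with
#' affinity `K_I` followed by irreversible bond formation at rate `k_inact`):
#'
#' \deqn{occ(C, t) = occ_{max} \cdot (1 - e^{-k_{inact} \, t \, C / (K_I + C)})}
#'
#' Unliganded sites have zero occupancy at every concentration, as do zero
#' concentration and zero time. The model makes the half-occupancy
#' concentration (TE50) shrink as pre-incubation time grows, the hallmark
#' behaviour of covalent ligands (see [te50_kinetic()]).
#'
#' @param truth A site-truth row (see [site_truth()]) or any list with fields
#'   `liganded`, `k_inact`, `K_I` and `occ_max`.
#' @param conc Compound concentration(s), uM. Vectorized.
#' @param time Pre-incubation time, minutes.
#' @return Fractional occupancy in `[0, 1]`, same length as `conc`.
#' @examples
#' s <- site_truth("JAK1", 817, liganded = TRUE, k_inact = 0.1, K_I = 2)
#' occupancy(s, conc = c(0, 2, 20), time = 60)
#' @export
occupancy <- function(truth, conc, time) {
  if (any(conc < 0) || any(time < 0)) {
    stop("`conc` and `time` must be non-negative", call. = FALSE)
  }
  if (!isTRUE(truth$liganded)) {
    return(rep(0, length(conc)))
  }
  stopifnot(truth$K_I > 0, truth$k_inact >= 0,
            truth$occ_max >= 0, truth$occ_max <= 1)
  truth$occ_max * (1 - exp(-truth$k_inact * time * conc / (truth$K_I + conc)))
}

#' Closed-form TE50 of the covalent-occupancy model
#'
#' Concentration at which [occupancy()] reaches one half (for `occ_max = 1`),
#' obtained by inverting the occupancy expression:
#' \deqn{TE_{50}(t) = K_I \ln 2 / (k_{inact} t - \ln 2)}
#'
#' Defined only when `k_inact * time > ln 2`; below that the site can never
#' reach 50% occupancy and the function throws. TE50 is strictly decreasing
#' in both `time` and `k_inact`, and proportional to `K_I` -- covalent
#' potency is a moving target that improves with exposure time.
#'
#' @param K_I Reversible-binding constant, uM.
#' @param k_inact Inactivation rate constant, per minute.
#' @param time Pre-incubation time, minutes.
#' @return TE50 in uM.
#' @examples
#' te50_kinetic(K_I = 10, k_inact = 2 * log(2), time = 1) # == 10
#' @export
te50_kinetic <- function(K_I, k_inact, time) {
  stopifnot(K_I > 0, k_inact >= 0, time >= 0)
  kt <- k_inact * time
  if (any(kt <= log(2))) {
    stop("TE50 undefined: k_inact * time must exceed ln(2) ",
         "(occupancy never reaches 50%)", call. = FALSE)
  }
  K_I * log(2) / (kt - log(2))
}
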