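# Small builders shared across the suite.

# one PSM row with explicit channel intensities
make_psm <- function(id, intensities, protein = "PROT0001", residue = 100,
                     peptide = "LAVCDEFGK", tryptic = TRUE, reverse = FALSE,
                     residues = as.character(residue)) {
  row <- tibble::tibble(
    psm_id = id, site_id = sprintf("%s_C%d", protein, residue),
    protein = protein, peptide = peptide, modified_residues = residues,
    charge = 2L, is_tryptic = tryptic, is_reverse = reverse
  )
  row[names(intensities)] <- as.list(unname(intensities))
  row
}

# duplicate-DMSO / single-treatment-channel layout
toy_layout <- function(trt_channels = list(`trt` = "127C"),
                       meta = NULL) {
  channel_layout(c("126", "127N"), trt_channels, meta)
}

# a covalent site whose kinetic TE50 (occ_max = 1) is `te50` at `time` min:
# k_inact * time = 8 ln 2 so saturation is ~99.6% and K_I = 7 * te50
kinetic_truth <- function(te50, time = 60, protein = "JAK1", residue = 817,
                          n_psms = 3) {
  site_truth(protein, residue, liganded = TRUE,
             k_inact = 8 * log(2) / time, K_I = 7 * te50, n_psms = n_psms)
}

# competition dose-response over two TMT 10-plexes (7 concentrations,
# duplicate compound channels), returning an engagement series
engagement_series <- function(truth, concs, noise_cv, seed, time = 60) {
  eng <- NULL
  splits <- split(concs, ceiling(seq_along(concs) / 4))
  for (i in seq_along(splits)) {
    d <- tmt10_design(splits[[i]], preincubation_time = time,
                      noise_cv = noise_cv, seed = seed + i)
    g <- generate_psm_table(truth, d)
    q <- quantify_sites(g$psms, design_layout(d))
    eng <- rbind(eng, q$sites[, c("conc_uM", "engagement_pct")])
  }
  dose_response_series(eng$conc_uM, eng$engagement_pct)
}
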