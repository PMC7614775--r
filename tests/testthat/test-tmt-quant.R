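test_that("per-channel fractions divide by the mean DMSO intensity", {
  lay <- toy_layout()
  p1 <- make_psm("p1", c(`126` = 1e5, `127N` = 1e5, `127C` = 2.5e4))
  fr <- compute_psm_fractions(p1, lay)
  expect_equal(fr$fraction[fr$channel == "127C"], 0.25)
  expect_equal(fr$fraction[fr$channel == "126"], 1)
  # unequal DMSO replicates: denominator is their mean (hand-checked)
  p2 <- make_psm("p2", c(`126` = 8e4, `127N` = 1.2e5, `127C` = 5e4))
  fr2 <- compute_psm_fractions(p2, lay)
  expect_equal(fr2$fraction[fr2$channel == "127C"], 0.5)
  # all channels equal -> all fractions 1
  p3 <- make_psm("p3", c(`126` = 7e4, `127N` = 7e4, `127C` = 7e4))
  expect_equal(compute_psm_fractions(p3, lay)$fraction, rep(1, 3))
  # zero DMSO mean -> flagged unquantifiable, not an error
  p4 <- make_psm("p4", c(`126` = 0, `127N` = 0, `127C` = 5e4))
  fr4 <- compute_psm_fractions(p4, lay)
  expect_false(any(fr4$quantifiable))
  expect_true(all(is.na(fr4$fraction)))
})

test_that("QC filters match the stated rules including boundaries", {
  lay <- toy_layout()
  mk <- function(id, d1, d2, ...) {
    make_psm(id, c(`126` = d1, `127N` = d2, `127C` = 1e4), ...)
  }
  psms <- dplyr::bind_rows(
    mk("low", 4000, 5000),           # sum 9000 < 10,000 -> excluded
    mk("cv", 10000, 30000),          # sample-sd CV 0.707 > 0.5 -> excluded
    mk("sum_edge", 5000, 5000),      # sum exactly 10,000 -> retained
    mk("rev", 1e5, 1e5, reverse = TRUE),
    mk("ntr", 1e5, 1e5, tryptic = FALSE),
    mk("short", 1e5, 1e5, peptide = "ACDEK"), # 5 residues -> excluded
    mk("clean", 1e5, 1e5)
  )
  res <- apply_qc_filters(psms, lay)
  expect_setequal(res$psms$psm_id, c("sum_edge", "clean"))
  expect_equal(unname(res$report$excluded),
               c(1L, 1L, 1L, 1L, 1L)) # one per rule, fixed order
  expect_equal(res$report$retained + sum(res$report$excluded),
               res$report$total)
  # CV boundary: sd/mean exactly 0.5 is retained (rule is strictly >)
  # channels (a, b) with mean m and sample sd m/2: b - a = m / sqrt(2)
  m <- 2e4; delta <- m / sqrt(2) / 2
  edge <- mk("cv_edge", m - delta, m + delta)
  expect_equal(nrow(apply_qc_filters(edge, lay)$psms), 1)
})

test_that("first-failing-rule attribution and idempotence hold", {
  lay <- toy_layout()
  # record violating both reverse and low-sum counts under reverse only
  both <- make_psm("b1", c(`126` = 100, `127N` = 100, `127C` = 10),
                   reverse = TRUE)
  rep1 <- apply_qc_filters(both, lay)$report
  expect_equal(rep1$excluded[["reverse"]], 1L)
  expect_equal(rep1$excluded[["low_dmso_sum"]], 0L)
  set.seed(7)
  truths <- sample_site_truths(50)
  d <- tmt10_design(c(10, 1), noise_cv = 0.1, seed = 8,
                    qc_violation_rates = c(low_intensity = 0.1,
                                           reverse = 0.1))
  psms <- generate_psm_table(truths, d)$psms
  lay2 <- design_layout(d)
  once <- apply_qc_filters(psms, lay2)
  twice <- apply_qc_filters(once$psms, lay2)
  expect_identical(once$psms, twice$psms)
  expect_equal(sum(twice$report$excluded), 0L)
})

test_that("QC report on generator output matches the injected ledger", {
  set.seed(31)
  truths <- sample_site_truths(400)
  d <- tmt10_design(c(10, 1), noise_cv = 0, seed = 32,
                    qc_violation_rates = c(low_intensity = 0.03,
                                           high_cv = 0.03,
                                           reverse = 0.03,
                                           nontryptic = 0.03))
  g <- generate_psm_table(truths, d)
  rep <- apply_qc_filters(g$psms, design_layout(d))$report
  truth_counts <- table(factor(g$ledger$violation,
                               c("low_intensity", "high_cv", "reverse",
                                 "nontryptic", "none")))
  expect_equal(rep$excluded[["low_dmso_sum"]],
               unname(truth_counts[["low_intensity"]]))
  expect_equal(rep$excluded[["high_dmso_cv"]],
               unname(truth_counts[["high_cv"]]))
  expect_equal(rep$excluded[["reverse"]], unname(truth_counts[["reverse"]]))
  expect_equal(rep$excluded[["nontryptic"]],
               unname(truth_counts[["nontryptic"]]))
  expect_equal(rep$retained, unname(truth_counts[["none"]]))
})

test_that("site aggregation takes replicate means then the PSM median", {
  lay <- toy_layout(list(trt = c("127C", "128N")))
  # PSM 1: replicate fractions (0.15, 0.25) -> mean 0.2
  # PSM 2: replicate fractions (0.35, 0.25) -> mean 0.3
  psms <- dplyr::bind_rows(
    make_psm("p1", c(`126` = 1e5, `127N` = 1e5, `127C` = 1.5e4,
                     `128N` = 2.5e4)),
    make_psm("p2", c(`126` = 1e5, `127N` = 1e5, `127C` = 3.5e4,
                     `128N` = 2.5e4))
  )
  sites <- aggregate_sites(psms, lay)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$fraction, 0.25) # median of {0.2, 0.3}
  expect_equal(sites$ratio, 4)
  expect_equal(sites$engagement_pct, 75)
  expect_equal(sites$n_psms, 2L)
  # single PSM with equal duplicate channels passes through
  one <- aggregate_sites(psms[1, ], lay)
  expect_equal(one$fraction, 0.2)
  # mean aggregation is available
  expect_equal(aggregate_sites(psms, lay, agg = "mean")$fraction, 0.25)
})

test_that("multi-cysteine peptides yield identical flagged rows per residue", {
  lay <- toy_layout()
  psm <- make_psm("p1", c(`126` = 1e5, `127N` = 1e5, `127C` = 2.5e4),
                  protein = "JAK1", residue = 810, residues = "810,817")
  sites <- aggregate_sites(psm, lay)
  expect_setequal(sites$site_id, c("JAK1_C810", "JAK1_C817"))
  expect_true(all(sites$ambiguous))
  expect_equal(unique(sites$fraction), 0.25)
  # site with no quantifiable PSM is absent, not imputed
  bad <- make_psm("p2", c(`126` = 0, `127N` = 0, `127C` = 1e4),
                  protein = "GONE", residue = 5)
  expect_equal(nrow(aggregate_sites(bad, lay)), 0)
})

test_that("engagement calls cap ratios and keep the engagement identity", {
  lay <- toy_layout()
  mk <- function(id, trt, prot, res) {
    make_psm(id, c(`126` = 1e5, `127N` = 1e5, `127C` = trt),
             protein = prot, residue = res)
  }
  psms <- dplyr::bind_rows(mk("a", 2.5e4, "A", 1),   # ratio 4
                           mk("b", 1e5 / 3.9, "B", 1), # ratio 3.9
                           mk("c", 0, "C", 1))       # ratio Inf -> cap
  sites <- call_engagement(aggregate_sites(psms, lay))
  a <- sites[sites$site_id == "A_C1", ]
  expect_true(a$engaged)
  expect_equal(a$engagement_pct, 75)
  expect_false(sites$engaged[sites$site_id == "B_C1"])
  cc <- sites[sites$site_id == "C_C1", ]
  expect_equal(cc$ratio, 20)
  expect_true(cc$engaged)
  # identity audit across all emitted rows
  expect_equal(sites$engagement_pct, 100 * (1 - 1 / sites$ratio))
  expect_equal(sites$fraction, 1 / sites$ratio)
})

test_that("noise-free engagement equals planted occupancy exactly", {
  tr <- dplyr::bind_rows(
    kinetic_truth(2, residue = 817),
    site_truth("DECOY", 10, n_psms = 4)
  )
  d <- tmt10_design(c(30, 10, 3, 1), noise_cv = 0, seed = 5)
  g <- generate_psm_table(tr, d)
  lay <- design_layout(d)
  sites <- aggregate_sites(apply_qc_filters(g$psms, lay)$psms, lay)
  jak <- sites[sites$protein == "JAK1", ]
  occ <- occupancy(tr[1, ], jak$conc_uM, 60)
  expect_equal(jak$engagement_pct, 100 * occ, tolerance = 1e-12)
  expect_equal(sites$engagement_pct[sites$protein == "DECOY"],
               rep(0, 4), tolerance = 1e-12)
})

test_that("engagement error stays small under 10% reporter noise", {
  set.seed(61)
  n <- 250
  truths <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    site_truth(sprintf("LIG%03d", i), 100, liganded = TRUE,
               k_inact = 8 * log(2) / 60, K_I = 10^runif(1, -0.5, 1.5),
               n_psms = 1L + rpois(1, 2))
  }))
  d <- tmt10_design(4, noise_cv = 0.1, seed = 62)
  g <- generate_psm_table(truths, d)
  lay <- design_layout(d)
  sites <- aggregate_sites(apply_qc_filters(g$psms, lay)$psms, lay)
  planted <- 100 * vapply(seq_len(n),
                          function(i) occupancy(truths[i, ], 4, 60), 0)
  obs <- sites$engagement_pct[match(truths$site_id, sites$site_id)]
  expect_lt(median(abs(obs - planted)), 5)
})
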