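test_that("HTRF ratio formula and guards", {
  expect_equal(htrf_ratio(2000, 1000), 20000)
  expect_equal(htrf_ratio(0, 1000), 0)
  expect_equal(round(htrf_ratio(1234, 5678), 1), 2173.3)
  expect_error(htrf_ratio(100, 0), "positive")
})

well <- function(condition, ratio, conc = 0) {
  tibble::tibble(condition = condition, conc_uM = conc,
                 signal_665 = ratio * 5, signal_620 = 50000)
}

test_that("plate normalization subtracts basal and scales to stim controls", {
  plate <- dplyr::bind_rows(
    well("unstim_dmso", 5000), well("unstim_dmso", 5000),
    well("stim_dmso", 15000), well("stim_dmso", 15000),
    well("stim_compound", 7500, conc = 1),
    well("stim_compound", 5000, conc = 10),  # at basal -> 0%
    well("stim_compound", 4000, conc = 50)   # below basal -> negative
  )
  np <- htrf_normalize_plate(plate)
  expect_equal(np$pct_of_control[np$condition == "stim_dmso"], c(100, 100))
  cw <- np$pct_of_control[np$condition == "stim_compound"]
  expect_equal(cw, c(25, 0, -10)) # (7500-5000)/(15000-5000); below-basal kept
  # rescaling every raw signal by a common factor changes nothing
  sc <- plate
  sc$signal_665 <- sc$signal_665 * 3.7
  sc$signal_620 <- sc$signal_620 * 3.7
  expect_equal(htrf_normalize_plate(sc)$pct_of_control, np$pct_of_control)
  # dead plate (no stimulation window) is rejected
  dead <- dplyr::bind_rows(well("unstim_dmso", 5000), well("stim_dmso", 5000))
  expect_error(htrf_normalize_plate(dead), "rejected")
})

test_that("densitometry normalizes corrected signal to control lanes", {
  recs <- tibble::tibble(
    lane = c("c1", "c2", "s1", "s2"), target = "pSTAT1",
    raw = c(900, 1300, 600, 150), background = c(100, 100, 100, 150),
    group = c("ctrl", "ctrl", "trt", "trt")
  )
  out <- densitometry_normalize(recs, "ctrl")
  expect_equal(out$pct_of_control, c(80, 120, 50, 0))
  expect_equal(mean(out$pct_of_control[out$group == "ctrl"]), 100)
  # scale invariance of raw signals
  sc <- recs
  sc$raw <- sc$raw * 2
  sc$background <- sc$background * 2
  expect_equal(densitometry_normalize(sc, "ctrl")$pct_of_control,
               out$pct_of_control)
  zero <- tibble::tibble(lane = "c1", target = "x", raw = 50,
                         background = 50, group = "ctrl")
  expect_error(densitometry_normalize(zero, "ctrl"), "rejected")
})

test_that("2^-ddCt fold changes behave as the method prescribes", {
  # sample one cycle later than control relative to reference -> halved
  expect_equal(ddct_fold_change(25, 20, 24, 20), 0.5)
  # control against itself -> 1
  expect_equal(ddct_fold_change(24, 20, 24, 20), 1)
  # hand computation: dCt 2.0 vs 4.5 -> fold 2^2.5
  expect_equal(ddct_fold_change(22, 20, 24.5, 20), 2^2.5)
  expect_error(ddct_fold_change(50, 20, 24, 20), "45")
})

test_that("ddCt reciprocity: fold(a,b) * fold(b,a) == 1", {
  set.seed(5)
  for (i in 1:20) {
    ct <- runif(4, 15, 35)
    expect_equal(ddct_fold_change(ct[1], ct[2], ct[3], ct[4]) *
                   ddct_fold_change(ct[3], ct[4], ct[1], ct[2]), 1)
  }
})

transphos_fixture <- function() {
  tibble::tibble(
    donor = rep(c("WT", "WT", "C817A", "C817A"), 2),
    recipient = rep(c("K908E", "K908E/C817A"), 4),
    treatment = rep(c("DMSO", "compound"), each = 4),
    pjak1 = c(1000, 800, 400, 300, # DMSO: WT pairs strongest
              0, 0, 380, 290)      # compound blocks only WT-donor pairs
  )
}

test_that("trans-phosphorylation efficiency normalizes to the WT/K908E pair", {
  recs <- transphos_fixture()
  out <- transphos_efficiency(recs)
  ref <- out[out$donor == "WT" & out$recipient == "K908E" &
               out$treatment == "DMSO", ]
  expect_equal(ref$dmso_efficiency_pct, 100)
  halfpair <- out[out$donor == "C817A" & out$recipient == "K908E" &
                    out$treatment == "DMSO", ]
  expect_equal(halfpair$dmso_efficiency_pct, 40)
  # complete blockade: compound signal 0 against nonzero DMSO baseline
  blocked <- out[out$donor == "WT" & out$treatment == "compound", ]
  expect_equal(blocked$pct_of_pair_dmso, c(0, 0))
  # compound rows are normalized within their own pair
  spared <- out[out$donor == "C817A" & out$treatment == "compound", ]
  expect_equal(spared$pct_of_pair_dmso, 100 * c(380 / 400, 290 / 300))
  # scale invariance
  sc <- recs
  sc$pjak1 <- sc$pjak1 * 2.5
  expect_equal(transphos_efficiency(sc)$pct_of_pair_dmso,
               out$pct_of_pair_dmso)
  # pair without DMSO baseline is skipped with a warning
  extra <- tibble::tibble(donor = "EXTRA", recipient = "K908E",
                          treatment = "compound", pjak1 = 5)
  expect_warning(res <- transphos_efficiency(dplyr::bind_rows(recs, extra)),
                 "skipped")
  expect_false("EXTRA" %in% res$donor)
})
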