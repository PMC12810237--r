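ladder10 <- data.frame(carbon_n = 10:12, rt1_min = c(10, 12, 14.5))

test_that("retention indices interpolate between bracketing alkanes", {
  expect_equal(retention_index(10, ladder10), 1000)
  expect_equal(retention_index(11, ladder10), 1050)
  expect_equal(retention_index(10.5, ladder10), 1025)
  # every ladder alkane sits exactly at 100 n
  lad <- default_alkane_ladder()
  expect_equal(retention_index(lad$rt1_min, lad), 100 * lad$carbon_n)
  # strictly increasing within a bracket
  rts <- seq(10, 12, by = 0.1)
  expect_true(all(diff(retention_index(rts, ladder10)) > 0))
  expect_error(retention_index(9, ladder10), "outside")
  expect_silent(retention_index(9, ladder10, extrapolate = TRUE))
  expect_equal(rt1_from_ri(retention_index(c(10.3, 13.2), ladder10), ladder10),
               c(10.3, 13.2))
})

mk_peaks <- function(rt1, rt2, cas, abundance = NULL, fraction = "F1") {
  n <- length(rt1)
  data.frame(fraction = fraction, rt1_min = rt1, rt2_s = rt2,
             abundance = abundance %||% rep(10, n), cas = cas,
             name = paste0("c", seq_len(n)), match_score = 90,
             class_label = "PAH", stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("binning merges same-CAS peaks within the retention quadrant", {
  pk <- mk_peaks(c(5.00, 5.15, 5.50, 5.05), c(1.00, 1.10, 1.00, 1.05),
                 c("X", "X", "X", "Y"))
  b <- bin_peaks(pk)
  expect_equal(nrow(b$peaks), 3)
  expect_equal(b$bin_of[1], b$bin_of[2])
  expect_false(b$bin_of[3] == b$bin_of[1])
  expect_false(b$bin_of[4] %in% b$bin_of[1:3])
  expect_equal(b$bin_of, oracle_bin_components(pk))
  # single peak passes through unchanged
  one <- bin_peaks(pk[3, ])
  expect_equal(one$peaks$rt1_min, 5.50)
  expect_equal(one$peaks$n_merged, 1)
})

test_that("binning is transitive across chains (connected components)", {
  pk <- mk_peaks(c(5.00, 5.15, 5.30), c(1, 1, 1), rep("X", 3))
  b <- bin_peaks(pk)
  expect_equal(nrow(b$peaks), 1)
  expect_equal(b$peaks$n_merged, 3)
  expect_equal(length(unique(oracle_bin_components(pk))), 1)
})

test_that("binning conserves abundance and matches the component oracle", {
  for (seed in 1:3) {
    gen <- generate_peaklist(peak_config(seed = seed, n_true = 60,
                                         n_decoys = 10, duplicate_rate = 0.25))
    b <- bin_peaks(gen$peaks)
    expect_equal(sum(b$peaks$abundance), sum(gen$peaks$abundance))
    oracle <- oracle_bin_components(gen$peaks)
    # identical partitions: same co-membership relation
    expect_equal(outer(b$bin_of, b$bin_of, "=="),
                 outer(oracle, oracle, "=="))
  }
})

test_that("binned positions are abundance-weighted centroids with max score", {
  pk <- mk_peaks(c(5.0, 5.2), c(1.0, 1.2), c("X", "X"), abundance = c(30, 10))
  pk$match_score <- c(85, 95)
  b <- bin_peaks(pk)
  expect_equal(b$peaks$rt1_min, (5.0 * 30 + 5.2 * 10) / 40)
  expect_equal(b$peaks$rt2_s, (1.0 * 30 + 1.2 * 10) / 40)
  expect_equal(b$peaks$abundance, 40)
  expect_equal(b$peaks$match_score, 95)
})

test_that("empty-CAS peaks pass through unbinned", {
  pk <- mk_peaks(c(5.0, 5.05), c(1, 1), c("", ""))
  b <- bin_peaks(pk)
  expect_equal(nrow(b$peaks), 2)
})

test_that("baseline nulling removes constant and drifting offsets", {
  # constant 0.5 s offset
  base <- data.frame(rt1_min = c(0, 50), rt2_s = c(0.5, 0.5))
  expect_equal(baseline_align_rt2(c(1.5, 2.5), c(10, 20), base), c(1.0, 2.0))
  # already-null baseline -> identity
  base0 <- data.frame(rt1_min = c(0, 50), rt2_s = c(0, 0))
  expect_equal(baseline_align_rt2(c(1.5, 2.5), c(10, 20), base0), c(1.5, 2.5))
  # linear drift 0 -> 0.4 s across the run, sparse baseline observations
  set.seed(12)
  rt1 <- runif(40, 0, 50)
  true_rt2 <- runif(40, 0.5, 5.5)
  drift <- function(x) 0.4 * x / 50
  obs <- true_rt2 + drift(rt1)
  base_d <- data.frame(rt1_min = seq(0, 50, by = 5),
                       rt2_s = drift(seq(0, 50, by = 5)))
  corrected <- baseline_align_rt2(obs, rt1, base_d)
  expect_lt(max(abs(corrected - true_rt2)), 0.02)
})

test_that("PLS retention model recovers a noiseless linear map", {
  cal <- generate_retention_calibration(119, seed = 21)
  m <- fit_retention_model(cal, n_train = 100, n_test = 19, seed = 21)
  expect_lt(m$test_rmse["ri"], 1e-6 * sd(cal$ri))
  expect_lt(m$test_rmse["rt2"], 1e-6 * sd(cal$rt2_s))
  pred <- predict(m, cal)
  expect_equal(pred$ri_pred, cal$ri, tolerance = 1e-8)
})

test_that("pure-noise responses give small CV rank and RMSE near response SD", {
  set.seed(33)
  cal <- generate_retention_calibration(119, seed = 33)
  cal$ri <- rnorm(119, 1500, 100)    # response independent of descriptors
  cal$rt2_s <- rnorm(119, 3, 0.5)
  m <- fit_retention_model(cal, n_train = 100, n_test = 19, seed = 33)
  expect_lte(m$ri$ncomp, 4)
  expect_lt(abs(m$test_rmse["ri"] - 100), 0.35 * 100)
  expect_lt(abs(m$test_rmse["rt2"] - 0.5), 0.35 * 0.5)
})

test_that("constant descriptors are dropped with a warning", {
  cal <- generate_retention_calibration(60, seed = 3)
  cal$undefined_stereo <- 0
  expect_warning(m <- fit_retention_model(cal, n_train = 40, n_test = 15,
                                          seed = 3),
                 "constant descriptor")
  expect_false("undefined_stereo" %in% m$descriptors)
})

test_that("retention models persist to flat JSON and predict identically", {
  cal <- generate_retention_calibration(119, seed = 8)
  m <- fit_retention_model(cal, seed = 8)
  f <- withr::local_tempfile(fileext = ".json")
  write_retention_model(m, f)
  m2 <- read_retention_model(f)
  newd <- generate_retention_calibration(25, seed = 9)
  expect_equal(predict(m2, newd)$ri_pred, predict(m, newd)$ri_pred,
               tolerance = 1e-9)
  expect_equal(predict(m2, newd)$rt2_pred, predict(m, newd)$rt2_pred,
               tolerance = 1e-9)
})

test_that("plausibility filter applies strict thresholds per criterion", {
  base <- data.frame(ri_meas = 1000, rt2_s = 3, match_score = 95,
                     ri_pred = 1000, rt2_pred = 3)
  ok <- base; ok$ri_meas <- 1150; ok$rt2_s <- 4      # dRI 150, drt2 1
  f <- filter_identifications(ok)
  expect_equal(nrow(f$retained), 1)
  expect_equal(nrow(f$rejected), 0)
  ri_bad <- base; ri_bad$ri_meas <- 1250             # dRI 250
  expect_equal(filter_identifications(ri_bad)$rejected$reason, "ri_deviation")
  # boundary: dRI 199.9 passes, drt2 exactly 2.0 fails (strict)
  edge <- base; edge$ri_meas <- 1199.9; edge$rt2_s <- 5
  expect_equal(filter_identifications(edge)$rejected$reason, "rt2_deviation")
  low <- base; low$match_score <- 80                 # not > 80
  expect_equal(filter_identifications(low)$rejected$reason, "match_score")
  nop <- base; nop$ri_pred <- NA
  expect_equal(filter_identifications(nop)$rejected$reason, "no_prediction")
})

test_that("filter partitions its input and decoy retention matches theory", {
  cfg <- peak_config(seed = 14, n_true = 150, n_decoys = 400,
                     duplicate_rate = 0)
  lad <- default_alkane_ladder()
  gen <- generate_peaklist(cfg, lad)
  cal <- generate_retention_calibration(119, seed = 14)
  m <- fit_retention_model(cal, seed = 14)
  pk <- gen$peaks
  pk$ri_meas <- retention_index(pk$rt1_min, lad)
  pred <- predict(m, gen$descriptors[match(pk$cas, gen$descriptors$cas), ])
  pk$ri_pred <- pred$ri_pred
  pk$rt2_pred <- pred$rt2_pred
  f <- filter_identifications(pk)
  expect_equal(nrow(f$retained) + nrow(f$rejected), nrow(pk))
  expect_length(intersect(f$retained$peak_id, f$rejected$peak_id), 0)
  # analytic retention probability for each decoy: measured RI ~ U(lo, hi),
  # rt2 ~ U(0, 6), independent of the predicted position
  dec <- pk[gen$truth$role == "decoy", ]
  ri_rng <- range(retention_index(lad$rt1_min, lad)) + c(50, -50)
  p_ri <- (pmin(dec$ri_pred + 200, ri_rng[2]) -
             pmax(dec$ri_pred - 200, ri_rng[1])) / diff(ri_rng)
  p_rt2 <- (pmin(dec$rt2_pred + 2, 6) - pmax(dec$rt2_pred - 2, 0)) / 6
  p_exp <- mean(pmax(p_ri, 0) * pmax(p_rt2, 0))
  obs <- mean(dec$peak_id %in% f$retained$peak_id)
  mc_se <- sqrt(p_exp * (1 - p_exp) / nrow(dec))
  expect_lt(abs(obs - p_exp), 4 * mc_se)
})

test_that("composition summaries give percent shares with alphabetical ties", {
  pk <- data.frame(fraction = "PAH",
                   name = c("phenanthrene", "2-methylanthracene",
                            "ethyl 4-ethoxybenzoate", "minor1", "minor2",
                            "minor3"),
                   cas = paste0("c", 1:6), class_label = "PAH",
                   abundance = c(50, 15, 11, 9, 8, 7))
  cs <- composition_summary(pk, top_n = 3)
  expect_equal(cs$relative$rel_pct[1], 50)
  expect_equal(sum(cs$relative$rel_pct), 100, tolerance = 1e-9)
  expect_equal(sum(cs$top$rel_pct[1:3]), 76)
  one <- composition_summary(pk[1, ])
  expect_equal(one$relative$rel_pct, 100)
  tie <- composition_summary(data.frame(fraction = "F", name = c("b", "a"),
                                        cas = c("1", "2"), class_label = "x",
                                        abundance = c(5, 5)))
  expect_equal(tie$relative$name, c("a", "b"))
  expect_equal(tie$relative$rel_pct, c(50, 50))
  expect_warning(empty <- composition_summary(pk[0, ]), "empty")
})
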