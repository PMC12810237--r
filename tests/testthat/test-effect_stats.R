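test_that("ssmd matches its closed form and degenerate rules", {
  expect_equal(ssmd(c(1, 2, 3), c(1, 2, 3)), 0)
  # mean_t 2, mean_c 1, var 0.5 each -> 1
  t <- c(1, 2, 3); c <- c(0, 1, 2)  # var = 1 each
  expect_equal(ssmd(t, c), 1 / sqrt(2))
  t2 <- c(1.5, 2, 2.5); c2 <- c(0.5, 1, 1.5)  # var = 0.25 each
  expect_equal(ssmd(t2, c2), 1 / sqrt(0.5))
  # zero variance, unequal means -> capped
  expect_equal(ssmd(rep(2, 3), rep(1, 3)), 10)
  expect_equal(ssmd(rep(0, 3), rep(1, 3)), -10)
  expect_warning(s <- ssmd(1, c(1, 2)), "2 non-missing")
  expect_true(is.na(s))
})

test_that("ssmd Monte-Carlo estimate converges to delta/sqrt(2 sigma^2)", {
  set.seed(61)
  reps <- 1000
  est <- replicate(reps, ssmd(rnorm(40, 1), rnorm(40, 0)))
  se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - 1 / sqrt(2)), 3 * se)
})

test_that("ssmd is antisymmetric and location/scale equivariant", {
  set.seed(8)
  for (i in 1:10) {
    t <- rnorm(15); c <- rnorm(12, 0.5)
    s <- ssmd(t, c)
    expect_equal(ssmd(c, t), -s)
    expect_equal(ssmd(t + 3, c + 3), s)
    expect_equal(ssmd(-2 * t, -2 * c), -s)
    expect_equal(ssmd(2 * t, 2 * c), s)
  }
})

test_that("robust ssmd uses medians and MADs", {
  set.seed(9)
  t <- rnorm(30, 2); c <- rnorm(30)
  expect_equal(ssmd(t, c, robust = TRUE),
               (median(t) - median(c)) / sqrt(mad(t)^2 + mad(c)^2))
})

test_that("bootstrap p handles degenerate and separated arms", {
  expect_equal(bootstrap_test(rep(2, 10), rep(2, 10), B = 1000, seed = 1), 1)
  # disjoint supports: every centered resample deviates less than observed
  p <- bootstrap_test(rep(0, 20), rep(10, 20), B = 1000, seed = 1)
  expect_equal(p, 1 / 1001)
  expect_error(bootstrap_test(rnorm(5), rnorm(5), B = 50), "at least 100")
})

test_that("bootstrap p is reproducible given the seed", {
  set.seed(2); t <- rnorm(20, 0.5); c <- rnorm(20)
  expect_identical(bootstrap_test(t, c, B = 300, seed = 7),
                   bootstrap_test(t, c, B = 300, seed = 7))
})

test_that("BH adjustment matches p.adjust arithmetic", {
  expect_equal(adjust_p(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_p(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(adjust_p(0.2), 0.2)
})

test_that("rejection rate is non-decreasing in the injected effect size", {
  set.seed(31)
  reps <- 500
  rate <- vapply(c(0, 1, 2.5), function(delta) {
    mean(replicate(reps,
      vamrscreen:::boot_p_core(rnorm(16, delta), rnorm(16), B = 199) < 0.05))
  }, 0)
  expect_true(all(diff(rate) >= 0))
  expect_gt(rate[3], 0.9)
})

make_effect_input <- function(seed = 5, n = 10, shift = 0) {
  set.seed(seed)
  wells <- paste0("W", seq_len(2 * n))
  ep <- data.frame(well = wells, check.names = FALSE)
  for (nm in endpoint_names())
    ep[[nm]] <- c(rnorm(n), rnorm(n) + shift)
  pm <- data.frame(well = wells,
                   group = rep(c("ctrl", "trt"), each = n),
                   treatment = "x", concentration = 1, unit = "uM",
                   is_control = rep(c(TRUE, FALSE), each = n),
                   control_group = "ctrl")
  list(ep = ep, pm = pm)
}

test_that("effect_table is deterministic and direction-consistent", {
  d <- make_effect_input(shift = 2)
  e1 <- effect_table(d$ep, d$pm, B = 200, seed = 4)
  e2 <- effect_table(d$ep, d$pm, B = 200, seed = 4)
  expect_identical(e1$effects, e2$effects)
  expect_true(all(e1$effects$p_adj >= e1$effects$p_raw))
  called <- e1$effects$direction != "none"
  expect_true(all(e1$effects$p_adj[called] < 0.05))
  expect_true(all(e1$effects$p_adj[!called] >= 0.05))
  # calls never contradict the SSMD sign
  expect_true(all(sign(e1$effects$ssmd[called]) ==
                  ifelse(e1$effects$direction[called] == "increase", 1, -1)))
  expect_true(all(e1$effects$direction[called] == "increase"))
})

test_that("effect_table validates its plate map", {
  d <- make_effect_input()
  pm_bad <- d$pm; pm_bad$control_group <- "missing_ctrl"
  expect_error(effect_table(d$ep, pm_bad, B = 200), "control")
  pm_empty <- d$pm[d$pm$is_control, ]
  expect_error(effect_table(d$ep, pm_empty, B = 200), "no treatment groups")
})

test_that("fingerprints carry SSMDs with zero-imputed missing entries", {
  d <- make_effect_input(shift = 1)
  d$ep[["ASH1"]] <- NA_real_  # degenerate ratio endpoint
  e <- effect_table(d$ep, d$pm, B = 200, seed = 2)
  fp <- e$fingerprints
  expect_equal(dim(fp), c(1, 26))
  expect_equal(unname(fp[1, "ASH1"]), 0)
  expect_true(attr(fp, "imputed")[1, "ASH1"])
  f <- withr::local_tempfile(fileext = ".csv")
  write_fingerprints(e, f)
  back <- read.csv(f, check.names = FALSE)
  expect_equal(unlist(back[1, endpoint_names()], use.names = FALSE),
               unname(fp[1, ]))
})
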