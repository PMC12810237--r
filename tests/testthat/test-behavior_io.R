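make_long_csv <- function(path, wells = c("A1", "A2"), n = 10, fps = 25,
                          drop = list()) {
  rows <- do.call(rbind, lapply(wells, function(w) {
    d <- data.frame(time_s = (seq_len(n) - 1) / fps, well = w,
                    activity = seq_len(n) / 10)
    if (!is.null(drop[[w]])) d <- d[-drop[[w]], ]
    d
  }))
  write.csv(rows, path, row.names = FALSE)
  path
}

test_that("long and wide tracking exports parse to one trace per well", {
  f <- make_long_csv(withr::local_tempfile(fileext = ".csv"))
  tr <- read_traces(f)
  expect_named(tr$activity, c("A1", "A2"))
  expect_true(all(lengths(tr$activity) == 10))
  expect_equal(tr$activity$A1, (1:10) / 10)

  wide <- data.frame(time_s = (0:9) / 25, A1 = (1:10) / 10, A2 = (10:1) / 10)
  fw <- withr::local_tempfile(fileext = ".csv")
  write.csv(wide, fw, row.names = FALSE)
  tw <- read_traces(fw)
  expect_equal(tw$activity$A2, (10:1) / 10)
})

test_that("missing frames are zero-padded with a warning and gap recorded", {
  f <- make_long_csv(withr::local_tempfile(fileext = ".csv"),
                     drop = list(A1 = 3L))
  expect_warning(tr <- read_traces(f), "padded")
  expect_equal(length(tr$activity$A1), 10)
  expect_equal(tr$activity$A1[3], 0)
  expect_equal(unname(tr$gap_fraction["A1"]), 0.1)
  expect_equal(unname(tr$gap_fraction["A2"]), 0)
})

test_that("malformed exports are rejected", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("", f)
  expect_error(read_traces(f), "empty|columns")
  write.csv(data.frame(a = 1, b = 2), f, row.names = FALSE)
  expect_error(read_traces(f), "columns")
  write.csv(data.frame(time_s = c(0.04, 0), well = "A1", activity = c(1, 2)),
            f, row.names = FALSE)
  expect_error(read_traces(f), "non-monotone")
})

test_that("write/read round-trip reproduces activity values exactly", {
  set.seed(11)
  tr <- vamrscreen:::new_traces(list(A1 = rexp(50) * pi, B2 = runif(50) / 3), 25)
  f <- withr::local_tempfile(fileext = ".csv")
  write_traces(tr, f)
  back <- read_traces(f)
  expect_identical(back$activity$A1, tr$activity$A1)
  expect_identical(back$activity$B2, tr$activity$B2)
})

test_that("viability exclusions follow the fixed reason precedence", {
  tr <- vamrscreen:::new_traces(setNames(replicate(10, rexp(5), simplify = FALSE),
                                         paste0("W", 1:10)), 25)
  st <- data.frame(well = paste0("W", 1:10),
                   dead = c(TRUE, TRUE, rep(FALSE, 8)),
                   malformed = c(TRUE, rep(FALSE, 9)),
                   swim_bladder_inflated = c(FALSE, rep(TRUE, 8), FALSE))
  res <- apply_exclusions(tr, st)
  expect_equal(length(res$traces$activity), 7)
  # W1 is dead+malformed+uninflated but counted once, under "dead"
  expect_equal(unname(res$counts[c("dead", "malformed", "swim_bladder")]),
               c(2L, 0L, 1L))
  expect_setequal(c(names(res$traces$activity), res$report$well),
                  paste0("W", 1:10))
})

test_that("exclusion is idempotent, order-independent, identity when viable", {
  tr <- vamrscreen:::new_traces(setNames(replicate(6, rexp(5), simplify = FALSE),
                                         paste0("W", 1:6)), 25)
  st <- data.frame(well = c("W3", "W5"), dead = c(TRUE, FALSE),
                   malformed = c(FALSE, TRUE), swim_bladder_inflated = TRUE)
  r1 <- apply_exclusions(tr, st)
  r2 <- apply_exclusions(r1$traces, st)
  expect_identical(names(r1$traces$activity), names(r2$traces$activity))
  r3 <- apply_exclusions(tr, st[2:1, ])
  expect_identical(r1$counts, r3$counts)
  all_ok <- apply_exclusions(tr, NULL)
  expect_identical(names(all_ok$traces$activity), names(tr$activity))
  expect_equal(nrow(all_ok$report), 0)
})

test_that("wells with excessive tracking gaps are excluded as tracking_gap", {
  tr <- vamrscreen:::new_traces(list(A1 = rexp(100), A2 = rexp(100)), 25,
                                gap_fraction = c(A1 = 0.05, A2 = 0))
  res <- apply_exclusions(tr, NULL)
  expect_equal(res$report$reason, "tracking_gap")
  expect_equal(res$report$well, "A1")
})

test_that("plate maps validate control references and unique wells", {
  pm <- data.frame(well = c("A1", "A2"), group = c("ctrl", "trt"),
                   treatment = c("vehicle", "x"), concentration = c(0, 1),
                   unit = "uM", is_control = c(TRUE, FALSE),
                   control_group = "ctrl")
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(pm, f, row.names = FALSE)
  expect_silent(read_plate_map(f))
  pm_bad <- pm; pm_bad$control_group <- "nonexistent"
  write.csv(pm_bad, f, row.names = FALSE)
  expect_error(read_plate_map(f), "missing control")
  pm_dup <- rbind(pm, pm[1, ])
  write.csv(pm_dup, f, row.names = FALSE)
  expect_error(read_plate_map(f), "duplicated")
})
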