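fps <- 25

test_that("visual startle is the mean over the post-transition second", {
  expect_equal(visual_startle(rep(3, 100), 1, fps), 3)
  expect_equal(visual_startle(rep(0, 100), 2, fps), 0)
  v <- rep(0, 100); v[30] <- 25  # one spiked frame inside [1, 2)
  expect_equal(visual_startle(v, 1, fps), 1)
  expect_error(visual_startle(rep(1, 30), 1, fps), "exceeds")
})

test_that("visual motor subdivides phases with remainder-to-last policy", {
  expect_equal(visual_motor(rep(5, 100 * fps), 0, 100, 4, fps), rep(5, 4))
  ramp <- seq(0, 1, length.out = 100 * fps)
  m <- visual_motor(ramp, 0, 100, 2, fps)
  expect_lt(m[1], m[2])
  # 101 s -> 2525 frames: 631+631+631+632, last absorbs the remainder
  v <- seq_len(101 * fps)
  m4 <- visual_motor(v, 0, 101, 4, fps)
  expect_equal(m4[4], mean(v[(3 * 631 + 1):2525]))
  expect_error(visual_motor(numeric(0), 0, 0, 2, fps), "window|empty|exceeds")
})

test_that("acoustic startle averages the five concatenated tap windows", {
  taps <- c(10, 20, 30, 40, 50)
  expect_equal(acoustic_startle(rep(0, 60 * fps), taps, fps), 0)
  expect_equal(acoustic_startle(rep(2, 60 * fps), taps, fps), 2)
  v <- rep(0, 60 * fps)
  for (k in 1:5) v[(taps[k] * fps + 1):((taps[k] + 1) * fps)] <- k
  expect_equal(acoustic_startle(v, taps, fps), 3)
  expect_error(acoustic_startle(v, taps[1:4], fps), "exactly 5")
})

test_that("interval sums are additive over disjoint segments", {
  v <- rep(1, 100 * fps)
  expect_equal(interval_sum(rep(0, 100 * fps),
                            data.frame(start_s = 0, end_s = 60), fps), 0)
  expect_equal(interval_sum(v, data.frame(start_s = 0, end_s = 60), fps), 1500)
  two <- data.frame(start_s = c(0, 70), end_s = c(30, 90))
  expect_equal(interval_sum(v, two, fps),
               interval_sum(v, two[1, ], fps) + interval_sum(v, two[2, ], fps))
})

make_bouts <- function() lapply(0:4, function(b) seq(b * 70, by = 2, length.out = 30))

test_that("habituation ratios follow their defining proportions", {
  bouts <- make_bouts()
  n <- 360 * fps
  flat <- rep(1, n)
  h <- habituation_endpoints(flat, bouts, fps)
  expect_equal(h$ASH1, 0.5)
  expect_equal(h$ASH1_5, 0.5)
  # bout 1: taps 1-10 respond, taps 21-30 silent -> ASH1 = 0
  v <- rep(0, n)
  for (t in bouts[[1]][1:10]) v[(t * fps + 1):((t + 1) * fps)] <- 1
  expect_equal(habituation_endpoints(v, bouts, fps)$ASH1, 0)
  # bout totals 8 vs 2 -> ASH1/5 = 0.2
  v <- rep(0, n)
  for (t in bouts[[1]]) v[(t * fps + 1):((t + 1) * fps)] <- 8 / (30 * fps)
  for (t in bouts[[5]]) v[(t * fps + 1):((t + 1) * fps)] <- 2 / (30 * fps)
  h <- habituation_endpoints(v, bouts, fps)
  expect_equal(h$ASH1_5, 0.2)
  expect_equal(h$ASHsum, 10)
  expect_error(habituation_endpoints(flat, bouts[1:4], fps), "5 bouts")
  # zero denominator -> missing
  expect_true(is.na(habituation_endpoints(rep(0, n), bouts, fps)$ASH1))
})

test_that("memory retention is ASR2 / (ASR2 + ASR3)", {
  expect_equal(memory_retention(2, 2), 0.5)
  expect_equal(memory_retention(0, 3), 0)
  expect_equal(memory_retention(3, 1), 0.75)
  expect_true(is.na(memory_retention(0, 0)))
  expect_error(memory_retention(-1, 1), "non-negative")
})

test_that("endpoint vector on an all-zero trace is 0 / missing-ratios", {
  sch <- default_schedule()
  v <- rep(0, sch$duration_s * fps)
  ep <- compute_endpoint_vector(v, sch, fps)
  st <- endpoint_stat_types()
  expect_true(all(ep[st != "ratio"] == 0))
  expect_true(all(is.na(ep[st == "ratio"])))
})

test_that("endpoint extraction matches the brute-force per-frame oracle", {
  sch <- default_schedule()
  n <- sch$duration_s * fps
  for (seed in 1:4) {
    v <- random_trace(n, seed)
    expect_equal(compute_endpoint_vector(v, sch, fps),
                 oracle_endpoints(v, sch, fps), tolerance = 1e-12)
  }
})

test_that("scaling a trace scales mean/sum endpoints and fixes ratios", {
  sch <- default_schedule()
  v <- random_trace(sch$duration_s * fps, 99)
  ep <- compute_endpoint_vector(v, sch, fps)
  ep_scaled <- compute_endpoint_vector(3.5 * v, sch, fps)
  st <- endpoint_stat_types()
  expect_equal(ep_scaled[st != "ratio"], 3.5 * ep[st != "ratio"])
  expect_equal(ep_scaled[st == "ratio"], ep[st == "ratio"])
})

test_that("joint time-shift of trace and schedule leaves endpoints unchanged", {
  sch <- default_schedule()
  shift <- 7
  segs <- sch$segments
  segs$start_s <- segs$start_s + shift
  segs$end_s <- segs$end_s + shift
  taps <- lapply(sch$tap_times, function(t) t + shift)
  shifted <- vamrscreen:::new_schedule(segs, taps)
  v <- random_trace(sch$duration_s * fps, 5)
  v_shift <- c(rep(0, shift * fps), v)
  expect_equal(compute_endpoint_vector(v_shift, shifted, fps),
               compute_endpoint_vector(v, sch, fps))
})

test_that("ASHsum equals the sum of the five per-bout totals", {
  sch <- default_schedule()
  v <- random_trace(sch$duration_s * fps, 42)
  hb <- which(sch$segments$kind == "habituation_bout")
  h <- habituation_endpoints(v, sch$tap_times[hb], fps)
  expect_equal(h$ASHsum, sum(h$bout_totals))
})

test_that("endpoint matrices round-trip through CSV", {
  sch <- default_schedule()
  plate <- generate_plate(trace_config(seed = 3, n_per_group = 3), sch)
  ep <- compute_endpoint_matrix(plate$traces, sch)
  expect_equal(names(ep), c("well", endpoint_names()))
  f <- withr::local_tempfile(fileext = ".csv")
  write_endpoint_matrix(ep, f)
  back <- read_endpoint_matrix(f)
  expect_equal(back[endpoint_names()], ep[endpoint_names()], tolerance = 1e-12)
})
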