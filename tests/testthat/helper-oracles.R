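# Independent oracles used across the suite. These deliberately re-derive
# endpoint windows and statistics from the schedule semantics with naive
# per-frame loops, sharing no code with the package implementation.

# Frames whose timestamp (i-1)/fps falls in [s, e), found by scanning times.
oracle_frames <- function(n, fps, s, e) {
  t <- (seq_len(n) - 1) / fps
  which(t >= s - 1e-9 & t < e - 1e-9)
}

oracle_mean <- function(v, fps, windows) {
  idx <- unlist(lapply(seq_len(nrow(windows)), function(i)
    oracle_frames(length(v), fps, windows$s[i], windows$e[i])))
  mean(v[idx])
}

oracle_sum <- function(v, fps, windows) {
  idx <- unlist(lapply(seq_len(nrow(windows)), function(i)
    oracle_frames(length(v), fps, windows$s[i], windows$e[i])))
  sum(v[idx])
}

w1 <- function(s, e) data.frame(s = s, e = e)
tapw <- function(tt) data.frame(s = tt, e = tt + 1)

# Full 26-endpoint vector by brute force from the schedule structure.
oracle_endpoints <- function(v, schedule, fps) {
  segs <- schedule$segments
  taps <- schedule$tap_times
  out <- setNames(rep(NA_real_, 26), endpoint_names())
  vis <- which(segs$kind %in% c("light", "dark"))
  for (k in 1:3)
    out[c("VSRB", "VSR1", "VSR2")[k]] <-
      oracle_mean(v, fps, w1(segs$start_s[vis[k]], segs$start_s[vis[k]] + 1))
  li <- which(segs$kind == "light")[1]
  out["VMR1"] <- oracle_mean(v, fps, w1(segs$start_s[li], segs$end_s[li]))
  dk <- which(segs$kind == "dark")[1]
  idx <- oracle_frames(length(v), fps, segs$start_s[dk], segs$end_s[dk])
  per <- length(idx) %/% 4
  for (k in 1:4) {
    sub <- if (k < 4) idx[((k - 1) * per + 1):(k * per)]
           else idx[(3 * per + 1):length(idx)]
    out[paste0("VMR", k + 1)] <- mean(v[sub])
  }
  bl <- which(segs$kind == "baseline")
  for (k in 1:4)
    out[paste0("BSL", k)] <- oracle_mean(v, fps, w1(segs$start_s[bl[k]], segs$end_s[bl[k]]))
  tr <- which(segs$kind == "acoustic_train")
  for (k in 1:3) {
    tt <- taps[[tr[k]]]
    out[paste0("ASR", k)] <- oracle_mean(v, fps, tapw(tt))
    out[paste0("ISI", k)] <- oracle_sum(v, fps, data.frame(s = tt[1:4] + 1, e = tt[2:5]))
  }
  ie <- which(segs$kind == "inter_endpoint")
  for (k in 1:3)
    out[paste0("IEI", k)] <- oracle_sum(v, fps, w1(segs$start_s[ie[k]], segs$end_s[ie[k]]))
  hb <- which(segs$kind == "habituation_bout")
  bout_tap_sum <- function(b) vapply(taps[[b]], function(t)
    sum(v[oracle_frames(length(v), fps, t, t + 1)]), 0)
  b1 <- bout_tap_sum(hb[1])
  den <- sum(b1[1:10]) + sum(b1[21:30])
  out["ASH1"] <- if (den > 0) sum(b1[21:30]) / den else NA_real_
  totals <- vapply(hb, function(b) sum(bout_tap_sum(b)), 0)
  out["ASH1/5"] <- if (totals[1] + totals[5] > 0)
    totals[5] / (totals[1] + totals[5]) else NA_real_
  out["ASHsum"] <- sum(totals)
  ib <- which(segs$kind == "inter_bout")
  out["IBI"] <- oracle_sum(v, fps, w1(segs$start_s[ib], segs$end_s[ib]))
  out["ASR2/3"] <- if (out[["ASR2"]] + out[["ASR3"]] > 0)
    out[["ASR2"]] / (out[["ASR2"]] + out[["ASR3"]]) else NA_real_
  out
}

# Union-find connected components over pairwise within-window linkage.
oracle_bin_components <- function(peaks, rt1_window = 0.2, rt2_window = 0.2) {
  n <- nrow(peaks)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union <- function(i, j) parent[find(i)] <<- find(j)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j &&
        nzchar(peaks$cas[i]) &&
        peaks$cas[i] == peaks$cas[j] &&
        peaks$fraction[i] == peaks$fraction[j] &&
        abs(peaks$rt1_min[i] - peaks$rt1_min[j]) <= rt1_window &&
        abs(peaks$rt2_s[i] - peaks$rt2_s[j]) <= rt2_window)
      union(i, j)
  }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, unique(roots))
}

# Tiny random schedule-compatible trace
random_trace <- function(n, seed) {
  set.seed(seed)
  stats::rexp(n, rate = 0.5)
}
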