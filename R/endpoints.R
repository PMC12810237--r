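#' @title The 26 VAMR behavioral endpoints
#' @description
#' Per-frame locomotor activity (delta pixel/s) is reduced to 26 named
#' endpoints per larva. Mean endpoints average per-frame activity over their
#' windows, sum endpoints total it, and the three ratio endpoints (ASH1,
#' ASH1/5, ASR2/3) are dimensionless proportions in `[0, 1]` that are missing
#' (`NA`) when their denominator is zero.
#' @name endpoints
NULL

# first frame whose timestamp (i-1)/fps falls inside [start_s, ...)
frame_index <- function(start_s, fps) floor(start_s * fps + 1e-6) + 1L
# last frame whose timestamp is < end_s
frame_index_end <- function(end_s, fps) as.integer(ceiling(end_s * fps - 1e-6))

window_frames <- function(start_s, end_s, fps, n_frames) {
  i0 <- frame_index(start_s, fps)
  i1 <- frame_index_end(end_s, fps)
  if (i1 < i0) stop(sprintf("empty window [%g, %g)", start_s, end_s))
  if (i0 < 1 || i1 > n_frames)
    stop(sprintf("window [%g, %g) exceeds trace duration", start_s, end_s))
  i0:i1
}

#' Visual startle response
#'
#' Mean activity over the 1-s window following a light-to-dark or
#' dark-to-light transition (VSRB, VSR1, VSR2).
#'
#' @param values Per-frame activity vector.
#' @param transition_time Transition time (s from assay start).
#' @param sampling_rate Frames per second.
#' @param window Window length in seconds (default 1).
#' @return Mean activity over the window.
#' @export
visual_startle <- function(values, transition_time, sampling_rate = 25, window = 1) {
  idx <- window_frames(transition_time, transition_time + window,
                       sampling_rate, length(values))
  mean(values[idx])
}

#' Visual motor response over subdivided phase intervals
#'
#' Splits a light or dark phase into `n_subintervals` equal frame blocks
#' (remainder frames absorbed by the last) and returns the mean activity of
#' each (VMR1-VMR5, and the BSL subdivisions when a schedule uses them).
#'
#' @param values Per-frame activity vector.
#' @param start_s,end_s Phase window, half-open `[start_s, end_s)`.
#' @param n_subintervals Number of subintervals.
#' @param sampling_rate Frames per second.
#' @return Numeric vector of per-subinterval means.
#' @export
visual_motor <- function(values, start_s, end_s, n_subintervals, sampling_rate = 25) {
  idx <- window_frames(start_s, end_s, sampling_rate, length(values))
  if (length(idx) == 0) stop("empty phase segment")
  per <- length(idx) %/% n_subintervals
  if (per == 0) stop("segment too short for ", n_subintervals, " subintervals")
  bounds <- c(idx[1] + per * (0:(n_subintervals - 1)), idx[length(idx)] + 1L)
  vapply(seq_len(n_subintervals),
         function(k) mean(values[bounds[k]:(bounds[k + 1] - 1L)]), 0)
}

#' Acoustic startle response
#'
#' Mean activity over the five concatenated 1-s tap windows of an acoustic
#' train (ASR1 low intensity; ASR2/ASR3 high intensity).
#'
#' @param values Per-frame activity vector.
#' @param tap_times Vector of exactly 5 tap onset times (s).
#' @param sampling_rate Frames per second.
#' @return Mean activity over all tap-window frames.
#' @export
acoustic_startle <- function(values, tap_times, sampling_rate = 25) {
  if (length(tap_times) != 5) stop("acoustic train must have exactly 5 taps")
  idx <- unlist(lapply(tap_times, function(t)
    window_frames(t, t + TAP_WINDOW_S, sampling_rate, length(values))))
  mean(values[idx])
}

#' Summed activity over one or more intervals
#'
#' Total per-frame activity over the given windows (ISI1-3, IEI1-3, IBI).
#'
#' @param values Per-frame activity vector.
#' @param windows Data frame with columns `start_s`, `end_s`.
#' @param sampling_rate Frames per second.
#' @return Summed activity.
#' @export
interval_sum <- function(values, windows, sampling_rate = 25) {
  sum(unlist(lapply(seq_len(nrow(windows)), function(i)
    values[window_frames(windows$start_s[i], windows$end_s[i],
                         sampling_rate, length(values))])))
}

tap_window_sums <- function(values, tap_times, sampling_rate) {
  vapply(tap_times, function(t)
    sum(values[window_frames(t, t + TAP_WINDOW_S, sampling_rate, length(values))]), 0)
}

#' Habituation endpoints from five 30-tap bouts
#'
#' `ASH1` is the within-bout habituation of the first bout: the activity of
#' its final ten tap windows over the summed activity of its initial and
#' final ten. `ASH1/5` compares the last bout to the first:
#' `A5 / (A1 + A5)` with `Ak` the total tap-window activity of bout k.
#' `ASHsum` is the total tap-window activity across all five bouts. Ratios
#' are `NA` when their denominator is zero.
#'
#' @param values Per-frame activity vector.
#' @param bout_taps List of 5 numeric vectors of 30 tap onset times each.
#' @param sampling_rate Frames per second.
#' @return Named list with `ASH1`, `ASH1_5`, `ASHsum` and the per-bout
#'   totals `bout_totals`.
#' @export
habituation_endpoints <- function(values, bout_taps, sampling_rate = 25) {
  if (length(bout_taps) != 5 || !all(lengths(bout_taps) == 30))
    stop("habituation requires 5 bouts of 30 taps each")
  sums <- lapply(bout_taps, tap_window_sums, values = values,
                 sampling_rate = sampling_rate)
  b1 <- sums[[1]]
  s_first <- sum(b1[1:10]); s_last <- sum(b1[21:30])
  totals <- vapply(sums, sum, 0)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  list(ASH1 = ratio(s_last, s_first + s_last),
       ASH1_5 = ratio(totals[5], totals[1] + totals[5]),
       ASHsum = sum(totals),
       bout_totals = totals)
}

#' Memory-retention ratio
#'
#' Relative proportion of the pre-habituation startle (ASR2) to the combined
#' pre- and post-habituation responses: `ASR2 / (ASR2 + ASR3)`; `NA` when
#' both are zero. Computed per larva.
#'
#' @param asr2,asr3 Non-negative startle activities.
#' @return Ratio in `[0, 1]` or `NA`.
#' @export
memory_retention <- function(asr2, asr3) {
  if (any(c(asr2, asr3) < 0, na.rm = TRUE)) stop("startle activities must be non-negative")
  den <- asr2 + asr3
  ifelse(is.na(den) | den == 0, NA_real_, asr2 / den)
}

#' Compute the full 26-endpoint vector for one larva
#'
#' @param values Per-frame activity vector of one larva.
#' @param schedule A `vamr_schedule`.
#' @param sampling_rate Frames per second (default 25).
#' @return Named numeric vector over [endpoint_names()]; ratio endpoints are
#'   `NA` when their denominator is zero.
#' @export
compute_endpoint_vector <- function(values, schedule, sampling_rate = 25) {
  segs <- schedule$segments
  taps <- schedule$tap_times
  w <- schedule$windows
  out <- setNames(rep(NA_real_, 26), endpoint_names())
  one <- function(ep) w[w$endpoint == ep, , drop = FALSE]
  for (ep in c("VSRB", "VSR1", "VSR2", paste0("VMR", 1:5), paste0("BSL", 1:4))) {
    ww <- one(ep)
    out[ep] <- mean(values[window_frames(ww$start_s, ww$end_s, sampling_rate,
                                         length(values))])
  }
  tr <- which(segs$kind == "acoustic_train")
  for (k in 1:3) {
    out[paste0("ASR", k)] <- acoustic_startle(values, taps[[tr[k]]], sampling_rate)
    out[paste0("ISI", k)] <- interval_sum(values, one(paste0("ISI", k)), sampling_rate)
  }
  for (k in 1:3)
    out[paste0("IEI", k)] <- interval_sum(values, one(paste0("IEI", k)), sampling_rate)
  hb <- which(segs$kind == "habituation_bout")
  hab <- habituation_endpoints(values, taps[hb], sampling_rate)
  out["ASH1"] <- hab$ASH1
  out["ASH1/5"] <- hab$ASH1_5
  out["ASHsum"] <- hab$ASHsum
  out["IBI"] <- interval_sum(values, one("IBI"), sampling_rate)
  out["ASR2/3"] <- memory_retention(out[["ASR2"]], out[["ASR3"]])
  out
}

#' Compute the endpoint matrix for a set of traces
#'
#' @param traces A `vamr_traces` object.
#' @param schedule A `vamr_schedule`.
#' @return Data frame: one row per well (`well` column) plus the 26 endpoint
#'   columns in canonical order.
#' @export
compute_endpoint_matrix <- function(traces, schedule) {
  mat <- t(vapply(traces$activity, compute_endpoint_vector,
                  setNames(numeric(26), endpoint_names()),
                  schedule = schedule, sampling_rate = traces$sampling_rate))
  out <- data.frame(well = names(traces$activity), stringsAsFactors = FALSE,
                    check.names = FALSE)
  out[endpoint_names()] <- as.data.frame(mat, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Write / read an endpoint matrix CSV
#'
#' Columns: `well`, the 26 endpoints in canonical order, plus any metadata
#' columns already joined (group, treatment, ...).
#'
#' @param endpoints Endpoint matrix data frame.
#' @param path CSV path.
#' @return `path` (write) or the data frame (read).
#' @export
write_endpoint_matrix <- function(endpoints, path) {
  utils::write.csv(endpoints, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_endpoint_matrix
#' @export
read_endpoint_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(endpoint_names(), names(df))
  if (length(miss)) stop("endpoint matrix missing columns: ",
                         paste(miss, collapse = ", "))
  df
}
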