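#' @title Stimulus schedules for the VAMR assay
#' @description
#' A stimulus schedule is an ordered, non-overlapping list of typed segments
#' (baseline, light, dark, acoustic tap trains, habituation bouts, and the
#' intervals between them) that defines the window of every one of the 26
#' behavioral endpoints. Times are seconds from assay start, 0-based, and all
#' windows are half-open `[start, end)`.
#' @name vamr_schedule
NULL

SEGMENT_KINDS <- c("baseline", "light", "dark", "acoustic_train",
                   "habituation_bout", "inter_stimulus", "inter_endpoint",
                   "inter_bout")

TAP_WINDOW_S <- 1  # every acoustic stimulus is scored over 1 s

#' The 26 VAMR endpoint names, in canonical order
#'
#' Order is fixed across the whole pipeline: endpoint matrices, fingerprints
#' and reference libraries all use these names as columns.
#'
#' @return Character vector of length 26.
#' @export
endpoint_names <- function() {
  c("VSRB", "VSR1", "VSR2",
    paste0("VMR", 1:5),
    paste0("BSL", 1:4),
    paste0("ASR", 1:3),
    paste0("ISI", 1:3),
    paste0("IEI", 1:3),
    "ASH1", "ASH1/5", "ASHsum", "IBI", "ASR2/3")
}

#' Statistic type of each endpoint
#'
#' @return Named character vector over [endpoint_names()]: `"mean"` (mean
#'   activity per frame), `"sum"` (summed per-frame activity) or `"ratio"`
#'   (dimensionless proportion in `[0, 1]`).
#' @export
endpoint_stat_types <- function() {
  nm <- endpoint_names()
  st <- setNames(rep("mean", length(nm)), nm)
  st[c(paste0("ISI", 1:3), paste0("IEI", 1:3), "ASHsum", "IBI")] <- "sum"
  st[c("ASH1", "ASH1/5", "ASR2/3")] <- "ratio"
  st
}

new_schedule <- function(segments, tap_times) {
  sched <- structure(
    list(segments = segments, tap_times = tap_times,
         duration_s = max(segments$end_s)),
    class = "vamr_schedule")
  sched$windows <- endpoint_windows(sched)
  sched
}

#' Load and validate a stimulus schedule
#'
#' Reads a YAML or JSON schedule config containing a `segments` list. Each
#' segment needs `kind`, `start_s`, `end_s`; acoustic segments
#' (`acoustic_train`, `habituation_bout`) additionally need `tap_times_s` and
#' (trains only) `intensity` ("low"/"high"). The schedule is validated against
#' all structural invariants and the derived endpoint-window table is attached.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` schedule file.
#' @return A `vamr_schedule` object with elements `segments` (data frame),
#'   `tap_times` (list, parallel to segments), `duration_s`, and `windows`
#'   (the endpoint-window table, see [endpoint_windows()]).
#' @export
load_schedule <- function(path) {
  if (!file.exists(path)) stop("schedule file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (is.null(cfg$segments) || length(cfg$segments) == 0)
    stop("schedule config has no 'segments' list")
  segs <- cfg$segments
  # yaml gives a list of lists; json with simplifyVector may give a data.frame
  if (is.data.frame(segs)) segs <- lapply(seq_len(nrow(segs)), function(i) {
    row <- as.list(segs[i, , drop = FALSE])
    row$tap_times_s <- if (is.list(row$tap_times_s)) row$tap_times_s[[1]] else row$tap_times_s
    row
  })
  n <- length(segs)
  df <- data.frame(
    kind = vapply(segs, function(s) as.character(s$kind %||% NA_character_), ""),
    start_s = vapply(segs, function(s) as.numeric(s$start_s %||% NA_real_), 0),
    end_s = vapply(segs, function(s) as.numeric(s$end_s %||% NA_real_), 0),
    intensity = vapply(segs, function(s) as.character(s$intensity %||% NA_character_), ""),
    stringsAsFactors = FALSE)
  taps <- lapply(segs, function(s) {
    tt <- s$tap_times_s
    if (is.null(tt)) numeric(0) else as.numeric(unlist(tt))
  })
  validate_schedule(df, taps)
  new_schedule(df, taps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_schedule <- function(segments, tap_times) {
  bad <- function(i, msg) stop(sprintf("schedule segment %d (%s): %s",
                                       i, segments$kind[i], msg), call. = FALSE)
  if (anyNA(segments$kind) || !all(segments$kind %in% SEGMENT_KINDS))
    stop("unknown segment kind(s): ",
         paste(setdiff(segments$kind, SEGMENT_KINDS), collapse = ", "))
  for (i in seq_len(nrow(segments))) {
    if (is.na(segments$start_s[i]) || is.na(segments$end_s[i]))
      bad(i, "missing start_s/end_s")
    if (segments$end_s[i] <= segments$start_s[i])
      bad(i, "end_s must be greater than start_s")
  }
  o <- order(segments$start_s)
  if (is.unsorted(segments$start_s)) stop("schedule segments must be sorted by start_s")
  if (any(segments$end_s[-nrow(segments)] > segments$start_s[-1] + 1e-9))
    stop("schedule segments overlap")
  for (i in seq_len(nrow(segments))) {
    kind <- segments$kind[i]
    tt <- tap_times[[i]]
    if (kind == "acoustic_train") {
      if (length(tt) != 5) bad(i, sprintf("acoustic_train needs exactly 5 taps, got %d", length(tt)))
      if (!segments$intensity[i] %in% c("low", "high"))
        bad(i, "acoustic_train needs intensity 'low' or 'high'")
    } else if (kind == "habituation_bout") {
      if (length(tt) != 30) bad(i, sprintf("habituation_bout needs exactly 30 taps, got %d", length(tt)))
    } else if (length(tt) > 0) {
      bad(i, "tap_times_s only allowed on acoustic segments")
    }
    if (length(tt) > 0) {
      if (is.unsorted(tt, strictly = TRUE)) bad(i, "tap times must be strictly increasing")
      if (any(tt < segments$start_s[i] - 1e-9) ||
          any(tt + TAP_WINDOW_S > segments$end_s[i] + 1e-9))
        bad(i, "tap windows (1 s) must lie inside the segment")
      if (any(diff(tt) < TAP_WINDOW_S - 1e-9)) bad(i, "tap windows overlap")
    }
  }
  # structural requirements for the 26-endpoint mapping
  n_trans <- sum(segments$kind %in% c("light", "dark"))
  if (n_trans < 3)
    stop("schedule needs at least 3 light/dark segments (visual transitions VSRB/VSR1/VSR2)")
  if (sum(segments$kind == "light") < 1 || sum(segments$kind == "dark") < 1)
    stop("schedule needs at least one light and one dark phase (VMR endpoints)")
  if (sum(segments$kind == "baseline") != 4)
    stop("schedule needs exactly 4 baseline segments (BSL1-BSL4)")
  if (sum(segments$kind == "acoustic_train") != 3)
    stop("schedule needs exactly 3 acoustic trains (ASR1-ASR3)")
  if (sum(segments$kind == "habituation_bout") != 5)
    stop("schedule needs exactly 5 habituation bouts")
  if (sum(segments$kind == "inter_endpoint") != 3)
    stop("schedule needs exactly 3 inter_endpoint segments (IEI1-IEI3)")
  if (sum(segments$kind == "inter_bout") < 1)
    stop("schedule needs at least one inter_bout segment (IBI)")
  tr <- which(segments$kind == "acoustic_train")
  hb <- which(segments$kind == "habituation_bout")
  if (!(max(tr[1:2]) < min(hb) && tr[3] > max(hb)))
    stop("acoustic trains 1-2 must precede and train 3 follow the habituation bouts (ASR2/3)")
  invisible(TRUE)
}

#' Derive the endpoint-window table from a schedule
#'
#' Maps every one of the 26 endpoints to the set of time windows it is
#' computed from. Mean endpoints average per-frame activity over their
#' (concatenated) windows, sum endpoints total it, and ratio endpoints are
#' assembled from the tap windows listed here (see
#' [habituation_endpoints()] and [memory_retention()]).
#'
#' Mapping rules: VSRB/VSR1/VSR2 are 1-s windows at the start of the 1st/2nd/
#' 3rd light or dark segment; VMR1 is the first light phase; VMR2-VMR5 are the
#' first dark phase split into 4 equal subintervals (remainder frames absorbed
#' by the last); BSL1-BSL4 are the four baseline segments; ASR1-3 are the tap
#' windows of the three trains; ISI1-3 are the inter-tap intervals within each
#' train; IEI1-3 the inter_endpoint segments; IBI all inter_bout segments.
#'
#' @param schedule A `vamr_schedule`.
#' @param sampling_rate Frames per second used to place frame-exact VMR
#'   subinterval boundaries (default 25).
#' @return Data frame with columns `endpoint`, `stat`, `start_s`, `end_s`
#'   (one row per window; endpoints may own several windows).
#' @export
endpoint_windows <- function(schedule, sampling_rate = 25) {
  segs <- schedule$segments
  taps <- schedule$tap_times
  rows <- list()
  add <- function(endpoint, stat, start, end)
    rows[[length(rows) + 1]] <<- data.frame(endpoint = endpoint, stat = stat,
                                            start_s = start, end_s = end)
  vis <- which(segs$kind %in% c("light", "dark"))
  vsr <- c("VSRB", "VSR1", "VSR2")
  for (k in 1:3)
    add(vsr[k], "mean", segs$start_s[vis[k]], segs$start_s[vis[k]] + 1)
  li <- which(segs$kind == "light")[1]
  add("VMR1", "mean", segs$start_s[li], segs$end_s[li])
  dk <- which(segs$kind == "dark")[1]
  qb <- subdivide_frames(segs$start_s[dk], segs$end_s[dk], 4, sampling_rate)
  for (k in 1:4) add(paste0("VMR", k + 1), "mean", qb$start_s[k], qb$end_s[k])
  bl <- which(segs$kind == "baseline")
  for (k in 1:4) add(paste0("BSL", k), "mean", segs$start_s[bl[k]], segs$end_s[bl[k]])
  tr <- which(segs$kind == "acoustic_train")
  for (k in 1:3) {
    tt <- taps[[tr[k]]]
    for (t in tt) add(paste0("ASR", k), "mean", t, t + TAP_WINDOW_S)
    for (j in 1:4) add(paste0("ISI", k), "sum", tt[j] + TAP_WINDOW_S, tt[j + 1])
  }
  ie <- which(segs$kind == "inter_endpoint")
  for (k in 1:3) add(paste0("IEI", k), "sum", segs$start_s[ie[k]], segs$end_s[ie[k]])
  hb <- which(segs$kind == "habituation_bout")
  for (t in taps[[hb[1]]]) add("ASH1", "ratio", t, t + TAP_WINDOW_S)
  for (t in c(taps[[hb[1]]], taps[[hb[5]]])) add("ASH1/5", "ratio", t, t + TAP_WINDOW_S)
  for (b in hb) for (t in taps[[b]]) add("ASHsum", "sum", t, t + TAP_WINDOW_S)
  ib <- which(segs$kind == "inter_bout")
  for (k in ib) add("IBI", "sum", segs$start_s[k], segs$end_s[k])
  for (k in 2:3) for (t in taps[[tr[k]]]) add("ASR2/3", "ratio", t, t + TAP_WINDOW_S)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  stopifnot(setequal(unique(out$endpoint), endpoint_names()))
  out
}

# Split [start_s, end_s) into n frame-exact subintervals; remainder frames go
# to the last one. Returned boundaries sit on the frame grid.
subdivide_frames <- function(start_s, end_s, n, sampling_rate) {
  i0 <- frame_index(start_s, sampling_rate)
  i1 <- frame_index_end(end_s, sampling_rate)
  nf <- i1 - i0 + 1
  if (nf < n) stop("segment too short to subdivide into ", n, " subintervals")
  per <- nf %/% n
  starts <- i0 + per * (0:(n - 1))
  ends <- c(starts[-1], i1 + 1)
  data.frame(start_s = (starts - 1) / sampling_rate,
             end_s = (ends - 1) / sampling_rate)
}

#' Bundled default stimulus schedule
#'
#' Builds the repo-defined default VAMR schedule: dark baseline, light/dark
#' alternation with three visual transitions, a low-intensity 5-tap train
#' (ASR1), a high-intensity 5-tap train (ASR2), five 30-tap habituation bouts
#' separated by inter-bout intervals, and a final high-intensity train (ASR3),
#' with baseline and inter-endpoint intervals interleaved. Total 923 s.
#'
#' Segment timings are the package's own compact choice; published assays use
#' the same structure with longer phases, and any timing can be supplied via
#' [load_schedule()].
#'
#' @return A `vamr_schedule`.
#' @export
default_schedule <- function() {
  seg <- list(); tap <- list()
  push <- function(kind, start, end, intensity = NA_character_, taps = numeric(0)) {
    seg[[length(seg) + 1]] <<- data.frame(kind = kind, start_s = start,
                                          end_s = end, intensity = intensity,
                                          stringsAsFactors = FALSE)
    tap[[length(tap) + 1]] <<- taps
  }
  push("baseline", 0, 30)                                   # BSL1 (dark acclimation)
  push("light", 30, 90)                                     # VSRB transition, VMR1
  push("dark", 90, 210)                                     # VSR1 transition, VMR2-5
  push("light", 210, 240)                                   # VSR2 transition
  push("baseline", 240, 270)                                # BSL2
  push("acoustic_train", 270, 311, "low", seq(270, 310, 10))  # ASR1, ISI1
  push("inter_endpoint", 311, 341)                          # IEI1
  push("acoustic_train", 341, 382, "high", seq(341, 381, 10)) # ASR2, ISI2
  push("inter_endpoint", 382, 412)                          # IEI2
  push("baseline", 412, 442)                                # BSL3
  bout_start <- 442
  for (b in 1:5) {
    s <- bout_start + (b - 1) * 80
    push("habituation_bout", s, s + 60, taps = seq(s, by = 2, length.out = 30))
    if (b < 5) push("inter_bout", s + 60, s + 80)            # IBI
  }
  push("inter_endpoint", 822, 852)                          # IEI3
  push("baseline", 852, 882)                                # BSL4
  push("acoustic_train", 882, 923, "high", seq(882, 922, 10)) # ASR3, ISI3
  segments <- do.call(rbind, seg)
  validate_schedule(segments, tap)
  new_schedule(segments, tap)
}

#' Write a schedule to a YAML config
#'
#' @param schedule A `vamr_schedule`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  segs <- lapply(seq_len(nrow(schedule$segments)), function(i) {
    s <- as.list(schedule$segments[i, c("kind", "start_s", "end_s")])
    if (!is.na(schedule$segments$intensity[i]))
      s$intensity <- schedule$segments$intensity[i]
    if (length(schedule$tap_times[[i]]) > 0)
      s$tap_times_s <- schedule$tap_times[[i]]
    s
  })
  yaml::write_yaml(list(segments = segs), path)
  invisible(path)
}

#' @export
print.vamr_schedule <- function(x, ...) {
  cat(sprintf("VAMR stimulus schedule: %d segments, %.0f s total\n",
              nrow(x$segments), x$duration_s))
  tab <- table(x$segments$kind)
  cat("  segments:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  endpoint windows: %d windows over %d endpoints\n",
              nrow(x$windows), length(unique(x$windows$endpoint))))
  invisible(x)
}
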