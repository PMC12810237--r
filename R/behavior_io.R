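#' @title Reading tracking exports, plate maps and larva statuses
#' @name behavior_io
NULL

new_traces <- function(activity, sampling_rate, t0 = 0,
                       gap_fraction = NULL) {
  if (is.null(gap_fraction))
    gap_fraction <- setNames(rep(0, length(activity)), names(activity))
  structure(list(activity = activity, sampling_rate = sampling_rate,
                 t0 = t0, gap_fraction = gap_fraction),
            class = "vamr_traces")
}

#' @export
print.vamr_traces <- function(x, ...) {
  n <- lengths(x$activity)
  cat(sprintf("vamr_traces: %d wells, %d frames each (%.1f s at %g fps)\n",
              length(x$activity), if (length(n)) max(n) else 0,
              if (length(n)) max(n) / x$sampling_rate else 0, x$sampling_rate))
  invisible(x)
}

#' Read per-larva activity traces from a tracking export
#'
#' Accepts the two common CSV dialects of quantization-mode tracking exports:
#' long format with columns `time_s,well,activity`, or wide format with a
#' `time_s` column followed by one column per well (auto-detected from the
#' header). Activity is the per-frame locomotor magnitude (delta pixel/s).
#'
#' Frames missing from the export are padded with 0 activity (with a warning);
#' the fraction of padded frames per well is recorded and wells above the gap
#' threshold are flagged for exclusion by [apply_exclusions()].
#'
#' @param path CSV file path.
#' @param sampling_rate Frames per second of the recording (default 25).
#' @return A `vamr_traces` object: named list of non-negative per-frame
#'   activity vectors plus `sampling_rate` and per-well `gap_fraction`.
#' @export
read_traces <- function(path, sampling_rate = 25) {
  if (!file.exists(path)) stop("tracking file not found: ", path)
  df <- tryCatch(utils::read.csv(path, check.names = FALSE,
                                 stringsAsFactors = FALSE),
                 error = function(e) stop("tracking export is empty or unreadable: ",
                                          path, call. = FALSE))
  if (nrow(df) == 0 || ncol(df) == 0) stop("tracking export is empty: ", path)
  hdr <- names(df)
  long <- all(c("time_s", "well", "activity") %in% hdr)
  if (!long && !("time_s" %in% hdr))
    stop("tracking export must have columns time_s,well,activity (long) or time_s,<wells> (wide)")
  if (long) {
    wells <- unique(df$well)
    per_well <- split(df[c("time_s", "activity")], factor(df$well, levels = wells))
  } else {
    wells <- setdiff(hdr, "time_s")
    if (length(wells) == 0) stop("wide tracking export has no well columns")
    per_well <- lapply(wells, function(w)
      data.frame(time_s = df$time_s, activity = df[[w]]))
    names(per_well) <- wells
  }
  n_frames <- max(vapply(per_well, function(d) length(d$time_s), 0L))
  grid <- (seq_len(n_frames) - 1) / sampling_rate
  activity <- list(); gaps <- numeric(length(wells)); names(gaps) <- wells
  padded_any <- FALSE
  for (w in wells) {
    d <- per_well[[w]]
    if (is.unsorted(d$time_s, strictly = TRUE))
      stop("non-monotone time for well ", w)
    if (any(d$activity < 0, na.rm = TRUE))
      stop("negative activity values for well ", w)
    idx <- round(d$time_s * sampling_rate) + 1
    if (any(idx < 1 | idx > n_frames))
      stop("time values outside recording for well ", w)
    v <- rep(0, n_frames)
    v[idx] <- d$activity
    miss <- n_frames - length(idx)
    gaps[w] <- miss / n_frames
    if (miss > 0) padded_any <- TRUE
    activity[[w]] <- v
  }
  if (padded_any)
    warning(sprintf("padded missing frames with 0 activity in %d well(s)",
                    sum(gaps > 0)))
  new_traces(activity, sampling_rate, t0 = min(grid), gap_fraction = gaps)
}

#' Write traces back to a long-format tracking CSV
#'
#' Values are written with full precision so that
#' `read_traces(write_traces(x))` reproduces activity exactly.
#'
#' @param traces A `vamr_traces` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  wells <- names(traces$activity)
  n <- lengths(traces$activity)
  df <- data.frame(
    time_s = unlist(lapply(n, function(k) (seq_len(k) - 1) / traces$sampling_rate)),
    well = rep(wells, n),
    activity = sprintf("%.17g", unlist(traces$activity, use.names = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plate map CSV
#'
#' Expected columns: `well,group,treatment,concentration,unit,is_control,
#' control_group`. Every non-control group must reference an existing
#' control group; well ids must be unique.
#'
#' @param path CSV file path.
#' @return Validated plate-map data frame.
#' @export
read_plate_map <- function(path) {
  pm <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("well", "group", "treatment", "concentration", "unit",
           "is_control", "control_group")
  miss <- setdiff(req, names(pm))
  if (length(miss)) stop("plate map missing columns: ", paste(miss, collapse = ", "))
  pm$is_control <- as.logical(pm$is_control)
  validate_plate_map(pm)
  pm
}

validate_plate_map <- function(pm) {
  if (anyDuplicated(pm$well)) stop("plate map has duplicated well ids")
  ctrl_groups <- unique(pm$group[pm$is_control])
  refs <- unique(pm$control_group[!pm$is_control])
  missing_ctrl <- setdiff(refs, ctrl_groups)
  if (length(missing_ctrl))
    stop("non-control group(s) reference missing control group(s): ",
         paste(missing_ctrl, collapse = ", "))
  invisible(pm)
}

#' Read a larva status CSV
#'
#' Expected columns: `well,dead,malformed,swim_bladder_inflated`. Wells not
#' listed are treated as viable.
#'
#' @param path CSV file path.
#' @return Data frame with logical status flags.
#' @export
read_statuses <- function(path) {
  st <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("well", "dead", "malformed", "swim_bladder_inflated")
  miss <- setdiff(req, names(st))
  if (length(miss)) stop("status table missing columns: ", paste(miss, collapse = ", "))
  for (cc in req[-1]) st[[cc]] <- as.logical(st[[cc]])
  st
}

#' Apply larva viability exclusions
#'
#' Removes wells whose larvae were dead, malformed, or had an uninflated swim
#' bladder, plus wells with excessive tracking gaps. A well matching several
#' reasons is counted once, under the first matching reason in the fixed
#' precedence dead > malformed > swim_bladder > tracking_gap.
#'
#' @param traces A `vamr_traces` object.
#' @param statuses Status data frame as from [read_statuses()]; wells absent
#'   from it are viable. May be `NULL` (no status-based exclusions).
#' @param gap_threshold Maximum tolerated fraction of padded frames per well
#'   (default 0.01); wells above it are excluded with reason `tracking_gap`.
#' @return List with `traces` (retained wells), `report` (data frame
#'   `well,reason`) and `counts` (named integer vector per reason).
#' @export
apply_exclusions <- function(traces, statuses = NULL, gap_threshold = 0.01) {
  wells <- names(traces$activity)
  reason <- setNames(rep(NA_character_, length(wells)), wells)
  if (!is.null(statuses)) {
    st <- statuses[statuses$well %in% wells, , drop = FALSE]
    for (i in seq_len(nrow(st))) {
      w <- st$well[i]
      reason[w] <-
        if (isTRUE(st$dead[i])) "dead"
        else if (isTRUE(st$malformed[i])) "malformed"
        else if (identical(st$swim_bladder_inflated[i], FALSE)) "swim_bladder"
        else reason[w]
    }
  }
  gap_wells <- wells[traces$gap_fraction[wells] > gap_threshold]
  reason[gap_wells[is.na(reason[gap_wells])]] <- "tracking_gap"
  excluded <- wells[!is.na(reason)]
  retained <- setdiff(wells, excluded)
  report <- data.frame(well = excluded, reason = unname(reason[excluded]),
                       stringsAsFactors = FALSE)
  counts <- table(factor(report$reason,
                         levels = c("dead", "malformed", "swim_bladder", "tracking_gap")))
  out <- new_traces(traces$activity[retained], traces$sampling_rate,
                    traces$t0, traces$gap_fraction[retained])
  list(traces = out, report = report,
       counts = setNames(as.integer(counts), names(counts)))
}
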