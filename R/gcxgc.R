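#' @title GCxGC-MS identification refinement
#' @description
#' Consumes deconvoluted peak lists (first-dimension retention time in
#' minutes, second-dimension retention time in seconds within the modulation
#' period, abundance, tentative CAS identity and spectral match score) and
#' refines identifications: retention-window binning of split peaks,
#' van den Dool-Kratz retention indices against an n-alkane ladder,
#' PLS prediction of retention from physicochemical descriptors, and
#' deviation-based plausibility filtering of tentative identities.
#' @name gcxgc
NULL

DESCRIPTOR_COLS <- c("mw", "xlogp", "tpsa", "complexity", "atom_stereo",
                     "hbd", "hba", "rotb", "heavy_atoms", "defined_stereo",
                     "undefined_stereo")

#' Read a GCxGC peak list CSV
#'
#' Expected columns `fraction,rt1_min,rt2_s,abundance,cas,name,match_score`
#' with an optional `class_label`.
#'
#' @param path CSV file path.
#' @return Validated peak data frame.
#' @export
read_peaks <- function(path) {
  pk <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("fraction", "rt1_min", "rt2_s", "abundance", "cas", "name", "match_score")
  miss <- setdiff(req, names(pk))
  if (length(miss)) stop("peak list missing columns: ", paste(miss, collapse = ", "))
  if (!"class_label" %in% names(pk)) pk$class_label <- NA_character_
  pk$cas[is.na(pk$cas)] <- ""
  validate_peaks(pk)
  pk
}

validate_peaks <- function(pk) {
  if (any(pk$rt1_min < 0 | pk$rt2_s < 0 | pk$abundance < 0, na.rm = TRUE))
    stop("peak retention times and abundances must be non-negative")
  if (any(pk$match_score < 0 | pk$match_score > 100, na.rm = TRUE))
    stop("match_score must lie in [0, 100]")
  invisible(pk)
}

#' Read a physicochemical descriptor table
#'
#' Eleven PubChem descriptors per CAS: molecular weight, xlogP, TPSA,
#' complexity, atom stereo count, H-bond donor and acceptor counts,
#' rotatable bond count, heavy atom count, defined and undefined atom
#' stereo counts. Columns: `cas,mw,xlogp,tpsa,complexity,atom_stereo,hbd,
#' hba,rotb,heavy_atoms,defined_stereo,undefined_stereo`.
#'
#' @param path CSV file path.
#' @return Descriptor data frame.
#' @export
read_descriptors <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("cas", DESCRIPTOR_COLS), names(d))
  if (length(miss)) stop("descriptor table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(d$mw <= 0, na.rm = TRUE)) stop("molecular weight must be positive")
  d
}

#' Read an n-alkane ladder CSV (`carbon_n,rt1_min`)
#'
#' @param path CSV file path.
#' @return Ladder data frame sorted by carbon number, validated strictly
#'   increasing in retention time.
#' @export
read_alkane_ladder <- function(path) {
  l <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("carbon_n", "rt1_min"), names(l))
  if (length(miss)) stop("alkane ladder missing columns: ", paste(miss, collapse = ", "))
  validate_ladder(l)
}

validate_ladder <- function(ladder) {
  ladder <- ladder[order(ladder$carbon_n), , drop = FALSE]
  if (nrow(ladder) < 2) stop("alkane ladder needs at least 2 entries")
  if (any(diff(ladder$carbon_n) != 1))
    stop("alkane ladder must cover consecutive carbon numbers")
  if (any(diff(ladder$rt1_min) <= 0))
    stop("alkane retention times must be strictly increasing with carbon number")
  ladder
}

#' Van den Dool-Kratz retention index
#'
#' Linear interpolation of the first-dimension retention time between the
#' bracketing n-alkanes: `RI = 100 n + 100 (t - t_n) / (t_{n+1} - t_n)`,
#' so every ladder alkane sits exactly at `100 n`.
#'
#' @param rt1 First-dimension retention time(s) in minutes (vectorized).
#' @param ladder Alkane ladder data frame (`carbon_n,rt1_min`).
#' @param extrapolate Allow linear extrapolation beyond the ladder ends
#'   (default FALSE: out-of-range queries are an error).
#' @return Retention index (dimensionless), same length as `rt1`.
#' @export
retention_index <- function(rt1, ladder, extrapolate = FALSE) {
  ladder <- validate_ladder(ladder)
  tn <- ladder$rt1_min
  cn <- ladder$carbon_n
  out_of_range <- rt1 < tn[1] | rt1 > tn[length(tn)]
  if (any(out_of_range, na.rm = TRUE) && !extrapolate)
    stop(sprintf("%d retention time(s) outside the alkane ladder [%g, %g] min",
                 sum(out_of_range, na.rm = TRUE), tn[1], tn[length(tn)]))
  i <- findInterval(rt1, tn, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(tn) - 1L)
  100 * cn[i] + 100 * (rt1 - tn[i]) / (tn[i + 1] - tn[i])
}

#' Invert a retention index back to a first-dimension retention time
#'
#' Inverse of [retention_index()] on the same ladder (used by the synthetic
#' peak generator).
#'
#' @param ri Retention index (vectorized).
#' @param ladder Alkane ladder data frame.
#' @return Retention time(s) in minutes.
#' @export
rt1_from_ri <- function(ri, ladder) {
  ladder <- validate_ladder(ladder)
  tn <- ladder$rt1_min
  cn <- ladder$carbon_n
  i <- findInterval(ri / 100, cn, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(cn) - 1L)
  tn[i] + (ri / 100 - cn[i]) * (tn[i + 1] - tn[i])
}

#' Bin split peaks within a retention quadrant
#'
#' Peaks sharing the same CAS number are merged when they lie within a
#' `[0.2 min, 0.2 s]` retention position quadrant of each other (inclusive
#' windows). Linkage is transitive: connected components of the
#' within-window graph are merged into abundance-weighted centroid positions
#' with summed abundance and the maximum match score. Peaks with an empty
#' CAS pass through unbinned.
#'
#' @param peaks Peak data frame ([read_peaks()] layout).
#' @param rt1_window,rt2_window Half-window sizes (default 0.2 min, 0.2 s).
#' @return List with `peaks` (binned peak table, including `n_merged`) and
#'   `bin_of` (integer bin id per input row).
#' @export
bin_peaks <- function(peaks, rt1_window = 0.2, rt2_window = 0.2) {
  n <- nrow(peaks)
  if (n == 0) return(list(peaks = peaks, bin_of = integer(0)))
  bin_of <- integer(n)
  next_bin <- 0L
  groups <- split(seq_len(n), interaction(peaks$fraction, peaks$cas, drop = TRUE))
  for (idx in groups) {
    cas <- peaks$cas[idx[1]]
    if (!nzchar(cas) || length(idx) == 1) {
      for (i in idx) { next_bin <- next_bin + 1L; bin_of[i] <- next_bin }
      next
    }
    r1 <- peaks$rt1_min[idx]; r2 <- peaks$rt2_s[idx]
    pairs <- which(outer(r1, r1, function(a, b) abs(a - b) <= rt1_window + 1e-12) &
                   outer(r2, r2, function(a, b) abs(a - b) <= rt2_window + 1e-12),
                   arr.ind = TRUE)
    g <- igraph::graph_from_edgelist(cbind(pairs[, 1], pairs[, 2]),
                                     directed = FALSE)
    comp <- igraph::components(g)$membership[seq_along(idx)]
    bin_of[idx] <- next_bin + comp
    next_bin <- next_bin + max(comp)
  }
  merged <- lapply(split(seq_len(n), bin_of), function(ii) {
    p <- peaks[ii, , drop = FALSE]
    w <- p$abundance
    if (sum(w) == 0) w <- rep(1, nrow(p))
    top <- ii[which.max(p$abundance)]
    data.frame(fraction = p$fraction[1],
               rt1_min = sum(p$rt1_min * w) / sum(w),
               rt2_s = sum(p$rt2_s * w) / sum(w),
               abundance = sum(p$abundance),
               cas = p$cas[1],
               name = peaks$name[top],
               match_score = max(p$match_score),
               class_label = peaks$class_label[top],
               n_merged = nrow(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  list(peaks = out, bin_of = bin_of)
}

#' Null the second-dimension baseline
#'
#' Corrects raw second-dimension retention times against the observed
#' positions of the unretained baseline signal, forcing the baseline to rt2
#' = 0. Baseline observations (one per modulation cycle, possibly sparse or
#' noisy) are interpolated linearly along the first dimension; the
#' interpolated offset is subtracted and the result wrapped into
#' `[0, modulation_period)`.
#'
#' @param rt2 Raw second-dimension retention times (s).
#' @param rt1 First-dimension retention times (min) of the same peaks.
#' @param baseline Data frame `rt1_min,rt2_s` of baseline-signal positions.
#' @param modulation_period Modulation period in seconds (default 6).
#' @return Corrected rt2 values in `[0, modulation_period)`.
#' @export
baseline_align_rt2 <- function(rt2, rt1, baseline, modulation_period = 6) {
  if (nrow(baseline) == 1) {
    off <- rep(baseline$rt2_s, length(rt2))
  } else {
    off <- stats::approx(baseline$rt1_min, baseline$rt2_s, xout = rt1,
                         rule = 2)$y
  }
  (rt2 - off) %% modulation_period
}

#' Fit PLS retention models from physicochemical descriptors
#'
#' Fits two independent partial least-squares regressions on the 11
#' descriptors: one predicting the first-dimension retention index, one the
#' second-dimension retention time. Descriptors are standardized internally;
#' constant descriptors are dropped with a warning. The number of components
#' is chosen per response by seeded 10-fold cross-validation on the training
#' set (minimum RMSE), and held-out test RMSE is reported for both responses.
#'
#' @param training Data frame with the descriptor columns plus `ri` and
#'   `rt2_s` responses (one row per calibration compound).
#' @param n_train,n_test Train/test split sizes (default 100/19, drawn
#'   without replacement from the calibration set).
#' @param seed Integer seed for the split and the CV folds.
#' @param max_ncomp Maximum number of PLS components considered (default:
#'   number of usable descriptors).
#' @param folds Cross-validation folds (default 10).
#' @return A `vamr_retention_model`: mixOmics fits and chosen component
#'   counts per response, descriptor set, split record and `test_rmse`.
#' @export
fit_retention_model <- function(training, n_train = 100, n_test = 19,
                                seed = 1L, max_ncomp = NULL, folds = 10) {
  miss <- setdiff(c(DESCRIPTOR_COLS, "ri", "rt2_s"), names(training))
  if (length(miss)) stop("training table missing columns: ",
                         paste(miss, collapse = ", "))
  if (n_train + n_test > nrow(training))
    stop("split larger than the calibration set")
  set.seed(seed)
  perm <- sample(nrow(training))
  train_idx <- perm[seq_len(n_train)]
  test_idx <- perm[n_train + seq_len(n_test)]
  X <- as.matrix(training[DESCRIPTOR_COLS])
  keep <- apply(X[train_idx, , drop = FALSE], 2, function(v) stats::sd(v) > 0)
  if (!all(keep))
    warning("dropping constant descriptor(s): ",
            paste(DESCRIPTOR_COLS[!keep], collapse = ", "))
  X <- X[, keep, drop = FALSE]
  if (is.null(max_ncomp)) max_ncomp <- ncol(X)
  max_ncomp <- min(max_ncomp, ncol(X), n_train - 1)
  fold_id <- sample(rep(seq_len(folds), length.out = n_train))
  fit_one <- function(y) {
    ytr <- y[train_idx]; Xtr <- X[train_idx, , drop = FALSE]
    cv_rmse <- vapply(seq_len(max_ncomp), function(nc) {
      errs <- vapply(seq_len(folds), function(f) {
        tr <- fold_id != f
        m <- mixOmics::pls(Xtr[tr, , drop = FALSE],
                           matrix(ytr[tr], ncol = 1),
                           ncomp = nc, mode = "regression", scale = TRUE)
        pr <- predict_pls(m, Xtr[!tr, , drop = FALSE], nc)
        mean((pr - ytr[!tr])^2)
      }, 0)
      sqrt(mean(errs))
    }, 0)
    nc <- which.min(cv_rmse)
    model <- mixOmics::pls(Xtr, matrix(ytr, ncol = 1), ncomp = nc,
                           mode = "regression", scale = TRUE)
    pr_test <- predict_pls(model, X[test_idx, , drop = FALSE], nc)
    list(model = model, ncomp = nc, cv_rmse = cv_rmse,
         test_rmse = sqrt(mean((pr_test - y[test_idx])^2)))
  }
  f_ri <- fit_one(training$ri)
  f_rt2 <- fit_one(training$rt2_s)
  structure(list(ri = f_ri, rt2 = f_rt2, descriptors = colnames(X),
                 split = list(train = train_idx, test = test_idx, seed = seed),
                 test_rmse = c(ri = f_ri$test_rmse, rt2 = f_rt2$test_rmse)),
            class = "vamr_retention_model")
}

predict_pls <- function(model, X, ncomp) {
  p <- stats::predict(model, X)$predict
  as.numeric(p[, 1, ncomp])
}

#' Predict retention coordinates for tentatively identified compounds
#'
#' @param object A `vamr_retention_model` (or a linear serialization read
#'   back with [read_retention_model()]).
#' @param newdata Data frame carrying the descriptor columns (and optionally
#'   `cas`, carried through).
#' @param ... Unused.
#' @return Data frame with `ri_pred` and `rt2_pred` (plus `cas` if present).
#' @export
predict.vamr_retention_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata[object$descriptors])
  out <- data.frame(ri_pred = predict_pls(object$ri$model, X, object$ri$ncomp),
                    rt2_pred = predict_pls(object$rt2$model, X, object$rt2$ncomp))
  if ("cas" %in% names(newdata)) out <- cbind(cas = newdata$cas, out)
  out
}

#' @export
print.vamr_retention_model <- function(x, ...) {
  cat(sprintf("PLS retention model on %d descriptors\n", length(x$descriptors)))
  cat(sprintf("  RI:  %d component(s), test RMSE %.4g\n", x$ri$ncomp, x$test_rmse["ri"]))
  cat(sprintf("  rt2: %d component(s), test RMSE %.4g s\n", x$rt2$ncomp, x$test_rmse["rt2"]))
  invisible(x)
}

# A fitted PLS predictor is linear in the descriptors; serialize it as the
# equivalent intercept + coefficient form (versioned JSON), recovered by
# probing the predictor on unit steps.
linearize_model <- function(object) {
  p <- length(object$descriptors)
  X0 <- matrix(0, 1, p, dimnames = list(NULL, object$descriptors))
  base <- predict.vamr_retention_model(object, as.data.frame(X0))
  steps <- as.data.frame(diag(p)); names(steps) <- object$descriptors
  probe <- predict.vamr_retention_model(object, steps)
  list(ri = list(intercept = base$ri_pred,
                 coef = setNames(probe$ri_pred - base$ri_pred, object$descriptors)),
       rt2 = list(intercept = base$rt2_pred,
                  coef = setNames(probe$rt2_pred - base$rt2_pred, object$descriptors)))
}

#' Persist / restore a retention model as flat JSON
#'
#' The fitted PLS predictor is exactly linear in the descriptors, so the
#' model is stored as its equivalent intercept-plus-coefficients form
#' together with a format version; predictions from the restored model
#' equal the original to machine precision.
#'
#' @param object A `vamr_retention_model`.
#' @param path JSON file path.
#' @return `path` (write); a `vamr_retention_model_linear` (read), usable
#'   with `predict()`.
#' @export
write_retention_model <- function(object, path) {
  lin <- linearize_model(object)
  jsonlite::write_json(
    list(format = "vamr_retention_model", version = 1L,
         descriptors = object$descriptors,
         ncomp = list(ri = object$ri$ncomp, rt2 = object$rt2$ncomp),
         test_rmse = as.list(object$test_rmse),
         ri = list(intercept = lin$ri$intercept, coef = as.list(lin$ri$coef)),
         rt2 = list(intercept = lin$rt2$intercept, coef = as.list(lin$rt2$coef))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_retention_model
#' @export
read_retention_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$format, "vamr_retention_model"))
    stop("not a retention model file: ", path)
  as_lin <- function(part) list(intercept = as.numeric(part$intercept),
                                coef = unlist(part$coef))
  structure(list(descriptors = j$descriptors, ri = as_lin(j$ri),
                 rt2 = as_lin(j$rt2), version = j$version),
            class = "vamr_retention_model_linear")
}

#' @export
predict.vamr_retention_model_linear <- function(object, newdata, ...) {
  X <- as.matrix(newdata[object$descriptors])
  out <- data.frame(
    ri_pred = object$ri$intercept + drop(X %*% object$ri$coef[object$descriptors]),
    rt2_pred = object$rt2$intercept + drop(X %*% object$rt2$coef[object$descriptors]))
  if ("cas" %in% names(newdata)) out <- cbind(cas = newdata$cas, out)
  out
}

#' Plausibility-filter tentative identifications
#'
#' A tentative identity is retained only when its spectral match score
#' exceeds 80, its measured retention index deviates from the predicted one
#' by less than 200 RI units, and its measured second-dimension retention
#' time deviates by less than 2 s (strict inequalities). Peaks without a
#' prediction are rejected with reason `no_prediction`; rejected rows carry
#' all failing criteria (`;`-separated).
#'
#' @param peaks Peak data frame with columns `ri_meas`, `rt2_s`,
#'   `match_score`, `ri_pred`, `rt2_pred` (`NA` predictions allowed).
#' @param ri_tol,rt2_tol,score_min Thresholds (defaults 200 RI, 2 s, 80).
#' @return List with `retained` and `rejected` (with a `reason` column);
#'   the two partition the input.
#' @export
filter_identifications <- function(peaks, ri_tol = 200, rt2_tol = 2,
                                   score_min = 80) {
  req <- c("ri_meas", "rt2_s", "match_score", "ri_pred", "rt2_pred")
  miss <- setdiff(req, names(peaks))
  if (length(miss)) stop("peaks missing columns: ", paste(miss, collapse = ", "))
  no_pred <- is.na(peaks$ri_pred) | is.na(peaks$rt2_pred)
  fail_score <- peaks$match_score <= score_min
  fail_ri <- !no_pred & abs(peaks$ri_meas - peaks$ri_pred) >= ri_tol
  fail_rt2 <- !no_pred & abs(peaks$rt2_s - peaks$rt2_pred) >= rt2_tol
  reason <- vapply(seq_len(nrow(peaks)), function(i) {
    r <- c(if (no_pred[i]) "no_prediction",
           if (fail_score[i]) "match_score",
           if (fail_ri[i]) "ri_deviation",
           if (fail_rt2[i]) "rt2_deviation")
    if (length(r)) paste(r, collapse = ";") else NA_character_
  }, "")
  keep <- is.na(reason)
  rejected <- peaks[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  list(retained = peaks[keep, , drop = FALSE], rejected = rejected)
}

#' Composition summaries of retained peaks
#'
#' Per fraction: relative abundance of every retained compound (percent of
#' the fraction's total retained abundance), cumulative abundance per
#' chemical class, and the top-N most abundant compounds (ties broken
#' alphabetically by name).
#'
#' @param peaks Retained peak data frame (needs `fraction`, `name`, `cas`,
#'   `abundance`; `class_label` used when present).
#' @param top_n Size of the top-compound table (default 10).
#' @return List with `relative` (per-compound percent per fraction),
#'   `classes` (per-class cumulative abundance per fraction) and `top`
#'   (top-N rows per fraction).
#' @export
composition_summary <- function(peaks, top_n = 10) {
  if (nrow(peaks) == 0) {
    warning("no retained peaks; empty composition summary")
    empty <- data.frame()
    return(list(relative = empty, classes = empty, top = empty))
  }
  rel <- do.call(rbind, lapply(split(peaks, peaks$fraction), function(p) {
    tot <- sum(p$abundance)
    p$rel_pct <- if (tot > 0) 100 * p$abundance / tot else 0
    p[order(-p$rel_pct, p$name), c("fraction", "name", "cas", "class_label",
                                   "abundance", "rel_pct")]
  }))
  rownames(rel) <- NULL
  classes <- stats::aggregate(abundance ~ fraction + class_label,
                              data = transform(peaks,
                                class_label = ifelse(is.na(class_label) | class_label == "",
                                                     "unassigned", class_label)),
                              FUN = sum)
  classes <- classes[order(classes$fraction, -classes$abundance), ]
  rownames(classes) <- NULL
  top <- do.call(rbind, lapply(split(rel, rel$fraction), utils::head, top_n))
  rownames(top) <- NULL
  list(relative = rel, classes = classes, top = top)
}
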