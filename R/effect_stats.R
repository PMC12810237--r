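#' @title SSMD effect sizes and bootstrap group statistics
#' @description
#' Every treatment group is compared endpoint-by-endpoint to its designated
#' control: a strictly standardized mean difference (SSMD) quantifies the
#' effect size, a stratified bootstrap on the difference of medians gives a
#' p-value, and Benjamini-Hochberg adjustment across the 26 endpoints within
#' each treatment controls the false discovery rate. The SSMD column of the
#' result is the treatment's behavioral fingerprint.
#' @name effect_stats
NULL

SSMD_CAP <- 10  # cap for infinite SSMD (zero total variance, unequal means)

#' Strictly standardized mean difference
#'
#' `SSMD = (mean_t - mean_c) / sqrt(var_t + var_c)` with unbiased variances.
#' When both variances are zero the SSMD is 0 for equal means and capped at
#' +/-10 otherwise (keeps downstream clustering finite). A robust variant
#' replaces means by medians and variances by squared scaled MADs.
#'
#' @param treatment,control Numeric vectors (NAs dropped pairwise).
#' @param robust Use median/MAD instead of mean/variance (default FALSE).
#' @param cap Magnitude cap for degenerate zero-variance cases.
#' @return SSMD effect size, or `NA` (with a warning) when either arm has
#'   fewer than 2 non-missing values.
#' @export
ssmd <- function(treatment, control, robust = FALSE, cap = SSMD_CAP) {
  t <- treatment[!is.na(treatment)]
  c <- control[!is.na(control)]
  if (length(t) < 2 || length(c) < 2) {
    warning("ssmd needs at least 2 non-missing values per arm")
    return(NA_real_)
  }
  if (robust) {
    d <- stats::median(t) - stats::median(c)
    v <- stats::mad(t)^2 + stats::mad(c)^2
  } else {
    d <- mean(t) - mean(c)
    v <- stats::var(t) + stats::var(c)
  }
  if (v > 0) return(d / sqrt(v))
  if (d == 0) 0 else sign(d) * cap
}

# Core resampling engine: uses the current RNG stream (callers seed it).
boot_p_core <- function(treatment, control, B) {
  t <- treatment[!is.na(treatment)]
  c <- control[!is.na(control)]
  t_obs <- stats::median(t) - stats::median(c)
  if (length(unique(c(t, c))) == 1L) return(1)
  ts <- matrix(sample(t, length(t) * B, replace = TRUE), nrow = B)
  cs <- matrix(sample(c, length(c) * B, replace = TRUE), nrow = B)
  t_star <- apply(ts, 1, stats::median) - apply(cs, 1, stats::median)
  (1 + sum(abs(t_star - t_obs) >= abs(t_obs))) / (B + 1)
}

#' Two-sided bootstrap test for a difference in medians
#'
#' Stratified case resampling within each arm; the bootstrap distribution of
#' the difference of medians is centered at the observed difference, and
#' `p = (1 + #\{|T* - T_obs| >= |T_obs|\}) / (B + 1)`, so p is bounded below
#' by `1/(B+1)`. Degenerate data (all values identical across both arms)
#' give p = 1.
#'
#' @param treatment,control Numeric vectors (NAs dropped).
#' @param B Number of bootstrap resamples (>= 100; default 1000).
#' @param seed Integer seed; the test is reproducible given the seed.
#' @return Bootstrap p-value in `[1/(B+1), 1]`.
#' @export
bootstrap_test <- function(treatment, control, B = 1000, seed = 1L) {
  if (B < 100) stop("B must be at least 100")
  set.seed(seed)
  boot_p_core(treatment, control, B)
}

#' Benjamini-Hochberg adjustment across endpoints
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`, applied within one
#' treatment group (26 endpoints).
#'
#' @param p Vector of raw p-values.
#' @return Adjusted p-values (monotone, capped at 1).
#' @export
adjust_p <- function(p) stats::p.adjust(p, method = "BH")

#' Group-versus-control effect table and fingerprints
#'
#' For every non-control group in the plate map and every endpoint: SSMD,
#' bootstrap p-value against the group's designated control, BH-adjusted
#' p-value (within group, across the 26 endpoints), and a ternary direction
#' call (`increase`/`decrease`/`none`). Direction is `none` unless
#' `p_adj < alpha`; called directions follow the sign of the median
#' difference (SSMD sign on median ties). Ratio endpoints missing for some
#' larvae are dropped pairwise.
#'
#' @param endpoints Endpoint matrix (from [compute_endpoint_matrix()]).
#' @param plate_map Plate map (from [read_plate_map()]).
#' @param alpha Significance level for direction calls (default 0.05).
#' @param B Bootstrap resamples (default 1000).
#' @param seed Integer seed; one RNG stream drives all bootstraps, so the
#'   full table is reproducible given the seed.
#' @param robust Use the median/MAD SSMD variant (default FALSE).
#' @return A `vamr_effects` object: list with `effects` (data frame
#'   `group,endpoint,ssmd,p_raw,p_adj,direction,n_t,n_c`), `fingerprints`
#'   (group x 26 SSMD matrix, missing SSMDs imputed to 0 with an `imputed`
#'   attribute), `alpha`, `B`, `seed`.
#' @export
effect_table <- function(endpoints, plate_map, alpha = 0.05, B = 1000,
                         seed = 1L, robust = FALSE) {
  validate_plate_map(plate_map)
  pm <- plate_map[plate_map$well %in% endpoints$well, , drop = FALSE]
  groups <- unique(pm$group[!pm$is_control])
  if (length(groups) == 0) stop("plate map contains no treatment groups")
  ep_names <- endpoint_names()
  set.seed(seed)
  rows <- vector("list", length(groups) * length(ep_names))
  r <- 0L
  for (g in groups) {
    g_wells <- pm$well[pm$group == g]
    ctrl <- unique(pm$control_group[pm$group == g])[1]
    c_wells <- pm$well[pm$group == ctrl]
    if (length(g_wells) == 0) stop("empty treatment group: ", g)
    if (length(c_wells) == 0) stop("control group missing for group: ", g)
    gm <- endpoints[match(g_wells, endpoints$well), ep_names, drop = FALSE]
    cm <- endpoints[match(c_wells, endpoints$well), ep_names, drop = FALSE]
    for (ep in ep_names) {
      tv <- gm[[ep]][!is.na(gm[[ep]])]
      cv <- cm[[ep]][!is.na(cm[[ep]])]
      s <- if (length(tv) >= 2 && length(cv) >= 2)
        ssmd(tv, cv, robust = robust) else NA_real_
      p <- if (length(tv) >= 2 && length(cv) >= 2)
        boot_p_core(tv, cv, B) else NA_real_
      r <- r + 1L
      rows[[r]] <- data.frame(group = g, endpoint = ep, ssmd = s, p_raw = p,
                              med_diff = if (length(tv) && length(cv))
                                stats::median(tv) - stats::median(cv) else NA_real_,
                              n_t = length(tv), n_c = length(cv),
                              stringsAsFactors = FALSE)
    }
  }
  eff <- do.call(rbind, rows[seq_len(r)])
  eff$p_adj <- stats::ave(eff$p_raw, eff$group,
                          FUN = function(p) adjust_p(p))
  eff$direction <- "none"
  called <- !is.na(eff$p_adj) & eff$p_adj < alpha
  dsign <- ifelse(eff$med_diff != 0, sign(eff$med_diff), sign(eff$ssmd))
  eff$direction[called & dsign > 0] <- "increase"
  eff$direction[called & dsign < 0] <- "decrease"
  eff <- eff[c("group", "endpoint", "ssmd", "p_raw", "p_adj",
               "direction", "n_t", "n_c")]
  fp <- matrix(eff$ssmd, nrow = length(groups), byrow = TRUE,
               dimnames = list(groups, ep_names))
  imputed <- is.na(fp)
  fp[imputed] <- 0
  attr(fp, "imputed") <- imputed
  structure(list(effects = eff, fingerprints = fp, alpha = alpha,
                 B = B, seed = seed, robust = robust),
            class = "vamr_effects")
}

#' @export
print.vamr_effects <- function(x, ...) {
  called <- x$effects$direction != "none"
  cat(sprintf("vamr_effects: %d group(s) x 26 endpoints, alpha = %g, B = %d\n",
              nrow(x$fingerprints), x$alpha, x$B))
  cat(sprintf("  %d of %d group-endpoint pairs called (%d increase, %d decrease)\n",
              sum(called), nrow(x$effects),
              sum(x$effects$direction == "increase"),
              sum(x$effects$direction == "decrease")))
  invisible(x)
}

#' Write the effect table / fingerprints to CSV
#'
#' Fingerprints are written in the reference-library column layout
#' (`group,<26 endpoint columns>`), directly comparable to library rows.
#'
#' @param x A `vamr_effects` object.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_effect_table <- function(x, path) {
  utils::write.csv(x$effects, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_effect_table
#' @export
write_fingerprints <- function(x, path) {
  fp <- as.data.frame(x$fingerprints, check.names = FALSE)
  fp <- cbind(group = rownames(x$fingerprints), fp)
  utils::write.csv(fp, path, row.names = FALSE)
  invisible(path)
}
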