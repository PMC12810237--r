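#' @title Synthetic-data generators
#' @description
#' Pure, seeded generators producing inputs with the statistical structure
#' every pipeline stage assumes: stimulus-locked activity traces with
#' habituation decay and injected treatment effects of known sign, GCxGC
#' peak lists with a generative descriptor-to-retention map plus decoy
#' identities, and reference fingerprint libraries built from mode-of-action
#' archetypes. Every generator is a pure function of its config (seed
#' included), so outputs are byte-identical across runs.
#' @name synthetic_data
NULL

#' Trace generator configuration
#'
#' Activity is modeled per frame as multiplicative-lognormal background
#' (`baseline_level x phase multiplier x per-larva scale x lognormal noise`)
#' plus stimulus-locked 1-s boxcar startle pulses. Tap responses decay
#' within a habituation bout as `exp(-lambda (tap - 1))` and carry a
#' between-bout potentiation factor `pot^(bout - 1)`. Treatment wells apply
#' per-endpoint-family multipliers: `baseline` (baseline segments and all
#' inter-stimulus background), `light`, `dark`, `visual` (visual startle
#' pulses), `acoustic` (tap pulses) and `habituation` (multiplies lambda).
#' These multipliers are the injected ground truth.
#'
#' @param seed Integer seed.
#' @param n_per_group Larvae per arm (default 36, the assay's typical size).
#' @param baseline_level Baseline activity (delta pixel/s).
#' @param noise_sigma Per-frame lognormal sigma.
#' @param larva_sigma Between-larva lognormal scale sigma.
#' @param light_mult,dark_mult Phase multipliers for light/dark segments.
#' @param visual_startle_amp Visual startle pulse amplitude.
#' @param acoustic_amp_low,acoustic_amp_high Tap pulse amplitudes.
#' @param tap_noise_sigma Lognormal sigma of per-pulse amplitude noise.
#' @param habituation_lambda Within-bout exponential decay rate per tap.
#' @param bout_potentiation Between-bout amplitude factor (bout k scales by
#'   `bout_potentiation^(k-1)`).
#' @param treatment Named list of family multipliers (see above), all 1 by
#'   default (no effect).
#' @return A `vamr_trace_config` list.
#' @export
trace_config <- function(seed = 1L, n_per_group = 36, baseline_level = 2,
                         noise_sigma = 0.6, larva_sigma = 0.3,
                         light_mult = 1.3, dark_mult = 2.0,
                         visual_startle_amp = 15,
                         acoustic_amp_low = 10, acoustic_amp_high = 25,
                         tap_noise_sigma = 0.4,
                         habituation_lambda = 0.12, bout_potentiation = 0.75,
                         treatment = list()) {
  tr <- utils::modifyList(
    list(baseline = 1, light = 1, dark = 1, visual = 1, acoustic = 1,
         habituation = 1), treatment)
  stopifnot(baseline_level >= 0, noise_sigma >= 0, larva_sigma >= 0,
            habituation_lambda >= 0, all(unlist(tr) > 0),
            visual_startle_amp >= 0, acoustic_amp_low >= 0,
            acoustic_amp_high >= 0)
  structure(list(seed = as.integer(seed), n_per_group = n_per_group,
                 baseline_level = baseline_level, noise_sigma = noise_sigma,
                 larva_sigma = larva_sigma, light_mult = light_mult,
                 dark_mult = dark_mult, visual_startle_amp = visual_startle_amp,
                 acoustic_amp_low = acoustic_amp_low,
                 acoustic_amp_high = acoustic_amp_high,
                 tap_noise_sigma = tap_noise_sigma,
                 habituation_lambda = habituation_lambda,
                 bout_potentiation = bout_potentiation,
                 treatment = tr),
            class = "vamr_trace_config")
}

simulate_trace <- function(config, schedule, treated, fps = 25) {
  segs <- schedule$segments
  n <- as.integer(round(schedule$duration_s * fps))
  tmult <- if (treated) config$treatment else
    list(baseline = 1, light = 1, dark = 1, visual = 1, acoustic = 1,
         habituation = 1)
  mult <- rep(1 * tmult$baseline, n)
  for (i in seq_len(nrow(segs))) {
    idx <- frame_index(segs$start_s[i], fps):frame_index_end(segs$end_s[i], fps)
    if (segs$kind[i] == "light") mult[idx] <- config$light_mult * tmult$light
    else if (segs$kind[i] == "dark") mult[idx] <- config$dark_mult * tmult$dark
  }
  larva_scale <- exp(stats::rnorm(1, 0, config$larva_sigma))
  v <- config$baseline_level * mult * larva_scale *
    exp(stats::rnorm(n, 0, config$noise_sigma))
  pulse <- function(t, amp) {
    idx <- frame_index(t, fps):frame_index_end(t + TAP_WINDOW_S, fps)
    v[idx] <<- v[idx] + amp * larva_scale * exp(stats::rnorm(1, 0, config$tap_noise_sigma))
  }
  vis <- which(segs$kind %in% c("light", "dark"))
  for (i in vis) pulse(segs$start_s[i], config$visual_startle_amp * tmult$visual)
  tr <- which(segs$kind == "acoustic_train")
  for (i in tr) {
    amp <- if (segs$intensity[i] == "low") config$acoustic_amp_low
           else config$acoustic_amp_high
    for (t in schedule$tap_times[[i]]) pulse(t, amp * tmult$acoustic)
  }
  hb <- which(segs$kind == "habituation_bout")
  lambda <- config$habituation_lambda * tmult$habituation
  for (b in seq_along(hb)) {
    taps <- schedule$tap_times[[hb[b]]]
    base_amp <- config$acoustic_amp_high * tmult$acoustic *
      config$bout_potentiation^(b - 1)
    for (j in seq_along(taps))
      pulse(taps[j], base_amp * exp(-lambda * (j - 1)))
  }
  v
}

#' Generate a synthetic assay plate
#'
#' Simulates a control arm and a treatment arm of `n_per_group` larvae each
#' under the given schedule, together with the plate map, (all-viable)
#' status table, and the ground-truth table of injected effect directions
#' per endpoint. Reproducible by `config$seed`.
#'
#' @param config A [trace_config()].
#' @param schedule A `vamr_schedule` (default [default_schedule()]).
#' @param sampling_rate Frames per second (default 25).
#' @return List with `traces` (`vamr_traces`), `plate_map`, `statuses`,
#'   `truth` (data frame `endpoint,direction`) and `config`.
#' @export
generate_plate <- function(config, schedule = default_schedule(),
                           sampling_rate = 25) {
  set.seed(config$seed)
  n <- config$n_per_group
  if (2 * n > 96) stop("at most 48 larvae per arm on a 96-well plate")
  wells <- paste0(rep(LETTERS[1:8], each = 12), rep(1:12, 8))[seq_len(2 * n)]
  groups <- rep(c("control", "treatment"), each = n)
  activity <- vector("list", 2 * n)
  names(activity) <- wells
  for (i in seq_len(2 * n))
    activity[[i]] <- simulate_trace(config, schedule,
                                    treated = groups[i] == "treatment",
                                    fps = sampling_rate)
  traces <- new_traces(activity, sampling_rate)
  plate_map <- data.frame(
    well = wells, group = groups,
    treatment = ifelse(groups == "control", "vehicle", "test_substance"),
    concentration = ifelse(groups == "control", 0, 1),
    unit = "au", is_control = groups == "control",
    control_group = "control", stringsAsFactors = FALSE)
  statuses <- data.frame(well = wells, dead = FALSE, malformed = FALSE,
                         swim_bladder_inflated = TRUE, stringsAsFactors = FALSE)
  list(traces = traces, plate_map = plate_map, statuses = statuses,
       truth = injected_truth(config), config = config)
}

# Expected direction per endpoint implied by the treatment multipliers.
injected_truth <- function(config) {
  tr <- config$treatment
  dir_of <- function(m) if (m > 1) "increase" else if (m < 1) "decrease" else "none"
  truth <- setNames(rep("none", 26), endpoint_names())
  truth[paste0("BSL", 1:4)] <- dir_of(tr$baseline)
  truth[c(paste0("ISI", 1:3), paste0("IEI", 1:3), "IBI")] <- dir_of(tr$baseline)
  truth["VMR1"] <- dir_of(tr$light)
  truth[paste0("VMR", 2:5)] <- dir_of(tr$dark)
  truth[c("VSRB", "VSR1", "VSR2")] <- dir_of(tr$visual)
  truth[c(paste0("ASR", 1:3), "ASHsum")] <- dir_of(tr$acoustic)
  # a larger decay rate lowers the late-tap share of bout 1
  truth["ASH1"] <- if (tr$habituation > 1) "decrease"
                   else if (tr$habituation < 1) "increase" else "none"
  data.frame(endpoint = names(truth), direction = unname(truth),
             stringsAsFactors = FALSE)
}

#' Peak-list generator configuration
#'
#' True compounds draw their retention from a fixed linear generative map of
#' the physicochemical descriptors plus Gaussian noise; decoys keep a real
#' compound's identity (and therefore its predicted retention) but draw
#' their measured retention uniformly over the chromatographic plane,
#' independent of the descriptors. Split duplicates are offset within the
#' binning quadrant for binning tests.
#'
#' @param seed Integer seed.
#' @param n_true,n_decoys Counts of true and decoy peaks.
#' @param duplicate_rate Probability that a true peak is split in two.
#' @param sigma_ri,sigma_rt2 Retention noise SDs (RI units, seconds).
#' @param abundance_meanlog,abundance_sdlog Lognormal abundance parameters.
#' @param fraction Fraction label stamped on generated peaks.
#' @return A `vamr_peak_config` list.
#' @export
peak_config <- function(seed = 1L, n_true = 80, n_decoys = 20,
                        duplicate_rate = 0.1, sigma_ri = 30, sigma_rt2 = 0.3,
                        abundance_meanlog = 10, abundance_sdlog = 1,
                        fraction = "synthetic") {
  stopifnot(sigma_ri >= 0, sigma_rt2 >= 0, n_true >= 0, n_decoys >= 0,
            duplicate_rate >= 0, duplicate_rate <= 1)
  structure(list(seed = as.integer(seed), n_true = n_true, n_decoys = n_decoys,
                 duplicate_rate = duplicate_rate, sigma_ri = sigma_ri,
                 sigma_rt2 = sigma_rt2, abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog, fraction = fraction),
            class = "vamr_peak_config")
}

# Fixed generative descriptor -> retention map shared by all chemistry
# generators; chosen to keep RI within a C8-C30 ladder and rt2 within a 6 s
# modulation period.
retention_map <- function(desc) {
  list(ri = 550 + 6 * desc$mw + 8 * desc$xlogp + 0.5 * desc$tpsa,
       rt2 = 0.5 + 0.35 * desc$xlogp + 0.01 * desc$tpsa + 0.002 * desc$complexity)
}

sample_descriptors <- function(n, cas) {
  data.frame(
    cas = cas,
    mw = stats::runif(n, 60, 380),
    xlogp = stats::runif(n, 0, 6),
    tpsa = stats::runif(n, 0, 80),
    complexity = stats::runif(n, 50, 600),
    atom_stereo = stats::rpois(n, 1),
    hbd = stats::rpois(n, 1),
    hba = stats::rpois(n, 2),
    rotb = stats::rpois(n, 3),
    heavy_atoms = stats::rpois(n, 15) + 5,
    defined_stereo = stats::rpois(n, 0.5),
    undefined_stereo = stats::rpois(n, 0.3),
    stringsAsFactors = FALSE)
}

synthetic_class <- function(desc) {
  ifelse(desc$tpsa > 40, "oxygenated",
         ifelse(desc$xlogp > 4, "PAH", "monoaromatic"))
}

#' Default C8-C30 n-alkane ladder
#'
#' Linear elution (1.3 min per carbon from 4 min), spanning RI 800-3000.
#'
#' @return Ladder data frame `carbon_n,rt1_min`.
#' @export
default_alkane_ladder <- function() {
  data.frame(carbon_n = 8:30, rt1_min = 4 + (8:30 - 8) * 1.3)
}

#' Generate a synthetic GCxGC peak list
#'
#' @param config A [peak_config()].
#' @param ladder Alkane ladder spanning the generated RI range (default
#'   [default_alkane_ladder()]).
#' @return List with `peaks` (peak-list data frame incl. `peak_id`),
#'   `descriptors` (one row per distinct CAS) and `truth` (data frame
#'   `peak_id,cas,role,parent_id`; roles `true`, `decoy`, `duplicate`).
#' @export
generate_peaklist <- function(config, ladder = default_alkane_ladder()) {
  set.seed(config$seed)
  n_cmpd <- config$n_true + config$n_decoys
  if (n_cmpd == 0) {
    empty <- data.frame(fraction = character(0), rt1_min = numeric(0),
                        rt2_s = numeric(0), abundance = numeric(0),
                        cas = character(0), name = character(0),
                        match_score = numeric(0), class_label = character(0),
                        peak_id = integer(0), stringsAsFactors = FALSE)
    return(list(peaks = empty,
                descriptors = sample_descriptors(0, character(0)),
                truth = data.frame(peak_id = integer(0), cas = character(0),
                                   role = character(0), parent_id = integer(0))))
  }
  cas <- sprintf("%04d-%02d-%d", seq_len(n_cmpd) + 1000,
                 seq_len(n_cmpd) %% 100, seq_len(n_cmpd) %% 10)
  desc <- sample_descriptors(n_cmpd, cas)
  map <- retention_map(desc)
  ri_range <- range(retention_index(ladder$rt1_min, ladder))
  role <- c(rep("true", config$n_true), rep("decoy", config$n_decoys))
  ri_meas <- ifelse(role == "true",
                    map$ri + stats::rnorm(n_cmpd, 0, config$sigma_ri),
                    stats::runif(n_cmpd, ri_range[1] + 50, ri_range[2] - 50))
  rt2_meas <- ifelse(role == "true",
                     pmax(0, map$rt2 + stats::rnorm(n_cmpd, 0, config$sigma_rt2)),
                     stats::runif(n_cmpd, 0, 6))
  peaks <- data.frame(
    fraction = config$fraction,
    rt1_min = rt1_from_ri(pmin(pmax(ri_meas, ri_range[1]), ri_range[2]), ladder),
    rt2_s = rt2_meas,
    abundance = stats::rlnorm(n_cmpd, config$abundance_meanlog,
                              config$abundance_sdlog),
    cas = cas,
    name = paste0("compound_", seq_len(n_cmpd)),
    match_score = stats::runif(n_cmpd, 81, 99),
    class_label = synthetic_class(desc),
    stringsAsFactors = FALSE)
  truth <- data.frame(peak_id = seq_len(n_cmpd), cas = cas, role = role,
                      parent_id = NA_integer_, stringsAsFactors = FALSE)
  dup <- which(role == "true" &
                 stats::runif(n_cmpd) < config$duplicate_rate)
  if (length(dup)) {
    twins <- peaks[dup, , drop = FALSE]
    twins$rt1_min <- twins$rt1_min + stats::runif(length(dup), -0.15, 0.15)
    twins$rt2_s <- pmax(0, twins$rt2_s + stats::runif(length(dup), -0.15, 0.15))
    share <- stats::runif(length(dup), 0.2, 0.5)
    twins$abundance <- peaks$abundance[dup] * share
    peaks$abundance[dup] <- peaks$abundance[dup] * (1 - share)
    peaks <- rbind(peaks, twins)
    truth <- rbind(truth, data.frame(peak_id = nrow(truth) + seq_along(dup),
                                     cas = twins$cas, role = "duplicate",
                                     parent_id = dup, stringsAsFactors = FALSE))
  }
  peaks$peak_id <- seq_len(nrow(peaks))
  list(peaks = peaks, descriptors = desc, truth = truth)
}

#' Generate a retention-model calibration set
#'
#' Draws `n` calibration compounds from the same generative
#' descriptor-to-retention map as [generate_peaklist()], with optional
#' Gaussian measurement noise, in the layout expected by
#' [fit_retention_model()].
#'
#' @param n Number of calibration compounds (default 119, split 100/19 by
#'   the model fitter).
#' @param seed Integer seed.
#' @param sigma_ri,sigma_rt2 Measurement noise SDs (default 0: noiseless).
#' @return Data frame `cas,<11 descriptors>,ri,rt2_s`.
#' @export
generate_retention_calibration <- function(n = 119, seed = 1L,
                                           sigma_ri = 0, sigma_rt2 = 0) {
  set.seed(seed)
  desc <- sample_descriptors(n, sprintf("cal-%03d-0", seq_len(n)))
  map <- retention_map(desc)
  desc$ri <- map$ri + stats::rnorm(n, 0, sigma_ri)
  desc$rt2_s <- map$rt2 + stats::rnorm(n, 0, sigma_rt2)
  desc
}

#' Generate a synthetic reference fingerprint library
#'
#' Builds `n_compounds` reference fingerprints around `n_archetypes`
#' mode-of-action archetype profiles (e.g. a disinhibition-like archetype
#' with raised interstimulus activity, a sedative-like archetype with global
#' hypoactivity, a stimulant-like archetype with raised startle and
#' dark-phase activity) plus isotropic Gaussian noise. This stand-in
#' emulates the structure of curated neuroactive reference libraries, whose
#' actual values are not redistributable.
#'
#' @param n_archetypes Number of archetypes (>= 2; 3 have curated profiles,
#'   further ones are seeded random sign patterns).
#' @param n_compounds Number of library rows (default 63).
#' @param sigma Profile noise SD (default 0.2).
#' @param seed Integer seed.
#' @return Reference library data frame (`compound,concentration,
#'   moa_target,moa_class,<26 endpoints>`) with an `archetypes` attribute
#'   holding the noise-free profiles.
#' @export
generate_reference_library <- function(n_archetypes = 3, n_compounds = 63,
                                       sigma = 0.2, seed = 1L) {
  if (n_archetypes < 2) stop("need at least 2 archetypes")
  set.seed(seed)
  nm <- endpoint_names()
  prof <- function(vals) { p <- setNames(rep(0, 26), nm); p[names(vals)] <- vals; p }
  arch <- list(
    disinhibition = prof(c(setNames(rep(2, 7), c(paste0("ISI", 1:3), paste0("IEI", 1:3), "IBI")),
                           VMR1 = 2, ASH1 = -0.8)),
    sedative = prof(setNames(rep(-2, 15),
                             c("VSRB", "VSR1", "VSR2", paste0("VMR", 1:5),
                               paste0("BSL", 1:4), paste0("ASR", 1:3)))),
    stimulant = prof(c(setNames(rep(2, 4), c(paste0("ASR", 1:3), "ASHsum")),
                       setNames(rep(1.5, 4), paste0("VMR", 2:5)),
                       setNames(rep(1, 4), paste0("BSL", 1:4)))))
  targets <- c(disinhibition = "GABA-A receptor (antagonist-like)",
               sedative = "GABA-A receptor (agonist-like)",
               stimulant = "monoamine transporter (stimulant-like)")
  if (n_archetypes > 3) {
    for (k in 4:n_archetypes) {
      nm_k <- paste0("archetype_", k)
      arch[[nm_k]] <- prof(setNames(sample(c(-2, 0, 2), 26, replace = TRUE),
                                    nm))
      targets[nm_k] <- paste0("synthetic target ", k)
    }
  }
  arch <- arch[seq_len(n_archetypes)]
  conc <- signif(80 / 10^(0:5 / 4), 3)
  assign_arch <- rep(seq_len(n_archetypes), length.out = n_compounds)
  rows <- lapply(seq_len(n_compounds), function(i) {
    a <- assign_arch[i]
    p <- arch[[a]] + stats::rnorm(26, 0, sigma)
    out <- data.frame(compound = sprintf("ref_%02d", i),
                      concentration = sample(conc, 1),
                      moa_target = unname(targets[names(arch)[a]]),
                      moa_class = names(arch)[a],
                      stringsAsFactors = FALSE, check.names = FALSE)
    out[nm] <- as.list(p)
    out
  })
  lib <- do.call(rbind, rows)
  attr(lib, "archetypes") <- arch
  attr(lib, "archetype_of") <- assign_arch
  lib
}
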