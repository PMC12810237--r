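#' @title Exposure-solution arithmetic
#' @description
#' Deterministic arithmetic for WAF loading rates, proportional artificial
#' mixtures of equal-molarity stocks, and serial dilution series. Rounding
#' conventions are fixed (mass to the nearest mg, loading to 2 significant
#' figures, percentages to 1 decimal, concentrations to 3 significant
#' figures) so that printed protocol values are reproduced exactly.
#' @name mixture_design
NULL

#' Oil-to-water loading of a WAF preparation
#'
#' `mass = oil volume x density`; `loading = mass / water volume`.
#'
#' @param oil_volume_uL Oil volume in microliters.
#' @param density_g_per_mL Oil density in g/mL.
#' @param water_volume_mL Water volume in milliliters.
#' @return List with raw `oil_mass_mg` and `loading_mg_per_L`, plus rounded
#'   `oil_mass_mg_rounded` (nearest mg) and `loading_rounded` (2 significant
#'   figures).
#' @export
waf_loading <- function(oil_volume_uL, density_g_per_mL, water_volume_mL) {
  if (any(c(oil_volume_uL, density_g_per_mL, water_volume_mL) <= 0))
    stop("all loading inputs must be positive")
  mass_mg <- oil_volume_uL * density_g_per_mL  # uL * g/mL = mg
  loading <- mass_mg / (water_volume_mL / 1000)
  list(oil_mass_mg = mass_mg,
       loading_mg_per_L = loading,
       oil_mass_mg_rounded = round(mass_mg),
       loading_rounded = signif(loading, 2))
}

#' Define an artificial mixture of equal-molarity stocks
#'
#' @param components Data frame `name,cas,proportion` with proportions in
#'   `(0, 1]` summing to 1 within +/-0.002 (printed protocol proportions may
#'   not sum exactly to 1).
#' @param stock_mM Molarity of each component stock (mM).
#' @param total_uL Total mixture volume (microliters).
#' @return A `vamr_mixture_spec` list.
#' @export
mixture_spec <- function(components, stock_mM, total_uL) {
  miss <- setdiff(c("name", "cas", "proportion"), names(components))
  if (length(miss)) stop("components missing columns: ", paste(miss, collapse = ", "))
  if (any(components$proportion <= 0 | components$proportion > 1))
    stop("proportions must lie in (0, 1]")
  s <- sum(components$proportion)
  if (abs(s - 1) > 0.002)
    stop(sprintf("proportions sum to %.4f; must be 1 within 0.002", s))
  if (stock_mM <= 0 || total_uL <= 0) stop("stock molarity and volume must be positive")
  structure(list(components = components, stock_mM = stock_mM,
                 total_uL = total_uL),
            class = "vamr_mixture_spec")
}

#' Per-component volumes of a proportional mixture
#'
#' `volume_i = proportion_i / sum(proportions) x total volume`. Combining
#' any volumes of equal-molarity stocks leaves the combined molarity at the
#' stock molarity.
#'
#' @param spec A `vamr_mixture_spec`.
#' @return Data frame `name,cas,proportion,volume_uL` plus attribute
#'   `combined_mM`.
#' @export
mixture_volumes <- function(spec) {
  stopifnot(inherits(spec, "vamr_mixture_spec"))
  p <- spec$components$proportion
  out <- spec$components
  out$volume_uL <- p / sum(p) * spec$total_uL
  attr(out, "combined_mM") <- spec$stock_mM
  out
}

#' Percent composition from component volumes
#'
#' Inverse of [mixture_volumes()]: `100 x volume_i / sum(volumes)`, rounded
#' to 1 decimal place (the protocol's printed precision).
#'
#' @param volumes_uL Numeric vector of component volumes.
#' @return Percentages rounded to 1 decimal.
#' @export
proportions_from_volumes <- function(volumes_uL) {
  if (any(volumes_uL <= 0)) stop("volumes must be positive")
  round(100 * volumes_uL / sum(volumes_uL), 1)
}

#' Serial dilution series
#'
#' Concentrations `top / factor^k`, k = 0..n-1, reported at 3 significant
#' figures. The `"quarter_log"` preset uses factor `10^0.25` (~1.778 x).
#' Published series that do not follow a constant factor can be used
#' verbatim instead of generating one.
#'
#' @param top Top concentration.
#' @param n Number of steps (>= 1).
#' @param factor Explicit step factor (> 1); overrides `preset`.
#' @param preset `"quarter_log"` (default), `"half_log"` or `"log"`.
#' @param unit Concentration unit label (default `"uM"`).
#' @return A `vamr_dilution_series`: list with `concentrations` (3
#'   significant figures), `raw`, `factor`, `unit`.
#' @export
dilution_series <- function(top, n, factor = NULL,
                            preset = c("quarter_log", "half_log", "log"),
                            unit = "uM") {
  if (n < 1) stop("n must be at least 1")
  if (top <= 0) stop("top concentration must be positive")
  if (is.null(factor)) {
    preset <- match.arg(preset)
    factor <- switch(preset, quarter_log = 10^0.25, half_log = 10^0.5, log = 10)
  }
  if (factor <= 1) stop("dilution factor must be greater than 1")
  raw <- top / factor^(0:(n - 1))
  structure(list(concentrations = signif(raw, 3), raw = raw,
                 factor = factor, unit = unit),
            class = "vamr_dilution_series")
}

#' @export
print.vamr_dilution_series <- function(x, ...) {
  cat(sprintf("%d-step dilution series (factor %.4g): %s %s\n",
              length(x$concentrations), x$factor,
              paste(x$concentrations, collapse = ", "), x$unit))
  invisible(x)
}

#' Export mixture volumes and a dilution series for lab handoff
#'
#' @param volumes Output of [mixture_volumes()].
#' @param series Optional `vamr_dilution_series`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_mixture_sheet <- function(volumes, series = NULL, path) {
  utils::write.csv(volumes, path, row.names = FALSE)
  if (!is.null(series)) {
    cat("\n", file = path, append = TRUE)
    utils::write.table(
      data.frame(step = seq_along(series$concentrations),
                 concentration = series$concentrations, unit = series$unit),
      path, append = TRUE, sep = ",", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
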