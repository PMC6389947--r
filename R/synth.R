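#' Simulate a dye-influx fluorescence trace
#'
#' Generates a Quin-2-style vesicle leakage trace with known ground truth:
#' a flat (optionally noisy) baseline before the peptide addition time,
#' followed by a saturating rise to `F_eq < F_max` under one of two
#' phenomenological kinetic laws, on the ionophore-normalized scale
#' (or a raw scale when `baseline`/`f_max` are changed):
#'
#' * `"exponential"`: `F(t) = F_eq (1 - exp(-k_exp (t - t_add)))`
#' * `"second_order"`: `F(t) = F_eq x / (1 + x)` with
#'   `x = k_a [P_b] (t - t_add)`
#'
#' Defaults mirror the reference assay: addition at 248 s, 1-s sampling
#' over 1500 s, normalized maximum 1. Noise is additive i.i.d. Gaussian.
#' The generator is a deterministic function of `seed`.
#'
#' @param model `"exponential"` or `"second_order"`.
#' @param f_eq Equilibrium level on the normalized scale (default 0.6).
#' @param k_exp Exponential rate constant, s^-1 (exponential model).
#' @param k_a Second-order rate constant, M^-1 s^-1 (second-order model).
#' @param p_b Membrane-bound peptide concentration, M (second-order
#'   model).
#' @param t_add Peptide addition time, s (default 248).
#' @param duration Total trace length, s (default 1500).
#' @param dt Sampling interval, s (default 1).
#' @param baseline Baseline fluorescence level (default 0).
#' @param f_max Ionophore maximum (default 1).
#' @param noise Gaussian noise standard deviation on the normalized scale
#'   (default 0).
#' @param seed Optional RNG seed; the trace is reproducible given the
#'   seed.
#' @return A [fluor_trace()] whose `ground_truth` attribute records every
#'   generating parameter.
#' @examples
#' tr <- simulate_trace(model = "second_order", k_a = 1e5, p_b = 2e-6,
#'                      noise = 0.01, seed = 42)
#' @export
simulate_trace <- function(model = c("exponential", "second_order"),
                           f_eq = 0.6, k_exp = 0.01, k_a = 1e5, p_b = 2e-6,
                           t_add = 248, duration = 1500, dt = 1,
                           baseline = 0, f_max = 1, noise = 0, seed = NULL) {
  model <- arg_match(model)
  if (duration <= 0 || dt <= 0) abort("`duration` and `dt` must be positive.")
  if (t_add < 0 || t_add >= duration) {
    abort("`t_add` must fall inside the trace duration.")
  }
  if (!is.null(seed)) set.seed(seed)
  time <- seq(0, duration, by = dt)
  tau <- pmax(time - t_add, 0)
  rel <- switch(model,
    exponential = f_eq * (1 - exp(-k_exp * tau)),
    second_order = {
      x <- k_a * p_b * tau
      f_eq * x / (1 + x)
    }
  )
  rel[time < t_add] <- 0
  intensity <- baseline + (f_max - baseline) * rel
  if (noise > 0) intensity <- intensity + stats::rnorm(length(time), 0, noise)
  gt <- list(model = model, f_eq = f_eq, t_add = t_add, baseline = baseline,
             f_max = f_max, noise = noise, seed = seed)
  if (model == "exponential") gt$k_exp <- k_exp else {
    gt$k_a <- k_a
    gt$p_b <- p_b
  }
  fluor_trace(tibble(time = time, intensity = intensity),
              t_add = t_add, f_max = f_max, ground_truth = gt)
}

#' Amide I and CH2 generator scenarios
#'
#' Component tables for [simulate_polarized_pair()]: `label`, `center`
#' (cm^-1), `fwhm` (cm^-1), `area` (pseudo-isotropic band area
#' `(a_par + 2 a_perp)/3`), and `r` (per-component dichroic ratio).
#'
#' `amide_i_scenario()` is a five-component amide I pattern typical of
#' this peptide in membranes — beta-sheet fraction 0.40 with a sheet
#' dichroic ratio of 0.89, plus turn, helix, irregular and side-chain
#' bands. `ch2_scenario()` builds the two lipid methylene stretching
#' bands with the dichroic ratio implied by an acyl-chain order parameter
#' `s_l` (dipoles perpendicular to the chain).
#'
#' @param sheet_r Dichroic ratio of the sheet component (default 0.89).
#' @return A component tibble.
#' @export
amide_i_scenario <- function(sheet_r = 0.89) {
  tibble(
    label = c("turn", "helix", "irregular", "sheet", "side"),
    center = c(1683, 1657, 1643, 1629, 1610),
    fwhm = c(24, 16, 12, 18, 14),
    area = c(0.20, 0.25, 0.15, 0.40, 0.10),
    r = c(1.05, 1.00, 1.00, sheet_r, 1.00)
  )
}

#' @rdname amide_i_scenario
#' @param s_l Acyl-chain order parameter in `[-0.5, 1]` (default 0.6).
#' @param geometry [atr_geometry()] used to convert `s_l` to a dichroic
#'   ratio (alpha forced to 90 degrees).
#' @export
ch2_scenario <- function(s_l = 0.6, geometry = atr_geometry()) {
  geometry$alpha <- 90
  r <- r_from_order_parameter(s_l, geometry)
  tibble(
    label = c("ch2_antisym", "ch2_sym"),
    center = c(2922, 2852),
    fwhm = c(20, 16),
    area = c(1.0, 0.6),
    r = c(r, r)
  )
}

#' Simulate a polarized spectrum pair from band components
#'
#' Builds matched parallel/perpendicular absorbance spectra as sums of
#' pseudo-Voigt components. Each component's polarized areas satisfy
#' `a_par / a_perp = r` exactly (before noise) with the pseudo-isotropic
#' total fixed by `area`: `a_perp = 3 area / (r + 2)`,
#' `a_par = r a_perp`. Gaussian noise is added independently per
#' polarization, scaled to the peak of the noise-free parallel spectrum.
#'
#' @param components A component tibble (see [amide_i_scenario()]).
#' @param grid Wavenumber grid, cm^-1 (default 1 cm^-1 over 1550-1750).
#' @param shape Gaussian fraction of the line shape (default 1).
#' @param noise_frac Noise standard deviation as a fraction of the peak
#'   parallel absorbance (default 0).
#' @param seed Optional RNG seed.
#' @return An [ir_pair()] carrying the generating components (with their
#'   exact `a_par`, `a_perp`) in `ground_truth`.
#' @examples
#' pair <- simulate_polarized_pair(amide_i_scenario(), noise_frac = 0.005,
#'                                 seed = 7)
#' @export
simulate_polarized_pair <- function(components, grid = seq(1550, 1750, by = 1),
                                    shape = 1, noise_frac = 0, seed = NULL) {
  need <- c("label", "center", "fwhm", "area", "r")
  if (!is.data.frame(components) || !all(need %in% names(components))) {
    abort("`components` needs columns label, center, fwhm, area, r.")
  }
  if (any(diff(grid) <= 0)) abort("`grid` must be strictly increasing.")
  if (any(components$center < min(grid) | components$center > max(grid))) {
    abort("All component centers must lie inside the grid.")
  }
  if (!is.null(seed)) set.seed(seed)
  a_perp <- 3 * components$area / (components$r + 2)
  a_par <- components$r * a_perp
  unit <- pseudo_voigt_area(components$fwhm, shape)
  par <- perp <- numeric(length(grid))
  for (i in seq_len(nrow(components))) {
    prof <- pseudo_voigt(grid, components$center[i], components$fwhm[i], shape)
    par <- par + (a_par[i] / unit[i]) * prof
    perp <- perp + (a_perp[i] / unit[i]) * prof
  }
  if (noise_frac > 0) {
    sdv <- noise_frac * max(par)
    par <- par + stats::rnorm(length(grid), 0, sdv)
    perp <- perp + stats::rnorm(length(grid), 0, sdv)
  }
  gt <- mutate(components, a_par = a_par, a_perp = a_perp, shape = shape)
  ir_pair(grid, par, perp,
          ground_truth = list(components = gt, noise_frac = noise_frac,
                              seed = seed))
}

#' Simulate a mixed bound/free CD spectrum
#'
#' The inverse of [bound_difference_spectrum()]: forms the
#' population-weighted mixture `f_bound * bound + (1 - f_bound) * free`
#' (plus optional Gaussian noise) on the common wavelength grid.
#'
#' @param bound,free [cd_spectrum()]s (or compatible data frames).
#' @param f_bound Bound fraction in `[0, 1]`.
#' @param noise Gaussian noise standard deviation (default 0).
#' @param seed Optional RNG seed.
#' @return A [cd_spectrum()] with ground truth attached.
#' @export
simulate_cd_mixture <- function(bound, free, f_bound, noise = 0, seed = NULL) {
  if (!is.numeric(f_bound) || length(f_bound) != 1L ||
      f_bound < 0 || f_bound > 1) {
    abort("`f_bound` must be a single fraction in [0, 1].")
  }
  b <- as_cd(bound)
  f <- as_cd(free)
  grid <- common_grid(b, f)
  be <- approx(b$wavelength, b$ellipticity, xout = grid)$y
  fe <- approx(f$wavelength, f$ellipticity, xout = grid)$y
  if (!is.null(seed)) set.seed(seed)
  y <- f_bound * be + (1 - f_bound) * fe
  if (noise > 0) y <- y + stats::rnorm(length(grid), 0, noise)
  out <- cd_spectrum(grid, y)
  attr(out, "ground_truth") <- list(f_bound = f_bound, noise = noise,
                                    seed = seed)
  out
}
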