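#' Polarized infrared spectrum pair
#'
#' A matched pair of absorbance spectra measured at parallel and
#' perpendicular polarization on a common wavenumber grid, as produced by
#' polarized ATR-FTIR on a germanium internal-reflection element.
#'
#' @param wavenumber Wavenumber grid in cm^-1 (ascending or descending).
#' @param par,perp Absorbance at parallel / perpendicular polarization.
#' @param ground_truth Optional generator parameters (see
#'   [simulate_polarized_pair()]).
#' @return A tibble of class `ir_pair` with columns `wavenumber`, `par`,
#'   `perp`.
#' @export
ir_pair <- function(wavenumber, par, perp, ground_truth = NULL) {
  wavenumber <- as.numeric(wavenumber)
  if (length(par) != length(wavenumber) || length(perp) != length(wavenumber)) {
    abort("Both polarizations must share the wavenumber grid.")
  }
  if (anyNA(wavenumber) || anyNA(par) || anyNA(perp) ||
      any(!is.finite(c(par, perp)))) {
    abort("Absorbance and wavenumber values must be finite.")
  }
  d <- diff(wavenumber)
  if (!(all(d > 0) || all(d < 0))) {
    abort("`wavenumber` must be strictly monotone.")
  }
  out <- tibble(wavenumber = wavenumber, par = as.numeric(par),
                perp = as.numeric(perp))
  class(out) <- c("ir_pair", class(out))
  attr(out, "ground_truth") <- ground_truth
  out
}

#' Band models for curve fitting
#'
#' A band model is a tibble with one row per component: `label`,
#' `center_min`/`center_max` (allowed center window, cm^-1),
#' `fwhm_min`/`fwhm_max` (width bounds, cm^-1), and `shape` (Gaussian
#' fraction of a pseudo-Voigt profile; 1 = pure Gaussian).
#'
#' `amide_i_bands()` gives the standard amide I assignment for this
#' peptide-lipid system: beta/gamma turns 1670-1700, alpha-helix
#' 1654-1660, irregular (unordered) 1642-1644, beta-sheet 1628-1630, and
#' amino-acid side-chain bands 1600-1620 cm^-1. `ch2_bands()` covers the
#' lipid acyl-chain methylene stretches: antisymmetric at 2921-2923 and
#' symmetric at 2851-2853 cm^-1.
#'
#' @param shape Gaussian fraction for all components (default 1).
#' @return A band-model tibble.
#' @export
amide_i_bands <- function(shape = 1) {
  tibble(
    label = c("turn", "helix", "irregular", "sheet", "side"),
    center_min = c(1670, 1654, 1642, 1628, 1600),
    center_max = c(1700, 1660, 1644, 1630, 1620),
    fwhm_min = rep(8, 5),
    fwhm_max = rep(42, 5),
    shape = rep(shape, 5)
  )
}

#' @rdname amide_i_bands
#' @export
ch2_bands <- function(shape = 1) {
  tibble(
    label = c("ch2_antisym", "ch2_sym"),
    center_min = c(2916, 2846),
    center_max = c(2928, 2858),
    fwhm_min = rep(8, 2),
    fwhm_max = rep(32, 2),
    shape = rep(shape, 2)
  )
}

# pseudo-Voigt profile with unit amplitude
pseudo_voigt <- function(x, center, fwhm, shape) {
  g <- exp(-4 * log(2) * ((x - center) / fwhm)^2)
  l <- 1 / (1 + 4 * ((x - center) / fwhm)^2)
  shape * g + (1 - shape) * l
}

# analytic area of a unit-amplitude pseudo-Voigt
pseudo_voigt_area <- function(fwhm, shape) {
  shape * fwhm * 0.5 * sqrt(pi / log(2)) + (1 - shape) * pi * fwhm / 2
}

#' Decompose a polarized spectrum pair into band components
#'
#' Nonlinear least-squares decomposition of a spectral region into the
#' components of a band model, fitted jointly to both polarizations:
#' centers and widths are shared across polarizations (the molecular bands
#' are the same species) while amplitudes are free per polarization, which
#' is what makes per-component dichroic ratios meaningful.
#'
#' A linear baseline anchored at the region endpoints is subtracted from
#' each polarization before fitting (`baseline = "none"` disables this).
#'
#' @param pair An [ir_pair()].
#' @param model A band-model tibble (see [amide_i_bands()]).
#' @param region Length-2 wavenumber window (cm^-1), e.g. `c(1600, 1700)`.
#' @param baseline `"linear"` (default) or `"none"`.
#' @return An object of class `band_fit` with element `components`: a
#'   tibble of `label`, `center`, `fwhm`, `shape`, `amp_par`, `amp_perp`,
#'   `area_par`, `area_perp`, plus `rss`, `flags` (components whose width
#'   collapsed to a bound are flagged), and the baseline-corrected data.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' pair <- simulate_polarized_pair(amide_i_scenario(), seed = 1)
#' fit <- fit_bands(pair, amide_i_bands(), region = c(1590, 1710))
#' tidy(fit)
#' @export
fit_bands <- function(pair, model, region, baseline = c("linear", "none")) {
  stopifnot(inherits(pair, "ir_pair"))
  baseline <- arg_match(baseline)
  if (length(region) != 2L) abort("`region` must be a length-2 window (cm^-1).")
  region <- sort(region)
  sel <- pair$wavenumber >= region[1] & pair$wavenumber <= region[2]
  if (sum(sel) < 5L) abort("The requested region contains too few grid points.")
  x <- pair$wavenumber[sel]
  ypar <- pair$par[sel]
  yperp <- pair$perp[sel]
  if (baseline == "linear") {
    bl <- function(y) {
      b <- y[which.min(x)] + (y[which.max(x)] - y[which.min(x)]) *
        (x - min(x)) / (max(x) - min(x))
      y - b
    }
    ypar <- bl(ypar)
    yperp <- bl(yperp)
  }

  k <- nrow(model)
  centers0 <- (model$center_min + model$center_max) / 2
  fwhm0 <- pmin(pmax(16, model$fwhm_min), model$fwhm_max)
  # amplitudes are conditionally linear given centers and widths: seed them
  # with a non-negative linear least-squares solve at the starting shapes
  basis <- vapply(seq_len(k), function(i) {
    pseudo_voigt(x, centers0[i], fwhm0[i], model$shape[i])
  }, numeric(length(x)))
  amp0 <- function(y) {
    a <- tryCatch(qr.solve(basis, y), error = function(e) rep(NA_real_, k))
    a[!is.finite(a) | a <= 0] <- max(y, 1e-6) / 10
    a
  }
  p0 <- c(centers0, fwhm0, amp0(ypar), amp0(yperp))
  lower <- c(model$center_min, model$fwhm_min, rep(0, 2 * k))
  upper <- c(model$center_max, model$fwhm_max, rep(Inf, 2 * k))

  resid_fn <- function(p) {
    cen <- p[seq_len(k)]
    wid <- p[k + seq_len(k)]
    apar <- p[2 * k + seq_len(k)]
    aperp <- p[3 * k + seq_len(k)]
    mp <- rowSums(vapply(seq_len(k), function(i) {
      apar[i] * pseudo_voigt(x, cen[i], wid[i], model$shape[i])
    }, numeric(length(x))))
    ms <- rowSums(vapply(seq_len(k), function(i) {
      aperp[i] * pseudo_voigt(x, cen[i], wid[i], model$shape[i])
    }, numeric(length(x))))
    c(ypar - mp, yperp - ms)
  }

  fit <- minpack.lm::nls.lm(
    par = p0, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 400)
  )
  if (fit$info %in% c(0, 9)) {
    abort(sprintf(
      "Band fit did not converge (info = %d) from starting centers %s.",
      fit$info, paste(signif(centers0, 5), collapse = ", ")
    ))
  }
  p <- fit$par
  cen <- p[seq_len(k)]
  wid <- p[k + seq_len(k)]
  apar <- p[2 * k + seq_len(k)]
  aperp <- p[3 * k + seq_len(k)]
  unit_area <- pseudo_voigt_area(wid, model$shape)
  comps <- tibble(
    label = model$label, center = cen, fwhm = wid, shape = model$shape,
    amp_par = apar, amp_perp = aperp,
    area_par = apar * unit_area, area_perp = aperp * unit_area
  )
  flags <- model$label[wid <= model$fwhm_min + 1e-6 | wid >= model$fwhm_max - 1e-6]
  out <- list(
    components = comps,
    rss = sum(fit$fvec^2),
    flags = if (length(flags)) paste0("width_at_bound:", flags) else character(),
    data = tibble(wavenumber = x, par = ypar, perp = yperp),
    model = model, region = region
  )
  class(out) <- "band_fit"
  out
}

#' @export
print.band_fit <- function(x, ...) {
  cat(sprintf("Band decomposition over %g-%g cm^-1 (rss %.3g)\n",
              x$region[1], x$region[2], x$rss))
  print(x$components)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Secondary-structure fractions from fitted amide I components
#'
#' The relative areas of the conformational amide I components give the
#' fractions of secondary structure. Side-chain components (label
#' `"side"`) absorb in the same region but are not backbone conformation,
#' so they are excluded from the denominator. Because band areas differ
#' between polarizations for oriented samples, a polarization combination
#' must be chosen: the default `"iso"` uses `area_par + 2 * area_perp`,
#' the pseudo-isotropic combination that removes the orientational
#' weighting for uniaxial samples; `"par"` and `"perp"` use one
#' polarization only.
#'
#' @param components A `band_fit` (from [fit_bands()]) or its `components`
#'   tibble.
#' @param combine `"iso"` (default), `"par"`, or `"perp"`.
#' @param exclude Labels excluded from the conformational total (default
#'   `"side"`).
#' @return A tibble of `label`, `area`, `fraction` (fractions sum to 1),
#'   with the combination recorded in attribute `combine`.
#' @examples
#' fit <- fit_bands(simulate_polarized_pair(amide_i_scenario(), seed = 1),
#'                  amide_i_bands(), region = c(1590, 1710))
#' structure_fractions(fit)
#' @export
structure_fractions <- function(components, combine = c("iso", "par", "perp"),
                                exclude = "side") {
  combine <- arg_match(combine)
  if (inherits(components, "band_fit")) components <- components$components
  if (!all(c("label", "area_par", "area_perp") %in% names(components))) {
    abort("`components` must carry `label`, `area_par`, `area_perp`.")
  }
  conf <- components[!(components$label %in% exclude), ]
  area <- switch(combine,
    iso = conf$area_par + 2 * conf$area_perp,
    par = conf$area_par,
    perp = conf$area_perp
  )
  total <- sum(area)
  if (total <= 0) abort("Total conformational band area is zero.")
  out <- tibble(label = conf$label, area = area, fraction = area / total)
  attr(out, "combine") <- combine
  out
}

#' Dichroic ratio of a band
#'
#' `R = a_par / a_perp`, the ratio of a band's integrated area at parallel
#' and perpendicular polarization. R encodes the orientation of the band's
#' transition dipole relative to the membrane normal.
#'
#' @param area_par,area_perp Band areas at the two polarizations
#'   (vectorized).
#' @return The dichroic ratio.
#' @examples
#' dichroic_ratio(0.89, 1)
#' @export
dichroic_ratio <- function(area_par, area_perp) {
  if (any(area_perp <= 0)) {
    abort("`area_perp` must be positive to form a dichroic ratio.")
  }
  area_par / area_perp
}
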