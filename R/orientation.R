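#' ATR experiment geometry
#'
#' Electric-field amplitudes and angle conventions for converting dichroic
#' ratios into orientational order parameters. The defaults are the
#' thick-film field amplitudes for a germanium internal-reflection element
#' at 45 degrees incidence (`E_x = 1.398`, `E_y = 1.516`, `E_z = 0.629`),
#' the standard convention for this instrument geometry; all values are
#' configurable for other elements or film regimes.
#'
#' @param e_x,e_y,e_z Relative electric-field amplitudes at the interface
#'   (x: in the incidence plane, parallel to the surface; y: perpendicular
#'   to the incidence plane; z: along the surface normal).
#' @param alpha Angle (degrees) between the transition dipole and the
#'   molecular axis whose order parameter is sought (90 for the lipid CH2
#'   stretches relative to the acyl chain).
#' @param gamma Tilt (degrees) of the barrel axis from the membrane
#'   normal, used by [strand_tilt()].
#' @return A list of class `atr_geometry`.
#' @export
atr_geometry <- function(e_x = 1.398, e_y = 1.516, e_z = 0.629,
                         alpha = 90, gamma = 0) {
  if (any(c(e_x, e_y, e_z) <= 0)) abort("Field amplitudes must be positive.")
  if (alpha < 0 || alpha > 90) abort("`alpha` must lie in [0, 90] degrees.")
  structure(list(e_x = e_x, e_y = e_y, e_z = e_z,
                 alpha = alpha, gamma = gamma),
            class = "atr_geometry")
}

# second-Legendre order parameter of an angle in degrees
legendre_s <- function(deg) (3 * cos(deg * pi / 180)^2 - 1) / 2

# dipole-level order parameter (relative to the membrane normal) from the
# thick-film ATR dichroic ratio:
#   R = [E_x^2 (1 - C)/2 + E_z^2 C] / [E_y^2 (1 - C)/2],  C = (2 S_d + 1)/3
dipole_order_from_r <- function(r, geometry) {
  a <- geometry$e_x^2
  b <- geometry$e_y^2
  z <- geometry$e_z^2
  cc <- (r * b - a) / (r * b - a + 2 * z)
  (3 * cc - 1) / 2
}

dipole_r_from_order <- function(s_d, geometry) {
  a <- geometry$e_x^2
  b <- geometry$e_y^2
  z <- geometry$e_z^2
  cc <- (2 * s_d + 1) / 3
  (a * (1 - cc) / 2 + z * cc) / (b * (1 - cc) / 2)
}

#' Orientational order parameter from a dichroic ratio
#'
#' Inverts the thick-film ATR dichroic-ratio relation to obtain the
#' uniaxial order parameter of the molecular axis. The measured ratio
#' first yields the order parameter of the transition dipole itself
#' (relative to the membrane normal); dividing by the second Legendre
#' factor of the dipole-to-axis angle `alpha`,
#' `(3 cos^2 alpha - 1)/2`, gives the molecular-axis order parameter
#' `S = (3 <cos^2 theta> - 1)/2`, bounded by -0.5 (axis in the membrane
#' plane) and 1 (axis along the normal).
#'
#' Values that fall outside `[-0.5, 1]` (possible when R is outside the
#' physically attainable range for the given fields) are flagged, not
#' silently clipped.
#'
#' @param r Dichroic ratio(s).
#' @param geometry An [atr_geometry()]; `alpha` must differ from the magic
#'   angle (54.7 degrees), at which the molecular axis is undetermined.
#' @return A tibble with columns `r`, `s_dipole`, `s`, `in_range`.
#' @examples
#' order_parameter_from_r(1.022)  # isotropic: S ~ 0
#' @export
order_parameter_from_r <- function(r, geometry = atr_geometry()) {
  stopifnot(inherits(geometry, "atr_geometry"))
  if (any(r <= 0)) abort("Dichroic ratios must be positive.")
  fac <- legendre_s(geometry$alpha)
  if (abs(fac) < 1e-6) {
    abort(paste(
      "`alpha` is at the magic angle (54.7 deg):",
      "the molecular-axis order parameter is undetermined there."
    ))
  }
  s_d <- dipole_order_from_r(r, geometry)
  s <- s_d / fac
  tibble(r = r, s_dipole = s_d, s = s,
         in_range = s >= -0.5 - 1e-9 & s <= 1 + 1e-9)
}

#' @rdname order_parameter_from_r
#' @param s Molecular-axis order parameter(s) in `[-0.5, 1]`.
#' @return `r_from_order_parameter()` returns the dichroic ratio that the
#'   given order parameter would produce (the exact inverse of
#'   [order_parameter_from_r()]).
#' @export
r_from_order_parameter <- function(s, geometry = atr_geometry()) {
  stopifnot(inherits(geometry, "atr_geometry"))
  fac <- legendre_s(geometry$alpha)
  if (abs(fac) < 1e-6) abort("`alpha` is at the magic angle (54.7 deg).")
  dipole_r_from_order(s * fac, geometry)
}

#' Lipid acyl-chain order from the CH2 stretching region
#'
#' Fits the methylene stretching region (~2990-2830 cm^-1) of a polarized
#' spectrum pair with the antisymmetric (2921-2923) and symmetric
#' (2851-2853 cm^-1) CH2 components, forms the lipid dichroic ratio
#' `R_L = a_L_par / a_L_perp` from the total CH2 areas, and converts it to
#' the acyl-chain order parameter `S_L` using `alpha = 90` degrees (the
#' CH2 stretching dipoles are perpendicular to the chain axis). The
#' antisymmetric peak wavenumber is reported as an independent fluidity
#' marker (it rises ~4-5 cm^-1 on melting).
#'
#' @param pair An [ir_pair()] covering the CH2 region.
#' @param geometry An [atr_geometry()]; its `alpha` is overridden to 90.
#' @param region Fit window (default `c(2830, 2990)`).
#' @param model Band model (default [ch2_bands()]).
#' @return A one-row tibble: `r_l`, `s_l`, `in_range`,
#'   `antisym_peak` (cm^-1), plus the `band_fit` in attribute `fit`.
#' @export
lipid_order <- function(pair, geometry = atr_geometry(),
                        region = c(2830, 2990), model = ch2_bands()) {
  stopifnot(inherits(pair, "ir_pair"))
  rng <- range(pair$wavenumber)
  if (rng[1] > region[1] || rng[2] < region[2]) {
    abort(sprintf(
      "The CH2 stretching region (%g-%g cm^-1) is not covered by this pair.",
      region[1], region[2]
    ))
  }
  fit <- fit_bands(pair, model, region = region)
  comps <- fit$components
  r_l <- dichroic_ratio(sum(comps$area_par), sum(comps$area_perp))
  geometry$alpha <- 90
  op <- order_parameter_from_r(r_l, geometry)
  anti <- comps$center[grepl("antisym", comps$label)][1]
  out <- tibble(r_l = r_l, s_l = op$s, in_range = op$in_range,
                antisym_peak = anti)
  attr(out, "fit") <- fit
  out
}

#' Beta-strand tilt within a (possibly tilted) barrel
#'
#' Converts a measured beta-sheet amide I dichroic ratio into the tilt
#' angle `beta` of the strands from the barrel axis, for a grid of barrel
#' tilts `gamma` from the membrane normal. The model is the nested
#' uniaxial-order factorization: the order parameter of the amide I
#' transition dipole relative to the membrane normal is the product
#' `S_dipole = S(gamma) * S(beta) * S(theta_d)`, with
#' `S(x) = (3 cos^2 x - 1)/2` and `theta_d` the dipole angle from the
#' strand axis (default 90 degrees for amide I in beta-sheets).
#' `S_dipole` comes from the thick-film field relation (see
#' [order_parameter_from_r()]). For a given `gamma` the strand factor
#' `S(beta)` must land in `[-0.5, 1]`; otherwise no real tilt solves the
#' relation and the row is flagged unsolvable.
#'
#' This factorization is the package's stand-in for the full
#' barrel-orientation formalism and is isolated here so an alternative
#' relation can be swapped in; see the methods vignette for its known
#' limitations.
#'
#' @param r_beta Measured beta-sheet dichroic ratio.
#' @param geometry An [atr_geometry()] (field amplitudes).
#' @param gamma Grid of barrel tilts in degrees (default `0:20`).
#' @param theta_d Amide I dipole angle from the strand axis, degrees
#'   (default 90).
#' @return A tibble with columns `gamma`, `s_dipole`, `s_strand`
#'   (required strand order factor), `beta` (degrees, `NA` when
#'   unsolvable) and `solvable`.
#' @examples
#' strand_tilt(0.89)  # beta ~ 27 deg at gamma = 0
#' @export
strand_tilt <- function(r_beta, geometry = atr_geometry(), gamma = 0:20,
                        theta_d = 90) {
  if (!is.numeric(r_beta) || length(r_beta) != 1L || r_beta <= 0) {
    abort("`r_beta` must be a single positive dichroic ratio.")
  }
  if (length(gamma) == 0L) abort("`gamma` grid is empty.")
  s_th <- legendre_s(theta_d)
  if (abs(s_th) < 1e-6) {
    abort("`theta_d` is at the magic angle; the strand tilt is undetermined.")
  }
  s_d <- dipole_order_from_r(r_beta, geometry)
  s_g <- legendre_s(gamma)
  s_strand <- s_d / (s_g * s_th)
  cos2 <- (2 * s_strand + 1) / 3
  solvable <- is.finite(cos2) & cos2 >= 0 & cos2 <= 1
  beta <- ifelse(solvable, acos(sqrt(pmin(pmax(cos2, 0), 1))) * 180 / pi,
                 NA_real_)
  tibble(gamma = gamma, s_dipole = s_d, s_strand = s_strand,
         beta = beta, solvable = solvable)
}
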