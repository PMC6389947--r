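#' Beta-barrel radius
#'
#' Inner (backbone) radius of an ideal beta-barrel of `z` strands tilted
#' by `beta` degrees from the barrel axis:
#' `R = d / (2 sin(pi/z) cos(beta))`, where `d` is the interstrand
#' (H-bonding) distance. For standard beta-barrels `d = 4.72` Angstrom.
#'
#' @param z Number of strands (>= 3), vectorized.
#' @param beta Strand tilt from the barrel axis in degrees, `[0, 90)`.
#' @param d Interstrand distance in Angstrom (default 4.72).
#' @return Radius in Angstrom.
#' @examples
#' barrel_radius(z = 6, beta = 22)  # 5.09
#' barrel_radius(z = 8, beta = 22)  # 6.65
#' @export
barrel_radius <- function(z, beta, d = 4.72) {
  check_barrel_args(z, beta, d = d)
  d / (2 * sin(pi / z) * cos(beta * pi / 180))
}

#' Beta-barrel height
#'
#' `h_b = m a cos(beta)`: the strand length projected on the barrel axis,
#' with `m` residues per strand and rise `a` per residue along the strand.
#'
#' @param m Residues per strand (default 11, the Abeta(25-35) strand).
#' @param beta Strand tilt from the barrel axis, degrees.
#' @param a Rise per residue along the strand in Angstrom (default 3.48).
#' @return Height in Angstrom.
#' @examples
#' barrel_height(m = 11, beta = 22)  # 35.5
#' @export
barrel_height <- function(m = 11, beta, a = 3.48) {
  check_barrel_args(3, beta, a = a)
  if (any(m < 0)) abort("`m` must be non-negative.")
  m * a * cos(beta * pi / 180)
}

#' Beta-barrel internal volume
#'
#' `V = pi R^2 h_b` with the radius from [barrel_radius()] and the height
#' from [barrel_height()] — the barrel treated as an ideal cylinder of
#' backbone radius R.
#'
#' @inheritParams barrel_radius
#' @inheritParams barrel_height
#' @return Volume in cubic Angstrom.
#' @examples
#' barrel_volume(z = 6, beta = 22)  # 2890
#' barrel_volume(z = 8, beta = 22)  # 4930
#' @export
barrel_volume <- function(z, beta, m = 11, d = 4.72, a = 3.48) {
  pi * barrel_radius(z, beta, d)^2 * barrel_height(m, beta, a)
}

#' Full barrel geometry table
#'
#' @inheritParams barrel_volume
#' @return A tibble with one row per `(z, beta)` combination and columns
#'   `z`, `beta`, `radius`, `height`, `volume`.
#' @export
barrel_geometry <- function(z, beta, m = 11, d = 4.72, a = 3.48) {
  g <- tidyr::expand_grid(z = z, beta = beta)
  mutate(g,
    radius = barrel_radius(.data$z, .data$beta, d),
    height = barrel_height(m, .data$beta, a),
    volume = pi * .data$radius^2 * .data$height
  )
}

check_barrel_args <- function(z, beta, d = 4.72, a = 3.48) {
  if (any(z < 3)) abort("A barrel needs at least 3 strands (`z` >= 3).")
  if (any(beta < 0 | beta >= 90)) {
    abort("`beta` must lie in [0, 90) degrees (cos(beta) > 0).")
  }
  if (any(c(d, a) <= 0)) abort("`d` and `a` must be positive lengths.")
  invisible(TRUE)
}

#' Van der Waals side-chain volumes
#'
#' Side-chain van der Waals volumes (cubic Angstrom) for the residues of
#' the Abeta(25-35) sequence: Gly 48, Ala 67, Ser 73, Asn 96,
#' Ile/Leu/Met 124, Lys 135.
#'
#' @return A named numeric vector keyed by one-letter residue code.
#' @export
aa_vdw_volumes <- function() {
  c(G = 48, A = 67, S = 73, N = 96, I = 124, L = 124, M = 124, K = 135)
}

#' Alternating side-chain topology of a beta-strand
#'
#' In a beta-strand the side chains of consecutive residues point
#' alternately to the two faces; in a barrel that means alternately into
#' and out of the lumen. For an 11-mer there are two phases: for
#' Abeta(25-35) (GSNKGAIIGLM, residues 25-35) phase 1 puts Ser26, Lys28,
#' Ala30, Ile32, Leu34 inside ("topology-1") and phase 0 the complement
#' Gly25, Asn27, Gly29, Ile31, Gly33, Met35 ("topology-2").
#'
#' @param sequence Peptide sequence in one-letter code (default
#'   `"GSNKGAIIGLM"`).
#' @param phase 0 or 1: residues at positions with `position %% 2 ==
#'   phase` (1-based) face inward. Phase 1 selects the even... see
#'   Details.
#' @param start_residue Residue number of the first position (default 25).
#' @details With 1-based positions `i`, phase 1 marks even `i` inward
#'   (topology-1 for GSNKGAIIGLM) and phase 0 marks odd `i` inward
#'   (topology-2).
#' @return A tibble of class `topology` with columns `position`,
#'   `residue_number`, `residue`, `inward`, and attribute `label`
#'   (`"topology-1"` or `"topology-2"`).
#' @examples
#' assign_topology(phase = 1)  # S, K, A, I32, L inward
#' @export
assign_topology <- function(sequence = "GSNKGAIIGLM", phase,
                            start_residue = 25) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0) {
    abort("`sequence` must be a non-empty one-letter-code string.")
  }
  if (!phase %in% c(0, 1)) abort("`phase` must be 0 or 1.")
  res <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(res, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  if (length(bad)) {
    abort(sprintf("Invalid residue letter(s): %s.", paste(unique(bad), collapse = ", ")))
  }
  pos <- seq_along(res)
  inward <- (pos %% 2) == (if (phase == 1) 0 else 1)
  out <- tibble(
    position = pos,
    residue_number = pos + start_residue - 1,
    residue = res,
    inward = inward
  )
  class(out) <- c("topology", class(out))
  attr(out, "label") <- if (phase == 1) "topology-1" else "topology-2"
  out
}

#' Volume required by the inward-facing side chains
#'
#' Total van der Waals volume needed to accommodate the inward-oriented
#' side chains of all `z` strands of a barrel:
#' `z * sum(volumes[inward residues])`.
#'
#' @param topology A [assign_topology()] result.
#' @param z Number of strands.
#' @param volumes Named volume table (default [aa_vdw_volumes()]).
#' @return Required volume in cubic Angstrom.
#' @examples
#' inward_volume(assign_topology(phase = 1), z = 6)  # 3138
#' inward_volume(assign_topology(phase = 0), z = 6)  # 2928
#' @export
inward_volume <- function(topology, z, volumes = aa_vdw_volumes()) {
  stopifnot(inherits(topology, "topology"))
  res <- topology$residue[topology$inward]
  unknown <- setdiff(res, names(volumes))
  if (length(unknown)) {
    abort(sprintf(
      "No van der Waals volume for residue(s): %s.",
      paste(unique(unknown), collapse = ", ")
    ))
  }
  z * sum(volumes[res])
}

#' Side-chain packing feasibility
#'
#' A barrel interior of volume `V` can accommodate inward side chains
#' requiring volume `required` iff `V >= required`; the signed difference
#' is the free (or missing, if negative) volume.
#'
#' @param v Barrel internal volume (cubic Angstrom), vectorized.
#' @param required Total inward side-chain volume (cubic Angstrom).
#' @return A tibble with `v`, `required`, `feasible`, `free_volume`.
#' @examples
#' packing_feasibility(2890, 2928)  # infeasible by 38 A^3
#' @export
packing_feasibility <- function(v, required) {
  tibble(v = v, required = required,
         feasible = v >= required, free_volume = v - required)
}

#' Equivalent-cylinder channel radius of a free volume
#'
#' If the free volume left after side-chain packing were collected into an
#' ideal coaxial cylinder spanning the barrel height, its radius would be
#' `r = sqrt(free_volume / (pi h_b))`.
#'
#' @param free_volume Free volume in cubic Angstrom (>= 0).
#' @param h_b Barrel height in Angstrom (> 0).
#' @return Radius in Angstrom.
#' @examples
#' equivalent_channel_radius(750, 35.5)   # ~2.6
#' equivalent_channel_radius(1000, 35.5)  # ~3.0
#' @export
equivalent_channel_radius <- function(free_volume, h_b) {
  if (any(free_volume < 0)) {
    abort("`free_volume` is negative: no channel exists (infeasible packing).")
  }
  if (any(h_b <= 0)) abort("`h_b` must be positive.")
  sqrt(free_volume / (pi * h_b))
}

#' Central pore radius of a ring of barrels
#'
#' Models the supramolecular pore as `n_barrels` identical barrels whose
#' outer surfaces (backbone radius plus a side-chain lining, ~2 Angstrom)
#' touch in a closed ring. The barrel centers then sit on a circle of
#' radius `rho = R_out / sin(pi/n)`, and the inscribed central hole has
#' radius `rho - R_out`. Because the side chains facing the central
#' cavity do not form a continuous layer, an effective pore radius is
#' also reported with a configurable central lining (default half the
#' interbarrel lining) subtracted; both conventions are returned.
#'
#' @param n_barrels Number of barrels in the ring (>= 3), vectorized.
#' @param inner_r Barrel inner (backbone) radius, Angstrom.
#' @param lining Side-chain layer thickness added to the backbone radius
#'   (default 2 Angstrom).
#' @param pore_lining Thickness subtracted from the raw hole for the
#'   side chains lining the central cavity (default `lining / 2`).
#' @return A tibble with `n_barrels`, `r_out`, `rho` (center-circle
#'   radius), `radius_raw`, `radius_lined`.
#' @examples
#' ring_pore_radius(6, inner_r = 5.09)  # raw 7.09, lined ~6.1
#' @export
ring_pore_radius <- function(n_barrels, inner_r, lining = 2,
                             pore_lining = lining / 2) {
  if (any(n_barrels < 3)) abort("A ring needs at least 3 barrels.")
  if (any(inner_r <= 0) || any(lining < 0)) {
    abort("`inner_r` must be positive and `lining` non-negative.")
  }
  r_out <- inner_r + lining
  rho <- r_out / sin(pi / n_barrels)
  raw <- rho - r_out
  tibble(
    n_barrels = n_barrels, r_out = r_out, rho = rho,
    radius_raw = raw,
    radius_lined = pmax(raw - pore_lining, 0)
  )
}

#' Barrel pore report
#'
#' One-stop summary for a candidate pore: barrel geometry, the inward
#' side-chain volumes of both topologies, packing feasibility, the
#' equivalent free-volume channel radius (topology with the smaller
#' requirement, when feasible), and the ring-of-barrels pore table.
#'
#' @inheritParams barrel_volume
#' @param sequence Peptide sequence (default `"GSNKGAIIGLM"`).
#' @param n_ring Ring sizes for the supramolecular pore table (default
#'   `3:8`).
#' @param lining Side-chain lining thickness for the ring model.
#' @return A list with tibbles `geometry`, `packing`, and `ring`.
#' @export
pore_report <- function(z = c(6, 8), beta = 22, m = 11, d = 4.72, a = 3.48,
                        sequence = "GSNKGAIIGLM", n_ring = 3:8, lining = 2) {
  geom <- barrel_geometry(z, beta, m = m, d = d, a = a)
  topo <- list(`topology-1` = assign_topology(sequence, phase = 1),
               `topology-2` = assign_topology(sequence, phase = 0))
  packing <- purrr::map_dfr(names(topo), function(lab) {
    req <- purrr::map_dbl(geom$z, ~ inward_volume(topo[[lab]], .x))
    pf <- packing_feasibility(geom$volume, req)
    tibble(
      z = geom$z, beta = geom$beta, topology = lab,
      volume = geom$volume, required = req,
      feasible = pf$feasible, free_volume = pf$free_volume,
      channel_radius = ifelse(
        pf$feasible,
        sqrt(pmax(pf$free_volume, 0) / (pi * geom$height)),
        NA_real_
      )
    )
  })
  ring <- purrr::map_dfr(seq_len(nrow(geom)), function(i) {
    mutate(ring_pore_radius(n_ring, geom$radius[i], lining = lining),
           z = geom$z[i], beta = geom$beta[i], .before = 1)
  })
  list(geometry = geom, packing = packing, ring = ring)
}
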