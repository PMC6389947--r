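# default thick-film fields: E = (1.398, 1.516, 0.629); isotropic R
# closed form: R_iso = (E_x^2 + E_z^2) / E_y^2
r_iso <- (1.398^2 + 0.629^2) / 1.516^2

test_that("a single Gaussian band is refit to its exact area", {
  comp <- tibble::tibble(label = "sheet", center = 1628, fwhm = 20,
                         area = 1.0, r = 1.0)
  pair <- simulate_polarized_pair(comp, grid = seq(1550, 1750, 1))
  model <- amide_i_bands()[amide_i_bands()$label == "sheet", ]
  fit <- fit_bands(pair, model, region = c(1550, 1750))
  expect_equal(fit$components$area_par, 1.0, tolerance = 1e-6)
  expect_equal(fit$components$area_perp, 1.0, tolerance = 1e-6)
  expect_equal(fit$components$center, 1628, tolerance = 1e-4)
})

test_that("an empty fit region is rejected", {
  pair <- simulate_polarized_pair(amide_i_scenario())
  expect_error(fit_bands(pair, amide_i_bands(), region = c(1400, 1450)),
               "too few grid points")
})

test_that("noise-free five-component spectra refit to areas within 1%", {
  pair <- simulate_polarized_pair(amide_i_scenario())
  fit <- fit_bands(pair, amide_i_bands(), region = c(1550, 1750))
  gt <- attr(pair, "ground_truth")$components
  expect_true(all(abs(fit$components$area_par / gt$a_par - 1) < 0.01))
  expect_true(all(abs(fit$components$area_perp / gt$a_perp - 1) < 0.01))
})

test_that("five-component areas are recovered on average at 0.5% peak noise", {
  err_par <- err_perp <- matrix(NA_real_, 10, 5)
  for (s in 1:10) {
    pair <- simulate_polarized_pair(amide_i_scenario(), noise_frac = 0.005,
                                    seed = s)
    fit <- fit_bands(pair, amide_i_bands(), region = c(1550, 1750))
    gt <- attr(pair, "ground_truth")$components
    err_par[s, ] <- fit$components$area_par / gt$a_par - 1
    err_perp[s, ] <- fit$components$area_perp / gt$a_perp - 1
  }
  expect_true(all(abs(colMeans(err_par)) < 0.05))
  expect_true(all(abs(colMeans(err_perp)) < 0.05))
})

test_that("structure fractions follow relative conformational areas", {
  comps <- tibble::tibble(
    label = c("sheet", "turn", "helix", "irregular", "side"),
    area_par = c(4, 2, 2, 2, 9),
    area_perp = c(4, 2, 2, 2, 9)
  )
  fr <- structure_fractions(comps)
  expect_equal(fr$fraction[fr$label == "sheet"], 0.4)
  expect_equal(sum(fr$fraction), 1, tolerance = 1e-12)

  eq <- dplyr::mutate(comps, area_par = c(1, 1, 1, 1, 5),
                      area_perp = c(1, 1, 1, 1, 5))
  expect_equal(structure_fractions(eq)$fraction, rep(0.25, 4))

  single <- dplyr::mutate(comps, area_par = c(2, 0, 0, 0, 1),
                          area_perp = c(2, 0, 0, 0, 1))
  expect_equal(structure_fractions(single)$fraction,
               c(1, 0, 0, 0))

  # permutation invariance
  perm <- comps[c(3, 1, 5, 2, 4), ]
  fr2 <- structure_fractions(perm)
  expect_equal(fr2$fraction[fr2$label == "sheet"],
               fr$fraction[fr$label == "sheet"])

  zero <- dplyr::mutate(comps, area_par = c(0, 0, 0, 0, 1),
                        area_perp = c(0, 0, 0, 0, 1))
  expect_error(structure_fractions(zero), "zero")
})

test_that("dichroic ratio is the plain area ratio", {
  expect_equal(dichroic_ratio(1, 1), 1)
  expect_equal(dichroic_ratio(0.89, 1), 0.89)
  expect_equal(dichroic_ratio(2, 4), 0.5)
  expect_error(dichroic_ratio(1, 0), "positive")
})

test_that("isotropy gives the closed-form dichroic ratio for default fields", {
  expect_equal(r_from_order_parameter(0), r_iso, tolerance = 1e-12)
  expect_equal(r_iso, 1.022, tolerance = 1e-3)
  op <- order_parameter_from_r(r_iso)
  expect_equal(op$s, 0, tolerance = 1e-12)
  expect_equal(op$s_dipole, 0, tolerance = 1e-12)
})

test_that("order parameter <-> dichroic ratio is an exact inverse pair", {
  for (alpha in c(0, 30, 90)) {
    geom <- atr_geometry(alpha = alpha)
    for (s in c(-0.4, -0.1, 0, 0.3, 0.7, 1)) {
      s_ok <- if (alpha == 90) s else s # molecular S; dipole S must stay in range
      r <- r_from_order_parameter(s_ok, geom)
      if (r <= 0 || !is.finite(r)) next
      expect_equal(order_parameter_from_r(r, geom)$s, s_ok, tolerance = 1e-9)
    }
  }
})

test_that("the magic angle is rejected", {
  geom <- atr_geometry(alpha = 54.7356)
  expect_error(order_parameter_from_r(1.0, geom), "magic angle")
  expect_error(r_from_order_parameter(0.5, geom), "magic angle")
})

test_that("S is monotone in R with direction set by the alpha factor", {
  r <- seq(0.6, 2, length.out = 30)
  s90 <- order_parameter_from_r(r, atr_geometry(alpha = 90))$s
  s0 <- order_parameter_from_r(r, atr_geometry(alpha = 0))$s
  expect_true(all(diff(s90) < 0)) # 3cos^2(90) - 1 < 0: decreasing
  expect_true(all(diff(s0) > 0))  # 3cos^2(0) - 1 > 0: increasing
})

test_that("out-of-range order parameters are flagged, not clipped", {
  op <- order_parameter_from_r(5, atr_geometry(alpha = 90))
  expect_false(op$in_range)
  expect_lt(op$s, -0.5)
})

test_that("lipid order round-trips through a synthetic CH2 pair", {
  for (s_l in c(0.5, 0.6, 0.7)) {
    pair <- simulate_polarized_pair(ch2_scenario(s_l),
                                    grid = seq(2750, 3050, 1))
    res <- lipid_order(pair)
    expect_equal(res$s_l, s_l, tolerance = 0.01)
    expect_true(res$in_range)
    expect_equal(res$antisym_peak, 2922, tolerance = 0.5)
  }
})

test_that("lipid isotropy maps to S_L = 0", {
  geom <- atr_geometry(alpha = 90)
  pair <- simulate_polarized_pair(ch2_scenario(0), grid = seq(2750, 3050, 1))
  expect_equal(lipid_order(pair, geom)$s_l, 0, tolerance = 1e-6)
})

test_that("a pair missing the CH2 region is rejected", {
  pair <- simulate_polarized_pair(amide_i_scenario())
  expect_error(lipid_order(pair), "not covered")
})

test_that("an isotropic sheet band tilts the strands to the magic angle", {
  tilt <- strand_tilt(r_iso, gamma = 0)
  expect_equal(tilt$beta, 54.7356, tolerance = 1e-3)
})

test_that("paper-scale dichroic ratios give upright strand tilts of 20-27 deg", {
  # R over the fixture range maps to beta in the 20-27 degree band at gamma = 0
  for (r in seq(0.872, 0.890, length.out = 7)) {
    b <- strand_tilt(r, gamma = 0)$beta
    expect_gte(b, 20)
    expect_lte(b, 27.1)
  }
})

test_that("strand tilt is monotone in barrel tilt over the solvable range", {
  tilt <- strand_tilt(0.89, gamma = seq(0, 20, 0.5))
  expect_true(all(tilt$solvable))
  expect_true(all(diff(tilt$beta) < 0))
})

test_that("solvability boundary matches the closed-form barrel-tilt limit", {
  # for R = 0.89 the nested factorization stops admitting a real strand
  # tilt when S(gamma) < -2 S_dipole; the boundary is gamma ~ 27.06 deg
  s_d <- strand_tilt(0.89, gamma = 0)$s_dipole
  gamma_star <- acos(sqrt((2 * (-2 * s_d) + 1) / 3)) * 180 / pi
  expect_equal(gamma_star, 27.06, tolerance = 0.01)
  wide <- strand_tilt(0.89, gamma = seq(0, 40, 0.25))
  expect_true(all(wide$solvable[wide$gamma < gamma_star - 0.25]))
  expect_false(any(wide$solvable[wide$gamma > gamma_star + 0.25]))
})

test_that("degenerate strand-tilt inputs are rejected", {
  expect_error(strand_tilt(0.89, gamma = numeric(0)), "empty")
  expect_error(strand_tilt(-1), "positive")
  expect_error(strand_tilt(0.89, theta_d = 54.7356), "magic angle")
})
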