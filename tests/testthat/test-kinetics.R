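# second-order model used throughout: F(t) = F_eq * x / (1 + x), x = k_a [P_b] t

test_that("single-exponential fit recovers noise-free parameters exactly", {
  tr <- simulate_trace(model = "exponential", f_eq = 0.6, k_exp = 0.01)
  fit <- fit_single_exponential(tr)
  expect_equal(fit$f_eq, 0.6, tolerance = 1e-6)
  expect_equal(fit$k_exp, 0.01, tolerance = 1e-6)
  expect_equal(fit$f_rel, fit$f_eq)
  expect_length(fit$flags, 0)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error"))
})

test_that("single-exponential fit is unbiased at sigma = 0.01 over many seeds", {
  f_eq_hat <- vapply(1:500, function(s) {
    tr <- simulate_trace(model = "exponential", f_eq = 0.6, k_exp = 0.01,
                         noise = 0.01, seed = s)
    fit_single_exponential(tr)$f_eq
  }, numeric(1))
  expect_lt(abs(mean(f_eq_hat) / 0.6 - 1), 0.02)
})

test_that("a flat zero trace is flagged degenerate, not fitted", {
  tr <- fluor_trace(data.frame(time = 0:500, intensity = rep(0, 501)),
                    t_add = 100, f_max = 1)
  fit <- fit_single_exponential(tr)
  expect_true("degenerate" %in% fit$flags)
  expect_equal(fit$f_eq, 0, tolerance = 1e-9)
  expect_true(is.na(fit$k_exp))
})

test_that("the linearized transform has intercept 1/[P_b] at t = 0", {
  p_b <- 2e-6
  tr <- simulate_trace(model = "second_order", f_eq = 0.6, k_a = 1e5,
                       p_b = p_b)
  series <- linearize_second_order(tr, f_eq = 0.6, p_b = p_b, quiet = TRUE)
  expect_equal(series$y[series$t == 0], 1 / p_b, tolerance = 1e-12)
})

test_that("second-order traces linearize to an exact straight line", {
  k_a <- 1e5
  p_b <- 2e-6
  tr <- simulate_trace(model = "second_order", f_eq = 0.6, k_a = k_a,
                       p_b = p_b)
  series <- linearize_second_order(tr, f_eq = 0.6, p_b = p_b, quiet = TRUE)
  fit <- fit_ka(series, p_b = p_b)
  expect_equal(fit$k_a, k_a, tolerance = 1e-9)
  expect_equal(fit$intercept, 5e5, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$intercept_ratio, 1, tolerance = 1e-9)
})

test_that("linearizing exponential-model data reports convexity", {
  # analytically y = exp(k t) / [P_b] for exponential data: convex in t
  tr <- simulate_trace(model = "exponential", f_eq = 0.6, k_exp = 0.005)
  series <- linearize_second_order(tr, f_eq = 0.6, p_b = 2e-6, quiet = TRUE)
  expect_equal(series$y, exp(0.005 * series$t) / 2e-6, tolerance = 1e-9)
  fit <- fit_ka(series, p_b = 2e-6)
  expect_gt(fit$curvature, 0)
  expect_true("nonlinear" %in% fit$flags)
})

test_that("saturated points are dropped with a message and an attribute", {
  tr <- simulate_trace(model = "second_order", f_eq = 0.6, k_a = 2.5e5,
                       p_b = 5e-6)
  expect_message(
    series <- linearize_second_order(tr, f_eq = 0.6, p_b = 5e-6),
    "dropped"
  )
  expect_gt(length(attr(series, "dropped")), 0)
  # retained points obey the floor: y = F_eq/([P_b] gap) <= 1/([P_b] floor_frac)
  expect_true(all(series$y <= 1 / (5e-6 * 0.01) + 1e-6))
})

test_that("an equilibrium level below the trace is rejected", {
  tr <- simulate_trace(model = "second_order", f_eq = 0.6, k_a = 1e5,
                       p_b = 2e-6)
  expect_error(linearize_second_order(tr, f_eq = 1e-4, p_b = 2e-6),
               "equilibrium")
})

test_that("fit_ka flags flat and negative-slope series", {
  flat <- tibble::tibble(t = 0:9, y = rep(5e5, 10))
  fit <- fit_ka(flat, p_b = 2e-6)
  expect_equal(unname(fit$k_a), 0, tolerance = 1e-12)
  neg <- tibble::tibble(t = 0:9, y = seq(5e5, 4e5, length.out = 10))
  fit2 <- fit_ka(neg, p_b = 2e-6)
  expect_true(is.na(fit2$k_a))
  expect_true("negative_slope" %in% fit2$flags)
})

test_that("OLS slope is nearly unbiased for homoscedastic series noise", {
  # direct noise on the linearized ordinate (2% of range), 200 seeds
  k_a <- 1e5
  p_b <- 2e-6
  t <- 0:600
  y0 <- 1 / p_b + k_a * t
  slopes <- vapply(1:200, function(s) {
    set.seed(s)
    y <- y0 + rnorm(length(t), 0, 0.02 * diff(range(y0)))
    fit_ka(tibble::tibble(t = t, y = y), p_b = p_b)$k_a
  }, numeric(1))
  expect_lt(abs(mean(slopes) / k_a - 1), 0.03)
})

test_that("initial slope matches exact and limiting cases", {
  t <- 0:500
  tr <- fluor_trace(data.frame(time = t, intensity = 0.001 * t),
                    t_add = 100, f_max = 1)
  expect_equal(initial_slope(tr)$slope, 0.001, tolerance = 1e-12)

  flat <- fluor_trace(data.frame(time = t, intensity = rep(0.3, 501)),
                      t_add = 100, f_max = 1)
  expect_equal(initial_slope(flat)$slope, 0, tolerance = 1e-12)

  # far below saturation the initial slope approximates F_eq k_a [P_b]
  k_a <- 1e3
  p_b <- 1e-6 # k_a [P_b] = 1e-3 << 1/window
  tr2 <- simulate_trace(model = "second_order", f_eq = 0.6, k_a = k_a,
                        p_b = p_b)
  expect_equal(initial_slope(tr2)$slope, 0.6 * k_a * p_b, tolerance = 0.1)

  short <- fluor_trace(data.frame(time = seq(0, 500, by = 45),
                                  intensity = seq(0, 1, length.out = 12)),
                       t_add = 0, f_max = 1)
  expect_error(initial_slope(short, window = 45), "Fewer than 3")
})

test_that("affinity constant is the ratio k_a / k_exp", {
  expect_equal(affinity_constant(2.5e5, 0.025), 1e7)
  expect_equal(affinity_constant(0, 0.01), 0)
  expect_equal(affinity_constant(3.3e4, 0.011), 3e6)
  expect_error(affinity_constant(1e5, 0), "undefined")
  # homogeneity: common scaling of both rates cancels
  for (s in c(0.1, 3, 42)) {
    expect_equal(affinity_constant(s * 2.5e5, s * 0.025), 1e7)
  }
})

test_that("oligomer count follows the isodesmic closed form", {
  expect_equal(estimate_n(0, 1e-6), 1)
  expect_equal(estimate_n(6e6, 1e-6), 3)   # K_p [P_b] = 6 -> (1 + 5)/2
  expect_equal(estimate_n(5.6e7, 1e-6), 8) # K_p [P_b] = 56 -> (1 + 15)/2
  expect_error(estimate_n(1e6, 1e-6, model = "nope"), "isodesmic")
})

test_that("oligomer count is non-decreasing in K_p [P_b] and -> 1 at 0", {
  x <- 10^seq(-6, 3, length.out = 40)
  n <- estimate_n(x, 1)
  expect_true(all(diff(n) >= 0))
  expect_equal(estimate_n(1e-12, 1), 1, tolerance = 1e-6)
})

test_that("alternative association models can be registered", {
  register_n_model("dimer_only", function(k_p, p_b) 1 + k_p * p_b / (1 + k_p * p_b))
  expect_equal(estimate_n(1e6, 1e-6, model = "dimer_only"), 1.5)
})

test_that("linearize + fit recovers k_a across a parameter grid (noise-free)", {
  grid <- expand.grid(k_a = c(1e4, 1e5), p_b = c(5e-7, 5e-6), f_eq = c(0.3, 0.9))
  for (i in seq_len(nrow(grid))) {
    tr <- simulate_trace(model = "second_order", f_eq = grid$f_eq[i],
                         k_a = grid$k_a[i], p_b = grid$p_b[i])
    series <- linearize_second_order(tr, f_eq = grid$f_eq[i],
                                     p_b = grid$p_b[i], quiet = TRUE)
    fit <- fit_ka(series, p_b = grid$p_b[i])
    expect_equal(fit$k_a, grid$k_a[i], tolerance = 1e-6)
    expect_equal(fit$intercept * grid$p_b[i], 1, tolerance = 1e-6)
  }
})

test_that("the full kinetics pipeline chains to K_p and n", {
  tr <- simulate_trace(model = "second_order", f_eq = 0.6, k_a = 1e5,
                       p_b = 2e-6, noise = 0.01, seed = 11)
  res <- fit_pore_kinetics(tr, p_b = 2e-6, f_eq = 0.6)
  expect_equal(res$k_a, 1e5, tolerance = 0.1)
  expect_equal(res$k_p, res$k_a / res$k_exp, tolerance = 1e-9)
  expect_equal(res$n, estimate_n(res$k_p, 2e-6), tolerance = 1e-9)
  gl <- glance(res)
  expect_equal(gl$k_a, res$k_a)
  expect_named(tidy(res), c("term", "estimate", "unit"))
})
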