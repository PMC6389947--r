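#' Single-exponential fit of a dye-influx trace
#'
#' Fits the post-addition segment of a normalized trace with
#' `F(t) = F_eq * (1 - exp(-k_exp * (t - t_add)))`, the empirical model for
#' peptide-induced Quin-2 fluorescence rise. On the normalized scale the
#' fitted plateau `F_eq` equals the relative equilibrium fluorescence
#' `F_rel`, and `k_exp` is the experimentally observed first-order rate
#' constant of membrane permeabilization.
#'
#' A trace whose post-addition signal is indistinguishable from zero is
#' returned with `F_eq ~ 0` and flagged degenerate rather than fitted.
#'
#' @param trace A normalized [fluor_trace()] (see [normalize_trace()]).
#' @param start Optional named list of starting values `f_eq`, `k_exp`;
#'   by default they are derived from the data (late-time mean and the
#'   half-rise time).
#' @return An object of class `exp_fit`: a list with elements
#'   `estimate` (tibble of `term`, `estimate`, `std.error`), `f_eq`,
#'   `k_exp`, `f_rel`, `rss`, `flags` (character vector, e.g.
#'   `"degenerate"`, `"negative_parameter"`), and the fitted trace.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' tr <- simulate_trace(model = "exponential", f_eq = 0.6, k_exp = 0.01)
#' fit <- fit_single_exponential(tr)
#' glance(fit)
#' @export
fit_single_exponential <- function(trace, start = NULL) {
  stopifnot(inherits(trace, "fluor_trace"))
  t_add <- trace_t_add(trace)
  post <- trace[trace$time >= t_add, ]
  tt <- post$time - t_add
  ff <- post$intensity

  flags <- character()
  late <- ff[tt >= stats::quantile(tt, 0.75)]
  if (max(abs(ff)) < 1e-12 || abs(mean(late)) < 3 * sd(ff) / sqrt(length(ff))) {
    flags <- "degenerate"
    est <- tibble(
      term = c("f_eq", "k_exp"),
      estimate = c(mean(late), NA_real_),
      std.error = c(sd(late) / sqrt(length(late)), NA_real_)
    )
    out <- list(
      estimate = est, f_eq = est$estimate[1], k_exp = NA_real_,
      f_rel = est$estimate[1], rss = sum((ff - mean(ff))^2),
      flags = flags, trace = trace, fit = NULL
    )
    class(out) <- "exp_fit"
    return(out)
  }

  if (is.null(start)) {
    f0 <- mean(late)
    half_idx <- which(ff >= 0.5 * f0)[1]
    k0 <- if (is.na(half_idx) || tt[half_idx] <= 0) 1 / max(tt) else log(2) / tt[half_idx]
    start <- list(f_eq = f0, k_exp = k0)
  }

  fit <- tryCatch(
    minpack.lm::nlsLM(
      ff ~ f_eq * (1 - exp(-k_exp * tt)),
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      abort(sprintf(
        "Single-exponential fit did not converge (start f_eq = %.4g, k_exp = %.4g): %s",
        start$f_eq, start$k_exp, conditionMessage(e)
      ))
    }
  )
  cf <- coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  if (any(cf < 0)) flags <- c(flags, "negative_parameter")
  out <- list(
    estimate = tibble(
      term = c("f_eq", "k_exp"),
      estimate = unname(cf[c("f_eq", "k_exp")]),
      std.error = unname(se[c("f_eq", "k_exp")])
    ),
    f_eq = unname(cf[["f_eq"]]), k_exp = unname(cf[["k_exp"]]),
    f_rel = unname(cf[["f_eq"]]),
    rss = sum(stats::resid(fit)^2),
    flags = flags, trace = trace, fit = fit
  )
  class(out) <- "exp_fit"
  out
}

#' @export
print.exp_fit <- function(x, ...) {
  cat("Single-exponential dye-influx fit\n")
  cat(sprintf("  F_eq (= F_rel): %.4g   k_exp: %.4g s^-1   rss: %.3g\n",
              x$f_eq, x$k_exp, x$rss))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Linearize a trace under the second-order pore-formation model
#'
#' Pore formation by in-membrane peptide association is treated as a
#' second-order process, for which
#' `F_eq / ([P_b] (F_eq - F_t)) = 1/[P_b] + k_a t`
#' with time counted from peptide addition. This function applies the
#' left-hand-side transform so that a straight-line fit of the result
#' ([fit_ka()]) yields the second-order rate constant `k_a` as slope and
#' `1/[P_b]` as intercept.
#'
#' Points where `F_eq - F_t` falls below `floor_frac * F_eq` are excluded
#' (the transform blows up at saturation); exclusions are reported via the
#' `dropped` attribute and a message.
#'
#' @param trace A normalized [fluor_trace()].
#' @param f_eq Equilibrium fluorescence level on the normalized scale
#'   (from [fit_single_exponential()], a measured plateau, or generator
#'   ground truth).
#' @param p_b Membrane-bound peptide particle concentration in molar,
#'   determined externally (e.g. by microelectrophoresis).
#' @param floor_frac Saturation floor: points with
#'   `F_eq - F_t < floor_frac * F_eq` are dropped. Default 0.01.
#' @param quiet Suppress the dropped-points message.
#' @return A tibble with columns `t` (seconds since addition) and `y`
#'   (M^-1), attribute `dropped` holding the excluded times, and
#'   attribute `p_b`.
#' @examples
#' tr <- simulate_trace(model = "second_order", f_eq = 0.6, k_a = 1e5, p_b = 2e-6)
#' series <- linearize_second_order(tr, f_eq = 0.6, p_b = 2e-6)
#' fit_ka(series, p_b = 2e-6)
#' @export
linearize_second_order <- function(trace, f_eq, p_b, floor_frac = 0.01,
                                   quiet = FALSE) {
  stopifnot(inherits(trace, "fluor_trace"))
  if (!is.numeric(f_eq) || length(f_eq) != 1L || f_eq <= 0) {
    abort("`f_eq` must be a single positive number.")
  }
  if (!is.numeric(p_b) || length(p_b) != 1L || p_b <= 0) {
    abort("`p_b` must be a single positive molar concentration.")
  }
  t_add <- trace_t_add(trace)
  post <- trace[trace$time >= t_add, ]
  tt <- post$time - t_add
  ff <- post$intensity
  gap <- f_eq - ff
  keep <- gap >= floor_frac * f_eq
  if (sum(keep) < 5L) {
    abort(paste(
      "Almost all post-addition points sit at or above the saturation floor:",
      "the supplied equilibrium level does not exceed the trace. Check",
      sprintf("`f_eq` (max F_t = %.4g, f_eq = %.4g).", max(ff), f_eq)
    ))
  }
  if (any(!keep) && !quiet) {
    inform(sprintf(
      "linearize_second_order: dropped %d point(s) within %.3g%% of F_eq (t = %s s).",
      sum(!keep), 100 * floor_frac,
      paste(utils::head(signif(tt[!keep] + t_add, 5), 5), collapse = ", ")
    ))
  }
  out <- tibble(t = tt[keep], y = f_eq / (p_b * gap[keep]))
  attr(out, "dropped") <- tt[!keep] + t_add
  attr(out, "p_b") <- p_b
  out
}

#' Fit the second-order rate constant from a linearized series
#'
#' Ordinary (or weighted) least-squares line through the `(t, y)` points
#' produced by [linearize_second_order()]. The slope is the second-order
#' pore-formation rate constant `k_a` (M^-1 s^-1); under the second-order
#' model the intercept equals `1/[P_b]`, so the ratio of fitted to expected
#' intercept is reported as a model-consistency check. A quadratic curvature
#' coefficient is reported as a nonlinearity diagnostic: data generated by a
#' different kinetic law (e.g. single-exponential) produce a convex plot.
#'
#' @param series Tibble with columns `t`, `y` (from
#'   [linearize_second_order()]).
#' @param p_b Membrane-bound peptide concentration (M); defaults to the
#'   value carried by `series`.
#' @param weights Optional non-negative weights for weighted least squares
#'   (default ordinary least squares).
#' @return An object of class `ka_fit` with elements `k_a`, `intercept`,
#'   `r2`, `intercept_expected`, `intercept_ratio`, `curvature`
#'   (quadratic coefficient relative to the linear trend), `flags`, and the
#'   fitted series. A negative slope is flagged and `k_a` set to `NA`.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @export
fit_ka <- function(series, p_b = attr(series, "p_b"), weights = NULL) {
  if (!is.data.frame(series) || !all(c("t", "y") %in% names(series))) {
    abort("`series` must have columns `t` and `y` (see linearize_second_order()).")
  }
  if (nrow(series) < 5L) {
    abort("At least 5 points are required to fit the second-order line.")
  }
  if (is.null(p_b)) abort("`p_b` is required (not carried by `series`).")
  w <- if (is.null(weights)) rep(1, nrow(series)) else weights
  if (length(w) != nrow(series) || any(w < 0)) {
    abort("`weights` must be non-negative and match the number of points.")
  }
  fit <- lm(y ~ t, data = series, weights = w)
  cf <- coef(fit)
  slope <- unname(cf[["t"]])
  intercept <- unname(cf[["(Intercept)"]])
  r2 <- suppressWarnings(summary(fit))$r.squared
  # curvature diagnostic: quadratic term scaled by the linear trend
  quad <- lm(y ~ t + I(t^2), data = series, weights = w)
  curv <- unname(coef(quad)[["I(t^2)"]]) * max(series$t) /
    max(abs(slope), .Machine$double.eps)
  flags <- character()
  k_a <- slope
  if (abs(slope) <= 1e-12 * max(abs(series$y))) {
    flags <- "flat"
    k_a <- 0
  } else if (slope < 0) {
    flags <- "negative_slope"
    k_a <- NA_real_
  }
  if (abs(curv) > 0.1) flags <- c(flags, "nonlinear")
  out <- list(
    k_a = k_a, intercept = intercept, r2 = r2,
    intercept_expected = 1 / p_b,
    intercept_ratio = intercept * p_b,
    curvature = curv, flags = flags,
    p_b = p_b, series = series, fit = fit
  )
  class(out) <- "ka_fit"
  out
}

#' @export
print.ka_fit <- function(x, ...) {
  cat("Second-order pore-formation fit\n")
  cat(sprintf("  k_a: %.4g M^-1 s^-1   intercept: %.4g M^-1 (expected 1/[P_b] = %.4g)\n",
              x$k_a, x$intercept, x$intercept_expected))
  cat(sprintf("  R^2: %.6g   curvature: %.3g\n", x$r2, x$curvature))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Initial-slope estimate of the pore-formation rate
#'
#' Linear slope of the normalized fluorescence over a short window after
#' peptide addition (default the first two minutes). For second-order
#' kinetics well below saturation the initial slope approximates
#' `F_eq * k_a * [P_b]`, providing a quick cross-check of the
#' linearization route.
#'
#' @param trace A normalized [fluor_trace()].
#' @param window Window length in seconds after `t_add` (default 120).
#' @return A one-row tibble with `slope` (s^-1), `std.error`, and `n`
#'   points used. Map over a list of traces with [purrr::map_dfr()] for a
#'   per-condition table.
#' @export
initial_slope <- function(trace, window = 120) {
  stopifnot(inherits(trace, "fluor_trace"))
  t_add <- trace_t_add(trace)
  sel <- trace$time >= t_add & trace$time <= t_add + window
  if (sum(sel) < 3L) {
    abort(sprintf("Fewer than 3 points in the %g-s window after addition.", window))
  }
  fit <- lm(intensity ~ I(time - t_add), data = trace[sel, ])
  sm <- suppressWarnings(summary(fit))$coefficients
  tibble(slope = sm[2, 1], std.error = sm[2, 2], n = sum(sel))
}

#' In-membrane peptide-peptide affinity constant
#'
#' `K_p = k_a / k_exp`: the ratio of the second-order pore-formation rate
#' constant to the observed first-order rate constant gives the affinity
#' constant of peptide-peptide association within the membrane (M^-1).
#' For octamer suspensions this ratio reaches the 10^7 M^-1 scale.
#'
#' @param k_a Second-order rate constant (M^-1 s^-1), vectorized.
#' @param k_exp Observed exponential rate constant (s^-1), vectorized.
#' @return `K_p` in M^-1.
#' @examples
#' affinity_constant(2.5e5, 0.025)  # 1e7
#' @export
affinity_constant <- function(k_a, k_exp) {
  if (any(k_exp == 0)) {
    abort(paste(
      "`k_exp` is zero: the affinity constant K_p = k_a / k_exp is undefined.",
      "Use a trace with a measurable fluorescence rise."
    ))
  }
  k_a / k_exp
}

# registry of association models for the oligomer count
.n_models <- new.env(parent = emptyenv())
.n_models$isodesmic <- function(k_p, p_b) (1 + sqrt(1 + 4 * k_p * p_b)) / 2

#' Mean oligomer count per pore
#'
#' Estimates the average number of peptide oligomer units assembled into a
#' pore from the in-membrane affinity constant `K_p` and the
#' membrane-bound particle concentration `[P_b]`. The closed form depends
#' on the assumed association scheme; the default is isodesmic stepwise
#' association (equal affinity at every step), for which the mean aggregate
#' size is `n = (1 + sqrt(1 + 4 K_p [P_b])) / 2`. This default is an
#' explicit modelling assumption: other schemes can be registered via
#' [register_n_model()].
#'
#' @param k_p Affinity constant (M^-1), vectorized.
#' @param p_b Membrane-bound peptide concentration (M), vectorized.
#' @param model Name of a registered association model (default
#'   `"isodesmic"`).
#' @return Mean oligomer count `n` (dimensionless); `n -> 1` as
#'   `K_p [P_b] -> 0`.
#' @examples
#' estimate_n(k_p = 3e6, p_b = 2e-6)
#' @export
estimate_n <- function(k_p, p_b, model = "isodesmic") {
  if (any(k_p < 0)) abort("`k_p` must be non-negative.")
  if (any(p_b <= 0)) abort("`p_b` must be positive.")
  if (!is.character(model) || !exists(model, envir = .n_models, inherits = FALSE)) {
    abort(sprintf(
      "Unknown association model %s. Registered models: %s.",
      deparse(model), paste(ls(.n_models), collapse = ", ")
    ))
  }
  get(model, envir = .n_models)(k_p, p_b)
}

#' @rdname estimate_n
#' @param name Model name to register.
#' @param fn Function of `(k_p, p_b)` returning the mean oligomer count.
#' @export
register_n_model <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .n_models)
  invisible(name)
}

#' Full pore-formation kinetics analysis of one trace
#'
#' End-to-end estimator for one membrane condition: fits the single
#' exponential (for `F_rel` and `k_exp`), linearizes the trace under the
#' second-order model, fits `k_a`, and derives `K_p = k_a / k_exp` and the
#' oligomer count `n`.
#'
#' For noisy traces the raw linearization is ill-conditioned near
#' saturation, where the transform `F_eq / (F_eq - F_t)` amplifies noise
#' and selecting points by their observed distance from `F_eq` biases the
#' slope. The estimator therefore restricts the line fit to the time window
#' in which the modelled signal stays below `sat_frac * F_eq`, determined
#' self-consistently: a preliminary rate from the half-rise time fixes the
#' window, the weighted line fit updates the rate, and the window is
#' re-derived for a few iterations. Weights are the fourth power of the
#' model-predicted distance from saturation (inverse variance of the
#' transformed points under additive noise), evaluated from the current
#' rate so they are independent of the noise realization.
#'
#' @param trace A normalized [fluor_trace()].
#' @param p_b Membrane-bound peptide concentration (M).
#' @param f_eq Equilibrium level; by default taken from the
#'   single-exponential fit. Supply the measured plateau (or generator
#'   ground truth) to decouple the two estimators.
#' @param sat_frac Saturation cutoff as a fraction of `f_eq` (default 0.9).
#' @param floor_frac Hard floor passed to [linearize_second_order()].
#' @param iters Self-consistency iterations (default 4).
#' @param weighted Use the model-based inverse-variance weights (default
#'   `TRUE`); `FALSE` gives plain OLS on the truncated window.
#' @param n_model Association model for [estimate_n()].
#' @return An object of class `pore_kinetics` with the `exp_fit`, the
#'   `ka_fit`, and scalars `f_rel`, `k_exp`, `k_a`, `k_p`, `n`.
#'   Supports [tidy()] and [glance()].
#' @examples
#' tr <- simulate_trace(model = "second_order", f_eq = 0.6, k_a = 1e5,
#'                      p_b = 2e-6, noise = 0.01, seed = 1)
#' res <- fit_pore_kinetics(tr, p_b = 2e-6, f_eq = 0.6)
#' glance(res)
#' @export
fit_pore_kinetics <- function(trace, p_b, f_eq = NULL, sat_frac = 0.9,
                              floor_frac = 0.01, iters = 4, weighted = TRUE,
                              n_model = "isodesmic") {
  stopifnot(inherits(trace, "fluor_trace"))
  exp_fit <- fit_single_exponential(trace)
  if (is.null(f_eq)) f_eq <- exp_fit$f_eq
  if (!is.numeric(f_eq) || f_eq <= 0) {
    abort("No positive equilibrium level available; supply `f_eq`.")
  }
  series <- linearize_second_order(trace, f_eq = f_eq, p_b = p_b,
                                   floor_frac = floor_frac, quiet = TRUE)
  # preliminary rate from the half-rise time (x = k_a [P_b] t = 1 there)
  t_add <- trace_t_add(trace)
  post <- trace[trace$time >= t_add, ]
  tt <- post$time - t_add
  sm <- stats::filter(post$intensity, rep(1 / 9, 9), sides = 2)
  half <- which(sm >= 0.5 * f_eq)[1]
  rate <- if (is.na(half) || tt[half] <= 0) 1 / max(tt) else 1 / tt[half]

  xmax <- sat_frac / (1 - sat_frac)
  fit <- NULL
  for (i in seq_len(iters)) {
    tmax <- xmax / rate
    keep <- series$t > 0 & series$t <= tmax
    if (sum(keep) < 5L) {
      keep <- series$t > 0 & series$t <= sort(series$t[series$t > 0])[5]
    }
    sub <- series[keep, ]
    attr(sub, "p_b") <- p_b
    w <- if (weighted) (f_eq / (1 + rate * sub$t))^4 else NULL
    fit <- fit_ka(sub, p_b = p_b, weights = w)
    if (is.na(fit$k_a) || fit$k_a <= 0) break
    rate <- fit$k_a * p_b
  }
  k_p <- if (!is.na(fit$k_a) && !is.na(exp_fit$k_exp) && exp_fit$k_exp > 0) {
    affinity_constant(fit$k_a, exp_fit$k_exp)
  } else NA_real_
  n <- if (!is.na(k_p)) estimate_n(k_p, p_b, model = n_model) else NA_real_
  out <- list(
    exp_fit = exp_fit, ka_fit = fit,
    f_rel = exp_fit$f_rel, k_exp = exp_fit$k_exp,
    k_a = fit$k_a, k_p = k_p, n = n, p_b = p_b
  )
  class(out) <- "pore_kinetics"
  out
}

#' @export
print.pore_kinetics <- function(x, ...) {
  cat("Pore-formation kinetics\n")
  cat(sprintf("  F_rel: %.3g   k_exp: %.4g s^-1\n", x$f_rel, x$k_exp))
  cat(sprintf("  k_a: %.4g M^-1 s^-1   K_p: %.4g M^-1   n: %.3g\n",
              x$k_a, x$k_p, x$n))
  invisible(x)
}
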