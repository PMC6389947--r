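#' Tidy methods for fitted objects
#'
#' broom-style accessors: `tidy()` returns one row per estimated quantity,
#' `glance()` a one-row model summary.
#'
#' @param x A fitted object (`exp_fit`, `ka_fit`, `pore_kinetics`,
#'   `band_fit`).
#' @param ... Unused.
#' @return A tibble.
#' @name abpore-tidiers
NULL

#' @rdname abpore-tidiers
#' @export
tidy.exp_fit <- function(x, ...) x$estimate

#' @rdname abpore-tidiers
#' @export
glance.exp_fit <- function(x, ...) {
  tibble(f_eq = x$f_eq, k_exp = x$k_exp, f_rel = x$f_rel, rss = x$rss,
         flags = paste(x$flags, collapse = ";"))
}

#' @rdname abpore-tidiers
#' @export
tidy.ka_fit <- function(x, ...) {
  tibble(
    term = c("k_a", "intercept"),
    estimate = c(x$k_a, x$intercept),
    std.error = suppressWarnings(summary(x$fit))$coefficients[c("t", "(Intercept)"), "Std. Error"]
  )
}

#' @rdname abpore-tidiers
#' @export
glance.ka_fit <- function(x, ...) {
  tibble(k_a = x$k_a, intercept = x$intercept, r.squared = x$r2,
         intercept_expected = x$intercept_expected,
         intercept_ratio = x$intercept_ratio,
         curvature = x$curvature,
         flags = paste(x$flags, collapse = ";"))
}

#' @rdname abpore-tidiers
#' @export
tidy.pore_kinetics <- function(x, ...) {
  tibble(
    term = c("f_rel", "k_exp", "k_a", "k_p", "n"),
    estimate = c(x$f_rel, x$k_exp, x$k_a, x$k_p, x$n),
    unit = c("", "s^-1", "M^-1 s^-1", "M^-1", "")
  )
}

#' @rdname abpore-tidiers
#' @export
glance.pore_kinetics <- function(x, ...) {
  tibble(f_rel = x$f_rel, k_exp = x$k_exp, k_a = x$k_a, k_p = x$k_p,
         n = x$n, p_b = x$p_b,
         r.squared = x$ka_fit$r2,
         intercept_ratio = x$ka_fit$intercept_ratio)
}

#' @rdname abpore-tidiers
#' @export
tidy.band_fit <- function(x, ...) x$components

#' @rdname abpore-tidiers
#' @export
glance.band_fit <- function(x, ...) {
  tibble(rss = x$rss, n_components = nrow(x$components),
         region_min = x$region[1], region_max = x$region[2],
         flags = paste(x$flags, collapse = ";"))
}
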