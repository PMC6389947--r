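#' Construct a dye-influx fluorescence trace
#'
#' Bundles a timed fluorescence record from a Quin-2 vesicle leakage assay
#' with its two pieces of assay metadata: the peptide addition time and the
#' ionophore-induced maximum fluorescence used as the normalization
#' reference.
#'
#' The underlying data are a tibble with columns `time` (seconds, strictly
#' increasing) and `intensity` (arbitrary fluorescence units); `t_add` and
#' `f_max` travel as attributes so the trace can flow through a dplyr-style
#' pipeline. At least 10 samples after `t_add` are required, since all
#' downstream fits act on the post-addition segment.
#'
#' @param data A data frame with numeric columns `time` and `intensity`.
#' @param t_add Peptide addition time in seconds (e.g. 248 s).
#' @param f_max Ionophore-induced maximum fluorescence (same arbitrary units
#'   as `intensity`), or `NULL` when no ionophore reference was recorded.
#' @param ground_truth Optional list of generating parameters (attached by
#'   the synthetic-data generators; see [simulate_trace()]).
#'
#' @return A tibble of class `fluor_trace` with columns `time`, `intensity`
#'   and attributes `t_add`, `f_max`, `ground_truth`.
#' @seealso [normalize_trace()], [fit_single_exponential()],
#'   [simulate_trace()]
#' @examples
#' tr <- fluor_trace(
#'   data.frame(time = 0:600, intensity = c(rep(0, 248), 1 - exp(-0.01 * (248:600 - 248)))),
#'   t_add = 248, f_max = 1
#' )
#' trace_t_add(tr)
#' @export
fluor_trace <- function(data, t_add, f_max = NULL, ground_truth = NULL) {
  if (!is.data.frame(data) || !all(c("time", "intensity") %in% names(data))) {
    abort("`data` must be a data frame with columns `time` and `intensity`.")
  }
  time <- as.numeric(data$time)
  intensity <- as.numeric(data$intensity)
  if (anyNA(time) || anyNA(intensity)) {
    abort("`time` and `intensity` must be numeric without missing values.")
  }
  if (any(diff(time) <= 0)) {
    abort("`time` must be strictly increasing.")
  }
  if (!is.numeric(t_add) || length(t_add) != 1L) {
    abort("`t_add` must be a single numeric value (seconds).")
  }
  if (sum(time >= t_add) < 10L) {
    abort("A trace needs at least 10 samples at or after `t_add`.")
  }
  if (!is.null(f_max)) {
    if (!is.numeric(f_max) || length(f_max) != 1L || f_max <= 0) {
      abort("`f_max` must be a single positive number when supplied.")
    }
  }
  out <- tibble(time = time, intensity = intensity)
  class(out) <- c("fluor_trace", class(out))
  attr(out, "t_add") <- as.numeric(t_add)
  attr(out, "f_max") <- if (is.null(f_max)) NULL else as.numeric(f_max)
  attr(out, "ground_truth") <- ground_truth
  out
}

#' Trace metadata accessors
#'
#' @param trace A [fluor_trace()].
#' @return `trace_t_add()` the addition time (s); `trace_f_max()` the
#'   ionophore reference level or `NULL`; `trace_ground_truth()` the
#'   generating parameters or `NULL`.
#' @export
trace_t_add <- function(trace) attr(trace, "t_add")

#' @rdname trace_t_add
#' @export
trace_f_max <- function(trace) attr(trace, "f_max")

#' @rdname trace_t_add
#' @export
trace_ground_truth <- function(trace) attr(trace, "ground_truth")

#' Normalize a trace to the ionophore maximum
#'
#' Converts a raw fluorescence trace to the relative scale on which the
#' ionophore-induced maximum equals 1. The pre-addition mean (baseline) is
#' subtracted first, then intensities are divided by the baseline-corrected
#' ionophore level, so a post-addition plateau at `f_eq` reads directly as
#' the relative equilibrium fluorescence `F_rel = F_eq / F_max`.
#'
#' @param trace A [fluor_trace()] with a recorded `f_max`.
#' @return A normalized `fluor_trace` with `f_max = 1` and baseline 0.
#' @examples
#' raw <- simulate_trace(model = "exponential", f_eq = 0.6, k_exp = 0.01,
#'                       baseline = 0.05, f_max = 2)
#' norm <- normalize_trace(raw)
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "fluor_trace"))
  f_max <- trace_f_max(trace)
  if (is.null(f_max)) {
    abort(paste(
      "This trace has no ionophore reference (`f_max`).",
      "Record the maximum fluorescence induced by an ionophore such as",
      "4-Br-A23187 and supply it via `fluor_trace(..., f_max = )`."
    ))
  }
  t_add <- trace_t_add(trace)
  pre <- trace$time < t_add
  baseline <- if (any(pre)) mean(trace$intensity[pre]) else 0
  denom <- f_max - baseline
  if (denom <= 0) {
    abort("Ionophore reference does not exceed the baseline; cannot normalize.")
  }
  fluor_trace(
    tibble(time = trace$time, intensity = (trace$intensity - baseline) / denom),
    t_add = t_add, f_max = 1,
    ground_truth = trace_ground_truth(trace)
  )
}

#' Read a fluorescence trace from a two-column delimited file
#'
#' Expects columns time (seconds) and intensity, in that order; a header
#' line is detected automatically.
#'
#' @param file Path to a CSV/TSV file.
#' @param t_add,f_max Assay metadata, as in [fluor_trace()].
#' @param sep Field separator (default `","`).
#' @return A [fluor_trace()].
#' @export
read_trace <- function(file, t_add, f_max = NULL, sep = ",") {
  first <- readLines(file, n = 1L)
  has_header <- anyNA(suppressWarnings(as.numeric(strsplit(first, sep, fixed = TRUE)[[1]])))
  df <- utils::read.table(file, header = has_header, sep = sep)
  names(df)[1:2] <- c("time", "intensity")
  fluor_trace(df[1:2], t_add = t_add, f_max = f_max)
}
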