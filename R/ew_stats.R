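#' Sample moments of a time series
#'
#' Mean, unbiased variance (divisor n-1), and the standardized third and
#' fourth moments computed from divisor-n central moments: skewness
#' m3 / m2^(3/2) and excess kurtosis m4 / m2^2 - 3 (a Gaussian series has
#' excess kurtosis 0).  For a constant series the standardized moments are
#' undefined and reported as `NA`.
#'
#' @param samples numeric vector with at least 4 values.
#' @return list with components `mean`, `variance`, `skewness`,
#'   `excess_kurtosis`.
#' @export
#' @examples
#' moments(c(1, 2, 3, 4, 5))  # mean 3, variance 2.5, skewness 0
moments <- function(samples) {
  samples <- as.numeric(samples)
  if (length(samples) < 4L)
    stop("'samples' must contain at least 4 values", call. = FALSE)
  if (any(!is.finite(samples)))
    stop("'samples' must be finite", call. = FALSE)
  v <- var(samples)
  if (v == 0) {
    sk <- NA_real_
    ku <- NA_real_
  } else {
    sk <- e1071::skewness(samples, type = 1)
    ku <- e1071::kurtosis(samples, type = 1)
  }
  list(mean = mean(samples), variance = v, skewness = sk,
       excess_kurtosis = ku)
}

#' Lag-1 autocorrelation
#'
#' Autocovariance at lag 1 over the lag-0 autocovariance, both about the
#' full-series mean -- the short-term-memory early-warning indicator, which
#' approaches 1 under critical slowing down.  Undefined (`NA`) for a
#' constant series.
#'
#' @param series numeric vector with at least 3 values.
#' @return a single number in `[-1, 1]`, or `NA` for a constant series.
#' @export
lag1_autocorrelation <- function(series) {
  series <- as.numeric(series)
  if (length(series) < 3L)
    stop("'series' must contain at least 3 values", call. = FALSE)
  if (any(!is.finite(series)))
    stop("'series' must be finite", call. = FALSE)
  if (var(series) == 0) return(NA_real_)
  as.numeric(acf(series, lag.max = 1, plot = FALSE, demean = TRUE)$acf[2])
}

# internal: pull the numeric samples out of whatever trace object we get
as_series <- function(x) {
  if (inherits(x, "r_trace")) return(x$r_values)
  if (inherits(x, "intensity_trace")) return(x$values)
  as.numeric(x)
}

#' Ensemble early-warning summary at one control-parameter value
#'
#' Pools an ensemble of post-transient traces into one row of early-warning
#' indicators.  In `"pooled"` mode the moments are computed on the
#' concatenation of all samples, while the lag-1 autocorrelation is always
#' computed per trace and then averaged (lag-1 products across trace
#' boundaries are meaningless).  In `"per_run_mean"` mode every statistic
#' is computed per trace and averaged.
#'
#' @param traces list of numeric vectors, `r_trace` or `intensity_trace`
#'   objects.
#' @param control_value the control-parameter value (K or nu) the ensemble
#'   was simulated at.
#' @param pooling `"pooled"` (default) or `"per_run_mean"`.
#' @return a one-row `data.frame` of class `ew_summary` with columns
#'   `control_value`, `mean`, `variance`, `skewness`, `excess_kurtosis`,
#'   `lag1_ac`, `n_samples`.
#' @export
ensemble_ew <- function(traces, control_value = NA_real_,
                        pooling = c("pooled", "per_run_mean")) {
  pooling <- match.arg(pooling)
  if (!is.list(traces)) traces <- list(traces)
  if (length(traces) == 0L)
    stop("'traces' must contain at least one trace", call. = FALSE)
  series <- lapply(traces, as_series)
  lag1 <- mean(vapply(series, lag1_autocorrelation, numeric(1)),
               na.rm = TRUE)
  if (pooling == "pooled") {
    all <- unlist(series, use.names = FALSE)
    mom <- moments(all)
  } else {
    per <- lapply(series, moments)
    mom <- lapply(c("mean", "variance", "skewness", "excess_kurtosis"),
                  function(f) mean(vapply(per, `[[`, numeric(1), f),
                                   na.rm = TRUE))
    names(mom) <- c("mean", "variance", "skewness", "excess_kurtosis")
  }
  out <- data.frame(control_value = control_value, mean = mom$mean,
                    variance = mom$variance, skewness = mom$skewness,
                    excess_kurtosis = mom$excess_kurtosis, lag1_ac = lag1,
                    n_samples = sum(lengths(series)))
  class(out) <- c("ew_summary", "data.frame")
  out
}

#' Estimate the critical point from a sweep of summaries
#'
#' `"max_variance"` returns the control value with the largest ensemble
#' variance (the variance of the observable diverges at the transition);
#' `"max_abs_mean_slope"` returns the midpoint of the adjacent pair of
#' control values with the largest absolute slope of the ensemble mean
#' (suited to an abrupt change of the mean, as in the atrial model).  Ties
#' are broken toward the smaller control value.  A `boundary` attribute
#' flags an argmax at the edge of the grid.
#'
#' @param sweep a `data.frame` with strictly increasing `control_value` and
#'   columns `variance` and/or `mean` (e.g. rbound [ensemble_ew()] rows),
#'   at least 3 rows.
#' @param method `"max_variance"` or `"max_abs_mean_slope"`.
#' @return the estimated critical control value, with attributes `method`
#'   and `boundary`.
#' @export
#' @examples
#' sw <- data.frame(control_value = c(1, 1.5, 2), variance = c(1, 5, 2),
#'                  mean = c(1, 0.9, 0.1))
#' estimate_cp(sw, "max_variance")  # 1.5
estimate_cp <- function(sweep, method = c("max_variance",
                                          "max_abs_mean_slope")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(sweep), "control_value" %in% names(sweep))
  x <- sweep$control_value
  n <- length(x)
  if (n < 3L)
    stop("need at least 3 control values to estimate a critical point",
         call. = FALSE)
  if (any(diff(x) <= 0))
    stop("'control_value' must be strictly increasing", call. = FALSE)
  if (method == "max_variance") {
    v <- sweep$variance
    i <- which.max(v)          # first max = smaller control on ties
    cp <- x[i]
    boundary <- i == 1L || i == n
  } else {
    m <- sweep$mean
    s <- diff(m) / diff(x)
    j <- which.max(abs(s))
    cp <- (x[j] + x[j + 1L]) / 2
    boundary <- j == 1L || j == n - 1L
  }
  structure(cp, method = method, boundary = boundary)
}

#' Summarize a parameter sweep and estimate its critical point
#'
#' @param sweep a `coupling_sweep`, `nu_sweep`, or plain list of lists of
#'   traces keyed by control value.
#' @param control_values the control values, in the same order as `sweep`;
#'   taken from the sweep object when omitted.
#' @param cp_method critical-point estimator passed to [estimate_cp()].
#' @param pooling passed to [ensemble_ew()].
#' @return an object of class `sweep_summary`: list with `summaries` (the
#'   stacked [ensemble_ew()] rows), `cp_estimate`, `cp_method`, `aligned`
#'   flag and the `shift` applied (0 until [align_to_cp()] is called).
#' @export
summarize_sweep <- function(sweep, control_values = NULL,
                            cp_method = c("max_variance",
                                          "max_abs_mean_slope"),
                            pooling = c("pooled", "per_run_mean")) {
  cp_method <- match.arg(cp_method)
  pooling <- match.arg(pooling)
  if (is.null(control_values)) {
    control_values <- attr(sweep, "k_values")
    if (is.null(control_values)) control_values <- attr(sweep, "nu_values")
    if (is.null(control_values))
      stop("supply 'control_values' for a plain list sweep", call. = FALSE)
  }
  stopifnot(length(sweep) == length(control_values))
  rows <- Map(function(traces, cv) ensemble_ew(traces, cv, pooling),
              sweep, control_values)
  summaries <- do.call(rbind, rows)
  cp <- estimate_cp(summaries, cp_method)
  structure(list(summaries = summaries, cp_estimate = as.numeric(cp),
                 cp_method = cp_method,
                 cp_boundary = isTRUE(attr(cp, "boundary")),
                 aligned = FALSE, shift = 0),
            class = "sweep_summary")
}

#' @export
print.sweep_summary <- function(x, ...) {
  cat(sprintf(
    "sweep summary: %d control values in [%g, %g], CP = %g (%s)%s%s\n",
    nrow(x$summaries), min(x$summaries$control_value),
    max(x$summaries$control_value), x$cp_estimate, x$cp_method,
    if (x$cp_boundary) " [boundary]" else "",
    if (x$aligned) sprintf(", aligned (shift %g)", x$shift) else ""))
  invisible(x)
}

#' Align sweeps on their critical points
#'
#' Translates each sweep's control axis by minus its critical-point
#' estimate, so the CPs of all sweeps coincide at 0 and the indicator
#' curves can be compared across perturbation levels.  Summaries are
#' otherwise untouched; the shift is recorded.  A boundary-flagged CP
#' produces a warning but the alignment is still performed.
#'
#' @param sweeps a `sweep_summary` or list of them.
#' @return a list of aligned `sweep_summary` objects.
#' @export
align_to_cp <- function(sweeps) {
  if (inherits(sweeps, "sweep_summary")) sweeps <- list(sweeps)
  lapply(sweeps, function(s) {
    stopifnot(inherits(s, "sweep_summary"))
    if (s$cp_boundary)
      warning("critical-point estimate lies on the sweep boundary; ",
              "aligning anyway", call. = FALSE)
    s$summaries$control_value <- s$summaries$control_value - s$cp_estimate
    s$shift <- -s$cp_estimate
    s$aligned <- TRUE
    s
  })
}
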