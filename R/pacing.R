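#' Pulse-to-pulse pacing schedule
#'
#' An ordered vector of strictly positive pulse-to-pulse intervals in
#' milliseconds.  The reference interval of 13.2 ms matches the automaton's
#' 220-step pacing period at 0.06 ms/step.
#'
#' @param intervals_ms numeric vector of intervals (ms), all > 0 and
#'   finite.
#' @param kind one of `"fixed"`, `"uniform"`, `"gaussian"`, `"rr_file"`,
#'   `"rr_synthetic"`.
#' @param source_meta free-text provenance note.
#' @return an object of class `pacing_schedule`.
#' @export
pacing_schedule <- function(intervals_ms,
                            kind = c("fixed", "uniform", "gaussian",
                                     "rr_file", "rr_synthetic"),
                            source_meta = "") {
  kind <- match.arg(kind)
  intervals_ms <- as.numeric(intervals_ms)
  if (length(intervals_ms) == 0L)
    stop("schedule must contain at least one interval", call. = FALSE)
  if (any(!is.finite(intervals_ms)) || any(intervals_ms <= 0))
    stop("all intervals must be strictly positive and finite",
         call. = FALSE)
  structure(list(intervals_ms = intervals_ms, kind = kind,
                 source_meta = source_meta),
            class = "pacing_schedule")
}

#' @export
print.pacing_schedule <- function(x, ...) {
  cat(sprintf(
    "pacing schedule (%s): %d intervals, mean = %.3f ms, sd = %.3f ms\n",
    x$kind, length(x$intervals_ms), mean(x$intervals_ms),
    if (length(x$intervals_ms) > 1) sd(x$intervals_ms) else 0))
  invisible(x)
}

#' Fixed-interval pacing (artificial pacemaker)
#'
#' @param n number of intervals (>= 1).
#' @param base_ms the constant interval (default 13.2 ms).
#' @return a `pacing_schedule` of kind `"fixed"`.
#' @export
fixed_schedule <- function(n, base_ms = 13.2) {
  check_number(n, "n", lower = 1, integer = TRUE)
  check_number(base_ms, "base_ms", lower = 0, strict_lower = TRUE)
  pacing_schedule(rep(base_ms, n), "fixed",
                  sprintf("fixed %g ms", base_ms))
}

#' Uniformly jittered pacing
#'
#' Intervals are i.i.d. Uniform(`base_ms - half_width_ms`,
#' `base_ms + half_width_ms`); the defaults reproduce the 13.2 +/- 1.3 ms
#' regime.
#'
#' @param n number of intervals.
#' @param base_ms centre of the distribution.
#' @param half_width_ms half-width (must satisfy
#'   `0 <= half_width_ms < base_ms`).
#' @param seed optional integer seed.
#' @return a `pacing_schedule` of kind `"uniform"`.
#' @export
uniform_schedule <- function(n, base_ms = 13.2, half_width_ms = 1.3,
                             seed = NULL) {
  check_number(n, "n", lower = 1, integer = TRUE)
  check_number(base_ms, "base_ms", lower = 0, strict_lower = TRUE)
  check_number(half_width_ms, "half_width_ms", lower = 0)
  if (half_width_ms >= base_ms)
    stop("'half_width_ms' must be smaller than 'base_ms'", call. = FALSE)
  seed_if_given(seed)
  pacing_schedule(runif(n, base_ms - half_width_ms, base_ms + half_width_ms),
                  "uniform",
                  sprintf("uniform %g +/- %g ms", base_ms, half_width_ms))
}

#' Gaussian-jittered pacing
#'
#' Intervals are i.i.d. Gaussian(`mean_ms`, `sd_ms`), truncated below at
#' `floor_ms` to preserve positivity; the defaults reproduce the
#' 13.2 ms +/- 1.3 ms regime.
#'
#' @param n number of intervals.
#' @param mean_ms mean interval.
#' @param sd_ms standard deviation (>= 0).
#' @param seed optional integer seed.
#' @param floor_ms lower truncation bound (default 1 ms).
#' @return a `pacing_schedule` of kind `"gaussian"`.
#' @export
gaussian_schedule <- function(n, mean_ms = 13.2, sd_ms = 1.3, seed = NULL,
                              floor_ms = 1) {
  check_number(n, "n", lower = 1, integer = TRUE)
  check_number(mean_ms, "mean_ms", lower = 0, strict_lower = TRUE)
  check_number(sd_ms, "sd_ms", lower = 0)
  check_number(floor_ms, "floor_ms", lower = 0, strict_lower = TRUE)
  seed_if_given(seed)
  pacing_schedule(pmax(rnorm(n, mean_ms, sd_ms), floor_ms), "gaussian",
                  sprintf("gaussian mean %g sd %g ms", mean_ms, sd_ms))
}

#' Read an RR-interval file as a pacing schedule
#'
#' Reads a plain-text file with one RR interval per line (`#` comments and
#' blank lines ignored).  Units are auto-detected by magnitude: values
#' greater than 100 are taken as milliseconds, otherwise as seconds.  The
#' series is then affinely rescaled onto the automaton's pacing scale:
#' `"preserve_cv"` multiplies by a constant so the mean is exactly
#' `target_mean_ms` while keeping the recording's coefficient of variation;
#' `"force_sd"` additionally rescales the deviations to standard deviation
#' `sd_ms`, for comparability with the uniform/Gaussian regimes.  Order is
#' preserved.
#'
#' @param path file path.
#' @param target_mean_ms mean of the rescaled schedule (default 13.2 ms).
#' @param scale_mode `"preserve_cv"` (default) or `"force_sd"`.
#' @param sd_ms target standard deviation for `"force_sd"`.
#' @return a `pacing_schedule` of kind `"rr_file"`.
#' @export
read_rr_file <- function(path, target_mean_ms = 13.2,
                         scale_mode = c("preserve_cv", "force_sd"),
                         sd_ms = 1.3) {
  scale_mode <- match.arg(scale_mode)
  check_number(target_mean_ms, "target_mean_ms", lower = 0,
               strict_lower = TRUE)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L)
    stop(sprintf("no RR intervals found in '%s'", path), call. = FALSE)
  vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
  if (anyNA(vals))
    stop(sprintf("non-numeric RR value at line %d of '%s'",
                 keep[which(is.na(vals))[1]], path), call. = FALSE)
  if (any(vals <= 0))
    stop(sprintf("non-positive RR value at line %d of '%s'",
                 keep[which(vals <= 0)[1]], path), call. = FALSE)
  if (median(vals) <= 100) vals <- vals * 1000   # seconds -> ms
  out <- if (scale_mode == "preserve_cv" || length(vals) == 1L) {
    vals * (target_mean_ms / mean(vals))
  } else {
    s <- sd(vals)
    if (s == 0) rep(target_mean_ms, length(vals))
    else target_mean_ms + (vals - mean(vals)) * (sd_ms / s)
  }
  if (any(out <= 0))
    stop(sprintf("interval at line %d is non-positive after rescaling",
                 keep[which(out <= 0)[1]]), call. = FALSE)
  pacing_schedule(out, "rr_file",
                  sprintf("%s rescaled to mean %g ms (%s)", path,
                          target_mean_ms, scale_mode))
}

#' Write a schedule as a plain-text RR file
#'
#' One interval (ms) per line, with a `#` header noting provenance.
#'
#' @param schedule a `pacing_schedule`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rr_file <- function(schedule, path) {
  stopifnot(inherits(schedule, "pacing_schedule"))
  writeLines(c(sprintf("# RR intervals (ms); kind = %s", schedule$kind),
               format(schedule$intervals_ms, digits = 15, trim = TRUE)),
             path)
  invisible(path)
}

#' Synthetic RR surrogate with 1/f-like correlations
#'
#' Spectral synthesis of a surrogate heart-rate-variability series: a
#' Gaussian random spectrum with power proportional to f^(-beta) and
#' uniformly random phases is inverse-transformed, then affinely rescaled
#' to the requested mean and coefficient of variation and truncated below
#' at `floor_ms`.  With `spectral_beta = 1` the schedule carries the
#' long-range 1/f correlations characteristic of healthy RR series; with
#' `spectral_beta = 0` it reduces (in distribution) to white Gaussian
#' jitter.
#'
#' @param n number of intervals (>= 16).
#' @param target_mean_ms mean interval (default 13.2 ms).
#' @param cv coefficient of variation (>= 0, default 0.1).
#' @param spectral_beta spectral exponent beta in `[0, 2]` (default 1).
#' @param seed optional integer seed.
#' @param floor_ms lower truncation bound (default 1 ms).
#' @return a `pacing_schedule` of kind `"rr_synthetic"`.
#' @export
synthetic_rr_schedule <- function(n, target_mean_ms = 13.2, cv = 0.1,
                                  spectral_beta = 1, seed = NULL,
                                  floor_ms = 1) {
  check_number(n, "n", lower = 16, integer = TRUE)
  check_number(target_mean_ms, "target_mean_ms", lower = 0,
               strict_lower = TRUE)
  check_number(cv, "cv", lower = 0)
  check_number(spectral_beta, "spectral_beta", lower = 0, upper = 2)
  seed_if_given(seed)
  if (cv == 0) {
    x <- rep(target_mean_ms, n)
  } else {
    nh <- n %/% 2L
    amp <- (seq_len(nh) / n)^(-spectral_beta / 2)
    z <- complex(real = rnorm(nh), imaginary = rnorm(nh)) * amp
    spec <- complex(real = numeric(n))
    spec[2L:(nh + 1L)] <- z
    # Re() of the inverse transform implicitly Hermitian-symmetrizes the
    # one-sided spectrum, so each bin k carries power ~ (k/n)^(-beta)
    x <- Re(fft(spec, inverse = TRUE)) / n
    x <- (x - mean(x)) / sd(x)
    x <- pmax(target_mean_ms * (1 + cv * x), floor_ms)
  }
  pacing_schedule(x, "rr_synthetic",
                  sprintf("spectral synthesis beta = %g, cv = %g",
                          spectral_beta, cv))
}
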