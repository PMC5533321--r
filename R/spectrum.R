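#' Welch power-spectral-density estimate
#'
#' Averaged modified periodogram: the series is split into overlapping
#' segments, each segment is mean-detrended and Hann-tapered, and the
#' modulus-squared discrete Fourier transforms are averaged.  The returned
#' spectrum is one-sided, excludes the zero frequency, and is scaled as a
#' density so that sum(power) * df approximates the series variance.
#'
#' @param series numeric vector.
#' @param sampling_interval time between samples (sets the frequency axis).
#' @param segment_length samples per segment; when `NULL` it is chosen so
#'   that `n_segments` segments fit at the requested overlap.
#' @param overlap fractional overlap between segments (default 0.5).
#' @param n_segments target number of segments when `segment_length` is
#'   `NULL` (default 8).
#' @return an object of class `spectrum_fit` with `frequencies`, `power`,
#'   the segmentation used, and (after [powerlaw_fit()]) the log-log fit
#'   diagnostics.
#' @export
psd <- function(series, sampling_interval = 1, segment_length = NULL,
                overlap = 0.5, n_segments = 8) {
  series <- as.numeric(series)
  n <- length(series)
  check_number(sampling_interval, "sampling_interval", lower = 0,
               strict_lower = TRUE)
  check_number(overlap, "overlap", lower = 0, upper = 0.95)
  if (is.null(segment_length)) {
    segment_length <- floor(n / (1 + (n_segments - 1) * (1 - overlap)))
    segment_length <- max(segment_length, 8L)
  }
  segment_length <- as.integer(segment_length)
  if (n < 2L * segment_length)
    stop(sprintf(
      "series too short for PSD: need at least %d samples (2 segments), got %d",
      2L * segment_length, n), call. = FALSE)
  hop <- max(1L, as.integer(floor(segment_length * (1 - overlap))))
  starts <- seq.int(1L, n - segment_length + 1L, by = hop)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, segment_length - 1) /
                        (segment_length - 1)))  # Hann taper
  scale <- sampling_interval / sum(w^2)
  nf <- segment_length %/% 2L
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- series[s0:(s0 + segment_length - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)
    p <- scale * Mod(X[2L:(nf + 1L)])^2
    p <- 2 * p
    if (segment_length %% 2L == 0L) p[nf] <- p[nf] / 2  # Nyquist not doubled
    acc <- acc + p
  }
  structure(list(frequencies = seq_len(nf) / (segment_length *
                                                sampling_interval),
                 power = acc / length(starts),
                 segment_length = segment_length,
                 n_segments_used = length(starts),
                 sampling_interval = sampling_interval,
                 loglog_slope = NA_real_, loglog_curvature = NA_real_,
                 r_squared = NA_real_, fit_band = NULL),
            class = "spectrum_fit")
}

#' Average a PSD across an ensemble of traces
#'
#' Computes [psd()] with identical segmentation for every trace and
#' averages the power, sharpening spectral shape estimates for the
#' power-law diagnostics.
#'
#' @param traces list of numeric vectors or trace objects of equal length.
#' @param ... passed to [psd()].
#' @return a `spectrum_fit`.
#' @export
ensemble_psd <- function(traces, ...) {
  if (!is.list(traces)) traces <- list(traces)
  specs <- lapply(traces, function(tr) psd(as_series(tr), ...))
  out <- specs[[1]]
  if (length(specs) > 1) {
    for (s in specs[-1]) {
      if (length(s$power) != length(out$power))
        stop("all traces must have equal length", call. = FALSE)
      out$power <- out$power + s$power
    }
    out$power <- out$power / length(specs)
  }
  out
}

#' Power-law diagnostics of a spectrum
#'
#' Least-squares fit of log10 power against log10 frequency inside
#' `fit_band`.  The linear fit gives the spectral slope (the exponent of a
#' power-law model P ~ f^slope) and its R-squared; the quadratic
#' coefficient of a second-order fit on the same points measures the
#' curvature of the spectrum in log-log coordinates -- near-zero curvature
#' means the spectrum is power-law-like, as expected at a critical point,
#' while substantial curvature means a power law is a poor description.
#'
#' @param spectrum a `spectrum_fit` from [psd()] or [ensemble_psd()].
#' @param fit_band numeric `c(f_lo, f_hi)`; the default drops the two
#'   lowest frequency bins and fits up to the Nyquist frequency.  Pass a
#'   band below the pacing frequency for the paced automaton, whose
#'   spectra carry pacing harmonics.
#' @return the `spectrum_fit` with `loglog_slope`, `loglog_curvature`,
#'   `r_squared`, `fit_band` and `n_dropped` (non-positive power values
#'   excluded from the fit) filled in.
#' @export
powerlaw_fit <- function(spectrum, fit_band = NULL) {
  stopifnot(inherits(spectrum, "spectrum_fit"))
  f <- spectrum$frequencies
  p <- spectrum$power
  if (is.null(fit_band)) {
    if (length(f) < 3L)
      stop("spectrum has too few bins for a fit band", call. = FALSE)
    fit_band <- c(f[3L], max(f))
  }
  if (fit_band[1] >= fit_band[2])
    stop("'fit_band' must satisfy f_lo < f_hi", call. = FALSE)
  sel <- f >= fit_band[1] & f <= fit_band[2]
  n_dropped <- sum(sel & p <= 0)
  sel <- sel & p > 0
  if (!any(sel))
    stop("all power values inside the fit band are non-positive",
         call. = FALSE)
  if (sum(sel) < 8L)
    stop(sprintf("need at least 8 usable frequency bins in the fit band, got %d",
                 sum(sel)), call. = FALSE)
  lf <- log10(f[sel])
  lp <- log10(p[sel])
  lin <- lm(lp ~ lf)
  quad <- lm(lp ~ lf + I(lf^2))
  spectrum$loglog_slope <- unname(coef(lin)[2])
  spectrum$loglog_curvature <- unname(coef(quad)[3])
  # suppressed: lm warns on exactly log-linear input ("perfect fit")
  spectrum$r_squared <- suppressWarnings(summary(lin)$r.squared)
  spectrum$fit_band <- fit_band
  spectrum$n_dropped <- n_dropped
  spectrum
}

#' @export
print.spectrum_fit <- function(x, ...) {
  cat(sprintf("PSD: %d bins, f in [%.4g, %.4g] (%d segments of %d)\n",
              length(x$frequencies), min(x$frequencies),
              max(x$frequencies), x$n_segments_used, x$segment_length))
  if (!is.na(x$loglog_slope))
    cat(sprintf(
      "  power-law fit on [%.4g, %.4g]: slope = %.3f, curvature = %.3f, R^2 = %.4f\n",
      x$fit_band[1], x$fit_band[2], x$loglog_slope, x$loglog_curvature,
      x$r_squared))
  invisible(x)
}
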