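#' Read a flat key = value configuration file
#'
#' One `key = value` pair per line; blank lines and `#` comments are
#' ignored.  Values are returned as strings; [validate_config()] does the
#' typing and range checking.
#'
#' @param path file path.
#' @return a named list of character values.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "=", fixed = TRUE)[[1]]
    if (length(parts) < 2L)
      stop(sprintf("malformed config line (expected key = value): '%s'",
                   lines[i]), call. = FALSE)
    key <- trimws(parts[1])
    out[[key]] <- trimws(paste(parts[-1], collapse = "="))
  }
  out
}

#' Write a flat key = value configuration file
#'
#' @param config named list of scalar values (vectors are comma-joined).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    vals <- vapply(config[[k]], function(v) format(v, trim = TRUE),
                   character(1))
    sprintf("%s = %s", k, paste(vals, collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# recognized keys per system, plus alias hints for common slips
config_keys <- function(system) {
  common <- c("system", "n_runs", "base_seed", "out_dir")
  if (system == "kuramoto")
    c(common, "n_oscillators", "dt", "n_steps", "transient_steps", "thin",
      "freq_family", "freq_location", "freq_scale", "k_values", "sigmas")
  else
    c(common, "grid_size", "delta", "epsilon", "refractory_steps",
      "ms_per_step", "n_steps", "warmup_steps", "nu_values", "pacing",
      "base_ms", "half_width_ms", "sd_ms", "cv", "spectral_beta",
      "rr_file", "schedule_length")
}

config_aliases <- c(tau = "refractory_steps", taus = "refractory_steps",
                    sigma = "sigmas", noise_sigma = "sigmas",
                    seed = "base_seed", K = "k_values", k = "k_values",
                    nu = "nu_values", N = "n_oscillators",
                    runs = "n_runs", out = "out_dir")

num_field <- function(raw, key, default, lower = -Inf, upper = Inf,
                      integer = FALSE) {
  if (is.null(raw[[key]])) return(default)
  v <- suppressWarnings(as.numeric(raw[[key]]))
  if (is.na(v))
    stop(sprintf("config field '%s' must be numeric (got '%s')",
                 key, raw[[key]]), call. = FALSE)
  check_number(v, key, lower = lower, upper = upper, integer = integer)
  v
}

num_vec_field <- function(raw, key, default, lower = -Inf, upper = Inf) {
  if (is.null(raw[[key]])) return(default)
  v <- suppressWarnings(as.numeric(strsplit(as.character(raw[[key]]),
                                            ",")[[1]]))
  if (anyNA(v) || length(v) == 0L)
    stop(sprintf("config field '%s' must be a comma-separated numeric list",
                 key), call. = FALSE)
  if (any(v < lower) || any(v > upper))
    stop(sprintf("config field '%s' must lie in [%g, %g] (got %s)",
                 key, lower, upper, paste(v, collapse = ",")),
         call. = FALSE)
  v
}

#' Validate and type a raw experiment configuration
#'
#' Turns a raw key-value mapping (e.g. from [read_config()]) into a typed,
#' range-checked experiment configuration with documented defaults filled
#' in.  Unknown keys are rejected with the offending key named and, where
#' possible, the intended key suggested.
#'
#' @param raw named list of values (strings are fine).
#' @return an object of class `experiment_config`.
#' @export
validate_config <- function(raw) {
  stopifnot(is.list(raw))
  system <- raw[["system"]]
  if (is.null(system) || !system %in% c("kuramoto", "atrial"))
    stop("config field 'system' must be \"kuramoto\" or \"atrial\"",
         call. = FALSE)
  known <- config_keys(system)
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    key <- unknown[1]
    hint <- config_aliases[[key]]
    if (is.null(hint)) {
      near <- agrep(key, known, max.distance = 0.3, value = TRUE)
      hint <- if (length(near) > 0) near[1] else NULL
    }
    stop(sprintf("unknown config key '%s'%s", key,
                 if (!is.null(hint)) sprintf(" (did you mean '%s'?)", hint)
                 else ""),
         call. = FALSE)
  }
  cfg <- list(
    system = system,
    n_runs = as.integer(num_field(raw, "n_runs", 10, lower = 1,
                                  integer = TRUE)),
    base_seed = as.integer(num_field(raw, "base_seed", 1, integer = TRUE)),
    out_dir = if (is.null(raw[["out_dir"]])) NULL
              else as.character(raw[["out_dir"]]))
  if (system == "kuramoto") {
    cfg$n_oscillators <- as.integer(num_field(raw, "n_oscillators", 2000,
                                              lower = 1, integer = TRUE))
    cfg$dt <- num_field(raw, "dt", 0.01, lower = 1e-6)
    cfg$n_steps <- as.integer(num_field(raw, "n_steps", 20000, lower = 2,
                                        integer = TRUE))
    cfg$transient_steps <- as.integer(
      num_field(raw, "transient_steps", cfg$n_steps %/% 2, lower = 0,
                integer = TRUE))
    if (cfg$transient_steps >= cfg$n_steps)
      stop("'transient_steps' must be < 'n_steps'", call. = FALSE)
    cfg$thin <- as.integer(num_field(raw, "thin", 50, lower = 1,
                                     integer = TRUE))
    fam <- if (is.null(raw[["freq_family"]])) "gaussian"
           else as.character(raw[["freq_family"]])
    cfg$freq_dist <- freq_dist(fam,
                               num_field(raw, "freq_location", 0),
                               num_field(raw, "freq_scale", 1,
                                         lower = 0))
    cfg$k_values <- num_vec_field(raw, "k_values",
                                  seq(0, 3.5, by = 0.1), lower = 0)
    cfg$sigmas <- num_vec_field(raw, "sigmas", c(0, 0.5, 1), lower = 0)
    if (any(diff(cfg$k_values) <= 0))
      stop("'k_values' must be strictly increasing", call. = FALSE)
  } else {
    cfg$grid_size <- as.integer(num_field(raw, "grid_size", 200, lower = 2,
                                          integer = TRUE))
    cfg$delta <- num_field(raw, "delta", 0.05, lower = 0, upper = 1)
    cfg$epsilon <- num_field(raw, "epsilon", 0.05, lower = 0, upper = 1)
    cfg$refractory_steps <- as.integer(
      num_field(raw, "refractory_steps", 50, lower = 1, integer = TRUE))
    cfg$ms_per_step <- num_field(raw, "ms_per_step", 0.06, lower = 1e-6)
    cfg$n_steps <- as.integer(num_field(raw, "n_steps", 20000, lower = 1,
                                        integer = TRUE))
    cfg$warmup_steps <- as.integer(num_field(raw, "warmup_steps", 2000,
                                             lower = 0, integer = TRUE))
    cfg$nu_values <- num_vec_field(raw, "nu_values",
                                   seq(0.02, 0.25, by = 0.01),
                                   lower = 0, upper = 1)
    if (any(diff(cfg$nu_values) <= 0))
      stop("'nu_values' must be strictly increasing", call. = FALSE)
    pac <- if (is.null(raw[["pacing"]])) "fixed"
           else trimws(strsplit(as.character(raw[["pacing"]]), ",")[[1]])
    bad <- setdiff(pac, c("fixed", "uniform", "gaussian", "rr_file",
                          "rr_synthetic"))
    if (length(bad) > 0)
      stop(sprintf("unknown pacing regime '%s'", bad[1]), call. = FALSE)
    cfg$pacing <- pac
    cfg$base_ms <- num_field(raw, "base_ms", 13.2, lower = 1e-3)
    cfg$half_width_ms <- num_field(raw, "half_width_ms", 1.3, lower = 0)
    cfg$sd_ms <- num_field(raw, "sd_ms", 1.3, lower = 0)
    cfg$cv <- num_field(raw, "cv", 0.1, lower = 0)
    cfg$spectral_beta <- num_field(raw, "spectral_beta", 1, lower = 0,
                                   upper = 2)
    cfg$rr_file <- if (is.null(raw[["rr_file"]])) NULL
                   else as.character(raw[["rr_file"]])
    if ("rr_file" %in% pac && is.null(cfg$rr_file))
      stop("pacing regime 'rr_file' requires config field 'rr_file'",
           call. = FALSE)
    cfg$schedule_length <- as.integer(
      num_field(raw, "schedule_length", 2048, lower = 16, integer = TRUE))
  }
  structure(cfg, class = "experiment_config")
}
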