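#' Read and write binned intensity traces (columnar CSV)
#'
#' Columns: `time_s`, `DexDem`, `DexAem`, `AexAem`, `AexDem`.
#'
#' @param traces an `intensity_traces` object
#' @param path file path
#' @return `write_traces`: the path, invisibly; `read_traces`: an
#'   `intensity_traces` object
#' @export
write_traces <- function(traces, path) {
  stopifnot(inherits(traces, "intensity_traces"))
  n <- nrow(traces$counts)
  df <- data.frame(time_s = (seq_len(n) - 1) * traces$bin_us * 1e-6,
                   traces$counts)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  need <- c("time_s", "DexDem", "DexAem", "AexAem", "AexDem")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("malformed traces file: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  bin_s <- if (nrow(df) > 1) df$time_s[2] - df$time_s[1] else 1e-6
  intensity_traces(as.matrix(df[, need[-1]]), bin_us = bin_s * 1e6,
                   duration_s = nrow(df) * bin_s)
}

#' Read and write correlation curves (CSV with a metadata header)
#'
#' Plain CSV with columns `lag_s`, `G`, `stderr`, preceded by `#`-prefixed
#' header lines carrying the channel pair and gating/binning metadata.
#'
#' @param curve a `corr_curve`
#' @param path file path
#' @return `write_curve`: the path, invisibly; `read_curve`: a `corr_curve`
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "corr_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# channel_pair: %s", curve$channel_pair), con)
  for (k in names(curve$meta))
    writeLines(sprintf("# %s: %s", k, paste(curve$meta[[k]], collapse = " ")), con)
  df <- as.data.frame(curve)
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(apply(df, 1, function(r)
    paste(formatC(r, format = "g", digits = 15), collapse = ",")), con)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  pair <- "GG"
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    if (key == "channel_pair") pair <- val else meta[[key]] <- val
  }
  body <- lines[!grepl("^#", lines)]
  df <- read.csv(text = paste(body, collapse = "\n"))
  for (col in c("lag_s", "G"))
    if (!col %in% names(df))
      stop("malformed curve file: missing column ", col)
  se <- if ("stderr" %in% names(df) && !all(is.na(df$stderr))) df$stderr else NULL
  correlation_curve(df$lag_s, df$G, stderr = se, channel_pair = pair,
                    meta = meta)
}

#' Read and write fit results (JSON)
#'
#' Serialises an [fcs_fit()] as a JSON object with one record per parameter
#' (value, standard error, fixed flag), the model name, the fixed `kappa`,
#' and fit diagnostics.  Time constants are stored in seconds.
#'
#' @param fit an `fcs_fit`
#' @param path file path
#' @return `write_fit`: the path, invisibly; `read_fit`: a named list (not a
#'   refittable object)
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "fcs_fit"))
  out <- list(
    model = fit$model, kappa = fit$kappa,
    units = list(time = "s"),
    parameters = lapply(names(fit$par), function(p) list(
      name = p, value = fit$par[[p]], stderr = fit$se[[p]],
      fixed = fit$fixed[[p]])),
    chi2 = fit$chi2, reduced_chi2 = fit$reduced_chi2,
    converged = fit$converged, at_bounds = as.list(fit$at_bounds),
    n_lags = fit$n)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$parameters) || is.null(x$model))
    stop("malformed fit file: missing field 'parameters' or 'model'")
  pars <- setNames(x$parameters$value, x$parameters$name)
  list(model = x$model, kappa = x$kappa, par = pars,
       se = setNames(x$parameters$stderr, x$parameters$name),
       fixed = setNames(x$parameters$fixed, x$parameters$name),
       chi2 = x$chi2, reduced_chi2 = x$reduced_chi2,
       converged = x$converged)
}

#' Read and write photon streams (columnar text container)
#'
#' Plain tab-separated container for time-tagged photon records with
#' Photon-HDF5-compatible field naming: `#`-prefixed attribute lines
#' (`sync_period_ns`, `duration_s`, `config_digest`, `seed`) followed by the
#' columns `channel`, `macrotime`, `microtime_ns`.
#'
#' @param stream a `photon_stream`
#' @param path file path
#' @return `write_photons`: the path, invisibly; `read_photons`: a
#'   `photon_stream`
#' @export
write_photons <- function(stream, path) {
  stopifnot(inherits(stream, "photon_stream"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sync_period_ns: %.9g", stream$sync_period_ns), con)
  writeLines(sprintf("# duration_s: %.9g", stream$duration_s), con)
  if (!is.null(stream$meta$red_pulse_delay_ns))
    writeLines(sprintf("# red_pulse_delay_ns: %.9g",
                       stream$meta$red_pulse_delay_ns), con)
  if (!is.null(stream$meta$config_digest))
    writeLines(sprintf("# config_digest: %s", stream$meta$config_digest), con)
  if (!is.null(stream$meta$seed))
    writeLines(sprintf("# seed: %d", stream$meta$seed), con)
  writeLines("channel\tmacrotime\tmicrotime_ns", con)
  rec <- stream$records
  writeLines(sprintf("%s\t%.0f\t%.9g", rec$channel, rec$macrotime,
                     rec$microtime_ns), con)
  invisible(path)
}

#' @rdname write_photons
#' @export
read_photons <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  attrs <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    attrs[[sub(":.*$", "", kv)]] <- trimws(sub("^[^:]*:", "", kv))
  }
  for (field in c("sync_period_ns", "duration_s"))
    if (is.null(attrs[[field]]))
      stop("malformed photon file: missing attribute ", field)
  body <- lines[!grepl("^#", lines)]
  df <- read.delim(text = paste(body, collapse = "\n"))
  need <- c("channel", "macrotime", "microtime_ns")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("malformed photon file: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  meta <- list()
  if (!is.null(attrs$config_digest)) meta$config_digest <- attrs$config_digest
  if (!is.null(attrs$seed)) meta$seed <- as.integer(attrs$seed)
  if (!is.null(attrs$red_pulse_delay_ns))
    meta$red_pulse_delay_ns <- as.numeric(attrs$red_pulse_delay_ns)
  photon_stream(df$channel, df$macrotime, df$microtime_ns,
                sync_period_ns = as.numeric(attrs$sync_period_ns),
                duration_s = as.numeric(attrs$duration_s), meta = meta)
}

#' Read a pipeline configuration file (YAML)
#'
#' Sections: `titration` (with `ligand_concs`) and `simulation`
#' ([fccs_config()] argument overrides).
#'
#' @param path YAML file path
#' @return named list
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}
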