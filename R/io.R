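#' Write an evoked trace to CSV with a YAML sidecar
#'
#' The CSV holds columns `time_s,value`; the sidecar (`<path>.yaml`) records
#' the format version, analyte, units, stimulation metadata and
#' baseline-subtraction flag so the file round-trips losslessly.
#'
#' @param trace an [evoked_trace()].
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "evoked_trace"))
  df <- data.frame(time_s = trace$times, value = trace$values)
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(format_version = 1L,
               analyte = trace$analyte,
               units = if (trace$analyte == "histamine") "uM" else "nM",
               stim_start_s = trace$stim_start,
               stim_duration_s = trace$stim_duration,
               is_baseline_subtracted = trace$is_baseline_subtracted)
  yaml::write_yaml(side, paste0(path, ".yaml"))
  invisible(path)
}

#' Read an evoked trace from CSV plus sidecar
#'
#' Validates the header, grid uniformity and declared units. If the sidecar
#' declares `units: nA` together with a `calibration_factor_uM_per_nA`, the
#' current is converted to concentration on read.
#'
#' @param path CSV path with columns `time_s,value`.
#' @param sidecar sidecar path; defaults to `<path>.yaml`.
#' @return an [evoked_trace()].
#' @export
read_trace_csv <- function(path, sidecar = paste0(path, ".yaml")) {
  side <- yaml::read_yaml(sidecar)
  if (is.null(side$format_version)) stop("sidecar lacks format_version")
  if (side$format_version > 1L) {
    stop("trace file format_version ", side$format_version,
         " is newer than this package understands (1)")
  }
  df <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(df))) {
    stop("trace CSV must have columns time_s,value")
  }
  if (any(diff(df$time_s) <= 0) ||
      diff(range(diff(df$time_s))) > 1e-9) {
    stop("trace CSV grid is not strictly increasing and uniform")
  }
  values <- df$value
  units <- side$units
  expected <- if (side$analyte == "histamine") "uM" else "nM"
  if (identical(units, "nA")) {
    fac <- side$calibration_factor_uM_per_nA
    if (is.null(fac)) {
      stop("units are nA but no calibration_factor_uM_per_nA is declared")
    }
    values <- values * fac
  } else if (!identical(units, expected)) {
    stop("unknown units '", units, "' for analyte '", side$analyte,
         "' (expected ", expected, " or nA with a calibration factor)")
  }
  evoked_trace(df$time_s, values, analyte = side$analyte,
               stim_start = side$stim_start_s,
               stim_duration = side$stim_duration_s,
               is_baseline_subtracted = isTRUE(side$is_baseline_subtracted))
}

#' Write / read an ambient serotonin series
#'
#' CSV columns `minute,serotonin_nM`; the sidecar records the injection
#' minute and format version.
#'
#' @param series an [ambient_series()].
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_ambient_csv <- function(series, path) {
  s <- as_ambient_df(series)
  utils::write.csv(s[c("minute", "serotonin_nM")], path, row.names = FALSE)
  yaml::write_yaml(list(format_version = 1L,
                        injection_minute = s$injection_minute[1]),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_ambient_csv
#' @param sidecar sidecar path; defaults to `<path>.yaml`.
#' @export
read_ambient_csv <- function(path, sidecar = paste0(path, ".yaml")) {
  side <- yaml::read_yaml(sidecar)
  if (is.null(side$format_version) || side$format_version > 1L) {
    stop("ambient file has a missing or unsupported format_version")
  }
  df <- utils::read.csv(path)
  if (!all(c("minute", "serotonin_nM") %in% names(df))) {
    stop("ambient CSV must have columns minute,serotonin_nM")
  }
  ambient_series(df$minute, df$serotonin_nM, side$injection_minute)
}

#' Write a per-animal cohort metrics table to CSV
#'
#' @param metrics a data.frame as from [cohort_metrics()].
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path)
}

#' Run the full synthetic pipeline
#'
#' Generate a paired cohort and an ambient cohort, extract per-trace
#' metrics, fit the autoreceptor strength to the averaged post-condition
#' trace, run the cohort statistics, and write every artifact (trace CSVs,
#' metrics CSV, fit JSON, stats CSV) together with a run manifest recording
#' the package version, seed, configuration digest and input/output file
#' digests. Reruns with an identical manifest reproduce identical outputs.
#'
#' @param config a [gen_config()].
#' @param condition drug preset for the post condition; default "dph".
#' @param seed top-level integer seed; expanded deterministically per stage.
#' @param out_dir output directory (created if missing).
#' @return list with `metrics`, `fit`, `stats`, `manifest` (also written to
#'   `out_dir`).
#' @export
run_pipeline <- function(config, condition = "dph", seed, out_dir) {
  stopifnot(inherits(config, "gen_config"))
  if (missing(seed)) stop("seed is mandatory")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # stage seeds derived from the top-level seed, kept within 32-bit range
  seeds <- (seed * 1000L + c(1L, 2L, 3L)) %% .Machine$integer.max

  cohort <- gen_cohort(config, condition = condition, seed = seeds[1])
  metrics <- cohort_metrics(cohort)
  write_cohort_csv(metrics, file.path(out_dir, "cohort_metrics.csv"))

  mean_post <- cohort$animals[[1]]$post
  mean_post$values <- rowMeans(vapply(cohort$animals,
                                      function(a) a$post$values,
                                      numeric(length(mean_post$values))))
  write_trace_csv(mean_post, file.path(out_dir, "mean_post_trace.csv"))

  fit <- fit_autoreceptor(mean_post, config$params)
  fit_out <- list(estimate = as.list(fit$estimate), rss = fit$rss,
                  converged = fit$converged)
  jsonlite::write_json(fit_out, file.path(out_dir, "fit.json"),
                       auto_unbox = TRUE, digits = NA)

  pt <- paired_test(metrics$amp_max[metrics$condition == "control"],
                    metrics$amp_max[metrics$condition == "post"])
  th <- paired_test(metrics$t_half[metrics$condition == "control"],
                    metrics$t_half[metrics$condition == "post"])
  amb <- gen_ambient_series(config, seed = seeds[2])
  sl <- ancova_slopes(amb)
  write_ambient_csv(amb, file.path(out_dir, "ambient.csv"))
  stats_df <- data.frame(
    test = c("paired_t_amp", "paired_t_thalf", "ancova_interaction"),
    term = c("amp_max", "t_half", "segment:minute"),
    statistic = c(pt$statistic, th$statistic, sl$F),
    p = c(pt$p, th$p, sl$interaction_p),
    n = c(length(cohort$animals), length(cohort$animals), nrow(amb)))
  utils::write.csv(stats_df, file.path(out_dir, "stats.csv"),
                   row.names = FALSE)

  cfg_file <- file.path(out_dir, "config_used.yaml")
  write_params(config$params, cfg_file)
  outputs <- c("cohort_metrics.csv", "mean_post_trace.csv", "fit.json",
               "ambient.csv", "stats.csv", "config_used.yaml")
  manifest <- list(
    package = "histadyn",
    version = as.character(utils::packageVersion("histadyn")),
    seed = seed, stage_seeds = as.list(seeds), condition = condition,
    config_digest = unname(tools::md5sum(cfg_file)),
    output_digests = as.list(tools::md5sum(file.path(out_dir, outputs))),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(metrics = metrics, fit = fit, stats = stats_df,
                 manifest = manifest))
}
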