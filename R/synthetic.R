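#' Per-minute ambient serotonin series
#'
#' @param minute strictly increasing minute indices.
#' @param serotonin_nM ambient serotonin concentrations (nM).
#' @param injection_minute injection breakpoint, inside the observed range.
#' @return an object of class `ambient_series` (a data.frame with an
#'   `injection_minute` column).
#' @export
ambient_series <- function(minute, serotonin_nM, injection_minute) {
  if (length(minute) != length(serotonin_nM)) {
    stop("minute and serotonin_nM must have equal length")
  }
  if (any(diff(minute) <= 0)) stop("minute indices must strictly increase")
  if (injection_minute < min(minute) || injection_minute > max(minute)) {
    stop("injection_minute must lie inside the observed range")
  }
  structure(data.frame(minute = as.numeric(minute),
                       serotonin_nM = as.numeric(serotonin_nM),
                       injection_minute = injection_minute),
            class = c("ambient_series", "data.frame"))
}

# Coerce an ambient_series (or equivalent data.frame) to a plain data.frame
as_ambient_df <- function(x) {
  if (inherits(x, "ambient_series")) return(as.data.frame(x))
  if (is.data.frame(x) && all(c("minute", "serotonin_nM") %in% names(x))) {
    if (!"injection_minute" %in% names(x)) {
      inj <- attr(x, "injection_minute")
      if (is.null(inj)) stop("missing injection_minute")
      x$injection_minute <- inj
    }
    return(as.data.frame(x))
  }
  stop("expected an ambient_series")
}

#' Synthetic-data generator configuration
#'
#' Bundles everything the generators need. Defaults emulate the study
#' conditions: 30 s evoked traces sampled at 10 Hz with a 2 s stimulation at
#' t = 5 s, histamine peaks in the 5-10 uM band decaying with a 2-6 s
#' half-life, concurrent serotonin dips of 30-50 nM, between-animal
#' variability matching reported SEM-to-mean ratios, and ambient serotonin
#' series with a near-flat 30 min control segment (slope 0.05 nM/min from a
#' 60.7 nM baseline) followed by a -0.21 nM/min post-injection drift over
#' 60 min.
#'
#' @param params model parameters; default [ha_params()].
#' @param protocol stimulation protocol; default [stim_protocol()].
#' @param trace_noise_sd iid Gaussian noise on histamine traces (uM);
#'   default 0.1.
#' @param dip_amp_nM,dip_lag_s,dip_recovery_s serotonin dip template: depth
#'   (nM), onset lag after stimulation (s), recovery time constant (s).
#' @param dip_noise_sd serotonin trace noise (nM); default 2.
#' @param n_animals cohort size; default 6.
#' @param animal_sdlog lognormal sd of the per-animal amplitude-scale
#'   multiplier; default 0.1 (about a 10% coefficient of variation).
#' @param ambient_baseline_nM ambient serotonin baseline (nM); default 60.7.
#' @param slope_pre,slope_post ambient drift (nM/min) before/after
#'   injection; defaults 0.05 and -0.21.
#' @param ambient_noise_sd ambient noise sd (nM); default 1.3.
#' @param n_pre,n_post minutes of control and post-injection recording;
#'   defaults 30 and 60.
#' @return a list of class `gen_config`.
#' @export
gen_config <- function(params = ha_params(), protocol = stim_protocol(),
                       trace_noise_sd = 0.1, dip_amp_nM = 40,
                       dip_lag_s = 0.5, dip_recovery_s = 4,
                       dip_noise_sd = 2, n_animals = 6, animal_sdlog = 0.1,
                       ambient_baseline_nM = 60.7, slope_pre = 0.05,
                       slope_post = -0.21, ambient_noise_sd = 1.3,
                       n_pre = 30, n_post = 60) {
  sds <- c(trace_noise_sd, dip_noise_sd, animal_sdlog, ambient_noise_sd)
  if (any(sds < 0)) stop("all noise/variability sds must be >= 0")
  if (n_animals < 1) stop("n_animals must be >= 1")
  structure(list(params = params, protocol = protocol,
                 trace_noise_sd = trace_noise_sd, dip_amp_nM = dip_amp_nM,
                 dip_lag_s = dip_lag_s, dip_recovery_s = dip_recovery_s,
                 dip_noise_sd = dip_noise_sd, n_animals = n_animals,
                 animal_sdlog = animal_sdlog,
                 ambient_baseline_nM = ambient_baseline_nM,
                 slope_pre = slope_pre, slope_post = slope_post,
                 ambient_noise_sd = ambient_noise_sd,
                 n_pre = n_pre, n_post = n_post),
            class = "gen_config")
}

# Smooth negative pulse: difference of exponentials normalised to depth
# `amp` (nM), starting `lag` s after stimulation onset.
.dip_template <- function(times, stim_start, amp, lag, recovery) {
  tau_on <- 0.8
  t0 <- stim_start + lag
  u <- pmax(times - t0, 0)
  shape <- exp(-u / recovery) - exp(-u / tau_on)
  shape[u == 0] <- 0
  peak <- max(shape)
  if (peak <= 0) return(rep(0, length(times)))
  -amp * shape / peak
}

#' Generate one synthetic evoked histamine/serotonin trace pair
#'
#' The histamine trace is the model simulation plus iid Gaussian noise; the
#' serotonin trace is a phenomenological smooth dip (difference of
#' exponentials at the configured depth, lag, and recovery) plus noise,
#' since the coupled serotonin kinetics are outside this model's scope.
#' Deterministic given `seed`.
#'
#' @param config a [gen_config()].
#' @param seed integer seed (mandatory for reproducibility).
#' @param amp_scale optional multiplier on the stimulation coupling
#'   (`f_stim - 1`) used for between-animal variability.
#' @return list with `histamine` and `serotonin` [evoked_trace()]s.
#' @export
gen_evoked_trace <- function(config, seed, amp_scale = 1) {
  stopifnot(inherits(config, "gen_config"))
  if (missing(seed)) stop("seed is mandatory")
  p <- config$params
  p$f_stim <- 1 + amp_scale * (p$f_stim - 1)
  sim <- simulate_evoked(p, config$protocol)
  ha <- sim$evoked
  times <- ha$times
  withr_seed <- .with_seed(seed)
  on.exit(withr_seed())
  ha$values <- ha$values + stats::rnorm(length(times),
                                        sd = config$trace_noise_sd)
  dip <- .dip_template(times, config$protocol$t_start,
                       amp_scale * config$dip_amp_nM,
                       config$dip_lag_s, config$dip_recovery_s)
  se <- evoked_trace(times, dip + stats::rnorm(length(times),
                                               sd = config$dip_noise_sd),
                     analyte = "serotonin",
                     stim_start = config$protocol$t_start,
                     stim_duration = config$protocol$duration,
                     is_baseline_subtracted = TRUE)
  list(histamine = ha, serotonin = se)
}

# Save/restore the RNG state around a seeded block.
.with_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Generate a paired synthetic cohort
#'
#' Per synthetic animal: draw one lognormal amplitude-scale multiplier
#' (shared animal effect), simulate the control condition and the
#' preset-applied condition with that multiplier, and add independent trace
#' noise. Deterministic given `seed`. When `animal_sdlog` is 0 the
#' noise-free base traces are simulated once and reused across animals.
#'
#' @param config a [gen_config()].
#' @param condition preset name for the post condition (see
#'   [drug_presets()]); "control" gives a null control-vs-control cohort.
#' @param seed integer seed.
#' @return list of class `ha_cohort`: per animal, `control` and `post`
#'   histamine [evoked_trace()]s plus the drawn `amp_scale`.
#' @export
gen_cohort <- function(config, condition = "control", seed) {
  stopifnot(inherits(config, "gen_config"))
  if (missing(seed)) stop("seed is mandatory")
  p_post <- apply_preset(config$params, condition)
  restore <- .with_seed(seed)
  on.exit(restore())
  n <- config$n_animals
  scales <- if (config$animal_sdlog > 0) {
    stats::rlnorm(n, meanlog = 0, sdlog = config$animal_sdlog)
  } else rep(1, n)

  sim_for <- function(params, scale) {
    p <- params
    p$f_stim <- 1 + scale * (p$f_stim - 1)
    simulate_evoked(p, config$protocol)$evoked
  }
  # cache noise-free traces per unique (condition, scale)
  base_ctrl <- if (config$animal_sdlog == 0) sim_for(config$params, 1)
  base_post <- if (config$animal_sdlog == 0) sim_for(p_post, 1)

  animals <- lapply(seq_len(n), function(i) {
    ctrl <- if (is.null(base_ctrl)) sim_for(config$params, scales[i])
            else base_ctrl
    post <- if (is.null(base_post)) sim_for(p_post, scales[i])
            else base_post
    m <- length(ctrl$values)
    ctrl$values <- ctrl$values + stats::rnorm(m, sd = config$trace_noise_sd)
    post$values <- post$values + stats::rnorm(m, sd = config$trace_noise_sd)
    list(animal = i, amp_scale = scales[i], control = ctrl, post = post)
  })
  structure(list(animals = animals, condition = condition, seed = seed),
            class = "ha_cohort")
}

#' @export
print.ha_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d animals, condition '%s' (seed %d)\n",
              length(x$animals), x$condition, x$seed))
  invisible(x)
}

#' Per-animal metrics table for a cohort
#'
#' @param cohort an `ha_cohort` from [gen_cohort()].
#' @return data.frame: `animal`, `condition` ("control"/"post"), `amp_max`,
#'   `t_half`.
#' @export
cohort_metrics <- function(cohort) {
  stopifnot(inherits(cohort, "ha_cohort"))
  do.call(rbind, lapply(cohort$animals, function(a) {
    data.frame(animal = a$animal,
               condition = c("control", "post"),
               amp_max = c(amp_max(a$control), amp_max(a$post)),
               t_half = c(as.numeric(half_life(a$control)),
                          as.numeric(half_life(a$post))))
  }))
}

#' Generate a synthetic ambient serotonin series (or cohort)
#'
#' Piecewise-linear mean: `baseline + slope_pre * minute` up to the
#' injection minute, continuous there, then drifting at `slope_post`; iid
#' Gaussian noise on top. Deterministic given `seed`.
#'
#' @param config a [gen_config()].
#' @param seed integer seed.
#' @param n_series number of series (animals); default 1.
#' @return an [ambient_series()] (or a list of them when `n_series > 1`).
#' @export
gen_ambient_series <- function(config, seed, n_series = 1) {
  stopifnot(inherits(config, "gen_config"))
  if (missing(seed)) stop("seed is mandatory")
  restore <- .with_seed(seed)
  on.exit(restore())
  minute <- seq_len(config$n_pre + config$n_post)
  inj <- config$n_pre
  mean_line <- ifelse(
    minute <= inj,
    config$ambient_baseline_nM + config$slope_pre * minute,
    config$ambient_baseline_nM + config$slope_pre * inj +
      config$slope_post * (minute - inj))
  one <- function() {
    ambient_series(minute,
                   mean_line + stats::rnorm(length(minute),
                                            sd = config$ambient_noise_sd),
                   injection_minute = inj)
  }
  if (n_series == 1L) one() else lapply(seq_len(n_series), function(i) one())
}
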