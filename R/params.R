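#' Default model parameters for histaminergic transmission
#'
#' Returns the full kinetic parameter set of the compartmental histamine
#' model. Defaults are read from the versioned configuration file shipped
#' with the package (`inst/extdata/control_params.yaml`), whose control set
#' is calibrated so that the resting extracellular histamine concentration
#' is 5.32 uM and a standard 2 s stimulation evokes a peak in the 5-10 uM
#' band with a clearance half-life of 2-6 s.
#'
#' Parameter groups (units):
#' \describe{
#'   \item{bHT}{clamped blood histidine concentration (uM)}
#'   \item{V_HTL, K_HTL}{histidine transporter Vmax (uM/s) and Km (uM)}
#'   \item{k_pool_in, k_pool_out}{histidine pool exchange rates (1/s)}
#'   \item{V_HTDC, K_HTDC}{histidine decarboxylase Vmax (uM/s) and Km (uM)}
#'   \item{k_cht_loss}{first-order consumption of cytosolic histidine by
#'     competing pathways (1/s)}
#'   \item{V_MAT, K_MAT}{vesicular packaging (VMAT2) Vmax (uM/s) and Km (uM)}
#'   \item{k_rel}{release rate constant (1/s per unit firing drive)}
#'   \item{f0, f_stim}{basal firing drive and stimulation multiplier
#'     (dimensionless)}
#'   \item{V_HAT, K_HAT}{extracellular clearance Vmax (uM/s) and Km (uM)}
#'   \item{K_HAT_gi}{trans-side inhibition constant of clearance by glial
#'     histamine (uM); encodes reuptake slowing as the intracellular
#'     concentration gradient builds}
#'   \item{V_HNMT_g, K_HNMT_g, V_HNMT_c, K_HNMT_c}{glial and cytosolic
#'     N-methyltransferase Vmax (uM/s) and Km (uM)}
#'   \item{k_on, k_off}{H3 autoreceptor binding (1/(uM s)) and unbinding (1/s)}
#'   \item{k_Gact, k_Gdeact, k_Tact, k_Tdeact}{G-protein / RGS cascade rates
#'     (1/s)}
#'   \item{alpha}{H3 autoreceptor strength (dimensionless; control 0.9)}
#'   \item{gstar_eq}{reference active-G fraction used to normalise feedback}
#'   \item{s_strength, s_window}{depth (in [0,1]) and [start, end] times (s)
#'     of the H1-triggered retrograde inhibition of release}
#' }
#'
#' @param config path to a YAML parameter file; defaults to the shipped
#'   control configuration.
#' @return an object of class `ha_params` (named list of numerics with a
#'   `s_window` length-2 vector and an `applied_presets` attribute).
#' @export
#' @examples
#' p <- ha_params()
#' p$alpha
ha_params <- function(config = NULL) {
  if (is.null(config)) {
    cached <- get0("default_params", envir = .histadyn_cache)
    if (!is.null(cached)) return(cached)
    config <- system.file("extdata", "control_params.yaml",
                          package = "histadyn", mustWork = TRUE)
    p <- load_params(config)
    assign("default_params", p, envir = .histadyn_cache)
    return(p)
  }
  load_params(config)
}

.histadyn_cache <- new.env(parent = emptyenv())

#' Read a model parameter configuration file
#'
#' The file is YAML with nested sections (synthesis, packaging, release,
#' clearance, metabolism, autoreceptor, retrograde) and a `format_version`
#' field; files declaring a newer format than the package understands are
#' rejected.
#'
#' @param path path to a YAML file following the shipped schema.
#' @return an `ha_params` object.
#' @export
load_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  ver <- cfg$format_version
  if (is.null(ver)) stop("parameter file lacks a format_version field")
  if (ver > 1L) {
    stop("parameter file format_version ", ver,
         " is newer than this package understands (1)")
  }
  flat <- list()
  for (section in setdiff(names(cfg), "format_version")) {
    sec <- cfg[[section]]
    if (is.list(sec)) flat[names(sec)] <- sec else flat[[section]] <- sec
  }
  flat$s_window <- as.numeric(unlist(flat$s_window))
  missing <- setdiff(.param_names, names(flat))
  if (length(missing)) {
    stop("parameter file is missing: ", paste(missing, collapse = ", "))
  }
  p <- structure(lapply(flat[.param_names], as.numeric),
                 class = "ha_params", applied_presets = character(0))
  validate_params(p)
  p
}

.param_names <- c(
  "bHT", "V_HTL", "K_HTL", "k_pool_in", "k_pool_out",
  "V_HTDC", "K_HTDC", "k_cht_loss",
  "V_MAT", "K_MAT", "k_rel", "f0", "f_stim",
  "V_HAT", "K_HAT", "K_HAT_gi",
  "V_HNMT_g", "K_HNMT_g", "V_HNMT_c", "K_HNMT_c",
  "k_on", "k_off", "k_Gact", "k_Gdeact", "k_Tact", "k_Tdeact",
  "alpha", "gstar_eq", "s_strength", "s_window"
)

#' Validate a model parameter set
#'
#' Checks nonnegativity of every rate and Michaelis constant, `alpha >= 0`,
#' `s_strength` in [0, 1], and an ordered retrograde-inhibition window.
#'
#' @param params an `ha_params` object or plain named list.
#' @return `params`, invisibly, if valid; otherwise an error.
#' @export
validate_params <- function(params) {
  for (nm in .param_names) {
    v <- params[[nm]]
    if (is.null(v) || !is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
      stop("parameter '", nm, "' is missing or non-finite")
    }
  }
  scalars <- setdiff(.param_names, "s_window")
  neg <- scalars[vapply(scalars, function(nm) params[[nm]] < 0, logical(1))]
  if (length(neg)) {
    stop("negative parameter(s): ", paste(neg, collapse = ", "))
  }
  if (params$s_strength > 1) stop("s_strength must lie in [0, 1]")
  w <- params$s_window
  if (length(w) != 2L || w[1] >= w[2]) {
    stop("s_window must be c(start, end) with start < end")
  }
  invisible(params)
}

#' Write a parameter set to a YAML configuration file
#'
#' @param params an `ha_params` object.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  validate_params(params)
  cfg <- list(
    format_version = 1L,
    units_note = "concentrations uM, times s, rates 1/s, Vmax uM/s, Km uM",
    supply = params[c("bHT", "V_HTL", "K_HTL", "k_pool_in", "k_pool_out")],
    synthesis = params[c("V_HTDC", "K_HTDC", "k_cht_loss")],
    packaging = params[c("V_MAT", "K_MAT")],
    release = params[c("k_rel", "f0", "f_stim")],
    clearance = params[c("V_HAT", "K_HAT", "K_HAT_gi")],
    metabolism = params[c("V_HNMT_g", "K_HNMT_g", "V_HNMT_c", "K_HNMT_c")],
    autoreceptor = params[c("k_on", "k_off", "k_Gact", "k_Gdeact",
                            "k_Tact", "k_Tdeact", "alpha", "gstar_eq")],
    retrograde = list(s_strength = params$s_strength,
                      s_window = as.list(params$s_window))
  )
  yaml::write_yaml(cfg, path, precision = 12L)
  invisible(path)
}

#' @export
print.ha_params <- function(x, ...) {
  cat("Histamine kinetic model parameters\n")
  cat(sprintf("  alpha (H3 strength): %.3g   s_strength: %.3g  window [%g, %g] s\n",
              x$alpha, x$s_strength, x$s_window[1], x$s_window[2]))
  cat(sprintf("  V_HAT: %.4g uM/s  K_HAT: %.3g uM  (clearance)\n",
              x$V_HAT, x$K_HAT))
  cat(sprintf("  f0: %.3g  f_stim: %.3g  k_rel: %.3g 1/s\n",
              x$f0, x$f_stim, x$k_rel))
  ap <- attr(x, "applied_presets")
  if (length(ap)) cat("  presets applied:", paste(ap, collapse = ", "), "\n")
  invisible(x)
}

#' Stimulation protocol
#'
#' Describes one electrical stimulation epoch. Only the onset and duration
#' enter the simulation (the firing drive is a square pulse); frequency,
#' current and pulse width are carried as metadata because the 10 Hz
#' sampling of the recordings cannot resolve individual 2 ms pulses.
#'
#' @param t_start stimulation onset (s); default 5.
#' @param duration stimulation length (s); default 2.
#' @param frequency pulse train frequency (Hz), metadata; default 60.
#' @param current stimulation current (uA), metadata; default 360.
#' @param pulse_width pulse width (ms), metadata; default 2.
#' @return an object of class `stim_protocol`.
#' @export
stim_protocol <- function(t_start = 5, duration = 2, frequency = 60,
                          current = 360, pulse_width = 2) {
  if (!is.numeric(t_start) || t_start < 0) stop("t_start must be >= 0")
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0")
  structure(list(t_start = t_start, duration = duration,
                 frequency = frequency, current = current,
                 pulse_width = pulse_width),
            class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("Stimulation: t = %g s for %g s (%g Hz, %g uA, %g ms pulses)\n",
              x$t_start, x$duration, x$frequency, x$current, x$pulse_width))
  invisible(x)
}

# Validate a model state vector (named), erroring on violations.
validate_state <- function(state) {
  need <- .state_names
  if (!all(need %in% names(state))) {
    stop("state must contain: ", paste(need, collapse = ", "))
  }
  s <- state[need]
  if (anyNA(s) || any(!is.finite(unlist(s)))) stop("non-finite model state")
  conc <- c("bHT", "cHT", "HTpool", "cHA", "vHA", "eHA", "gHA")
  if (any(unlist(s[conc]) < 0)) stop("negative concentration in model state")
  frac <- c("bHA", "gstar", "tstar")
  if (any(unlist(s[frac]) < 0) || any(unlist(s[frac]) > 1)) {
    stop("receptor/G-protein fractions must lie in [0, 1]")
  }
  invisible(state)
}

.state_names <- c("bHT", "cHT", "HTpool", "cHA", "vHA", "eHA", "gHA",
                  "bHA", "gstar", "tstar")
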