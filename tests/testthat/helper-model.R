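# Shared fixtures: the default parameter set and a cache of noise-free
# simulations so slow ODE runs are shared across test files.

default_params <- ha_params()

.sim_cache <- new.env(parent = emptyenv())

# Noise-free evoked simulation for a preset, computed once per test run.
sim_preset <- function(preset = "control") {
  key <- preset
  got <- get0(key, envir = .sim_cache)
  if (!is.null(got)) return(got)
  p <- if (identical(preset, "control")) default_params
       else apply_preset(default_params, preset)
  sim <- simulate_evoked(p)
  assign(key, sim, envir = .sim_cache)
  sim
}

# Jittered but feasible random parameter set (multiplicative lognormal
# perturbation of the defaults; infeasible draws are rejected).
random_params <- function(sdlog = 0.1) {
  repeat {
    p <- default_params
    for (nm in setdiff(names(p), c("s_window", "f0", "alpha", "gstar_eq",
                                   "s_strength"))) {
      p[[nm]] <- p[[nm]] * stats::rlnorm(1, 0, sdlog)
    }
    ss <- tryCatch(steady_state(p), error = function(e) NULL)
    if (!is.null(ss)) return(p)
  }
}

# Synthetic monoexponential evoked trace: flat zero baseline, linear rise,
# then every sample from the first grid point at or after t_peak lying
# exactly on A*exp(-k*(t - t_peak)), so the decay is a pure exponential
# whatever the sampling phase.
exp_decay_trace <- function(A, k, t_peak = 7, times = seq(0, 30, by = 0.1)) {
  stim_start <- 5
  v <- numeric(length(times))
  dec <- times >= t_peak
  v[dec] <- A * exp(-k * (times[dec] - t_peak))
  i0 <- which(dec)[1]
  rise <- which(times >= stim_start & times < times[i0])
  v[rise] <- v[i0] * seq_along(rise) / (length(rise) + 1)
  evoked_trace(times, v, analyte = "histamine", stim_start = stim_start,
               stim_duration = 2, is_baseline_subtracted = TRUE)
}
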