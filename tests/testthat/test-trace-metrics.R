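test_that("current converts to concentration by the calibration factors", {
  expect_equal(current_to_concentration(1, "histamine"), 2.8)
  expect_equal(current_to_concentration(1, "serotonin"), 11)
  expect_equal(current_to_concentration(0, "histamine"), 0)
  expect_equal(current_to_concentration(2.68, "histamine"), 7.504)
  expect_equal(current_to_concentration(c(1, 2), "serotonin"), c(11, 22))
  expect_error(current_to_concentration(NA_real_, "histamine"), "finite")
})

test_that("baseline is the pre-stimulation mean", {
  t <- seq(0, 30, by = 0.1)
  tr <- evoked_trace(t, rep(3.5, length(t)), "histamine", stim_start = 5)
  expect_equal(baseline(tr), 3.5)

  # symmetric pre-stimulation ramp 0 -> 1 averages to 1/2
  npre <- sum(t < 5)
  v <- c(seq(0, 1, length.out = npre), rep(1, length(t) - npre))
  tr2 <- evoked_trace(t, v, "histamine", stim_start = 5)
  expect_equal(baseline(tr2), 0.5)

  # seeded noise vs an independently coded mean
  set.seed(101)
  v3 <- c(rnorm(50), rep(0, length(t) - 50))
  tr3 <- evoked_trace(t, v3, "histamine", stim_start = 5)
  expect_equal(baseline(tr3), sum(v3[1:50]) / 50, tolerance = 1e-12)
})

test_that("amp_max is the post-stimulation maximum above baseline", {
  t <- seq(0, 30, by = 0.1)
  v <- numeric(length(t)); v[which.min(abs(t - 8))] <- 7.5
  tr <- evoked_trace(t, v, "histamine", stim_start = 5)
  expect_equal(amp_max(tr), 7.5)
  # invariant to a constant offset
  tr_off <- evoked_trace(t, v + 2.3, "histamine", stim_start = 5)
  expect_equal(amp_max(tr_off), 7.5)

  # simulated control trace vs a dense-grid maximum oracle
  coarse <- amp_max(sim_preset("control")$evoked)
  dense <- simulate_evoked(default_params,
                           grid = seq(0, 30, by = 0.01))$evoked
  dense_max <- max(dense$values)
  dt <- 0.1
  # a uniform sample can miss the true peak by at most the local curvature
  # over one sample interval; bound it from the dense solution near the peak
  ipk <- which.max(dense$values)
  win <- max(1, ipk - 50):min(length(dense$values), ipk + 50)
  curv <- max(abs(diff(diff(dense$values[win])))) / 0.01^2
  expect_lt(abs(coarse - dense_max), 0.5 * curv * dt^2 + 1e-9)
})

test_that("half-life inverts exact monoexponential decays", {
  tr <- exp_decay_trace(A = 7, k = log(2) / 3.1)
  th <- half_life(tr)
  expect_equal(as.numeric(th), 3.1, tolerance = 1e-6)
  expect_equal(attr(th, "method"), "exp_fit")

  tr2 <- exp_decay_trace(A = 5, k = 0.2)
  expect_equal(as.numeric(half_life(tr2)), log(2) / 0.2, tolerance = 1e-6)
})

test_that("half-life is sampling-phase invariant on exact exponentials", {
  for (tp in c(7, 7.03, 7.57, 8.249)) {
    k <- log(2) / 2.8
    tr <- exp_decay_trace(A = 6, k = k, t_peak = tp)
    expect_equal(as.numeric(half_life(tr)), 2.8, tolerance = 1e-6)
  }
})

test_that("half-life under noise stays within one sample interval of the crossing oracle", {
  k <- log(2) / 3
  clean <- exp_decay_trace(A = 8, k = k)
  # noise-free crossing-time oracle by linear interpolation
  ipk <- which.max(clean$values)
  y <- clean$values; t <- clean$times
  j <- which(y[ipk:length(y)] <= 4)[1] + ipk - 1L
  oracle <- t[j - 1] + (4 - y[j - 1]) * (t[j] - t[j - 1]) /
    (y[j] - y[j - 1]) - t[ipk]
  set.seed(11)
  noisy <- clean
  noisy$values <- noisy$values + rnorm(length(y), sd = 0.1)
  expect_lt(abs(as.numeric(half_life(noisy)) - oracle), 0.1)
})

test_that("serotonin inhibition amplitude measures the dip below baseline", {
  t <- seq(0, 30, by = 0.1)
  flat <- evoked_trace(t, rep(0, length(t)), "serotonin", stim_start = 5,
                       is_baseline_subtracted = TRUE)
  expect_equal(inhibition_amplitude(flat), 0)

  v <- rep(0, length(t)); v[t >= 6 & t <= 10] <- -45.3
  dip <- evoked_trace(t, v, "serotonin", stim_start = 5,
                      is_baseline_subtracted = TRUE)
  expect_equal(inhibition_amplitude(dip), 45.3)
  # offset invariance
  dip2 <- evoked_trace(t, v + 60, "serotonin", stim_start = 5)
  expect_equal(inhibition_amplitude(dip2), 45.3)

  # seeded noisy dip vs brute-force minimum oracle
  set.seed(3)
  vn <- v + rnorm(length(t), sd = 2)
  tr <- evoked_trace(t, vn, "serotonin", stim_start = 5,
                     is_baseline_subtracted = TRUE)
  expect_equal(inhibition_amplitude(tr), -min(vn[t >= 5]))
  expect_error(inhibition_amplitude(sim_preset("control")$evoked),
               "serotonin")
})

test_that("the histamine/serotonin ratio uses the tabulated mixed units", {
  r <- ha_5ht_ratio(7.5, 42.5)
  expect_equal(as.numeric(r), 7.5 / 42.5, tolerance = 1e-9)
  expect_equal(round(as.numeric(r), 5), 0.17647)
  expect_equal(attr(r, "units"), "uM/nM")
  expect_equal(as.numeric(ha_5ht_ratio(42.5, 42.5)), 1)
  expect_equal(as.numeric(ha_5ht_ratio(15, 42.5)),
               2 * as.numeric(ha_5ht_ratio(7.5, 42.5)))
  expect_error(ha_5ht_ratio(7.5, 0), "> 0")
})

test_that("percent change is anchored to the control amplitude", {
  expect_equal(percent_change(5, 5), 0)
  expect_equal(percent_change(5, 8.08), 61.6)
  expect_equal(percent_change(5, 0), -100)
  expect_error(percent_change(0, 5), "> 0")
})

test_that("zero-phase smoothing keeps DC and kills far stopband tones", {
  t <- seq(0, 30, by = 0.1)
  const <- evoked_trace(t, rep(2, length(t)), "histamine", stim_start = 5)
  expect_lt(max(abs(smooth_trace(const, 1)$values - 2)), 1e-10)

  # 4 Hz tone filtered at 1 Hz: amplitude down > 90%, checked spectrally
  tone <- evoked_trace(t, sin(2 * pi * 4 * t), "histamine", stim_start = 5,
                       is_baseline_subtracted = TRUE)
  sm <- smooth_trace(tone, 1)
  amp_at <- function(v, f) {
    n <- length(v)
    sp <- abs(stats::fft(v)) / n * 2
    freqs <- (seq_len(n) - 1) / n * 10
    sp[which.min(abs(freqs - f))]
  }
  expect_lt(amp_at(sm$values, 4) / amp_at(tone$values, 4), 0.1)

  # repeated filtering changes little beyond the first pass
  sm2 <- smooth_trace(sm, 1)
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(abs(rms(sm2$values) - rms(sm$values)),
            0.05 * rms(tone$values))
  expect_error(smooth_trace(tone, 6), "Nyquist")
})

test_that("the simulated control trace lands in the experimental bands", {
  m <- trace_metrics(sim_preset("control")$evoked)
  expect_gt(m$amp_max, 5); expect_lt(m$amp_max, 10)
  expect_gt(m$t_half, 2); expect_lt(m$t_half, 6)
})
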