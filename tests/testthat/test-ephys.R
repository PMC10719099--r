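rate <- 20000

test_that("spike template hits its designed half width and amplitude", {
  for (hw in c(0.5, 1, 2)) {
    tmpl <- spikeTemplate(hw, amplitude = 1, sampling_rate = rate)
    expect_equal(min(tmpl), -1, tolerance = 1e-9)
    w <- halfPeakWidth(tmpl, rate)
    expect_lt(abs(w - hw), 1000 / rate)   # within one sample period
  }
})

test_that("cell-attached generation: determinism, Poisson rate, degenerate cases", {
  cfg <- EphysSimConfig(firing_rate_true = 2.5, noise_sd = 0, seed = 30L)
  a <- generateCellAttachedTrace(cfg, 10)
  b <- generateCellAttachedTrace(cfg, 10)
  expect_identical(a$trace, b$trace)
  expect_identical(a$spike_times, b$spike_times)

  silent <- generateCellAttachedTrace(
    EphysSimConfig(firing_rate_true = 0, noise_sd = 0.1), 10)
  expect_length(silent$spike_times, 0)

  # spike counts across seeds stay within Poisson error of rate * duration
  counts <- vapply(1:15, function(s) length(generateCellAttachedTrace(
    EphysSimConfig(firing_rate_true = 2.5, noise_sd = 0, seed = s),
    10)$spike_times), numeric(1))
  expect_lt(abs(mean(counts) - 25), 3 * sqrt(25 / 15))
  expect_error(generateCellAttachedTrace(
    EphysSimConfig(firing_rate_true = 150)), "overlap")
})

test_that("spike detection recovers planted spikes and enforces isolation", {
  # flat trace: nothing detected
  flat <- detectSpikesCellAttached(rnorm(10 * rate, 0, 0.1), rate)
  expect_length(flat$spike_times, 0)

  # planted spikes at SNR 10 are all recovered
  cfg <- EphysSimConfig(firing_rate_true = 2.5, spike_amplitude = 5,
                        noise_sd = 0.5, seed = 31L)
  tr <- generateCellAttachedTrace(cfg, 12)
  det <- detectSpikesCellAttached(tr$trace, rate, 0, 12)
  expect_equal(length(det$spike_times), length(tr$spike_times))
  expect_lt(max(abs(det$spike_times - tr$spike_times)), 0.001)

  # two spikes 3 ms apart are both rejected as non-single
  tmpl <- spikeTemplate(1, 5, rate)
  half <- (length(tmpl) - 1) / 2
  tr2 <- rnorm(2 * rate, 0, 0.05)
  for (t0 in c(1.000, 1.003)) {
    idx <- (round(t0 * rate) - half):(round(t0 * rate) + half) + 1
    tr2[idx] <- tr2[idx] + tmpl
  }
  det2 <- detectSpikesCellAttached(tr2, rate, 0, 2)
  expect_length(det2$spike_times, 0)
  expect_error(detectSpikesCellAttached(tr2, rate, 0, 5), "past the trace")
})

test_that("waveform normalization is exact and averaging preserves shape", {
  tmpl <- spikeTemplate(1, 5, rate)
  w <- rbind(tmpl + 2, 3 * tmpl - 1)      # offsets and scalings
  avg <- normalizeAndAverage(w, rate)
  expect_equal(min(avg), -1, tolerance = 1e-12)
  nb <- round(0.00375 * rate)
  expect_equal(mean(avg[seq_len(nb)]), 0, tolerance = 1e-12)
  # two identical waveforms average to either one
  same <- rbind(tmpl, tmpl)
  expect_equal(normalizeAndAverage(same, rate), tmpl / max(abs(tmpl)) * 1,
               tolerance = 1e-9, ignore_attr = TRUE)
  # epsilon noise keeps the averaged peak within epsilon of -1
  set.seed(32)
  eps <- 1e-3
  noisy <- t(replicate(20, tmpl + runif(length(tmpl), -eps, eps)))
  avgn <- normalizeAndAverage(noisy, rate)
  expect_lt(abs(min(avgn) + 1), 2 * eps)
})

test_that("half-peak width matches closed forms", {
  # symmetric triangle 0 -> -1 over 1 ms and back: width exactly 1 ms
  n1 <- rate / 1000
  tri <- c(rep(0, 100), seq(0, -1, length.out = n1 + 1),
           seq(-1, 0, length.out = n1 + 1)[-1], rep(0, 100))
  expect_equal(halfPeakWidth(tri, rate), 1, tolerance = 1e-9)

  # Gaussian spike: FWHM = 2 sigma sqrt(2 ln 2)
  sigma_ms <- 0.4
  t_ms <- seq(-5, 5, length.out = 10 * rate / 1000 + 1)
  gauss <- -exp(-(t_ms)^2 / (2 * sigma_ms^2))
  fwhm <- 2 * sigma_ms * sqrt(2 * log(2))
  expect_lt(abs(halfPeakWidth(gauss, rate) - fwhm), 1000 / rate)

  # rectangular pulse of 0.8 ms at -1
  npulse <- round(0.8 * rate / 1000)
  rect <- c(rep(0, 200), rep(-1, npulse), rep(0, 200))
  expect_lt(abs(halfPeakWidth(rect, rate) - 0.8), 1.5 * 1000 / rate)
  expect_error(halfPeakWidth(rep(0, 100) - 0.1, rate), "boundary|cross")
})

test_that("AP threshold follows the dV/dt rule on the worked example", {
  v <- c(-65, -64.9, -64.7, -64.0, -62.0)
  th <- apThreshold(v, rate)
  expect_equal(th$threshold, -64.7)
  # a constant ramp below the criterion (10 V/s) has no AP
  ramp <- -65 + seq_len(2000) * (10 * 1000 / rate) / 1000
  expect_error(apThreshold(ramp, rate), "no AP")
  # exponential onset: crossing within one sample of the analytic point
  tt <- seq(0, 0.01, by = 1 / rate)
  v2 <- -65 + 0.05 * exp(tt * 1000)          # dV/dt = 0.05e^t mV/ms
  d_per_sample <- 12 * 1000 / rate
  # analytic first sample where the forward difference reaches 0.6 mV
  dif <- diff(v2)
  i_true <- which(dif >= d_per_sample)[1]
  th2 <- apThreshold(v2, rate)
  expect_equal(th2$index, i_true)
})

test_that("AP features: amplitude, interpolated width, fAHP sign", {
  # triangular AP: linear rise from threshold, linear fall below it
  up <- seq(-65, -45, length.out = 50)          # subthreshold creep
  rise <- seq(-45, 15, length.out = 21)         # 3 mV/sample
  fall <- seq(15, -58, length.out = 31)[-1]
  tail <- seq(-58, -60, length.out = 100)
  v <- c(up, rise, fall, tail)
  f <- apFeatures(v, rate)
  expect_equal(f$threshold, -45, tolerance = 1e-9)
  expect_equal(f$peak, 15)
  expect_equal(f$amplitude, 60)
  expect_equal(f$fahp, -45 - min(v[which.max(v) + 1:80]))
  # analytic flank crossings of the -15 mV half level
  half_level <- -45 + 30
  t_up <- 50 + approx(rise, seq_along(rise), xout = half_level)$y
  vv <- c(rise, fall)
  i_dn <- max(which(vv >= half_level))
  t_dn <- 50 + i_dn + (vv[i_dn] - half_level) / (vv[i_dn] - vv[i_dn + 1])
  expect_equal(f$half_width_us, (t_dn - t_up) / rate * 1e6, tolerance = 1e-6)
  # simple subtraction examples
  expect_equal(f$peak - f$threshold, f$amplitude)
})

test_that("spontaneous rate counts APs per window", {
  ws <- generateWholeCellSweeps(EphysSimConfig(noise_sd = 0),
                                data.frame(current_pA = 300, duration_s = 1))
  v <- ws$sweeps[[1]]
  n_true <- length(ws$truth$spike_times[[1]])
  r <- spontaneousRate(v, rate, window_start = 0,
                       window_len = length(v) / rate)
  expect_equal(r * length(v) / rate, n_true)
  expect_equal(spontaneousRate(rep(-65, 10 * rate), rate), 0)
  expect_error(spontaneousRate(rep(-65, rate), rate, 0, 10), "exceeds")
})

test_that("input resistance recovers the slope in megaohm", {
  defl <- data.frame(current_pA = seq(0, -50, -10),
                     delta_mV = seq(0, -5, -1))
  expect_equal(inputResistance(defl), 100, tolerance = 1e-10)
  expect_equal(inputResistance(data.frame(current_pA = c(0, -10, -20),
                                          delta_mV = c(0, 0, 0))), 0)
  expect_error(inputResistance(data.frame(current_pA = 0, delta_mV = 0)),
               "three")
  # noisy ohmic cell: R = 150 Mohm recovered within 5%
  set.seed(33)
  ws <- generateWholeCellSweeps(
    EphysSimConfig(input_resistance_true = 150, noise_sd = 0.2),
    data.frame(current_pA = seq(0, -250, -50), duration_s = 0.5))
  i0 <- ws$step_window["start"]
  base <- vapply(ws$sweeps, function(v) mean(v[seq_len(i0 - 1)]), numeric(1))
  ss <- vapply(ws$sweeps, function(v)
    mean(v[(i0 + 0.4 * rate):(i0 + 0.5 * rate - 1)]), numeric(1))
  defl2 <- data.frame(current_pA = seq(0, -250, -50), delta_mV = ss - base)
  expect_lt(abs(inputResistance(defl2) - 150) / 150, 0.05)
})

test_that("F-I counts match the closed-form integrate-and-fire rate", {
  proto <- data.frame(current_pA = seq(0, 1000, 50), duration_s = 1)
  ws <- generateWholeCellSweeps(EphysSimConfig(noise_sd = 0), proto)
  fi <- fiCurve(ws$sweeps, proto$current_pA, rate)
  expect_equal(fi$current_pA, seq(0, 1000, 50))
  ana <- vapply(proto$current_pA, lifSpikeCount, numeric(1))
  expect_true(all(abs(fi$n_spikes - ana) <= 1))
  expect_true(all(diff(fi$n_spikes) >= 0))          # nondecreasing F-I
  expect_equal(fi$n_spikes[1], 0)                   # 0 pA -> silent
  # missing sweep recorded as NA, not zero
  sw2 <- ws$sweeps; sw2[[3]] <- NULL; sw2 <- c(sw2[1:2], list(NULL), sw2[3:20])
  fi2 <- fiCurve(sw2, proto$current_pA, rate)
  expect_true(is.na(fi2$n_spikes[3]))
})

test_that("ohmic deflections obey Ohm's law exactly at zero noise", {
  ws <- generateWholeCellSweeps(
    EphysSimConfig(input_resistance_true = 100, noise_sd = 0),
    data.frame(current_pA = c(0, -50), duration_s = 0.5))
  expect_equal(ws$truth$deflection, c(0, -5))
  i0 <- ws$step_window["start"]
  v <- ws$sweeps[[2]]
  expect_equal(mean(v[(i0 + 0.45 * rate):(i0 + 0.5 * rate - 1)]) + 65,
               -5, tolerance = 0.01)
})

test_that("Mann-Whitney comparison matches exact enumeration and handles ties", {
  out <- compareGroups(c(1, 2, 3), c(10, 11, 12))
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 0.1, tolerance = 1e-12)   # 2/20 arrangements
  expect_equal(compareGroups(c(5, 5, 5), c(5, 5))$p_value, 1)
  same <- compareGroups(1:10, 1:10)
  expect_gt(same$p_value, 0.9)
  # null p-values are roughly uniform
  set.seed(34)
  ps <- replicate(300, compareGroups(rnorm(12), rnorm(12))$p_value)
  # exact p-values on n = 12 are discrete, hence tied; KS still applies
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})
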