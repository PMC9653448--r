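test_that("spike detection finds embedded APs and ignores quiet traces", {
  sim <- simulateSweepSet(smallSweepConfig(), seed = 1)
  v <- sweepVoltages(sim$sweeps)
  dt <- samplingInterval(sim$sweeps)
  peaks <- detectActionPotentials(v[, "d2"], dt, 150, 500)
  truth_idx <- round(sim$truth$spike_times_ms$d2 / dt) + 1
  expect_equal(length(peaks), length(truth_idx))
  expect_true(all(abs(peaks - truth_idx) <= 1))

  flat <- rep(-70, 5000)
  expect_length(detectActionPotentials(flat, dt), 0)

  set.seed(1)
  noisy <- rep(-60, 25000) + rnorm(25000, 0, 0.5)
  expect_length(detectActionPotentials(noisy, dt, 100, 400), 0)
})

test_that("threshold search truncates near the trace start", {
  # a synthetic rise starting almost immediately
  dt <- 0.02
  t <- seq(0, 5, by = dt)
  v <- -60 + 80 * exp(-exp(-(t - 0.5) / 0.2))
  pk <- which.max(v)
  thr <- apThreshold(v, dt, pk, smooth_ms = 0)
  expect_true(is.finite(thr$voltage))
  expect_lt(thr$index, pk)
  expect_error(apThreshold(v, dt, peak_index = 3), "samples before")
})

test_that("waveform features match hand geometry on a triangular AP", {
  dt <- 0.02
  # baseline 0; rise 0 -> 80 over 1 ms; fall 80 -> 0 over 2 ms
  up <- seq(0, 80, length.out = 51)
  down <- seq(80, 0, length.out = 101)[-1]
  v <- c(rep(0, 100), up, down, rep(0, 200))
  pk <- 100 + 51
  thr <- list(voltage = 0, frac_index = 100, index = 100)
  wf <- apWaveformFeatures(v, dt, pk, thr, smooth_ms = 0)
  # the kinked vertex makes sub-sample refinement overshoot very slightly
  expect_equal(wf$amplitude_mV, 80, tolerance = 1e-3)
  # half height 40 crossed at 0.5 ms and 2.0 ms after rise onset
  expect_equal(wf$width_ms, 1.5, tolerance = dt)
  expect_equal(wf$rising_time_ms, 51 * dt, tolerance = 0.02)
  expect_equal(wf$decay_time_ms, 2.0, tolerance = 0.03)
})

test_that("AHP is threshold minus the post-spike trough", {
  dt <- 0.02
  up <- seq(-40, 30, length.out = 40)
  down <- seq(30, -55, length.out = 60)[-1]
  rec <- seq(-55, -45, length.out = 150)[-1]
  v <- c(rep(-40, 150), up, down, rec)
  pk <- 150 + 40
  thr <- list(voltage = -40, frac_index = 150, index = 150)
  wf <- apWaveformFeatures(v, dt, pk, thr, smooth_ms = 0)
  expect_true(wf$ahp_available)
  expect_equal(wf$ahp_mV, 15, tolerance = 0.05)
})

test_that("rheobase is the weakest spiking current, with its delay", {
  cfg <- sweepSimConfig(total_ms = 700, onset_ms = 100, offset_ms = 500,
                        hyper_currents_pA = numeric(0),
                        depol_currents_pA = c(50, 100, 150),
                        rheobase_pA = 100)
  sim <- simulateSweepSet(cfg, seed = 1)
  rd <- rheobaseAndDelay(sim$sweeps)
  expect_true(rd$available)
  expect_equal(rd$rheobase_pA, 100)
  expect_equal(rd$spike_delay_ms, sim$truth$spike_delay_ms,
               tolerance = 0.05)
})

test_that("protocols without spikes or without hyperpolarization flag
           the corresponding features unavailable", {
  only_hyper <- simulateSweepSet(
    sweepSimConfig(depol_currents_pA = numeric(0), dt_ms = 0.1), seed = 1)
  f1 <- extractFeatureTable(only_hyper$sweeps)
  av1 <- featureAvailable(f1)
  expect_false(any(av1[c("rheobase_pA", "ap_threshold_mV",
                         "ap_amplitude_mV", "adaptive_index")]))
  expect_true(all(av1[c("rmp_mV", "tau_ms", "sag_ratio",
                        "input_resistance_MOhm")]))

  only_depol <- simulateSweepSet(
    smallSweepConfig(hyper_currents_pA = numeric(0)), seed = 1)
  f2 <- extractFeatureTable(only_depol$sweeps)
  av2 <- featureAvailable(f2)
  expect_false(any(av2[c("rmp_mV", "tau_ms", "sag_ratio", "rebound_mV",
                         "input_resistance_MOhm")]))
  expect_true(av2[["rheobase_pA"]])
  expect_true(all(is.na(featureValues(f2)[!av2])))
})

test_that("sag ratio follows its defining formula on a shaped trace", {
  # RMP -70, trough -90, steady -85  ->  sag = 20/15
  dt <- 0.1
  t <- seq(0, 1000, by = dt)
  v <- rep(-70, length(t))
  stim <- t >= 200 & t <= 800
  v[stim] <- -85
  v[t >= 240 & t <= 260] <- -90   # trough well before the last 100 ms
  ss <- SweepSet(matrix(v, dimnames = list(NULL, "h1")),
                 data.frame(sweep_id = "h1", current_pA = -100,
                            onset_ms = 200, offset_ms = 800), dt)
  pf <- passiveMembraneFeatures(ss)
  expect_equal(pf$rmp_mV, -70)
  expect_equal(pf$sag_ratio, 20 / 15, tolerance = 1e-6)
  expect_equal(pf$input_resistance_MOhm, 150, tolerance = 1e-6)
})

test_that("adaptive index needs at least three spikes", {
  expect_false(adaptiveIndex(c(10, 20))$available)
  expect_equal(adaptiveIndex(c(0, 10, 25, 45))$adaptive_index, 2.0)
  expect_equal(adaptiveIndex(c(0, 15, 30))$adaptive_index, 1.0)
  expect_error(adaptiveIndex(c(10, 10, 20)), "strictly increasing")
})

test_that("noiseless features recover sweep truth within tolerances", {
  sim <- simulateSweepSet(sweepSimConfig(noise_sd_mV = 0), seed = 1)
  tr <- sim$truth
  v <- featureValues(extractFeatureTable(sim$sweeps))
  dt <- samplingInterval(sim$sweeps)
  expect_equal(v[["rmp_mV"]], tr$rmp_mV, tolerance = 1e-8)
  expect_lt(abs(v[["ap_threshold_mV"]] - tr$ap_threshold_mV), 1)
  expect_lt(abs(v[["ap_amplitude_mV"]] - tr$ap_amplitude_mV), 0.1)
  expect_lt(abs(v[["ap_width_ms"]] - tr$ap_width_ms), dt)
  expect_lt(abs(v[["tau_ms"]] - tr$tau_ms) / tr$tau_ms, 0.02)
  expect_lt(abs(v[["sag_ratio"]] - tr$sag_ratio), 1e-6)
  expect_lt(abs(v[["input_resistance_MOhm"]] - tr$input_resistance_MOhm) /
              tr$input_resistance_MOhm, 0.01)
  expect_identical(v[["adaptive_index"]], tr$adaptive_index)
  expect_equal(v[["rheobase_pA"]], tr$rheobase_pA)
  expect_lt(abs(v[["spike_delay_ms"]] - tr$spike_delay_ms), 0.05)
  expect_lt(abs(v[["ap_rising_time_ms"]] - tr$ap_rising_time_ms), 0.05)
  expect_lt(abs(v[["ap_decay_time_ms"]] - tr$ap_decay_time_ms), 0.05)
  expect_lt(abs(v[["ahp_mV"]] - tr$ahp_mV), 0.1)
  expect_lt(abs(v[["rebound_mV"]] - tr$rebound_mV), 0.01)
  # extracted amplitude is internally consistent
  expect_lt(v[["ap_width_ms"]],
            v[["ap_rising_time_ms"]] + v[["ap_decay_time_ms"]])
})

test_that("time features agree between 20 kHz and 50 kHz sampling", {
  f50 <- featureValues(extractFeatureTable(
    simulateSweepSet(sweepSimConfig(dt_ms = 0.02), seed = 1)$sweeps))
  f20 <- featureValues(extractFeatureTable(
    simulateSweepSet(sweepSimConfig(dt_ms = 0.05), seed = 1)$sweeps))
  for (nm in c("ap_width_ms", "ap_rising_time_ms", "ap_decay_time_ms",
               "spike_delay_ms")) {
    expect_lt(abs(f50[[nm]] - f20[[nm]]), 0.05)
  }
  expect_lt(abs(f50[["tau_ms"]] - f20[["tau_ms"]]), 0.1)
})

test_that("input resistance is invariant to the Ohmic sweep subset", {
  cfg <- sweepSimConfig(hyper_currents_pA = c(-120, -80, -40),
                        depol_currents_pA = numeric(0), dt_ms = 0.1,
                        sag_extra_mV = 0, rebound_mV = 0)
  sim <- simulateSweepSet(cfg, seed = 1)
  full <- passiveMembraneFeatures(sim$sweeps)$input_resistance_MOhm
  subset_ss <- SweepSet(sweepVoltages(sim$sweeps)[, 1:2],
                        sweepProtocol(sim$sweeps)[1:2, ],
                        samplingInterval(sim$sweeps))
  sub <- passiveMembraneFeatures(subset_ss)$input_resistance_MOhm
  expect_equal(full, sub, tolerance = 1e-6)
})

test_that("feature container enforces the 14-feature contract", {
  sim <- simulateSweepSet(smallSweepConfig(), seed = 1)
  f <- extractFeatureTable(sim$sweeps)
  expect_s4_class(f, "EphysFeatures")
  expect_length(featureValues(f), 14)
  expect_named(featureValues(f), names(featureAvailable(f)))
  expect_true(all(is.na(featureValues(f)[!featureAvailable(f)])))
})
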