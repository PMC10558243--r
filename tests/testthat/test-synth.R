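# Synthetic session generator: spike trains, rendering, whole sessions.

test_that("spike train respects rate, refractory and determinism contracts", {
  # zero rate forces no events
  expect_length(generate_spike_train(0, 10)$times, 0L)

  # invalid arguments
  expect_error(generate_spike_train(-1, 10), "rate")
  expect_error(generate_spike_train(10, 0), "duration")
  expect_error(generate_spike_train(300, 10, refractory = 0.004), "refractory")

  # ISI >= refractory and strict monotonicity, across seeds and rates
  for (seed in 1:20) {
    tr <- generate_spike_train(rate = 60, duration = 5, refractory = 0.004,
                               seed = seed)
    expect_true(all(tr$times >= 0 & tr$times < 5))
    expect_true(all(diff(tr$times) > 0))
    expect_true(all(diff(tr$times) >= 0.004 - 1e-12))
  }

  # determinism
  t1 <- generate_spike_train(80, 3, 0.004, seed = 42)
  t2 <- generate_spike_train(80, 3, 0.004, seed = 42)
  expect_identical(t1$times, t2$times)
})

test_that("spike counts match the Poisson oracle", {
  # rate 100 Hz x 10 s, no dead time: mean count over 200 seeds within
  # 3 * sqrt(1000) of the Poisson mean 1000
  counts <- vapply(1:200, function(s) {
    length(generate_spike_train(100, 10, refractory = 0, seed = s)$times)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 1000), 3 * sqrt(1000))
  # dead-time process preserves the requested mean rate too
  counts_r <- vapply(1:200, function(s) {
    length(generate_spike_train(100, 10, refractory = 0.004, seed = s)$times)
  }, numeric(1))
  expect_lt(abs(mean(counts_r) - 1000), 3 * sqrt(1000))
})

test_that("channel rendering is an exact superposition of templates", {
  fs <- 24414
  tpl <- spike_template(fs, amplitude = 10)

  empty <- structure(list(times = numeric(0), duration = 0.1),
                     class = "eng_spike_train")
  expect_equal(as.numeric(render_channel(empty, tpl, fs, noise_sd = 0)),
               numeric(round(0.1 * fs)))

  one <- structure(list(times = 0, duration = 0.1), class = "eng_spike_train")
  y <- render_channel(one, tpl, fs, noise_sd = 0)
  expect_equal(y[seq_along(tpl)], as.numeric(tpl))
  expect_equal(y[(length(tpl) + 1):length(y)],
               numeric(length(y) - length(tpl)))

  # direct-summation oracle with two non-overlapping events
  two <- structure(list(times = c(0.01, 0.05), duration = 0.1),
                   class = "eng_spike_train")
  y2 <- render_channel(two, tpl, fs, noise_sd = 0)
  ref <- numeric(round(0.1 * fs))
  for (t0 in two$times) {
    s0 <- round(t0 * fs) + 1
    ref[s0:(s0 + length(tpl) - 1)] <- ref[s0:(s0 + length(tpl) - 1)] + tpl
  }
  expect_equal(as.numeric(y2), ref)

  expect_error(render_channel(one, numeric(0), fs), "template")
})

test_that("generated sessions honor dead channels, balance and determinism", {
  cfg <- synth_config(n_channels = 8L, n_dead_channels = 5L,
                      segment_duration_s = 2, physio = FALSE, seed = 31L)
  s <- generate_session(cfg)

  expect_identical(sum(s$channel_status == "dead"), 5L)
  # dead channels are spike-free: no ground-truth events on them
  dead <- which(s$channel_status == "dead")
  expect_false(any(s$ground_truth$channel %in% dead))
  # ... but not flat: they carry noise
  expect_gt(stats::sd(s$signal[dead[1], ]), 0.5)

  # equal class durations, exactly
  durs <- s$intervals$end - s$intervals$start
  expect_identical(durs, rep(durs[1], 3))
  expect_identical(as.character(s$intervals$state),
                   c("baseline", "full", "micturition"))
  # intervals tile the signal, half-open
  expect_identical(s$intervals$start[-1], s$intervals$end[-3])
  expect_identical(s$intervals$end[3] - 1L, ncol(s$signal))
  expect_false(any(!is.finite(s$signal)))

  # bit-identical regeneration
  s2 <- generate_session(cfg)
  expect_identical(s$signal, s2$signal)
  expect_identical(s$ground_truth, s2$ground_truth)
})

test_that("physio traces follow the infusion protocol shape", {
  cfg <- synth_config(n_channels = 2L, n_dead_channels = 0L,
                      segment_duration_s = 4, seed = 5L)
  s <- generate_session(cfg)
  seg <- round(4 * cfg$fs_physio)
  vol <- s$physio$volume
  # flat at zero during baseline, monotone ramp while filling, capped at 150
  expect_true(all(vol[1:seg] == 0))
  expect_true(all(diff(vol[(seg + 1):(2 * seg)]) >= 0))
  expect_equal(max(vol), 150)
  # pressure rises from baseline towards micturition
  p <- s$physio$pressure
  expect_gt(mean(p[(2 * seg + 1):(3 * seg)]), mean(p[1:seg]) + 5)
})

test_that("per-state firing rates are recovered from noise-free renders", {
  # generator ground truth vs Poisson sampling error, QC-detected
  fs <- 24414
  dur <- 60
  tpl <- spike_template(fs, amplitude = 10)
  det <- spike_detect_spec(refractory_s = 0.0035)
  for (rate in c(5, 40, 80)) {
    tr <- generate_spike_train(rate, dur, refractory = 0.004,
                               seed = 1000 + rate)
    x <- render_channel(tr, tpl, fs, noise_sd = 0)
    found <- detect_spikes(x, fs, det)
    expect_lt(abs(length(found$times) - rate * dur),
              3 * sqrt(rate * dur) + 2)
  }
})

test_that("config validation rejects inconsistent parameters", {
  expect_error(synth_config(n_dead_channels = 40, n_channels = 32),
               "n_dead_channels")
  expect_error(synth_config(state_rates = c(baseline = -1, full = 10,
                                            micturition = 20)))
  expect_error(synth_config(refractory_s = 0))
  expect_error(synth_config(state_rates = c(baseline = 10, full = 40,
                                            micturition = 300)),
               "refractory")
})
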