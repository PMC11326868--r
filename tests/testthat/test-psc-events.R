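test_that("baseline RMS noise is the mean-removed root mean square", {
  expect_equal(compute_rms_noise(rep(7, 500), 0.02, c(0, 5)), 0)
  # unit square wave, equal high/low time, mean removed -> RMS exactly 1
  sq <- rep(c(1, -1), each = 50, times = 5)
  expect_equal(compute_rms_noise(sq, 0.02, c(0, 10)), 1)
  expect_error(compute_rms_noise(rep(0, 100), 0.02, c(10, 20)), "outside")
  expect_error(compute_rms_noise(rep(0, 100), 0.02, c(0, 0.5)), "50 samples")
  # generator oracle: known noise_rms recovered from a blank sweep
  cl <- cluster_gen_spec("excitatory", 2, 0, 0, 60, 0, 0.25, 2.5)
  ss <- generate_sweep_set(sweep_gen_spec(1, 60, 30, cl, noise_rms = 5,
                                          seed = 8))
  expect_lt(abs(compute_rms_noise(ss$traces[1, ], ss$dt, c(0, 25)) - 5), 0.25)
})

test_that("detection applies the 2x-RMS threshold rule exactly", {
  dt <- 0.02
  n <- 2500  # 50 ms
  make_set <- function(amp) {
    trace <- numeric(n)
    # baseline pattern with RMS exactly 1 and zero median in any window
    a <- sqrt(3 / 2)
    trace[1:501] <- rep(c(a, 0, -a), 167)
    t <- (seq_len(n) - 1) * dt
    trace <- trace - amp * mocsyn::synapse_conductance(
      synapse_spec(0.5, 6, 1, 0, onset = 20), t)
    structure(list(traces = matrix(trace, nrow = 1), dt = dt,
                   holding_potential = -60, stim_times = 15,
                   ground_truth = tibble::tibble()), class = "sweep_set")
  }
  low <- detect_events(make_set(1.9), baseline_window = c(0, 10))
  high <- detect_events(make_set(2.1), baseline_window = c(0, 10))
  expect_equal(nrow(low), 0)
  expect_equal(nrow(high), 1)
  expect_lt(abs(high$amplitude + 2.1), 0.05)
})

test_that("degenerate sweeps are handled as specified", {
  flat <- structure(list(traces = matrix(0, 1, 1000), dt = 0.02,
                         holding_potential = -60, stim_times = 5,
                         ground_truth = tibble::tibble()),
                    class = "sweep_set")
  expect_equal(nrow(detect_events(flat)), 0)
  nas <- flat
  nas$traces[1, ] <- NA_real_
  expect_error(detect_events(nas), "NaN")
  deg <- flat
  deg$traces[1, 600] <- -50  # event but zero baseline RMS
  expect_error(detect_events(deg), "degenerate")
})

test_that("kinetic features are recovered from noise-free events", {
  dt <- 0.02
  t <- seq(0, 60, by = dt)
  trace <- -60 * mocsyn:::psc_waveform(t - 10, 0.2, 6)
  ev <- extract_features(trace, dt, peak_index = which.min(trace),
                         polarity = -1, stim_times = 8)
  expect_lt(abs(ev$amplitude + 60), 1)
  expect_lt(abs(ev$decay_tau - 6), 0.3)
  expect_lt(abs(ev$onset_latency - 2), 0.3)
  expect_lte(ev$rise_time, ev$time_to_peak)

  # near-instantaneous rise -> rise time bounded by discretisation
  step_tr <- c(rep(0, 500), -30 * exp(-seq(0, 40, by = dt) / 5))
  ev2 <- extract_features(step_tr, dt, peak_index = 501, polarity = -1)
  expect_lte(ev2$rise_time, 2 * dt + 1e-9)
})

test_that("single-exponential decay fits recover tau", {
  dt <- 0.02
  t <- seq(0, 25, by = dt)
  expect_lt(abs(fit_decay_tau(40 * exp(-t / 3.51), dt) - 3.51), 0.01)
  expect_true(is.na(fit_decay_tau(rep(5, 100), dt)))
  # Monte-Carlo: exponential + white noise at SNR 10, median within 5%
  set.seed(99)
  taus <- replicate(200, {
    fit_decay_tau(40 * exp(-t / 3.51) + rnorm(length(t), 0, 4), dt)
  })
  expect_lt(abs(median(taus, na.rm = TRUE) - 3.51) / 3.51, 0.05)
})

test_that("detected events recover the generator's latency structure", {
  ss <- generate_sweep_set(two_cluster_spec(n_sweeps = 60, noise_rms = 4,
                                            seed = 13))
  ev <- detect_events(ss)
  ev <- ev[!ev$spontaneous, ]
  # inhibitory cluster latency (4.47 ms) recovered by the median of the
  # later latency mode
  late <- ev$onset_latency[ev$onset_latency > 3.2]
  expect_lt(abs(median(late) - 4.47), 0.25)
  early <- ev$onset_latency[ev$onset_latency <= 3.2]
  expect_lt(abs(median(early) - 1.92), 0.25)
})

test_that("event tables round-trip as TSV", {
  ss <- generate_sweep_set(two_cluster_spec(5, seed = 3))
  ev <- detect_events(ss)
  path <- file.path(withr::local_tempdir(), "events.tsv")
  write_events_tsv(ev, path)
  back <- read_events_tsv(path)
  expect_equal(nrow(back), nrow(ev))
  expect_equal(back$onset_time, ev$onset_time, tolerance = 1e-6)
})
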