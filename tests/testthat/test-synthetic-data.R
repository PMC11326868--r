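test_that("sweep generation is deterministic and validates its spec", {
  spec <- two_cluster_spec(n_sweeps = 5, seed = 7)
  a <- generate_sweep_set(spec)
  b <- generate_sweep_set(spec)
  expect_identical(a$traces, b$traces)
  expect_identical(a$ground_truth, b$ground_truth)

  expect_error(sweep_gen_spec(0, 40, 5, moc_cluster_presets()), "n_sweeps")
  expect_error(sweep_gen_spec(5, 40, 45, moc_cluster_presets()), "stim_times")
  expect_error(sweep_gen_spec(5, 40, 5, moc_cluster_presets(),
                              sampling_rate = 15), "sampling_rate")
  expect_error(cluster_gen_spec("excitatory", 2, 0.2, 1.4, 50, 5, 0.3, 3),
               "probability")
  expect_error(cluster_gen_spec("excitatory", 2, 0.2, 0.5, 50, 5, 3, 0.3),
               "tau_rise")
})

test_that("noise-free unit-probability sweeps contain one identical event each", {
  cl <- cluster_gen_spec("excitatory", 2, 0, 1, 60, 0, 0.25, 2.5)
  spec <- sweep_gen_spec(10, 30, stim_times = 5, clusters = cl,
                         noise_rms = 0, seed = 3)
  ss <- generate_sweep_set(spec)
  expect_equal(nrow(ss$ground_truth), 10)
  expect_true(all(ss$ground_truth$onset_ms == 7))
  # all sweeps bit-identical
  expect_true(all(apply(ss$traces, 2, function(col) length(unique(col)) == 1)))
  # unit-peak waveform scaled by rendered amplitude (inward at -60)
  expect_lt(abs(min(ss$traces[1, ]) + 60), 0.1)
})

test_that("event occurrence matches the cluster probability", {
  cl <- cluster_gen_spec("excitatory", 2, 0.1, 0.45, 60, 5, 0.25, 2.5)
  spec <- sweep_gen_spec(1000, 20, stim_times = 5, clusters = cl,
                         noise_rms = 0, seed = 11)
  ss <- generate_sweep_set(spec)
  frac <- length(unique(ss$ground_truth$sweep)) / 1000
  expect_lt(abs(frac - 0.45), 0.05)
})

test_that("polarity follows holding potential and class reversal", {
  # both classes inward at -60 mV
  gt60 <- generate_sweep_set(two_cluster_spec(10, noise_rms = 0))$ground_truth
  expect_true(all(gt60$amplitude_pa < 0))
  # at 0 mV excitatory events vanish, inhibitory events are outward
  gt0 <- generate_sweep_set(
    two_cluster_spec(10, noise_rms = 0, holding_potential = 0))$ground_truth
  expect_true(all(gt0$amplitude_pa[gt0$label == "excitatory"] == 0))
  expect_true(all(gt0$amplitude_pa[gt0$label == "inhibitory"] > 0))
  # at the chloride reversal (-20 mV) inhibitory events vanish
  gt20 <- generate_sweep_set(
    two_cluster_spec(10, noise_rms = 0, holding_potential = -20))$ground_truth
  expect_true(all(gt20$amplitude_pa[gt20$label == "inhibitory"] == 0))
})

test_that("baseline noise RMS is calibrated", {
  cl <- cluster_gen_spec("excitatory", 2, 0, 0, 60, 0, 0.25, 2.5)
  spec <- sweep_gen_spec(1, 2500, stim_times = 1, clusters = cl,
                         noise_rms = 5, seed = 5)   # 125000 samples
  ss <- generate_sweep_set(spec)
  expect_lt(abs(sqrt(mean(ss$traces^2)) - 5) / 5, 0.05)
})

test_that("sweep sets round-trip through plain-text files", {
  ss <- generate_sweep_set(two_cluster_spec(3, seed = 9))
  path <- file.path(withr::local_tempdir(), "sweeps")
  write_sweep_set(ss, path)
  back <- read_sweep_set(path)
  expect_equal(back$traces, ss$traces, tolerance = 1e-6)
  expect_equal(back$stim_times, ss$stim_times)
  expect_equal(nrow(back$ground_truth), nrow(ss$ground_truth))
})

test_that("feature tables carry the seven features and honour class medians", {
  expect_error(generate_feature_table(0), "n_per_class")
  tab <- generate_feature_table(400, seed = 21)
  expect_setequal(levels(tab$label), c("excitatory", "inhibitory"))
  expect_true(all(c("rise_time", "decay_tau", "amplitude", "probability",
                    "onset_jitter", "peak_jitter", "age") %in% names(tab)))
  med <- tab |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(rise = median(.data$rise_time))
  # medians track the generating means (0.63 E vs 0.86 I) within MC error
  expect_lt(abs(med$rise[med$label == "excitatory"] - 0.63), 0.05)
  expect_lt(abs(med$rise[med$label == "inhibitory"] - 0.86), 0.05)
})

test_that("calcium generator obeys suppression and validation rules", {
  expect_error(calcium_gen_spec(stim_bout_frames = c(16, 31, 90)),
               "stim_bout_frames")
  expect_error(calcium_gen_spec(baseline_frames = 20), "baseline")
  # full suppression + no noise -> blocked movie flat at baseline
  spec <- calcium_gen_spec(n_rois = 4, suppression_factor = 1, noise_sd = 0,
                           seed = 2)
  blocked <- generate_calcium_movie(spec, "blocked")
  per_roi_range <- blocked$traces |>
    dplyr::group_by(.data$roi) |>
    dplyr::summarise(r = diff(range(.data$f)))
  expect_true(all(per_roi_range$r < 1e-9))
  # zero suppression -> control and blocked identical under one seed
  spec0 <- calcium_gen_spec(n_rois = 4, suppression_factor = 0, seed = 2)
  expect_identical(generate_calcium_movie(spec0, "control")$traces,
                   generate_calcium_movie(spec0, "blocked")$traces)
})
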