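# Shared fixtures, memoised so expensive objects (the calibrated model and
# its holding state) are built once per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

default_model <- function() memo("model", build_model())

default_holding <- function(dt = 0.025) {
  memo(paste0("holding_", dt), set_holding(default_model(), dt = dt))
}

default_calibration <- function() {
  memo("calibration", calibrate_model(default_model()))
}

# A small two-cluster sweep spec mirroring the midline-evoked E/I latency
# structure (E 1.92 +/- 0.25 ms, I 4.47 +/- 0.50 ms after the stimulus).
two_cluster_spec <- function(n_sweeps = 40, noise_rms = 4, seed = 42,
                             holding_potential = -60, prob_e = 1, prob_i = 1) {
  cl <- dplyr::bind_rows(
    cluster_gen_spec("excitatory", 1.92, 0.25, prob_e, 80, 10, 0.25, 2.23),
    cluster_gen_spec("inhibitory", 4.47, 0.50, prob_i, 70, 10, 0.40, 3.51)
  )
  sweep_gen_spec(n_sweeps, 40, stim_times = 5, clusters = cl,
                 holding_potential = holding_potential,
                 noise_rms = noise_rms, seed = seed)
}

# Isotropic Gaussian mixture in 3 features with centres `sep` SDs apart
# along the first axis; returns a plain matrix.
gaussian_blobs <- function(k, n_per, sep = 8, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(k), function(j) {
    cbind(rnorm(n_per, mean = (j - 1) * sep), rnorm(n_per), rnorm(n_per))
  }))
}
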