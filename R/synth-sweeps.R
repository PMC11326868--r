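#' Specification of one latency-defined synthetic PSC cluster
#'
#' Describes a population of stimulus-locked postsynaptic currents: where
#' their onsets fall relative to each stimulus (Gaussian with mean
#' `mean_onset_latency` and SD `onset_jitter_sd`), how often they occur
#' (independent Bernoulli draw per stimulus per sweep with `probability`),
#' their amplitude distribution (truncated normal, stored as positive
#' magnitudes) and their biexponential kinetics.
#'
#' Polarity is applied at render time from the holding potential and the
#' class reversal potential (excitatory 0 mV; inhibitory -20 mV, the
#' chloride reversal of the high-chloride internal solution this emulates).
#'
#' @param label `"excitatory"` or `"inhibitory"`.
#' @param mean_onset_latency Mean onset latency after each stimulus, ms.
#' @param onset_jitter_sd SD of the onset latency, ms (>= 0).
#' @param probability Fraction of stimuli evoking an event, in `[0, 1]`.
#' @param amplitude_mean,amplitude_sd Amplitude magnitude distribution, pA.
#' @param tau_rise,tau_decay Waveform time constants, ms (`tau_rise <
#'   tau_decay`).
#' @return A one-row tibble.
#' @export
cluster_gen_spec <- function(label, mean_onset_latency, onset_jitter_sd,
                             probability, amplitude_mean, amplitude_sd,
                             tau_rise, tau_decay) {
  check_field(label %in% c("excitatory", "inhibitory"), "label",
              "must be 'excitatory' or 'inhibitory'")
  check_field(probability >= 0 && probability <= 1, "probability",
              "must be in [0, 1]")
  check_field(onset_jitter_sd >= 0, "onset_jitter_sd", "must be >= 0")
  check_field(tau_rise < tau_decay, "tau_rise", "must be < tau_decay")
  check_field(amplitude_mean > 0, "amplitude_mean",
              "amplitudes are stored as positive magnitudes")
  tibble::tibble(label = label, mean_onset_latency = mean_onset_latency,
                 onset_jitter_sd = onset_jitter_sd, probability = probability,
                 amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd,
                 tau_rise = tau_rise, tau_decay = tau_decay)
}

#' Reference excitatory and inhibitory cluster parameters
#'
#' Cluster generator settings parameterised by the recorded midline-evoked
#' EPSC/IPSC population medians (latency 1.92 vs 4.47 ms, jitter 0.25 vs
#' 0.50 ms, probability 0.80 vs 0.45, amplitude ~67 vs ~55 pA, decay 2.23
#' vs 3.51 ms); excitatory kinetics are strictly faster than inhibitory.
#'
#' @return A two-row tibble of cluster specifications.
#' @export
moc_cluster_presets <- function() {
  dplyr::bind_rows(
    cluster_gen_spec("excitatory", 1.92, 0.25, 0.80, 66.95, 20, 0.25, 2.23),
    cluster_gen_spec("inhibitory", 4.47, 0.50, 0.45, 55.39, 16, 0.40, 3.51)
  )
}

#' Specification of a synthetic PSC sweep set
#'
#' @param n_sweeps Number of sweeps.
#' @param duration Sweep length, ms.
#' @param stim_times Stimulus times, ms, all within `[0, duration)`.
#' @param clusters Tibble of cluster specifications ([cluster_gen_spec()]).
#' @param holding_potential Holding potential, mV (-60 shows both classes,
#'   0 isolates inhibitory events).
#' @param noise_rms Baseline noise RMS, pA.
#' @param sampling_rate Sampling rate, kHz (default 50).
#' @param noise_bandwidth Low-pass corner of the noise, kHz (default 10);
#'   must be below half the sampling rate.
#' @param seed Integer RNG seed.
#' @return A list of class `sweep_gen_spec`.
#' @export
sweep_gen_spec <- function(n_sweeps, duration, stim_times, clusters,
                           holding_potential = -60, noise_rms = 5,
                           sampling_rate = 50, noise_bandwidth = 10,
                           seed = 1) {
  check_field(n_sweeps >= 1, "n_sweeps", "must be >= 1")
  check_field(duration > 0, "duration", "must be > 0")
  check_field(all(stim_times >= 0 & stim_times < duration), "stim_times",
              "must lie within [0, duration)")
  check_field(!is.unsorted(stim_times, strictly = TRUE), "stim_times",
              "must be strictly increasing")
  check_field(sampling_rate > 2 * noise_bandwidth, "sampling_rate",
              "must exceed twice the noise bandwidth")
  check_field(noise_rms >= 0, "noise_rms", "must be >= 0")
  if (!is.data.frame(clusters) || nrow(clusters) == 0) {
    stop_field("clusters", "must be a non-empty tibble of cluster_gen_spec() rows")
  }
  structure(list(n_sweeps = as.integer(n_sweeps), duration = duration,
                 stim_times = stim_times, clusters = clusters,
                 holding_potential = holding_potential, noise_rms = noise_rms,
                 sampling_rate = sampling_rate,
                 noise_bandwidth = noise_bandwidth, seed = seed),
            class = "sweep_gen_spec")
}

# Driving-force factor turning a stored positive magnitude into a rendered
# signed amplitude.  Reversals: excitatory 0 mV, inhibitory -20 mV; the
# factor is normalised to magnitude 1 at -60 mV holding.
render_polarity <- function(label, holding) {
  e_rev <- ifelse(label == "excitatory", 0, -20)
  (holding - e_rev) / abs(-60 - e_rev)
}

# Unit-peak biexponential waveform at sample times t (ms) after onset.
psc_waveform <- function(t, tau_rise, tau_decay) {
  w <- numeric(length(t))
  pos <- t > 0
  w[pos] <- exp(-t[pos] / tau_decay) - exp(-t[pos] / tau_rise)
  w * biexp_norm_factor(tau_rise, tau_decay)
}

# Gaussian white noise low-pass filtered (4-pole Butterworth at
# `bandwidth_khz`) and rescaled to the requested RMS.
band_limited_noise <- function(n, rms, sampling_khz, bandwidth_khz) {
  if (rms == 0) return(numeric(n))
  x <- rnorm(n + 400)
  bf <- signal::butter(4, 2 * bandwidth_khz / sampling_khz, type = "low")
  y <- signal::filter(bf, x)
  y <- y[-seq_len(400)]  # discard filter transient
  as.numeric(y) * rms / sd(y)
}

#' Generate a synthetic PSC sweep set with ground truth
#'
#' Renders multicomponent voltage-clamp sweeps: for every sweep, stimulus
#' and cluster an event is drawn with the cluster's probability, its onset
#' jittered, and a unit-peak biexponential waveform scaled by the rendered
#' signed amplitude is summed into the trace; band-limited Gaussian noise is
#' added.  Identical spec and seed give identical output.
#'
#' @param spec A [sweep_gen_spec()].
#' @return A list of class `sweep_set` with `traces` (n_sweeps x n_samples
#'   matrix, pA), `dt` (ms), `holding_potential`, `stim_times`, and
#'   `ground_truth`: one row per injected event (`sweep`, `stim_index`,
#'   `cluster`, `label`, `onset_ms`, `amplitude_pa` signed,
#'   `magnitude_pa`, `tau_rise`, `tau_decay`).
#' @examples
#' spec <- sweep_gen_spec(5, 50, stim_times = 5, clusters = moc_cluster_presets())
#' ss <- generate_sweep_set(spec)
#' dim(ss$traces)
#' @export
generate_sweep_set <- function(spec) {
  stopifnot(inherits(spec, "sweep_gen_spec"))
  dt <- 1 / spec$sampling_rate
  n_samp <- as.integer(round(spec$duration / dt))
  times <- seq(0, by = dt, length.out = n_samp)
  with_seed(spec$seed, {
    traces <- matrix(0, nrow = spec$n_sweeps, ncol = n_samp)
    gt <- list()
    for (sw in seq_len(spec$n_sweeps)) {
      trace <- numeric(n_samp)
      for (si in seq_along(spec$stim_times)) {
        for (ci in seq_len(nrow(spec$clusters))) {
          cl <- spec$clusters[ci, ]
          if (rbinom(1, 1, cl$probability) == 0) next
          onset <- spec$stim_times[si] + rnorm(1, cl$mean_onset_latency,
                                               cl$onset_jitter_sd)
          mag <- rnorm_trunc(1, cl$amplitude_mean, cl$amplitude_sd, lower = 1)
          amp <- mag * render_polarity(cl$label, spec$holding_potential)
          if (abs(amp) > 0) {
            trace <- trace + amp * psc_waveform(times - onset,
                                                cl$tau_rise, cl$tau_decay)
          }
          gt[[length(gt) + 1L]] <- tibble::tibble(
            sweep = sw, stim_index = si, cluster = ci, label = cl$label,
            onset_ms = onset, amplitude_pa = amp, magnitude_pa = mag,
            tau_rise = cl$tau_rise, tau_decay = cl$tau_decay
          )
        }
      }
      traces[sw, ] <- trace + band_limited_noise(n_samp, spec$noise_rms,
                                                 spec$sampling_rate,
                                                 spec$noise_bandwidth)
    }
    ground_truth <- if (length(gt) > 0) dplyr::bind_rows(gt) else {
      tibble::tibble(sweep = integer(), stim_index = integer(),
                     cluster = integer(), label = character(),
                     onset_ms = numeric(), amplitude_pa = numeric(),
                     magnitude_pa = numeric(), tau_rise = numeric(),
                     tau_decay = numeric())
    }
    structure(list(traces = traces, dt = dt,
                   holding_potential = spec$holding_potential,
                   stim_times = spec$stim_times,
                   ground_truth = ground_truth, spec = spec),
              class = "sweep_set")
  })
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> %d sweeps x %d samples (dt %.3f ms), holding %g mV, %d true events\n",
              nrow(x$traces), ncol(x$traces), x$dt, x$holding_potential,
              nrow(x$ground_truth)))
  invisible(x)
}

#' @export
tidy.sweep_set <- function(x, ...) {
  tibble::tibble(
    sweep = rep(seq_len(nrow(x$traces)), each = ncol(x$traces)),
    time = rep(seq(0, by = x$dt, length.out = ncol(x$traces)), nrow(x$traces)),
    current = as.vector(t(x$traces))
  )
}

#' Write / read a sweep set as plain-text files
#'
#' Traces go to `<path>.csv` (one row per sweep), metadata to
#' `<path>_meta.yaml`, and ground truth (if any) to `<path>_truth.tsv`.
#'
#' @param x A `sweep_set`.
#' @param path Base path (no extension).
#' @return `write_sweep_set()` returns `path` invisibly; `read_sweep_set()`
#'   returns a `sweep_set`.
#' @export
write_sweep_set <- function(x, path) {
  stopifnot(inherits(x, "sweep_set"))
  write.table(x$traces, paste0(path, ".csv"), sep = ",",
              row.names = FALSE, col.names = FALSE)
  yaml::write_yaml(list(dt_ms = x$dt, holding_mV = x$holding_potential,
                        stim_times_ms = as.list(x$stim_times)),
                   paste0(path, "_meta.yaml"))
  if (nrow(x$ground_truth) > 0) {
    write.table(x$ground_truth, paste0(path, "_truth.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_sweep_set
#' @export
read_sweep_set <- function(path) {
  traces <- as.matrix(read.csv(paste0(path, ".csv"), header = FALSE))
  dimnames(traces) <- NULL
  meta <- yaml::read_yaml(paste0(path, "_meta.yaml"))
  truth_path <- paste0(path, "_truth.tsv")
  gt <- if (file.exists(truth_path)) {
    tibble::as_tibble(read.delim(truth_path))
  } else {
    tibble::tibble()
  }
  structure(list(traces = traces, dt = meta$dt_ms,
                 holding_potential = meta$holding_mV,
                 stim_times = unlist(meta$stim_times_ms),
                 ground_truth = gt, spec = NULL),
            class = "sweep_set")
}
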