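#' Root-mean-square baseline noise of a sweep
#'
#' RMS of the mean-removed segment of `sweep` inside `baseline_window`,
#' which must precede the first stimulus and contain at least 50 samples.
#'
#' @param sweep Numeric trace, pA.
#' @param dt Sample interval, ms.
#' @param baseline_window Two-element `c(from, to)` window, ms.
#' @return RMS noise in pA.
#' @examples
#' compute_rms_noise(rep(3, 500), dt = 0.02, baseline_window = c(0, 5))
#' @export
compute_rms_noise <- function(sweep, dt, baseline_window) {
  stopifnot(length(baseline_window) == 2, baseline_window[1] < baseline_window[2])
  idx_from <- floor(baseline_window[1] / dt) + 1L
  idx_to <- min(ceiling(baseline_window[2] / dt), length(sweep))
  if (idx_from < 1 || idx_from > length(sweep)) {
    abort("baseline_window lies outside the trace")
  }
  seg <- sweep[idx_from:idx_to]
  if (length(seg) < 50) abort("baseline_window must contain at least 50 samples")
  seg <- seg - mean(seg)
  sqrt(mean(seg^2))
}

# Expected deflection polarity given the holding potential: positive
# (outward) at holdings above the chloride reversal (-20 mV), else negative.
event_polarity <- function(holding) {
  if (holding > -20) 1 else -1
}

#' Detect PSC events in a sweep set
#'
#' Threshold detection in the polarity expected for the holding potential:
#' candidates are local extrema of a lightly smoothed trace whose deviation
#' from a local baseline (median of the preceding 2 ms) exceeds
#' `threshold_multiple` times the baseline RMS noise; candidates closer than
#' `refractory` keep only the larger.  A minimal shape filter then requires
#' the deflection to persist over the 0.3-1.3 ms after the peak (at half the
#' detection threshold), rejecting isolated noise excursions.  Accepted
#' candidates are passed to [extract_features()].
#'
#' Events with onset latency beyond `evoked_window` after the preceding
#' stimulus are flagged `spontaneous` and excluded from evoked analyses.
#'
#' @param sweep_set A `sweep_set` ([generate_sweep_set()] or
#'   [read_sweep_set()]).
#' @param threshold_multiple Detection threshold in units of baseline RMS
#'   (default 2).
#' @param refractory Minimum separation between event peaks, ms (default
#'   2; candidates closer than this are merged, keeping the larger).
#' @param baseline_window Window used for the RMS noise estimate, ms;
#'   defaults to the span before the first stimulus.
#' @param evoked_window Maximum evoked onset latency, ms (default 20).
#' @return A tibble of events: `sweep`, `onset_time`, `onset_latency`,
#'   `stim_index`, `rise_time`, `time_to_peak`, `amplitude` (signed pA),
#'   `decay_tau`, `holding_potential`, `spontaneous`, `fit_failed`.
#' @export
detect_events <- function(sweep_set, threshold_multiple = 2, refractory = 2,
                          baseline_window = NULL, evoked_window = 20) {
  stopifnot(inherits(sweep_set, "sweep_set"))
  dt <- sweep_set$dt
  stims <- sweep_set$stim_times
  if (is.null(baseline_window)) {
    baseline_window <- c(0, max(min(stims), 50 * dt))
  }
  pol <- event_polarity(sweep_set$holding_potential)
  out <- list()
  for (sw in seq_len(nrow(sweep_set$traces))) {
    trace <- sweep_set$traces[sw, ]
    if (all(is.na(trace))) abort(sprintf("sweep %d is all-NaN", sw))
    rms <- compute_rms_noise(trace, dt, baseline_window)
    if (rms == 0) {
      if (max(trace) == min(trace)) next  # flat trace: no events
      abort("zero baseline RMS with a nonzero threshold; degenerate input")
    }
    cand <- find_candidates(trace * pol, dt, rms * threshold_multiple,
                            refractory)
    for (j in seq_along(cand)) {
      pk <- cand[j]
      # cap the decay-fit window at the rise of the following event
      next_onset <- if (j < length(cand)) (cand[j + 1] - 1) * dt - 0.5 else NA
      ev <- extract_features(trace, dt, peak_index = pk, polarity = pol,
                             stim_times = stims,
                             holding_potential = sweep_set$holding_potential,
                             next_onset = next_onset)
      if (is.null(ev)) next
      ev$sweep <- sw
      out[[length(out) + 1L]] <- ev
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(sweep = integer(), onset_time = numeric(),
                          onset_latency = numeric(), stim_index = integer(),
                          rise_time = numeric(), time_to_peak = numeric(),
                          amplitude = numeric(), decay_tau = numeric(),
                          holding_potential = numeric(),
                          spontaneous = logical(), fit_failed = logical()))
  }
  ev <- dplyr::bind_rows(out)
  ev$spontaneous <- is.na(ev$onset_latency) | ev$onset_latency > evoked_window
  dplyr::relocate(ev, "sweep")
}

# Candidate peaks on the polarity-corrected trace `x` (events positive):
# local maxima of a short boxcar-smoothed trace exceeding `thr` above the
# local baseline, >= refractory apart, passing the persistence filter.
find_candidates <- function(x, dt, thr, refractory) {
  n <- length(x)
  ksm <- max(3L, round(0.1 / dt))           # ~0.1 ms boxcar
  sm <- as.numeric(stats::filter(x, rep(1 / ksm, ksm), sides = 2))
  sm[is.na(sm)] <- x[is.na(sm)]
  base_k <- max(1L, round(2 / dt))          # 2 ms local baseline
  refr_k <- max(1L, round(refractory / dt))
  persist_from <- round(0.3 / dt); persist_to <- round(1.3 / dt)
  is_max <- c(FALSE, diff(sign(diff(sm))) < 0, FALSE)
  cand <- which(is_max)
  # candidates too close to the trace edges lack a local-baseline window
  cand <- cand[cand > base_k + round(0.7 / dt) & cand < n - 3]
  keep <- integer(0)
  for (i in cand) {
    lb <- median(x[max(1, i - base_k - round(0.5 / dt)):max(1, i - round(0.5 / dt))])
    # raw peak near the smoothed maximum
    win <- max(1, i - round(0.2 / dt)):min(n, i + round(0.2 / dt))
    ipk <- win[which.max(x[win])]
    amp <- x[ipk] - lb
    if (amp < thr) next
    pstart <- ipk + persist_from
    pend <- min(n, ipk + persist_to)
    if (pend - pstart < 2) next
    if (mean(x[pstart:pend]) - lb < thr / 2) next
    if (length(keep) > 0 && ipk - keep[length(keep)] < refr_k) {
      if (x[ipk] > x[keep[length(keep)]]) keep[length(keep)] <- ipk
      next
    }
    keep <- c(keep, ipk)
  }
  keep
}

#' Extract kinetic features of one PSC candidate
#'
#' Onset is the last crossing of (local baseline + 10% of peak deflection)
#' before the peak, linearly interpolated; rise time spans 10% to 90% of
#' peak; amplitude is peak minus local baseline (signed); the decay time
#' constant comes from [fit_decay_tau()] over the falling phase from 90% of
#' peak to at most 5 estimated tau (or the next event onset).
#'
#' @param trace Numeric sweep, pA.
#' @param dt Sample interval, ms.
#' @param peak_index Sample index of the event peak.
#' @param polarity +1 or -1 (expected deflection sign).
#' @param stim_times Stimulus times, ms (for onset latency); may be empty.
#' @param holding_potential Holding potential, mV.
#' @param next_onset Optional onset time of the following event, ms.
#' @return A one-row tibble, or `NULL` if the candidate has no measurable
#'   rising phase.
#' @export
extract_features <- function(trace, dt, peak_index, polarity = -1,
                             stim_times = numeric(), holding_potential = -60,
                             next_onset = NA) {
  n <- length(trace)
  x <- trace * polarity
  base_k <- max(1L, round(2 / dt))
  lb <- median(x[max(1, peak_index - base_k - round(0.5 / dt)):
                   max(1, peak_index - round(0.5 / dt))])
  amp <- x[peak_index] - lb
  if (amp <= 0) return(NULL)
  # walk back for threshold crossings
  search_from <- max(1, peak_index - round(10 / dt))
  seg <- x[search_from:peak_index] - lb
  cross_time <- function(frac) {
    level <- frac * amp
    below <- which(seg[-length(seg)] < level & seg[-1] >= level)
    if (length(below) == 0) return((search_from - 1) * dt)
    i <- below[length(below)]
    f <- (level - seg[i]) / (seg[i + 1] - seg[i])
    (search_from - 1 + i - 1 + f) * dt
  }
  t10 <- cross_time(0.10)
  t90 <- cross_time(0.90)
  onset_time <- cross_time(0.10)
  peak_time <- (peak_index - 1) * dt
  rise_time <- max(t90 - t10, dt)
  time_to_peak <- max(peak_time - onset_time, dt)
  # decay fit window
  after <- x[peak_index:n] - lb
  i90 <- which(after <= 0.9 * amp)[1]
  decay_tau <- NA_real_
  fit_failed <- TRUE
  if (!is.na(i90)) {
    end_idx <- length(after)
    if (!is.na(next_onset)) {
      end_idx <- min(end_idx, max(i90 + 3, floor(next_onset / dt) - peak_index))
    }
    segment <- after[i90:end_idx]
    if (length(segment) >= 3) {
      tau0 <- fit_decay_tau(segment, dt)
      if (!is.na(tau0)) {
        end2 <- min(end_idx, i90 + ceiling(5 * tau0 / dt))
        decay_tau <- fit_decay_tau(after[i90:end2], dt)
        fit_failed <- is.na(decay_tau)
      }
    }
  }
  stim_index <- NA_integer_
  onset_latency <- NA_real_
  prior <- which(stim_times <= onset_time)
  if (length(prior) > 0) {
    stim_index <- prior[length(prior)]
    onset_latency <- onset_time - stim_times[stim_index]
  }
  tibble::tibble(
    onset_time = onset_time, onset_latency = onset_latency,
    stim_index = stim_index, rise_time = rise_time,
    time_to_peak = time_to_peak, amplitude = amp * polarity,
    decay_tau = decay_tau, holding_potential = holding_potential,
    fit_failed = fit_failed
  )
}

#' Fit a single-exponential decay time constant
#'
#' Least-squares fit of `A * exp(-t / tau) + C` to a post-peak segment by
#' profiling: for each candidate `tau` the amplitude and offset are solved
#' linearly, and `tau` is optimised on a log grid refined by
#' [stats::optimize()].  Returns `NA` (with no error) when the segment
#' carries no decaying component (e.g. a constant segment).
#'
#' @param segment Numeric trace values from the start of the decay, same
#'   polarity as the peak (decaying towards baseline).
#' @param dt Sample interval, ms.
#' @param tau_range Search range for tau, ms.
#' @return The fitted tau in ms, or `NA_real_`.
#' @examples
#' t <- seq(0, 20, by = 0.02)
#' fit_decay_tau(5 * exp(-t / 3.51), dt = 0.02)
#' @export
fit_decay_tau <- function(segment, dt, tau_range = c(NA, NA)) {
  n <- length(segment)
  if (n < 3 || any(!is.finite(segment))) return(NA_real_)
  if (max(segment) - min(segment) <= 0) return(NA_real_)
  t <- (seq_len(n) - 1) * dt
  if (is.na(tau_range[1])) tau_range <- c(dt / 2, max(t) * 20)
  sse <- function(log_tau) {
    basis <- exp(-t / exp(log_tau))
    fit <- lm.fit(cbind(1, basis), segment)
    sum(fit$residuals^2)
  }
  grid <- seq(log(tau_range[1]), log(tau_range[2]), length.out = 40)
  vals <- vapply(grid, sse, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(sse, c(lo, hi))
  tau <- exp(opt$minimum)
  basis <- exp(-t / tau)
  co <- lm.fit(cbind(1, basis), segment)$coefficients
  if (is.na(co[2]) || co[2] <= 0) return(NA_real_)  # no decaying component
  # reject boundary solutions (flat or unresolvable decay)
  if (tau >= tau_range[2] * 0.99) return(NA_real_)
  unname(tau)
}

#' Write detected events as a TSV table
#'
#' @param events Event tibble from [detect_events()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  write.table(events, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  tibble::as_tibble(read.delim(path))
}
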