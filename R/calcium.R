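#' Relative fluorescence (dF/F) of ROI traces
#'
#' For each ROI, the baseline `F` is the mean of the first
#' `baseline_frames` frames; the per-frame ratio is `frame / F`; and `dff`
#' is the maximum ratio within the stimulation window (first bout onset to
#' the end of the trace).  A quiescent ROI therefore yields a dff near 1 —
#' the relative-fluorescence values here are F_max/F_baseline ratios, the
#' scale on which the group statistics of this protocol are reported.
#'
#' @param traces Tibble with `roi`, `frame`, `f` (a `calcium_movie$traces`).
#' @param baseline_frames Frames defining the baseline.
#' @param stim_bout_frames Bout onset frame indices (first one opens the
#'   stimulation window).
#' @return A tibble with one row per ROI: `roi`, `baseline_f`, `dff`.
#' @export
compute_dff <- function(traces, baseline_frames = 15,
                        stim_bout_frames = c(16, 31, 46)) {
  stopifnot(baseline_frames >= 2)
  traces |>
    dplyr::group_by(.data$roi) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$frame)
      f0 <- mean(d$f[seq_len(baseline_frames)])
      if (!is.finite(f0) || f0 <= 0) {
        abort(sprintf("ROI %s has non-positive baseline fluorescence",
                      as.character(key$roi)))
      }
      stim <- d$frame >= min(stim_bout_frames)
      tibble::tibble(baseline_f = f0, dff = max(d$f[stim]) / f0)
    }) |>
    dplyr::ungroup()
}

#' Per-frame fluorescence ratio series of one ROI
#'
#' @param f Per-frame fluorescence of one ROI.
#' @param baseline_frames Frames defining the baseline.
#' @return `f / mean(f[1:baseline_frames])`.
#' @export
dff_series <- function(f, baseline_frames = 15) {
  f0 <- mean(f[seq_len(baseline_frames)])
  if (!is.finite(f0) || f0 <= 0) abort("non-positive baseline fluorescence")
  f / f0
}

#' Classify ROIs as active or quiescent
#'
#' An ROI is active if its fluorescence reaches `z_threshold` baseline
#' standard deviations above the baseline mean in at least `min_bouts` of
#' the three stimulation bouts.  Each bout window runs from its onset to
#' the frame before the next bout (or the end of the trace).
#'
#' @param traces Tibble with `roi`, `frame`, `f`.
#' @param stim_bout_frames Three bout onset frame indices.
#' @param baseline_frames Frames defining the baseline.
#' @param z_threshold SD multiple above baseline (default 2).
#' @param min_bouts Minimum qualifying bouts (default 2 of 3).
#' @return A tibble per ROI: `roi`, `active`, `n_bouts_passing`,
#'   `bout_peak_z` (list of the three per-bout peak z-scores), `dff`,
#'   `degenerate_baseline` flag (zero baseline SD).
#' @export
classify_active <- function(traces, stim_bout_frames = c(16, 31, 46),
                            baseline_frames = 15, z_threshold = 2,
                            min_bouts = 2) {
  stopifnot(length(stim_bout_frames) == 3)
  dff_tab <- compute_dff(traces, baseline_frames, stim_bout_frames)
  act <- traces |>
    dplyr::group_by(.data$roi) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$frame)
      base <- d$f[seq_len(baseline_frames)]
      mu <- mean(base); sdev <- sd(base)
      degenerate <- sdev == 0
      bounds <- c(stim_bout_frames, max(d$frame) + 1L)
      z <- vapply(1:3, function(b) {
        win <- d$f[d$frame >= bounds[b] & d$frame < bounds[b + 1]]
        if (degenerate) {
          if (max(win) > mu) Inf else 0
        } else {
          (max(win) - mu) / sdev
        }
      }, numeric(1))
      tibble::tibble(n_bouts_passing = sum(z >= z_threshold),
                     active = sum(z >= z_threshold) >= min_bouts,
                     bout_peak_z = list(z),
                     degenerate_baseline = degenerate)
    }) |>
    dplyr::ungroup()
  if (any(act$degenerate_baseline)) {
    warn("zero baseline SD in some ROIs; their activity criterion is degenerate")
  }
  dplyr::left_join(act, dff_tab, by = "roi")
}

#' Percent suppression of the evoked calcium signal
#'
#' Operates on the evoked component above the baseline ratio of 1:
#' `100 * (dff_control - dff_blocked) / (dff_control - 1)`, clipped to
#' `[0, 100]`.  Returns `NA` (no evoked signal) when `dff_control <= 1`.
#'
#' @param dff_control,dff_blocked Relative fluorescence ratios
#'   (element-wise vectors allowed).
#' @return Percent suppression in `[0, 100]`, or `NA`.
#' @examples
#' percent_suppression(1.18, 1.06) # ~66.7
#' @export
percent_suppression <- function(dff_control, dff_blocked) {
  out <- ifelse(dff_control > 1,
                100 * (dff_control - dff_blocked) / (dff_control - 1),
                NA_real_)
  if (any(is.na(out) & !is.na(dff_control))) {
    warn("dff_control <= 1 for some ROIs: no evoked signal, suppression NA")
  }
  pmin(pmax(out, 0), 100)
}
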