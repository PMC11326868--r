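#' Specification of a synthetic calcium-imaging recording
#'
#' Emulates the stimulation protocol used for cochlear-nucleus bushy-cell
#' imaging: baseline frames, then three stimulation bouts at regular
#' intervals, imaged at a slow frame rate.  Each region of interest (ROI)
#' shows stimulus-locked fluorescence transients whose peak relative
#' fluorescence (F_max / F_baseline) equals `evoked_dff` in the control
#' condition; under the `blocked` condition the evoked component above
#' baseline is multiplied by `1 - suppression_factor`.
#'
#' @param n_rois Number of ROIs.
#' @param frame_rate Frames per second (default 3).
#' @param n_frames Total frames (default 60, ~20 s).
#' @param baseline_frames Frames before the first bout used as baseline
#'   (default 15, ~5 s).
#' @param stim_bout_frames Frame indices (1-based) of the three bout onsets.
#' @param evoked_dff Peak relative fluorescence ratio in control (e.g. 1.2).
#' @param suppression_factor Fraction of the evoked component removed under
#'   blockade, in `[0, 1]`.
#' @param noise_sd Gaussian frame noise SD, fluorescence units.
#' @param baseline_f Mean baseline fluorescence, arbitrary units.
#' @param decay_frames Exponential decay constant of the transient, frames.
#' @param seed Integer RNG seed.
#' @return A list of class `calcium_gen_spec`.
#' @export
calcium_gen_spec <- function(n_rois = 10, frame_rate = 3, n_frames = 60,
                             baseline_frames = 15,
                             stim_bout_frames = c(16, 31, 46),
                             evoked_dff = 1.2, suppression_factor = 0,
                             noise_sd = 0.3, baseline_f = 100,
                             decay_frames = 3, seed = 1) {
  check_field(n_rois >= 1, "n_rois", "must be >= 1")
  check_field(length(stim_bout_frames) == 3, "stim_bout_frames",
              "exactly three bout onsets required")
  check_field(all(stim_bout_frames >= 1 & stim_bout_frames <= n_frames),
              "stim_bout_frames", "bout onsets outside the frame range")
  check_field(baseline_frames < min(stim_bout_frames), "baseline_frames",
              "baseline must end before the first bout")
  check_field(suppression_factor >= 0 && suppression_factor <= 1,
              "suppression_factor", "must be in [0, 1]")
  check_field(evoked_dff >= 1, "evoked_dff",
              "peak relative fluorescence must be >= 1")
  structure(list(n_rois = as.integer(n_rois), frame_rate = frame_rate,
                 n_frames = as.integer(n_frames),
                 baseline_frames = as.integer(baseline_frames),
                 stim_bout_frames = as.integer(stim_bout_frames),
                 evoked_dff = evoked_dff,
                 suppression_factor = suppression_factor,
                 noise_sd = noise_sd, baseline_f = baseline_f,
                 decay_frames = decay_frames, seed = seed),
            class = "calcium_gen_spec")
}

#' Generate synthetic ROI fluorescence traces
#'
#' @param spec A [calcium_gen_spec()].
#' @param condition `"control"` or `"blocked"`.
#' @return A list of class `calcium_movie` with `traces` (tibble: `roi`,
#'   `frame`, `f`), protocol metadata, and `ground_truth` (per-ROI baseline,
#'   true peak ratio and the applied suppression).
#' @examples
#' mv <- generate_calcium_movie(calcium_gen_spec(n_rois = 3, noise_sd = 0))
#' max(mv$traces$f) / 100
#' @export
generate_calcium_movie <- function(spec, condition = c("control", "blocked")) {
  stopifnot(inherits(spec, "calcium_gen_spec"))
  condition <- match.arg(condition)
  scale <- if (condition == "blocked") 1 - spec$suppression_factor else 1
  with_seed(spec$seed, {
    frames <- seq_len(spec$n_frames)
    rows <- vector("list", spec$n_rois)
    gt <- vector("list", spec$n_rois)
    for (r in seq_len(spec$n_rois)) {
      f0 <- spec$baseline_f * runif(1, 0.9, 1.1)
      evoked <- numeric(spec$n_frames)
      for (b in spec$stim_bout_frames) {
        t_rel <- frames - b
        on <- t_rel >= 0
        evoked[on] <- pmax(evoked[on],
                           exp(-t_rel[on] / spec$decay_frames))
      }
      peak_ratio <- 1 + (spec$evoked_dff - 1) * scale
      f <- f0 * (1 + (spec$evoked_dff - 1) * scale * evoked) +
        rnorm(spec$n_frames, 0, spec$noise_sd)
      rows[[r]] <- tibble::tibble(roi = r, frame = frames, f = f)
      gt[[r]] <- tibble::tibble(roi = r, baseline_f = f0,
                                true_peak_ratio = peak_ratio,
                                suppression_applied = 1 - scale)
    }
    structure(list(traces = dplyr::bind_rows(rows),
                   frame_rate = spec$frame_rate,
                   baseline_frames = spec$baseline_frames,
                   stim_bout_frames = spec$stim_bout_frames,
                   condition = condition,
                   ground_truth = dplyr::bind_rows(gt),
                   spec = spec),
              class = "calcium_movie")
  })
}

#' @export
print.calcium_movie <- function(x, ...) {
  cat(sprintf("<calcium_movie> %d ROIs x %d frames at %g Hz (%s)\n",
              max(x$traces$roi), max(x$traces$frame), x$frame_rate,
              x$condition))
  invisible(x)
}

# ---- pixel-level movie + polygon ROIs ---------------------------------

# Even-odd rule point-in-polygon test; px, py are pixel-centre coordinates.
point_in_polygon <- function(px, py, poly_x, poly_y) {
  n <- length(poly_x)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((poly_y[i] > py) != (poly_y[j] > py)) &
      (px < (poly_x[j] - poly_x[i]) * (py - poly_y[i]) /
         (poly_y[j] - poly_y[i]) + poly_x[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterise a polygon ROI onto a pixel grid
#'
#' A pixel belongs to the ROI if its centre lies inside the polygon
#' (even-odd rule).
#'
#' @param polygon A list or data frame with `x` and `y` vertex coordinates
#'   (pixel units).
#' @param width,height Image dimensions in pixels.
#' @return A logical `height x width` mask matrix.
#' @export
rasterize_roi <- function(polygon, width, height) {
  centres <- expand.grid(x = seq_len(width) - 0.5, y = seq_len(height) - 0.5)
  mask <- point_in_polygon(centres$x, centres$y, polygon$x, polygon$y)
  matrix(mask, nrow = height, ncol = width, byrow = TRUE)
}

#' Average pixel movie frames over polygon ROIs
#'
#' @param movie_frames A numeric array `frames x height x width`.
#' @param rois A named list of polygons (each with `x`, `y`).
#' @return A tibble with `roi`, `frame`, `f` (mean fluorescence of the ROI's
#'   pixels per frame).
#' @export
compute_roi_traces <- function(movie_frames, rois) {
  stopifnot(length(dim(movie_frames)) == 3)
  h <- dim(movie_frames)[2]; w <- dim(movie_frames)[3]
  purrr::imap_dfr(rois, function(poly, nm) {
    mask <- rasterize_roi(poly, w, h)
    if (!any(mask)) abort(sprintf("ROI '%s' covers no pixel centres", nm))
    f <- vapply(seq_len(dim(movie_frames)[1]), function(k) {
      mean(movie_frames[k, , ][mask])
    }, numeric(1))
    tibble::tibble(roi = nm, frame = seq_along(f), f = f)
  })
}
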