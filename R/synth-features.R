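#' Per-class feature distributions for the synthetic classifier table
#'
#' Defaults are parameterised by the recorded midline-evoked EPSC/IPSC
#' cluster statistics (rise time 0.63 vs 0.86 ms, decay 2.23 vs 3.51 ms,
#' amplitude ~67 vs ~55 pA, probability 0.80 vs 0.45, onset jitter 0.25 vs
#' 0.50 ms); peak jitter combines onset jitter with rise-time variability.
#'
#' @return A named list (`excitatory`, `inhibitory`) of per-feature
#'   `c(mean, sd)` pairs.
#' @export
moc_feature_params <- function() {
  list(
    excitatory = list(rise_time = c(0.63, 0.19), decay_tau = c(2.23, 0.52),
                      amplitude = c(66.95, 20), probability = c(0.80, 0.19),
                      onset_jitter = c(0.25, 0.13), peak_jitter = c(0.35, 0.15)),
    inhibitory = list(rise_time = c(0.86, 0.15), decay_tau = c(3.51, 0.93),
                      amplitude = c(55.39, 16), probability = c(0.45, 0.15),
                      onset_jitter = c(0.50, 0.17), peak_jitter = c(0.65, 0.20))
  )
}

#' Generate a labeled synthetic feature table for classifier testing
#'
#' Draws `n_per_class` rows per class carrying the seven classification
#' features (rise time, decay tau, amplitude, occurrence probability, onset
#' jitter, peak jitter, and categorical animal age) plus the true label.
#' Continuous features are truncated normals; probability is clipped to
#' `(0, 1]`; age is drawn uniformly from `age_levels` for both classes.
#'
#' @param n_per_class Rows per class (>= 1).
#' @param class_params Per-class feature distributions
#'   ([moc_feature_params()] format).
#' @param age_levels Age categories (postnatal days).
#' @param seed Integer RNG seed.
#' @return A tibble with the seven features and a `label` factor.
#' @examples
#' tab <- generate_feature_table(50, seed = 7)
#' table(tab$label)
#' @export
generate_feature_table <- function(n_per_class,
                                   class_params = moc_feature_params(),
                                   age_levels = paste0("P", 14:19),
                                   seed = 1) {
  check_field(is.numeric(n_per_class) && n_per_class >= 1, "n_per_class",
              "must be a positive count")
  n_per_class <- as.integer(n_per_class)
  with_seed(seed, {
    rows <- purrr::imap_dfr(class_params, function(p, lab) {
      draw <- function(f, lower = 1e-4) {
        rnorm_trunc(n_per_class, p[[f]][1], p[[f]][2], lower = lower)
      }
      tibble::tibble(
        rise_time = draw("rise_time"),
        decay_tau = draw("decay_tau"),
        amplitude = draw("amplitude"),
        probability = pmin(draw("probability"), 1),
        onset_jitter = draw("onset_jitter", lower = 0),
        peak_jitter = draw("peak_jitter", lower = 0),
        age = factor(sample(age_levels, n_per_class, replace = TRUE),
                     levels = age_levels),
        label = factor(lab, levels = names(class_params))
      )
    })
    rows[sample(nrow(rows)), ]
  })
}
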