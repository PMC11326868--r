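#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_errorbar labs
#'   facet_wrap geom_abline geom_hline theme_minimal
NULL

#' Plot a simulated somatic voltage trace
#'
#' @param object A [simulate()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.moc_sim <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$time, y = .data$v_soma)) +
    geom_line(linewidth = 0.3) +
    labs(x = "time (ms)", y = "somatic V (mV)") +
    theme_minimal()
}

#' Plot a gap-statistic curve
#'
#' @param object A [gap_select_k()] result.
#' @param ... Unused.
#' @return A ggplot with Gap(k) +/- its simulation SE and the selected k.
#' @export
autoplot.gap_curve <- function(object, ...) {
  d <- object$curve
  ggplot(d, aes(x = .data$k, y = .data$gap)) +
    geom_line() +
    geom_point() +
    geom_errorbar(aes(ymin = .data$gap - .data$SE_sim,
                      ymax = .data$gap + .data$SE_sim), width = 0.15) +
    geom_point(data = d[d$k == object$k_star, ], colour = "red", size = 3) +
    labs(x = "number of clusters k", y = "Gap(k)") +
    theme_minimal()
}

#' Plot a classifier ROC curve
#'
#' @param object An [evaluate_classifier()] result.
#' @param ... Unused.
#' @return A ggplot of the ROC curve with the chance diagonal.
#' @export
autoplot.ei_evaluation <- function(object, ...) {
  ggplot(object$roc, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    geom_line() +
    labs(x = "false positive rate", y = "true positive rate",
         title = sprintf("AUC = %.3f", object$auc)) +
    theme_minimal()
}

#' Plot synthetic or recorded sweeps
#'
#' @param object A `sweep_set`.
#' @param sweeps Indices of sweeps to draw (default up to 10).
#' @param ... Unused.
#' @return A ggplot of overlaid sweeps.
#' @export
autoplot.sweep_set <- function(object, sweeps = NULL, ...) {
  d <- tidy(object)
  if (is.null(sweeps)) sweeps <- seq_len(min(10, nrow(object$traces)))
  d <- d[d$sweep %in% sweeps, ]
  ggplot(d, aes(x = .data$time, y = .data$current,
                group = .data$sweep)) +
    geom_line(alpha = 0.4, linewidth = 0.2) +
    labs(x = "time (ms)", y = "current (pA)") +
    theme_minimal()
}

#' Plot ROI fluorescence traces
#'
#' @param object A [generate_calcium_movie()] result.
#' @param ... Unused.
#' @return A ggplot of per-ROI traces with bout onsets marked.
#' @export
autoplot.calcium_movie <- function(object, ...) {
  ggplot(object$traces, aes(x = .data$frame, y = .data$f,
                            group = .data$roi)) +
    geom_line(alpha = 0.5, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = object$stim_bout_frames,
                        linetype = 3, colour = "steelblue") +
    labs(x = "frame", y = "fluorescence (a.u.)") +
    theme_minimal()
}

#' Plot an E-I latency train sweep
#'
#' @param sweep A [run_ei_train_sweep()] table.
#' @return A ggplot of AP rate and first-AP latency against the E-I latency
#'   difference; the dashed line is the EPSP-only reference.
#' @export
plot_ei_sweep <- function(sweep) {
  ref <- sweep[is.na(sweep$delta), ]
  d <- sweep[!is.na(sweep$delta), ] |>
    tidyr::pivot_longer(c("rate_span_hz", "first_ap_latency_ms"),
                        names_to = "metric")
  refd <- tibble::tibble(
    metric = c("rate_span_hz", "first_ap_latency_ms"),
    value = c(ref$rate_span_hz, ref$first_ap_latency_ms)
  )
  ggplot(d, aes(x = .data$delta, y = .data$value)) +
    geom_hline(data = refd, aes(yintercept = .data$value),
               linetype = 2, colour = "grey50") +
    geom_line() +
    geom_point() +
    facet_wrap(~metric, scales = "free_y", ncol = 1,
               labeller = ggplot2::as_labeller(c(
                 rate_span_hz = "AP rate (Hz)",
                 first_ap_latency_ms = "first-AP latency (ms)"))) +
    labs(x = "E-I latency difference (ms)", y = NULL) +
    theme_minimal()
}
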