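#' Build the clustering feature matrix from an event table
#'
#' Assembles the per-event features used to sort one cell's PSCs into
#' latency-defined clusters.  The default feature set is onset latency, rise
#' time and decay tau; `include_amplitude = TRUE` adds amplitude.  Columns
#' are z-scored by default since latency and kinetics live on different
#' scales.  Events with missing features (e.g. failed decay fits) or flagged
#' spontaneous are dropped.
#'
#' @param events Event tibble ([detect_events()]).
#' @param include_amplitude Add amplitude to the feature set.
#' @param standardize Z-score each column.
#' @return A list of class `psc_features`: `x` (numeric matrix used for
#'   clustering), `events` (the retained rows), `features`.
#' @export
feature_matrix <- function(events, include_amplitude = FALSE,
                           standardize = TRUE) {
  feats <- c("onset_latency", "rise_time", "decay_tau")
  if (include_amplitude) feats <- c(feats, "amplitude")
  keep <- stats::complete.cases(events[, feats])
  if ("spontaneous" %in% names(events)) keep <- keep & !events$spontaneous
  ev <- events[keep, ]
  if (nrow(ev) < 2) abort("need at least 2 events with complete features to cluster")
  x <- as.matrix(ev[, feats])
  if (standardize) {
    x <- scale(x)
    x[, apply(is.na(x), 2, all)] <- 0  # constant column
    x[is.na(x)] <- 0
  }
  structure(list(x = unclass(x), events = ev, features = feats),
            class = "psc_features")
}

#' Select the number of PSC clusters with the gap statistic
#'
#' Computes `Gap(k) = E*[log(W_k)] - log(W_k)` for `k = 1..kmax` against `B`
#' uniform reference sets drawn over each feature's observed range
#' (Tibshirani's method), with best-of-`nstart` k-means at each `k`.  The
#' selected `k*` is the smallest `k` with
#' `Gap(k) >= Gap(k+1) - s_{k+1}` (the 1-SE rule); if no `k` qualifies,
#' the `k` maximising the gap is used.  The method can select `k* = 1`,
#' which is why it suits cells with a single PSC cluster.
#'
#' @param features A [feature_matrix()] object (or plain numeric matrix).
#' @param kmax Maximum clusters considered (clipped with a warning when
#'   there are fewer distinct rows).
#' @param B Reference bootstrap sets.
#' @param nstart Random k-means starts.
#' @param seed Integer RNG seed.
#' @param space Reference distribution: `"original"` (uniform over range)
#'   or `"scaledPCA"` (uniform in the PCA-aligned box).
#' @return A list of class `gap_curve`: `k_star` and `curve`, a tibble with
#'   `k`, `logW`, `E_logW`, `gap`, `SE_sim`.
#' @export
gap_select_k <- function(features, kmax = 10, B = 500, nstart = 25,
                         seed = 1, space = c("original", "scaledPCA")) {
  space <- match.arg(space)
  x <- if (inherits(features, "psc_features")) features$x else as.matrix(features)
  n_distinct <- nrow(unique(x))
  if (kmax > n_distinct) {
    warn(sprintf("kmax clipped from %d to %d (distinct rows)", kmax, n_distinct))
    kmax <- n_distinct
  }
  kmax <- max(1L, kmax)
  with_seed(seed, {
    if (kmax == 1) {
      w1 <- sum(scale(x, scale = FALSE)^2)
      curve <- tibble::tibble(k = 1L, logW = log(max(w1, .Machine$double.eps)),
                              E_logW = NA_real_, gap = NA_real_,
                              SE_sim = NA_real_)
      return(structure(list(k_star = 1L, curve = curve), class = "gap_curve"))
    }
    cg <- cluster::clusGap(x,
                           FUNcluster = function(xx, k) {
                             kmeans(xx, k, nstart = nstart, iter.max = 50)
                           },
                           K.max = kmax, B = B, spaceH0 = space,
                           verbose = FALSE)
    tab <- cg$Tab
    curve <- tibble::tibble(k = seq_len(nrow(tab)), logW = tab[, "logW"],
                            E_logW = tab[, "E.logW"], gap = tab[, "gap"],
                            SE_sim = tab[, "SE.sim"])
    k_star <- select_k_one_se(curve$gap, curve$SE_sim)
    structure(list(k_star = k_star, curve = curve), class = "gap_curve")
  })
}

# Smallest k with gap(k) >= gap(k+1) - se(k+1); fall back to argmax gap.
select_k_one_se <- function(gap, se) {
  kmax <- length(gap)
  for (k in seq_len(kmax - 1)) {
    if (gap[k] >= gap[k + 1] - se[k + 1]) return(k)
  }
  which.max(gap)
}

#' @export
print.gap_curve <- function(x, ...) {
  cat(sprintf("<gap_curve> k* = %d (kmax %d)\n", x$k_star, max(x$curve$k)))
  invisible(x)
}

#' @export
tidy.gap_curve <- function(x, ...) x$curve

#' @export
glance.gap_curve <- function(x, ...) {
  tibble::tibble(k_star = x$k_star, kmax = max(x$curve$k))
}

#' Write a gap curve to JSON
#' @param x A `gap_curve`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gap_curve <- function(x, path) {
  jsonlite::write_json(list(k_star = x$k_star, curve = x$curve), path,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Best-of-nstart k-means clustering of PSC features
#'
#' Runs [stats::kmeans()] with `nstart` random starts and re-indexes the
#' clusters by ascending mean onset latency, so cluster 1 is always the
#' earliest.  Deterministic under `seed`.
#'
#' @param features A [feature_matrix()] object.
#' @param k Number of clusters (from [gap_select_k()]).
#' @param nstart Random starts.
#' @param seed Integer RNG seed.
#' @return A list of class `psc_clustering`: `assignments` (integer vector
#'   over the retained events), `events`, `tot_withinss`, `k`.
#' @export
kmeans_cluster <- function(features, k, nstart = 25, seed = 1) {
  stopifnot(inherits(features, "psc_features"))
  x <- features$x
  if (k > nrow(x)) abort("k exceeds the number of events")
  with_seed(seed, {
    km <- kmeans(x, centers = k, nstart = nstart, iter.max = 50)
    lat <- tapply(features$events$onset_latency, km$cluster, mean)
    remap <- match(km$cluster, as.integer(names(sort(lat))))
    structure(list(assignments = remap, events = features$events,
                   tot_withinss = km$tot.withinss, k = k),
              class = "psc_clustering")
  })
}

#' Summarise PSC clusters
#'
#' Per-cluster event counts, latency statistics, jitter and occurrence
#' probability.  Onset jitter is the SD of onset latency within the
#' cluster; peak jitter is the SD of (onset latency + time to peak);
#' probability is events per stimulus per sweep, capped at 1.
#'
#' @param events Event tibble covering the clustered events.
#' @param assignments Integer cluster assignment per event row.
#' @param n_sweeps Number of sweeps in the recording.
#' @param n_stimuli Number of stimuli per sweep.
#' @return A tibble with one row per cluster (`cluster`, `n`,
#'   `mean_onset_latency`, `median_onset_latency`, `onset_jitter`,
#'   `peak_jitter`, `probability`, `median_amplitude`, `median_rise_time`,
#'   `median_decay_tau`, `label`).
#' @export
summarize_clusters <- function(events, assignments, n_sweeps, n_stimuli = 1) {
  stopifnot(nrow(events) == length(assignments))
  events$cluster <- assignments
  events |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_onset_latency = mean(.data$onset_latency),
      median_onset_latency = median(.data$onset_latency),
      onset_jitter = ifelse(dplyr::n() > 1, sd(.data$onset_latency), 0),
      peak_jitter = ifelse(dplyr::n() > 1,
                           sd(.data$onset_latency + .data$time_to_peak), 0),
      probability = min(1, dplyr::n() / (n_sweeps * n_stimuli)),
      median_amplitude = median(.data$amplitude),
      median_rise_time = median(.data$rise_time),
      median_decay_tau = median(.data$decay_tau, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(label = "unknown") |>
    dplyr::arrange(.data$mean_onset_latency)
}

#' Label clusters excitatory/inhibitory by holding-potential correspondence
#'
#' At 0 mV only chloride-mediated (inhibitory) currents are visible, so a
#' -60 mV cluster is labeled inhibitory iff some 0 mV cluster's mean onset
#' latency lies within `match_tolerance`; otherwise excitatory.  All 0 mV
#' clusters are inhibitory by construction.  With no 0 mV data every
#' -60 mV cluster is labeled excitatory and flagged.
#'
#' @param clusters_m60 Cluster summary at -60 mV ([summarize_clusters()]).
#' @param clusters_0mv Cluster summary at 0 mV (may be `NULL` or empty).
#' @param match_tolerance Latency tolerance, ms; default
#'   `max(2 * pooled onset jitter, 0.5)`.
#' @return `clusters_m60` with `label` filled in and a `no_0mv_data` flag
#'   column.
#' @export
label_clusters_by_holding <- function(clusters_m60, clusters_0mv,
                                      match_tolerance = NULL) {
  if (is.null(clusters_0mv) || nrow(clusters_0mv) == 0) {
    clusters_m60$label <- "excitatory"
    clusters_m60$no_0mv_data <- TRUE
    return(clusters_m60)
  }
  labs <- character(nrow(clusters_m60))
  for (i in seq_len(nrow(clusters_m60))) {
    tol <- match_tolerance
    if (is.null(tol)) {
      pooled <- sqrt(mean(c(clusters_m60$onset_jitter[i]^2,
                            clusters_0mv$onset_jitter^2)))
      tol <- max(2 * pooled, 0.5)
    }
    d <- abs(clusters_0mv$mean_onset_latency - clusters_m60$mean_onset_latency[i])
    labs[i] <- if (any(d <= tol)) "inhibitory" else "excitatory"
  }
  clusters_m60$label <- labs
  clusters_m60$no_0mv_data <- FALSE
  clusters_m60
}

#' Excitation-inhibition latency difference of a cell
#'
#' `(first inhibitory cluster onset latency) - (first excitatory cluster
#' onset latency)`; positive values mean excitation precedes inhibition.
#' Returns `NA` when either class is absent.
#'
#' @param clusters A labeled cluster summary
#'   ([label_clusters_by_holding()]).
#' @return The latency difference in ms (scalar).
#' @examples
#' cl <- tibble::tibble(mean_onset_latency = c(1.9, 4.7),
#'                      label = c("excitatory", "inhibitory"))
#' ei_latency_difference(cl) # +2.8
#' @export
ei_latency_difference <- function(clusters) {
  e <- clusters$mean_onset_latency[clusters$label == "excitatory"]
  i <- clusters$mean_onset_latency[clusters$label == "inhibitory"]
  if (length(e) == 0 || length(i) == 0) return(NA_real_)
  min(i) - min(e)
}
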