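test_that("gap statistic selects one cluster for a single blob", {
  x <- gaussian_blobs(1, 200, seed = 4)
  g <- gap_select_k(x, kmax = 6, B = 60, seed = 4)
  expect_equal(g$k_star, 1L)
  expect_s3_class(tidy(g), "tbl_df")
})

test_that("gap statistic separates two well-spaced blobs", {
  hits <- vapply(1:10, function(s) {
    x <- gaussian_blobs(2, 100, sep = 10, seed = s)
    gap_select_k(x, kmax = 6, B = 40, seed = s)$k_star == 2L
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("degenerate inputs clip kmax with a warning", {
  x <- matrix(c(1, 2, 1, 2), nrow = 2)  # 2 identical rows... distinct rows
  x_id <- matrix(1, nrow = 2, ncol = 2)
  expect_warning(g <- gap_select_k(x_id, kmax = 10, B = 10, seed = 1),
                 "clipped")
  expect_equal(g$k_star, 1L)
})

test_that("k-means honours the exhaustive-partition oracle and W_k identity", {
  pts <- tibble::tibble(
    onset_latency = c(0, 0, 10, 10), rise_time = c(0, 1, 0, 1),
    decay_tau = c(1, 1, 1, 1), amplitude = c(5, 5, 5, 5),
    spontaneous = FALSE
  )
  fm <- feature_matrix(pts, standardize = FALSE)
  cl <- kmeans_cluster(fm, k = 2, seed = 1)
  expect_equal(cl$assignments[1], cl$assignments[2])
  expect_equal(cl$assignments[3], cl$assignments[4])
  expect_false(cl$assignments[1] == cl$assignments[3])
  # clusters re-indexed by ascending onset latency
  expect_equal(cl$assignments, c(1L, 1L, 2L, 2L))
  # k = 1: objective equals total sum of squares about the centroid
  cl1 <- kmeans_cluster(fm, k = 1, seed = 1)
  tss <- sum(scale(fm$x, scale = FALSE)^2)
  expect_equal(cl1$tot_withinss, tss, tolerance = 1e-8)
  # brute-force recomputation of W_k from the assignments
  w2 <- sum(vapply(1:2, function(j) {
    xs <- fm$x[cl$assignments == j, , drop = FALSE]
    sum(scale(xs, scale = FALSE)^2)
  }, numeric(1)))
  expect_equal(cl$tot_withinss, w2, tolerance = 1e-8)
  expect_error(kmeans_cluster(fm, k = 10), "exceeds")
})

test_that("synthetic two-cluster latency data are assigned to ground truth", {
  # feature rows drawn from the generator's two latency clusters
  # (means 1.92 and 4.47 ms, jitter 0.25 and 0.50 ms)
  set.seed(17)
  ev <- tibble::tibble(
    onset_latency = c(rnorm(100, 1.92, 0.25), rnorm(80, 4.47, 0.50)),
    rise_time = c(rnorm(100, 0.45, 0.08), rnorm(80, 0.70, 0.10)),
    decay_tau = c(rnorm(100, 2.23, 0.4), rnorm(80, 3.51, 0.6)),
    amplitude = rnorm(180, -70, 15)
  )
  truth <- rep(1:2, c(100, 80))
  fm <- feature_matrix(ev)
  cl <- kmeans_cluster(fm, k = 2, seed = 5)
  expect_gte(mean(cl$assignments == truth), 0.98)
})

test_that("cluster summaries compute jitter and occurrence probability", {
  ev <- tibble::tibble(
    onset_latency = c(rep(2, 5), 4 + c(-0.2, -0.1, 0, 0.1, 0.2)),
    time_to_peak = rep(0.5, 10),
    rise_time = 0.3, decay_tau = 3, amplitude = -50
  )
  s <- summarize_clusters(ev, rep(1:2, each = 5), n_sweeps = 10, n_stimuli = 1)
  expect_equal(s$onset_jitter[1], 0)
  expect_equal(s$peak_jitter[2], sd(4 + c(-0.2, -0.1, 0, 0.1, 0.2)))
  expect_equal(s$probability, c(0.5, 0.5))
  # probability capped at 1
  s2 <- summarize_clusters(ev, rep(1L, 10), n_sweeps = 2, n_stimuli = 1)
  expect_equal(s2$probability, 1)
  # generator-based probability recovery
  ss <- generate_sweep_set(two_cluster_spec(n_sweeps = 80, noise_rms = 4,
                                            seed = 19, prob_i = 0.45))
  ev2 <- detect_events(ss)
  ev2 <- ev2[!ev2$spontaneous & !ev2$fit_failed, ]
  fm <- feature_matrix(ev2)
  cl <- kmeans_cluster(fm, k = 2, seed = 5)
  s3 <- summarize_clusters(cl$events, cl$assignments, n_sweeps = 80)
  expect_lt(abs(s3$probability[2] - 0.45), 0.12)
  expect_lt(abs(s3$onset_jitter[1] - 0.25), 0.08)
})

test_that("holding-potential correspondence labels clusters", {
  m60 <- tibble::tibble(cluster = 1:2, mean_onset_latency = c(1.9, 4.5),
                        onset_jitter = c(0.25, 0.5), label = "unknown")
  v0 <- tibble::tibble(cluster = 1L, mean_onset_latency = 4.6,
                       onset_jitter = 0.5)
  lab <- label_clusters_by_holding(m60, v0)
  expect_equal(lab$label, c("excitatory", "inhibitory"))
  expect_false(any(lab$no_0mv_data))
  # no 0 mV data: all excitatory plus a flag
  lab2 <- label_clusters_by_holding(m60, NULL)
  expect_equal(lab2$label, rep("excitatory", 2))
  expect_true(all(lab2$no_0mv_data))
})

test_that("E-I latency differences follow the sign convention", {
  cl <- tibble::tibble(mean_onset_latency = c(1.9, 4.7),
                       label = c("excitatory", "inhibitory"))
  expect_equal(ei_latency_difference(cl), 2.8)
  cl$mean_onset_latency <- c(2, 2)
  expect_equal(ei_latency_difference(cl), 0)
  cl2 <- tibble::tibble(mean_onset_latency = c(5.4, 1.0),
                        label = c("excitatory", "inhibitory"))
  expect_equal(ei_latency_difference(cl2), -4.4)
  expect_true(is.na(ei_latency_difference(cl[cl$label == "excitatory", ])))
})

test_that("full pipeline labels synthetic cells correctly", {
  run_cell <- function(seed) {
    ss60 <- generate_sweep_set(two_cluster_spec(50, noise_rms = 4, seed = seed))
    ss0 <- generate_sweep_set(two_cluster_spec(50, noise_rms = 4,
                                               seed = seed + 1000,
                                               holding_potential = 0))
    cluster_cell <- function(ss, kmax = 4) {
      ev <- detect_events(ss)
      ev <- ev[!ev$spontaneous & !ev$fit_failed, ]
      fm <- feature_matrix(ev)
      k <- gap_select_k(fm, kmax = kmax, B = 30, seed = seed)$k_star
      cl <- kmeans_cluster(fm, k, seed = seed)
      summarize_clusters(cl$events, cl$assignments, n_sweeps = 50)
    }
    lab <- label_clusters_by_holding(cluster_cell(ss60), cluster_cell(ss0))
    # earliest cluster excitatory, latest inhibitory
    c(first = lab$label[1], last = lab$label[nrow(lab)])
  }
  res <- vapply(1:3, run_cell, character(2))
  expect_true(all(res["first", ] == "excitatory"))
  expect_true(all(res["last", ] == "inhibitory"))
})
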