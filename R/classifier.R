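#' Train the excitatory/inhibitory PSC classifier
#'
#' Fits a bootstrap-aggregated decision-tree ensemble (random forest) on
#' labeled PSC feature rows carrying the seven classification variables:
#' rise time, decay tau, amplitude, occurrence probability, onset jitter,
#' peak jitter and categorical animal age.  Mirrors the workflow of
#' training on midline-evoked PSCs (labeled by holding-potential
#' correspondence) and applying the model to auditory-nerve-evoked PSCs
#' that lack 0 mV data.
#'
#' @param rows Labeled tibble ([generate_feature_table()] format) with a
#'   `label` factor of two levels and the seven features.
#' @param n_trees Trees in the ensemble (default 500; the out-of-bag error
#'   typically stabilises well before that).
#' @param mtry Features tried per split (default `floor(sqrt(7)) = 2`).
#' @param seed Integer RNG seed.
#' @return An object of class `ei_classifier` wrapping the forest, the
#'   cumulative out-of-bag (OOB) error curve and variable importances.
#' @export
train_ei_classifier <- function(rows, n_trees = 500, mtry = 2, seed = 1) {
  req <- c("rise_time", "decay_tau", "amplitude", "probability",
           "onset_jitter", "peak_jitter", "age", "label")
  missing <- setdiff(req, names(rows))
  if (length(missing) > 0) {
    abort(paste0("rows are missing columns: ", paste(missing, collapse = ", ")))
  }
  rows$label <- droplevels(factor(rows$label))
  if (nlevels(rows$label) < 2) abort("need at least 2 rows of each class")
  if (min(table(rows$label)) < 2) abort("need at least 2 rows of each class")
  rows$age <- factor(rows$age)
  with_seed(seed, {
    rf <- randomForest::randomForest(
      label ~ rise_time + decay_tau + amplitude + probability +
        onset_jitter + peak_jitter + age,
      data = rows, ntree = n_trees, mtry = mtry, importance = TRUE
    )
    structure(list(
      forest = rf,
      n_trees = n_trees,
      classes = levels(rows$label),
      age_levels = levels(rows$age),
      oob_curve = tibble::tibble(trees = seq_len(n_trees),
                                 oob_error = unname(rf$err.rate[, "OOB"])),
      importance = tibble::as_tibble(rf$importance, rownames = "feature"),
      training = rows
    ), class = "ei_classifier")
  })
}

#' @export
print.ei_classifier <- function(x, ...) {
  cat(sprintf("<ei_classifier> %d trees, OOB error %.4f\n",
              x$n_trees, tail(x$oob_curve$oob_error, 1)))
  invisible(x)
}

#' @export
tidy.ei_classifier <- function(x, ...) x$importance

#' @export
glance.ei_classifier <- function(x, ...) {
  resub <- mean(predict(x$forest, x$training) == x$training$label)
  tibble::tibble(
    n_trees = x$n_trees,
    oob_error = tail(x$oob_curve$oob_error, 1),
    oob_accuracy = 1 - tail(x$oob_curve$oob_error, 1),
    resubstitution_accuracy = resub
  )
}

#' Classify PSC feature rows as excitatory or inhibitory
#'
#' `p_excitatory` is the fraction of trees voting for the excitatory class;
#' the label is the class with probability above 0.5.  An exact tie (0.5)
#' is classified inhibitory and flagged.  Rows with an age category unseen
#' in training are mapped to the nearest trained category with a warning.
#'
#' @param model An [train_ei_classifier()] model.
#' @param rows Feature tibble (label column not required).
#' @return `rows` with `p_excitatory`, `pred_label` and `tie` appended.
#' @export
predict_ei <- function(model, rows) {
  stopifnot(inherits(model, "ei_classifier"))
  rows$age <- as.character(rows$age)
  unseen <- setdiff(unique(rows$age), model$age_levels)
  if (length(unseen) > 0) {
    num <- function(a) suppressWarnings(as.numeric(gsub("[^0-9.]", "", a)))
    trained <- num(model$age_levels)
    for (u in unseen) {
      nearest <- model$age_levels[which.min(abs(trained - num(u)))]
      rows$age[rows$age == u] <- nearest
    }
    warn(sprintf("unseen age categories mapped to nearest trained: %s",
                 paste(unseen, collapse = ", ")))
  }
  rows$age <- factor(rows$age, levels = model$age_levels)
  if (!"excitatory" %in% model$classes) {
    abort("model was not trained with an 'excitatory' class")
  }
  votes <- predict(model$forest, rows, type = "vote", norm.votes = TRUE)
  p_exc <- unname(votes[, "excitatory"])
  rows$p_excitatory <- p_exc
  rows$pred_label <- ifelse(p_exc > 0.5, "excitatory", "inhibitory")
  rows$tie <- p_exc == 0.5
  tibble::as_tibble(rows)
}

#' Evaluate the classifier on labeled rows
#'
#' Accuracy at the 0.5 probability threshold, the ROC curve over
#' `p_excitatory` thresholds (excitatory = positive class) and the area
#' under it by the trapezoid rule.
#'
#' @param model An [train_ei_classifier()] model.
#' @param rows Labeled feature tibble.
#' @return A list of class `ei_evaluation`: `accuracy`, `auc`, `roc`
#'   (tibble with `threshold`, `fpr`, `tpr`).
#' @export
evaluate_classifier <- function(model, rows) {
  if (length(unique(rows$label)) < 2) {
    abort("AUC undefined on a single-class evaluation set")
  }
  pred <- predict_ei(model, rows)
  truth <- as.character(rows$label)
  acc <- mean(pred$pred_label == truth)
  roc <- roc_points(pred$p_excitatory, truth == "excitatory")
  structure(list(accuracy = acc, auc = trapezoid_auc(roc$fpr, roc$tpr),
                 roc = roc),
            class = "ei_evaluation")
}

# ROC points over all distinct score thresholds (descending); predicted
# positive when score >= threshold.
roc_points <- function(score, is_pos) {
  thr <- c(Inf, sort(unique(score), decreasing = TRUE))
  pts <- purrr::map_dfr(thr, function(th) {
    pred_pos <- score >= th
    tibble::tibble(threshold = th,
                   fpr = sum(pred_pos & !is_pos) / sum(!is_pos),
                   tpr = sum(pred_pos & is_pos) / sum(is_pos))
  })
  pts
}

trapezoid_auc <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  sum(diff(fpr[o]) * (head(tpr[o], -1) + tail(tpr[o], -1)) / 2)
}

#' @export
print.ei_evaluation <- function(x, ...) {
  cat(sprintf("<ei_evaluation> accuracy %.4f, AUC %.4f\n", x$accuracy, x$auc))
  invisible(x)
}

#' @export
tidy.ei_evaluation <- function(x, ...) x$roc

#' @export
glance.ei_evaluation <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, auc = x$auc)
}

#' Cluster-level labels from per-event classifications
#'
#' Each cluster takes the majority label of its member events.  A mixed
#' cluster (events of both labels) is split into one excitatory and one
#' inhibitory cluster, suffixed `"E"` / `"I"`.
#'
#' @param predictions A tibble with `cluster` and `pred_label` per event.
#' @return A tibble with `cluster_out`, `cluster_in`, `label`, `n`.
#' @export
assign_cluster_labels <- function(predictions) {
  predictions |>
    dplyr::count(.data$cluster, .data$pred_label) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::mutate(mixed = dplyr::n() > 1) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      cluster_in = .data$cluster,
      cluster_out = ifelse(.data$mixed,
                           paste0(.data$cluster,
                                  ifelse(.data$pred_label == "excitatory",
                                         "E", "I")),
                           as.character(.data$cluster)),
      label = .data$pred_label,
      n = .data$n
    )
}
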