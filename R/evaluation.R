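# Participant-level repeated k-fold cross-validation with separate vs
# pooled (combined) training strategies, and the classification metrics
# reported per task x strategy x group cell.
#
# Splits are made at the participant level so no subject contributes to
# more than one of train/validation/test in any split; folds are
# stratified by diagnostic group, which both balances group proportions
# across folds and makes the separate and combined strategies share
# identical test folds (their metrics are paired).

#' Stratified participant-level fold plan for repeated k-fold CV
#'
#' For each repetition, participants are shuffled within their diagnostic
#' group and dealt round-robin into `k` folds, so fold sizes within each
#' group differ by at most one. Each repetition yields `k` splits by
#' rotation: test fold `i`, validation fold `(i + 1) mod k`, the
#' remaining `k - 2` folds train.
#'
#' @param participants data.frame with columns `id` and `group`, or an
#'   `rri_cohort`.
#' @param k number of folds (default 10).
#' @param reps number of repetitions (default 10).
#' @param seed integer seed; the plan is deterministic given the seed.
#' @return An object of class `fold_plan`: list with `k`, `reps`, and
#'   `assignments` (list of named integer vectors, participant id ->
#'   fold in 0..k-1, one per repetition).
#' @export
participant_folds <- function(participants, k = 10L, reps = 10L, seed = 1L) {
  if (inherits(participants, "rri_cohort"))
    participants <- data.frame(
      id = vapply(participants$participants, `[[`, "", "id"),
      group = vapply(participants$participants, `[[`, "", "group"),
      stringsAsFactors = FALSE)
  stopifnot(all(c("id", "group") %in% names(participants)), k >= 2)
  counts <- table(participants$group)
  if (any(counts < k))
    stop(sprintf("configuration error: group %s has %d participants, fewer than k = %d folds",
                 names(counts)[which.min(counts)], min(counts), k),
         call. = FALSE)
  assignments <- with_seed(seed, lapply(seq_len(reps), function(r) {
    fold <- integer(nrow(participants))
    names(fold) <- participants$id
    for (g in unique(participants$group)) {
      ids <- participants$id[participants$group == g]
      ids <- ids[sample.int(length(ids))]
      fold[ids] <- (seq_along(ids) - 1L) %% k
    }
    fold
  }))
  structure(list(k = as.integer(k), reps = as.integer(reps),
                 assignments = assignments),
            class = "fold_plan")
}

#' The k train/validation/test splits of one repetition
#'
#' @param plan a [participant_folds()] plan.
#' @param rep repetition index.
#' @return List of `k` splits, each with integer `test`, `val` and
#'   `train` fold ids.
#' @export
fold_splits <- function(plan, rep = 1L) {
  stopifnot(inherits(plan, "fold_plan"), rep >= 1, rep <= plan$reps)
  k <- plan$k
  lapply(seq_len(k) - 1L, function(i) {
    v <- (i + 1L) %% k
    list(test = i, val = v, train = setdiff(0:(k - 1L), c(i, v)))
  })
}

#' Binary classification metrics at a fixed threshold
#'
#' Predictions are positive iff `probabilities >= threshold` (stress is
#' the positive class throughout the pipeline). AUROC is the probability
#' that a random positive outranks a random negative, counting ties as
#' 0.5 (midrank Mann-Whitney statistic). With single-class labels the
#' AUROC is undefined and returned as `NA` with a warning; the other
#' metrics are still computed.
#'
#' @param labels 0/1 vector.
#' @param probabilities same-length numeric vector.
#' @param threshold decision threshold (default 0.5).
#' @return Named numeric vector: `accuracy`, `auroc`, `sensitivity`,
#'   `specificity`.
#' @examples
#' compute_metrics(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.2))
#' @export
compute_metrics <- function(labels, probabilities, threshold = 0.5) {
  stopifnot(length(labels) == length(probabilities),
            all(labels %in% c(0, 1)))
  pred <- as.integer(probabilities >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  auroc <- if (n1 == 0 || n0 == 0) {
    warning("AUROC undefined: labels contain a single class", call. = FALSE)
    NA_real_
  } else {
    r <- rank(probabilities) # midranks handle ties as 0.5
    (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  c(accuracy = (tp + tn) / length(labels),
    auroc = auroc,
    sensitivity = if (n1 > 0) tp / (tp + fn) else NA_real_,
    specificity = if (n0 > 0) tn / (tn + fp) else NA_real_)
}

# Hard leakage audit: a participant's segments may appear in at most one
# of train/val/test for a given split.
assert_no_leakage <- function(meta, fold, split) {
  role <- ifelse(fold[meta$participant_id] == split$test, "test",
          ifelse(fold[meta$participant_id] == split$val, "val", "train"))
  tab <- table(meta$participant_id, role)
  if (any(rowSums(tab > 0) > 1))
    stop("leakage: a participant appears in more than one of train/val/test",
         call. = FALSE)
  invisible(role)
}

#' Repeated cross-validated training and evaluation of the classifier
#'
#' Runs `reps` repetitions of participant-level `k`-fold CV for one binary
#' task under one training strategy. With `strategy = "separate"` a model
#' is trained, validated and tested within each diagnostic group; with
#' `"combined"` one model per split is trained on the pooled groups and
#' its test metrics are additionally stratified by group. Test
#' predictions are pooled within each repetition (every participant is
#' tested exactly once per repetition) before metrics are computed, and
#' the final summary is the mean and SD over the per-repetition metrics.
#'
#' @param segments a segment store from [build_segments()].
#' @param task one of `"phase5min"`, `"b4b5"`, `"b5s1"`, `"s1s2"`.
#' @param strategy `"combined"` (pooled training) or `"separate"`.
#' @param model_spec a [resnet_spec()] for the task's input length.
#' @param train_cfg a [train_config()].
#' @param k,reps folds and repetitions (study protocol: 10 and 10).
#' @param seed seed governing fold plans and per-split training seeds.
#' @return An object of class `cv_result`: data.frame with columns task,
#'   strategy, group, repetition and the four metrics; attribute
#'   `n_models` counts trained models.
#' @export
run_repeated_cv <- function(segments, task, strategy = c("combined", "separate"),
                            model_spec, train_cfg = train_config(),
                            k = 10L, reps = 10L, seed = 1L) {
  strategy <- match.arg(strategy)
  ts <- task_segments(segments, task)
  if (ncol(ts$x) != model_spec$input_len)
    stop(sprintf("input error: task %s segments have length %d, model spec expects %d",
                 task, ncol(ts$x), model_spec$input_len), call. = FALSE)
  parts <- unique(ts$meta[, c("participant_id", "group")])
  names(parts)[1] <- "id"
  plan <- participant_folds(parts, k = k, reps = reps,
                            seed = mix_seed(seed, "folds"))
  groups <- sort(unique(parts$group))
  rows <- list()
  n_models <- 0L
  for (r in seq_len(reps)) {
    fold <- plan$assignments[[r]]
    pred <- rep(NA_real_, nrow(ts$x))
    for (split in fold_splits(plan, r)) {
      role <- assert_no_leakage(ts$meta, fold, split)
      if (strategy == "combined") {
        model <- build_model(model_spec,
                             seed = mix_seed(seed, "init", r, split$test))
        cfg <- train_cfg
        cfg$seed <- mix_seed(seed, "train", r, split$test)
        model <- train_model(model,
                             ts$x[role == "train", , drop = FALSE],
                             ts$y[role == "train"],
                             ts$x[role == "val", , drop = FALSE],
                             ts$y[role == "val"], cfg)
        n_models <- n_models + 1L
        pred[role == "test"] <-
          predict(model, ts$x[role == "test", , drop = FALSE])
      } else {
        for (g in groups) {
          gi <- ts$meta$group == g
          model <- build_model(model_spec,
                               seed = mix_seed(seed, "init", r, split$test, g))
          cfg <- train_cfg
          cfg$seed <- mix_seed(seed, "train", r, split$test, g)
          model <- train_model(model,
                               ts$x[gi & role == "train", , drop = FALSE],
                               ts$y[gi & role == "train"],
                               ts$x[gi & role == "val", , drop = FALSE],
                               ts$y[gi & role == "val"], cfg)
          n_models <- n_models + 1L
          pred[gi & role == "test"] <-
            predict(model, ts$x[gi & role == "test", , drop = FALSE])
        }
      }
    }
    stopifnot(!anyNA(pred)) # every segment tested exactly once per repetition
    cells <- c(as.list(groups), list(groups))
    names(cells) <- c(groups, "all")
    for (cn in names(cells)) {
      sel <- ts$meta$group %in% cells[[cn]]
      m <- compute_metrics(ts$y[sel], pred[sel])
      rows[[length(rows) + 1L]] <- data.frame(
        task = task, strategy = strategy, group = cn, repetition = r,
        accuracy = m[["accuracy"]], auroc = m[["auroc"]],
        sensitivity = m[["sensitivity"]], specificity = m[["specificity"]],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_models") <- n_models
  class(out) <- c("cv_result", class(out))
  out
}

#' @export
summary.cv_result <- function(object, ...) {
  df <- as.data.frame(unclass(object), stringsAsFactors = FALSE)
  metrics <- c("accuracy", "auroc", "sensitivity", "specificity")
  agg <- do.call(rbind, lapply(
    split(df, df[, c("task", "strategy", "group")], drop = TRUE),
    function(d) {
      out <- data.frame(task = d$task[1], strategy = d$strategy[1],
                        group = d$group[1], stringsAsFactors = FALSE)
      for (m in metrics) {
        out[[paste0(m, "_mean")]] <- mean(d[[m]])
        out[[paste0(m, "_sd")]] <- stats::sd(d[[m]])
      }
      out
    }))
  rownames(agg) <- NULL
  agg
}

#' @export
print.cv_result <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("Cross-validation result: task %s, strategy %s, %d repetition(s)\n",
              s$task[1], s$strategy[1], max(x$repetition)))
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-4s accuracy %.3f +/- %.3f  AUROC %s\n",
                s$group[i], s$accuracy_mean[i],
                ifelse(is.na(s$accuracy_sd[i]), 0, s$accuracy_sd[i]),
                ifelse(is.na(s$auroc_mean[i]), "NA",
                       sprintf("%.3f", s$auroc_mean[i]))))
  invisible(x)
}
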