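# Orchestration and on-disk formats: cohort CSV round-tripping, result
# writers, and the staged pipeline binding simulation, preprocessing, GEE
# reactivity analysis and cross-validated classification.

#' Write a cohort of beat series to CSV (with a JSON config sidecar)
#'
#' One row per beat: `participant_id, group, visit, phase, beat_index,
#' time_s, rri_ms`. Times are written to 1e-9 s and intervals to 1e-6 ms
#' so a read-back reproduces every series exactly at those tolerances. A
#' sidecar `<path>.json` stores the full simulation config (including the
#' seed) and the config hash.
#'
#' @param sessions list of session records ([simulate_cohort_sessions()]).
#' @param path output CSV path.
#' @param config optional [sim_config()] stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(sessions, path, config = NULL) {
  rows <- lapply(sessions, function(s) {
    do.call(rbind, lapply(list(s$baseline, s$stress), function(b)
      data.frame(participant_id = s$participant_id, group = s$group,
                 visit = s$visit, phase = b$phase,
                 beat_index = seq_along(b$rri),
                 time_s = sprintf("%.10f", b$beat_times),
                 rri_ms = sprintf("%.7f", b$rri),
                 stringsAsFactors = FALSE)))
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  if (!is.null(config)) {
    side <- unclass(config)
    side$config_hash <- config_hash(config)
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a cohort CSV back into session records
#'
#' Validates the file row by row: beat indices must run 1, 2, ... within
#' each recording (a duplicated or skipped index raises an error naming
#' the offending line) and beat times must be strictly increasing. A
#' header-only file yields an empty cohort with a warning.
#'
#' @param path CSV written by [write_cohort_csv()].
#' @return List of session records (`participant_id`, `group`, `visit`,
#'   `baseline`, `stress`).
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path))
    stop("missing artifact: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "group", "visit", "phase", "beat_index",
            "time_s", "rri_ms")
  if (!all(need %in% names(tab)))
    stop("malformed cohort CSV: missing columns ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  if (nrow(tab) == 0) {
    warning("cohort CSV has a header but no beats; returning an empty cohort",
            call. = FALSE)
    return(list())
  }
  key <- paste(tab$participant_id, tab$visit, tab$phase, sep = "\r")
  # line numbers in the file: header is line 1
  tab$line <- seq_len(nrow(tab)) + 1L
  out <- list()
  for (k in unique(key)) {
    d <- tab[key == k, , drop = FALSE]
    bad <- which(d$beat_index != seq_len(nrow(d)))
    if (length(bad))
      stop(sprintf("validation error at line %d: beat_index %d out of sequence (expected %d)",
                   d$line[bad[1]], d$beat_index[bad[1]], bad[1]), call. = FALSE)
    if (any(diff(d$time_s) <= 0))
      stop(sprintf("validation error at line %d: beat times not strictly increasing",
                   d$line[which(diff(d$time_s) <= 0)[1] + 1L]), call. = FALSE)
    series <- beat_series(d$participant_id[1], d$visit[1], d$phase[1],
                          d$time_s, d$rri_ms)
    skey <- paste(d$participant_id[1], d$visit[1], sep = "\r")
    if (is.null(out[[skey]]))
      out[[skey]] <- list(participant_id = d$participant_id[1],
                          group = d$group[1], visit = d$visit[1])
    out[[skey]][[d$phase[1]]] <- series
  }
  unname(out)
}

#' Write cross-validation results as tidy CSV
#'
#' Long format: one row per task x strategy x group x repetition x metric.
#'
#' @param results a `cv_result` (or rbind of several).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  df <- as.data.frame(results)
  metrics <- c("accuracy", "auroc", "sensitivity", "specificity")
  long <- do.call(rbind, lapply(metrics, function(m)
    data.frame(task = df$task, strategy = df$strategy, group = df$group,
               repetition = df$repetition, metric = m, value = df[[m]],
               stringsAsFactors = FALSE)))
  long <- long[order(long$task, long$strategy, long$group, long$repetition), ]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Assemble a full run configuration
#'
#' @param sim a [sim_config()].
#' @param model_spec a [resnet_spec()] for the 1-min tasks; the 5-min
#'   task reuses the spec with `input_len = 1200`.
#' @param train a [train_config()].
#' @param eval_reps,eval_folds repetitions and folds for cross-validation.
#' @param tasks classification tasks to evaluate.
#' @param gee_models GEE designs to fit.
#' @param seed global seed; stage seeds are derived deterministically
#'   from it, so every stage is independently reproducible.
#' @return An object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       model_spec = resnet_spec_small(240),
                       train = train_config(epochs = 10, patience = 3),
                       eval_reps = 1L, eval_folds = 10L,
                       tasks = c("b4b5", "b5s1", "s1s2"),
                       gee_models = c("phase5min", "epoch1min"),
                       seed = 1L) {
  stopifnot(inherits(sim, "sim_config"), inherits(model_spec, "resnet_spec"),
            inherits(train, "train_config"))
  tasks <- match.arg(tasks, c("phase5min", "b4b5", "b5s1", "s1s2"),
                     several.ok = TRUE)
  gee_models <- match.arg(gee_models, c("phase5min", "epoch1min"),
                          several.ok = TRUE)
  structure(list(sim = sim, model_spec = model_spec, train = train,
                 eval_reps = as.integer(eval_reps),
                 eval_folds = as.integer(eval_folds), tasks = tasks,
                 gee_models = gee_models, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Recognized top-level blocks: `sim`, `train`, `eval` (`reps`, `folds`),
#' `tasks`, `gee_models`, `seed`. Unknown keys raise a validation error
#' naming them.
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("sim", "train", "eval", "tasks", "gee_models", "seed",
             "model_spec")
  extra <- setdiff(names(y), known)
  if (length(extra))
    stop("config validation error: unknown keys ",
         paste(extra, collapse = ", "), call. = FALSE)
  sim <- do.call(sim_config, as.list(y$sim %||% list()))
  train <- do.call(train_config, as.list(y$train %||% list()))
  spec <- if (is.null(y$model_spec)) resnet_spec_small(240)
          else do.call(resnet_spec_small, as.list(y$model_spec))
  run_config(sim = sim, model_spec = spec, train = train,
             eval_reps = y$eval$reps %||% 1L,
             eval_folds = y$eval$folds %||% 10L,
             tasks = y$tasks %||% c("b4b5", "b5s1", "s1s2"),
             gee_models = y$gee_models %||% c("phase5min", "epoch1min"),
             seed = y$seed %||% 1L)
}

#' Run the staged analysis pipeline
#'
#' Stages (fixed order): `simulate` writes `cohort.csv` (+ JSON sidecar);
#' `preprocess` reads the cohort and writes the segment stores
#' (`phase_segments.csv`, `epoch_segments.csv` and metadata);
#' `gee` writes coefficient and contrast tables; `evaluate` runs
#' cross-validated classification for the configured tasks and writes
#' `cv_results.csv` plus `summary.json`. Every run writes
#' `provenance.json` (config hash, seed, package version, stage record
#' counts). A stage whose upstream artifact is missing stops with an
#' error naming the absent file. Re-running with an identical config
#' reproduces the artifacts byte-identically.
#'
#' @param config a [run_config()] or path to a YAML file.
#' @param out_dir output directory (created if needed).
#' @param stages subset of `c("simulate", "preprocess", "gee",
#'   "evaluate")`.
#' @param quiet suppress per-stage messages.
#' @return Invisibly, a list of the in-memory artifacts produced.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "preprocess", "gee",
                                    "evaluate"),
                         quiet = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, c("simulate", "preprocess", "gee", "evaluate"),
                      several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort_csv <- file.path(out_dir, "cohort.csv")
  say <- function(...) if (!quiet) message(sprintf(...))
  artifacts <- list()
  counts <- list()
  sessions <- NULL

  if ("simulate" %in% stages) {
    t0 <- proc.time()[3]
    cohort <- simulate_cohort(config$sim)
    sessions <- simulate_cohort_sessions(cohort)
    write_cohort_csv(sessions, cohort_csv, config = config$sim)
    counts$simulate <- length(sessions)
    say("simulate: %d sessions in %.1fs", length(sessions),
        proc.time()[3] - t0)
    artifacts$cohort <- cohort
    artifacts$sessions <- sessions
  }

  need_sessions <- function() {
    if (!is.null(sessions)) return(sessions)
    if (!file.exists(cohort_csv))
      stop("missing artifact: ", cohort_csv,
           " (run the simulate stage first)", call. = FALSE)
    sessions <<- read_cohort_csv(cohort_csv)
    sessions
  }

  segments <- NULL
  if ("preprocess" %in% stages) {
    t0 <- proc.time()[3]
    segments <- build_segments(need_sessions())
    for (set in c("phase", "epoch")) {
      st <- segments[[set]]
      utils::write.csv(cbind(st$meta, as.data.frame(st$x)),
                       file.path(out_dir, paste0(set, "_segments.csv")),
                       row.names = FALSE)
    }
    counts$preprocess <- nrow(segments$phase$meta) +
      nrow(segments$epoch$meta)
    say("preprocess: %d segments in %.1fs", counts$preprocess,
        proc.time()[3] - t0)
    artifacts$segments <- segments
  }

  if ("gee" %in% stages) {
    t0 <- proc.time()[3]
    ss <- need_sessions()
    gee_out <- list()
    for (m in config$gee_models) {
      tab <- if (m == "phase5min") phase_table(ss) else epoch_table(ss)
      utils::write.csv(tab, file.path(out_dir, paste0("gee_", m, "_table.csv")),
                       row.names = FALSE)
      fit <- fit_gee(tab, model = m)
      ct <- if (m == "phase5min") phase_contrasts(fit) else epoch_contrasts(fit)
      sm <- summary(fit)$coefficients
      utils::write.csv(data.frame(term = rownames(sm), sm, row.names = NULL),
                       file.path(out_dir, paste0("gee_", m, "_coefficients.csv")),
                       row.names = FALSE)
      utils::write.csv(ct, file.path(out_dir, paste0("gee_", m, "_contrasts.csv")),
                       row.names = FALSE)
      gee_out[[m]] <- list(fit = fit, contrasts = ct)
    }
    counts$gee <- length(gee_out)
    say("gee: %d models in %.1fs", length(gee_out), proc.time()[3] - t0)
    artifacts$gee <- gee_out
  }

  if ("evaluate" %in% stages) {
    t0 <- proc.time()[3]
    if (is.null(segments)) segments <- build_segments(need_sessions())
    res <- list()
    for (task in config$tasks) {
      spec <- config$model_spec
      if (task == "phase5min" && spec$input_len != 1200)
        spec <- resnet_spec(1200, stem = spec$stem, stages = spec$stages)
      for (strat in c("combined", "separate")) {
        res[[paste(task, strat, sep = "_")]] <- run_repeated_cv(
          segments, task, strategy = strat, model_spec = spec,
          train_cfg = config$train, k = config$eval_folds,
          reps = config$eval_reps,
          seed = mix_seed(config$seed, "evaluate", task, strat))
      }
    }
    all_res <- do.call(rbind, lapply(res, as.data.frame))
    utils::write.csv(all_res, file.path(out_dir, "cv_results.csv"),
                     row.names = FALSE)
    summ <- lapply(res, function(r) as.list(summary(r)))
    jsonlite::write_json(list(config_hash = config_hash(config),
                              tasks = config$tasks,
                              strategies = c("combined", "separate"),
                              results = summ),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    counts$evaluate <- nrow(all_res)
    say("evaluate: %d result rows in %.1fs", nrow(all_res),
        proc.time()[3] - t0)
    artifacts$cv <- res
  }

  jsonlite::write_json(
    list(config_hash = config_hash(config), seed = config$seed,
         package_version = as.character(utils::packageVersion("rristress")),
         stages = stages, record_counts = counts),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(artifacts)
}
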