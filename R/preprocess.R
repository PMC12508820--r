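# Preprocessing: irregular beat series -> fixed-length model inputs.
# Artifact filtering, natural-cubic-spline resampling onto an equidistant
# 4 Hz grid, 5-min phase segmentation with trailing zero padding, and
# 1-min epoch extraction (B4, B5 from the end of baseline; S1, S2 from the
# start of stress).

RESAMPLE_FS <- 4 # Hz
EPOCH_LEN <- 240L # 1 min at 4 Hz
PHASE_LEN <- 1200L # 5 min at 4 Hz

#' Filter artifactual beats from a beat series
#'
#' Flags beats whose RRI falls outside `[low, high]` ms or deviates from
#' the 5-beat running median by more than `rel_tol` (25% by default), then
#' replaces flagged intervals by natural cubic-spline interpolation over
#' beat index and recomputes beat times cumulatively. Series with more
#' than `max_frac` flagged beats are rejected outright: a recording that
#' corrupted is not trustworthy enough to repair.
#'
#' Idempotent on its own output: a repaired series passes the filter
#' unchanged.
#'
#' @param series a [beat_series()].
#' @param low,high acceptance bounds on the RRI (ms).
#' @param rel_tol maximal relative deviation from the local running median.
#' @param max_frac rejection threshold on the fraction of flagged beats.
#' @return The filtered [beat_series()], with attribute `"n_corrected"`
#'   holding the number of replaced beats.
#' @export
artifact_filter <- function(series, low = 300, high = 2000,
                            rel_tol = 0.25, max_frac = 0.2) {
  stopifnot(inherits(series, "beat_series"))
  r <- series$rri
  n <- length(r)
  if (n < 5) {
    attr(series, "n_corrected") <- 0L
    return(series)
  }
  med <- stats::runmed(r, 5, endrule = "median")
  flagged <- r < low | r > high | abs(r - med) > rel_tol * med
  n_flag <- sum(flagged)
  if (n_flag > max_frac * n)
    stop(sprintf("artifact filter: %d of %d beats flagged (> %.0f%%); series %s visit %d %s rejected",
                 n_flag, n, 100 * max_frac, series$participant_id,
                 series$visit, series$phase), call. = FALSE)
  if (n_flag > 0) {
    idx <- seq_len(n)
    f <- stats::splinefun(idx[!flagged], r[!flagged], method = "natural")
    r[flagged] <- pmax(f(idx[flagged]), 1)
    times <- cumsum(r) / 1000
    keep <- times <= series$duration + 1e-9
    series <- beat_series(series$participant_id, series$visit, series$phase,
                          times[keep], r[keep], duration = series$duration)
  }
  attr(series, "n_corrected") <- n_flag
  series
}

#' Resample a beat series onto an equidistant 4 Hz grid
#'
#' Fits a natural cubic spline to the (beat time, RRI) pairs and evaluates
#' it on the grid `k / 4` s for `k = 0 .. ceiling(4 * duration) - 1`. The
#' grid covers the span of the recording including the final ongoing
#' interval: a recording whose last beat falls at 299.4 s with an 850 ms
#' interval still covers the full 300 s phase (the heart keeps beating;
#' the phase ends mid-interval), so grid points up to one interval beyond
#' the last beat are evaluated (mild linear extrapolation of the natural
#' spline). Grid points beyond that are dropped and zero padding is
#' applied downstream when fixed-length segments are formed. Without this
#' tolerance the last window of every phase would carry a systematic
#' trailing-zero signature that downstream classifiers can exploit as an
#' artifactual class cue.
#'
#' @param series a [beat_series()] with at least 4 beats.
#' @param duration grid extent in seconds; defaults to the series' phase
#'   duration.
#' @return An object of class `resampled_series`: list with the recording
#'   metadata, `t0 = 0`, `fs = 4`, the grid `values` (ms) and the nominal
#'   grid length `n_grid = ceiling(4 * duration)`.
#' @export
resample_4hz <- function(series, duration = NULL) {
  stopifnot(inherits(series, "beat_series"))
  duration <- duration %||% series$duration
  if (length(series$rri) < 4)
    stop("insufficient data: cubic-spline resampling needs at least 4 beats",
         call. = FALSE)
  n_grid <- as.integer(ceiling(duration * RESAMPLE_FS))
  grid <- (seq_len(n_grid) - 1) / RESAMPLE_FS
  nb <- length(series$beat_times)
  span <- series$beat_times[nb] + series$rri[nb] / 1000
  keep <- grid <= span + 1e-9
  f <- stats::splinefun(series$beat_times, series$rri, method = "natural")
  values <- f(grid[keep])
  if (!all(is.finite(values)))
    stop("resampling produced non-finite values", call. = FALSE)
  structure(list(participant_id = series$participant_id,
                 visit = series$visit, phase = series$phase,
                 t0 = 0, fs = RESAMPLE_FS, values = values,
                 n_grid = n_grid, duration = duration),
            class = "resampled_series")
}

#' @export
print.resampled_series <- function(x, ...) {
  cat(sprintf("Resampled series: %s visit %d %s | %d of %d grid points at %g Hz\n",
              x$participant_id, x$visit, x$phase, length(x$values),
              x$n_grid, x$fs))
  invisible(x)
}

new_segment <- function(values, n_valid, label, participant_id, group,
                        visit) {
  structure(list(values = values, n_valid = as.integer(n_valid),
                 label = label, participant_id = participant_id,
                 group = group, visit = visit),
            class = "rri_segment")
}

#' Form a fixed-length 5-min segment from a resampled phase
#'
#' Pads the available 4 Hz samples with trailing zeros to exactly 1200
#' points (5 min at 4 Hz); `n_valid` records how many points are real.
#'
#' @param rs a `resampled_series` covering a 5-min phase.
#' @param group optional diagnostic group stamped on the segment.
#' @return An `rri_segment` of length 1200 labeled with the phase.
#' @export
segment_phase <- function(rs, group = NA_character_) {
  stopifnot(inherits(rs, "resampled_series"))
  nv <- length(rs$values)
  if (nv < 1) stop("segment has no valid samples", call. = FALSE)
  if (nv > PHASE_LEN)
    stop("resampled phase longer than 1200 samples", call. = FALSE)
  values <- c(rs$values, rep(0, PHASE_LEN - nv))
  new_segment(values, nv, rs$phase, rs$participant_id, group, rs$visit)
}

# Pull samples for grid window [from, to) seconds out of a resampled
# series; returns NULL when fewer than the full window is required and
# `require_full` is set.
epoch_window <- function(rs, from, to, label, group, require_full) {
  k0 <- as.integer(from * rs$fs) # first grid index (0-based)
  k1 <- as.integer(to * rs$fs) - 1L # last grid index
  avail <- length(rs$values)
  if (require_full && avail < k1 + 1L) return(NULL)
  if (avail < k0 + 1L) return(NULL)
  idx <- seq.int(k0 + 1L, min(k1 + 1L, avail))
  vals <- rs$values[idx]
  nv <- length(vals)
  new_segment(c(vals, rep(0, EPOCH_LEN - nv)), nv, label,
              rs$participant_id, group, rs$visit)
}

#' Extract the four 1-min epochs around stress onset
#'
#' B4 and B5 are the last two baseline minutes (grid windows [180, 240)
#' and [240, 300) s); S1 and S2 are the first two stress minutes ([0, 60)
#' and [60, 120) s). Each epoch is zero-padded to 240 points. Baseline
#' epochs require full coverage of their window (a baseline with fewer
#' than 240 s of valid samples yields `NULL` for the missing epoch, with a
#' warning); stress epochs tolerate a short tail.
#'
#' @param baseline,stress `resampled_series` for the two phases of one
#'   visit.
#' @param group optional diagnostic group stamped on the segments.
#' @return Named list with elements `B4`, `B5`, `S1`, `S2` (each an
#'   `rri_segment` or `NULL` if excluded).
#' @export
extract_epochs <- function(baseline, stress, group = NA_character_) {
  stopifnot(inherits(baseline, "resampled_series"),
            inherits(stress, "resampled_series"))
  out <- list(
    B4 = epoch_window(baseline, 180, 240, "B4", group, require_full = TRUE),
    B5 = epoch_window(baseline, 240, 300, "B5", group, require_full = FALSE),
    S1 = epoch_window(stress, 0, 60, "S1", group, require_full = FALSE),
    S2 = epoch_window(stress, 60, 120, "S2", group, require_full = FALSE))
  if (is.null(out$B4))
    warning(sprintf("epoch B4 excluded for %s visit %d: baseline shorter than 240 s of valid samples",
                    baseline$participant_id, baseline$visit), call. = FALSE)
  out
}

#' Build the classifier's segment sets from simulated sessions
#'
#' Runs the full preprocessing chain (artifact filter, 4 Hz resampling,
#' segmentation) over a list of sessions and assembles two matrices of
#' fixed-length inputs: the 5-min phase segments (1200 columns, labels
#' baseline/stress) and the 1-min epoch segments (240 columns, labels
#' B4/B5/S1/S2).
#'
#' @param sessions output of [simulate_cohort_sessions()] (or the
#'   equivalent read back from disk).
#' @param zscore if `TRUE`, z-score each segment over its valid points
#'   (padding stays zero). Off by default: raw ms preserves the mean-RRI
#'   shift that distinguishes the phases.
#' @param filter if `TRUE` (default) apply [artifact_filter()] first.
#' @return A list with components `phase` and `epoch`, each a list holding
#'   matrix `x` (one row per segment) and data.frame `meta`
#'   (`participant_id`, `group`, `visit`, `label`, `n_valid`).
#' @export
build_segments <- function(sessions, zscore = FALSE, filter = TRUE) {
  phase_rows <- list(); phase_meta <- list()
  epoch_rows <- list(); epoch_meta <- list()
  for (s in sessions) {
    b <- s$baseline; st <- s$stress
    if (filter) {
      b <- artifact_filter(b)
      st <- artifact_filter(st)
    }
    rb <- resample_4hz(b)
    rs <- resample_4hz(st)
    for (seg in list(segment_phase(rb, s$group), segment_phase(rs, s$group))) {
      phase_rows[[length(phase_rows) + 1L]] <- seg$values
      phase_meta[[length(phase_meta) + 1L]] <-
        data.frame(participant_id = seg$participant_id, group = seg$group,
                   visit = seg$visit, label = seg$label,
                   n_valid = seg$n_valid, stringsAsFactors = FALSE)
    }
    eps <- extract_epochs(rb, rs, s$group)
    for (seg in eps) {
      if (is.null(seg)) next
      epoch_rows[[length(epoch_rows) + 1L]] <- seg$values
      epoch_meta[[length(epoch_meta) + 1L]] <-
        data.frame(participant_id = seg$participant_id, group = seg$group,
                   visit = seg$visit, label = seg$label,
                   n_valid = seg$n_valid, stringsAsFactors = FALSE)
    }
  }
  pack <- function(rows, meta) {
    x <- do.call(rbind, rows)
    m <- do.call(rbind, meta)
    if (zscore && !is.null(x)) {
      for (i in seq_len(nrow(x))) {
        nv <- m$n_valid[i]
        v <- x[i, seq_len(nv)]
        s <- stats::sd(v)
        x[i, seq_len(nv)] <- if (s > 0) (v - mean(v)) / s else 0
      }
    }
    list(x = x, meta = m)
  }
  list(phase = pack(phase_rows, phase_meta),
       epoch = pack(epoch_rows, epoch_meta))
}

#' Select and label segments for one binary classification task
#'
#' Tasks: `phase5min` (baseline vs stress 5-min segments, stress
#' positive), `b4b5` (B4 positive), `b5s1` (S1 positive), `s1s2` (S2
#' positive).
#'
#' @param segments output of [build_segments()].
#' @param task one of `"phase5min"`, `"b4b5"`, `"b5s1"`, `"s1s2"`.
#' @return List with `x` (matrix), `y` (0/1 labels) and `meta`.
#' @export
task_segments <- function(segments,
                          task = c("phase5min", "b4b5", "b5s1", "s1s2")) {
  task <- match.arg(task)
  spec <- switch(task,
    phase5min = list(set = "phase", pos = "stress", neg = "baseline"),
    b4b5 = list(set = "epoch", pos = "B4", neg = "B5"),
    b5s1 = list(set = "epoch", pos = "S1", neg = "B5"),
    s1s2 = list(set = "epoch", pos = "S2", neg = "S1"))
  st <- segments[[spec$set]]
  if (is.null(st$x) || !any(st$meta$label %in% c(spec$pos, spec$neg)))
    stop(sprintf("input error: no segments labeled for task %s", task),
         call. = FALSE)
  sel <- st$meta$label %in% c(spec$pos, spec$neg)
  list(x = st$x[sel, , drop = FALSE],
       y = as.integer(st$meta$label[sel] == spec$pos),
       meta = st$meta[sel, , drop = FALSE],
       task = task, positive = spec$pos)
}
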