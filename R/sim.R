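# Synthetic cohort generator: longitudinal beat-by-beat RRI recordings for
# three diagnostic groups (MDD, PD, HC) over up to five visits, each visit
# holding a 5-min resting baseline and a 5-min mental-arithmetic stress phase.
#
# The generator encodes the autonomic structure the downstream stages are
# built to detect: stress shortens the mean RRI in every group (vagal
# withdrawal), the shortening is attenuated in MDD and PD relative to HC,
# the first stress minute (S1) is the nadir, and from the second minute (S2)
# the RRI rebounds in HC and PD but not in MDD.

GROUPS <- c("MDD", "PD", "HC")
PHASE_DURATION <- 300 # seconds per phase

#' Simulation configuration for a synthetic RRI cohort
#'
#' Bundles every knob of the cohort generator and validates the
#' physiological invariants. Defaults describe a resting adult cohort with
#' group sizes 41 (MDD), 47 (PD) and 59 (HC), the visit-attendance pattern
#' 110/16/4/7/10 participants completing 5/4/3/2/1 visits (rescaled when
#' the cohort size differs), and stress reactivity ordered
#' |delta_HC| > |delta_MDD|, |delta_PD| with an S1-to-S2 rebound in HC and
#' PD only. The reactivity magnitudes are tunable model choices, not
#' measured values.
#'
#' @param n_per_group named integer vector of participants per diagnostic
#'   group (names `MDD`, `PD`, `HC`).
#' @param visit_attendance named numeric vector: number of participants
#'   completing 5, 4, 3, 2, 1 visits (names `"5"` .. `"1"`). Rescaled to
#'   the cohort size by largest-remainder rounding.
#' @param mu_rri population mean baseline RRI (ms).
#' @param sigma_subject between-subject SD of the baseline RRI (ms).
#' @param delta named vector, mean stress-induced RRI change per group
#'   (ms, negative = shortening).
#' @param rebound named vector, mean S1-to-S2 RRI recovery per group (ms).
#' @param sigma_delta SD of the per-session perturbation of the stress
#'   shift (ms); models visit-to-visit reactivity variability.
#' @param lf_amp,hf_amp_base,hf_amp_stress amplitudes (ms) of the
#'   low-frequency oscillation and of the high-frequency (respiratory)
#'   oscillation during baseline and stress. `hf_amp_stress <
#'   hf_amp_base` encodes vagal withdrawal.
#' @param lf_freq,hf_freq oscillation frequencies (Hz).
#' @param sigma_noise per-beat Gaussian noise SD (ms).
#' @param rri_floor physiological floor applied to generated intervals (ms).
#' @param visit_shift optional length-5 vector of per-visit additive RRI
#'   shifts (ms); zero by default (visit enters the GEE models only as a
#'   nuisance covariate).
#' @param seed integer seed governing every random draw of the cohort.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_per_group = c(MDD = 2, PD = 2, HC = 2), seed = 42)
#' cfg$delta
#' @export
sim_config <- function(n_per_group = c(MDD = 41, PD = 47, HC = 59),
                       visit_attendance = c(`5` = 110, `4` = 16, `3` = 4,
                                            `2` = 7, `1` = 10),
                       mu_rri = 850,
                       sigma_subject = 70,
                       delta = c(MDD = -35, PD = -30, HC = -60),
                       rebound = c(MDD = 0, PD = 12, HC = 15),
                       sigma_delta = 8,
                       lf_amp = 25,
                       hf_amp_base = 40,
                       hf_amp_stress = 20,
                       lf_freq = 0.1,
                       hf_freq = 0.25,
                       sigma_noise = 10,
                       rri_floor = 300,
                       visit_shift = rep(0, 5),
                       seed = 1L) {
  n_per_group <- unlist(n_per_group)[GROUPS]
  visit_attendance <- unlist(visit_attendance)
  delta <- unlist(delta)[GROUPS]
  rebound <- unlist(rebound)[GROUPS]
  visit_shift <- unlist(visit_shift)
  if (anyNA(n_per_group) || any(n_per_group < 0) || sum(n_per_group) < 1)
    stop("configuration error: `n_per_group` must give non-negative counts for MDD, PD, HC",
         call. = FALSE)
  if (length(visit_attendance) == 0 || any(visit_attendance < 0) ||
      sum(visit_attendance) <= 0)
    stop("configuration error: `visit_attendance` must be a non-empty, non-negative distribution",
         call. = FALSE)
  if (is.null(names(visit_attendance)) ||
      !all(names(visit_attendance) %in% as.character(1:5)))
    stop("configuration error: `visit_attendance` names must be visit counts in 1..5",
         call. = FALSE)
  amps <- c(lf_amp = lf_amp, hf_amp_base = hf_amp_base,
            hf_amp_stress = hf_amp_stress, sigma_noise = sigma_noise,
            sigma_subject = sigma_subject, sigma_delta = sigma_delta)
  if (any(amps < 0))
    stop("configuration error: amplitudes and SDs must be >= 0", call. = FALSE)
  if (anyNA(delta) || anyNA(rebound))
    stop("configuration error: `delta` and `rebound` need entries for MDD, PD, HC",
         call. = FALSE)
  if (any(mu_rri + delta <= rri_floor))
    stop("configuration error: mu_rri + delta must exceed the ", rri_floor,
         " ms physiological floor for every group", call. = FALSE)
  if (length(visit_shift) != 5)
    stop("configuration error: `visit_shift` must have length 5", call. = FALSE)
  structure(
    list(n_per_group = n_per_group, visit_attendance = visit_attendance,
         mu_rri = mu_rri, sigma_subject = sigma_subject, delta = delta,
         rebound = rebound, sigma_delta = sigma_delta, lf_amp = lf_amp,
         hf_amp_base = hf_amp_base, hf_amp_stress = hf_amp_stress,
         lf_freq = lf_freq, hf_freq = hf_freq, sigma_noise = sigma_noise,
         rri_floor = rri_floor, visit_shift = visit_shift,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic RRI cohort configuration\n")
  cat(sprintf("  participants: MDD %d, PD %d, HC %d (seed %d)\n",
              x$n_per_group[["MDD"]], x$n_per_group[["PD"]],
              x$n_per_group[["HC"]], x$seed))
  cat(sprintf("  baseline RRI: %g ms (between-subject SD %g ms)\n",
              x$mu_rri, x$sigma_subject))
  cat(sprintf("  stress delta (ms): MDD %g, PD %g, HC %g\n",
              x$delta[["MDD"]], x$delta[["PD"]], x$delta[["HC"]]))
  cat(sprintf("  S1->S2 rebound (ms): MDD %g, PD %g, HC %g\n",
              x$rebound[["MDD"]], x$rebound[["PD"]], x$rebound[["HC"]]))
  invisible(x)
}

# Largest-remainder rescaling of the attendance distribution to n participants.
rescale_attendance <- function(visit_attendance, n) {
  p <- visit_attendance / sum(visit_attendance)
  raw <- p * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    take <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[take] <- cnt[take] + 1
  }
  stats::setNames(as.integer(cnt), names(visit_attendance))
}

#' Construct a validated beat series
#'
#' A beat series is one participant-visit-phase recording: strictly
#' increasing beat times (seconds from phase onset) and per-beat RR
#' intervals in ms, self-consistent with the successive time differences
#' (the phase onset acts as time zero for the first interval).
#'
#' @param participant_id,visit,phase recording metadata; `phase` is
#'   `"baseline"` or `"stress"`.
#' @param beat_times numeric vector, strictly increasing, `<= duration`.
#' @param rri per-beat intervals (ms), `rri[i] = (t[i] - t[i-1]) * 1000`
#'   with `t[0] = 0`.
#' @param duration phase duration in seconds (default 300).
#' @return An object of class `beat_series`.
#' @export
beat_series <- function(participant_id, visit, phase, beat_times, rri,
                        duration = PHASE_DURATION) {
  phase <- match.arg(phase, c("baseline", "stress"))
  if (length(beat_times) != length(rri))
    stop("beat_times and rri must have equal length", call. = FALSE)
  if (length(beat_times)) {
    if (any(diff(beat_times) <= 0) || beat_times[1] <= 0)
      stop("beat times must be strictly increasing and positive", call. = FALSE)
    if (any(rri <= 0)) stop("rri must be positive", call. = FALSE)
    if (beat_times[length(beat_times)] > duration + 1e-9)
      stop("last beat time exceeds the phase duration", call. = FALSE)
    implied <- diff(c(0, beat_times)) * 1000
    if (max(abs(implied - rri)) > 1e-6) # 1e-9 s expressed in ms
      stop("rri inconsistent with successive beat-time differences", call. = FALSE)
  }
  structure(list(participant_id = participant_id, visit = as.integer(visit),
                 phase = phase, beat_times = as.numeric(beat_times),
                 rri = as.numeric(rri), duration = duration),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("Beat series: %s visit %d %s | %d beats over %.1f s, mean RRI %.1f ms\n",
              x$participant_id, x$visit, x$phase, length(x$rri),
              if (length(x$beat_times)) max(x$beat_times) else 0,
              if (length(x$rri)) mean(x$rri) else NA_real_))
  invisible(x)
}

# Core beat-by-beat integrator. The instantaneous mean is a step function
# of time (constant `mu` before `step_at`, `mu + step` after), on top of
# which LF and HF sinusoids and white per-beat noise are superposed:
#   rri(t_n) = mu(t_n) + lf_amp sin(2 pi f_lf t_n) + hf_amp sin(2 pi f_hf t_n) + eps_n
#   t_{n+1}  = t_n + rri(t_n) / 1000
# starting at t_0 = 0 and stopping once the next beat would pass `duration`.
# Intervals are clipped below at `floor` ms; parameter sets that would push
# more than 1% of raw intervals to <= 0 trigger a warning.
rri_generate <- function(mu, step = 0, step_at = Inf,
                         lf_amp, hf_amp, sigma_noise, duration,
                         lf_freq, hf_freq, floor_ms = 300) {
  nmax <- as.integer(ceiling(duration * 1000 / floor_ms)) + 8L
  eps <- if (sigma_noise > 0) stats::rnorm(nmax, 0, sigma_noise) else numeric(nmax)
  times <- numeric(nmax)
  rris <- numeric(nmax)
  w_lf <- 2 * pi * lf_freq
  w_hf <- 2 * pi * hf_freq
  t <- 0
  n <- 0L
  n_nonpos <- 0L
  repeat {
    m <- if (t < step_at) mu else mu + step
    r <- m + lf_amp * sin(w_lf * t) + hf_amp * sin(w_hf * t) + eps[n + 1L]
    if (r <= 0) n_nonpos <- n_nonpos + 1L
    if (r < floor_ms) r <- floor_ms
    tn <- t + r / 1000
    if (tn > duration) break
    n <- n + 1L
    times[n] <- tn
    rris[n] <- r
    t <- tn
  }
  if (n > 0L && n_nonpos > 0.01 * n)
    warning(sprintf("rri generator: %d of %d raw intervals were <= 0 before clipping",
                    n_nonpos, n), call. = FALSE)
  list(beat_times = times[seq_len(n)], rri = rris[seq_len(n)])
}

#' Generate one beat series from an oscillatory RRI process
#'
#' Beats are produced iteratively: the interval at time `t` is the mean RRI
#' plus LF and HF sinusoids plus Gaussian per-beat noise, and the next beat
#' falls one interval later. Generation stops at `duration`; intervals are
#' clipped below at `floor_ms`.
#'
#' @param mean_rri mean RRI (ms), `> 0`.
#' @param lf_amp,hf_amp oscillation amplitudes (ms).
#' @param sigma_noise per-beat noise SD (ms).
#' @param duration recording length (s), `> 0`.
#' @param seed integer seed; the same seed reproduces the series exactly.
#' @param lf_freq,hf_freq oscillation frequencies (Hz).
#' @param floor_ms clipping floor (ms).
#' @param participant_id,visit,phase metadata stamped on the result.
#' @return A [beat_series()].
#' @examples
#' s <- rri_process(1000, 0, 0, 0, duration = 300, seed = 1)
#' length(s$rri)      # 300 beats
#' unique(s$rri)      # all exactly 1000 ms
#' @export
rri_process <- function(mean_rri, lf_amp = 0, hf_amp = 0, sigma_noise = 0,
                        duration = PHASE_DURATION, seed = 1L,
                        lf_freq = 0.1, hf_freq = 0.25, floor_ms = 300,
                        participant_id = "sim", visit = 1L,
                        phase = "baseline") {
  stopifnot(mean_rri > 0, duration > 0)
  g <- with_seed(seed,
    rri_generate(mu = mean_rri, lf_amp = lf_amp, hf_amp = hf_amp,
                 sigma_noise = sigma_noise, duration = duration,
                 lf_freq = lf_freq, hf_freq = hf_freq, floor_ms = floor_ms))
  beat_series(participant_id, visit, phase, g$beat_times, g$rri,
              duration = duration)
}

#' Simulate the participant roster of a cohort
#'
#' Draws each participant's subject-level baseline RRI and the set of
#' visits attended. Group sizes equal the configured counts exactly; the
#' number of attended visits follows the configured attendance
#' distribution rescaled to the cohort size. Deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return An object of class `rri_cohort`: a list with `participants`
#'   (list of participant records with `id`, `group`, `baseline_mu`,
#'   `visits`) and the `config`.
#' @examples
#' coh <- simulate_cohort(sim_config(n_per_group = c(MDD = 1, PD = 1, HC = 1)))
#' length(coh$participants)
#' @export
simulate_cohort <- function(config = sim_config()) {
  if (!inherits(config, "sim_config"))
    stop("configuration error: `config` must be a sim_config", call. = FALSE)
  n_total <- sum(config$n_per_group)
  counts <- rescale_attendance(config$visit_attendance, n_total)
  with_seed(config$seed, {
    group <- rep(GROUPS, times = config$n_per_group)
    id <- sprintf("%s%03d", group, unlist(lapply(config$n_per_group, seq_len)))
    baseline_mu <- stats::rnorm(n_total, config$mu_rri, config$sigma_subject)
    # assign attendance counts to a random permutation of the cohort
    n_visits_pool <- rep(as.integer(names(counts)), times = counts)
    n_visits <- n_visits_pool[sample.int(n_total)]
    participants <- vector("list", n_total)
    for (i in seq_len(n_total)) {
      v <- if (n_visits[i] >= 5L) 1:5 else sort(sample(1:5, n_visits[i]))
      participants[[i]] <- list(id = id[i], group = group[i],
                                baseline_mu = baseline_mu[i],
                                visits = as.integer(v))
    }
    structure(list(participants = participants, config = config),
              class = "rri_cohort")
  })
}

#' @export
print.rri_cohort <- function(x, ...) {
  grp <- vapply(x$participants, `[[`, "", "group")
  nv <- vapply(x$participants, function(p) length(p$visits), 0L)
  cat(sprintf("Synthetic RRI cohort: %d participants (MDD %d, PD %d, HC %d), %d attended visits\n",
              length(x$participants), sum(grp == "MDD"), sum(grp == "PD"),
              sum(grp == "HC"), sum(nv)))
  cat("  visits per participant: ",
      paste(sprintf("%dx%d", tabulate(nv, 5), 1:5)[tabulate(nv, 5) > 0],
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Simulate the two phase recordings of one attended visit
#'
#' The baseline phase uses the participant's subject-level mean RRI and the
#' baseline HF amplitude. The stress phase applies the group's stress shift
#' (plus a per-session Normal(0, `sigma_delta`) perturbation) from onset,
#' and adds the group's rebound from the second minute onward; its HF
#' amplitude is the reduced stress value, encoding vagal withdrawal. Both
#' phases last 300 s. Deterministic given the cohort seed, participant and
#' visit.
#'
#' @param p a participant record from [simulate_cohort()].
#' @param visit visit index; must be in `p$visits`.
#' @param config the [sim_config()] used to build the cohort.
#' @return A list with elements `baseline` and `stress`, both [beat_series()].
#' @export
simulate_session <- function(p, visit, config) {
  if (!visit %in% p$visits)
    stop(sprintf("lookup error: participant %s did not attend visit %d",
                 p$id, visit), call. = FALSE)
  seed_s <- mix_seed(config$seed, "session", p$id, visit)
  mu_b <- p$baseline_mu + config$visit_shift[visit]
  g <- p$group
  with_seed(seed_s, {
    d <- config$delta[[g]] +
      if (config$sigma_delta > 0) stats::rnorm(1, 0, config$sigma_delta) else 0
    base <- rri_generate(mu = mu_b, lf_amp = config$lf_amp,
                         hf_amp = config$hf_amp_base,
                         sigma_noise = config$sigma_noise,
                         duration = PHASE_DURATION,
                         lf_freq = config$lf_freq, hf_freq = config$hf_freq,
                         floor_ms = config$rri_floor)
    stre <- rri_generate(mu = mu_b + d, step = config$rebound[[g]],
                         step_at = 60,
                         lf_amp = config$lf_amp,
                         hf_amp = config$hf_amp_stress,
                         sigma_noise = config$sigma_noise,
                         duration = PHASE_DURATION,
                         lf_freq = config$lf_freq, hf_freq = config$hf_freq,
                         floor_ms = config$rri_floor)
    list(baseline = beat_series(p$id, visit, "baseline",
                                base$beat_times, base$rri),
         stress = beat_series(p$id, visit, "stress",
                              stre$beat_times, stre$rri))
  })
}

#' Simulate every attended session of a cohort
#'
#' Convenience wrapper running [simulate_session()] for each
#' participant-visit; one baseline and one stress recording per attended
#' visit.
#'
#' @param cohort an `rri_cohort` from [simulate_cohort()].
#' @return A list of session records, each with `participant_id`, `group`,
#'   `visit`, `baseline`, `stress`.
#' @export
simulate_cohort_sessions <- function(cohort) {
  stopifnot(inherits(cohort, "rri_cohort"))
  out <- vector("list", sum(vapply(cohort$participants,
                                   function(p) length(p$visits), 0L)))
  k <- 0L
  for (p in cohort$participants) {
    for (v in p$visits) {
      k <- k + 1L
      s <- simulate_session(p, v, cohort$config)
      out[[k]] <- list(participant_id = p$id, group = p$group, visit = v,
                       baseline = s$baseline, stress = s$stress)
    }
  }
  out
}
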