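# Population-average reactivity analysis: Gaussian-identity generalized
# estimating equations with an exchangeable (or independence / AR(1))
# working correlation, moment estimation of the correlation parameter,
# Liang-Zeger robust sandwich covariance, and Wald z contrasts.
#
# Two designs are supported: the 5-min model (response = per-recording
# mean RRI; fixed effects phase * group + visit) and the 1-min model
# (response = per-epoch mean RRI; epoch * group + visit). References:
# phase = baseline, group = HC, epoch = S1.

#' Long-format table of 5-min phase means
#'
#' One row per participant-visit-phase. The response is the mean of the
#' 4 Hz resampled RRI series — the time-weighted summary of the recording,
#' matching the classifier's preprocessing. (The naive per-beat mean is
#' biased low by about `osc_var / (2 mu)` because short intervals are
#' sampled more often; since the oscillation amplitude differs between
#' phases, that bias would leak into the phase contrast.) Observations
#' are ordered by participant, visit, then phase (baseline before
#' stress).
#'
#' @param sessions output of [simulate_cohort_sessions()].
#' @param filter apply [artifact_filter()] before averaging (default
#'   `FALSE`; the synthetic generator emits clean beats, and filtering is
#'   performed explicitly in the preprocessing pipeline).
#' @return data.frame with columns `participant_id`, `group`, `visit`,
#'   `phase`, `rri`.
#' @export
phase_table <- function(sessions, filter = FALSE) {
  rows <- lapply(sessions, function(s) {
    b <- if (filter) artifact_filter(s$baseline) else s$baseline
    st <- if (filter) artifact_filter(s$stress) else s$stress
    data.frame(participant_id = s$participant_id, group = s$group,
               visit = s$visit, phase = c("baseline", "stress"),
               rri = c(mean(resample_4hz(b)$values),
                       mean(resample_4hz(st)$values)),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab[order(tab$participant_id, tab$visit, tab$phase), , drop = FALSE]
}

#' Long-format table of 1-min epoch means
#'
#' One row per participant-visit-epoch (B4, B5 = last two baseline
#' minutes; S1, S2 = first two stress minutes). As in [phase_table()],
#' the response is the mean over the epoch's window of the 4 Hz
#' resampled series.
#'
#' @inheritParams phase_table
#' @return data.frame with columns `participant_id`, `group`, `visit`,
#'   `epoch`, `rri`.
#' @export
epoch_table <- function(sessions, filter = FALSE) {
  win_mean <- function(rs, from, to) {
    idx <- seq.int(from * rs$fs + 1L, to * rs$fs)
    idx <- idx[idx <= length(rs$values)]
    if (!length(idx)) return(NA_real_)
    mean(rs$values[idx])
  }
  rows <- lapply(sessions, function(s) {
    b <- if (filter) artifact_filter(s$baseline) else s$baseline
    st <- if (filter) artifact_filter(s$stress) else s$stress
    rb <- resample_4hz(b)
    rst <- resample_4hz(st)
    data.frame(participant_id = s$participant_id, group = s$group,
               visit = s$visit, epoch = c("B4", "B5", "S1", "S2"),
               rri = c(win_mean(rb, 180, 240), win_mean(rb, 240, 300),
                       win_mean(rst, 0, 60), win_mean(rst, 60, 120)),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[!is.na(tab$rri), , drop = FALSE]
  tab[order(tab$participant_id, tab$visit, tab$epoch), , drop = FALSE]
}

# Iteratively reweighted GEE solver, Gaussian family, identity link.
# Exchangeable alpha is the moment estimator over within-cluster residual
# products; phi is the mean squared Pearson residual; both use the
# conventional bias correction subtracting the parameter count.
gee_engine <- function(X, y, id, corstr = "exchangeable",
                       tol = 1e-8, maxit = 100L) {
  p <- ncol(X)
  if (qr(X)$rank < p)
    stop("design error: model matrix is rank deficient", call. = FALSE)
  id <- as.character(id)
  clusters <- split(seq_along(y), factor(id, levels = unique(id)))
  n_clus <- length(clusters)
  if (n_clus < 2) stop("design error: need at least 2 clusters", call. = FALSE)
  sizes <- lengths(clusters)
  beta <- qr.solve(qr(X), y) # OLS start
  alpha <- 0
  phi <- mean((y - X %*% beta)^2)
  converged <- FALSE
  iter <- 0L
  N <- length(y)
  for (iter in seq_len(maxit)) {
    r <- as.vector(y - X %*% beta)
    phi <- sum(r^2) / (N - p)
    if (corstr == "exchangeable") {
      num <- 0
      den <- 0
      for (ix in clusters) {
        ni <- length(ix)
        if (ni < 2) next
        ri <- r[ix]
        num <- num + (sum(ri)^2 - sum(ri^2)) / 2
        den <- den + ni * (ni - 1) / 2
      }
      alpha <- if (den > p) num / phi / (den - p) else 0
      alpha <- min(max(alpha, -1 / (max(sizes) - 1 + 1e-12) + 1e-8),
                   1 - 1e-8)
    } else if (corstr == "ar1") {
      num <- 0
      den <- 0
      for (ix in clusters) {
        ni <- length(ix)
        if (ni < 2) next
        ri <- r[ix]
        num <- num + sum(ri[-ni] * ri[-1])
        den <- den + (ni - 1)
      }
      alpha <- if (den > p) num / phi / (den - p) else 0
      alpha <- min(max(alpha, -1 + 1e-8), 1 - 1e-8)
    } else alpha <- 0
    A <- matrix(0, p, p)
    bvec <- numeric(p)
    for (ix in clusters) {
      ni <- length(ix)
      Ri <- switch(corstr,
        exchangeable = (1 - alpha) * diag(ni) + alpha,
        ar1 = alpha^abs(outer(seq_len(ni), seq_len(ni), "-")),
        independence = diag(ni))
      Wi <- solve(Ri)
      Xi <- X[ix, , drop = FALSE]
      A <- A + crossprod(Xi, Wi %*% Xi)
      bvec <- bvec + crossprod(Xi, Wi %*% y[ix])
    }
    beta_new <- solve(A, bvec)
    delta <- max(abs(beta_new - beta)) / max(1, max(abs(beta)))
    beta <- as.vector(beta_new)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  # Liang-Zeger sandwich: B^-1 M B^-1 with B the model-based information
  # and M the empirical meat.
  r <- as.vector(y - X %*% beta)
  B <- matrix(0, p, p)
  M <- matrix(0, p, p)
  for (ix in clusters) {
    ni <- length(ix)
    Ri <- switch(corstr,
      exchangeable = (1 - alpha) * diag(ni) + alpha,
      ar1 = alpha^abs(outer(seq_len(ni), seq_len(ni), "-")),
      independence = diag(ni))
    Wi <- solve(Ri)
    Xi <- X[ix, , drop = FALSE]
    u <- crossprod(Xi, Wi %*% r[ix])
    B <- B + crossprod(Xi, Wi %*% Xi)
    M <- M + tcrossprod(u)
  }
  Binv <- solve(B)
  vrobust <- Binv %*% M %*% Binv
  vrobust <- (vrobust + t(vrobust)) / 2
  list(beta = stats::setNames(as.vector(beta), colnames(X)),
       vrobust = vrobust, vnaive = Binv * phi, alpha = alpha, phi = phi,
       n_clusters = n_clus, iterations = iter, converged = converged)
}

#' Fit a population-average GEE reactivity model
#'
#' Gaussian family, identity link. The `phase5min` model regresses the
#' per-recording mean RRI on phase * group + visit (references: baseline,
#' HC); the `epoch1min` model regresses the per-epoch mean RRI on
#' epoch * group + visit (reference epoch S1). Participants are clusters,
#' observations ordered by visit then phase/epoch. The visit covariate is
#' included only when more than one visit level is present. Coefficients
#' solve the estimating equations under the chosen working correlation
#' (moment estimator for the correlation parameter, updated each
#' iteration, relative tolerance 1e-8, at most 100 iterations); the
#' reported covariance is the Liang-Zeger robust sandwich.
#'
#' @param table a long table from [phase_table()] or [epoch_table()] (or
#'   equivalent data with the same columns).
#' @param model `"phase5min"` or `"epoch1min"`.
#' @param corstr working correlation: `"exchangeable"` (default),
#'   `"independence"`, or `"ar1"` (implemented but off by default; AR(1)
#'   can fail to converge when clusters hold as few as two observations).
#' @param tol,maxit convergence control.
#' @return An object of class `rri_gee` with elements `coefficients`,
#'   `vrobust`, `vnaive`, `alpha`, `phi`, `n_clusters`, `converged`,
#'   `iterations`, `model`, `corstr`.
#' @export
fit_gee <- function(table, model = c("phase5min", "epoch1min"),
                    corstr = c("exchangeable", "independence", "ar1"),
                    tol = 1e-8, maxit = 100L) {
  model <- match.arg(model)
  corstr <- match.arg(corstr)
  need <- c("participant_id", "group", "visit", "rri",
            if (model == "phase5min") "phase" else "epoch")
  if (!all(need %in% names(table)))
    stop("input error: table lacks columns ",
         paste(setdiff(need, names(table)), collapse = ", "), call. = FALSE)
  tab <- as.data.frame(table)
  tab$group <- droplevels(factor(tab$group, levels = c("HC", "MDD", "PD")))
  one_group <- nlevels(tab$group) < 2 # single-cohort table: no group terms
  if (model == "phase5min") {
    tab$phase <- factor(tab$phase, levels = c("baseline", "stress"))
    tab <- tab[order(tab$participant_id, tab$visit, tab$phase), ]
    rhs <- if (one_group) "phase" else "phase * group"
  } else {
    tab$epoch <- factor(tab$epoch, levels = c("S1", "B4", "B5", "S2"))
    tab <- tab[order(tab$participant_id, tab$visit, as.integer(tab$epoch)), ]
    rhs <- if (one_group) "epoch" else "epoch * group"
  }
  tab$visit <- factor(tab$visit, levels = sort(unique(tab$visit)))
  if (nlevels(tab$visit) > 1) rhs <- paste(rhs, "+ visit")
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), data = tab)
  fit <- gee_engine(X, tab$rri, tab$participant_id, corstr = corstr,
                    tol = tol, maxit = maxit)
  if (!fit$converged)
    warning("GEE did not converge in ", maxit, " iterations", call. = FALSE)
  structure(c(fit, list(model = model, corstr = corstr, n_obs = nrow(tab))),
            class = "rri_gee")
}

#' @export
coef.rri_gee <- function(object, ...) object$beta

#' @export
vcov.rri_gee <- function(object, ...) object$vrobust

#' @export
print.rri_gee <- function(x, ...) {
  cat(sprintf("GEE (%s, Gaussian identity, %s working correlation)\n",
              x$model, x$corstr))
  cat(sprintf("  %d observations in %d clusters | alpha = %.3f, phi = %.1f | %s in %d iterations\n",
              x$n_obs, x$n_clusters, x$alpha, x$phi,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  print(round(summary(x)$coefficients, 4))
  invisible(x)
}

#' @export
summary.rri_gee <- function(object, ...) {
  se <- sqrt(diag(object$vrobust))
  z <- object$beta / se
  tab <- cbind(estimate = object$beta, robust_se = se, z = z,
               p = 2 * stats::pnorm(-abs(z)))
  out <- list(coefficients = tab, alpha = object$alpha, phi = object$phi,
              n_clusters = object$n_clusters, model = object$model)
  class(out) <- "summary.rri_gee"
  out
}

#' @export
print.summary.rri_gee <- function(x, ...) {
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Wald z test of a linear contrast of GEE coefficients
#'
#' @param fit an `rri_gee`.
#' @param L named list of contrast vectors in coefficient space (each of
#'   length `length(coef(fit))`), or a single vector.
#' @return data.frame with `contrast`, `estimate`, `se` (robust),
#'   `z = estimate / se`, and two-sided `p`.
#' @export
gee_contrast <- function(fit, L) {
  stopifnot(inherits(fit, "rri_gee"))
  if (!is.list(L)) L <- list(contrast = L)
  rows <- lapply(names(L), function(nm) {
    cv <- L[[nm]]
    if (length(cv) != length(fit$beta))
      stop("contrast outside coefficient space: expected length ",
           length(fit$beta), call. = FALSE)
    est <- sum(cv * fit$beta)
    se <- sqrt(as.vector(t(cv) %*% fit$vrobust %*% cv))
    if (se <= 0) stop("contrast has zero robust variance", call. = FALSE)
    data.frame(contrast = nm, estimate = est, se = se, z = est / se,
               p = 2 * stats::pnorm(-abs(est / se)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

unit_contrast <- function(fit, terms) {
  cv <- numeric(length(fit$beta))
  names(cv) <- names(fit$beta)
  for (tm in terms) {
    if (!tm %in% names(cv))
      stop("contrast outside coefficient space: no term ", tm, call. = FALSE)
    cv[tm] <- cv[tm] + 1
  }
  cv
}

#' Baseline-to-stress phase contrasts per group
#'
#' The within-group stress effect is the main phase coefficient (HC, the
#' reference) or the phase coefficient plus the group's interaction term
#' (MDD, PD); the between-group difference contrasts (MDD - HC, PD - HC)
#' are the interaction terms alone. A negative within-group estimate is a
#' stress-induced RRI shortening; a positive difference contrast means
#' the shortening is attenuated relative to HC.
#'
#' @param fit an `rri_gee` fitted with `model = "phase5min"`.
#' @return data.frame of Wald z contrasts (see [gee_contrast()]).
#' @export
phase_contrasts <- function(fit) {
  stopifnot(inherits(fit, "rri_gee"))
  if (fit$model != "phase5min")
    stop("phase_contrasts needs a phase5min fit", call. = FALSE)
  L <- list(
    `stress-baseline (HC)` = unit_contrast(fit, "phasestress"),
    `stress-baseline (MDD)` = unit_contrast(fit, c("phasestress",
                                                   "phasestress:groupMDD")),
    `stress-baseline (PD)` = unit_contrast(fit, c("phasestress",
                                                  "phasestress:groupPD")),
    `difference MDD-HC` = unit_contrast(fit, "phasestress:groupMDD"),
    `difference PD-HC` = unit_contrast(fit, "phasestress:groupPD"))
  gee_contrast(fit, L)
}

#' Epoch contrasts versus the first stress minute per group
#'
#' For each group, contrasts of B4, B5 and S2 against the reference epoch
#' S1: the epoch main effect for HC, plus the epoch x group interaction
#' for MDD and PD. Positive B4 - S1 and B5 - S1 estimates reproduce the
#' stress-onset RRI drop; a positive S2 - S1 estimate is the second-minute
#' rebound.
#'
#' @param fit an `rri_gee` fitted with `model = "epoch1min"`.
#' @return data.frame of Wald z contrasts.
#' @export
epoch_contrasts <- function(fit) {
  stopifnot(inherits(fit, "rri_gee"))
  if (fit$model != "epoch1min")
    stop("epoch_contrasts needs an epoch1min fit", call. = FALSE)
  L <- list()
  for (ep in c("B4", "B5", "S2")) {
    main <- paste0("epoch", ep)
    L[[sprintf("%s-S1 (HC)", ep)]] <- unit_contrast(fit, main)
    for (g in c("MDD", "PD"))
      L[[sprintf("%s-S1 (%s)", ep, g)]] <-
        unit_contrast(fit, c(main, sprintf("%s:group%s", main, g)))
  }
  gee_contrast(fit, L)
}
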