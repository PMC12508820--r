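# GEE reactivity analysis: estimator oracles, working-correlation
# behaviour, robust-variance properties and contrast construction.

test_that("singleton clusters reduce the GEE to ordinary least squares", {
  set.seed(4)
  n <- 60
  d <- data.frame(participant_id = sprintf("p%02d", 1:n),
                  group = sample(c("HC", "MDD", "PD"), n, TRUE),
                  visit = 1L,
                  phase = sample(c("baseline", "stress"), n, TRUE),
                  rri = rnorm(n, 850, 50), stringsAsFactors = FALSE)
  f <- fit_gee(d, "phase5min")
  X <- stats::model.matrix(~ phase * group, data = transform(
    d, phase = factor(phase, c("baseline", "stress")),
    group = factor(group, c("HC", "MDD", "PD"))))
  beta_ols <- qr.solve(qr(X), d$rri) # closed-form oracle
  expect_lt(max(abs(coef(f) - beta_ols)), 1e-8)
  expect_equal(f$alpha, 0)
  expect_true(f$converged)
})

test_that("exchangeable alpha equals the brute-force residual-product moment estimate", {
  set.seed(5)
  d <- clustered_data(n_clus = 40, n_obs = 2)
  f <- fit_gee(d, "phase5min")
  # brute-force oracle: loop over clusters, accumulate the within-cluster
  # residual product, scale by phi with the parameter-count correction
  X <- stats::model.matrix(~ phase, data = transform(
    d, phase = factor(phase, c("baseline", "stress"))))
  r <- d$rri - as.vector(X %*% coef(f))
  ids <- unique(d$participant_id)
  num <- 0
  for (cid in ids) {
    ri <- r[d$participant_id == cid]
    num <- num + ri[1] * ri[2]
  }
  p <- length(coef(f))
  phi <- sum(r^2) / (length(r) - p)
  alpha_oracle <- num / phi / (length(ids) - p)
  expect_lt(abs(f$alpha - alpha_oracle), 1e-6)
  expect_gt(f$alpha, 0.5) # strong random intercept induces within-cluster correlation
})

test_that("the independence working correlation reproduces OLS for clustered data", {
  set.seed(6)
  d <- clustered_data(n_clus = 25, n_obs = 3)
  f_ind <- fit_gee(d, "phase5min", corstr = "independence")
  X <- stats::model.matrix(~ phase, data = transform(
    d, phase = factor(phase, c("baseline", "stress"))))
  expect_lt(max(abs(coef(f_ind) - qr.solve(qr(X), d$rri))), 1e-8)
  # robust SE differs from the naive one under clustering
  expect_gt(max(abs(sqrt(diag(f_ind$vrobust)) - sqrt(diag(f_ind$vnaive)))),
            1e-3)
})

test_that("estimates are invariant to cluster and within-cluster row order", {
  set.seed(7)
  d <- clustered_data(n_clus = 20, n_obs = 2)
  f1 <- fit_gee(d, "phase5min")
  d2 <- d[sample(nrow(d)), ]
  f2 <- fit_gee(d2, "phase5min")
  expect_equal(coef(f1), coef(f2), tolerance = 1e-10)
  expect_equal(f1$alpha, f2$alpha, tolerance = 1e-10)
  expect_equal(f1$vrobust, f2$vrobust, tolerance = 1e-10)
})

test_that("robust variance shrinks at the 1/n_clusters rate", {
  tr <- function(n_clus, seed) {
    set.seed(seed)
    mean(replicate(20, {
      f <- fit_gee(clustered_data(n_clus = n_clus, n_obs = 2), "phase5min")
      sum(diag(f$vrobust))
    }))
  }
  ratio <- tr(30, 8) / tr(60, 9)
  expect_gt(ratio, 2 * 0.75)
  expect_lt(ratio, 2 * 1.25)
})

test_that("Wald machinery: z equals estimate/SE and contrast arithmetic is exact", {
  set.seed(10)
  d <- clustered_data(n_clus = 15, n_obs = 2)
  f <- fit_gee(d, "phase5min")
  ct <- gee_contrast(f, list(stress = c(0, 1)))
  expect_equal(ct$z, ct$estimate / ct$se)
  expect_equal(ct$p, 2 * pnorm(-abs(ct$z)))
  expect_error(gee_contrast(f, list(bad = c(0, 1, 0))), "coefficient space")

  # synthetic coefficient vector: phase -60, MDD interaction +25 -> MDD
  # within-group contrast -35
  beta <- c("(Intercept)" = 850, phasestress = -60, groupMDD = 10,
            groupPD = 5, "phasestress:groupMDD" = 25,
            "phasestress:groupPD" = 30)
  fake <- structure(list(beta = beta, vrobust = diag(length(beta)),
                         model = "phase5min"), class = "rri_gee")
  pc <- phase_contrasts(fake)
  expect_equal(pc$estimate[pc$contrast == "stress-baseline (MDD)"], -35)
  expect_equal(pc$estimate[pc$contrast == "stress-baseline (HC)"], -60)
  expect_equal(pc$estimate[pc$contrast == "difference PD-HC"], 30)
})

test_that("phase and epoch contrasts recover the generative truth on one cohort", {
  cfg <- small_cfg(n = 15, seed = 21)
  ses <- simulate_cohort_sessions(simulate_cohort(cfg))
  fit <- fit_gee(phase_table(ses), "phase5min")
  pc <- phase_contrasts(fit)
  truth <- cfg$delta + (240 / 300) * cfg$rebound
  for (g in c("HC", "MDD", "PD")) {
    row <- pc[pc$contrast == sprintf("stress-baseline (%s)", g), ]
    expect_lt(abs(row$estimate - truth[[g]]), 4 * row$se + 3)
    expect_lt(row$estimate, 0) # stress shortens RRI everywhere
  }
  # attenuation: interaction contrasts positive
  expect_gt(pc$estimate[pc$contrast == "difference MDD-HC"], 0)
  expect_gt(pc$estimate[pc$contrast == "difference PD-HC"], 0)

  fe <- fit_gee(epoch_table(ses), "epoch1min")
  ec <- epoch_contrasts(fe)
  # S1 is the nadir: B4/B5 sit above S1 in every group
  for (nm in grep("^B", ec$contrast, value = TRUE))
    expect_gt(ec$estimate[ec$contrast == nm], 0)
  # rebound in HC and PD, none in MDD
  expect_gt(ec$estimate[ec$contrast == "S2-S1 (HC)"], 5)
  expect_gt(ec$estimate[ec$contrast == "S2-S1 (PD)"], 5)
  expect_lt(abs(ec$estimate[ec$contrast == "S2-S1 (MDD)"]), 3)
})

test_that("the null configuration keeps the type-I error near nominal", {
  # 150 null cohorts: fraction of |z| > 1.96 phase contrasts within the
  # binomial band around 0.05
  set.seed(30)
  zs <- replicate(150, {
    cfg <- null_cfg(n = 8, visits = 2, seed = sample.int(2^30, 1))
    ses <- simulate_cohort_sessions(simulate_cohort(cfg))
    pc <- phase_contrasts(fit_gee(phase_table(ses), "phase5min"))
    pc$z[pc$contrast == "stress-baseline (HC)"]
  })
  frac <- mean(abs(zs) > 1.96)
  expect_gte(frac, 0.0)
  expect_lte(frac, 0.12)
})

test_that("degenerate designs raise informative errors", {
  set.seed(31)
  d <- clustered_data(n_clus = 10, n_obs = 2)
  d$phase <- "baseline" # constant covariate -> rank deficiency
  expect_error(fit_gee(d, "phase5min"), "rank deficient")
  expect_error(fit_gee(d[, c("participant_id", "rri", "visit", "group")],
                       "phase5min"), "lacks columns")
  d1 <- clustered_data(n_clus = 1, n_obs = 2)
  expect_error(fit_gee(d1, "phase5min"), "2 clusters")
})
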