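# The cohort generator: accounting, the beat-level process, and the
# group-specific stress reactivity it encodes.

test_that("cohort accounting matches configured group sizes and attendance", {
  coh <- simulate_cohort(sim_config(seed = 3))
  expect_length(coh$participants, 147)
  grp <- vapply(coh$participants, `[[`, "", "group")
  expect_equal(unname(table(grp)[c("MDD", "PD", "HC")]),
               c(41, 47, 59), ignore_attr = TRUE)
  nv <- vapply(coh$participants, function(p) length(p$visits), 0L)
  # attendance distribution: 110/16/4/7/10 completing 5/4/3/2/1 visits
  expect_equal(tabulate(nv, 5), c(10, 7, 4, 16, 110))
  expect_equal(sum(nv), 650) # recordings per phase

  tiny <- simulate_cohort(sim_config(
    n_per_group = c(MDD = 1, PD = 1, HC = 1),
    visit_attendance = c(`5` = 1)))
  expect_length(tiny$participants, 3)
  ses <- simulate_cohort_sessions(tiny)
  expect_length(ses, 15) # attended visits
  expect_equal(sum(vapply(ses, function(s)
    inherits(s$baseline, "beat_series") + inherits(s$stress, "beat_series"),
    0L)), 30) # phase recordings
})

test_that("cohort generation is deterministic in the seed", {
  a <- simulate_cohort(small_cfg(n = 4, seed = 7))
  b <- simulate_cohort(small_cfg(n = 4, seed = 7))
  expect_identical(a, b)
  c <- simulate_cohort(sim_config(seed = 8))
  d <- simulate_cohort(sim_config(seed = 9))
  va <- vapply(c$participants, function(p) length(p$visits), 0L)
  vb <- vapply(d$participants, function(p) length(p$visits), 0L)
  expect_false(identical(order(va), order(vb))) # different attendance draw
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_per_group = c(MDD = -1, PD = 2, HC = 2)),
               "configuration error")
  expect_error(sim_config(visit_attendance = numeric(0)),
               "configuration error")
  expect_error(sim_config(sigma_noise = -1), "configuration error")
  expect_error(sim_config(mu_rri = 320), "physiological floor")
  expect_error(simulate_cohort(list()), "configuration error")
})

test_that("beat generation follows the oscillatory interval process", {
  s <- rri_process(1000, 0, 0, 0, duration = 300, seed = 1)
  expect_length(s$rri, 300)
  expect_true(all(s$rri == 1000))
  expect_equal(s$beat_times, as.numeric(1:300))

  # zero-mean HF sinusoid leaves the sample mean unchanged to first order
  s2 <- rri_process(800, 0, 30, 0, duration = 300, seed = 2)
  expect_lt(abs(mean(s2$rri) - 800), 1)

  # bit-identical regeneration under the same seed
  a <- rri_process(850, 25, 40, 10, duration = 300, seed = 7)
  b <- rri_process(850, 25, 40, 10, duration = 300, seed = 7)
  expect_identical(a, b)

  # parameters that push raw intervals <= 0 raise a warning
  expect_warning(rri_process(400, 0, 0, 600, duration = 60, seed = 1),
                 "before clipping")
})

test_that("beat series are self-consistent and respect the phase span", {
  ses <- simulate_cohort_sessions(simulate_cohort(small_cfg(n = 2, seed = 5)))
  for (s in ses) {
    for (b in list(s$baseline, s$stress)) {
      expect_true(all(diff(b$beat_times) > 0))
      expect_true(all(b$rri > 0))
      expect_lte(max(b$beat_times), 300)
      expect_lt(max(abs(diff(c(0, b$beat_times)) * 1000 - b$rri)), 1e-6)
    }
  }
  expect_error(beat_series("x", 1, "baseline", c(1, 2), c(1000, 999)),
               "inconsistent")
  expect_error(beat_series("x", 1, "baseline", c(2, 1), c(2000, -1000)),
               "strictly increasing")
})

test_that("a null configuration makes stress indistinguishable from baseline", {
  cfg <- null_cfg(n = 1, visits = 1, sigma_noise = 0)
  ses <- simulate_cohort_sessions(simulate_cohort(cfg))[[1]]
  expect_equal(ses$baseline$rri, ses$stress$rri)
  expect_equal(ses$baseline$beat_times, ses$stress$beat_times)
})

test_that("sessions reproduce the configured reactivity structure", {
  # HC-only cohort, ~300 sessions: mean stress-baseline difference matches
  # delta_HC plus the rebound acting over minutes 2-5 (240 of 300 s)
  cfg <- sim_config(n_per_group = c(MDD = 0, PD = 0, HC = 100),
                    visit_attendance = c(`3` = 1), seed = 11)
  ses <- simulate_cohort_sessions(simulate_cohort(cfg))
  d <- vapply(ses, function(s) mean(s$stress$rri) - mean(s$baseline$rri), 0)
  truth_hc <- cfg$delta[["HC"]] + (240 / 300) * cfg$rebound[["HC"]]
  expect_lt(abs(mean(d) - truth_hc), 3)

  # MDD: no S1-to-S2 rebound
  cfg_m <- sim_config(n_per_group = c(MDD = 100, PD = 0, HC = 0),
                      visit_attendance = c(`2` = 1), seed = 12)
  ses_m <- simulate_cohort_sessions(simulate_cohort(cfg_m))
  s2s1 <- vapply(ses_m, function(s) {
    st <- s$stress
    mean(st$rri[st$beat_times >= 60 & st$beat_times < 120]) -
      mean(st$rri[st$beat_times < 60])
  }, 0)
  expect_lt(abs(mean(s2s1)), 3)
})

test_that("stress shortens RRI in every group, most strongly in HC", {
  ses <- simulate_cohort_sessions(simulate_cohort(small_cfg(n = 67, seed = 13)))
  grp <- vapply(ses, `[[`, "", "group")
  d <- vapply(ses, function(s) mean(s$stress$rri) - mean(s$baseline$rri), 0)
  dg <- tapply(d, grp, mean)
  for (g in c("MDD", "PD", "HC")) {
    expect_gte(sum(grp == g), 200) # sessions per group
    expect_lt(stats::t.test(d[grp == g], alternative = "less")$p.value, 1e-6)
  }
  expect_gt(abs(dg[["HC"]]), abs(dg[["MDD"]]))
  expect_gt(abs(dg[["HC"]]), abs(dg[["PD"]]))
})

test_that("sessions are deterministic and visit lookup is validated", {
  coh <- simulate_cohort(small_cfg(n = 2, seed = 21))
  p <- coh$participants[[1]]
  a <- simulate_session(p, p$visits[1], coh$config)
  b <- simulate_session(p, p$visits[1], coh$config)
  expect_identical(a, b)
  expect_error(simulate_session(list(id = "x", group = "HC",
                                     baseline_mu = 850, visits = 1L),
                                4, coh$config), "lookup error")
})
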