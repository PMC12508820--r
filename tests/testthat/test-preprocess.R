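# Preprocessing: artifact filtering, 4 Hz cubic-spline resampling,
# fixed-length segmentation and 1-min epoch extraction.

test_that("artifact filter repairs isolated ectopic beats and rejects corrupt series", {
  clean <- rri_process(1000, 0, 0, 0, duration = 200, seed = 1)
  f <- artifact_filter(clean)
  expect_identical(f$rri, clean$rri)
  expect_equal(attr(f, "n_corrected"), 0L)

  # one inserted short beat in a constant series: exactly one correction,
  # spline through constant neighbours restores the constant
  r <- rep(1000, 200)
  r[100] <- 150
  spiky <- beat_series("p", 1, "baseline", cumsum(r) / 1000, r, duration = 300)
  g <- artifact_filter(spiky)
  expect_equal(attr(g, "n_corrected"), 1L)
  expect_true(all(g$rri >= 999 & g$rri <= 1001))

  # 30% random spikes: beyond repair
  set.seed(4)
  r2 <- rep(1000, 200)
  bad <- sample(200, 60)
  r2[bad] <- sample(c(150, 2600), 60, replace = TRUE)
  corrupt <- beat_series("p", 1, "baseline", cumsum(r2) / 1000, r2,
                         duration = 400)
  expect_error(artifact_filter(corrupt), "rejected")
})

test_that("artifact filter is idempotent on its own output", {
  s <- rri_process(850, 25, 40, 10, duration = 300, seed = 31)
  r <- s$rri
  set.seed(32)
  r[sample(length(r), 8)] <- c(200, 2500, 400, 1900, 250, 2200, 350, 2100)
  noisy <- beat_series("p", 1, "baseline", cumsum(r) / 1000, r,
                       duration = 400)
  once <- artifact_filter(noisy)
  twice <- artifact_filter(once)
  expect_equal(attr(twice, "n_corrected"), 0L)
  expect_identical(once$rri, twice$rri)
})

test_that("4 Hz resampling obeys the sample-count law and reproduces polynomials", {
  s300 <- rri_process(1000, 0, 0, 0, duration = 300, seed = 1)
  rs <- resample_4hz(s300)
  expect_length(rs$values, 1200)
  expect_true(all(rs$values == 1000))
  expect_equal(rs$fs, 4)

  s60 <- rri_process(1000, 0, 0, 0, duration = 60, seed = 1)
  expect_length(resample_4hz(s60)$values, 240)

  # a constant series of arbitrary duration resamples to that constant
  s77 <- rri_process(850, 0, 0, 0, duration = 77, seed = 1)
  r77 <- resample_4hz(s77)
  expect_true(all(abs(r77$values - 850) < 1e-9))

  # natural cubic splines reproduce a line exactly
  lin <- linear_beat_series(800, 0.1, 300)
  rl <- resample_4hz(lin)
  grid <- (seq_along(rl$values) - 1) / 4
  expect_lt(max(abs(rl$values - (800 + 0.1 * grid))), 1e-6)

  few <- beat_series("p", 1, "baseline", c(1, 2, 3), rep(1000, 3),
                     duration = 300)
  expect_error(resample_4hz(few), "insufficient data")
})

test_that("phase segmentation pads to 1200 points with trailing zeros", {
  full <- segment_phase(resample_4hz(rri_process(900, 0, 0, 0, 300, seed = 2)))
  expect_length(full$values, 1200)
  expect_equal(full$n_valid, 1200L)
  expect_equal(full$label, "baseline")

  # a recording that stops early gets a zeroed tail
  short <- rri_process(1000, 0, 0, 0, duration = 287, seed = 2)
  seg <- segment_phase(resample_4hz(short, duration = 300))
  expect_length(seg$values, 1200)
  expect_lt(seg$n_valid, 1200L)
  expect_true(all(seg$values[(seg$n_valid + 1):1200] == 0))
  expect_true(all(seg$values[seq_len(seg$n_valid)] > 0))
})

test_that("epoch extraction takes B4/B5 from late baseline and S1/S2 from early stress", {
  base <- resample_4hz(rri_process(1000, 0, 0, 0, 300, seed = 1))
  stre <- resample_4hz(rri_process(900, 0, 0, 0, 300, seed = 2))
  ep <- extract_epochs(base, stre)
  expect_named(ep, c("B4", "B5", "S1", "S2"))
  for (e in ep) expect_equal(e$n_valid, 240L)
  expect_equal(mean(ep$B5$values), 1000)
  expect_equal(mean(ep$S1$values[seq_len(ep$S1$n_valid)]), 900)

  # B4 and B5 partition the last 120 s of baseline: no overlap, no gap
  expect_equal(c(ep$B4$values, ep$B5$values), base$values[721:1200])

  # a baseline too short for the B4 window excludes that epoch
  shortb <- resample_4hz(rri_process(1000, 0, 0, 0, duration = 200, seed = 3),
                         duration = 300)
  expect_warning(ep2 <- extract_epochs(shortb, stre), "excluded")
  expect_null(ep2$B4)
})

test_that("epoch means track the generative S1/S2 structure through the spline", {
  # noise-free session with S1 at 820 ms and S2 rebounding to 835 ms
  cfg <- sim_config(n_per_group = c(MDD = 0, PD = 0, HC = 1),
                    visit_attendance = c(`1` = 1),
                    sigma_subject = 0, sigma_delta = 0, sigma_noise = 0,
                    lf_amp = 0, hf_amp_base = 0, hf_amp_stress = 0,
                    delta = c(MDD = -30, PD = -30, HC = -30),
                    rebound = c(MDD = 15, PD = 15, HC = 15),
                    seed = 6)
  s <- simulate_cohort_sessions(simulate_cohort(cfg))[[1]]
  ep <- extract_epochs(resample_4hz(s$baseline), resample_4hz(s$stress))
  expect_lt(abs(mean(ep$S1$values[seq_len(ep$S1$n_valid)]) - 820), 1)
  expect_lt(abs(mean(ep$S2$values[seq_len(ep$S2$n_valid)]) - 835), 1)
})

test_that("segment stores carry matched matrices and metadata per task", {
  ses <- simulate_cohort_sessions(simulate_cohort(small_cfg(n = 2, seed = 8)))
  segs <- build_segments(ses)
  expect_equal(nrow(segs$phase$x), nrow(segs$phase$meta))
  expect_equal(ncol(segs$phase$x), 1200)
  expect_equal(ncol(segs$epoch$x), 240)
  expect_setequal(unique(segs$epoch$meta$label), c("B4", "B5", "S1", "S2"))

  ts <- task_segments(segs, "b5s1")
  expect_setequal(unique(ts$meta$label), c("B5", "S1"))
  expect_equal(ts$y, as.integer(ts$meta$label == "S1"))
  expect_error(task_segments(list(phase = list(x = NULL, meta = NULL),
                                  epoch = list(x = NULL, meta = NULL)),
                             "b4b5"), "input error")

  zs <- build_segments(ses, zscore = TRUE)
  m1 <- zs$epoch$x[1, seq_len(zs$epoch$meta$n_valid[1])]
  expect_lt(abs(mean(m1)), 1e-9)
  expect_lt(abs(stats::sd(m1) - 1), 1e-9)
})
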