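# Shared fixtures: all built in code at test time.

# Small cohort config: three visits each, optional overrides.
small_cfg <- function(n = 12, visits = 3, seed = 1, ...) {
  sim_config(n_per_group = c(MDD = n, PD = n, HC = n),
             visit_attendance = stats::setNames(1, as.character(visits)),
             seed = seed, ...)
}

# A no-effect config: stress indistinguishable from baseline by design
# (no shift, no rebound, no vagal withdrawal, no session noise).
null_cfg <- function(n = 12, visits = 3, seed = 1, ...) {
  small_cfg(n = n, visits = visits, seed = seed,
            delta = c(MDD = 0, PD = 0, HC = 0),
            rebound = c(MDD = 0, PD = 0, HC = 0),
            hf_amp_stress = 40, sigma_delta = 0, ...)
}

# Beat series whose RRI is exactly linear in beat time AND self-consistent
# with the successive time differences: t_i solves
# t_i = t_{i-1} + (a + b t_i)/1000.
linear_beat_series <- function(a = 800, b = 0.1, duration = 300) {
  t <- 0
  times <- numeric(0)
  repeat {
    tn <- (t + a / 1000) / (1 - b / 1000)
    if (tn > duration) break
    times <- c(times, tn)
    t <- tn
  }
  beat_series("lin", 1, "baseline", times, diff(c(0, times)) * 1000,
              duration = duration)
}

# Gaussian toy segments: two classes separated by a mean shift.
toy_segments <- function(n = 120, len = 240, shift = 200, noise = 10,
                         seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(900 + rnorm(n / 2 * len, 0, noise), n / 2, len),
             matrix(900 - shift + rnorm(n / 2 * len, 0, noise), n / 2, len))
  y <- rep(c(0, 1), each = n / 2)
  ord <- sample(n)
  list(x = x[ord, , drop = FALSE], y = y[ord])
}

# Tiny architecture used wherever a full network is unnecessary.
tiny_spec <- function(input_len = 240) resnet_spec_small(input_len, width = 8,
                                                         blocks = 3)

fast_train <- function(epochs = 10, patience = 4, seed = 1)
  train_config(epochs = epochs, patience = patience, seed = seed)

# Clustered Gaussian data with a random intercept (for GEE unit tests;
# bypasses the beat-level generator where only the estimator is under
# test).
clustered_data <- function(n_clus = 30, n_obs = 2, sd_b = 20, sd_e = 10,
                           beta0 = 850, beta1 = -40) {
  id <- rep(sprintf("c%03d", seq_len(n_clus)), each = n_obs)
  b <- rep(rnorm(n_clus, 0, sd_b), each = n_obs)
  phase <- rep_len(c("baseline", "stress"), n_clus * n_obs)
  y <- beta0 + (phase == "stress") * beta1 + b + rnorm(n_clus * n_obs, 0, sd_e)
  data.frame(participant_id = id, group = "HC", visit = 1L,
             phase = phase, rri = y, stringsAsFactors = FALSE)
}
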