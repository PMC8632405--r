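# synthetic ERP generator and its ground truth

test_that("generation is deterministic under the config seed", {
  s1 <- simulate_epochs(sim_preset("small", seed = 9))
  s2 <- simulate_epochs(sim_preset("small", seed = 9))
  expect_identical(s1$epochs$trials, s2$epochs$trials)
  expect_identical(s1$truth$artifact_ids, s2$truth$artifact_ids)
  s3 <- simulate_epochs(sim_preset("small", seed = 10))
  expect_false(identical(s1$epochs$trials, s3$epochs$trials))
})

test_that("generated epochs have the configured geometry", {
  sim <- simulate_epochs(sim_preset("small", seed = 1))
  expect_equal(n_trials(sim$epochs), 90)
  expect_equal(n_channels(sim$epochs), 8)
  expect_equal(n_samples(sim$epochs), 501)
  expect_equal(sim$epochs$onset_index, 100)
  expect_equal(as.vector(table(sim$epochs$labels)), c(30, 30, 30))
  # noise RMS near the configured 5 uV in the signal-free baseline
  base <- vapply(sim$epochs$trials, function(m) sqrt(mean(m[, 1:80]^2)), 0)
  expect_lt(abs(mean(base) - 5) / 5, 0.15)
})

test_that("equal class amplitudes produce no planted difference", {
  labels <- c("Ug", "Sc")
  cfg <- sim_config(n_channels = 2, trials_per_class = 5, labels = labels,
                    components = list(
                      sim_component("P300", 300, 2.5,
                                    c(Ug = 4, Sc = 4), jitter_sd_ms = 0)),
                    seed = 1)
  w <- component_windows(500, 100, 501)
  expect_warning(d <- analytic_direction(cfg, labels, w), "identical")
  expect_true(all(d == 0))
  expect_true(attr(d, "degenerate"))
})

test_that("planted artifacts are exactly the trials the threshold removes", {
  cfg <- sim_config(n_channels = 8, trials_per_class = 50,
                    artifact_rate = 0.1, seed = 21)
  sim <- simulate_epochs(cfg)
  out <- reject_artifacts(sim$epochs, 75)
  expect_identical(out$report$removed, sim$truth$artifact_ids)
  expect_gt(length(sim$truth$artifact_ids), 0)
})

test_that("background noise power decreases across octave bands (1/f)", {
  slopes <- numeric(10)
  for (seed in 1:10) {
    cfg <- sim_config(n_channels = 2, trials_per_class = 4, labels = "a",
                      components = list(), noise_exponent = 1, seed = seed)
    sim <- simulate_epochs(cfg)
    m <- sim$epochs$trials[[1]]
    Tn <- ncol(m)
    pw <- Mod(stats::mvfft(t(m)))^2 / Tn
    f <- (0:(Tn - 1)) * 500 / Tn
    octaves <- list(c(1, 2), c(2, 4), c(4, 8), c(8, 16), c(16, 30))
    bp <- vapply(octaves, function(o) mean(pw[f >= o[1] & f < o[2], ]), 0)
    slopes[seed] <- stats::coef(stats::lm(log(bp) ~ seq_along(bp)))[2]
  }
  expect_lt(mean(slopes), 0)
  expect_gt(mean(slopes < 0), 0.8)
})

test_that("analytic direction matches a large-sample empirical estimate", {
  # white-ish small world: 2 channels, two point components, no jitter
  labels <- c("Ug", "Sc")
  cfg <- sim_config(n_channels = 2, trials_per_class = 5000, labels = labels,
                    components = list(
                      sim_component("N70", 70, 2.5, c(Ug = -6, Sc = -1),
                                    jitter_sd_ms = 0),
                      sim_component("P120", 120, 2.5, c(Ug = 6, Sc = 1),
                                    jitter_sd_ms = 0)),
                    noise_rms = 5, seed = 31)
  tab <- default_component_table()[1:2, ]
  w <- component_windows(500, 100, 501, table = tab)
  d <- analytic_direction(cfg, labels, w)
  expect_equal(sum(d^2), 1, tolerance = 1e-10)
  # doubling both class amplitudes leaves the unit direction unchanged
  cfg2 <- cfg
  for (i in 1:2) cfg2$components[[i]]$amplitude <- 2 * cfg$components[[i]]$amplitude
  expect_gt(abs(cosine(d, analytic_direction(cfg2, labels, w))), 1 - 1e-10)

  # Monte-Carlo oracle: pooled within-class covariance + mean difference
  sim <- simulate_epochs(cfg)
  vt <- vectorize_trials(extract_combine(sim$epochs, w))
  cc <- dspline:::class_center(vt$vectors, vt$labels)
  Sigma <- crossprod(cc$Xc) / (nrow(vt$vectors) - 2)
  emp <- solve(Sigma, cc$Mj[, "Ug"] - cc$Mj[, "Sc"])
  expect_gt(abs(cosine(d, emp)), 0.99)
})

test_that("single-channel white-world direction is supported on the component", {
  labels <- c("a", "b")
  cfg <- sim_config(n_channels = 1, trials_per_class = 5, labels = labels,
                    components = list(
                      sim_component("P300", 300, 2.5, c(a = 5, b = 0),
                                    topography = 1, jitter_sd_ms = 0)),
                    noise_exponent = 0, seed = 1)
  tab <- default_component_table()[c(1, 4), ]   # N70 (empty) + P300 windows
  w <- component_windows(500, 100, 501, table = tab)
  d <- analytic_direction(cfg, labels, w)
  # first 5 entries are the N70 window: no planted effect there. The synthesis
  # spectrum has no DC bin, which couples all samples weakly (-1/T), so the
  # off-component weights are small but not exactly zero.
  expect_lt(max(abs(d[1:5])), 0.02)
  expect_gt(sum(d[6:10]^2), 0.99)
})

test_that("noiseless separable world classifies perfectly end to end", {
  cfg <- sim_config(n_channels = 4, trials_per_class = 10,
                    labels = c("Ug", "Sc"),
                    components = list(
                      sim_component("P300", 300, 2.5, c(Ug = 5, Sc = 0),
                                    jitter_sd_ms = 0)),
                    noise_rms = 1e-6, seed = 2)
  sim <- simulate_epochs(cfg)
  w <- component_windows(500, 100, 501)
  ev <- evaluate_task(list(whole = extract_combine(sim$epochs, w)),
                      c("Ug", "Sc"), cv_config(n_repeats = 2, seed = 5))
  expect_equal(ev$reports$whole$acc_mean, 100)
  expect_equal(ev$reports$whole$acc_sd, 0)
})
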