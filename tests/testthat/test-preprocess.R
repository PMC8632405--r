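# band filtering, artifact rejection, baseline correction, segmentation

test_that("Butterworth band-pass design matches the reference implementation", {
  # oracle: scipy.signal.butter(4, [1, 30], btype='bandpass', fs=500)
  cf <- butter_bandpass(1, 30, 500, 4)
  expect_equal(cf$b,
    c(0.000713744053206, 0, -0.00285497621282, 0, 0.00428246431923, 0,
      -0.00285497621282, 0, 0.000713744053206), tolerance = 1e-10)
  expect_equal(cf$a,
    c(1, -7.03326144169, 21.6871335638, -38.3052914808, 42.3989536341,
      -30.1209708821, 13.4135995545, -3.42361481955, 0.383451872017),
    tolerance = 1e-10)
  expect_error(butter_bandpass(30, 1, 500), "band edges")
  expect_error(butter_bandpass(1, 300, 500), "band edges")
})

test_that("zero-phase filtering matches the reference implementation", {
  # oracle: scipy.signal.filtfilt on sin(2*pi*10 t) + 0.5 sin(2*pi*45 t),
  # 200 samples at 500 Hz, alpha band (8-13 Hz), order 4
  t <- (0:199) / 500
  x <- matrix(sin(2 * pi * 10 * t) + 0.5 * sin(2 * pi * 45 * t), ncol = 1)
  cf <- butter_bandpass(8, 13, 500, 4)
  y <- filtfilt_matrix(cf$b, cf$a, x)
  expect_equal(y[c(1, 50, 100, 150, 200), 1],
               c(-0.01262526428, -0.195445537, -0.1589967368,
                 0.001895792835, 0.01467083977),
               tolerance = 1e-4)
})

test_that("band-pass response: pass band preserved, stop bands suppressed", {
  rate <- 500
  t <- (0:499) / rate
  tone10 <- sin(2 * pi * 10 * t)
  mk <- function(sig) epoch_set(list(matrix(sig, 1, length(sig))), "x",
                                sampling_rate = rate, onset_index = 0)
  trim <- 51:450
  rms <- function(v) sqrt(mean(v^2))

  # DC is far outside 1-30 Hz
  dc <- bandpass_filter(mk(rep(5, 500)), eeg_bands("whole")[[1]])
  expect_lt(max(abs(dc$trials[[1]])), 5 * 1e-6)

  # 10 Hz tone passes alpha nearly unchanged
  alpha <- bandpass_filter(mk(tone10), eeg_bands("alpha")[[1]])
  expect_lt(abs(rms(alpha$trials[[1]][1, trim]) / rms(tone10[trim]) - 1), 0.05)

  # ... and is crushed by delta
  delta <- bandpass_filter(mk(tone10), eeg_bands("delta")[[1]])
  expect_lt(rms(delta$trials[[1]][1, trim]) / rms(tone10[trim]), 0.10)

  # band_tag updated, dimensions unchanged
  expect_identical(alpha$band_tag, "alpha")
  expect_equal(dim(alpha$trials[[1]]), c(1L, 500L))

  # too-short trials are rejected with the minimum length
  expect_error(bandpass_filter(mk(rep(0, 20)), eeg_bands("alpha")[[1]]),
               "too short")
})

test_that("band-pass filtering is linear", {
  es <- tiny_epochs(n = 2, N = 3, Tn = 120, seed = 11)
  band <- eeg_bands("theta")[[1]]
  x <- es$trials[[1]]; y <- es$trials[[2]]
  mk <- function(m) epoch_set(list(m), "z", sampling_rate = 500, onset_index = 10)
  f <- function(m) bandpass_filter(mk(m), band)$trials[[1]]
  # recursive filtering loses a few digits; linearity holds to fp tolerance
  expect_equal(f(2 * x - 3 * y), 2 * f(x) - 3 * f(y), tolerance = 1e-4)
})

test_that("artifact rejection retains exactly the within-threshold trials", {
  base <- matrix(0, 2, 10)
  hot <- base; hot[1, 4] <- 80
  edge <- base; edge[2, 7] <- 75           # inclusive bound: retained
  es <- epoch_set(list(base, hot, edge), c("a", "b", "a"))
  out <- reject_artifacts(es, 75)
  expect_equal(n_trials(out$epochs), 2)
  expect_equal(out$report$removed, 2L)
  expect_equal(out$report$surviving_by_class, list(a = 2L))

  # planted exceedances in known trials, checked against a brute-force scan
  withr::with_seed(5, {
    trials <- lapply(1:10, function(i) matrix(rnorm(40, sd = 10), 4, 10))
  })
  for (i in c(2, 5, 9)) trials[[i]][2, 3] <- 99
  es10 <- epoch_set(trials, rep("x", 10))
  out10 <- reject_artifacts(es10, 75)
  brute <- which(vapply(trials, function(m) max(abs(m)) > 75, TRUE))
  expect_identical(out10$report$removed, brute)
  expect_identical(out10$report$kept, setdiff(1:10, brute))

  # survivor set is invariant to trial order
  perm <- c(7, 3, 10, 1, 5, 8, 2, 9, 4, 6)
  outp <- reject_artifacts(subset_epochs(es10, perm), 75)
  expect_setequal(perm[outp$report$kept], out10$report$kept)

  expect_error(reject_artifacts(es, 0), "threshold")
})

test_that("baseline correction zeroes per-channel baseline means", {
  es <- tiny_epochs(n = 3, N = 4, Tn = 60, onset = 20, seed = 3)
  # constant offset comes out exactly
  off <- es
  off$trials <- lapply(es$trials, function(m) m * 0 + 5)
  bc <- baseline_correct(off)
  expect_equal(bc$trials[[1]], matrix(0, 4, 60))
  # all-zero trial unchanged
  zero <- epoch_set(list(matrix(0, 2, 30)), "z", onset_index = 10)
  expect_equal(baseline_correct(zero)$trials[[1]], matrix(0, 2, 30))
  # random trials: baseline mean of the output is numerically zero
  bc2 <- baseline_correct(es)
  for (m in bc2$trials)
    expect_lt(max(abs(rowMeans(m[, 1:20]))), 1e-12)
  expect_error(baseline_correct(es, c(5, 5)), "empty")
  expect_error(baseline_correct(es, c(0, 25)), "onset")
})

test_that("segmentation arithmetic and edge handling", {
  rate <- 500
  cont <- matrix(rep(seq_len(3100), each = 2), 2, 3100)
  events <- data.frame(sample = c(10, 500, 1000, 2600),
                       label = c("Ug", "Tg", "Sc", "Ug"))
  expect_warning(
    es <- segment_epochs(cont, events, pre_ms = 200, post_ms = 800, rate = rate),
    "skipped")
  expect_equal(n_samples(es), 501)       # round(1000/1000*500)+1
  expect_equal(es$onset_index, 100)
  rep <- attr(es, "segmentation_report")
  expect_equal(rep$skipped, 1L)          # event at sample 10: pre-window cut off
  expect_equal(n_trials(es), 3)
  # onset sample of each epoch carries the event sample's value (1-based +1)
  expect_equal(es$trials[[1]][1, 101], 501)
})
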