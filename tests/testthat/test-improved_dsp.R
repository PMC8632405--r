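# scatter matrices, Fisher criterion, classic and improved DSP backends

test_that("vectorization is channel-major and invertible", {
  m <- rbind(c(1, 2, 3), c(4, 5, 6))
  es <- epoch_set(list(m), "a", onset_index = 0)
  vt <- vectorize_trials(es)
  expect_equal(vt$vectors[1, ], c(1, 2, 3, 4, 5, 6))
  expect_equal(devectorize_trial(vt$vectors[1, ], vt$dims), m)

  es2 <- tiny_epochs(n = 3, N = 4, Tn = 7, seed = 4)
  vt2 <- vectorize_trials(es2)
  for (i in 1:3)
    expect_identical(devectorize_trial(vt2$vectors[i, ], vt2$dims),
                     es2$trials[[i]])
  expect_error(vectorize_trials(epoch_set(list(), character(0))), "empty")
})

test_that("scatter matrices match the hand-computed toy instance", {
  s <- scatter_matrices(toy_vt())
  expect_equal(s$S_W, rbind(c(1, -1), c(-1, 1)))
  expect_equal(s$S_B, rbind(c(1, 1), c(1, 1)))
  expect_equal(s$grand_mean, c(0, 0))
  expect_equal(s$S_W + s$S_B, total_scatter(toy_vt()$vectors))
  expect_error(scatter_matrices(make_vt(matrix(rnorm(10), 5), rep("a", 5))),
               "2 classes")
})

test_that("equal class means give a zero between-class scatter", {
  X <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  s <- scatter_matrices(make_vt(X, c("A", "A", "B", "B")))
  expect_equal(s$S_B, matrix(0, 2, 2))
})

test_that("Fisher criterion: toy arithmetic and scale invariance", {
  s <- scatter_matrices(toy_vt())
  s$reg_gamma <- 0.1 / mean(diag(s$S_W))   # gamma*c = 0.1 exactly
  expect_equal(fisher_criterion(c(1, 1), s), 20)      # 4 / 0.2
  expect_equal(fisher_criterion(c(1, -1), s), 0)      # orthogonal to S_B
  for (cc in c(-3, 0.5, 10))
    expect_equal(fisher_criterion(cc * c(1, 1), s), 20)
})

test_that("classic backend solves the whitened eigenproblem", {
  s <- scatter_matrices(toy_vt())
  s$reg_gamma <- 0.1 / mean(diag(s$S_W))
  m <- dsp_classic(s, m = 2)
  expect_equal(abs(cosine(m$W1[, 1], c(1, 1))), 1, tolerance = 1e-10)
  expect_gt(m$eigenvalues[1], 0)
  expect_equal(m$eigenvalues[2], 0, tolerance = 1e-10)  # rank(S_B) = K - 1 = 1
  expect_equal(colSums(m$W1^2), c(1, 1))                # unit-norm columns

  # random instances: agree with the dense generalized eigensolver on
  # (S_B, S_W + gamma*c*I), solved independently via solve() + eigen()
  for (seed in 1:5) {
    v <- rand_instance(8, 6, 3, seed)
    s <- scatter_matrices(v, reg_gamma = 1e-3)
    R <- s$S_W + diag(1e-3 * mean(diag(s$S_W)), 6)
    eg <- eigen(solve(R, s$S_B))
    expect_lt(max(abs(Im(eg$values))), 1e-8)
    w_oracle <- Re(eg$vectors[, which.max(Re(eg$values))])
    m <- dsp_classic(s, m = 1)
    expect_gt(abs(cosine(m$W1[, 1], w_oracle)), 1 - 1e-8)
    expect_true(all(m$eigenvalues > -1e-10))
  }
})

test_that("improved backend: toy directions and the K=2 LDA equivalence", {
  s <- scatter_matrices(toy_vt())
  m <- dsp_improved(s)
  expect_equal(ncol(m$W1), 2)                       # m = K
  for (j in 1:2)
    expect_equal(abs(cosine(m$W1[, j], c(1, 1))), 1, tolerance = 1e-10)

  for (seed in 1:10) {
    v <- rand_instance(10, 12, 2, seed)
    s2 <- scatter_matrices(v, reg_gamma = 1e-3)
    wi <- dsp_improved(s2)$W1[, 1]
    wc <- dsp_classic(s2, m = 1)$W1[, 1]
    expect_gt(abs(cosine(wi, wc)), 1 - 1e-6)
  }
})

test_that("zero-sum identity: the summed per-class direction target vanishes", {
  for (seed in 1:10) {
    K <- sample(2:4, 1)
    v <- rand_instance(sample(3:9, 1), 5, K, seed)
    cc <- dspline:::class_center(v$vectors, v$labels)
    z <- sweep(cc$Mj, 1, cc$M) %*% cc$nj
    expect_lt(max(abs(z)), 1e-10 * max(abs(v$vectors)))
  }
})

test_that("matrix-free ridge solve agrees with the dense route", {
  withr::with_seed(42, {
    Xc <- matrix(rnorm(30 * 80), 30, 80)
    B <- matrix(rnorm(80 * 2), 80, 2)
  })
  d <- dspline:::ridge_within_solve(Xc, 0.5, B, "dense")
  l <- dspline:::ridge_within_solve(Xc, 0.5, B, "lowrank")
  expect_equal(l, d, tolerance = 1e-9)
})

test_that("scale invariance: rescaling all trials leaves directions unchanged", {
  v <- rand_instance(12, 10, 3, 77)
  w1 <- dsp_improved(v)$W1
  v2 <- v; v2$vectors <- 13.7 * v$vectors
  w2 <- dsp_improved(v2)$W1
  for (j in seq_len(ncol(w1)))
    expect_gt(abs(cosine(w1[, j], w2[, j])), 1 - 1e-10)
})

test_that("feature transform centers the fitting set and maps M to zero", {
  v <- rand_instance(10, 8, 2, 5)
  m <- dsp_improved(v)
  ft <- dsp_transform(m, v)
  expect_s3_class(ft, "FeatureTable")
  expect_lt(max(abs(colMeans(ft$matrix))), 1e-10)
  zM <- crossprod(m$W1, m$grand_mean) + m$delta
  expect_lt(max(abs(zM)), 1e-12)
  # hand-checked projection: W1 = (1,1)/sqrt(2), M = 0, x = (1,0) -> 1/sqrt(2)
  model <- dspline:::new_dsp_model(matrix(c(1, 1) / sqrt(2), 2, 1),
                                   c(0, 0), "improved", 0, c("A", "B"))
  z <- dsp_transform(model, matrix(c(1, 0), 1, 2))
  expect_equal(z$matrix[1, 1], 1 / sqrt(2))
  expect_error(dsp_transform(m, matrix(0, 1, 5)), "dimension mismatch")
})

test_that("model serialization round-trips", {
  v <- rand_instance(8, 6, 3, 19)
  m <- dsp_improved(v)
  path <- withr::local_tempfile(fileext = ".json")
  write_dsp_model(m, path)
  back <- read_dsp_model(path)
  expect_equal(back$W1, m$W1)
  expect_equal(back$delta, m$delta)
  expect_identical(back$backend, m$backend)
  expect_identical(back$class_order, m$class_order)
  ft1 <- dsp_transform(m, v)
  ft2 <- dsp_transform(back, v$vectors)
  expect_equal(ft2$matrix, ft1$matrix)
})

test_that("scatter identity and PSD hold across random fits", {
  for (seed in 1:8) {
    v <- rand_instance(sample(4:10, 1), sample(3:15, 1), sample(2:4, 1), seed)
    s <- scatter_matrices(v)
    tot <- total_scatter(v$vectors)
    expect_equal(s$S_W + s$S_B, tot, tolerance = 1e-8)
    expect_equal(s$S_W, t(s$S_W))
    expect_equal(s$S_B, t(s$S_B))
    floor_ev <- -1e-10 * mean(diag(s$S_W))
    expect_gt(min(eigen(s$S_W, symmetric = TRUE, only.values = TRUE)$values), floor_ev)
    expect_gt(min(eigen(s$S_B, symmetric = TRUE, only.values = TRUE)$values), floor_ev)
    expect_lte(sum(eigen(s$S_B, only.values = TRUE)$values > 1e-8 * sum(diag(s$S_B))),
               length(s$class_sizes) - 1)
  }
})
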