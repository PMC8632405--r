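# shared fixtures, all built in code

# wrap a bare matrix + labels as VectorizedTrials
make_vt <- function(X, labels, dims = c(N = 1L, Tprime = ncol(X)), band = "whole") {
  structure(list(vectors = X, labels = labels, class_sizes = table(labels),
                 dims = dims, band_tag = band),
            class = "VectorizedTrials")
}

# the 2-D toy instance whose scatter matrices are known by hand:
# class A = (1,0),(0,1); class B = (-1,0),(0,-1)
toy_vt <- function() {
  make_vt(rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1)), c("A", "A", "B", "B"))
}

# random labeled gaussian instance with guaranteed class counts
rand_instance <- function(n_per, D, K, seed, sep = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n_per * K * D), n_per * K, D)
    labels <- rep(LETTERS[seq_len(K)], each = n_per)
    for (k in seq_len(K)) {
      mu <- rnorm(D, sd = sep)
      idx <- labels == LETTERS[k]
      X[idx, ] <- sweep(X[idx, , drop = FALSE], 2, -mu)
    }
    make_vt(X, labels)
  })
}

# small EpochSet with reproducible content
tiny_epochs <- function(n = 4, N = 3, Tn = 50, rate = 500,
                        onset = min(10L, Tn %/% 2),
                        labels = rep(c("Ug", "Sc"), length.out = n), seed = 1) {
  withr::with_seed(seed, {
    trials <- lapply(seq_len(n), function(i) matrix(rnorm(N * Tn), N, Tn))
  })
  epoch_set(trials, labels, sampling_rate = rate, onset_index = onset)
}

# total scatter sum_i (x_i - M)(x_i - M)' computed the obvious way
total_scatter <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  crossprod(Xc)
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
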