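#' Vectorize epoch matrices
#'
#' Reshapes each N x T' trial matrix into a length `D = N * T'` row vector by
#' concatenating the channels' time courses in channel order (channel-major).
#' The flattening is invertible; [devectorize_trial()] restores the matrix
#' bit-exactly.
#'
#' @param epochs an [epoch_set()] with at least one trial.
#' @return object of class `VectorizedTrials`: list with `vectors`
#'   (n x D matrix), `labels`, `class_sizes`, `dims = c(N, Tprime)` and
#'   `band_tag`.
#' @export
vectorize_trials <- function(epochs) {
  validate_epoch_set(epochs)
  n <- n_trials(epochs)
  if (n == 0) stop("cannot vectorize an empty EpochSet")
  N <- n_channels(epochs)
  Tp <- n_samples(epochs)
  vecs <- matrix(0, n, N * Tp)
  for (i in seq_len(n)) vecs[i, ] <- as.vector(t(epochs$trials[[i]]))
  structure(
    list(vectors = vecs, labels = epochs$labels,
         class_sizes = table(epochs$labels), dims = c(N = N, Tprime = Tp),
         band_tag = epochs$band_tag),
    class = "VectorizedTrials")
}

#' Restore a trial matrix from its vectorized form
#'
#' @param v numeric vector of length `N * Tprime` (channel-major).
#' @param dims length-2 vector `c(N, Tprime)`.
#' @return N x Tprime matrix.
#' @export
devectorize_trial <- function(v, dims) {
  t(matrix(v, nrow = dims[2], ncol = dims[1]))
}

# mean-diagonal ridge constant gamma * c with c = mean(diag(S_W))
ridge_const <- function(S_W, gamma) gamma * mean(diag(S_W))

#' Within- and between-class scatter matrices
#'
#' Computes, on the vectorized trials, the class means `M_j`, grand mean `M`,
#' within-class scatter `S_W = sum_j sum_i (x_i - M_j)(x_i - M_j)'` and
#' between-class scatter `S_B = sum_j n_j (M_j - M)(M_j - M)'`. Classes are
#' ordered by sorted label. The ridge coefficient is stored but not applied;
#' downstream solvers add `gamma * mean(diag(S_W)) * I` where needed.
#'
#' Materializes two D x D matrices — intended for moderate D. The improved
#' backend ([dsp_improved()]) can work matrix-free from the data instead.
#'
#' @param v a [vectorize_trials()] result.
#' @param reg_gamma ridge coefficient as a fraction of the mean diagonal of
#'   `S_W` (default 1e-3).
#' @return object of class `ScatterSet`.
#' @export
scatter_matrices <- function(v, reg_gamma = 1e-3) {
  stopifnot(inherits(v, "VectorizedTrials"))
  X <- v$vectors
  labels <- v$labels
  classes <- sort(unique(labels))
  K <- length(classes)
  if (K < 2) stop("at least 2 classes are required (between-class scatter undefined)")
  D <- ncol(X)
  n <- nrow(X)
  M <- colMeans(X)
  Mj <- matrix(0, D, K, dimnames = list(NULL, classes))
  S_W <- matrix(0, D, D)
  S_B <- matrix(0, D, D)
  nj <- integer(K)
  for (k in seq_len(K)) {
    idx <- which(labels == classes[k])
    nj[k] <- length(idx)
    Mj[, k] <- colMeans(X[idx, , drop = FALSE])
    Xc <- sweep(X[idx, , drop = FALSE], 2, Mj[, k])
    S_W <- S_W + crossprod(Xc)
    d <- Mj[, k] - M
    S_B <- S_B + nj[k] * tcrossprod(d)
  }
  structure(
    list(S_W = S_W, S_B = S_B, class_means = Mj, grand_mean = M,
         class_sizes = stats::setNames(nj, classes), n = n, D = D,
         reg_gamma = reg_gamma),
    class = "ScatterSet")
}

#' Fisher discriminant criterion of a projection
#'
#' `J(W) = det(W' S_B W) / det(W' (S_W + gamma*c*I) W)` with
#' `c = mean(diag(S_W))` — the determinant-ratio form of the Fisher rule,
#' scale-invariant in `W`.
#'
#' @param W D x m projection matrix (or a vector for m = 1).
#' @param s a [scatter_matrices()] result.
#' @return the criterion value.
#' @export
fisher_criterion <- function(W, s) {
  stopifnot(inherits(s, "ScatterSet"))
  W <- as.matrix(W)
  rc <- ridge_const(s$S_W, s$reg_gamma)
  num <- det(crossprod(W, s$S_B %*% W))
  den <- det(crossprod(W, s$S_W %*% W) + rc * crossprod(W))
  if (!is.finite(den) || abs(den) < .Machine$double.xmin)
    stop("singular denominator even after ridge; increase reg_gamma")
  num / den
}

# unit-normalize columns and fix sign so the largest-magnitude entry is positive
normalize_directions <- function(W) {
  W <- as.matrix(W)
  for (j in seq_len(ncol(W))) {
    nrm <- sqrt(sum(W[, j]^2))
    if (nrm > 0) W[, j] <- W[, j] / nrm
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  W
}

new_dsp_model <- function(W1, grand_mean, backend, gamma, class_order,
                          dims = NULL, eigenvalues = NULL, solver = "dense") {
  structure(
    list(W1 = W1, delta = as.numeric(-crossprod(W1, grand_mean)),
         grand_mean = grand_mean, backend = backend, gamma = gamma,
         class_order = class_order, dims = dims, eigenvalues = eigenvalues,
         solver = solver),
    class = "DspModel")
}

#' @export
print.DspModel <- function(x, ...) {
  cat(sprintf("<DspModel> backend '%s', %d directions in D = %d (solver %s, gamma %g)\n",
              x$backend, ncol(x$W1), nrow(x$W1), x$solver, x$gamma))
  invisible(x)
}

#' Classic DSP: generalized eigenproblem backend
#'
#' Solves `S_B w = lambda (S_W + gamma*c*I) w` by symmetric whitening:
#' eigendecompose the regularized within-class scatter, whiten `S_B`, and
#' eigendecompose the (symmetric) whitened matrix. The symmetric route
#' guarantees a real spectrum — the naive `solve(S_W) %*% S_B` formulation is
#' non-symmetric and can return complex eigenpairs. Serves as the oracle
#' backend against which the improved closed form is checked.
#'
#' @param s a [scatter_matrices()] result.
#' @param m number of discriminant directions to keep (default `K - 1`).
#' @return a `DspModel` with unit-norm columns ordered by descending
#'   eigenvalue.
#' @export
dsp_classic <- function(s, m = NULL) {
  stopifnot(inherits(s, "ScatterSet"))
  K <- length(s$class_sizes)
  if (is.null(m)) m <- K - 1L
  if (m < 1 || m > s$D) stop("m must be in [1, D]")
  rc <- ridge_const(s$S_W, s$reg_gamma)
  R <- s$S_W + diag(rc, s$D)
  er <- eigen(R, symmetric = TRUE)
  if (min(er$values) <= 0)
    stop("regularized within-class scatter is not positive definite; increase reg_gamma")
  Rih <- er$vectors %*% (t(er$vectors) / sqrt(er$values))
  B <- Rih %*% s$S_B %*% Rih
  B <- (B + t(B)) / 2
  eb <- eigen(B, symmetric = TRUE)
  W <- normalize_directions(Rih %*% eb$vectors[, seq_len(m), drop = FALSE])
  new_dsp_model(W, s$grand_mean, backend = "classic", gamma = s$reg_gamma,
                class_order = names(s$class_sizes),
                eigenvalues = eb$values[seq_len(m)])
}

# solve (S_W + rc I) X = B either densely or via the low-rank (Woodbury)
# identity on the centered data, which never materializes D x D:
#   (rc I + Xc'Xc)^{-1} B = (B - Xc' (rc I_n + Xc Xc')^{-1} Xc B) / rc
ridge_within_solve <- function(Xc, rc, B, method = c("dense", "lowrank")) {
  method <- match.arg(method)
  B <- as.matrix(B)
  if (method == "dense") {
    S_W <- crossprod(Xc)
    solve(S_W + diag(rc, ncol(Xc)), B)
  } else {
    G <- tcrossprod(Xc)
    diag(G) <- diag(G) + rc
    (B - crossprod(Xc, solve(G, Xc %*% B))) / rc
  }
}

# center rows of X by their class mean; returns list(Xc, Mj, M, nj, classes)
class_center <- function(X, labels) {
  classes <- sort(unique(labels))
  D <- ncol(X)
  Mj <- matrix(0, D, length(classes), dimnames = list(NULL, classes))
  Xc <- X
  nj <- integer(length(classes))
  for (k in seq_along(classes)) {
    idx <- which(labels == classes[k])
    nj[k] <- length(idx)
    Mj[, k] <- colMeans(X[idx, , drop = FALSE])
    Xc[idx, ] <- sweep(X[idx, , drop = FALSE], 2, Mj[, k])
  }
  list(Xc = Xc, Mj = Mj, M = colMeans(X),
       nj = stats::setNames(nj, classes), classes = classes)
}

#' Improved DSP: closed-form per-class discriminant directions
#'
#' Instead of the generalized eigenproblem, computes one direction per class,
#' `w_j = (S_W + gamma*c*I)^{-1} n_j (M_j - M)`, unit-normalized, columns
#' ordered by sorted class label (`m = K`). Since only the direction matters
#' (the scalar coupling the class-mean projection and the eigenvalue has no
#' effect on feature extraction), this sidesteps the eigendecomposition
#' entirely and can never produce complex values. Note the per-class sum
#' `sum_j n_j (M_j - M)` is identically zero, which is why the directions are
#' kept per class rather than summed. For K = 2 each column is proportional
#' to the Fisher/LDA direction, i.e. the leading generalized eigenvector of
#' the classic backend.
#'
#' When given the data ([vectorize_trials()]), the solve is performed
#' matrix-free through the centered-data low-rank + ridge identity whenever
#' `D > 2000` or `D > 4n` (or on request), so the D x D scatter is never
#' materialized. A [scatter_matrices()] input forces the dense route.
#'
#' @param s a [vectorize_trials()] or [scatter_matrices()] object.
#' @param gamma ridge coefficient (fraction of `mean(diag(S_W))`); ignored
#'   for a `ScatterSet`, which carries its own. Default 1e-3.
#' @param solver `"auto"` (low-rank when D > 2000 or D > 4n), `"dense"`, or
#'   `"lowrank"`.
#' @return a `DspModel` with `K` unit-norm columns.
#' @export
dsp_improved <- function(s, gamma = 1e-3, solver = c("auto", "dense", "lowrank")) {
  solver <- match.arg(solver)
  if (inherits(s, "ScatterSet")) {
    K <- length(s$class_sizes)
    if (K < 2) stop("at least 2 classes are required")
    rc <- ridge_const(s$S_W, s$reg_gamma)
    B <- sweep(s$class_means, 1, s$grand_mean) %*% diag(s$class_sizes, K)
    W <- solve(s$S_W + diag(rc, s$D), B)
    return(new_dsp_model(normalize_directions(W), s$grand_mean,
                         backend = "improved", gamma = s$reg_gamma,
                         class_order = names(s$class_sizes), solver = "dense"))
  }
  stopifnot(inherits(s, "VectorizedTrials"))
  cc <- class_center(s$vectors, s$labels)
  K <- length(cc$classes)
  if (K < 2) stop("at least 2 classes are required")
  D <- ncol(s$vectors)
  n <- nrow(s$vectors)
  method <- switch(solver,
                   auto = if (D > 2000 || D > 4 * n) "lowrank" else "dense",
                   dense = "dense", lowrank = "lowrank")
  c_mean <- sum(cc$Xc^2) / D        # mean(diag(S_W)) without forming S_W
  rc <- gamma * c_mean
  B <- sweep(cc$Mj, 1, cc$M) %*% diag(cc$nj, K)
  W <- ridge_within_solve(cc$Xc, rc, B, method)
  new_dsp_model(normalize_directions(W), cc$M, backend = "improved",
                gamma = gamma, class_order = cc$classes,
                dims = s$dims, solver = method)
}

#' Project trials into DSP feature space
#'
#' Applies the fitted projection, `z_i = W1' x_i + delta`, with
#' `delta = -W1' M` frozen from the fitting data's grand mean so that the
#' features of the fitting set are centered and no information from a test
#' split leaks into the offset.
#'
#' @param model a `DspModel` from [dsp_improved()] or [dsp_classic()].
#' @param v a [vectorize_trials()] result (or bare n x D matrix plus
#'   `labels`).
#' @param labels labels when `v` is a bare matrix.
#' @return a [feature_table()] with `m` features per trial; provenance band
#'   is taken from `v$band_tag` when available.
#' @export
dsp_transform <- function(model, v, labels = NULL) {
  stopifnot(inherits(model, "DspModel"))
  if (inherits(v, "VectorizedTrials")) {
    X <- v$vectors
    labels <- v$labels
    band <- v$band_tag
  } else {
    X <- as.matrix(v)
    band <- ""
    if (is.null(labels)) labels <- rep(NA_character_, nrow(X))
  }
  if (ncol(X) != nrow(model$W1))
    stop(sprintf("dimension mismatch: data D = %d, model D = %d",
                 ncol(X), nrow(model$W1)))
  Z <- X %*% model$W1 + matrix(model$delta, nrow(X), ncol(model$W1), byrow = TRUE)
  feature_table(Z, labels,
                provenance = data.frame(band = band,
                                        column = seq_len(ncol(Z)),
                                        stringsAsFactors = FALSE))
}

#' Serialize a DSP model to JSON
#' @param model a `DspModel`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dsp_model <- function(model, path) {
  stopifnot(inherits(model, "DspModel"))
  payload <- list(
    format_version = 1L,
    backend = model$backend, gamma = model$gamma, solver = model$solver,
    class_order = model$class_order, dims = model$dims,
    eigenvalues = model$eigenvalues,
    delta = model$delta, grand_mean = model$grand_mean,
    W1 = model$W1)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' Read a serialized DSP model
#' @param path file written by [write_dsp_model()].
#' @return a `DspModel`.
#' @export
read_dsp_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- new_dsp_model(as.matrix(p$W1), as.numeric(p$grand_mean),
                     backend = p$backend, gamma = p$gamma,
                     class_order = p$class_order,
                     dims = p$dims, eigenvalues = p$eigenvalues,
                     solver = p$solver)
  m
}
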