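#' Cross-validation configuration
#'
#' @param k_neighbors KNN neighbourhood size (default 3).
#' @param n_folds folds per cross-validation (default 5).
#' @param n_repeats repetitions with re-randomized folds (default 10); repeat
#'   `r` uses RNG seed `seed + r - 1`.
#' @param seed base RNG seed.
#' @param positive_class label treated as "positive" for sensitivity /
#'   specificity; defaults to the first label encountered.
#' @return object of class `CvConfig`.
#' @export
cv_config <- function(k_neighbors = 3L, n_folds = 5L, n_repeats = 10L,
                      seed = 1L, positive_class = NULL) {
  if (n_folds < 2) stop("n_folds must be >= 2")
  structure(list(k_neighbors = as.integer(k_neighbors),
                 n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed),
                 positive_class = positive_class),
            class = "CvConfig")
}

#' k-nearest-neighbour prediction
#'
#' Euclidean-distance KNN with majority vote. Vote ties are broken by the
#' class of the nearest neighbour among the tied classes; distance ties are
#' resolved by training-row order, so predictions are deterministic.
#'
#' @param train a [feature_table()] (or bare matrix with `train_labels`).
#' @param test a [feature_table()] or bare matrix of query rows.
#' @param k neighbourhood size; must not exceed the training count.
#' @param train_labels labels when `train` is a bare matrix.
#' @return character vector of predicted labels.
#' @export
knn_predict <- function(train, test, k = 3L, train_labels = NULL) {
  if (inherits(train, "FeatureTable")) {
    train_labels <- train$labels
    train <- train$matrix
  }
  if (inherits(test, "FeatureTable")) test <- test$matrix
  train <- as.matrix(train); test <- as.matrix(test)
  if (k > nrow(train))
    stop(sprintf("k = %d exceeds training size %d", k, nrow(train)))
  # squared distances, test rows x train rows
  d2 <- outer(rowSums(test^2), rep(1, nrow(train))) +
    outer(rep(1, nrow(test)), rowSums(train^2)) - 2 * tcrossprod(test, train)
  pred <- character(nrow(test))
  for (i in seq_len(nrow(test))) {
    ord <- order(d2[i, ])             # stable: distance ties keep row order
    nn <- ord[seq_len(k)]
    votes <- table(train_labels[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) {
      pred[i] <- top
    } else {
      # nearest neighbour whose class is among the tied classes
      pred[i] <- train_labels[nn[match(TRUE, train_labels[nn] %in% top)]]
    }
  }
  pred
}

#' Stratified fold assignment
#'
#' @param labels class labels.
#' @param n_folds number of folds.
#' @param seed RNG seed (restored afterwards).
#' @return integer fold id per trial, each class spread evenly across folds.
#' @export
stratified_folds <- function(labels, n_folds, seed) {
  folds <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      if (length(idx) < n_folds)
        stop(sprintf("class '%s' has %d members, fewer than %d folds",
                     cl, length(idx), n_folds))
      folds[sample(idx)] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

#' Classification metrics from pooled confusion counts
#'
#' @param tp,fn,tn,fp confusion counts with respect to a designated positive
#'   class.
#' @return list with `acc`, `sen`, `spe` in percent.
#' @export
metrics_from_confusion <- function(tp, fn, tn, fp) {
  list(acc = 100 * (tp + tn) / (tp + fn + tn + fp),
       sen = 100 * tp / (tp + fn),
       spe = 100 * tn / (tn + fp))
}

new_metrics_report <- function(per_repeat, confusion, positive_class,
                               n_selected = NA_integer_, curve = NULL) {
  mets <- if (!is.null(confusion))
    metrics_from_confusion(confusion["tp"], confusion["fn"],
                           confusion["tn"], confusion["fp"])
  else list(acc = NA_real_, sen = NA_real_, spe = NA_real_)
  structure(
    list(acc_mean = mean(per_repeat),
         acc_sd = stats::sd(per_repeat),
         sensitivity = unname(mets$sen), specificity = unname(mets$spe),
         per_repeat = per_repeat, confusion = confusion,
         positive_class = positive_class,
         n_selected = n_selected, curve = curve),
    class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf("<MetricsReport> ACC %.2f%% (SD %.2f)", x$acc_mean, x$acc_sd))
  if (is.finite(x$sensitivity))
    cat(sprintf(", SEN %.2f%%, SPE %.2f%% (positive = %s)",
                x$sensitivity, x$specificity, x$positive_class))
  if (!is.na(x$n_selected)) cat(sprintf(", %d feature(s) selected", x$n_selected))
  cat("\n")
  invisible(x)
}

#' Repeated stratified cross-validation of a KNN classifier
#'
#' Runs `n_repeats` rounds of stratified `n_folds`-fold cross-validation with
#' re-randomized folds (repeat `r` seeded with `seed + r - 1`). The reported
#' accuracy is the mean of the repeat-level accuracies and the SD is taken
#' across repeats; sensitivity and specificity are computed from confusion
#' counts pooled over all folds and repeats (binary tasks only).
#'
#' @param features a [feature_table()].
#' @param cfg a [cv_config()].
#' @param columns optional column subset to use (e.g. a selection prefix).
#' @return a `MetricsReport`.
#' @export
repeated_cv <- function(features, cfg, columns = NULL) {
  stopifnot(inherits(features, "FeatureTable"), inherits(cfg, "CvConfig"))
  X <- features$matrix
  if (!is.null(columns)) X <- X[, columns, drop = FALSE]
  labels <- features$labels
  classes <- unique(labels)
  binary <- length(classes) == 2
  pos <- cfg$positive_class
  if (is.null(pos)) pos <- classes[1]
  per_repeat <- numeric(cfg$n_repeats)
  conf <- c(tp = 0, fn = 0, tn = 0, fp = 0)
  for (r in seq_len(cfg$n_repeats)) {
    folds <- stratified_folds(labels, cfg$n_folds, cfg$seed + r - 1L)
    correct <- 0L
    for (f in seq_len(cfg$n_folds)) {
      te <- folds == f
      pred <- knn_predict(X[!te, , drop = FALSE], X[te, , drop = FALSE],
                          cfg$k_neighbors, train_labels = labels[!te])
      truth <- labels[te]
      correct <- correct + sum(pred == truth)
      if (binary) {
        conf["tp"] <- conf["tp"] + sum(truth == pos & pred == pos)
        conf["fn"] <- conf["fn"] + sum(truth == pos & pred != pos)
        conf["tn"] <- conf["tn"] + sum(truth != pos & pred != pos)
        conf["fp"] <- conf["fp"] + sum(truth != pos & pred == pos)
      }
    }
    per_repeat[r] <- 100 * correct / length(labels)
  }
  new_metrics_report(per_repeat, if (binary) conf else NULL, pos)
}

#' Sequential forward feature selection
#'
#' Orders features by univariate Fisher score ([order_features()]) and
#' evaluates [repeated_cv()] on each prefix of the ordering, adding features
#' one by one; returns the shortest prefix achieving the global maximum mean
#' accuracy together with the full accuracy-vs-prefix curve.
#'
#' Run on a whole feature table this reproduces the leaky whole-set protocol;
#' for honest reporting use [evaluate_task()] with `selection = "sequential"`,
#' which nests the selection inside training folds.
#'
#' @param features a [feature_table()].
#' @param cfg a [cv_config()].
#' @return list of class `SequentialSelection` with `order`, `n_selected`,
#'   `selected` (original column indices of the chosen prefix), `curve`, and
#'   `report` (the `MetricsReport` of the chosen prefix, with curve attached).
#' @export
sequential_select <- function(features, cfg) {
  stopifnot(inherits(features, "FeatureTable"))
  ord <- order_features(features)
  Fn <- ncol(features$matrix)
  reports <- vector("list", Fn)
  curve <- numeric(Fn)
  for (f in seq_len(Fn)) {
    reports[[f]] <- repeated_cv(features, cfg, columns = ord[seq_len(f)])
    curve[f] <- reports[[f]]$acc_mean
  }
  best <- which.max(curve)     # which.max returns the first (shortest) argmax
  rep_best <- reports[[best]]
  rep_best$n_selected <- best
  rep_best$curve <- curve
  structure(list(order = as.integer(ord), n_selected = best,
                 selected = as.integer(ord[seq_len(best)]),
                 curve = curve, report = rep_best),
            class = "SequentialSelection")
}
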