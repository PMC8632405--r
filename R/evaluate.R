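# Task-level evaluation: per-band DSP fitting, band fusion, optional nested
# sequential selection, and repeated stratified CV with a KNN classifier.

# fit a DSP model on bare vectorized rows (used inside CV folds)
dsp_fit_rows <- function(X, labels, backend = "improved", gamma = 1e-3,
                         solver = "auto", band_tag = "") {
  vt <- structure(list(vectors = X, labels = labels,
                       class_sizes = table(labels),
                       dims = c(N = NA, Tprime = NA), band_tag = band_tag),
                  class = "VectorizedTrials")
  if (backend == "improved") {
    dsp_improved(vt, gamma = gamma, solver = solver)
  } else {
    dsp_classic(scatter_matrices(vt, reg_gamma = gamma))
  }
}

#' Evaluate a binary classification task over frequency bands
#'
#' Runs the full feature-extraction + classification protocol for one class
#' pair on component-extracted epochs from one or more frequency bands,
#' including the fused band (column-wise concatenation of all per-band
#' features).
#'
#' In `"nested"` mode (the default) the DSP model — and, when requested, the
#' sequential feature selection — is refit inside every training fold, so no
#' test-fold information reaches the projection or the selection; this is the
#' honest protocol and the one under which permuted labels score at chance.
#' `"pooled"` mode reproduces the conventional shortcut of fitting the
#' projection on the full set before cross-validating the features; it is
#' optimistically biased when trials are scarce relative to dimensions.
#'
#' @param band_epochs named list of [epoch_set()] objects (one per band, same
#'   trials in the same order), normally outputs of [extract_combine()].
#' @param pair character vector of the two class labels; the first is the
#'   positive class for sensitivity/specificity.
#' @param cfg a [cv_config()].
#' @param backend `"improved"` or `"classic"`.
#' @param gamma ridge coefficient for the DSP solve.
#' @param eval_bands bands to report; defaults to every supplied band plus
#'   `"fusion"` when more than one band is supplied.
#' @param selection `"none"` (use all model features) or `"sequential"`
#'   (forward selection on the Fisher-score ordering).
#' @param mode `"nested"` or `"pooled"` (see Details).
#' @param inner_repeats CV repeats of the inner selection loop in nested
#'   mode.
#' @return object of class `TaskEvaluation`: list with `pair`, `mode` and
#'   `reports` (named list of `MetricsReport`, one per evaluated band).
#' @export
evaluate_task <- function(band_epochs, pair, cfg = cv_config(),
                          backend = c("improved", "classic"), gamma = 1e-3,
                          eval_bands = NULL,
                          selection = c("none", "sequential"),
                          mode = c("nested", "pooled"),
                          inner_repeats = 2L) {
  backend <- match.arg(backend)
  selection <- match.arg(selection)
  mode <- match.arg(mode)
  stopifnot(is.list(band_epochs), length(band_epochs) >= 1, length(pair) == 2)
  if (is.null(names(band_epochs)))
    names(band_epochs) <- vapply(band_epochs, `[[`, "", "band_tag")
  src_bands <- names(band_epochs)
  if (is.null(eval_bands))
    eval_bands <- c(src_bands, if (length(src_bands) > 1) "fusion")
  labels_all <- band_epochs[[1]]$labels
  for (b in src_bands)
    if (!identical(band_epochs[[b]]$labels, labels_all))
      stop("band epoch sets do not share the same trial/label sequence")
  keep <- labels_all %in% pair
  if (sum(keep) == 0) stop("no trials with the requested pair of labels")
  labels <- labels_all[keep]
  vt <- lapply(band_epochs, function(es) vectorize_trials(subset_epochs(es, keep)))
  pos <- pair[1]

  if (mode == "pooled") {
    feats <- lapply(src_bands, function(b) dsp_transform(
      dsp_fit_rows(vt[[b]]$vectors, labels, backend, gamma, band_tag = b),
      vt[[b]]$vectors)$matrix)
    names(feats) <- src_bands
    tables <- lapply(src_bands, function(b)
      feature_table(feats[[b]], labels,
                    provenance = data.frame(band = b, column = seq_len(ncol(feats[[b]])))))
    names(tables) <- src_bands
    if ("fusion" %in% eval_bands) tables$fusion <- fuse_bands(tables[src_bands])
    cfg_pos <- cfg
    cfg_pos$positive_class <- pos
    reports <- lapply(eval_bands, function(b) {
      if (selection == "sequential") sequential_select(tables[[b]], cfg_pos)$report
      else repeated_cv(tables[[b]], cfg_pos)
    })
    names(reports) <- eval_bands
    return(structure(list(pair = pair, mode = mode, reports = reports),
                     class = "TaskEvaluation"))
  }

  # nested: refit the projection (and selection) inside each training fold
  n <- length(labels)
  per_repeat <- matrix(0, cfg$n_repeats, length(eval_bands),
                       dimnames = list(NULL, eval_bands))
  conf <- matrix(0, 4, length(eval_bands),
                 dimnames = list(c("tp", "fn", "tn", "fp"), eval_bands))
  n_sel <- stats::setNames(rep(list(integer(0)), length(eval_bands)), eval_bands)
  for (r in seq_len(cfg$n_repeats)) {
    folds <- stratified_folds(labels, cfg$n_folds, cfg$seed + r - 1L)
    correct <- stats::setNames(numeric(length(eval_bands)), eval_bands)
    for (f in seq_len(cfg$n_folds)) {
      te <- folds == f
      ftr <- list(); fte <- list()
      for (b in src_bands) {
        X <- vt[[b]]$vectors
        model <- dsp_fit_rows(X[!te, , drop = FALSE], labels[!te],
                              backend, gamma, band_tag = b)
        prov <- data.frame(band = b, column = seq_len(ncol(model$W1)))
        Ztr <- X[!te, , drop = FALSE] %*% model$W1 +
          matrix(model$delta, sum(!te), ncol(model$W1), byrow = TRUE)
        Zte <- X[te, , drop = FALSE] %*% model$W1 +
          matrix(model$delta, sum(te), ncol(model$W1), byrow = TRUE)
        ftr[[b]] <- feature_table(Ztr, labels[!te], provenance = prov)
        fte[[b]] <- feature_table(Zte, labels[te], provenance = prov)
      }
      if ("fusion" %in% eval_bands) {
        ftr$fusion <- fuse_bands(ftr[src_bands])
        fte$fusion <- fuse_bands(fte[src_bands])
      }
      for (b in eval_bands) {
        cols <- seq_len(ncol(ftr[[b]]$matrix))
        if (selection == "sequential") {
          inner_cfg <- cv_config(cfg$k_neighbors,
                                 min(cfg$n_folds, min(table(labels[!te]))),
                                 inner_repeats,
                                 seed = cfg$seed * 1000L + r * 37L + f,
                                 positive_class = pos)
          sel <- sequential_select(ftr[[b]], inner_cfg)
          cols <- sel$selected
          n_sel[[b]] <- c(n_sel[[b]], sel$n_selected)
        }
        pred <- knn_predict(ftr[[b]]$matrix[, cols, drop = FALSE],
                            fte[[b]]$matrix[, cols, drop = FALSE],
                            cfg$k_neighbors, train_labels = labels[!te])
        truth <- labels[te]
        correct[b] <- correct[b] + sum(pred == truth)
        conf["tp", b] <- conf["tp", b] + sum(truth == pos & pred == pos)
        conf["fn", b] <- conf["fn", b] + sum(truth == pos & pred != pos)
        conf["tn", b] <- conf["tn", b] + sum(truth != pos & pred != pos)
        conf["fp", b] <- conf["fp", b] + sum(truth != pos & pred == pos)
      }
    }
    per_repeat[r, ] <- 100 * correct / n
  }
  reports <- lapply(eval_bands, function(b)
    new_metrics_report(per_repeat[, b], conf[, b], pos,
                       n_selected = if (length(n_sel[[b]]) > 0)
                         as.integer(round(stats::median(n_sel[[b]]))) else NA_integer_))
  names(reports) <- eval_bands
  structure(list(pair = pair, mode = mode, reports = reports),
            class = "TaskEvaluation")
}

#' @export
print.TaskEvaluation <- function(x, ...) {
  cat(sprintf("<TaskEvaluation> %s vs %s (%s mode)\n", x$pair[1], x$pair[2], x$mode))
  for (b in names(x$reports)) {
    r <- x$reports[[b]]
    cat(sprintf("  %-8s ACC %6.2f%%  SD %5.2f  SEN %6.2f%%  SPE %6.2f%%\n",
                b, r$acc_mean, r$acc_sd, r$sensitivity, r$specificity))
  }
  invisible(x)
}
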