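#' Trials-by-features table
#'
#' Container for extracted classification features with per-feature
#' provenance (which frequency band and model column each feature came from),
#' used for band fusion and sequential selection.
#'
#' @param matrix numeric n x F matrix of feature values.
#' @param labels per-trial class labels (length n).
#' @param provenance data frame with one row per feature, columns `band` and
#'   `column`; autogenerated when `NULL`.
#' @param scores optional per-feature discriminability scores.
#' @return object of class `FeatureTable`.
#' @export
feature_table <- function(matrix, labels, provenance = NULL, scores = NULL) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != length(labels))
    stop("feature rows do not align with labels")
  if (is.null(provenance))
    provenance <- data.frame(band = "", column = seq_len(ncol(matrix)),
                             stringsAsFactors = FALSE)
  if (nrow(provenance) != ncol(matrix))
    stop("provenance length must equal feature count")
  structure(list(matrix = matrix, labels = as.character(labels),
                 provenance = provenance, scores = scores),
            class = "FeatureTable")
}

#' @export
print.FeatureTable <- function(x, ...) {
  cat(sprintf("<FeatureTable> %d trials x %d features", nrow(x$matrix), ncol(x$matrix)))
  bands <- unique(x$provenance$band)
  if (any(nzchar(bands))) cat(" | bands:", paste(bands, collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Fuse per-band feature tables
#'
#' Column-wise concatenation of feature tables computed from the same trials
#' in different frequency bands; provenance is preserved so every fused
#' column can be traced back to its band and model column.
#'
#' @param tables list of [feature_table()] objects sharing trial count and
#'   label sequence.
#' @return single fused `FeatureTable` with `F = sum F_b` columns.
#' @export
fuse_bands <- function(tables) {
  stopifnot(length(tables) >= 1)
  ref <- tables[[1]]
  for (t in tables[-1]) {
    if (nrow(t$matrix) != nrow(ref$matrix) || !identical(t$labels, ref$labels))
      stop("all tables must share trial count and label sequence")
  }
  feature_table(do.call(cbind, lapply(tables, `[[`, "matrix")),
                ref$labels,
                provenance = do.call(rbind, lapply(tables, `[[`, "provenance")))
}

#' Rank features by univariate Fisher score
#'
#' Score = between-class variance of the feature over within-class variance
#' (sum over classes of `n_j (m_jf - m_f)^2` divided by the pooled
#' within-class sum of squares). Deterministic: ties keep original column
#' order. A feature with zero within-class variance but nonzero between-class
#' separation gets an infinite score (ranked first) and is flagged in the
#' `degenerate` attribute; an entirely constant feature scores 0.
#'
#' @param features a [feature_table()].
#' @param labels class labels; defaults to the table's own.
#' @return integer permutation of the feature columns, best first, with
#'   attributes `scores` and `degenerate`.
#' @export
order_features <- function(features, labels = NULL) {
  stopifnot(inherits(features, "FeatureTable"))
  X <- features$matrix
  if (is.null(labels)) labels <- features$labels
  classes <- sort(unique(labels))
  m_all <- colMeans(X)
  between <- numeric(ncol(X))
  within <- numeric(ncol(X))
  for (cl in classes) {
    idx <- which(labels == cl)
    mj <- colMeans(X[idx, , drop = FALSE])
    between <- between + length(idx) * (mj - m_all)^2
    within <- within + colSums(sweep(X[idx, , drop = FALSE], 2, mj)^2)
  }
  score <- unname(ifelse(within > 0, between / within,
                         ifelse(between > 0, Inf, 0)))
  ord <- order(-score, seq_along(score))
  structure(ord, scores = score, degenerate = which(!is.finite(score)))
}
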