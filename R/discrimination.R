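# Sequence-vs-shape discrimination: one-hot sequence and min-max-scaled
# shape feature matrices, L2-regularized linear regression on 0/1 labels,
# and rank-based AUROC over cross-validated predictions.

#' One-hot encode site sequences
#'
#' Each position contributes four binary columns (A, C, G, T order) with
#' exactly one 1. Sequences containing N are dropped with a message.
#'
#' @param sequences Character vector of equal-length DNA strings.
#' @return Numeric matrix, rows = kept sites, columns
#'   `pos<k>_<base>`; attribute `kept` gives the retained row indices.
#' @export
encode_sequence <- function(sequences) {
  L <- unique(nchar(sequences))
  if (length(L) != 1L) abort("sequences must have equal length")
  keep <- !grepl("[^ACGT]", toupper(sequences))
  if (any(!keep)) {
    inform(paste0(sum(!keep), " sequence(s) with non-ACGT bases dropped"))
  }
  seqs <- toupper(sequences[keep])
  if (!length(seqs)) abort("no encodable sequences")
  codes <- t(vapply(seqs, function(s) match(strsplit(s, "")[[1]], DNA_BASES),
                    integer(L)))
  X <- matrix(0, nrow(codes), 4L * L)
  for (p in seq_len(L)) {
    X[cbind(seq_len(nrow(codes)), (p - 1L) * 4L + codes[, p])] <- 1
  }
  colnames(X) <- paste0("pos", rep(seq_len(L), each = 4), "_",
                        rep(DNA_BASES, L))
  attr(X, "kept") <- which(keep)
  X
}

#' Decode a one-hot sequence matrix back to strings
#' @param X Matrix from [encode_sequence()].
#' @return Character vector of sequences.
#' @export
decode_sequence <- function(X) {
  L <- ncol(X) / 4L
  apply(X, 1L, function(r) {
    paste(DNA_BASES[apply(matrix(r, nrow = 4L), 2L, which.max)],
          collapse = "")
  })
}

#' Shape-feature encoding of site sequences
#'
#' Concatenates per-position MGW, ProT, Roll and HelT predictions, then
#' min-max scales each feature to \[0, 1\] using the extremes of that
#' feature over the training set (a constant feature scales to 0). Columns
#' undefined at window edges are dropped. Stored scaling parameters can be
#' applied to held-out data, whose values may then fall outside \[0, 1\]
#' and are retained unclipped.
#'
#' @param sequences Character vector of equal-length DNA strings (N-free;
#'   offending rows dropped with a message).
#' @param table A `shape_table`.
#' @param scaling Optional scaling parameters (attribute of a previous
#'   result) to reuse; default fits scaling on these sequences.
#' @return Numeric matrix with attributes `kept` and `scaling` (tibble:
#'   feature, min, max).
#' @export
encode_shape <- function(sequences, table, scaling = NULL) {
  keep <- !grepl("[^ACGT]", toupper(sequences))
  if (any(!keep)) {
    inform(paste0(sum(!keep), " sequence(s) with non-ACGT bases dropped"))
  }
  seqs <- toupper(sequences[keep])
  if (!length(seqs)) abort("no encodable sequences")
  preds <- lapply(seqs, predict_shape, table = table)
  blocks <- list()
  for (f in SHAPE_FEATURES) {
    m <- t(vapply(preds, function(p) p[[f]], numeric(nchar(seqs[1]))))
    ok <- colSums(is.na(m)) == 0L
    m <- m[, ok, drop = FALSE]
    colnames(m) <- paste0(f, "_", which(ok) - 1L)
    blocks[[f]] <- m
  }
  if (is.null(scaling)) {
    scaling <- tibble(feature = SHAPE_FEATURES,
                      min = vapply(blocks, min, 0),
                      max = vapply(blocks, max, 0))
  }
  for (f in SHAPE_FEATURES) {
    s <- scaling[scaling$feature == f, ]
    rng <- s$max - s$min
    blocks[[f]] <- if (rng > 0) (blocks[[f]] - s$min) / rng else
      blocks[[f]] * 0
  }
  X <- do.call(cbind, blocks)
  attr(X, "kept") <- which(keep)
  attr(X, "scaling") <- scaling
  X
}

#' Area under the ROC curve
#'
#' Rank statistic of predictions against binary labels, ties counted half
#' (equivalent to the normalized Mann-Whitney U).
#'
#' @param predictions Numeric scores.
#' @param labels 0/1 (or logical) labels.
#' @return AUROC in \[0, 1\]; 0.5 indicates a random classifier.
#' @export
auroc <- function(predictions, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) abort("both classes must be present")
  r <- rank(predictions)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# closed-form ridge solve; intercept unpenalized
ridge_fit <- function(X, y, lambda) {
  Xi <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xi)
  pen <- diag(c(0, rep(lambda, p - 1L)))
  beta <- solve(crossprod(Xi) + pen, crossprod(Xi, y))
  drop(beta)
}

ridge_predict <- function(beta, X) drop(cbind(1, X) %*% beta)

#' Ridge-regression AUROC for a site feature matrix
#'
#' Fits least squares with an L2 penalty on 0/1 class labels and scores the
#' classification by AUROC. Predictions are pooled over k-fold
#' cross-validation with seeded fold assignment; the in-sample (training)
#' AUROC is also reported.
#'
#' @param X Feature matrix (rows = sites), e.g. from [encode_sequence()] or
#'   [encode_shape()].
#' @param labels 0/1 labels (1 = high-scoring class).
#' @param lambda L2 penalty (default 1).
#' @param folds Number of cross-validation folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @return A `chec_ridge` object: list with `auroc` (cross-validated),
#'   `auroc_train`, `predictions`, `labels`, `coef` (full-data fit),
#'   `lambda`, `folds`, `seed`, `n`.
#' @export
ridge_auroc <- function(X, labels, lambda = 1, folds = 10L, seed = 1L) {
  labels <- as.integer(labels)
  if (length(labels) != nrow(X)) abort("labels do not match feature rows")
  if (length(unique(labels)) < 2L) abort("need both classes")
  if (min(table(labels)) < 2L) abort("need at least 2 sites per class")
  n <- nrow(X)
  folds <- min(folds, n)
  fold_id <- withr_seed(seed, sample(rep_len(seq_len(folds), n)))
  pred <- numeric(n)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    beta <- ridge_fit(X[!test, , drop = FALSE], labels[!test], lambda)
    pred[test] <- ridge_predict(beta, X[test, , drop = FALSE])
  }
  beta_full <- ridge_fit(X, labels, lambda)
  structure(list(auroc = auroc(pred, labels),
                 auroc_train = auroc(ridge_predict(beta_full, X), labels),
                 predictions = pred, labels = labels, coef = beta_full,
                 lambda = lambda, folds = folds, seed = seed, n = n),
            class = "chec_ridge")
}

#' @export
print.chec_ridge <- function(x, ...) {
  cat("<chec_ridge> n =", x$n, "lambda =", x$lambda,
      "| cross-validated AUROC =", round(x$auroc, 4), "\n")
  invisible(x)
}

#' @describeIn ridge_auroc Coefficients of the full-data fit as a tibble.
#' @param x A `chec_ridge` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.chec_ridge <- function(x, ...) {
  tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' @describeIn ridge_auroc One-row model summary.
#' @exportS3Method generics::glance
glance.chec_ridge <- function(x, ...) {
  tibble(auroc = x$auroc, auroc_train = x$auroc_train, lambda = x$lambda,
         folds = x$folds, n = x$n)
}
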