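# The fitness oracle for the channel-subset search: stratified k-fold
# cross-validation of the four-classifier portfolio on the feature columns
# of a candidate channel subset.

#' Stratified k-fold assignment
#'
#' Every instance lands in exactly one test fold; per-fold class counts
#' differ by at most one. When the smaller class has fewer than `k`
#' members, `k` is reduced to that count (mirrors falling back from 10- to
#' 9-fold CV on patients with few seizure epochs).
#'
#' @param labels Class labels (two classes).
#' @param k Requested number of folds (>= 2).
#' @param seed Integer seed for the within-class shuffle.
#' @return Integer vector of fold ids in `1..k_eff`, with attribute `k`.
#' @export
stratified_folds <- function(labels, k = 10, seed = 1) {
  k <- assert_count(k, "k", min = 2L)
  counts <- table(labels)
  m <- min(counts)
  if (m < 2L) stop("each class needs at least 2 members", call. = FALSE)
  k_eff <- min(k, m)
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cls in names(counts)) {
      idx <- which(labels == cls)
      idx <- sample(idx)
      folds[idx] <- rep_len(seq_len(k_eff), length(idx))
    }
  })
  attr(folds, "k") <- k_eff
  folds
}

#' Accuracy, sensitivity, specificity from predictions
#'
#' Seizure (label 1) is the positive class. A rate whose class is absent
#' from `y_true` is reported as `NA` rather than 0.
#'
#' @param y_true,y_pred Equal-length binary label vectors.
#' @return Named list `accuracy`, `sensitivity`, `specificity`.
#' @export
confusion_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  tp <- sum(y_true == 1L & y_pred == 1L)
  tn <- sum(y_true == 0L & y_pred == 0L)
  fp <- sum(y_true == 0L & y_pred == 1L)
  fn <- sum(y_true == 1L & y_pred == 0L)
  list(
    accuracy = (tp + tn) / length(y_true),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
  )
}

#' Score a channel subset with the classifier portfolio
#'
#' Every parameter setting of every enabled family is scored by mean CV
#' accuracy over the same stratified folds (features standardized per fold
#' using training-fold statistics only). The returned accuracy is the
#' maximum over the grid; the winner's family and parameters are recorded,
#' and sensitivity/specificity come from the winner's pooled out-of-fold
#' predictions. Grid selection on the evaluation folds themselves mirrors
#' the original wrapper design and is optimistically biased; see the
#' methods vignette.
#'
#' Ties on accuracy break by family priority (margin classifier, kNN,
#' random forest, naive Bayes), then by parameter order within a family,
#' so reported classifier-usage statistics are deterministic.
#'
#' @param table A `feature_table` from [build_feature_table()].
#' @param subset Channel indices (1-based) or channel labels; non-empty,
#'   within the montage.
#' @param portfolio A [portfolio_spec()].
#' @param k Requested CV folds.
#' @param seed Integer seed (folds and forest randomness).
#' @return Object of class `subset_score`: list with `accuracy`,
#'   `classifier_id`, `sensitivity`, `specificity`,
#'   `per_family_accuracies`, `k`.
#' @export
evaluate_subset <- function(table, subset, portfolio = portfolio_spec(),
                            k = 10, seed = 1) {
  stopifnot(inherits(table, "feature_table"))
  cols <- subset_columns(table, subset)
  X <- table$matrix[, cols, drop = FALSE]
  y <- table$labels
  folds <- stratified_folds(y, k = k, seed = seed)
  k_eff <- attr(folds, "k")
  grid <- portfolio_grid(portfolio)
  n <- length(y)
  preds <- matrix(NA_integer_, nrow = n, ncol = length(grid))
  fold_acc <- matrix(NA_real_, nrow = k_eff, ncol = length(grid))
  for (f in seq_len(k_eff)) {
    te <- folds == f
    Xtr <- X[!te, , drop = FALSE]
    Xte <- X[te, , drop = FALSE]
    mu <- colMeans(Xtr)
    sdv <- apply(Xtr, 2L, sd)
    sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
    Xtr <- sweep(sweep(Xtr, 2L, mu), 2L, sdv, "/")
    Xte <- sweep(sweep(Xte, 2L, mu), 2L, sdv, "/")
    ytr <- y[!te]
    for (g in seq_along(grid)) {
      p <- grid[[g]]$fit(Xtr, ytr, Xte,
                         seed = substream_seed(seed, f * 1000L + g))
      preds[te, g] <- p
      fold_acc[f, g] <- mean(p == y[te])
    }
  }
  acc <- colMeans(fold_acc)
  best <- which.max(acc)               # grid is in tie-break priority order
  fams <- vapply(grid, `[[`, "", "family")
  per_family <- tapply(acc, fams, max)
  # keep a stable family order in the report
  fam_order <- intersect(c("svm", "knn", "rf", "nb"), names(per_family))
  per_family <- as.list(per_family[fam_order])
  cm <- confusion_metrics(y, preds[, best])
  structure(list(accuracy = unname(acc[best]),
                 classifier_id = grid[[best]]$id,
                 classifier_family = fams[best],
                 sensitivity = cm$sensitivity,
                 specificity = cm$specificity,
                 per_family_accuracies = per_family,
                 k = k_eff),
            class = "subset_score")
}

#' @export
print.subset_score <- function(x, ...) {
  cat(sprintf(
    "<subset_score> accuracy %.4f (%s, %d-fold CV), sens %.3f spec %.3f\n",
    x$accuracy, x$classifier_id, x$k, x$sensitivity, x$specificity))
  invisible(x)
}

#' Build a memoizing fitness evaluator from a feature table
#'
#' Returns a closure mapping a channel subset (integer indices) to its
#' [evaluate_subset()] score. Results are cached by subset bitmask: the CV
#' seed is fixed per evaluator, so each subset has a unique accuracy and
#' re-evaluation is free. The closure exposes its call statistics via
#' `attr(, "stats")()`.
#'
#' @param table A `feature_table`.
#' @param portfolio A [portfolio_spec()].
#' @param k CV folds.
#' @param seed CV/forest seed, fixed for the evaluator's lifetime.
#' @param log_file Optional path; one line per distinct evaluation.
#' @return Function `(subset) -> subset_score`.
#' @export
make_evaluator <- function(table, portfolio = portfolio_spec(), k = 10,
                           seed = 1, log_file = NULL) {
  cache <- new.env(parent = emptyenv())
  n_calls <- 0L
  n_distinct <- 0L
  C <- n_channels(table)
  ev <- function(subset) {
    subset <- sort(unique(as.integer(subset)))
    key <- paste(subset, collapse = ",")
    n_calls <<- n_calls + 1L
    if (!is.null(cache[[key]])) return(cache[[key]])
    score <- evaluate_subset(table, subset, portfolio, k = k, seed = seed)
    n_distinct <<- n_distinct + 1L
    cache[[key]] <- score
    if (!is.null(log_file)) {
      mask <- paste(as.integer(seq_len(C) %in% subset), collapse = "")
      cat(sprintf("eval mask=%s winner=%s acc=%.6f folds=%d\n",
                  mask, score$classifier_id, score$accuracy, score$k),
          file = log_file, append = TRUE)
    }
    score
  }
  attr(ev, "stats") <- function() list(calls = n_calls,
                                       distinct = n_distinct)
  attr(ev, "n_channels") <- C
  ev
}
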