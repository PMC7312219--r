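# The four-classifier portfolio scored inside the wrapper search.
# No SVM/kNN/NB/forest packages are available offline in this stack, so the
# classifiers are implemented here:
#  - margin classifier: kernel regularized least squares (LS-SVM form) with
#    sigmoid / linear / RBF kernels,
#  - k-nearest neighbours with deterministic tie-breaking,
#  - random forest (Rcpp, see src/rf.cpp),
#  - Gaussian naive Bayes.
# All are deterministic given their seed argument.

kernel_matrix <- function(X, Y, kernel, gamma) {
  G <- X %*% t(Y)
  switch(kernel,
    linear = G,
    sigmoid = tanh(gamma * G),
    rbf = {
      d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * G
      exp(-gamma * pmax(d2, 0))
    },
    stop("unknown kernel: ", kernel, call. = FALSE)
  )
}

# Kernel regularized least-squares margin classifier.
# lambda = 1/cost; gamma = 1/(p * var(X)) ("scale" convention).
svm_predict <- function(X_train, y_train, X_test, kernel, cost = 1) {
  p <- ncol(X_train)
  v <- var(as.vector(X_train))
  gamma <- if (is.finite(v) && v > 0) 1 / (p * v) else 1 / p
  yy <- ifelse(y_train == 1L, 1, -1)
  K <- kernel_matrix(X_train, X_train, kernel, gamma)
  n <- nrow(X_train)
  alpha <- solve(K + diag(1 / cost, n), yy)
  score <- kernel_matrix(X_test, X_train, kernel, gamma) %*% alpha
  as.integer(score >= 0)
}

# kNN; ties on the vote are broken by the label of the single nearest
# neighbour, so predictions are deterministic.
knn_predict <- function(X_train, y_train, X_test, k) {
  k <- min(k, length(y_train))
  d2 <- outer(rowSums(X_test^2), rowSums(X_train^2), "+") -
    2 * X_test %*% t(X_train)
  apply_rows <- vapply(seq_len(nrow(X_test)), function(i) {
    ord <- order(d2[i, ])
    nb <- y_train[ord[seq_len(k)]]
    votes <- sum(nb == 1L)
    if (2L * votes == k) y_train[ord[1L]] else as.integer(2L * votes > k)
  }, 0L)
  apply_rows
}

# Gaussian naive Bayes; tie on log-posterior -> class 0.
nb_predict <- function(X_train, y_train, X_test) {
  eps <- 1e-9
  classes <- c(0L, 1L)
  loglik <- matrix(0, nrow = nrow(X_test), ncol = 2L)
  for (j in 1:2) {
    idx <- y_train == classes[j]
    mu <- colMeans(X_train[idx, , drop = FALSE])
    s2 <- apply(X_train[idx, , drop = FALSE], 2L, var) + eps
    s2[!is.finite(s2)] <- eps
    ll <- -0.5 * sweep(sweep(X_test, 2L, mu)^2, 2L, s2, "/") -
      0.5 * matrix(log(2 * pi * s2), nrow(X_test), ncol(X_test),
                   byrow = TRUE)
    loglik[, j] <- rowSums(ll) + log(mean(idx) + eps)
  }
  as.integer(loglik[, 2L] > loglik[, 1L])
}

rf_predict <- function(X_train, y_train, X_test, depth, n_trees, seed) {
  mtry <- max(1L, as.integer(floor(sqrt(ncol(X_train)))))
  rf_fit_predict(X_train, as.integer(y_train), X_test,
                 as.integer(n_trees), as.integer(depth), mtry,
                 as.double(seed))
}

#' Classifier portfolio specification
#'
#' The grid of classifiers and parameters evaluated for every channel
#' subset; the best cross-validated accuracy over the whole grid is the
#' subset's score.
#'
#' @param kernels Margin-classifier kernels (subset of
#'   `c("sigmoid", "linear", "rbf")`; empty disables the family).
#' @param neighbors kNN neighbour counts (default 1..9).
#' @param tree_depths Random-forest depths (default 2..5).
#' @param naive_bayes Include Gaussian naive Bayes?
#' @param n_trees Trees per forest (default 100).
#' @param cost Margin-classifier regularization constant.
#' @return Object of class `portfolio_spec`.
#' @export
portfolio_spec <- function(kernels = c("sigmoid", "linear", "rbf"),
                           neighbors = 1:9, tree_depths = 2:5,
                           naive_bayes = TRUE, n_trees = 100, cost = 1) {
  kernels <- match.arg(kernels, c("sigmoid", "linear", "rbf"),
                       several.ok = TRUE)
  if (length(kernels) + length(neighbors) + length(tree_depths) +
      naive_bayes == 0) {
    stop("at least one classifier family must be enabled", call. = FALSE)
  }
  structure(list(kernels = kernels, neighbors = as.integer(neighbors),
                 tree_depths = as.integer(tree_depths),
                 naive_bayes = isTRUE(naive_bayes),
                 n_trees = assert_count(n_trees, "n_trees"),
                 cost = assert_number(cost, "cost", min = 1e-9)),
            class = "portfolio_spec")
}

# Flat list of (family, parameter, predict closure factory) entries, in
# tie-break priority order: svm > knn > rf > nb.
portfolio_grid <- function(portfolio) {
  grid <- list()
  for (kern in portfolio$kernels) {
    grid[[length(grid) + 1L]] <- list(
      family = "svm", id = paste0("svm:", kern),
      fit = local({
        kern_ <- kern
        cost_ <- portfolio$cost
        function(Xtr, ytr, Xte, seed) svm_predict(Xtr, ytr, Xte, kern_,
                                                  cost_)
      }))
  }
  for (k in portfolio$neighbors) {
    grid[[length(grid) + 1L]] <- list(
      family = "knn", id = paste0("knn:k=", k),
      fit = local({
        k_ <- k
        function(Xtr, ytr, Xte, seed) knn_predict(Xtr, ytr, Xte, k_)
      }))
  }
  for (d in portfolio$tree_depths) {
    grid[[length(grid) + 1L]] <- list(
      family = "rf", id = paste0("rf:depth=", d),
      fit = local({
        d_ <- d
        nt <- portfolio$n_trees
        function(Xtr, ytr, Xte, seed) rf_predict(Xtr, ytr, Xte, d_, nt,
                                                 seed)
      }))
  }
  if (portfolio$naive_bayes) {
    grid[[length(grid) + 1L]] <- list(
      family = "nb", id = "nb:gaussian",
      fit = function(Xtr, ytr, Xte, seed) nb_predict(Xtr, ytr, Xte))
  }
  grid
}
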