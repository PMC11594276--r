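#' Cross-validated Q2 for an OPLS-DA configuration
#'
#' Q2 = 1 - PRESS/SS: the class matrix is predicted out-of-fold over a
#' seeded stratified K-fold partition (scaling and the full orthogonal +
#' predictive decomposition are refit inside each training split), PRESS sums
#' the squared out-of-fold one-hot prediction errors, and SS is the total
#' centered class-matrix variance. Values near 1 indicate real predictive
#' ability; values at or below 0 indicate none.
#'
#' @param x Samples x variables matrix (unscaled).
#' @param labels Class labels.
#' @param n_pred,n_orth Component counts (defaults: classes - 1, 0).
#' @param n_folds Number of folds (default 7, stratified by class).
#' @param seed Seed for the fold assignment.
#' @param scale Scaling mode refit within each training split.
#' @return Q2 (scalar, <= 1).
#' @export
cross_validate_q2 <- function(x, labels, n_pred = NULL, n_orth = 0,
                              n_folds = 7, seed = 1L,
                              scale = c("uv", "pareto", "none")) {
  scale <- match.arg(scale)
  x <- as.matrix(x)
  labels <- droplevels(as.factor(labels))
  if (is.null(n_pred)) n_pred <- max(1L, nlevels(labels) - 1L)
  Yfull <- one_hot(labels, center = FALSE)
  SS <- sum(sweep(Yfull, 2, colMeans(Yfull), "-")^2)
  fold <- stratified_folds(labels, n_folds, seed, rownames(x))
  press <- 0
  for (k in sort(unique(fold))) {
    test <- fold == k
    if (!any(test)) next
    ytr <- labels[!test]
    if (nlevels(droplevels(ytr)) < nlevels(labels)) {
      stop("stratification error: fold ", k, " removes an entire class")
    }
    sc <- suppressWarnings(autoscale(x[!test, , drop = FALSE], scale))
    Ytr <- one_hot(ytr)
    fit <- opls_engine(sc$values, Ytr, n_pred, n_orth)
    Xte <- apply_scaling(x[test, , drop = FALSE], sc)
    pr <- opls_project(fit, Xte)
    Yte_hat <- sweep(pr$Yhat, 2, attr(Ytr, "means"), "+")
    press <- press + sum((Yfull[test, , drop = FALSE] - Yte_hat)^2)
  }
  1 - press / SS
}

#' Permutation test of an OPLS-DA model
#'
#' Refits the model under `n_perm` random permutations of the class labels
#' and records, for each, the R2Y and cross-validated Q2 together with the
#' correlation between the permuted and original class assignments (mean
#' |Pearson r| across the one-hot columns). Lines are fitted through each
#' statistic against the label correlation — including the unpermuted model
#' at correlation 1 — and their intercepts at correlation 0 are reported. A
#' sound model shows a Q2 intercept below 0: random labelings have no
#' predictive ability.
#'
#' @param x A fitted [opls_da] model, or a samples x variables matrix.
#' @param labels Class labels (matrix interface only).
#' @param n_pred,n_orth Component counts (matrix interface; defaults
#'   classes - 1 and 0).
#' @param n_perm Number of permutations (default 200).
#' @param n_folds CV folds for each Q2 (default 7).
#' @param seed Seed for permutations and fold splits.
#' @param scale Scaling mode.
#' @param ... Passed between methods.
#' @return An object of class `permutation_result`: data.frame `stats` with
#'   columns `correlation`, `r2y`, `q2` (first row = unpermuted model),
#'   `r2_intercept`, `q2_intercept`, `n_perm`.
#' @export
permutation_test <- function(x, ...) UseMethod("permutation_test")

#' @rdname permutation_test
#' @export
permutation_test.opls_da <- function(x, n_perm = 200, seed = x$seed, ...) {
  permutation_test.default(x$x, x$y, n_pred = x$n_pred, n_orth = x$n_orth,
                           n_perm = n_perm, n_folds = x$cv_folds,
                           seed = seed, scale = x$scaling$mode, ...)
}

#' @rdname permutation_test
#' @export
permutation_test.default <- function(x, labels, n_pred = NULL, n_orth = 0,
                                     n_perm = 200, n_folds = 7, seed = 1L,
                                     scale = c("uv", "pareto", "none"), ...) {
  scale <- match.arg(scale)
  if (n_perm < 2) stop("invalid parameter: n_perm must be >= 2")
  x <- as.matrix(x)
  labels <- droplevels(as.factor(labels))
  if (is.null(n_pred)) n_pred <- max(1L, nlevels(labels) - 1L)
  sc <- autoscale(x, scale)
  Y0 <- one_hot(labels)

  fit0 <- opls_engine(sc$values, Y0, n_pred, n_orth)
  q20 <- cross_validate_q2(x, labels, n_pred, n_orth, n_folds, seed, scale)

  set.seed(as.integer(seed))
  perms <- replicate(n_perm, sample.int(length(labels)), simplify = FALSE)
  rcor <- r2y <- q2 <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    lb <- labels[perms[[b]]]
    Yb <- one_hot(lb)
    rcor[b] <- mean(abs(diag(stats::cor(Y0, Yb))))
    r2y[b] <- opls_engine(sc$values, Yb, n_pred, n_orth)$r2y
    q2[b] <- cross_validate_q2(x, lb, n_pred, n_orth, n_folds,
                               seed = (seed + b) %% .Machine$integer.max,
                               scale)
  }
  stats_df <- data.frame(correlation = c(1, rcor),
                         r2y = c(fit0$r2y, r2y),
                         q2 = c(q20, q2))
  r2_int <- unname(stats::coef(stats::lm(r2y ~ correlation, stats_df))[1])
  q2_int <- unname(stats::coef(stats::lm(q2 ~ correlation, stats_df))[1])
  structure(list(stats = stats_df, r2_intercept = r2_int,
                 q2_intercept = q2_int, n_perm = n_perm),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation test (%d permutations)\n", x$n_perm))
  cat(sprintf("  original model: R2Y = %.3f, Q2 = %.3f\n",
              x$stats$r2y[1], x$stats$q2[1]))
  cat(sprintf("  intercepts at zero label correlation: R2 = %.3f, Q2 = %.3f\n",
              x$r2_intercept, x$q2_intercept))
  invisible(x)
}

#' @export
plot.permutation_result <- function(x, ...) {
  s <- x$stats
  graphics::plot(s$correlation, s$r2y, pch = 1, col = "darkgreen",
                 ylim = range(c(s$r2y, s$q2)),
                 xlab = "|correlation with original labels|",
                 ylab = expression(R^2 * "Y and " * Q^2),
                 main = "Permutation validation", ...)
  graphics::points(s$correlation, s$q2, pch = 2, col = "steelblue")
  graphics::abline(stats::lm(r2y ~ correlation, s), col = "darkgreen", lty = 2)
  graphics::abline(stats::lm(q2 ~ correlation, s), col = "steelblue", lty = 2)
  graphics::legend("bottomright", c(expression(R^2 * "Y"), expression(Q^2)),
                   pch = c(1, 2), col = c("darkgreen", "steelblue"), bty = "n")
  invisible(x)
}
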