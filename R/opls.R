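#' Orthogonal partial least squares discriminant analysis
#'
#' Fits an OPLS-DA model for producing-area (or any multi-class)
#' discrimination: the class membership is one-hot encoded and centered,
#' `n_orth` components of predictor variation orthogonal to class are
#' stripped from X (orthogonal signal correction), and `n_pred` predictive
#' components are then extracted by NIPALS partial least squares. With
#' `n_orth = 0` the model reduces exactly to plain PLS-DA.
#'
#' Model quality is summarized by R2X (fraction of scaled-X variance captured
#' by the predictive components), R2Y (fraction of class-matrix variance
#' explained in fit) and Q2 (cross-validated predictive fraction, see
#' [cross_validate_q2()]). Class prediction uses the nearest class centroid
#' in predictive-score space.
#'
#' @param x Samples x variables numeric matrix, or a formula.
#' @param y Class labels (factor or coercible), one per row of `x`.
#' @param n_pred Number of predictive components; default
#'   `nlevels(y) - 1`.
#' @param n_orth Number of orthogonal components. `NULL` (default) selects
#'   automatically: orthogonal components are added while cross-validated Q2
#'   improves by more than 0.01, up to `max_orth`.
#' @param scale Scaling mode passed to [autoscale()] (default unit variance).
#' @param cv_folds Folds for the Q2 cross-validation (default 7, stratified).
#' @param seed Seed for the cross-validation split.
#' @param max_orth Cap on automatically selected orthogonal components.
#' @param data,... For the formula method: a data.frame with the response and
#'   predictor columns; further arguments passed on.
#' @return An object of class `opls_da` with components `scores`, `loadings`,
#'   `weights`, `y_loadings`, `orth_scores`, `orth_loadings`, `orth_weights`,
#'   `r2x`, `r2x_orth`, `r2y`, `q2`, `vip`, `centroids`, `class_levels`,
#'   `scaling`, `n_pred`, `n_orth`.
#' @seealso [vip()], [cross_validate_q2()], [permutation_test()]
#' @examples
#' set.seed(1)
#' study <- generate_study(study_design(seed = 3), level = "winery")
#' fit <- opls_da(study$concentrations, study$group, n_orth = 1)
#' fit
#' head(sort(vip(fit), decreasing = TRUE))
#' @export
opls_da <- function(x, ...) UseMethod("opls_da")

#' @rdname opls_da
#' @export
opls_da.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  X <- as.matrix(mf[, -1, drop = FALSE])
  out <- opls_da.default(X, y, ...)
  out$call <- match.call()
  out
}

#' @rdname opls_da
#' @export
opls_da.default <- function(x, y, n_pred = NULL, n_orth = NULL,
                            scale = c("uv", "pareto", "none"),
                            cv_folds = 7, seed = 1L, max_orth = 5L, ...) {
  scale <- match.arg(scale)
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nrow(x) != length(y)) stop("x rows and y labels differ in length")
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  if (any(table(y) < 2L)) {
    stop("insufficient class: every class needs at least 2 samples")
  }
  if (is.null(n_pred)) n_pred <- max(1L, nlevels(y) - 1L)

  sc <- autoscale(x, scale)
  Y <- one_hot(y)

  if (is.null(n_orth)) {
    q2_prev <- cross_validate_q2(x, y, n_pred = n_pred, n_orth = 0,
                                 n_folds = cv_folds, seed = seed,
                                 scale = scale)
    n_orth <- 0L
    while (n_orth < max_orth &&
           n_pred + n_orth + 1L < min(nrow(x) - 1L, ncol(sc$values))) {
      q2_try <- cross_validate_q2(x, y, n_pred = n_pred,
                                  n_orth = n_orth + 1L,
                                  n_folds = cv_folds, seed = seed,
                                  scale = scale)
      if (q2_try - q2_prev > 0.01) {
        n_orth <- n_orth + 1L; q2_prev <- q2_try
      } else break
    }
    q2 <- q2_prev
  } else {
    q2 <- cross_validate_q2(x, y, n_pred = n_pred, n_orth = n_orth,
                            n_folds = cv_folds, seed = seed, scale = scale)
  }

  fit <- opls_engine(sc$values, Y, n_pred, n_orth)
  rownames(fit$W) <- rownames(fit$P) <- colnames(sc$values)
  if (ncol(fit$W_o)) rownames(fit$W_o) <- rownames(fit$P_o) <- colnames(sc$values)
  dimnames(fit$T) <- list(rownames(x), paste0("p", seq_len(fit$n_pred)))
  rownames(fit$Q) <- levels(y)
  centroids <- rowsum(fit$T, y) / as.vector(table(y))

  structure(list(scores = fit$T, loadings = fit$P, weights = fit$W,
                 y_loadings = fit$Q,
                 orth_scores = fit$T_o, orth_loadings = fit$P_o,
                 orth_weights = fit$W_o,
                 n_pred = fit$n_pred, n_orth = fit$n_orth,
                 r2x = fit$r2x, r2x_comp = fit$r2x_comp,
                 r2x_orth = fit$r2x_orth, r2x_orth_comp = fit$r2x_orth_comp,
                 r2y = fit$r2y, q2 = q2,
                 vip = engine_vip(fit),
                 centroids = centroids,
                 class_levels = levels(y),
                 y = y, y_means = attr(Y, "means"),
                 Yhat = fit$Yhat,
                 scaling = sc, x = x,
                 cv_folds = cv_folds, seed = seed,
                 call = match.call()),
            class = "opls_da")
}

#' @export
print.opls_da <- function(x, ...) {
  cat(sprintf("OPLS-DA: %d predictive + %d orthogonal component(s), %d classes\n",
              x$n_pred, x$n_orth, length(x$class_levels)))
  cat(sprintf("  R2X = %.3f  R2Y = %.3f  Q2 = %.3f\n", x$r2x, x$r2y, x$q2))
  invisible(x)
}

#' @export
summary.opls_da <- function(object, ...) {
  acc <- mean(predict(object) == object$y)
  comp <- data.frame(component = c(paste0("predictive ", seq_len(object$n_pred)),
                                   if (object$n_orth)
                                     paste0("orthogonal ", seq_len(object$n_orth))),
                     r2x = c(object$r2x_comp, object$r2x_orth_comp))
  out <- list(model = object, components = comp, train_accuracy = acc)
  class(out) <- "summary.opls_da"
  out
}

#' @export
print.summary.opls_da <- function(x, ...) {
  print(x$model)
  cat(sprintf("  training accuracy (nearest centroid): %.1f%%\n",
              100 * x$train_accuracy))
  cat("  variance captured per component:\n")
  print(x$components, row.names = FALSE, digits = 3)
  tv <- sort(x$model$vip, decreasing = TRUE)
  cat("  top VIP:", paste(sprintf("%s (%.2f)", names(tv)[1:min(5, length(tv))],
                                  tv[1:min(5, length(tv))]), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
coef.opls_da <- function(object, ...) {
  # regression coefficients on the scaled X: B = W (P'W)^-1 Q'
  Wstar <- object$weights %*%
    solve(crossprod(object$loadings, object$weights))
  B <- Wstar %*% t(object$y_loadings)
  dimnames(B) <- list(rownames(object$weights), object$class_levels)
  B
}

#' Predict classes or scores from an OPLS-DA model
#'
#' @param object A fitted [opls_da] model.
#' @param newdata Samples x variables matrix; defaults to the training data.
#' @param type `"class"` (nearest centroid in predictive-score space),
#'   `"scores"`, or `"response"` (one-hot scale class predictions).
#' @param ... Unused.
#' @return A factor, a score matrix, or a numeric response matrix.
#' @export
predict.opls_da <- function(object, newdata = NULL,
                            type = c("class", "scores", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$x
  Xs <- apply_scaling(newdata, object$scaling)
  fit <- list(W = object$weights, P = object$loadings, Q = object$y_loadings,
              W_o = object$orth_weights, P_o = object$orth_loadings,
              n_pred = object$n_pred, n_orth = object$n_orth)
  pr <- opls_project(fit, Xs)
  if (type == "scores") {
    colnames(pr$scores) <- paste0("p", seq_len(object$n_pred))
    rownames(pr$scores) <- rownames(newdata)
    return(pr$scores)
  }
  if (type == "response") {
    Yhat <- sweep(pr$Yhat, 2, object$y_means, "+")
    dimnames(Yhat) <- list(rownames(newdata), object$class_levels)
    return(Yhat)
  }
  d2 <- outer(rowSums(pr$scores^2), rowSums(object$centroids^2), "+") -
    2 * pr$scores %*% t(object$centroids)
  factor(object$class_levels[max.col(-d2)], levels = object$class_levels)
}

#' @export
fitted.opls_da <- function(object, ...) {
  sweep(object$Yhat, 2, object$y_means, "+")
}

#' @export
residuals.opls_da <- function(object, ...) {
  Y <- one_hot(object$y, center = FALSE)
  attr(Y, "means") <- NULL
  Y - fitted(object)
}

#' @export
plot.opls_da <- function(x, components = c(1, 2), ...) {
  s <- x$scores
  if (x$n_pred == 1L) {
    if (x$n_orth >= 1L) {
      s <- cbind(s, x$orth_scores[, 1])
      labs <- c("predictive score 1", "orthogonal score 1")
    } else {
      s <- cbind(s, seq_len(nrow(s)))
      labs <- c("predictive score 1", "sample index")
    }
  } else {
    s <- s[, components, drop = FALSE]
    labs <- paste("predictive score", components)
  }
  cls <- as.integer(x$y)
  graphics::plot(s[, 1], s[, 2], col = cls, pch = cls,
                 xlab = labs[1], ylab = labs[2],
                 main = sprintf("OPLS-DA scores (R2X %.2f, R2Y %.2f, Q2 %.2f)",
                                x$r2x, x$r2y, x$q2), ...)
  graphics::legend("topright", legend = x$class_levels,
                   col = seq_along(x$class_levels),
                   pch = seq_along(x$class_levels), bty = "n")
  invisible(x)
}

#' Variable importance in projection
#'
#' VIP_j = sqrt( p * sum_a SSY_a (w_ja / ||w_a||)^2 / sum_a SSY_a ) over the
#' predictive components, where SSY_a is the class-matrix variance captured
#' by component a and p the number of variables. The squared VIPs average to
#' 1, so VIP > 1 flags variables contributing more than average to the
#' discrimination.
#'
#' @param object A fitted [opls_da] model.
#' @param ... Unused.
#' @return Named numeric vector of VIP scores.
#' @export
vip <- function(object, ...) UseMethod("vip")

#' @rdname vip
#' @export
vip.opls_da <- function(object, ...) object$vip
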