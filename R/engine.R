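# Core numerical machinery: NIPALS PLS2 and the orthogonal-filter (OPLS)
# decomposition. Everything here works on an already-scaled X and a centered
# one-hot Y; the user-facing wrapper lives in opls.R.

# One NIPALS component. Returns normalized weight w, score t, X-loading p,
# Y-loading q. Converges on the score vector; when the iteration stalls
# (near-tied dominant directions of X'YY'X, typical of permuted labels) the
# exact fixed point — the leading left singular vector of X'Y — finishes it.
nipals_component <- function(X, Y, tol = 1e-9, maxit = 200L) {
  u <- Y[, which.max(colSums(Y^2))]
  t_old <- rep(Inf, nrow(X))
  converged <- FALSE
  for (it in seq_len(maxit)) {
    w <- crossprod(X, u)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) stop("degenerate component: X'u vanished")
    w <- w / nw
    tt <- X %*% w
    q <- crossprod(Y, tt) / sum(tt^2)
    u <- Y %*% q / sum(q^2)
    if (sqrt(sum((tt - t_old)^2)) <= tol * sqrt(sum(tt^2))) {
      converged <- TRUE
      break
    }
    t_old <- tt
  }
  if (!converged) {
    sv <- svd(crossprod(X, Y), nu = 1, nv = 0)
    if (sv$d[1] < 1e-14) stop("degenerate component: X'Y vanished")
    w <- sv$u[, 1, drop = FALSE]
    tt <- X %*% w
    q <- crossprod(Y, tt) / sum(tt^2)
    it <- maxit
  }
  p <- crossprod(X, tt) / sum(tt^2)
  list(w = w, t = tt, p = p, q = q, iterations = it)
}

# OPLS decomposition: strips n_orth Y-orthogonal components from X (the
# orthogonal-signal-correction step), then fits n_pred predictive NIPALS
# components on the filtered matrix. X scaled, Y centered one-hot.
opls_engine <- function(X, Y, n_pred, n_orth, tol = 1e-9, maxit = 200L) {
  stopifnot(n_pred >= 1L, n_orth >= 0L)
  if (n_pred + n_orth >= min(nrow(X) - 1L, ncol(X))) {
    stop("n_pred + n_orth must be < min(samples - 1, variables)")
  }
  ssx <- sum(X^2); ssy <- sum(Y^2)
  p <- ncol(X)
  Wo <- Po <- matrix(0, p, 0); To <- matrix(0, nrow(X), 0)
  Xk <- X
  for (j in seq_len(n_orth)) {
    comp <- nipals_component(Xk, Y, tol, maxit)
    Z <- crossprod(Xk, Y)
    qrz <- qr(Z)
    Wy <- qr.Q(qrz)[, seq_len(qrz$rank), drop = FALSE]
    wo <- comp$p - Wy %*% crossprod(Wy, comp$p)
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) break  # no Y-orthogonal structure left
    wo <- wo / nwo
    to <- Xk %*% wo
    po <- crossprod(Xk, to) / sum(to^2)
    Xk <- Xk - tcrossprod(to, po)
    Wo <- cbind(Wo, wo); Po <- cbind(Po, po); To <- cbind(To, to)
  }
  W <- P <- matrix(0, p, 0); Tm <- matrix(0, nrow(X), 0)
  Q <- matrix(0, ncol(Y), 0)
  Yk <- Y
  for (a in seq_len(n_pred)) {
    if (sum(Yk^2) < 1e-12 * max(ssy, 1)) break  # Y fully explained
    comp <- nipals_component(Xk, Yk, tol, maxit)
    Xk <- Xk - tcrossprod(comp$t, comp$p)
    Yk <- Yk - tcrossprod(comp$t, comp$q)
    W <- cbind(W, comp$w); P <- cbind(P, comp$p)
    Tm <- cbind(Tm, comp$t); Q <- cbind(Q, comp$q)
  }
  if (ncol(Tm) == 0L) stop("no predictive component could be extracted")
  r2x_comp <- colSums(Tm^2) * colSums(P^2) / ssx
  r2x_orth <- if (ncol(To)) colSums(To^2) * colSums(Po^2) / ssx else numeric(0)
  Yhat <- tcrossprod(Tm, Q)  # T Q'
  r2y <- 1 - sum((Y - Yhat)^2) / ssy
  ssy_comp <- colSums(Tm^2) * colSums(Q^2)
  list(W = W, P = P, T = Tm, Q = Q,
       W_o = Wo, P_o = Po, T_o = To,
       n_pred = ncol(Tm), n_orth = ncol(To),
       r2x = sum(r2x_comp), r2x_comp = r2x_comp,
       r2x_orth = sum(r2x_orth), r2x_orth_comp = r2x_orth,
       r2y = r2y, ssy_comp = ssy_comp,
       ssx = ssx, ssy = ssy, Yhat = Yhat)
}

# project new (already scaled) rows through a fitted engine: strip orthogonal
# components, then compute predictive scores and Y predictions
opls_project <- function(fit, Xnew) {
  Xk <- Xnew
  for (j in seq_len(fit$n_orth)) {
    to <- Xk %*% fit$W_o[, j, drop = FALSE]
    Xk <- Xk - tcrossprod(to, fit$P_o[, j, drop = FALSE])
  }
  Tm <- matrix(0, nrow(Xk), fit$n_pred)
  for (a in seq_len(fit$n_pred)) {
    Tm[, a] <- Xk %*% fit$W[, a, drop = FALSE]
    Xk <- Xk - tcrossprod(Tm[, a, drop = FALSE], fit$P[, a, drop = FALSE])
  }
  list(scores = Tm, Yhat = tcrossprod(Tm, fit$Q))
}

# VIP over predictive components: weight-based importance whose squares
# average to 1. SSY_a is the Y sum of squares captured by component a.
engine_vip <- function(fit) {
  p <- nrow(fit$W)
  ssy <- fit$ssy_comp
  w2 <- sweep(fit$W^2, 2, colSums(fit$W^2), "/")
  v <- sqrt(p * as.vector(w2 %*% ssy) / sum(ssy))
  names(v) <- rownames(fit$W)
  v
}

# stratified fold assignment; canonical within-class order comes from row
# ids when available so the split is invariant to row permutation
stratified_folds <- function(labels, n_folds, seed, ids = NULL) {
  if (n_folds < 2L) stop("n_folds must be >= 2")
  labels <- as.factor(labels)
  n <- length(labels)
  fold <- integer(n)
  set.seed(as.integer(seed))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (!is.null(ids)) idx <- idx[order(ids[idx])]
    v <- rep_len(sample.int(n_folds), length(idx))
    fold[idx] <- v[sample.int(length(v))]
  }
  fold
}
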