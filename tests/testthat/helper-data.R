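# small data builders shared across test files

# two well-separated classes with a handful of noise variables
make_two_class <- function(n = 40, p_noise = 8, delta = 1.5, seed = 42) {
  set.seed(seed)
  y <- factor(rep(c("A", "B"), each = n / 2))
  X <- matrix(rnorm(n * (p_noise + 2)), n, p_noise + 2)
  X[, 1] <- X[, 1] + ifelse(y == "A", delta, -delta)
  X[, 2] <- X[, 2] + ifelse(y == "A", delta / 2, -delta / 2)
  colnames(X) <- paste0("v", seq_len(ncol(X)))
  rownames(X) <- paste0("s", seq_len(n))
  list(X = X, y = y)
}

# class indicator in one column, pure noise elsewhere
make_single_informative <- function(n = 40, p_noise = 9, seed = 7) {
  set.seed(seed)
  y <- factor(rep(c("A", "B"), each = n / 2))
  X <- cbind(ind = as.numeric(y == "A"),
             matrix(rnorm(n * p_noise), n, p_noise))
  colnames(X) <- c("ind", paste0("n", seq_len(p_noise)))
  rownames(X) <- paste0("s", seq_len(n))
  list(X = X, y = y)
}

# minimal independent PLS2 (NIPALS with X and Y deflation), used as the
# reference implementation the OPLS reduction is checked against
reference_pls <- function(X, y, ncomp) {
  Y <- stats::model.matrix(~ 0 + y)
  Y <- sweep(Y, 2, colMeans(Y), "-")
  Xs <- scale(X)
  Xk <- Xs; Yk <- Y
  Tm <- NULL; Qm <- NULL
  for (a in seq_len(ncomp)) {
    u <- Yk[, which.max(colSums(Yk^2))]
    for (it in 1:5000) {
      w <- drop(crossprod(Xk, u)); w <- w / sqrt(sum(w^2))
      tt <- drop(Xk %*% w)
      q <- drop(crossprod(Yk, tt)) / sum(tt^2)
      u_new <- drop(Yk %*% q) / sum(q^2)
      if (sum((u_new - u)^2) < 1e-24 * sum(u_new^2)) { u <- u_new; break }
      u <- u_new
    }
    p <- drop(crossprod(Xk, tt)) / sum(tt^2)
    Xk <- Xk - outer(tt, p)
    Yk <- Yk - outer(tt, q)
    Tm <- cbind(Tm, tt); Qm <- cbind(Qm, q)
  }
  list(scores = Tm, Yhat = Tm %*% t(Qm))
}

# hand computation of a Tukey HSD significance matrix (equal group sizes)
# from the studentized range distribution
tukey_oracle_sig <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  k <- nlevels(groups); n <- table(groups)[1]
  means <- tapply(values, groups, mean)
  df <- length(values) - k
  s2 <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2))) / df
  crit <- qtukey(1 - alpha, k, df) * sqrt(s2 / n)
  outer(means, means, function(a, b) abs(a - b)) > crit
}
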