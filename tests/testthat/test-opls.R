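test_that("unit-variance scaling centers and scales, and is idempotent", {
  set.seed(2)
  X <- matrix(rnorm(60, mean = 5, sd = 3), 12, 5)
  sc <- autoscale(X, "uv")
  expect_equal(unname(colMeans(sc$values)), rep(0, 5), tolerance = 1e-9)
  expect_equal(unname(apply(sc$values, 2, sd)), rep(1, 5), tolerance = 1e-9)
  sc2 <- autoscale(sc, "uv")
  expect_equal(sc2$values, sc$values, tolerance = 1e-12)
  # pareto divides by sqrt(sd)
  scp <- autoscale(X, "pareto")
  expect_equal(unname(apply(scp$values, 2, sd)),
               unname(sqrt(apply(X, 2, sd))), tolerance = 1e-9)
  # none is the identity
  scn <- autoscale(X, "none")
  expect_equal(scn$values, X)
  # constant columns drop with a warning; all-constant errors
  Xc <- cbind(X, k = 7)
  expect_warning(scc <- autoscale(Xc, "uv"), "constant")
  expect_equal(ncol(scc$values), 5)
  expect_error(suppressWarnings(autoscale(matrix(1, 5, 3))), "degenerate")
})

test_that("score blocks are orthogonal and X variance is fully booked", {
  st <- generate_study(study_design(seed = 21), level = "winery")
  fit <- opls_da(log(st$concentrations), st$group, n_orth = 2)
  S <- cbind(fit$scores, fit$orth_scores)
  G <- crossprod(S)
  nrm <- sqrt(diag(G))
  off <- abs(G / outer(nrm, nrm))
  diag(off) <- 0
  expect_lt(max(off), 1e-8)
  # r2x(pred) + r2x(orth) + residual fraction = 1
  Xs <- fit$scaling$values
  resid <- Xs - tcrossprod(fit$scores, fit$loadings) -
    tcrossprod(fit$orth_scores, fit$orth_loadings)
  expect_equal(fit$r2x + fit$r2x_orth + sum(resid^2) / sum(Xs^2), 1,
               tolerance = 1e-6)
  expect_true(fit$r2x >= 0 && fit$r2x <= 1)
  expect_true(fit$r2y >= 0 && fit$r2y <= 1)
})

test_that("with no orthogonal components the model is plain PLS-DA", {
  d <- make_two_class()
  f <- opls_da(d$X, d$y, n_pred = 2, n_orth = 0)
  ref <- reference_pls(d$X, d$y, ncomp = 2)
  expect_equal(unname(f$Yhat), unname(ref$Yhat), tolerance = 1e-8)
  # independent library cross-check: scores span the same directions
  m <- mixOmics::plsda(d$X, d$y, ncomp = 2, scale = TRUE)
  expect_equal(unname(abs(diag(cor(f$scores, m$variates$X)))), c(1, 1),
               tolerance = 1e-6)
})

test_that("a single informative variable dominates weights and VIP", {
  d <- make_single_informative()
  f <- opls_da(d$X, d$y, n_pred = 1, n_orth = 0)
  expect_equal(rownames(f$weights)[which.max(abs(f$weights[, 1]))], "ind")
  v <- vip(f)
  expect_equal(names(which.max(v)), "ind")
  expect_gt(v["ind"], 1)
  expect_lt(median(v[names(v) != "ind"]), 1)
  expect_equal(mean(predict(f) == d$y), 1)  # training accuracy 100%
})

test_that("VIP squares average to one on any fitted model", {
  for (s in 1:5) {
    st <- generate_study(study_design(seed = s, n_compounds = 40),
                         level = "winery")
    f <- opls_da(log(st$concentrations), st$group, n_orth = s %% 3)
    expect_equal(mean(vip(f)^2), 1, tolerance = 1e-9)
  }
})

test_that("the orthogonal filter rescues R2Y under strong Y-orthogonal structure", {
  set.seed(11)
  n <- 30
  y <- factor(rep(c("A", "B"), each = 15))
  x1 <- ifelse(y == "A", 1, -1) + rnorm(n, sd = 0.3)
  Z <- matrix(rnorm(n * 8, sd = 0.3), n, 8)
  s_orth <- rnorm(n)
  s_orth <- stats::residuals(stats::lm(s_orth ~ scale(as.numeric(y == "A"))))
  s_orth <- s_orth / stats::sd(s_orth)
  X <- cbind(x1, Z) + 3 * s_orth %*% t(rnorm(9))
  colnames(X) <- paste0("v", 1:9); rownames(X) <- paste0("s", 1:n)
  r2y_pls <- opls_da(X, y, n_pred = 1, n_orth = 0)$r2y
  r2y_opls <- opls_da(X, y, n_pred = 1, n_orth = 1)$r2y
  expect_gte(r2y_opls, r2y_pls)
})

test_that("model statistics are invariant to sample order", {
  st <- generate_study(study_design(seed = 31, n_compounds = 50),
                       level = "winery")
  X <- log(st$concentrations)
  f1 <- opls_da(X, st$group, n_orth = 1, seed = 9)
  set.seed(1)
  perm <- sample(nrow(X))
  f2 <- opls_da(X[perm, ], st$group[perm], n_orth = 1, seed = 9)
  expect_equal(f1$r2x, f2$r2x, tolerance = 1e-9)
  expect_equal(f1$r2y, f2$r2y, tolerance = 1e-9)
  expect_equal(f1$q2, f2$q2, tolerance = 1e-9)
  expect_equal(abs(f1$vip), abs(f2$vip), tolerance = 1e-9)
  expect_equal(abs(f1$scores[rownames(X), ]), abs(f2$scores[rownames(X), ]),
               tolerance = 1e-8)
})

test_that("degenerate inputs are rejected with clear errors", {
  d <- make_two_class(n = 12)
  y1 <- d$y; y1[2:12] <- "B"  # class A left with one sample
  expect_error(opls_da(d$X, droplevels(y1)), "insufficient class")
  sub <- c(1:4, 7:10)  # 4 of each class, 10 variables
  expect_error(opls_da(d$X[sub, ], d$y[sub], n_pred = 4, n_orth = 3),
               "must be <")
  expect_error(opls_da(d$X, factor(rep("A", nrow(d$X)))), "2 classes")
})

test_that("formula interface, coef, predict and residuals are consistent", {
  d <- make_two_class()
  df <- data.frame(region = d$y, d$X)
  f <- opls_da(region ~ ., data = df, n_pred = 2, n_orth = 0)
  fd <- opls_da(d$X, d$y, n_pred = 2, n_orth = 0)
  expect_equal(f$r2y, fd$r2y, tolerance = 1e-10)
  # coefficients reproduce fitted responses: Yhat = Xs B + means
  B <- coef(fd)
  Yhat <- sweep(fd$scaling$values %*% B, 2, fd$y_means, "+")
  expect_equal(unname(Yhat), unname(fitted(fd)), tolerance = 1e-8)
  expect_equal(unname(predict(fd, d$X, type = "response")),
               unname(fitted(fd)), tolerance = 1e-10)
  # residuals complement fitted values in the one-hot scale
  R <- residuals(fd)
  Y <- stats::model.matrix(~ 0 + d$y)
  expect_equal(unname(R + fitted(fd)), unname(Y), tolerance = 1e-10,
               ignore_attr = TRUE)
  s <- summary(fd)
  expect_gte(s$train_accuracy, 0.95)
})
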