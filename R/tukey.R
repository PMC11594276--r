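#' One-way ANOVA with Tukey HSD compact letter display
#'
#' Runs a one-way analysis of variance, all pairwise Tukey honestly-
#' significant-difference comparisons at level `alpha`, and summarizes the
#' pairwise pattern as a compact letter display: groups sharing a letter are
#' not significantly different. Letters are assigned by the insertion
#' algorithm with groups taken in descending mean order, the convention used
#' in composition tables.
#'
#' @param values Numeric measurements.
#' @param groups Group labels, one per value; every group needs >= 2 values.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `tukey_letters`: list with `f`, `p` (ANOVA),
#'   `comparisons` (TukeyHSD table), `means` (group means, descending),
#'   `letters` (named character vector aligned with `means`), `alpha`.
#' @examples
#' set.seed(1)
#' v <- c(rnorm(5, 0, 0.1), rnorm(5, 100, 0.1))
#' anova_tukey_letters(v, rep(c("a", "b"), each = 5))
#' @export
anova_tukey_letters <- function(values, groups, alpha = 0.05) {
  groups <- droplevels(as.factor(groups))
  stopifnot(length(values) == length(groups))
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) {
    stop("insufficient replication: every group needs >= 2 values")
  }
  fit <- stats::aov(values ~ groups)
  an <- stats::anova(fit)
  f <- an[["F value"]][1]; p <- an[["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups

  means <- sort(tapply(values, groups, mean), decreasing = TRUE)
  k <- length(means)
  # significance matrix in descending-mean order
  sig <- matrix(FALSE, k, k, dimnames = list(names(means), names(means)))
  pair <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(pair)) {
    a <- pair[[i]][1]; b <- pair[[i]][2]
    s <- tk[i, "p adj"] < alpha
    sig[a, b] <- sig[b, a] <- s
  }
  letters_vec <- insertion_letters(sig)
  structure(list(f = f, p = p, comparisons = tk, means = means,
                 letters = letters_vec, alpha = alpha),
            class = "tukey_letters")
}

# compact letter display by insert-and-absorb; `sig` is a symmetric logical
# matrix whose row/column order (descending means) fixes letter order
insertion_letters <- function(sig) {
  k <- nrow(sig)
  cols <- list(seq_len(k))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      if (!sig[i, j]) next
      nxt <- list()
      for (cl in cols) {
        if (i %in% cl && j %in% cl) {
          nxt <- c(nxt, list(setdiff(cl, i)), list(setdiff(cl, j)))
        } else nxt <- c(nxt, list(cl))
      }
      # absorb columns contained in another column
      nxt <- unique(lapply(nxt, sort))
      keep <- vapply(seq_along(nxt), function(a) {
        !any(vapply(seq_along(nxt), function(b) {
          b != a && length(nxt[[a]]) < length(nxt[[b]]) &&
            all(nxt[[a]] %in% nxt[[b]])
        }, logical(1)))
      }, logical(1))
      cols <- nxt[keep]
    }
  }
  # order columns by their highest-mean member, then assign letters
  cols <- cols[order(vapply(cols, min, 1L))]
  out <- character(k)
  for (ci in seq_along(cols)) {
    out[cols[[ci]]] <- paste0(out[cols[[ci]]], letters[ci])
  }
  stats::setNames(out, rownames(sig))
}

#' @export
print.tukey_letters <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F = %.3f, p = %.3g (alpha = %g)\n",
              x$f, x$p, x$alpha))
  df <- data.frame(mean = round(x$means, 4), letters = x$letters)
  print(df)
  invisible(x)
}
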