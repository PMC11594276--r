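#' Column-wise scaling for multivariate analysis
#'
#' Chemical variables are normalized before multivariate modelling. Unit
#' variance (`"uv"`) centers each column and divides by its standard
#' deviation; `"pareto"` divides by the square root of the standard deviation;
#' `"none"` only records the identity transform. Constant columns cannot be
#' scaled and are dropped with a warning.
#'
#' @param x Samples x variables numeric matrix (>= 2 rows).
#' @param mode One of `"uv"`, `"pareto"`, `"none"`.
#' @return An object of class `scaled_matrix`: list with `values`, `center`,
#'   `scale`, `mode` and `dropped` (names/indices of constant columns).
#' @export
autoscale <- function(x, mode = c("uv", "pareto", "none")) {
  mode <- match.arg(mode)
  if (inherits(x, "scaled_matrix")) x <- x$values
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 samples")
  sds <- apply(x, 2, stats::sd)
  dropped <- character(0)
  if (mode != "none") {
    const <- sds == 0 | is.na(sds)
    if (all(const)) stop("degenerate matrix: all columns constant")
    if (any(const)) {
      dropped <- if (!is.null(colnames(x))) colnames(x)[const] else which(const)
      warning("dropping ", sum(const), " constant column(s)")
      x <- x[, !const, drop = FALSE]
      sds <- sds[!const]
    }
  }
  center <- switch(mode,
                   uv = colMeans(x), pareto = colMeans(x),
                   none = rep(0, ncol(x)))
  scl <- switch(mode, uv = sds, pareto = sqrt(sds), none = rep(1, ncol(x)))
  vals <- sweep(sweep(x, 2, center, "-"), 2, scl, "/")
  structure(list(values = vals, center = center, scale = scl, mode = mode,
                 dropped = dropped),
            class = "scaled_matrix")
}

#' @export
print.scaled_matrix <- function(x, ...) {
  cat(sprintf("scaled matrix (%s): %d x %d%s\n", x$mode, nrow(x$values),
              ncol(x$values),
              if (length(x$dropped)) paste0(", ", length(x$dropped),
                                            " constant column(s) dropped")
              else ""))
  invisible(x)
}

# apply a stored scaling to new data (columns matched by name when available)
apply_scaling <- function(newdata, sc) {
  newdata <- as.matrix(newdata)
  want <- names(sc$center)
  if (!is.null(want) && !is.null(colnames(newdata))) {
    miss <- setdiff(want, colnames(newdata))
    if (length(miss)) stop("newdata lacks columns: ", paste(miss, collapse = ", "))
    newdata <- newdata[, want, drop = FALSE]
  }
  sweep(sweep(newdata, 2, sc$center, "-"), 2, sc$scale, "/")
}

# centered one-hot class matrix; keeps factor level order
one_hot <- function(labels, center = TRUE) {
  labels <- as.factor(labels)
  Y <- stats::model.matrix(~ 0 + labels)
  colnames(Y) <- levels(labels)
  attr(Y, "assign") <- NULL; attr(Y, "contrasts") <- NULL
  m <- colMeans(Y)
  if (center) Y <- sweep(Y, 2, m, "-")
  attr(Y, "means") <- m
  Y
}
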