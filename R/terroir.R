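#' Aggregate station meteorology to region x phenology-stage covariates
#'
#' Each producing area is summarized by the three meteorological stations
#' closest to its sampling points: the regional value is the arithmetic mean
#' over its stations, and the two-month phenology stages (flowering =
#' May-June, coloring = July-August) average their months. Stages follow the
#' local grape calendar: germination (April), flowering (May-June), coloring
#' (July-August), maturation (September).
#'
#' @param station_records Long data.frame with columns `station`, `month`
#'   (integer 4-9), `variable`, `value`.
#' @param station_assignment Data.frame with columns `region`, `station`;
#'   exactly 3 stations per region.
#' @return Data.frame with columns `variable`, `stage` and one column per
#'   region (the layout of the packaged `meteorology` fixture).
#' @export
aggregate_meteo <- function(station_records, station_assignment) {
  need <- c("station", "month", "variable", "value")
  if (!all(need %in% names(station_records))) {
    stop("station_records needs columns: ", paste(need, collapse = ", "))
  }
  if (!all(c("region", "station") %in% names(station_assignment))) {
    stop("station_assignment needs columns region, station")
  }
  nst <- table(station_assignment$region)
  if (any(nst != 3L)) {
    stop("each region must be assigned exactly 3 stations")
  }
  stages <- list(germination = 4L, flowering = 5:6, coloring = 7:8,
                 maturation = 9L)
  regions <- unique(station_assignment$region)
  variables <- unique(station_records$variable)
  # completeness: every station x variable needs all months Apr-Sept
  for (st in unique(station_assignment$station)) {
    for (v in variables) {
      mo <- station_records$month[station_records$station == st &
                                    station_records$variable == v]
      if (!all(4:9 %in% mo)) {
        stop("incomplete record: station ", st, ", variable ", v,
             " missing a month in Apr-Sept")
      }
    }
  }
  grid <- expand.grid(stage = names(stages), variable = variables,
                      stringsAsFactors = FALSE)
  out <- data.frame(variable = grid$variable, stage = grid$stage,
                    stringsAsFactors = FALSE)
  for (r in regions) {
    sts <- station_assignment$station[station_assignment$region == r]
    out[[r]] <- mapply(function(stg, v) {
      sel <- station_records$station %in% sts &
        station_records$month %in% stages[[stg]] &
        station_records$variable == v
      mean(station_records$value[sel])
    }, grid$stage, grid$variable)
  }
  out[order(match(out$variable, variables)), , drop = FALSE]
}

#' Per-region physicochemical summaries
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of each
#' numeric variable by region, reported to 2 decimals — the "Average" rows of
#' a per-winery composition table.
#'
#' @param records Data.frame with a `region` column and numeric measurement
#'   columns; rows are wineries.
#' @param by Grouping column name (default `"region"`).
#' @param digits Rounding for the report (default 2).
#' @return Long data.frame with columns `region`, `variable`, `mean`, `sd`,
#'   `n`. Regions with a single record get sd 0 and are flagged in the
#'   `single_record` column.
#' @examples
#' tab <- load_fixture("wine_physchem")
#' physchem_summary(tab[!tab$is_average,
#'                      c("region", "titratable_acid_gL", "pH")])
#' @export
physchem_summary <- function(records, by = "region", digits = 2) {
  if (!by %in% names(records)) stop("missing grouping column: ", by)
  g <- factor(records[[by]], levels = unique(records[[by]]))
  if (any(table(g) < 1L)) stop("empty region")
  numcols <- names(records)[vapply(records, is.numeric, logical(1))]
  if (!length(numcols)) stop("no numeric variables to summarize")
  out <- expand.grid(region = levels(g), variable = numcols,
                     stringsAsFactors = FALSE)
  out$mean <- NA_real_; out$sd <- NA_real_; out$n <- NA_integer_
  for (i in seq_len(nrow(out))) {
    v <- records[[out$variable[i]]][g == out$region[i]]
    out$mean[i] <- round(mean(v), digits)
    out$sd[i] <- if (length(v) > 1L) round(stats::sd(v), digits) else 0
    out$n[i] <- length(v)
  }
  out$single_record <- out$n == 1L
  out
}

#' Pearson correlation of compounds with climate and geography covariates
#'
#' Pairwise Pearson r between each selected compound and each covariate, with
#' two-sided p-values from the t transform on n - 2 degrees of freedom and a
#' significance mask at `alpha`. Region-level covariates should be broadcast
#' to samples first (see [broadcast_regional()]); the effective sample size
#' used for each p-value is returned alongside.
#'
#' @param compound_values Samples x compounds numeric matrix.
#' @param covariates Samples x covariates numeric matrix (same row order).
#' @param alpha Significance level for the mask (default 0.05).
#' @param adjust P-value adjustment method passed to [stats::p.adjust()]
#'   (default `"none"`, matching single-level significance stars;
#'   `"BH"` available).
#' @return An object of class `correlation_result`: list with matrices `r`,
#'   `p`, `sig` (p < alpha), `n`, and the adjustment used. Zero-variance
#'   columns yield NA correlations (flagged, not zero).
#' @export
pearson_matrix <- function(compound_values, covariates, alpha = 0.05,
                           adjust = "none") {
  X <- as.matrix(compound_values); Z <- as.matrix(covariates)
  if (nrow(X) != nrow(Z)) stop("row counts differ")
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 paired samples")
  sdx <- apply(X, 2, stats::sd); sdz <- apply(Z, 2, stats::sd)
  r <- suppressWarnings(stats::cor(X, Z))
  r[sdx == 0, ] <- NA; r[, sdz == 0] <- NA
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[!is.na(r) & abs(r) >= 1] <- 0
  if (adjust != "none") {
    p[] <- stats::p.adjust(p, method = adjust)
  }
  structure(list(r = r, p = p, sig = !is.na(p) & p < alpha, n = n,
                 alpha = alpha, adjust = adjust),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("correlation: %d compounds x %d covariates, n = %d, %d significant at p < %g%s\n",
              nrow(x$r), ncol(x$r), x$n, sum(x$sig), x$alpha,
              if (x$adjust != "none") paste0(" (", x$adjust, "-adjusted)") else ""))
  invisible(x)
}

#' @rdname pearson_matrix
#' @param x A `correlation_result`.
#' @param ... Unused.
#' @export
as.data.frame.correlation_result <- function(x, ...) {
  idx <- expand.grid(compound = rownames(x$r), covariate = colnames(x$r),
                     stringsAsFactors = FALSE)
  data.frame(idx, r = as.vector(x$r), p = as.vector(x$p),
             significant = as.vector(x$sig))
}

#' Broadcast region-level covariates to samples
#'
#' @param covariates Data.frame or matrix of region-level covariates with
#'   region ids as row names.
#' @param region Vector of region ids, one per sample.
#' @return Matrix with one row per sample.
#' @export
broadcast_regional <- function(covariates, region) {
  covariates <- as.matrix(covariates)
  idx <- match(as.character(region), rownames(covariates))
  if (anyNA(idx)) {
    stop("regions without covariates: ",
         paste(unique(region[is.na(idx)]), collapse = ", "))
  }
  out <- covariates[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}
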