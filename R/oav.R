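#' Odor activity value
#'
#' OAV = c / t: the concentration of a volatile divided by its odor threshold.
#' Compounds with OAV > 1 are taken to contribute perceptibly to aroma. Values
#' are returned at full precision; reporting tables round to 2 decimals.
#'
#' @param concentration Concentration(s) in ug/L, >= 0. Zero (not detected)
#'   gives OAV 0.
#' @param threshold Odor threshold(s) in ug/L, > 0.
#' @return Numeric OAV, dimensionless.
#' @examples
#' compute_oav(365.31, 30)   # isoamyl acetate, HSP: 12.18 after rounding
#' compute_oav(196.33, 5)    # ethyl caprylate, HSP: 39.27 after rounding
#' @export
compute_oav <- function(concentration, threshold) {
  stopifnot(is.numeric(concentration), is.numeric(threshold))
  if (any(threshold <= 0)) stop("invalid threshold: must be > 0")
  if (any(concentration < 0)) stop("concentration must be >= 0")
  concentration / threshold
}

#' Build a group x compound OAV table
#'
#' @param concentrations Matrix of concentrations (ug/L), groups (or samples)
#'   in rows, compounds in columns; column names must appear in the catalog.
#' @param catalog Data.frame with columns `cas` (or the catalog key matching
#'   the matrix columns) and `threshold_ugL`.
#' @param id_col Name of the catalog column holding compound ids.
#' @return Matrix of OAVs with the same dimnames as `concentrations`.
#' @export
oav_table <- function(concentrations, catalog, id_col = "cas") {
  concentrations <- as.matrix(concentrations)
  ids <- colnames(concentrations)
  if (is.null(ids)) stop("concentration matrix must have compound column names")
  idx <- match(ids, catalog[[id_col]])
  if (anyNA(idx)) {
    stop("compounds missing from catalog: ",
         paste(ids[is.na(idx)], collapse = ", "))
  }
  t <- catalog$threshold_ugL[idx]
  if (any(is.na(t) | t <= 0)) stop("invalid threshold for some compounds")
  sweep(concentrations, 2, t, "/")
}

#' Aroma-activity filter
#'
#' Retains compounds whose maximum OAV across groups strictly exceeds the
#' cutoff. A compound active anywhere is kept for all groups, which is why
#' activity tables can contain sub-cutoff and 0.00 cells.
#'
#' @param oav Matrix of OAVs, groups in rows, compounds in columns.
#' @param cutoff Activity cutoff (default 1, strict inequality).
#' @return Character vector of active compound ids (column names), or column
#'   indices when the matrix is unnamed.
#' @export
filter_active <- function(oav, cutoff = 1) {
  oav <- as.matrix(oav)
  if (any(oav < 0, na.rm = TRUE)) stop("OAV values must be >= 0")
  mx <- apply(oav, 2, max, na.rm = TRUE)
  keep <- mx > cutoff
  if (!is.null(colnames(oav))) colnames(oav)[keep] else which(keep)
}

#' Aroma-series intensities
#'
#' Groups compounds with similar odor descriptors into aroma series (the
#' catalog's single `type` label per compound) and scores each series in each
#' group by the sum of its members' OAVs.
#'
#' @param oav Matrix of OAVs, groups in rows, compounds (ids as column names)
#'   in columns.
#' @param catalog Data.frame with the compound id column and a series label
#'   column.
#' @param id_col,series_col Catalog column names (defaults `cas`, `type`).
#' @param series_levels Optional character vector fixing the series reported;
#'   series with no detected member get intensity 0 in every group.
#' @return An object of class `aroma_profile`: list with `intensity` (groups x
#'   series matrix, groups in input order) and `membership` (named list of
#'   compound ids per series).
#' @export
aroma_series <- function(oav, catalog, id_col = "cas", series_col = "type",
                         series_levels = NULL) {
  oav <- as.matrix(oav)
  ids <- colnames(oav)
  idx <- match(ids, catalog[[id_col]])
  if (anyNA(idx)) {
    stop("catalog incomplete: compounds missing: ",
         paste(ids[is.na(idx)], collapse = ", "))
  }
  series <- catalog[[series_col]][idx]
  if (any(is.na(series) | !nzchar(series))) {
    stop("catalog incomplete: missing aroma-series label")
  }
  levels <- if (is.null(series_levels)) unique(series) else
    unique(c(series_levels, unique(series)))
  intensity <- vapply(levels, function(s) {
    rowSums(oav[, series == s, drop = FALSE])
  }, numeric(nrow(oav)))
  if (is.null(dim(intensity))) {
    intensity <- matrix(intensity, nrow = nrow(oav),
                        dimnames = list(rownames(oav), levels))
  } else {
    dimnames(intensity) <- list(rownames(oav), levels)
  }
  membership <- split(ids, factor(series, levels = levels))
  structure(list(intensity = intensity, membership = membership),
            class = "aroma_profile")
}

#' @export
print.aroma_profile <- function(x, digits = 2, ...) {
  cat("aroma profile:", ncol(x$intensity), "series x",
      nrow(x$intensity), "groups\n")
  print(round(x$intensity, digits))
  invisible(x)
}

#' Chemical-class composition of a detected-compound set
#'
#' @param catalog Data.frame with compound ids and a `chemical_class` column.
#' @param detected Character vector of detected compound ids (subset of the
#'   catalog).
#' @param id_col Catalog id column name.
#' @return Data.frame with `chemical_class`, `count` and `percent`
#'   (100 * count / total, rounded to 2 decimals), sorted by decreasing count.
#' @examples
#' cc <- data.frame(cas = sprintf("id%03d", 1:184),
#'                  chemical_class = rep(c("ester", "alcohol", "other"),
#'                                       c(99, 26, 59)))
#' class_composition(cc, cc$cas)  # esters: 53.80%
#' @export
class_composition <- function(catalog, detected, id_col = "cas") {
  if (length(detected) == 0L) stop("empty detected-compound set")
  idx <- match(detected, catalog[[id_col]])
  if (anyNA(idx)) {
    stop("detected ids not in catalog: ",
         paste(detected[is.na(idx)], collapse = ", "))
  }
  cls <- catalog$chemical_class[idx]
  tab <- sort(table(cls), decreasing = TRUE)
  data.frame(chemical_class = names(tab),
             count = as.integer(tab),
             percent = round(100 * as.integer(tab) / length(detected), 2),
             row.names = NULL, stringsAsFactors = FALSE)
}
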