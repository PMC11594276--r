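#' Construct a calibration curve object
#'
#' A linear internal-standard calibration: area ratio = slope * concentration
#' ratio + intercept, where both ratios are relative to the internal standard.
#'
#' @param compound_id Catalog identifier (CAS string) of the source compound.
#' @param slope,intercept Line coefficients (area ratio per concentration
#'   ratio, and area ratio).
#' @param r2 Coefficient of determination of the fit.
#' @param valid_range Length-2 numeric, observed concentration-ratio span.
#' @param chemical_class,carbon_count,name Optional source-compound metadata
#'   used for surrogate matching.
#' @return An object of class `calibration_curve`.
#' @export
new_calibration_curve <- function(compound_id, slope, intercept, r2,
                                  valid_range,
                                  chemical_class = NA_character_,
                                  carbon_count = NA_integer_,
                                  name = NA_character_) {
  stopifnot(is.numeric(slope), is.numeric(intercept),
            length(valid_range) == 2L, valid_range[1] < valid_range[2])
  if (!is.na(r2) && (r2 < 0 || r2 > 1)) stop("r2 must lie in [0, 1]")
  structure(list(compound_id = compound_id, slope = slope,
                 intercept = intercept, r2 = r2,
                 valid_range = as.numeric(valid_range),
                 chemical_class = chemical_class,
                 carbon_count = as.integer(carbon_count),
                 name = name),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration curve [%s%s]: y = %.6gx %s %.6g  (R2 = %s)\n",
              x$compound_id,
              if (is.na(x$name)) "" else paste0(", ", x$name),
              x$slope, if (x$intercept < 0) "-" else "+", abs(x$intercept),
              format(x$r2)))
  cat(sprintf("  valid concentration-ratio range: [%.4g, %.4g]\n",
              x$valid_range[1], x$valid_range[2]))
  invisible(x)
}

#' Fit an internal-standard calibration curve
#'
#' Ordinary least squares of area ratio on concentration ratio (unweighted),
#' as used when drawing standard curves from a 2^n dilution series of mixed
#' standards spiked with the internal standard.
#'
#' @param points A data.frame or 2-column matrix with concentration ratios in
#'   the first column and area ratios in the second (columns `conc_ratio`,
#'   `area_ratio` also recognized).
#' @param compound_id Optional identifier attached to the curve.
#' @return A [calibration_curve]. `r2` is 1 - SSres/SStot; when the response
#'   has zero variance `r2` is 0 and the curve is flagged non-invertible via a
#'   zero slope.
#' @examples
#' pts <- data.frame(conc_ratio = 2^(0:8), area_ratio = 2 * 2^(0:8))
#' fit_calibration(pts)  # slope 2, intercept 0, r2 = 1
#' @export
fit_calibration <- function(points, compound_id = NA_character_) {
  points <- as.data.frame(points)
  x <- if ("conc_ratio" %in% names(points)) points$conc_ratio else points[[1]]
  y <- if ("area_ratio" %in% names(points)) points$area_ratio else points[[2]]
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 calibration points")
  if (length(unique(x)) < 2L) {
    stop("degenerate design: all concentration ratios identical")
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  b <- unname(fit$coefficients[1]); a <- unname(fit$coefficients[2])
  sstot <- sum((y - mean(y))^2)
  ssres <- sum(fit$residuals^2)
  if (sstot == 0) a <- 0  # zero response variance: flat, non-invertible
  r2 <- if (sstot == 0) 0 else 1 - ssres / sstot
  new_calibration_curve(compound_id, slope = a, intercept = b,
                        r2 = max(0, min(1, r2)),
                        valid_range = range(x))
}

#' Invert a calibration curve to a concentration
#'
#' Maps a sample's analyte/internal-standard peak-area ratio back through the
#' linear curve and scales by the spiked internal-standard concentration:
#' c = ((area_ratio - intercept) / slope) * istd. Negative inversions are
#' clamped to 0 and flagged `below_range`; inversions outside the calibrated
#' concentration-ratio span are flagged `extrapolated`.
#'
#' @param area_ratio Numeric vector of area ratios.
#' @param curve A [calibration_curve].
#' @param istd An [internal_standard()] (default 324.4 ug/L).
#' @return Numeric vector of concentrations in ug/L with attributes
#'   `below_range` and `extrapolated` (logical vectors).
#' @examples
#' hexanol <- new_calibration_curve("111-27-3", 1.2458, -0.0375, 0.9643,
#'                                  valid_range = c(0.3, 5))
#' invert_calibration(1.2083, hexanol)  # 324.4 ug/L (concentration ratio 1)
#' @export
invert_calibration <- function(area_ratio, curve, istd = internal_standard()) {
  stopifnot(inherits(curve, "calibration_curve"), is.numeric(area_ratio))
  if (curve$slope == 0) stop("non-invertible curve: slope is 0")
  ratio <- (area_ratio - curve$intercept) / curve$slope
  below <- ratio < 0
  extrap <- !below & (ratio < curve$valid_range[1] | ratio > curve$valid_range[2])
  conc <- pmax(ratio, 0) * istd$concentration
  attr(conc, "below_range") <- below
  attr(conc, "extrapolated") <- extrap
  conc
}

#' Assign a surrogate calibration curve
#'
#' Compounds without their own standard are quantified on the curve of a
#' compound of the same chemical class with the closest carbon count. Ties in
#' |carbon difference| go to the smaller carbon count, then to the
#' lexicographically smaller CAS. A compound that has its own curve gets it
#' back.
#'
#' @param compound A list or one-row data.frame with fields `cas` (or
#'   `compound_id`), `chemical_class` and `carbon_count`.
#' @param curve_library Named list of [calibration_curve] objects carrying
#'   `chemical_class`/`carbon_count` metadata, e.g. [calibration_library()].
#' @param relax_class If `TRUE`, fall back to the nearest carbon count in the
#'   whole library when no same-class curve exists (default `FALSE`: error).
#' @return The `compound_id` of the selected curve.
#' @export
assign_surrogate_curve <- function(compound, curve_library,
                                   relax_class = FALSE) {
  if (length(curve_library) == 0L) stop("empty curve library")
  id <- if (!is.null(compound$cas)) compound$cas else compound$compound_id
  if (!is.null(id) && !is.na(id) && id %in%
      vapply(curve_library, `[[`, "", "compound_id")) {
    return(id)
  }
  cls <- vapply(curve_library, `[[`, "", "chemical_class")
  carb <- vapply(curve_library, function(c) as.integer(c$carbon_count), 1L)
  ids <- vapply(curve_library, `[[`, "", "compound_id")
  keep <- cls == compound$chemical_class & !is.na(cls)
  if (!any(keep)) {
    if (!relax_class) {
      stop("no surrogate: no calibration curve of class '",
           compound$chemical_class, "'")
    }
    keep <- rep(TRUE, length(ids))
  }
  d <- abs(carb[keep] - compound$carbon_count)
  ord <- order(d, carb[keep], ids[keep])
  unname(ids[keep][ord[1]])
}

#' Temperature-programmed retention index
#'
#' Linear retention index against an n-alkane ladder:
#' RI = 100 * (n + (rt - rt_n) / (rt_(n+1) - rt_n)) for the bracketing
#' alkanes with n and n+1 carbons. At an alkane's own retention time the
#' index is exactly 100 * n.
#'
#' @param rt Numeric vector of retention times (seconds).
#' @param alkane_rts Named numeric vector, alkane retention times keyed by
#'   carbon number (e.g. `c("7" = 120, "8" = 180, ...)`), strictly increasing
#'   in both carbon and time.
#' @return Numeric vector of retention indices.
#' @examples
#' ladder <- c("10" = 600, "11" = 660, "12" = 730, "13" = 810)
#' retention_index(630, ladder)  # 1050
#' @export
retention_index <- function(rt, alkane_rts) {
  carbons <- as.integer(names(alkane_rts))
  if (anyNA(carbons)) stop("alkane_rts must be named by carbon number")
  o <- order(carbons)
  carbons <- carbons[o]; times <- as.numeric(alkane_rts[o])
  if (any(diff(times) <= 0) || any(diff(carbons) <= 0)) {
    stop("alkane retention times must be strictly increasing")
  }
  if (any(rt < times[1] | rt > times[length(times)])) {
    stop("retention time outside the alkane ladder span")
  }
  # findInterval puts rt == times[k] in segment k; clamp the top endpoint
  seg <- pmin(findInterval(rt, times), length(times) - 1L)
  n <- carbons[seg]
  span_c <- carbons[seg + 1L] - n
  100 * (n + span_c * (rt - times[seg]) / (times[seg + 1L] - times[seg]))
}
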