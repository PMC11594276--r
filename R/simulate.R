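#' Describe a multi-region winery study design
#'
#' Captures the shape of the traceability study the generator emulates: five
#' producing areas contributing {5, 5, 5, 6, 5} wineries, three fermentation
#' replicates per winery, and a wide volatile panel of which a small subset
#' truly discriminates the regions.
#'
#' @param n_groups Number of producing areas.
#' @param wineries_per_group Integer vector, wineries in each area.
#' @param replicates_per_winery Fermentation replicates per winery.
#' @param n_compounds Number of volatile compounds simulated.
#' @param n_discriminant Number of truly region-discriminating compounds
#'   (each planted as a one-region log-scale shift, regions rotating).
#' @param effect_size Log-scale mean shift of a discriminant compound in its
#'   elevated region (dimensionless, natural-log units).
#' @param noise_sd Winery-level log-scale standard deviation.
#' @param replicate_sd Replicate-level log-scale standard deviation.
#' @param n_orth_factors Number of class-orthogonal nuisance factors (rank-1
#'   structures whose scores are orthogonalized against the region dummies).
#' @param orth_sd Log-scale scale of each nuisance factor.
#' @param seed Integer seed; identical (design, seed) gives identical data.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_groups = 5,
                         wineries_per_group = c(5, 5, 5, 6, 5),
                         replicates_per_winery = 3,
                         n_compounds = 180,
                         n_discriminant = 5,
                         effect_size = 2,
                         noise_sd = 0.5,
                         replicate_sd = 0.2,
                         n_orth_factors = 2,
                         orth_sd = 0.3,
                         seed = 1L) {
  d <- list(n_groups = as.integer(n_groups),
            wineries_per_group = as.integer(wineries_per_group),
            replicates_per_winery = as.integer(replicates_per_winery),
            n_compounds = as.integer(n_compounds),
            n_discriminant = as.integer(n_discriminant),
            effect_size = effect_size,
            noise_sd = noise_sd,
            replicate_sd = replicate_sd,
            n_orth_factors = as.integer(n_orth_factors),
            orth_sd = orth_sd,
            seed = as.integer(seed))
  validate_design(d)
  structure(d, class = "study_design")
}

validate_design <- function(d) {
  if (d$n_groups < 1L || length(d$wineries_per_group) != d$n_groups ||
      any(d$wineries_per_group < 1L)) {
    stop("invalid design: need >= 1 winery in each of n_groups groups")
  }
  if (d$replicates_per_winery < 1L || d$n_compounds < 1L) {
    stop("invalid design: counts must be >= 1")
  }
  if (d$n_discriminant < 0L || d$n_orth_factors < 0L) {
    stop("invalid design: n_discriminant and n_orth_factors must be >= 0")
  }
  if (d$n_discriminant > d$n_compounds) {
    stop("invalid design: n_discriminant exceeds n_compounds")
  }
  if (!(d$noise_sd > 0)) stop("invalid design: noise_sd must be > 0")
  invisible(d)
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(paste0("study design: %d groups, wineries {%s} x %d replicates, ",
                     "%d compounds (%d discriminant, effect %.3g on log scale)\n"),
              x$n_groups, paste(x$wineries_per_group, collapse = ","),
              x$replicates_per_winery, x$n_compounds, x$n_discriminant,
              x$effect_size))
  invisible(x)
}

#' Generate a study-shaped concentration dataset with known ground truth
#'
#' Concentrations are log-normal: a per-compound baseline log-mean, a planted
#' region effect on the discriminant compounds (compound k is shifted by
#' `effect_size` in region `(k - 1) %% n_groups + 1`), winery-level noise,
#' rank-1 class-orthogonal nuisance structure, and replicate noise — all on
#' the natural-log scale, then exponentiated so values are strictly positive.
#'
#' @param design A [study_design()].
#' @param catalog Optional data.frame of compound metadata with at least an id
#'   column (`cas`); its first `n_compounds` rows name the columns. When
#'   omitted, synthetic ids `vc001...` are used.
#' @param level `"replicate"` (one row per winery-replicate) or `"winery"`
#'   (replicates averaged to one row per winery, the unit used downstream).
#' @param id_col Catalog id column.
#' @return A list of class `synthetic_study` with `concentrations` (rows =
#'   samples, strictly positive, ug/L scale), `group` (factor), `winery`
#'   (factor), and `truth` (list: `discriminant_ids`, `group_mean_matrix` on
#'   the log scale, `orth_loadings`).
#' @export
generate_study <- function(design, catalog = NULL,
                           level = c("replicate", "winery"),
                           id_col = "cas") {
  stopifnot(inherits(design, "study_design"))
  level <- match.arg(level)
  d <- validate_design(design)
  if (!is.null(catalog)) {
    if (nrow(catalog) < d$n_compounds) {
      stop("catalog has fewer entries than n_compounds")
    }
    ids <- as.character(catalog[[id_col]][seq_len(d$n_compounds)])
  } else {
    ids <- sprintf("vc%03d", seq_len(d$n_compounds))
  }
  set.seed(d$seed)
  n_w <- sum(d$wineries_per_group)
  groups <- rep(paste0("G", seq_len(d$n_groups)), d$wineries_per_group)
  wineries <- sprintf("W%02d", seq_len(n_w))

  # baseline log-means: panel spanning roughly 5-5000 ug/L
  base <- stats::rnorm(d$n_compounds, mean = log(150), sd = 1.2)
  group_means <- matrix(base, nrow = d$n_groups, ncol = d$n_compounds,
                        byrow = TRUE,
                        dimnames = list(paste0("G", seq_len(d$n_groups)), ids))
  disc <- integer(0)
  if (d$n_discriminant > 0L) {
    disc <- seq_len(d$n_discriminant)
    for (k in disc) {
      g <- (k - 1L) %% d$n_groups + 1L
      group_means[g, k] <- group_means[g, k] + d$effect_size
    }
  }

  # winery-level log values
  logw <- group_means[match(groups, rownames(group_means)), , drop = FALSE] +
    matrix(stats::rnorm(n_w * d$n_compounds, sd = d$noise_sd),
           n_w, d$n_compounds)

  # class-orthogonal nuisance: scores residualized against group dummies so
  # the structure is exactly orthogonal to class in-sample
  orth_loadings <- NULL
  if (d$n_orth_factors > 0L) {
    G <- stats::model.matrix(~ 0 + factor(groups))
    s <- matrix(stats::rnorm(n_w * d$n_orth_factors), n_w)
    s <- s - G %*% solve(crossprod(G), crossprod(G, s))
    s <- scale(s, center = FALSE,
               scale = sqrt(colSums(s^2) / nrow(s)))  # unit RMS scores
    orth_loadings <- matrix(stats::rnorm(d$n_orth_factors * d$n_compounds,
                                         sd = d$orth_sd),
                            d$n_orth_factors, d$n_compounds,
                            dimnames = list(NULL, ids))
    logw <- logw + s %*% orth_loadings
  }

  # replicate level
  nrep <- d$replicates_per_winery
  ridx <- rep(seq_len(n_w), each = nrep)
  logx <- logw[ridx, , drop = FALSE] +
    matrix(stats::rnorm(n_w * nrep * d$n_compounds, sd = d$replicate_sd),
           n_w * nrep, d$n_compounds)
  X <- exp(logx)
  rownames(X) <- sprintf("%s_r%d", wineries[ridx], rep(seq_len(nrep), n_w))
  colnames(X) <- ids
  grp <- factor(groups[ridx], levels = unique(groups))
  win <- factor(wineries[ridx], levels = wineries)

  if (level == "winery") {
    X <- winery_means(X, win)
    grp <- factor(groups, levels = unique(groups))
    win <- factor(wineries, levels = wineries)
  }
  structure(list(concentrations = X, group = grp, winery = win,
                 truth = list(discriminant_ids = ids[disc],
                              group_mean_matrix = group_means,
                              orth_loadings = orth_loadings),
                 design = d),
            class = "synthetic_study")
}

#' Average replicate rows to winery means
#'
#' @param x Samples x compounds matrix.
#' @param winery Factor of winery ids, one per row of `x`.
#' @return Matrix with one row per winery (level order preserved).
#' @export
winery_means <- function(x, winery) {
  x <- as.matrix(x)
  winery <- factor(winery, levels = unique(as.character(winery)))
  out <- rowsum(x, winery) / as.vector(table(winery))
  out[levels(winery), , drop = FALSE]
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic study: %d samples x %d compounds, %d groups (%s)\n",
              nrow(x$concentrations), ncol(x$concentrations),
              nlevels(x$group), paste(levels(x$group), collapse = ", ")))
  cat(sprintf("  planted discriminants: %s\n",
              paste(x$truth$discriminant_ids, collapse = ", ")))
  invisible(x)
}

#' Simulate a 2^n dilution-series calibration point set
#'
#' Nine (by default) concentration levels, each half the previous, with
#' Gaussian noise on the instrument response ratio — the design used to draw
#' internal-standard curves.
#'
#' @param true_slope,true_intercept Line generating the response (area ratio
#'   per concentration ratio; area ratio).
#' @param noise_sd Standard deviation of the response noise (area-ratio
#'   units), >= 0.
#' @param n_points Number of dilution levels (>= 3).
#' @param top_conc_ratio Concentration ratio of the undiluted level.
#' @param seed Integer seed.
#' @return Data.frame with columns `conc_ratio`, `area_ratio`.
#' @export
generate_calibration <- function(true_slope, true_intercept = 0,
                                 noise_sd = 0.05, n_points = 9,
                                 top_conc_ratio = 4, seed = 1L) {
  if (noise_sd < 0) stop("invalid parameter: noise_sd must be >= 0")
  if (n_points < 3L) stop("need at least 3 dilution levels")
  set.seed(as.integer(seed))
  conc <- top_conc_ratio / 2^(seq_len(n_points) - 1L)
  area <- true_intercept + true_slope * conc +
    stats::rnorm(n_points, sd = noise_sd)
  data.frame(conc_ratio = conc, area_ratio = area)
}
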