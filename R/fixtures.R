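#' Load a packaged reference table
#'
#' The package ships the printed tables of a 26-winery, five-region Cabernet
#' Sauvignon producing-area study as plain CSV fixtures: the internal-standard
#' calibration curves, the per-winery wine physicochemistry, the per-region
#' phenology-stage meteorology, the odor-activity catalog (36 aroma-active
#' compounds with thresholds, descriptors and per-region OAVs), plus vineyard
#' geography and the meteorological-station coordinates.
#'
#' @param name One of `"calibration_curves"`, `"wine_physchem"`,
#'   `"meteorology"`, `"oav_catalog"`, `"geography"`, `"stations"`.
#' @return A `data.frame` with typed columns. `calibration_curves` carries a
#'   `carbon_count` column parsed from the molecular formula and a
#'   `chemical_class` column mapped from the table's category labels.
#' @examples
#' cat6 <- load_fixture("oav_catalog")
#' nrow(cat6)  # 36 aroma-active compounds
#' @export
load_fixture <- function(name) {
  known <- c("calibration_curves", "wine_physchem", "meteorology",
             "oav_catalog", "geography", "stations")
  if (length(name) != 1L || !name %in% known) {
    stop("unknown fixture '", paste(name, collapse = ","),
         "'; available: ", paste(known, collapse = ", "))
  }
  path <- system.file("extdata", paste0(name, ".csv"), package = "aromatrace")
  if (!nzchar(path)) stop("fixture file missing from installation: ", name)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (name == "calibration_curves") {
    df$carbon_count <- carbons_from_formula(df$formula)
    df$chemical_class <- class_from_category(df$category)
  }
  if (name == "oav_catalog") {
    regs <- c("HL", "YC", "YN", "QTX", "HSP")
    for (r in regs) df[[r]] <- as.numeric(df[[r]])
  }
  df
}

# carbon count from a Hill-style molecular formula, e.g. "C6H14O" -> 6
carbons_from_formula <- function(formula) {
  m <- regmatches(formula, regexpr("^C[0-9]*", formula))
  n <- suppressWarnings(as.integer(sub("^C", "", m)))
  n[is.na(n) & nzchar(m)] <- 1L
  n
}

# map the fixture's category labels onto the compound-class vocabulary
class_from_category <- function(category) {
  map <- c("C6 Compounds"       = "C6",
           "Alcohols"           = "alcohol",
           "Esters"             = "ester",
           "Aldehydes"          = "aldehyde/ketone",
           "Terpenes"           = "terpene",
           "Acids"              = "acid",
           "C13-Norisoprenoids" = "C13-norisoprenoid")
  out <- unname(map[category])
  out[is.na(out)] <- "other"
  out
}

#' Assemble the packaged calibration-curve library
#'
#' Turns the `calibration_curves` fixture into a list of [calibration_curve]
#' objects keyed by CAS number, each annotated with the source compound's
#' chemical class and carbon count so that [assign_surrogate_curve()] can
#' match unstandardized compounds. The printed determination coefficients are
#' carried as metadata (the raw calibration points were not published, so
#' they cannot be re-derived).
#'
#' @return Named list of `calibration_curve` objects (names are CAS numbers).
#' @export
calibration_library <- function() {
  tab <- load_fixture("calibration_curves")
  # valid range expressed as concentration ratios relative to the internal
  # standard (324.4 ug/L) used when the curves were drawn
  istd <- internal_standard()
  out <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    out[[i]] <- new_calibration_curve(
      compound_id    = tab$cas[i],
      slope          = tab$slope[i],
      intercept      = tab$intercept[i],
      r2             = tab$r2[i],
      valid_range    = c(tab$conc_min_ugL[i], tab$conc_max_ugL[i]) / istd$concentration,
      chemical_class = tab$chemical_class[i],
      carbon_count   = tab$carbon_count[i],
      name           = tab$name[i])
  }
  names(out) <- tab$cas
  out
}

#' The study's internal standard
#'
#' 4-Methyl-2-pentanol spiked at 324.4 ug/L, against which analyte peak areas
#' and concentrations are ratioed.
#'
#' @param concentration Spike concentration in ug/L.
#' @return A list with `name` and `concentration`.
#' @export
internal_standard <- function(concentration = 324.4) {
  stopifnot(is.numeric(concentration), length(concentration) == 1L,
            concentration > 0)
  structure(list(name = "4-methyl-2-pentanol", concentration = concentration),
            class = "internal_standard")
}
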