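make_station_records <- function(values_by_station) {
  # values_by_station: named list station -> function(month, variable) value
  grid <- expand.grid(station = names(values_by_station), month = 4:9,
                      variable = c("temperature_C", "humidity_pct"),
                      stringsAsFactors = FALSE)
  grid$value <- mapply(function(st, mo, v) values_by_station[[st]](mo, v),
                       grid$station, grid$month, grid$variable)
  grid
}

test_that("regional meteorology averages stations and stage months", {
  flat <- function(val) function(mo, v) val
  rec <- make_station_records(list(s1 = flat(10), s2 = flat(20),
                                   s3 = flat(30)))
  asg <- data.frame(region = "R1", station = c("s1", "s2", "s3"))
  agg <- aggregate_meteo(rec, asg)
  expect_equal(unique(agg$R1), 20)
  # identical stations reproduce the station value
  rec2 <- make_station_records(list(s1 = flat(7), s2 = flat(7), s3 = flat(7)))
  expect_equal(unique(aggregate_meteo(rec2, asg)$R1), 7)
  # two-month stages average their months
  bymonth <- function(mo, v) mo * 10
  rec3 <- make_station_records(list(s1 = bymonth, s2 = bymonth,
                                    s3 = bymonth))
  agg3 <- aggregate_meteo(rec3, asg)
  expect_equal(agg3$R1[agg3$stage == "germination"][1], 40)
  expect_equal(agg3$R1[agg3$stage == "flowering"][1], 55)   # mean(50, 60)
  expect_equal(agg3$R1[agg3$stage == "coloring"][1], 75)    # mean(70, 80)
  expect_equal(agg3$R1[agg3$stage == "maturation"][1], 90)
})

test_that("station order does not change the aggregate", {
  set.seed(4)
  fn <- function() { v <- runif(12, 0, 40)
    function(mo, var) v[(mo - 3) + ifelse(var == "humidity_pct", 6, 0)] }
  rec <- make_station_records(list(s1 = fn(), s2 = fn(), s3 = fn()))
  a1 <- aggregate_meteo(rec, data.frame(region = "R",
                                        station = c("s1", "s2", "s3")))
  a2 <- aggregate_meteo(rec, data.frame(region = "R",
                                        station = c("s3", "s1", "s2")))
  expect_equal(a1, a2)
})

test_that("incomplete station records and bad assignments error", {
  flat <- function(val) function(mo, v) val
  rec <- make_station_records(list(s1 = flat(1), s2 = flat(2), s3 = flat(3)))
  asg <- data.frame(region = "R1", station = c("s1", "s2", "s3"))
  expect_error(aggregate_meteo(rec[rec$month != 5, ], asg), "incomplete")
  expect_error(aggregate_meteo(rec, asg[1:2, ]), "exactly 3")
})

test_that("stations averaged to the fixture values round-trip the table", {
  met <- load_fixture("meteorology")
  months <- list(germination = 4, flowering = 5:6, coloring = 7:8,
                 maturation = 9)
  regions <- c("HL", "YC", "YN", "QTX", "HSP")
  rec <- do.call(rbind, lapply(regions, function(r) {
    do.call(rbind, lapply(seq_len(nrow(met)), function(i) {
      data.frame(station = paste0(r, "_st", 1:3),
                 month = rep(months[[met$stage[i]]], each = 3),
                 variable = met$variable[i], value = met[[r]][i])
    }))
  }))
  asg <- data.frame(region = rep(regions, each = 3),
                    station = paste0(rep(regions, each = 3), "_st", 1:3))
  agg <- aggregate_meteo(rec, asg)
  expect_equal(agg$HSP[agg$variable == "humidity_pct" &
                         agg$stage == "maturation"], 53.94)
  for (r in regions) {
    got <- agg[[r]][match(paste(met$variable, met$stage),
                          paste(agg$variable, agg$stage))]
    expect_equal(got, met[[r]], tolerance = 1e-9)
  }
})

test_that("per-region means reproduce the printed averages", {
  phys <- load_fixture("wine_physchem")
  w <- phys[!phys$is_average,
            c("region", "residual_sugar_gL", "titratable_acid_gL", "pH",
              "alcohol_pctvol")]
  s <- physchem_summary(w)
  avg <- phys[phys$is_average, ]
  # two printed cells reflect unrounded raw data and sit 0.006 off the mean
  # of the printed winery values; all others agree to the printed precision
  loose <- paste(c("YN", "YN"), c("residual_sugar_gL", "alcohol_pctvol"))
  for (i in seq_len(nrow(s))) {
    printed <- avg[[s$variable[i]]][avg$region == s$region[i]]
    tol <- if (paste(s$region[i], s$variable[i]) %in% loose) 0.01 else 0.005
    expect_lt(abs(s$mean[i] - printed), tol + 1e-12)
  }
  # spot values quoted in the study text
  expect_equal(s$mean[s$region == "HSP" & s$variable == "titratable_acid_gL"],
               5.60)
  expect_equal(s$mean[s$region == "QTX" & s$variable == "pH"], 3.59)
  expect_equal(s$mean[s$region == "HL" & s$variable == "alcohol_pctvol"],
               13.27)
  # sd uses the n - 1 denominator
  hl <- w$alcohol_pctvol[w$region == "HL"]
  expect_equal(s$sd[s$region == "HL" & s$variable == "alcohol_pctvol"],
               round(sd(hl), 2))
  # single record: sd 0 with a flag
  one <- physchem_summary(data.frame(region = "X", v = 5))
  expect_equal(one$sd, 0)
  expect_true(one$single_record)
})

test_that("pearson matrices carry r, t-transform p and the alpha mask", {
  set.seed(9)
  x <- rnorm(10)
  cm <- pearson_matrix(cbind(a = x), cbind(b = x, c = -x, d = 2 * x + 3))
  expect_equal(unname(cm$r[1, ]), c(1, -1, 1), tolerance = 1e-12)
  expect_equal(unname(cm$p[1, ]), c(0, 0, 0))
  expect_true(all(cm$sig))
  # bivariate normal rho = 0.8 at n = 1000
  set.seed(31)
  z <- rnorm(1000); e <- rnorm(1000)
  big <- pearson_matrix(cbind(u = z), cbind(v = 0.8 * z + sqrt(1 - 0.64) * e))
  expect_lt(abs(big$r[1, 1] - 0.8), 0.05)
  # p-values match cor.test
  set.seed(5)
  a <- rnorm(20); b <- a + rnorm(20, sd = 2)
  cm2 <- pearson_matrix(cbind(a = a), cbind(b = b))
  ct <- cor.test(a, b)
  expect_equal(cm2$p[1, 1], ct$p.value, tolerance = 1e-10)
  # zero variance: flagged missing, not zero
  cm3 <- pearson_matrix(cbind(a = a, k = rep(1, 20)), cbind(b = b))
  expect_true(is.na(cm3$r["k", "b"]))
  expect_false(cm3$sig["k", "b"])
  expect_error(pearson_matrix(cbind(a = 1:2), cbind(b = 2:1)), "at least 3")
})

test_that("broadcast covariates are invariant to within-region shuffles", {
  st <- generate_study(study_design(seed = 13, n_compounds = 20),
                       level = "winery")
  met <- load_fixture("meteorology")
  cov <- t(as.matrix(met[met$variable == "sunshine_h",
                         c("HL", "YC", "YN", "QTX", "HSP")]))
  colnames(cov) <- paste0("sun_", met$stage[met$variable == "sunshine_h"])
  rownames(cov) <- c("HL", "YC", "YN", "QTX", "HSP")
  region <- c("HL", "YC", "YN", "QTX", "HSP")[as.integer(st$group)]
  Z <- broadcast_regional(cov, region)
  X <- log(st$concentrations[, 1:5])
  c1 <- pearson_matrix(X, Z)
  # permute samples within each region
  set.seed(2)
  perm <- seq_along(region)
  for (r in unique(region)) {
    idx <- which(region == r)
    perm[idx] <- sample(idx)
  }
  expect_true(all(sort(perm) == seq_along(region)))
  expect_true(all(region[perm] == region))
  # covariates stay put: broadcast rows are identical within a region
  c2 <- pearson_matrix(X[perm, ], Z)
  expect_equal(c1$r, c2$r, tolerance = 1e-12)
  # long format export
  lf <- as.data.frame(c1)
  expect_equal(nrow(lf), length(c1$r))
  expect_true(all(c("compound", "covariate", "r", "p", "significant")
                  %in% names(lf)))
})
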