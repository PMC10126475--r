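wl <- spectral_grid()

test_that("flat spectrum zeroes every normalized index and derivative", {
  v <- extract_hyperspectral_features(wl, rep(0.5, length(wl)))
  cat22 <- dplyr::filter(default_catalog(), source == "hyperspectral")
  nd <- cat22$name[cat22$type == "nd_index"]
  dv <- cat22$name[cat22$type == "derivative"]
  expect_true(all(abs(v[nd]) < 1e-12))
  expect_true(all(abs(v[dv]) < 1e-12))
})

test_that("band-combination features match their closed forms", {
  refl <- rep(0.1, length(wl))
  refl[wl >= 750] <- 0.5                     # NIR plateau 0.5, red 0.1
  v <- extract_hyperspectral_features(wl, refl)
  expect_equal(unname(v["hs_ndvi"]), (0.5 - 0.1) / (0.5 + 0.1),
               tolerance = 1e-12)
  expect_equal(unname(v["hs_sr"]), 5, tolerance = 1e-12)
  expect_equal(unname(v["hs_evi2"]), 2.5 * 0.4 / (0.5 + 2.4 * 0.1 + 1),
               tolerance = 1e-12)
  expect_equal(unname(v["hs_savi"]), 1.5 * 0.4 / (0.5 + 0.1 + 0.5),
               tolerance = 1e-12)
})

test_that("integration equals a hand trapezoid on a triangular spectrum", {
  grid <- c(500, 520, 540, 560, 580, 600)
  refl <- c(0, 0.2, 0.4, 0.4, 0.2, 0)
  cat1 <- tibble::tibble(name = "tri", source = "hyperspectral",
                         type = "integration", b1 = 500, b2 = 600,
                         p1 = NA_real_, stat = NA_character_)
  v <- extract_hyperspectral_features(grid, refl, cat1)
  # hand trapezoid: 20 * (0/2+0.2) + 20*(0.3) + 20*(0.4) + 20*(0.3) + 20*(0.1)
  expect_equal(unname(v["tri"]), 20 * (0.1 + 0.3 + 0.4 + 0.3 + 0.1),
               tolerance = 1e-12)
})

test_that("catalog wavelengths outside the grid are rejected by name", {
  bad <- tibble::tibble(name = "oob", source = "hyperspectral",
                        type = "nd_index", b1 = 1200, b2 = 670,
                        p1 = NA_real_, stat = NA_character_)
  expect_error(extract_hyperspectral_features(wl, rep(0.5, length(wl)), bad),
               "oob")
})

test_that("nearest-band lookup is stable under sub-spacing grid perturbation", {
  refl <- 0.1 + 0.4 * stats::plogis((wl - 715) / 12)
  # catalog targets sitting on band centers: a grid shift below half the
  # band spacing (2.21 nm) cannot move the nearest-band lookup
  band_cat <- tibble::tibble(
    name = c("nd_a", "nd_b", "ratio_c"),
    source = "hyperspectral",
    type = c("nd_index", "nd_index", "ratio"),
    b1 = wl[c(180, 150, 200)], b2 = wl[c(120, 60, 120)],
    p1 = NA_real_, stat = NA_character_
  )
  v1 <- extract_hyperspectral_features(wl, refl, band_cat)
  v2 <- extract_hyperspectral_features(wl + 1.0, refl, band_cat)
  v3 <- extract_hyperspectral_features(wl - 1.0, refl, band_cat)
  expect_equal(v1, v2, tolerance = 1e-12)
  expect_equal(v1, v3, tolerance = 1e-12)
})

test_that("scaling reflectance leaves indices fixed and scales integrals", {
  refl <- 0.1 + 0.4 * stats::plogis((wl - 715) / 12)
  v1 <- extract_hyperspectral_features(wl, refl)
  v2 <- extract_hyperspectral_features(wl, 3 * refl)
  cat22 <- dplyr::filter(default_catalog(), source == "hyperspectral")
  nd <- cat22$name[cat22$type %in% c("nd_index", "ratio", "ci")]
  ints <- cat22$name[cat22$type == "integration"]
  expect_equal(v1[nd], v2[nd], tolerance = 1e-10)
  expect_equal(3 * v1[ints], v2[ints], tolerance = 1e-10)
})

test_that("vectorised extraction equals the per-spectrum extractor", {
  tt <- tiny_trial()
  sp <- tt$trial$spectra
  refl <- as.matrix(sp[band_cols <- grep("^wl_", names(sp), value = TRUE)])
  i <- 5
  single <- extract_hyperspectral_features(wl, as.numeric(refl[i, ]))
  mat <- phenocast:::extract_hs_matrix(wl, refl, default_catalog())
  expect_equal(single, mat[i, ], tolerance = 1e-12)
})

make_cloud <- function(z_canopy, z_ground = c(0, 0, 0)) {
  n <- length(z_canopy) + length(z_ground)
  tibble::tibble(
    x = seq(0.05, 2.95, length.out = n),
    y = rep(0.5, n),
    z = c(z_ground, z_canopy),
    is_ground = rep(c(TRUE, FALSE), c(length(z_ground), length(z_canopy)))
  )
}

test_that("canopy cover is a simple count ratio over all points", {
  cl <- make_cloud(z_canopy = c(0.2, 0.4, 1.2, 1.5, 1.8, 2.1, 0.1),
                   z_ground = c(0, 0, 0))
  v <- extract_lidar_features(cl)
  expect_equal(unname(v["ld_cover_100"]), 4 / 10)
  expect_true(all(v[c("ld_cover_100", "ld_cover_150", "ld_cover_200")] >= 0))
  expect_true(all(v[c("ld_cover_100", "ld_cover_150", "ld_cover_200")] <= 1))
})

test_that("degenerate canopy (all heights equal) collapses the statistics", {
  cl <- make_cloud(z_canopy = rep(1.3, 12))
  v <- extract_lidar_features(cl)
  pct <- grep("^ld_p", names(v), value = TRUE)
  expect_true(all(abs(v[pct] - 1.3) < 1e-12))
  expect_equal(unname(v["ld_sd"]), 0)
  expect_equal(unname(v["ld_skew"]), 0)
})

test_that("percentiles match a sort-based oracle and are monotone in level", {
  set.seed(99)
  hz <- runif(100, 0, 2.5)
  cl <- make_cloud(z_canopy = hz)
  v <- extract_lidar_features(cl)
  srt <- sort(hz)
  for (lev in c(10, 25, 50, 75, 90, 95, 99)) {
    # type-7 quantile oracle computed by hand from the sorted sample
    h <- (length(srt) - 1) * lev / 100 + 1
    lo <- floor(h)
    oracle <- srt[lo] + (h - lo) * (srt[min(lo + 1, length(srt))] - srt[lo])
    expect_equal(unname(v[sprintf("ld_p%02d", lev)]), oracle,
                 tolerance = 1e-9)
  }
  pct <- v[c("ld_p10", "ld_p25", "ld_p50", "ld_p75", "ld_p90", "ld_p95",
             "ld_p99", "ld_p100")]
  expect_true(all(diff(pct) >= 0))
})

test_that("empty canopy yields NA stats, zero cover, and a flag", {
  cl <- tibble::tibble(x = runif(10), y = runif(10), z = rep(0, 10),
                       is_ground = TRUE)
  v <- extract_lidar_features(cl)
  expect_true(isTRUE(attr(v, "empty_canopy")))
  expect_true(is.na(v["ld_p50"]))
  expect_equal(unname(v["ld_cover_100"]), 0)
  expect_error(extract_lidar_features(cl[0, ]), "empty")
  cl$is_ground <- FALSE
  expect_error(extract_lidar_features(cl), "ground")
})

test_that("weather sums follow the thermal-time arithmetic", {
  w <- tibble::tibble(day = 1:3, t_min = c(10, 15, 20), t_max = c(20, 25, 30),
                      precipitation = c(0, 5, 2), radiation = c(20, 18, 22))
  v <- extract_weather_features(w, 3)
  expect_equal(unname(v["wx_gdd"]), 5 + 10 + 15)
  expect_equal(unname(v["wx_cum_precip"]), 7)
  expect_equal(unname(v["wx_cum_radiation"]), 60)
  # single cold day: GDD clamps at zero
  cold <- tibble::tibble(day = 1, t_min = 2, t_max = 8,
                         precipitation = 0, radiation = 10)
  expect_equal(unname(extract_weather_features(cold, 1)["wx_gdd"]), 0)
  # gaps are reported with the missing day
  expect_error(extract_weather_features(w[-2, ], 3), "2")
})

test_that("cumulative weather features never decrease over the season", {
  tt <- tiny_trial()
  v <- tt$tensor$values
  for (f in c("wx_gdd", "wx_cum_precip", "wx_cum_radiation")) {
    series <- v[1, f, ]
    expect_true(all(diff(series) >= 0))
  }
})

test_that("tensor assembly flags imputed LiDAR slabs and is order-independent", {
  tt <- tiny_trial()
  full <- tt$tensor
  expect_false(any(full$imputed))

  # drop LiDAR on date 3: the whole block is carried from the nearest date
  sparse <- extract_features(tt$trial, lidar_dates = c(1, 2, 4))
  ld <- sparse$features$source == "lidar"
  expect_true(all(sparse$imputed[, ld, 3]))
  expect_false(any(sparse$imputed[, ld, c(1, 2, 4)]))
  expect_false(any(sparse$imputed[, !ld, ]))
  # carried from the nearest available date (ties resolve to the earlier one)
  expect_equal(sparse$values[, ld, 3], sparse$values[, ld, 2])

  # shuffled long-table rows assemble to the identical tensor
  long <- tidy(full)[c("plot_id", "date", "feature", "value")]
  shuf <- long[sample.int(nrow(long)), ]
  t2 <- assemble_feature_tensor(shuf, tt$trial$records, tt$trial$dates)
  expect_equal(full$values, t2$values)
})

test_that("assembly rejects plots with no feature rows", {
  tt <- tiny_trial()
  long <- tidy(tt$tensor)[c("plot_id", "date", "feature", "value")]
  recs <- dplyr::bind_rows(tt$trial$records,
                           tibble::tibble(trial = "X", year = 1L,
                                          plot_id = "GHOST",
                                          hybrid_id = "H0001",
                                          replicate = 1L))
  expect_error(assemble_feature_tensor(long, recs, tt$trial$dates), "GHOST")
})

test_that("dropping features removes exactly those slabs in survivor order", {
  tt <- tiny_trial()
  drop <- c("hs_int_905_925", "ld_cv")
  pruned <- drop_features(tt$tensor, drop)
  expect_equal(dim(pruned$values)[2], dim(tt$tensor$values)[2] - 2)
  expect_identical(pruned$features$name,
                   setdiff(tt$tensor$features$name, drop))
  expect_identical(drop_features(tt$tensor, character(0)), tt$tensor)
  expect_error(drop_features(tt$tensor, "nope"), "nope")

  # dropping then comparing against extraction from the reduced catalog
  cat2 <- dplyr::filter(default_catalog(), !name %in% drop)
  re <- extract_features(tt$trial, catalog = cat2)
  expect_equal(pruned$values, re$values)
})

test_that("catalog YAML round-trips", {
  path <- withr::local_tempfile(fileext = ".yaml")
  cat0 <- default_catalog()
  write_catalog(cat0, path)
  cat1 <- read_catalog(path)
  expect_equal(as.data.frame(cat1), as.data.frame(cat0))
})
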