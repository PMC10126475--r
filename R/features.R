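# Plot-level feature extraction: spectra, point clouds, weather.

#' Extract hyperspectral features from one plot-mean spectrum
#'
#' Band lookups use nearest-wavelength matching on the native grid,
#' integration features use the trapezoidal rule on the native grid, and
#' derivative features use central finite differences on the native grid.
#'
#' @param wavelengths Strictly increasing wavelength grid (nm).
#' @param reflectance Reflectance per band (same length).
#' @param catalog A [default_catalog()]-style catalog; only rows with
#'   `source == "hyperspectral"` are used.
#' @return A named numeric vector, one value per hyperspectral catalog row.
#' @examples
#' wl <- spectral_grid()
#' extract_hyperspectral_features(wl, rep(0.5, length(wl)))[["hs_ndvi"]]
#' @export
extract_hyperspectral_features <- function(wavelengths, reflectance,
                                           catalog = default_catalog()) {
  catalog <- validate_catalog(catalog)
  hs <- filter(catalog, .data$source == "hyperspectral")
  wl <- wavelengths
  if (is.unsorted(wl, strictly = TRUE)) {
    abort("wavelengths must be strictly increasing")
  }
  ref_wl <- stats::na.omit(c(hs$b1, hs$b2))
  bad <- ref_wl < min(wl) | ref_wl > max(wl)
  if (any(bad)) {
    off <- hs$name[hs$b1 %in% ref_wl[bad] | hs$b2 %in% ref_wl[bad]]
    abort(sprintf("catalog wavelength outside sensor grid for: %s",
                  paste(unique(off), collapse = ", ")))
  }
  band <- function(w) reflectance[nearest_index(wl, w)]
  vapply(seq_len(nrow(hs)), function(i) {
    row <- hs[i, ]
    switch(row$type,
      nd_index = {
        a <- band(row$b1); b <- band(row$b2)
        if (a + b == 0) 0 else (a - b) / (a + b)
      },
      ratio = band(row$b1) / band(row$b2),
      ci = band(row$b1) / band(row$b2) - 1,
      savi = {
        a <- band(row$b1); b <- band(row$b2); L <- row$p1
        (1 + L) * (a - b) / (a + b + L)
      },
      evi2 = {
        a <- band(row$b1); b <- band(row$b2)
        2.5 * (a - b) / (a + 2.4 * b + 1)
      },
      integration = {
        keep <- wl >= row$b1 & wl <= row$b2
        pracma::trapz(wl[keep], reflectance[keep])
      },
      derivative = spectral_derivative(wl, reflectance, row$b1, row$p1),
      abort(sprintf("unknown hyperspectral feature type `%s`", row$type))
    )
  }, numeric(1), USE.NAMES = FALSE) |> setNames(hs$name)
}

# Central finite differences on the native (possibly uneven) grid.
spectral_derivative <- function(wl, refl, at, order) {
  i <- nearest_index(wl, at)
  i <- min(max(i, 2L), length(wl) - 1L)
  d1 <- (refl[i + 1] - refl[i - 1]) / (wl[i + 1] - wl[i - 1])
  if (order == 1) return(d1)
  h1 <- wl[i] - wl[i - 1]
  h2 <- wl[i + 1] - wl[i]
  2 * (h1 * refl[i + 1] - (h1 + h2) * refl[i] + h2 * refl[i - 1]) /
    (h1 * h2 * (h1 + h2))
}

#' Extract LiDAR canopy-structure features from one plot point cloud
#'
#' Heights are normalized to `z - median(ground z)`. Percentiles and
#' statistics are computed on non-ground points; canopy cover is the
#' fraction of *all* points in the segment whose normalized height exceeds
#' the threshold; canopy volume sums cell-max normalized height times cell
#' area over a planimetric grid.
#'
#' @param cloud Tibble with `x`, `y`, `z` (m) and logical `is_ground`.
#' @param catalog Catalog; rows with `source == "lidar"` are used.
#' @return Named numeric vector. If the cloud has no canopy points, height
#'   statistics are `NA` (a structured "empty canopy" outcome) and cover
#'   features are 0; an `empty_canopy` attribute marks the case.
#' @export
extract_lidar_features <- function(cloud, catalog = default_catalog()) {
  catalog <- validate_catalog(catalog)
  ld <- filter(catalog, .data$source == "lidar")
  defs <- lidar_defs(ld)
  val <- lidar_kernel(cloud$x, cloud$y, cloud$z, cloud$is_ground, defs)
  names(val) <- ld$name
  attr(val, "empty_canopy") <- !any(!cloud$is_ground)
  val
}

# Pre-compiled catalog rows, so the per-plot kernel avoids tibble indexing.
lidar_defs <- function(ld_cat) {
  purrr::pmap(ld_cat[c("name", "type", "p1", "stat")], list)
}

# The actual per-cloud computation on plain vectors; shared by the single-
# cloud extractor and the vectorised trial-level path.
lidar_kernel <- function(x, y, z, is_ground, defs) {
  if (length(z) == 0) abort("empty point cloud")
  if (!any(is_ground)) abort("no ground points for height normalization")
  z0 <- median(z[is_ground])
  zn <- z - z0
  can <- !is_ground
  hz <- zn[can]
  empty <- length(hz) == 0
  n_all <- length(zn)
  hz_sd <- if (length(hz) > 1) sd(hz) else 0

  vapply(defs, function(row) {
    if (row$type == "cover") {
      return(sum(zn > row$p1 & can) / n_all)
    }
    if (empty) return(NA_real_)
    switch(row$type,
      percentile = unname(quantile(hz, row$p1 / 100)),
      stat = switch(row$stat,
        mean = mean(hz),
        sd = hz_sd,
        skew = if (length(hz) > 2 && hz_sd > 0) {
          e1071::skewness(hz, type = 2)
        } else 0,
        mad = stats::mad(hz),
        iqr = stats::IQR(hz),
        range = diff(range(hz)),
        cv = if (mean(hz) != 0) hz_sd / mean(hz) else 0,
        abort(sprintf("unknown lidar stat `%s`", row$stat))
      ),
      volume = canopy_volume(x[can], y[can], hz, row$p1),
      abort(sprintf("unknown lidar feature type `%s`", row$type))
    )
  }, numeric(1))
}

canopy_volume <- function(x, y, h, cell) {
  if (length(h) == 0) return(0)
  ix <- floor(x / cell)
  iy <- floor(y / cell)
  cellmax <- tapply(pmax(h, 0), paste(ix, iy), max)
  sum(cellmax) * cell^2
}

#' Extract cumulative weather features for one observation date
#'
#' Sums daily precipitation, solar radiation, and growing degree days
#' `max(0, (t_min + t_max)/2 - T_base)` over sowing..observation
#' (inclusive).
#'
#' @param weather A [simulate_weather()]-style daily tibble covering the
#'   interval, with a `day` column (1 = sowing day).
#' @param obs_day Observation day of season (1-based).
#' @param catalog Catalog; rows with `source == "weather"` are used.
#' @return Named numeric vector.
#' @examples
#' w <- tibble::tibble(day = 1:3, t_min = c(10, 15, 20),
#'                     t_max = c(20, 25, 30), precipitation = 0, radiation = 20)
#' extract_weather_features(w, 3)[["wx_gdd"]]  # 5 + 10 + 15
#' @export
extract_weather_features <- function(weather, obs_day,
                                     catalog = default_catalog()) {
  catalog <- validate_catalog(catalog)
  wt <- filter(catalog, .data$source == "weather")
  if (obs_day < min(weather$day)) {
    abort("observation date precedes sowing date")
  }
  want <- seq(min(weather$day), obs_day)
  missing <- setdiff(want, weather$day)
  if (length(missing) > 0) {
    abort(sprintf("weather series has gaps at day(s): %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  w <- filter(weather, .data$day <= obs_day)
  vapply(seq_len(nrow(wt)), function(i) {
    row <- wt[i, ]
    switch(row$type,
      cum_precip = sum(w$precipitation),
      cum_radiation = sum(w$radiation),
      gdd = sum(pmax(0, (w$t_min + w$t_max) / 2 - row$p1)),
      abort(sprintf("unknown weather feature type `%s`", row$type))
    )
  }, numeric(1)) |> setNames(wt$name)
}
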