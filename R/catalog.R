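#' Feature catalog: the definition of every extracted feature
#'
#' The catalog is data, not code: a tibble with one row per feature giving
#' its `name`, `source` (`"hyperspectral"`, `"lidar"`, `"weather"`), `type`
#' and parameters. It can be written to / read from YAML so a user holding
#' the exact feature list of a given sensor campaign can reproduce it.
#'
#' Feature types and their parameters:
#' \describe{
#'   \item{`nd_index`}{normalized difference `(R(b1) - R(b2)) / (R(b1) + R(b2))`}
#'   \item{`ratio`}{`R(b1) / R(b2)`}
#'   \item{`ci`}{chlorophyll-index form `R(b1) / R(b2) - 1`}
#'   \item{`savi`}{soil-adjusted `(1 + L) (R(b1) - R(b2)) / (R(b1) + R(b2) + L)`
#'     with `L` in `p1`}
#'   \item{`evi2`}{`2.5 (R(b1) - R(b2)) / (R(b1) + 2.4 R(b2) + 1)`}
#'   \item{`integration`}{trapezoidal area under the spectrum over `[b1, b2]` nm}
#'   \item{`derivative`}{first (`p1 = 1`) or second (`p1 = 2`) central finite
#'     difference at band `b1`}
#'   \item{`percentile`}{canopy-height percentile at level `p1` (0-100]}
#'   \item{`stat`}{canopy-height statistic named in `stat`}
#'   \item{`volume`}{canopy volume on a planimetric grid of cell size `p1` m}
#'   \item{`cover`}{fraction of all points with normalized height above `p1` m}
#'   \item{`cum_precip`, `cum_radiation`, `gdd`}{sums over sowing..observation;
#'     `gdd` uses base temperature `p1` (deg C)}
#' }
#'
#' @param hyperspectral,lidar,weather Logical; include each block.
#' @return A `feature_catalog` tibble.
#' @examples
#' cat22 <- default_catalog()
#' dplyr::count(cat22, source)
#' @export
default_catalog <- function(hyperspectral = TRUE, lidar = TRUE,
                            weather = TRUE) {
  hs <- tibble(
    name = c("hs_ndvi", "hs_gndvi", "hs_ndre", "hs_pri", "hs_npci",
             "hs_sr", "hs_ci_rededge", "hs_ci_green", "hs_savi", "hs_evi2",
             "hs_int_400_500", "hs_int_500_600", "hs_int_600_700",
             "hs_int_760_900",
             "hs_d1_705", "hs_d1_715", "hs_d1_725", "hs_d1_735",
             names(redundant_windows())),
    source = "hyperspectral",
    type = c("nd_index", "nd_index", "nd_index", "nd_index", "nd_index",
             "ratio", "ci", "ci", "savi", "evi2",
             rep("integration", 4),
             rep("derivative", 4),
             rep("integration", 4)),
    b1 = c(800, 800, 790, 531, 680,
           800, 800, 800, 800, 800,
           400, 500, 600, 760,
           705, 715, 725, 735,
           905, 930, 955, 980),
    b2 = c(670, 550, 720, 570, 450,
           670, 720, 550, 670, 670,
           500, 600, 700, 900,
           NA, NA, NA, NA,
           925, 950, 975, 1000),
    p1 = c(NA, NA, NA, NA, NA,
           NA, NA, NA, 0.5, NA,
           NA, NA, NA, NA,
           1, 1, 1, 1,
           NA, NA, NA, NA),
    stat = NA_character_
  )
  ld <- tibble(
    name = c(sprintf("ld_p%02d", c(10, 25, 50, 75, 90, 95, 99)), "ld_p100",
             "ld_mean", "ld_sd", "ld_skew", "ld_mad", "ld_iqr", "ld_range",
             "ld_cv", "ld_volume", "ld_cover_100", "ld_cover_150",
             "ld_cover_200"),
    source = "lidar",
    type = c(rep("percentile", 8), rep("stat", 7), "volume",
             rep("cover", 3)),
    b1 = NA_real_, b2 = NA_real_,
    p1 = c(10, 25, 50, 75, 90, 95, 99, 100,
           NA, NA, NA, NA, NA, NA, NA, 0.1, 1.0, 1.5, 2.0),
    stat = c(rep(NA, 8), "mean", "sd", "skew", "mad", "iqr", "range", "cv",
             rep(NA, 4))
  )
  wt <- tibble(
    name = c("wx_gdd", "wx_cum_precip", "wx_cum_radiation"),
    source = "weather",
    type = c("gdd", "cum_precip", "cum_radiation"),
    b1 = NA_real_, b2 = NA_real_,
    p1 = c(10, NA, NA),
    stat = NA_character_
  )
  out <- bind_rows(
    if (hyperspectral) hs,
    if (lidar) ld,
    if (weather) wt
  )
  validate_catalog(out)
}

validate_catalog <- function(catalog) {
  catalog <- as_tibble(catalog)
  need <- c("name", "source", "type", "b1", "b2", "p1", "stat")
  if (!all(need %in% names(catalog))) {
    abort(sprintf("catalog lacks columns: %s",
                  paste(setdiff(need, names(catalog)), collapse = ", ")))
  }
  if (anyDuplicated(catalog$name)) {
    abort(sprintf("duplicate feature names in catalog: %s",
                  paste(unique(catalog$name[duplicated(catalog$name)]),
                        collapse = ", ")))
  }
  pct <- catalog$type == "percentile"
  if (any(pct) && !all(catalog$p1[pct] > 0 & catalog$p1[pct] <= 100)) {
    abort("percentile levels must lie in (0, 100]")
  }
  class(catalog) <- c("feature_catalog", class(tibble()))
  catalog
}

#' Read / write a feature catalog as YAML
#'
#' @param path File path.
#' @return `read_catalog()` returns a `feature_catalog`; `write_catalog()`
#'   returns `path` invisibly.
#' @export
read_catalog <- function(path) {
  rows <- yaml::read_yaml(path)
  validate_catalog(bind_rows(lapply(rows, function(r) {
    tibble(name = r$name, source = r$source, type = r$type,
           b1 = r$b1 %||% NA_real_, b2 = r$b2 %||% NA_real_,
           p1 = r$p1 %||% NA_real_, stat = r$stat %||% NA_character_)
  })))
}

#' @rdname read_catalog
#' @param catalog A `feature_catalog`.
#' @export
write_catalog <- function(catalog, path) {
  catalog <- validate_catalog(catalog)
  rows <- purrr::pmap(catalog, function(name, source, type, b1, b2, p1, stat) {
    r <- list(name = name, source = source, type = type)
    if (!is.na(b1)) r$b1 <- b1
    if (!is.na(b2)) r$b2 <- b2
    if (!is.na(p1)) r$p1 <- p1
    if (!is.na(stat)) r$stat <- stat
    r
  })
  yaml::write_yaml(rows, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
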