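# The plots x features x dates tensor consumed by the recurrent model.

new_feature_tensor <- function(values, plot_ids, features, dates, imputed) {
  stopifnot(length(dim(values)) == 3)
  structure(
    list(values = values, plot_ids = plot_ids, features = features,
         dates = dates, imputed = imputed),
    class = "feature_tensor"
  )
}

#' Assemble a feature tensor from long-format per-plot per-date values
#'
#' Builds the plots x features x dates array from a long table. Every
#' (plot, date) cell must carry the full hyperspectral and weather blocks;
#' LiDAR blocks may be missing for some dates (sparse LiDAR campaigns are
#' common) and are imputed by carrying the nearest available date's LiDAR
#' block for the same plot, with the imputed cells flagged.
#'
#' @param values Tibble with columns `plot_id`, `date`, `feature`, `value`.
#' @param records Plot records tibble (`plot_id`, `hybrid_id`, ...).
#' @param dates Dates tibble (`date`, plus any metadata such as `day`).
#' @param catalog Feature catalog fixing the feature order.
#' @return A `feature_tensor`: `values` (array), `plot_ids`, `features`
#'   (catalog rows present), `dates`, `imputed` (logical array).
#' @export
assemble_feature_tensor <- function(values, records, dates,
                                    catalog = default_catalog()) {
  catalog <- validate_catalog(catalog)
  feats <- filter(catalog, .data$name %in% unique(values$feature))
  plot_ids <- records$plot_id
  missing_plots <- setdiff(plot_ids, unique(values$plot_id))
  if (length(missing_plots) > 0) {
    abort(sprintf("plots present in records but absent from features: %s",
                  paste(head(missing_plots, 5), collapse = ", ")))
  }
  n_p <- length(plot_ids)
  n_f <- nrow(feats)
  n_d <- nrow(dates)
  arr <- array(NA_real_, c(n_p, n_f, n_d),
               dimnames = list(plot_ids, feats$name, dates$date))
  ip <- match(values$plot_id, plot_ids)
  jf <- match(values$feature, feats$name)
  kd <- match(values$date, dates$date)
  keep <- !is.na(ip) & !is.na(jf) & !is.na(kd)
  arr[cbind(ip[keep], jf[keep], kd[keep])] <- values$value[keep]

  imputed <- array(FALSE, dim(arr), dimnames = dimnames(arr))

  # Mandatory blocks must be complete.
  mandatory <- feats$source %in% c("hyperspectral", "weather")
  if (any(is.na(arr[, mandatory, , drop = FALSE]))) {
    idx <- which(is.na(arr[, mandatory, , drop = FALSE]), arr.ind = TRUE)
    abort(sprintf(
      "missing hyperspectral/weather values, e.g. plot %s feature %s date %s",
      plot_ids[idx[1, 1]], feats$name[mandatory][idx[1, 2]],
      dates$date[idx[1, 3]]))
  }

  # Carry-nearest-date imputation for missing LiDAR cells.
  lidar <- which(feats$source == "lidar")
  if (length(lidar) > 0 && anyNA(arr[, lidar, , drop = FALSE])) {
    for (i in seq_len(n_p)) {
      have <- which(vapply(seq_len(n_d), function(d) {
        !anyNA(arr[i, lidar, d])
      }, logical(1)))
      if (length(have) == 0) {
        abort(sprintf("plot %s has no LiDAR data on any date", plot_ids[i]))
      }
      for (d in setdiff(seq_len(n_d), have)) {
        src <- have[which.min(abs(have - d))]
        arr[i, lidar, d] <- arr[i, lidar, src]
        imputed[i, lidar, d] <- TRUE
      }
    }
  }
  new_feature_tensor(arr, plot_ids, feats, dates, imputed)
}

#' Extract the full feature tensor from a simulated (or loaded) trial
#'
#' Runs hyperspectral, LiDAR, and weather extraction over every plot and
#' date of a trial and assembles the result. Hyperspectral extraction is
#' vectorised across plot-dates for speed; values equal the per-spectrum
#' [extract_hyperspectral_features()] results.
#'
#' @param trial A `trial_data` object (see [simulate_trial()]).
#' @param catalog Feature catalog.
#' @param lidar_dates Optional integer subset of dates for which LiDAR is
#'   available (others are imputed by carrying the nearest date); default all.
#' @return A `feature_tensor`.
#' @examples
#' cfg <- sim_config(n_hybrids = 8, n_markers = 100, n_cal_hybrids = 4,
#'                   points_per_plot = 60, seed = 1)
#' trial <- simulate_trial(cfg, simulate_markers(cfg), simulate_weather(cfg))
#' tensor <- extract_features(trial)
#' dim(tensor$values)
#' @export
extract_features <- function(trial, catalog = default_catalog(),
                             lidar_dates = NULL) {
  catalog <- validate_catalog(catalog)
  wl <- spectral_grid()
  band_cols <- band_names(wl)
  stopifnot(all(band_cols %in% names(trial$spectra)))
  refl <- as.matrix(trial$spectra[band_cols])

  hs_mat <- extract_hs_matrix(wl, refl, catalog)
  hs_long <- as_tibble(hs_mat) %>%
    mutate(plot_id = trial$spectra$plot_id, date = trial$spectra$date) %>%
    tidyr::pivot_longer(-c("plot_id", "date"),
                        names_to = "feature", values_to = "value")

  ld_cat <- filter(catalog, .data$source == "lidar")
  ld_long <- NULL
  if (nrow(ld_cat) > 0) {
    clouds <- trial$clouds
    if (!is.null(lidar_dates)) {
      clouds <- filter(clouds, .data$date %in% lidar_dates)
    }
    defs <- lidar_defs(ld_cat)
    grp <- split(seq_len(nrow(clouds)),
                 list(plot = clouds$plot_id, date = clouds$date),
                 drop = TRUE, sep = "\r")
    vals <- vapply(grp, function(ii) {
      lidar_kernel(clouds$x[ii], clouds$y[ii], clouds$z[ii],
                   clouds$is_ground[ii], defs)
    }, numeric(length(defs)))
    keys <- do.call(rbind, strsplit(names(grp), "\r", fixed = TRUE))
    ld_long <- tibble(
      plot_id = rep(keys[, 1], each = length(defs)),
      date = as.integer(rep(keys[, 2], each = length(defs))),
      feature = rep(ld_cat$name, times = length(grp)),
      value = as.numeric(vals)
    )
  }

  wx_cat <- filter(catalog, .data$source == "weather")
  wx_long <- NULL
  if (nrow(wx_cat) > 0) {
    wx_long <- purrr::map_dfr(seq_len(nrow(trial$dates)), function(d) {
      v <- extract_weather_features(trial$weather, trial$dates$day[d], wx_cat)
      tibble(date = trial$dates$date[d], feature = names(v),
             value = as.numeric(v))
    }) %>%
      tidyr::crossing(plot_id = trial$records$plot_id)
  }

  values <- bind_rows(hs_long, ld_long, wx_long)
  dates <- trial$dates
  if (nrow(wx_cat) > 0 && "wx_gdd" %in% wx_cat$name) {
    gdd <- filter(values, .data$feature == "wx_gdd") %>%
      distinct(.data$date, .data$value)
    dates <- left_join(dates, rename(gdd, gdd = "value"), by = "date")
  }
  assemble_feature_tensor(values, trial$records, dates, catalog)
}

# Vectorised hyperspectral extraction: one matrix op per catalog feature
# across all plot-date rows. Kept numerically identical to the per-spectrum
# extractor (same nearest-band, trapezoid, finite-difference rules).
extract_hs_matrix <- function(wl, refl, catalog) {
  hs <- filter(catalog, .data$source == "hyperspectral")
  band <- function(w) refl[, nearest_index(wl, w)]
  out <- matrix(NA_real_, nrow(refl), nrow(hs),
                dimnames = list(NULL, hs$name))
  for (i in seq_len(nrow(hs))) {
    row <- hs[i, ]
    out[, i] <- switch(row$type,
      nd_index = {
        a <- band(row$b1); b <- band(row$b2)
        ifelse(a + b == 0, 0, (a - b) / (a + b))
      },
      ratio = band(row$b1) / band(row$b2),
      ci = band(row$b1) / band(row$b2) - 1,
      savi = {
        a <- band(row$b1); b <- band(row$b2)
        (1 + row$p1) * (a - b) / (a + b + row$p1)
      },
      evi2 = {
        a <- band(row$b1); b <- band(row$b2)
        2.5 * (a - b) / (a + 2.4 * b + 1)
      },
      integration = {
        keep <- which(wl >= row$b1 & wl <= row$b2)
        w <- trapz_weights(wl[keep])
        as.numeric(refl[, keep, drop = FALSE] %*% w)
      },
      derivative = {
        j <- min(max(nearest_index(wl, row$b1), 2L), length(wl) - 1L)
        h1 <- wl[j] - wl[j - 1]; h2 <- wl[j + 1] - wl[j]
        if (row$p1 == 1) {
          (refl[, j + 1] - refl[, j - 1]) / (h1 + h2)
        } else {
          2 * (h1 * refl[, j + 1] - (h1 + h2) * refl[, j] +
                 h2 * refl[, j - 1]) / (h1 * h2 * (h1 + h2))
        }
      },
      abort(sprintf("unknown hyperspectral feature type `%s`", row$type))
    )
  }
  out
}

trapz_weights <- function(x) {
  n <- length(x)
  if (n < 2) return(rep(0, n))
  w <- numeric(n)
  dx <- diff(x)
  w[1] <- dx[1] / 2
  w[n] <- dx[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dx[-(n - 1)] + dx[-1]) / 2
  w
}

#' Drop features from a tensor
#'
#' @param tensor A `feature_tensor`.
#' @param drop Character vector of feature names to remove (e.g. the
#'   redundant set from [majority_vote_redundant()]).
#' @return The tensor with those feature slabs removed; survivor order
#'   preserved.
#' @export
drop_features <- function(tensor, drop) {
  stopifnot(inherits(tensor, "feature_tensor"))
  if (length(drop) == 0) return(tensor)
  unknown <- setdiff(drop, tensor$features$name)
  if (length(unknown) > 0) {
    abort(sprintf("unknown feature name(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  keep <- !(tensor$features$name %in% drop)
  new_feature_tensor(
    tensor$values[, keep, , drop = FALSE], tensor$plot_ids,
    tensor$features[keep, ], tensor$dates,
    tensor$imputed[, keep, , drop = FALSE]
  )
}

#' @export
print.feature_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<feature_tensor> %d plots x %d features x %d dates\n",
              d[1], d[2], d[3]))
  src <- table(x$features$source)
  cat("  features:", paste(sprintf("%s %d", names(src), src), collapse = ", "),
      "\n")
  if (any(x$imputed)) {
    cat(sprintf("  imputed cells: %d\n", sum(x$imputed)))
  }
  invisible(x)
}

#' Tidy a feature tensor into long format
#'
#' @param x A `feature_tensor`.
#' @param ... Unused.
#' @return Tibble with `plot_id`, `date`, `feature`, `source`, `value`,
#'   `imputed`.
#' @export
tidy.feature_tensor <- function(x, ...) {
  d <- dim(x$values)
  tibble(
    plot_id = rep(x$plot_ids, times = d[2] * d[3]),
    feature = rep(rep(x$features$name, each = d[1]), times = d[3]),
    source = rep(rep(x$features$source, each = d[1]), times = d[3]),
    date = rep(x$dates$date, each = d[1] * d[2]),
    value = as.numeric(x$values),
    imputed = as.logical(x$imputed)
  )
}

# Flatten to plots x (features * dates), used by phenotype selection.
flatten_tensor <- function(tensor) {
  d <- dim(tensor$values)
  m <- matrix(tensor$values, nrow = d[1])
  rownames(m) <- tensor$plot_ids
  colnames(m) <- as.vector(outer(tensor$features$name, tensor$dates$date,
                                 paste, sep = "@"))
  m
}
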