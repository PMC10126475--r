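# Synthetic breeding-trial generator.
#
# One latent logistic growth curve per plot drives (i) canopy point-cloud
# heights and cover per date, (ii) plot-mean reflectance through a
# two-endmember soil/vegetation linear mixing model, and (iii) end-of-season
# fresh biomass through the season-mean canopy height. A genotype-cluster
# biomass effect is added on top of growth (emulating, e.g., photoperiod
# driven late accumulation the canopy signal does not express), which is
# what makes genotype-blind models under-predict high-yielding plots.

# Reserved NIR-edge windows used for planted redundant features: flat
# detector-edge plateau plus a shared per-pair drift latent, no canopy
# signal. The default feature catalog integrates over exactly these windows.
redundant_windows <- function() {
  list(
    hs_int_905_925 = c(905, 925),
    hs_int_930_950 = c(930, 950),
    hs_int_955_975 = c(955, 975),
    hs_int_980_1000 = c(980, 1000)
  )
}

redundant_parent_map <- function(n_planted) {
  nm <- names(redundant_windows())[seq_len(n_planted)]
  if (n_planted == 0) return(character(0))
  setNames(nm[c(2, 1, 4, 3)][seq_len(n_planted)], nm)
}

# Hybrid-level genetic latents, shared across every trial (same hybrid, same
# growth potential). Drawn from the `hybrids` substream of the master seed.
hybrid_latents <- function(config) {
  with_substream(config$seed, "hybrids", {
    n <- config$n_hybrids
    len <- config$season_length
    tibble(
      hybrid_id = hybrid_ids(n),
      subpop = rep(seq_len(config$n_subpops), length.out = n),
      growth = 1 + config$hybrid_sd * rnorm(n),
      rate_tau = len * 0.09 * (1 + 0.08 * rnorm(n)),
      t_mid = len * 0.45 * (1 + 0.06 * rnorm(n)),
      roughness = pmax(0.5, 1 + 1.2 * (growth - 1) + 0.08 * rnorm(n))
    )
  })
}

# Deterministic representative calibration subset: hybrids sorted by hidden
# subpopulation, then evenly spaced, so every subpopulation is covered
# proportionally (mirrors a breeder picking a representative panel).
cal_hybrid_set <- function(config) {
  lat <- hybrid_latents(config)
  ord <- lat$hybrid_id[order(lat$subpop, lat$hybrid_id)]
  ord[unique(round(seq(1, length(ord), length.out = config$n_cal_hybrids)))]
}

#' Simulate one breeding trial (plots, spectra, point clouds, biomass)
#'
#' Generates a full trial panel: plot records, per-plot per-date mean
#' reflectance spectra (272 bands, 400-1000 nm), labelled 3D point clouds,
#' and end-of-season fresh biomass, together with the hidden truth needed by
#' oracle tests (growth parameters, subpopulation labels, planted redundant
#' features). A target-domain trial is produced with `apply_shift = TRUE`,
#' which applies the configured affine shift to reflectance and canopy
#' heights and the configured affine shift to biomass.
#'
#' @param config A [sim_config()].
#' @param markers A [simulate_markers()] result; plot hybrids are drawn from
#'   its rownames.
#' @param weather A [simulate_weather()] series for the season.
#' @param panel `"tc"` (all hybrids, `tc_replicates` reps) or `"cal"` (the
#'   representative calibration subset, `cal_replicates` reps).
#' @param trial_id Label for the trial (default `"Tc-1"`/`"Cal-1"`); also
#'   names the random substream, so distinct labels give independent trials.
#' @param year Year label stored in the plot records.
#' @param apply_shift Apply the configured target-domain shift?
#' @return A `trial_data` list: `records`, `spectra` (wide, one row per
#'   plot-date), `clouds`, `biomass`, `dates`, `weather`, `truth`.
#' @examples
#' cfg <- sim_config(n_hybrids = 12, n_markers = 100, n_cal_hybrids = 6,
#'                   points_per_plot = 60, seed = 1)
#' trial <- simulate_trial(cfg, simulate_markers(cfg), simulate_weather(cfg))
#' trial
#' @export
simulate_trial <- function(config, markers, weather,
                           panel = c("tc", "cal"),
                           trial_id = NULL, year = 2019L,
                           apply_shift = FALSE) {
  validate_sim_config(config)
  panel <- match.arg(panel)
  if (is.null(trial_id)) trial_id <- if (panel == "tc") "Tc-1" else "Cal-1"
  lat <- hybrid_latents(config)

  hyb <- if (panel == "tc") rownames(markers) else cal_hybrid_set(config)
  if (!all(hyb %in% rownames(markers))) {
    missing <- setdiff(hyb, rownames(markers))
    abort(sprintf("panel hybrids absent from marker matrix: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  reps <- if (panel == "tc") config$tc_replicates else config$cal_replicates

  len <- config$season_length
  n_dates <- config$n_dates
  obs_day <- round(seq(0.28, 0.95, length.out = n_dates) * len)
  dates <- tibble(date = seq_len(n_dates), day = obs_day,
                  doy = config$sowing_doy + obs_day - 1L)

  records <- tibble(
    trial = trial_id, year = as.integer(year),
    hybrid_id = rep(hyb, each = reps),
    replicate = rep(seq_len(reps), times = length(hyb))
  ) %>%
    mutate(plot_id = sprintf("%s_P%04d", trial_id, dplyr::row_number())) %>%
    select("trial", "year", "plot_id", "hybrid_id", "replicate")

  n_p <- nrow(records)
  idx <- match(records$hybrid_id, lat$hybrid_id)

  with_substream(config$seed, paste0("trial:", trial_id), {
    env <- config$env_effect * rnorm(1)
    gxe <- config$gxe_scale * rnorm(length(hyb))
    gxe_plot <- gxe[match(records$hybrid_id, hyb)]
    plot_sd <- 0.03 * min(1, config$biomass_noise / 150)
    plot_mult <- 1 + plot_sd * rnorm(n_p)

    h_max <- 2.6 * lat$growth[idx] * plot_mult
    tau <- lat$rate_tau[idx]
    t_mid <- lat$t_mid[idx]

    # plots x dates canopy height, and season-mean height for biomass
    h_pd <- vapply(obs_day, function(d) {
      h_max * stats::plogis((d - t_mid) / tau)
    }, numeric(n_p))
    season_days <- seq_len(len)
    mean_h <- h_max * vapply(seq_len(n_p), function(i) {
      mean(stats::plogis((season_days - t_mid[i]) / tau[i]))
    }, numeric(1))
    cover_pd <- 1 - exp(-h_pd / 1.1)

    spectra <- sim_spectra(config, records, dates, cover_pd)
    clouds <- sim_clouds(config, records, dates, h_pd, cover_pd,
                         lat$roughness[idx])

    beta <- if (config$n_subpops == 1) 0 else {
      config$subpop_effect * seq(-1, 1, length.out = config$n_subpops)
    }
    biomass_val <- 400 + 1400 * mean_h +
      beta[lat$subpop[idx]] + env + gxe_plot +
      config$biomass_noise * rnorm(n_p)
    biomass_val <- pmax(biomass_val, 50)

    if (apply_shift) {
      m <- config$shift_feature_mult
      band_cols <- setdiff(names(spectra), c("plot_id", "date"))
      spectra[band_cols] <- spectra[band_cols] * (1 + m) +
        config$shift_feature_add
      clouds$z <- ifelse(clouds$is_ground, clouds$z, clouds$z * (1 + m))
      biomass_val <- biomass_val * (1 + config$shift_biomass_mult) +
        config$shift_biomass_add
    }

    biomass <- tibble(
      plot_id = records$plot_id,
      fresh_biomass = biomass_val,
      harvest_doy = config$sowing_doy + len - 1L
    )

    n_red <- config$n_redundant_features
    truth <- list(
      subpop = setNames(lat$subpop, lat$hybrid_id),
      hybrid_latents = lat,
      env_effect = env,
      subpop_beta = beta,
      mean_height = setNames(mean_h, records$plot_id),
      canopy_height = h_pd,
      redundant_features = names(redundant_windows())[seq_len(n_red)],
      redundant_parent = redundant_parent_map(n_red)
    )

    structure(
      list(records = records, spectra = spectra, clouds = clouds,
           biomass = biomass, dates = dates, weather = weather,
           truth = truth, config = config, trial_id = trial_id,
           panel = panel, shifted = apply_shift),
      class = "trial_data"
    )
  })
}

# Plot-mean reflectance via linear soil/vegetation mixing. Latent factors
# give every catalog feature a within-date signal: chlorophyll (green bump
# and red trough), red-edge position, NIR plateau amplitude, soil
# brightness, and a xanthophyll-like wiggle at 531 nm; band-correlated
# smooth noise on top. Planted redundant windows are overwritten with a
# flat detector-edge plateau plus a per-campaign (per-date) calibration
# drift shared within each pair: pooled over dates the pair members are
# near-duplicates (corr > 0.95), while within a date they carry only
# independent low-amplitude noise and no canopy signal.
sim_spectra <- function(config, records, dates, cover_pd) {
  wl <- spectral_grid()
  n_b <- length(wl)
  n_p <- nrow(records)
  n_d <- nrow(dates)
  n_pd <- n_p * n_d
  ns <- config$spectral_noise

  # Latents per plot-date (rows ordered plot-major within date blocks).
  # Factor amplitudes vary by date: the physiological drivers of canopy
  # reflectance differ across growth stages, so which features dominate a
  # date's variance changes over the season.
  dd <- rep(seq_len(n_d), each = n_p)
  stage <- function(scale) pmax(0.6, exp(scale * rnorm(n_d)))[dd]
  chl <- 1 + 0.18 * stage(0.5) * rnorm(n_pd)
  nirstr <- 1 + 0.12 * stage(0.4) * rnorm(n_pd)
  soilbr <- 1 + 0.12 * stage(0.4) * rnorm(n_pd)
  re_shift <- 4 * stage(0.5) * rnorm(n_pd)
  xanth <- 0.8 * (chl - 1) / 0.18 + 0.6 * stage(0.5) * rnorm(n_pd)

  green <- exp(-((wl - 550) / 30)^2)
  trough <- exp(-((wl - 670) / 22)^2)
  x531 <- exp(-((wl - 531) / 8)^2)
  soil_base <- 0.10 + 0.00025 * (wl - 400)

  vis <- 0.035 + outer(0.05 * (2 - chl), green) -
    outer(0.045 * (chl - 1), trough) + outer(0.045 * xanth, x531)
  # per-row red-edge sigmoid position
  arg <- (matrix(wl, n_pd, n_b, byrow = TRUE) - 715 - re_shift) / 12
  red_edge <- stats::plogis(arg)
  nir <- 0.42 * nirstr
  veg <- vis * (1 - red_edge) + nir * red_edge
  soil <- outer(soilbr, soil_base)

  f <- pmin(as.vector(cover_pd), 0.97)  # plot-major per date block
  refl <- sweep(veg, 1, f, `*`) + sweep(soil, 1, 1 - f, `*`)

  if (ns > 0) {
    raw <- matrix(rnorm(n_pd * n_b), n_pd)
    sm <- t(apply(raw, 1, function(z) {
      as.numeric(stats::filter(z, rep(1 / 5, 5), sides = 2, circular = TRUE))
    }))
    refl <- refl + ns * sm * sqrt(5)
  }

  # planted redundant windows: flat plateau + per-date pair drift +
  # independent per-plot noise
  n_red <- config$n_redundant_features
  if (n_red > 0) {
    wins <- redundant_windows()[seq_len(n_red)]
    pair_of <- c(1, 1, 2, 2)
    date_drift <- matrix(rnorm(2 * n_d, sd = 0.12), nrow = n_d)
    date_of_row <- rep(seq_len(n_d), each = n_p)
    for (j in seq_along(wins)) {
      in_win <- wl >= wins[[j]][1] & wl <= wins[[j]][2]
      plot_noise <- rnorm(n_pd, sd = 0.004)
      band_noise <- matrix(rnorm(n_pd * sum(in_win), sd = 0.002), n_pd)
      refl[, in_win] <- 0.38 + date_drift[date_of_row, pair_of[j]] +
        plot_noise + band_noise
    }
  }
  refl <- pmin(pmax(refl, 0), 1.2)

  colnames(refl) <- band_names(wl)
  out <- tibble(
    plot_id = rep(records$plot_id, times = n_d),
    date = rep(dates$date, each = n_p)
  )
  dplyr::bind_cols(out, as_tibble(refl)) %>% arrange(.data$plot_id, .data$date)
}

#' The simulated hyperspectral wavelength grid
#'
#' @return 272 wavelengths (nm) evenly spanning 400-1000 nm.
#' @export
spectral_grid <- function() seq(400, 1000, length.out = 272)

band_names <- function(wl) sprintf("wl_%07.2f", wl)

# Plot-level point clouds: ground points near z = 0, canopy heights on a
# deterministic beta-quantile grid scaled by the plot's current canopy
# height, plus structural jitter. With structural_noise = 0 the height grid
# is deterministic, so canopy percentiles are exactly monotone in growth.
sim_clouds <- function(config, records, dates, h_pd, cover_pd, rough) {
  n_p <- nrow(records)
  n_tot <- config$points_per_plot
  sn <- config$structural_noise
  # per-plot-date canopy-shape latents (top-heaviness, spread, point
  # fraction); amplitudes scale with the structural-noise knob so that the
  # zero-noise cloud is fully deterministic
  amp <- min(1, sn / 0.03)
  pieces <- vector("list", n_p * nrow(dates))
  k <- 0L
  for (d in seq_len(nrow(dates))) {
    # stage-dependent emphasis of the canopy-shape factors
    w <- pmax(0.6, exp(0.4 * rnorm(3)))
    s1 <- exp(0.18 * amp * w[1] * rnorm(n_p))
    s2 <- exp(0.18 * amp * w[2] * rnorm(n_p))
    s3 <- exp(0.12 * amp * w[3] * rnorm(n_p))
    for (i in seq_len(n_p)) {
      k <- k + 1L
      f <- cover_pd[i, d]
      n_can <- max(5L, round(n_tot * min(0.95, (0.15 + 0.75 * f) * s3[i])))
      n_gnd <- max(10L, n_tot - n_can)
      h <- h_pd[i, d]
      qs <- (seq_len(n_can) - 0.5) / n_can
      z_can <- h * qbeta(qs, shape1 = 2.5 * rough[i] * s1[i],
                         shape2 = 1.6 * s2[i])
      z_gnd <- c(0, 0.25 * sn * abs(rnorm(n_gnd - 1)))
      if (sn > 0) z_can <- pmax(z_can + sn * rnorm(n_can), 0)
      n_all <- n_can + n_gnd
      pieces[[k]] <- tibble(
        plot_id = records$plot_id[i],
        date = dates$date[d],
        x = runif(n_all, 0, 3),
        y = runif(n_all, 0, 1),
        z = c(z_gnd, z_can),
        is_ground = rep(c(TRUE, FALSE), c(n_gnd, n_can))
      )
    }
  }
  bind_rows(pieces)
}

#' @export
print.trial_data <- function(x, ...) {
  cat(sprintf("<trial_data> %s (%s panel%s)\n", x$trial_id, x$panel,
              if (isTRUE(x$shifted)) ", domain-shifted" else ""))
  cat(sprintf("  %d plots x %d dates; %d hybrids\n",
              nrow(x$records), nrow(x$dates),
              dplyr::n_distinct(x$records$hybrid_id)))
  cat(sprintf("  biomass: mean %.0f g/m^2 (sd %.0f)\n",
              mean(x$biomass$fresh_biomass), sd(x$biomass$fresh_biomass)))
  invisible(x)
}
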