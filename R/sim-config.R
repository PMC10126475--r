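#' Configuration for the synthetic breeding-trial simulator
#'
#' Bundles every knob of the simulator: panel layout, marker model, season,
#' effect sizes, noise scales, planted feature redundancy and the
#' between-trial domain shift. Defaults mirror the layout of a large
#' sorghum testcross experiment: a `Tc` panel of 630 hybrids with two
#' replicates and a `Cal` panel of 72 hybrids drawn from the same set,
#' observed on four dates across the season.
#'
#' @param n_hybrids Number of hybrid genotypes in the experiment (default 630).
#' @param n_markers Number of biallelic markers per hybrid (default 2000; the
#'   genotype-clustering behaviour is width-invariant, so the simulator uses
#'   a desk-scale marker panel rather than a full genome-wide set).
#' @param n_subpops Number of latent marker subpopulations (default 5).
#' @param marker_fst Differentiation between subpopulations on the Wright
#'   fixation-index scale, in `[0, 1)` (default 0.3, strong structure of the
#'   kind breeding heterotic groups show).
#' @param tc_replicates Replicates per hybrid in the testcross panel (default 2).
#' @param n_cal_hybrids Size of the calibration subset (default 72); must be
#'   `<= n_hybrids`.
#' @param cal_replicates Replicates per hybrid in the calibration panel
#'   (default 2).
#' @param n_dates Number of remote-sensing observation dates (default 4).
#' @param sowing_doy Sowing day of year (default 140, late May).
#' @param season_length Days from sowing to harvest (default 110).
#' @param subpop_effect Standard scale (g/m^2) of the genotype-cluster biomass
#'   effect that is *not* expressed in canopy growth, e.g. photoperiod-driven
#'   late biomass accumulation (default 400).
#' @param env_effect Scale of the per-trial environment effect on biomass
#'   (g/m^2, default 150).
#' @param gxe_scale Scale of genotype-by-environment biomass noise
#'   (g/m^2, default 100).
#' @param hybrid_sd Relative sd of hybrid growth potential (default 0.12).
#' @param spectral_noise Band-correlated reflectance noise sd (default 0.008).
#' @param structural_noise Point-cloud height jitter sd in m (default 0.04).
#' @param biomass_noise Residual plot-level biomass noise sd (g/m^2,
#'   default 150).
#' @param weather_noise Daily weather noise scale in degrees C (default 1.5);
#'   0 gives a fully deterministic smooth series.
#' @param n_redundant_features Number of planted redundant spectral features:
#'   0, 2 or 4 (default 4). Planted in pairs of NIR-edge windows that share a
#'   low-amplitude drift latent and carry no canopy signal.
#' @param points_per_plot Points per plot-level point cloud (default 400).
#' @param shift_feature_add Additive reflectance shift applied to
#'   target-domain spectra (default 0.02).
#' @param shift_feature_mult Multiplicative reflectance/height shift applied
#'   to target-domain sensor data (default 0.10, i.e. scale by 1.10).
#' @param shift_biomass_add Additive biomass shift for the target domain
#'   (g/m^2, default 150).
#' @param shift_biomass_mult Multiplicative biomass shift for the target
#'   domain (default 0.20, i.e. scale by 1.20).
#' @param seed Master integer seed; all randomness flows from it through
#'   named substreams (`markers`, `weather`, one per trial).
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_hybrids = 60, n_markers = 300, seed = 1)
#' cfg$n_subpops
#' @export
sim_config <- function(n_hybrids = 630,
                       n_markers = 2000,
                       n_subpops = 5,
                       marker_fst = 0.3,
                       tc_replicates = 2,
                       n_cal_hybrids = 72,
                       cal_replicates = 2,
                       n_dates = 4,
                       sowing_doy = 140,
                       season_length = 110,
                       subpop_effect = 400,
                       env_effect = 150,
                       gxe_scale = 100,
                       hybrid_sd = 0.12,
                       spectral_noise = 0.008,
                       structural_noise = 0.03,
                       biomass_noise = 150,
                       weather_noise = 1.5,
                       n_redundant_features = 4,
                       points_per_plot = 400,
                       shift_feature_add = 0.02,
                       shift_feature_mult = 0.10,
                       shift_biomass_add = 150,
                       shift_biomass_mult = 0.20,
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  chk_count <- function(field, min = 1) {
    v <- cfg[[field]]
    check_that(is.numeric(v) && length(v) == 1L && v >= min && v == round(v),
               field, sprintf("must be an integer >= %d", min))
  }
  chk_scale <- function(field) {
    v <- cfg[[field]]
    check_that(is.numeric(v) && length(v) == 1L && is.finite(v) && v >= 0,
               field, "must be a finite non-negative scale")
  }
  chk_count("n_hybrids", 2)
  chk_count("n_markers", 10)
  chk_count("n_subpops", 1)
  chk_count("tc_replicates", 1)
  chk_count("n_cal_hybrids", 1)
  chk_count("cal_replicates", 1)
  chk_count("n_dates", 2)
  chk_count("sowing_doy", 1)
  chk_count("season_length", 2)
  chk_count("points_per_plot", 20)
  check_that(cfg$n_cal_hybrids <= cfg$n_hybrids, "n_cal_hybrids",
             "calibration hybrids must be a subset of the hybrid set")
  check_that(cfg$n_markers >= 10 * cfg$n_subpops, "n_markers",
             "need at least 10 markers per subpopulation")
  check_that(cfg$season_length >= cfg$n_dates, "season_length",
             "season must cover the observation dates")
  check_that(is.numeric(cfg$marker_fst) && cfg$marker_fst >= 0 &&
               cfg$marker_fst < 1, "marker_fst", "must be in [0, 1)")
  for (f in c("subpop_effect", "env_effect", "gxe_scale", "hybrid_sd",
              "spectral_noise", "structural_noise", "biomass_noise",
              "weather_noise", "shift_feature_add", "shift_feature_mult",
              "shift_biomass_add", "shift_biomass_mult")) {
    chk_scale(f)
  }
  check_that(cfg$n_redundant_features %in% c(0, 2, 4), "n_redundant_features",
             "planted redundancy comes in pairs: 0, 2 or 4")
  check_that(is.numeric(cfg$seed) && length(cfg$seed) == 1L &&
               is.finite(cfg$seed), "seed", "must be a single integer")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  panels: Tc %d hybrids x %d reps; Cal %d hybrids x %d reps\n",
              x$n_hybrids, x$tc_replicates, x$n_cal_hybrids, x$cal_replicates))
  cat(sprintf("  markers: %d (%d subpops, Fst %.2f)\n",
              x$n_markers, x$n_subpops, x$marker_fst))
  cat(sprintf("  season: sown doy %d, %d days, %d observation dates\n",
              x$sowing_doy, x$season_length, x$n_dates))
  cat(sprintf("  seed: %s\n", format(x$seed)))
  invisible(x)
}
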