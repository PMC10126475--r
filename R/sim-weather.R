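#' Simulate a daily weather series for one growing season
#'
#' Produces a contiguous daily series from sowing to harvest with a smooth
#' mid-summer temperature arc, sparse gamma-distributed precipitation
#' events, and solar radiation following day length with cloud-day dips.
#' With `weather_noise = 0` the series is fully deterministic (no
#' precipitation events, smooth trends), which several invariant tests rely
#' on.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per day: `day` (1-based day of season),
#'   `doy`, `t_min`, `t_max` (degrees C), `precipitation` (mm),
#'   `radiation` (MJ/m^2).
#' @examples
#' w <- simulate_weather(sim_config(n_hybrids = 20, n_markers = 100, seed = 1))
#' head(w)
#' @export
simulate_weather <- function(config) {
  validate_sim_config(config)
  with_substream(config$seed, "weather", {
    len <- config$season_length
    day <- seq_len(len)
    doy <- config$sowing_doy + day - 1L
    ns <- config$weather_noise

    # Seasonal mean temperature: warm arc peaking ~40% into the season.
    frac <- (day - 1) / max(len - 1, 1)
    t_mean <- 19 + 8 * sin(pi * (0.15 + 0.8 * frac)) + ns * rnorm(len)
    spread <- pmax(4, 10 + ns * rnorm(len))
    t_min <- t_mean - spread / 2
    t_max <- t_mean + spread / 2

    precip <- if (ns > 0) {
      rbinom(len, 1L, 0.25) * rgamma(len, shape = 1.2, scale = 8)
    } else {
      rep(0, len)
    }

    radiation <- pmax(
      1,
      20 + 6 * sin(pi * (0.2 + 0.7 * frac)) - 6 * (precip > 0) +
        ns * rnorm(len)
    )

    tibble(
      day = day, doy = doy,
      t_min = t_min, t_max = t_max,
      precipitation = precip, radiation = radiation
    )
  })
}
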