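test_that("config validation names the offending field", {
  expect_error(sim_config(n_hybrids = 1), "n_hybrids")
  expect_error(sim_config(n_cal_hybrids = 999), "n_cal_hybrids")
  expect_error(sim_config(n_markers = 20, n_subpops = 5), "n_markers")
  expect_error(sim_config(spectral_noise = -1), "spectral_noise")
  expect_error(sim_config(n_redundant_features = 3), "n_redundant_features")
})

test_that("marker simulation is deterministic and carries hidden structure", {
  cfg <- tiny_config(seed = 3)
  m1 <- simulate_markers(cfg)
  m2 <- simulate_markers(cfg)
  expect_identical(unclass(m1), unclass(m2))
  expect_true(all(m1 %in% 0:2))
  expect_equal(dim(m1), c(24, 120))
  expect_equal(sort(unique(attr(m1, "subpop"))), 1:3)

  # changing only the seed changes the draw
  m3 <- simulate_markers(tiny_config(seed = 4))
  expect_false(identical(unclass(m1), unclass(m3)))
})

test_that("single subpopulation yields no decisive elbow", {
  cfg <- tiny_config(seed = 5, n_subpops = 1)
  m <- simulate_markers(cfg)
  expect_true(all(attr(m, "subpop") == 1))
  proj <- marker_pca(m, n_components = 5)
  flat <- elbow_select(wcss_curve(proj, k_range = 1:6, seed = 1))

  # same panel with real subpopulation structure: a far more prominent elbow
  m3 <- simulate_markers(tiny_config(seed = 5))
  proj3 <- marker_pca(m3, n_components = 5)
  sharp <- elbow_select(wcss_curve(proj3, k_range = 1:6, seed = 1))
  expect_gt(attr(sharp, "prominence"), 2 * attr(flat, "prominence"))
})

test_that("weather series honors its invariants for every day", {
  w <- simulate_weather(tiny_config(seed = 11))
  expect_true(all(w$t_min <= w$t_max))
  expect_true(all(w$precipitation >= 0))
  expect_true(all(w$radiation >= 0))
  expect_equal(w$day, seq_len(nrow(w)))

  # zero noise scale -> fully deterministic smooth series, no rain events
  cfg0 <- tiny_config(seed = 12, weather_noise = 0)
  w0a <- simulate_weather(cfg0)
  w0b <- simulate_weather(tiny_config(seed = 99, weather_noise = 0))
  expect_identical(w0a$t_min, w0b$t_min)
  expect_true(all(w0a$precipitation == 0))
})

test_that("trial data is reproducible field by field under a fixed seed", {
  cfg <- tiny_config(seed = 21)
  mk <- simulate_markers(cfg)
  wx <- simulate_weather(cfg)
  t1 <- simulate_trial(cfg, mk, wx)
  t2 <- simulate_trial(cfg, mk, wx)
  expect_identical(t1$spectra, t2$spectra)
  expect_identical(t1$clouds, t2$clouds)
  expect_identical(t1$biomass, t2$biomass)
})

test_that("replicates of a hybrid are identical when noise and effects vanish", {
  cfg <- tiny_config(seed = 31, biomass_noise = 0, gxe_scale = 0,
                     subpop_effect = 0, env_effect = 0)
  tr <- simulate_trial(cfg, simulate_markers(cfg), simulate_weather(cfg))
  by_hyb <- split(tr$biomass$fresh_biomass, tr$records$hybrid_id)
  spread <- vapply(by_hyb, function(v) diff(range(v)), numeric(1))
  expect_true(all(spread < 1e-9))
})

test_that("replicate biomass correlates more within hybrids than between", {
  tr <- tiny_trial()$trial
  df <- dplyr::left_join(tr$biomass, tr$records, by = "plot_id")
  wide <- tidyr::pivot_wider(df[c("hybrid_id", "replicate", "fresh_biomass")],
                             names_from = "replicate",
                             values_from = "fresh_biomass")
  within_cor <- cor(wide$`1`, wide$`2`)
  between_cor <- cor(wide$`1`[-1], wide$`2`[-nrow(wide)])
  expect_gt(within_cor, between_cor)
  expect_gt(within_cor, 0.5)
})

test_that("canopy p95 is non-decreasing over dates when structural noise is 0", {
  cfg <- tiny_config(seed = 41, structural_noise = 0)
  tr <- simulate_trial(cfg, simulate_markers(cfg), simulate_weather(cfg))
  p95 <- tr$clouds %>%
    dplyr::filter(!is_ground) %>%
    dplyr::group_by(plot_id, date) %>%
    dplyr::summarise(p95 = quantile(z, 0.95), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = date, values_from = p95)
  mono <- apply(as.matrix(p95[-1]), 1, function(v) all(diff(v) >= -1e-9))
  expect_true(all(mono))
})

test_that("planted redundant features correlate > 0.95 with their partner", {
  tt <- tiny_trial()
  v <- tt$tensor$values
  parents <- tt$trial$truth$redundant_parent
  for (f in names(parents)) {
    r <- cor(as.vector(v[, f, ]), as.vector(v[, parents[[f]], ]))
    expect_gt(abs(r), 0.95)
  }
  # and they carry no canopy-growth signal
  r_growth <- cor(as.vector(v[, "hs_int_905_925", ]),
                  as.vector(v[, "hs_ndvi", ]))
  expect_lt(abs(r_growth), 0.9)
})

test_that("doubling the subpop effect scales the between-cluster variance 4x", {
  var_between <- function(effect) {
    cfg <- sim_config(n_hybrids = 200, n_markers = 120, n_subpops = 4,
                      n_cal_hybrids = 10, points_per_plot = 60,
                      tc_replicates = 1, subpop_effect = effect,
                      biomass_noise = 20, gxe_scale = 0, hybrid_sd = 0.02,
                      seed = 51)
    mk <- simulate_markers(cfg)
    tr <- simulate_trial(cfg, mk, simulate_weather(cfg))
    sp <- tr$truth$subpop[tr$records$hybrid_id]
    means <- tapply(tr$biomass$fresh_biomass, sp, mean)
    var(as.numeric(means))
  }
  v0 <- var_between(0)
  v1 <- var_between(300)
  v2 <- var_between(600)
  ratio <- (v2 - v0) / (v1 - v0)
  expect_gt(ratio, 3)
  expect_lt(ratio, 5)
})

test_that("zero domain shift leaves source and target distributions alike", {
  hits <- 0
  for (s in 1:8) {
    # per-trial environment effects are part of the generative model and
    # shift whole-trial means regardless of the domain-shift knob; hold them
    # at zero so the test isolates that knob
    cfg <- sim_config(n_hybrids = 40, n_markers = 120, n_subpops = 3,
                      n_cal_hybrids = 10, points_per_plot = 60,
                      env_effect = 0,
                      shift_feature_add = 0, shift_feature_mult = 0,
                      shift_biomass_add = 0, shift_biomass_mult = 0,
                      seed = 60 + s)
    mk <- simulate_markers(cfg)
    wx <- simulate_weather(cfg)
    a <- simulate_trial(cfg, mk, wx, trial_id = "A")
    b <- simulate_trial(cfg, mk, wx, trial_id = "B", apply_shift = TRUE)
    p <- t.test(a$biomass$fresh_biomass, b$biomass$fresh_biomass)$p.value
    hits <- hits + (p > 0.01)
  }
  expect_gte(hits, 7)
})

test_that("default domain shift moves target biomass upward", {
  cfg <- tiny_config(seed = 71)
  mk <- simulate_markers(cfg)
  wx <- simulate_weather(cfg)
  a <- simulate_trial(cfg, mk, wx, trial_id = "T1")
  b <- simulate_trial(cfg, mk, wx, trial_id = "T1", apply_shift = TRUE)
  expect_gt(mean(b$biomass$fresh_biomass), mean(a$biomass$fresh_biomass))
})

test_that("calibration panel is a representative subset of the hybrid set", {
  tt <- tiny_trial()
  cal <- simulate_trial(tt$cfg, tt$markers, tt$weather, panel = "cal")
  cal_hyb <- unique(cal$records$hybrid_id)
  expect_length(cal_hyb, tt$cfg$n_cal_hybrids)
  expect_true(all(cal_hyb %in% rownames(tt$markers)))
  # covers every hidden subpopulation
  expect_setequal(unique(tt$trial$truth$subpop[cal_hyb]),
                  unique(attr(tt$markers, "subpop")))
})
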