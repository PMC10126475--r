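test_that("genomic selection matches the calibration panel exactly", {
  recs <- tibble::tibble(
    plot_id = sprintf("P%03d", 1:20),
    hybrid_id = rep(sprintf("H%02d", 1:10), each = 2)
  )
  cal <- sprintf("H%02d", 1:4)
  sel <- select_genomic(recs, cal)
  expect_equal(nrow(sel$selected), 8)  # 4 hybrids x 2 reps, nothing held out
  expect_true(all(sel$selected$hybrid_id %in% cal))

  # with held-out test plots, selection is drawn only from the rest
  test_ids <- c("P001", "P003")
  sel2 <- select_genomic(recs, cal, test_ids)
  expect_length(intersect(sel2$selected$plot_id, test_ids), 0)
  expect_equal(nrow(sel2$selected), 6)

  # cal set covering every hybrid selects the whole non-test pool
  sel3 <- select_genomic(recs, unique(recs$hybrid_id), test_ids)
  expect_setequal(sel3$selected$plot_id, setdiff(recs$plot_id, test_ids))

  expect_error(select_genomic(recs, "H99"), "disjoint")
  expect_error(select_genomic(recs, character(0)), "empty")
})

test_that("phenotype selection picks the most central plots per cluster", {
  tt <- tiny_trial()
  sel <- select_phenotype(tt$tensor, tt$trial$records, k = 3,
                          n_per_cluster = 3, seed = 4)
  expect_equal(sel$k, 3)
  expect_true(all(sel$selected$plot_id %in% tt$trial$records$plot_id))

  # brute force: every non-selected pool member of a cluster sits at least
  # as far from its center as the farthest selected member
  x <- scale(phenocast:::flatten_tensor(tt$tensor))
  x[, !is.finite(colSums(x))] <- 0
  d2 <- phenocast:::proxy_dist2(x, sel$centers)
  for (cl in seq_len(sel$k)) {
    members <- names(sel$cluster_of_pool)[sel$cluster_of_pool == cl]
    chosen <- sel$selected$plot_id[sel$selected$cluster == cl]
    rest <- setdiff(members, chosen)
    if (length(rest) > 0) {
      expect_gte(min(d2[match(rest, tt$tensor$plot_ids), cl]),
                 max(d2[match(chosen, tt$tensor$plot_ids), cl]) - 1e-9)
    }
    # stored distances are the true center distances
    got <- sel$selected$distance[sel$selected$cluster == cl]
    expect_equal(sort(got),
                 sort(sqrt(d2[match(chosen, tt$tensor$plot_ids), cl])),
                 tolerance = 1e-9)
  }
})

test_that("k = 1 with one pick returns the single most central plot", {
  tt <- tiny_trial()
  sel <- select_phenotype(tt$tensor, tt$trial$records, k = 1,
                          n_per_cluster = 1, seed = 9)
  expect_equal(nrow(sel$selected), 1)
  x <- scale(phenocast:::flatten_tensor(tt$tensor))
  x[, !is.finite(colSums(x))] <- 0
  center <- matrix(colMeans(x), 1)
  d2 <- phenocast:::proxy_dist2(x, center)
  expect_equal(sel$selected$plot_id, tt$tensor$plot_ids[which.min(d2)])
})

test_that("undersized clusters are taken whole and logged as shortfall", {
  tt <- tiny_trial()
  sel <- select_phenotype(tt$tensor, tt$trial$records, k = 4,
                          n_per_cluster = 1000, seed = 2)
  expect_setequal(sel$selected$plot_id, tt$tensor$plot_ids)
  expect_length(sel$shortfall, 4)
})

test_that("fine-tuning with zero epochs returns the pre-trained model", {
  fx <- trained_fixture()
  out <- fine_tune(fx$model, fx$tt$tensor, fx$tt$trial$biomass,
                   fx$tt$tensor$plot_ids[1:15], static = fx$static,
                   epochs = 0)
  expect_identical(out$params, fx$model$params)
  expect_error(
    fine_tune(fx$model, fx$tt$tensor, fx$tt$trial$biomass,
              fx$tt$tensor$plot_ids[1:5], static = fx$static, epochs = 5),
    "fewer than 10"
  )
})

test_that("fine-tuning moves the weights and refits normalization", {
  fx <- trained_fixture()
  sel <- fx$tt$tensor$plot_ids[1:20]
  out <- fine_tune(fx$model, fx$tt$tensor, fx$tt$trial$biomass, sel,
                   static = fx$static, epochs = 10, seed = 3)
  expect_false(identical(out$params, fx$model$params))
  expect_true(isTRUE(out$fine_tuned))
  # normalization statistics come from the selection, not the old split
  rows <- match(out$split$train, fx$tt$tensor$plot_ids)
  want <- phenocast:::fit_norm_stats(fx$tt$tensor, rows)
  expect_equal(out$norm$mu, want$mu)
})

# One shared small transfer experiment for the structural checks.
transfer_fixture <- function() {
  cached("transfer_exp", function() {
    cfg <- sim_config(n_hybrids = 50, n_markers = 200, n_subpops = 3,
                      n_cal_hybrids = 10, cal_replicates = 3,
                      points_per_plot = 60, seed = 501)
    mk <- simulate_markers(cfg)
    wx <- simulate_weather(cfg)
    src <- simulate_trial(cfg, mk, wx, panel = "cal", trial_id = "Cal-1")
    tgt <- simulate_trial(cfg, mk, wx, panel = "tc", trial_id = "Tc-1",
                          apply_shift = TRUE)
    gc_fit <- genotype_clusters(mk, n_components = 8, k_range = 1:6, seed = 1)
    rc <- rnng_config(hidden = 8, epochs = 30, batch_size = 32, seed = 1)
    tl <- run_transfer_experiment(src, tgt, clusters = gc_fit, config = rc,
                                  ft_epochs = 20, seed = 3)
    list(cfg = cfg, markers = mk, tl = tl, clusters = gc_fit)
  })
}

test_that("the four-model experiment keeps test-set hygiene", {
  fx <- transfer_fixture()
  tl <- fx$tl
  expect_named(tl$evals, c("source_only", "fine_tuned_genomic",
                           "fine_tuned_phenotype", "target_trained"))
  for (sel in tl$selections) {
    expect_length(intersect(sel$selected$plot_id, tl$test_ids), 0)
  }
  # all four evaluated on the identical held-out test set
  for (ev in tl$evals) {
    expect_setequal(ev$predictions$plot_id, tl$test_ids)
  }
  # genomic invariant: selected hybrids are exactly within the cal set
  cal <- tl$selections$genomic$cal_hybrids
  expect_true(all(tl$selections$genomic$selected$hybrid_id %in% cal))
  tb <- tidy(tl)
  expect_equal(tb$n_target_train[tb$model == "source_only"], 0L)
  expect_s3_class(autoplot(tl), "ggplot")
})

test_that("both selections cover every genotype cluster in the pool", {
  fx <- transfer_fixture()
  tl <- fx$tl
  asg <- fx$clusters$assignment
  cluster_of <- function(hybs) sort(unique(asg$cluster[asg$hybrid_id %in% hybs]))
  all_clusters <- sort(unique(asg$cluster))
  expect_equal(cluster_of(tl$selections$genomic$selected$hybrid_id),
               all_clusters)
  expect_equal(cluster_of(tl$selections$phenotype$selected$hybrid_id),
               all_clusters)
})

test_that("zero domain shift makes the four models indistinguishable", {
  r2s <- matrix(NA_real_, 3, 4)
  for (s in 1:3) {
    cfg <- sim_config(n_hybrids = 50, n_markers = 200, n_subpops = 3,
                      n_cal_hybrids = 12, cal_replicates = 3,
                      points_per_plot = 60,
                      shift_feature_add = 0, shift_feature_mult = 0,
                      shift_biomass_add = 0, shift_biomass_mult = 0,
                      seed = 600 + s)
    mk <- simulate_markers(cfg)
    wx <- simulate_weather(cfg)
    src <- simulate_trial(cfg, mk, wx, panel = "cal", trial_id = "Cal-1")
    tgt <- simulate_trial(cfg, mk, wx, panel = "tc", trial_id = "Tc-1",
                          apply_shift = TRUE)
    gc_fit <- genotype_clusters(mk, n_components = 8, k_range = 1:6, seed = s)
    rc <- rnng_config(hidden = 16, epochs = 120, batch_size = 32, seed = s)
    tl <- run_transfer_experiment(src, tgt, clusters = gc_fit, config = rc,
                                  ft_epochs = 80, seed = s)
    r2s[s, ] <- tidy(tl)$r2_prediction
  }
  # no shift: no model should be dramatically better or worse than another
  spreads <- apply(r2s, 1, function(v) diff(range(v)))
  expect_lt(median(spreads), 0.35)
})
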