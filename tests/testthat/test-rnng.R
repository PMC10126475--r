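test_that("r2_ref reproduces its definition exactly", {
  expect_identical(r2_ref(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r2_ref(c(1, 2, 3), rep(2, 3)), 0, tolerance = 1e-15)
  y <- c(2, 4, 6, 8)
  yhat <- c(3, 3, 7, 7)
  expect_equal(r2_ref(y, yhat), 1 - sum((y - yhat)^2) / sum((y - mean(y))^2),
               tolerance = 1e-15)
  # heavily biased predictions go negative
  expect_lt(r2_ref(c(1, 2, 3), c(10, 11, 12)), 0)
  expect_warning(out <- r2_ref(c(5, 5, 5), c(1, 2, 3)), "undefined")
  expect_true(is.na(out))
  expect_error(r2_ref(1:3, 1:4), "length")
})

test_that("3-fold split partitions plots with the 1/3 - 90/10 layout", {
  recs <- tibble::tibble(plot_id = sprintf("P%04d", 1:1260))
  folds <- split_cv(recs, seed = 5)
  tests <- lapply(folds, `[[`, "test")
  expect_setequal(unlist(tests), recs$plot_id)
  expect_length(intersect(tests[[1]], tests[[2]]), 0)
  expect_length(intersect(tests[[1]], tests[[3]]), 0)
  for (f in folds) {
    expect_length(f$test, 420)
    expect_length(f$val, 84)
    expect_length(f$train, 756)
    expect_length(intersect(f$train, f$val), 0)
    expect_length(intersect(f$train, f$test), 0)
    expect_length(intersect(f$val, f$test), 0)
  }
  # 9 plots: thirds of size 3
  folds9 <- split_cv(tibble::tibble(plot_id = letters[1:12]), seed = 1)
  expect_length(folds9[[1]]$test, 4)
  expect_error(split_cv(tibble::tibble(plot_id = letters[1:5])), "10 plots")
})

test_that("parameter count follows the gate-dimension formula", {
  cfg <- rnng_config(hidden = 4, seed = 1)
  built <- rnng_build(cfg, n_features = 3, n_timesteps = 4, n_clusters = 2)
  H <- 4
  want <- 4 * (3 * H + H * H + H) +   # cell 1
    4 * (H * H + H * H + H) +         # cell 2
    H + 2 + 1                         # dense: hidden + one-hot + bias
  expect_equal(built$n_parameters, want)
  # no-genotype variant requires the explicit flag
  expect_error(rnng_build(cfg, 3, 4, 0), "n_clusters")
  b0 <- rnng_build(cfg, 3, 4, 0, genotype = FALSE)
  expect_equal(b0$n_parameters, want - 2)
  expect_error(rnng_build(cfg, 3, 1, 2), "time steps")
})

test_that("backpropagation matches numerical finite-difference gradients", {
  pc <- asNamespace("phenocast")
  set.seed(42)
  B <- 5; D <- 3; T_ <- 4; H <- 4; S <- 2
  params <- pc$lstm_init(D, H, S, 2, seed = 7)
  xlist <- lapply(1:T_, function(t) matrix(rnorm(B * D), B))
  static <- matrix(rnorm(B * S), B)
  y <- rnorm(B)
  loss_fn <- function(p) mean((pc$lstm_forward(p, xlist, static)$yhat - y)^2)
  fw <- pc$lstm_forward(params, xlist, static, keep_cache = TRUE)
  gr <- pc$lstm_backward(params, fw, static, 2 * (fw$yhat - y) / B)
  eps <- 1e-6
  num_grad <- function(get, set) {
    v <- get(params)
    g <- v * 0
    for (i in seq_along(v)) {
      up <- v; up[i] <- v[i] + eps
      dn <- v; dn[i] <- v[i] - eps
      g[i] <- (loss_fn(set(params, up)) - loss_fn(set(params, dn))) / (2 * eps)
    }
    g
  }
  checks <- list(
    list(function(p) p$layers[[1]]$W,
         function(p, v) {p$layers[[1]]$W <- v; p}, gr$layers[[1]]$W),
    list(function(p) p$layers[[2]]$U,
         function(p, v) {p$layers[[2]]$U <- v; p}, gr$layers[[2]]$U),
    list(function(p) p$layers[[1]]$b,
         function(p, v) {p$layers[[1]]$b <- v; p}, gr$layers[[1]]$b),
    list(function(p) p$w_h, function(p, v) {p$w_h <- v; p}, gr$w_h),
    list(function(p) p$w_s, function(p, v) {p$w_s <- v; p}, gr$w_s)
  )
  for (ch in checks) {
    expect_equal(num_grad(ch[[1]], ch[[2]]), ch[[3]], tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("training is deterministic and reduces the loss", {
  fx <- trained_fixture()
  m2 <- rnng_train(fx$tt$tensor, fx$tt$trial$biomass, fx$split,
                   static = fx$static, config = fx$cfg)
  expect_identical(fx$model$params, m2$params)
  hist <- fx$model$history
  expect_lt(hist$train_loss[nrow(hist)], hist$train_loss[1])
  expect_equal(nrow(hist), fx$cfg$epochs)
  expect_true(fx$model$best_epoch >= 1 &&
                fx$model$best_epoch <= fx$cfg$epochs)
})

test_that("prediction is finite, batch-size independent, and permutation-safe", {
  fx <- trained_fixture()
  pred <- predict(fx$model, fx$tt$tensor, static = fx$static)
  expect_true(all(is.finite(pred$predicted)))

  # permuting the tensor's plot order permutes the predictions identically
  perm <- sample(seq_along(fx$tt$tensor$plot_ids))
  tperm <- fx$tt$tensor
  tperm$plot_ids <- tperm$plot_ids[perm]
  tperm$values <- tperm$values[perm, , , drop = FALSE]
  tperm$imputed <- tperm$imputed[perm, , , drop = FALSE]
  pred2 <- predict(fx$model, tperm, static = fx$static)
  expect_equal(pred2$predicted[match(pred$plot_id, pred2$plot_id)],
               pred$predicted, tolerance = 1e-9)

  # forward pass on one plot equals the batched forward
  t1 <- fx$tt$tensor
  t1$plot_ids <- t1$plot_ids[3]
  t1$values <- t1$values[3, , , drop = FALSE]
  t1$imputed <- t1$imputed[3, , , drop = FALSE]
  p1 <- predict(fx$model, t1, static = fx$static)
  expect_equal(p1$predicted, pred$predicted[3], tolerance = 1e-9)
})

test_that("fingerprint mismatches are rejected with the differing field", {
  fx <- trained_fixture()
  dropped <- drop_features(fx$tt$tensor, "hs_ndvi")
  expect_error(predict(fx$model, dropped, static = fx$static), "feature")
  expect_error(predict(fx$model, fx$tt$tensor), "genotype")
})

test_that("serialization round-trips the model and its predictions", {
  fx <- trained_fixture()
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fx$model, path)
  back <- read_model(path)
  p1 <- predict(fx$model, fx$tt$tensor, static = fx$static)
  p2 <- predict(back, fx$tt$tensor, static = fx$static)
  expect_equal(p1$predicted, p2$predicted, tolerance = 1e-12)
  expect_equal(back$n_parameters, fx$model$n_parameters)
})

test_that("a constant target trains to the constant prediction", {
  tt <- tiny_trial()
  flat <- tt$trial$biomass
  flat$fresh_biomass <- 2000
  cfg <- rnng_config(hidden = 4, epochs = 15, batch_size = 16, seed = 2)
  split <- split_cv(tt$trial$records, seed = 2)[[1]]
  m <- rnng_train(tt$tensor, flat, split, config = cfg)
  pred <- predict(m, tt$tensor)
  expect_true(all(abs(pred$predicted - 2000) < 1))
})

test_that("evaluation metrics separate plot-level and ranking views", {
  # two hybrids x two reps with compensating replicate errors: perfect
  # ranking despite imperfect plot-level predictions
  records <- tibble::tibble(plot_id = c("p1", "p2", "p3", "p4"),
                            hybrid_id = c("a", "a", "b", "b"))
  obs <- c(10, 14, 20, 24)
  prd <- c(14, 10, 24, 20)
  by_h_obs <- c(12, 22)
  expect_equal(r2_ref(by_h_obs, c(mean(prd[1:2]), mean(prd[3:4]))), 1)
  plot_r2 <- r2_ref(obs, prd)
  expect_lt(plot_r2, 1)

  fx <- trained_fixture()
  ev <- evaluate_model(fx$model, fx$tt$tensor, fx$tt$trial$biomass,
                       fx$tt$trial$records, test_ids = fx$split$test,
                       static = fx$static)
  m <- glance(ev)
  expect_lte(m$r2_prediction, 1)
  expect_gte(m$rmse, 0)
  expect_equal(m$n_plots, length(fx$split$test))
  # perfect predictions give perfect metrics
  fake <- ev
  fake$predictions$predicted <- fake$predictions$observed
  expect_equal(r2_ref(fake$predictions$observed, fake$predictions$predicted), 1)
  expect_s3_class(autoplot(ev), "ggplot")
})
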