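# The recurrent biomass predictor: stacked LSTM cells over the observation
# dates, final hidden state concatenated with the static genotype-cluster
# encoding, one fully connected layer to scalar fresh biomass.

#' Configuration for the recurrent biomass model
#'
#' @param n_stacked_cells Stacked LSTM cells (default 2).
#' @param hidden Hidden-state size (default 64).
#' @param learning_rate Adam learning rate (default 0.0005).
#' @param epochs Training epochs (default 1000).
#' @param batch_size Mini-batch size (default 64).
#' @param static_encoding `"one_hot"` (default) or `"integer"` encoding of
#'   the genotype-cluster ID. One-hot avoids imposing a false ordinal
#'   structure on cluster IDs.
#' @param seed Integer seed for init, batching and splits.
#' @return An `rnng_config` list.
#' @export
rnng_config <- function(n_stacked_cells = 2, hidden = 64,
                        learning_rate = 5e-4, epochs = 1000,
                        batch_size = 64,
                        static_encoding = c("one_hot", "integer"),
                        seed = 1L) {
  static_encoding <- match.arg(static_encoding)
  for (f in c("n_stacked_cells", "hidden", "epochs", "batch_size")) {
    v <- get(f)
    check_that(is.numeric(v) && length(v) == 1 && v >= 1 && v == round(v),
               f, "must be a positive integer")
  }
  check_that(learning_rate > 0, "learning_rate", "must be > 0")
  structure(
    list(n_stacked_cells = as.integer(n_stacked_cells),
         hidden = as.integer(hidden), learning_rate = learning_rate,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         static_encoding = static_encoding, seed = seed),
    class = "rnng_config"
  )
}

#' Reference R-squared against ground truth
#'
#' `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`. Unlike a squared
#' correlation this penalizes bias, and it is negative when predictions are
#' worse than the reference mean — a negative value indicates a biased
#' predictor.
#'
#' @param y Ground-reference values (length >= 2).
#' @param yhat Predictions (same length).
#' @return A single number `<= 1`, or `NA` (with a warning) when `y` is
#'   constant so the reference variance is zero and the quantity is
#'   undefined.
#' @examples
#' r2_ref(c(1, 2, 3), c(2, 2, 2))  # 0
#' @export
r2_ref <- function(y, yhat) {
  if (length(y) != length(yhat)) abort("y and yhat must have equal length")
  if (length(y) < 2) abort("need at least 2 observations")
  denom <- sum((y - mean(y))^2)
  if (denom == 0) {
    warn("reference values are constant: R2_ref is undefined")
    return(NA_real_)
  }
  1 - sum((y - yhat)^2) / denom
}

#' Three-fold cross-validation split of plots
#'
#' One third of the plots forms each test set (disjoint thirds covering all
#' plots); within each fold the remaining plots are split 90% training /
#' 10% validation.
#'
#' @param records Plot records tibble with `plot_id`.
#' @param seed Integer seed.
#' @return List of 3 folds, each `list(train, val, test)` of plot IDs.
#' @export
split_cv <- function(records, seed = 1L) {
  ids <- records$plot_id
  n <- length(ids)
  if (n < 10) abort("need at least 10 plots for a 3-fold split")
  with_substream(seed, "split", {
    perm <- ids[shuffle(n)]
    fold_of <- rep(1:3, length.out = n)
    lapply(1:3, function(f) {
      test <- perm[fold_of == f]
      rest <- perm[fold_of != f]
      rest <- rest[shuffle(length(rest))]
      n_val <- max(1L, round(0.1 * length(rest)))
      list(train = sort(rest[-seq_len(n_val)]),
           val = sort(rest[seq_len(n_val)]),
           test = sort(test))
    })
  })
}

# --- input preparation -----------------------------------------------------

# Static genotype encoding for a set of plots. `static` is a tibble
# (plot_id, cluster); NULL gives the no-genotype model variant.
encode_static <- function(static, plot_ids, levels, encoding) {
  if (is.null(static)) {
    return(matrix(0, length(plot_ids), 0))
  }
  cl <- static$cluster[match(plot_ids, static$plot_id)]
  if (anyNA(cl)) {
    abort(sprintf("no cluster for plot(s): %s",
                  paste(head(plot_ids[is.na(cl)], 5), collapse = ", ")))
  }
  if (!all(cl %in% levels)) {
    abort("cluster IDs outside the model's cluster levels")
  }
  if (encoding == "integer") {
    matrix(as.numeric(cl), ncol = 1)
  } else {
    m <- matrix(0, length(plot_ids), length(levels))
    m[cbind(seq_along(cl), match(cl, levels))] <- 1
    m
  }
}

# Tensor -> list over dates of plots x features matrices, scaled by stats.
tensor_to_xlist <- function(tensor, rows, stats) {
  lapply(seq_len(nrow(tensor$dates)), function(d) {
    x <- tensor$values[rows, , d, drop = FALSE]
    dim(x) <- dim(x)[1:2]
    sweep(sweep(x, 2, stats$mu, `-`), 2, stats$sigma, `/`)
  })
}

# Per-feature mean/sd pooled over the training plots and all dates.
fit_norm_stats <- function(tensor, rows) {
  v <- tensor$values[rows, , , drop = FALSE]
  mu <- apply(v, 2, mean)
  sigma <- apply(v, 2, sd)
  sigma[sigma == 0 | !is.finite(sigma)] <- 1
  list(mu = mu, sigma = sigma)
}

schema_fingerprint <- function(tensor, levels, encoding) {
  list(features = tensor$features$name,
       n_dates = nrow(tensor$dates),
       cluster_levels = levels,
       static_encoding = encoding)
}

# --- training core ---------------------------------------------------------

# Mini-batch Adam on MSE; returns the weight snapshot with lowest
# validation loss and the per-epoch loss history.
train_core <- function(params, xtrain, ytrain, xval, yval, config,
                       lr = config$learning_rate, epochs = config$epochs,
                       stream = "train") {
  n <- length(ytrain)
  state <- adam_init(params)
  best <- list(params = params, val = Inf, epoch = 0L)
  hist <- matrix(NA_real_, epochs, 2,
                 dimnames = list(NULL, c("train_loss", "val_loss")))
  with_substream(config$seed, stream, {
    for (ep in seq_len(epochs)) {
      ord <- shuffle(n)
      starts <- seq(1, n, by = config$batch_size)
      ep_loss <- 0
      for (s in starts) {
        bi <- ord[s:min(s + config$batch_size - 1, n)]
        xb <- lapply(xtrain, function(m) m[bi, , drop = FALSE])
        sb <- params_static_rows(config, attr(xtrain, "static"), bi)
        fw <- lstm_forward(params, xb, sb, keep_cache = TRUE)
        resid <- fw$yhat - ytrain[bi]
        loss <- mean(resid^2)
        if (!is.finite(loss)) {
          abort(sprintf(paste0(
            "non-finite training loss at epoch %d; learning rate %.2g, ",
            "feature scale range [%.2g, %.2g] - check normalization"),
            ep, lr, min(vapply(xtrain, min, 0)),
            max(vapply(xtrain, max, 0))))
        }
        dy <- 2 * resid / length(bi)
        gr <- lstm_backward(params, fw, sb, dy)
        st <- adam_step(params, gr, state, lr)
        params <- st$params
        state <- st$state
        ep_loss <- ep_loss + loss * length(bi)
      }
      hist[ep, 1] <- ep_loss / n
      if (length(yval) > 0) {
        sv <- attr(xval, "static")
        pv <- lstm_forward(params, xval, sv)$yhat
        hist[ep, 2] <- mean((pv - yval)^2)
        if (hist[ep, 2] < best$val) {
          best <- list(params = params, val = hist[ep, 2], epoch = ep)
        }
      }
    }
  })
  if (length(yval) == 0 || !is.finite(best$val)) {
    best <- list(params = params, val = NA_real_, epoch = epochs)
  }
  list(params = best$params, final_params = params,
       history = as_tibble(hist) %>% mutate(epoch = dplyr::row_number(),
                                            .before = 1),
       best_epoch = best$epoch)
}

params_static_rows <- function(config, static_mat, rows) {
  static_mat[rows, , drop = FALSE]
}

# --- user-facing fit / predict / evaluate ---------------------------------

#' Train the recurrent biomass model
#'
#' Fits the stacked-LSTM regressor on the training split, tracking MSE on
#' the validation split each epoch and retaining the weights of the best
#' validation epoch. Features and the biomass target are z-scored with
#' statistics fitted on the training split only.
#'
#' @param tensor A `feature_tensor`.
#' @param outcome Tibble `plot_id`, `fresh_biomass` (g/m^2).
#' @param split `list(train, val)` of plot IDs (see [split_cv()]).
#' @param static Optional tibble `plot_id`, `cluster` for the genotype
#'   input; `NULL` fits the no-genotype variant.
#' @param config An [rnng_config()].
#' @return An `rnng_model`: weights, config, schema fingerprint,
#'   normalization statistics, training history.
#' @export
rnng_train <- function(tensor, outcome, split, static = NULL,
                       config = rnng_config()) {
  stopifnot(inherits(tensor, "feature_tensor"))
  levels <- if (is.null(static)) integer(0) else sort(unique(static$cluster))
  if (!is.null(static) && length(levels) < 1) {
    abort("static cluster input has no levels")
  }
  if (nrow(tensor$dates) < 2) abort("need at least 2 observation dates")
  fp <- schema_fingerprint(tensor, levels, config$static_encoding)

  tr_rows <- match(split$train, tensor$plot_ids)
  va_rows <- match(split$val, tensor$plot_ids)
  if (anyNA(tr_rows) || anyNA(va_rows)) {
    abort("split refers to plots absent from the tensor")
  }
  if (length(intersect(split$train, split$val)) > 0) {
    abort("train and validation sets overlap")
  }
  y <- outcome$fresh_biomass[match(tensor$plot_ids, outcome$plot_id)]
  if (anyNA(y[c(tr_rows, va_rows)])) abort("missing biomass for split plots")

  stats <- fit_norm_stats(tensor, tr_rows)
  y_mu <- mean(y[tr_rows])
  y_sd <- sd(y[tr_rows])
  if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1

  xtr <- tensor_to_xlist(tensor, tr_rows, stats)
  xva <- tensor_to_xlist(tensor, va_rows, stats)
  s_all <- encode_static(static, tensor$plot_ids, levels,
                         config$static_encoding)
  attr(xtr, "static") <- s_all[tr_rows, , drop = FALSE]
  attr(xva, "static") <- s_all[va_rows, , drop = FALSE]

  params <- lstm_init(ncol(tensor$values), config$hidden, ncol(s_all),
                      config$n_stacked_cells, config$seed)
  fit <- train_core(params, xtr, (y[tr_rows] - y_mu) / y_sd,
                    xva, (y[va_rows] - y_mu) / y_sd, config)

  structure(
    list(params = fit$params, config = config, fingerprint = fp,
         norm = c(stats, list(y_mu = y_mu, y_sd = y_sd)),
         history = fit$history, best_epoch = fit$best_epoch,
         n_parameters = lstm_param_count(fit$params),
         split = split),
    class = "rnng_model"
  )
}

check_fingerprint <- function(model, tensor, static) {
  fp <- model$fingerprint
  if (!identical(fp$features, tensor$features$name)) {
    abort("schema mismatch: feature names/order differ from training")
  }
  if (fp$n_dates != nrow(tensor$dates)) {
    abort("schema mismatch: number of observation dates differs")
  }
  if (length(fp$cluster_levels) > 0 && is.null(static)) {
    abort("schema mismatch: model expects a genotype-cluster input")
  }
  if (length(fp$cluster_levels) == 0 && !is.null(static)) {
    abort("schema mismatch: model was trained without genotype input")
  }
  invisible(TRUE)
}

#' Predict biomass for every plot in a tensor
#'
#' @param object A trained `rnng_model`.
#' @param tensor A `feature_tensor` matching the model's schema
#'   fingerprint.
#' @param static Genotype-cluster tibble (`plot_id`, `cluster`) if the
#'   model was trained with one.
#' @param ... Unused.
#' @return Tibble `plot_id`, `predicted` (g/m^2).
#' @export
predict.rnng_model <- function(object, tensor, static = NULL, ...) {
  check_fingerprint(object, tensor, static)
  rows <- seq_along(tensor$plot_ids)
  xl <- tensor_to_xlist(tensor, rows, object$norm)
  s <- encode_static(static, tensor$plot_ids, object$fingerprint$cluster_levels,
                     object$fingerprint$static_encoding)
  yhat <- lstm_forward(object$params, xl, s)$yhat
  tibble(plot_id = tensor$plot_ids,
         predicted = yhat * object$norm$y_sd + object$norm$y_mu)
}

#' Evaluate predictions on a test set
#'
#' Computes prediction `R2_ref` and RMSE over plots, and ranking `R2_ref`
#' over per-hybrid mean biomass (how well hybrids are ordered for selection
#' decisions).
#'
#' @param model A trained `rnng_model`.
#' @param tensor Feature tensor covering at least the test plots.
#' @param outcome Tibble `plot_id`, `fresh_biomass`.
#' @param records Plot records mapping `plot_id` to `hybrid_id`.
#' @param test_ids Plot IDs to evaluate on (default: all tensor plots).
#' @param static Genotype-cluster tibble if the model uses one.
#' @return An `rnng_eval`: `predictions` tibble and `metrics` one-row
#'   tibble (`r2_prediction`, `rmse`, `r2_ranking`, `n_plots`, `n_hybrids`).
#' @export
evaluate_model <- function(model, tensor, outcome, records,
                           test_ids = tensor$plot_ids, static = NULL) {
  pred <- predict(model, tensor, static = static)
  pred <- filter(pred, .data$plot_id %in% test_ids)
  df <- pred %>%
    left_join(select(records, "plot_id", "hybrid_id"), by = "plot_id") %>%
    left_join(select(outcome, "plot_id", "fresh_biomass"), by = "plot_id") %>%
    rename(observed = "fresh_biomass")
  if (anyNA(df$hybrid_id)) abort("test plot without a hybrid mapping")
  by_hyb <- df %>%
    group_by(.data$hybrid_id) %>%
    summarise(observed = mean(.data$observed),
              predicted = mean(.data$predicted), .groups = "drop")
  metrics <- tibble(
    r2_prediction = r2_ref(df$observed, df$predicted),
    rmse = sqrt(mean((df$observed - df$predicted)^2)),
    r2_ranking = r2_ref(by_hyb$observed, by_hyb$predicted),
    n_plots = nrow(df),
    n_hybrids = nrow(by_hyb)
  )
  structure(list(predictions = df, metrics = metrics), class = "rnng_eval")
}

#' Cross-validated fit and evaluation
#'
#' Runs the full 3-fold protocol: per fold, train on 90% of the non-test
#' plots with 10% validation, then pool the three test-fold predictions
#' before computing metrics.
#'
#' @inheritParams rnng_train
#' @param records Plot records (`plot_id`, `hybrid_id`).
#' @return An `rnng_cv`: `folds` (models), `eval` (pooled `rnng_eval`),
#'   `splits`.
#' @export
rnng_cv <- function(tensor, outcome, records, static = NULL,
                    config = rnng_config()) {
  splits <- split_cv(records, seed = config$seed)
  models <- vector("list", 3)
  preds <- vector("list", 3)
  for (f in 1:3) {
    models[[f]] <- rnng_train(tensor, outcome, splits[[f]], static = static,
                              config = config)
    preds[[f]] <- predict(models[[f]], tensor, static = static) %>%
      filter(.data$plot_id %in% splits[[f]]$test)
  }
  pooled <- bind_rows(preds) %>%
    left_join(select(records, "plot_id", "hybrid_id"), by = "plot_id") %>%
    left_join(select(outcome, "plot_id", "fresh_biomass"), by = "plot_id") %>%
    rename(observed = "fresh_biomass")
  by_hyb <- pooled %>%
    group_by(.data$hybrid_id) %>%
    summarise(observed = mean(.data$observed),
              predicted = mean(.data$predicted), .groups = "drop")
  ev <- structure(
    list(predictions = pooled,
         metrics = tibble(
           r2_prediction = r2_ref(pooled$observed, pooled$predicted),
           rmse = sqrt(mean((pooled$observed - pooled$predicted)^2)),
           r2_ranking = r2_ref(by_hyb$observed, by_hyb$predicted),
           n_plots = nrow(pooled), n_hybrids = nrow(by_hyb))),
    class = "rnng_eval")
  structure(list(folds = models, eval = ev, splits = splits),
            class = "rnng_cv")
}

#' @export
print.rnng_model <- function(x, ...) {
  cat(sprintf("<rnng_model> %d stacked cells, hidden %d, %d parameters\n",
              x$config$n_stacked_cells, x$config$hidden, x$n_parameters))
  cat(sprintf("  %d features x %d dates; %s genotype input\n",
              length(x$fingerprint$features), x$fingerprint$n_dates,
              if (length(x$fingerprint$cluster_levels) > 0) {
                sprintf("%d-cluster", length(x$fingerprint$cluster_levels))
              } else "no"))
  cat(sprintf("  best validation epoch %d of %d\n",
              x$best_epoch, x$config$epochs))
  invisible(x)
}

#' @export
print.rnng_eval <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<rnng_eval> R2 %.3f | RMSE %.1f g/m^2 | ranking R2 %.3f (%d plots)\n",
    m$r2_prediction, m$rmse, m$r2_ranking, m$n_plots))
  invisible(x)
}

#' Tidy per-plot predictions of an evaluation
#'
#' @param x An `rnng_eval`.
#' @param ... Unused.
#' @return The per-plot predictions tibble.
#' @export
tidy.rnng_eval <- function(x, ...) x$predictions

#' Metrics of an evaluation
#'
#' @param x An `rnng_eval`.
#' @param ... Unused.
#' @return One-row metrics tibble.
#' @export
glance.rnng_eval <- function(x, ...) x$metrics

#' Training history of a fitted model
#'
#' @param x An `rnng_model`.
#' @param ... Unused.
#' @return Tibble `epoch`, `train_loss`, `val_loss`.
#' @export
tidy.rnng_model <- function(x, ...) x$history

#' Model summary
#'
#' @param x An `rnng_model`.
#' @param ... Unused.
#' @return One-row tibble with architecture and best-epoch fields.
#' @export
glance.rnng_model <- function(x, ...) {
  tibble(n_stacked_cells = x$config$n_stacked_cells,
         hidden = x$config$hidden,
         n_parameters = x$n_parameters,
         epochs = x$config$epochs,
         best_epoch = x$best_epoch,
         best_val_loss = min(x$history$val_loss, na.rm = TRUE))
}

#' Observed-vs-predicted plot for an evaluation
#'
#' @param object An `rnng_eval`.
#' @param ... Unused.
#' @return A ggplot of predicted against observed biomass with the 1:1
#'   line; under-prediction of high-yield plots shows as points falling
#'   below the line at the high end.
#' @export
autoplot.rnng_eval <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "ground reference fresh biomass (g/m^2)",
                  y = "predicted fresh biomass (g/m^2)") +
    ggplot2::theme_minimal()
}

#' Build an untrained model (architecture only)
#'
#' Useful for inspecting the parameter count implied by a configuration:
#' each LSTM cell holds `4 (d_in H + H^2 + H)` weights and the output layer
#' `H + S + 1`, with `S` the static encoding width.
#'
#' @param config An [rnng_config()].
#' @param n_features Features per date.
#' @param n_timesteps Observation dates (>= 2).
#' @param n_clusters Number of genotype clusters; 0 builds the no-genotype
#'   variant (only valid with `genotype = FALSE`).
#' @param genotype Include the static genotype input (default TRUE).
#' @return List with `params` (initial weights) and `n_parameters`.
#' @export
rnng_build <- function(config, n_features, n_timesteps, n_clusters,
                       genotype = TRUE) {
  if (n_timesteps < 2) abort("need at least 2 time steps")
  if (genotype && n_clusters < 1) {
    abort("n_clusters must be >= 1 unless the no-genotype variant is requested")
  }
  n_static <- if (!genotype) 0L else if (config$static_encoding == "one_hot") {
    as.integer(n_clusters)
  } else 1L
  params <- lstm_init(n_features, config$hidden, n_static,
                      config$n_stacked_cells, config$seed)
  list(params = params, n_parameters = lstm_param_count(params))
}

#' Map a genotype-cluster assignment onto plots
#'
#' @param records Plot records (`plot_id`, `hybrid_id`).
#' @param clusters A `cluster_assignment` (or its `assignment` tibble).
#' @return Tibble `plot_id`, `cluster` suitable as the `static` input of
#'   [rnng_train()].
#' @export
plot_clusters <- function(records, clusters) {
  tbl <- if (inherits(clusters, "cluster_assignment")) {
    clusters$assignment
  } else clusters
  out <- records %>%
    left_join(tbl, by = "hybrid_id") %>%
    select("plot_id", "cluster")
  if (anyNA(out$cluster)) {
    abort("some plot hybrids have no cluster assignment")
  }
  out
}
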