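# Transfer learning: informative-sample selection in the target domain and
# fine-tuning of a pre-trained model.

#' Genomic sample selection
#'
#' Selects every target-domain plot whose hybrid also appears in the
#' calibration (source) panel, excluding plots reserved for the test set —
#' the assumption being that the calibration hybrids were chosen by the
#' breeder to be broadly representative.
#'
#' @param records Target-panel plot records (`plot_id`, `hybrid_id`).
#' @param cal_hybrids Character vector of calibration-panel hybrid IDs.
#' @param test_ids Plot IDs held out for testing (never selected).
#' @return A `selection_result`: `selected` tibble (`plot_id`,
#'   `hybrid_id`), `strategy = "genomic"`.
#' @export
select_genomic <- function(records, cal_hybrids, test_ids = character(0)) {
  if (length(cal_hybrids) == 0) abort("calibration hybrid set is empty")
  pool <- filter(records, !(.data$plot_id %in% test_ids))
  sel <- filter(pool, .data$hybrid_id %in% cal_hybrids)
  if (nrow(sel) == 0) {
    abort("disjoint panels: no target plot carries a calibration hybrid")
  }
  structure(
    list(strategy = "genomic",
         selected = select(sel, "plot_id", "hybrid_id"),
         cal_hybrids = cal_hybrids),
    class = "selection_result"
  )
}

#' Phenotype sample selection
#'
#' Clusters the target pool's remote-sensing features (flattened over
#' features x dates, z-scored pool-wide) with k-means, then from each
#' cluster takes the `n_per_cluster` plots closest (Euclidean) to the
#' cluster center — the most phenotypically representative plots.
#'
#' @param tensor Feature tensor restricted to (or covering) the target
#'   pool.
#' @param records Target-panel records (`plot_id`, `hybrid_id`).
#' @param test_ids Plot IDs excluded from the pool.
#' @param k Number of phenotype clusters, or `"auto"` for elbow selection
#'   over `k_range`.
#' @param k_range Candidate k values for auto selection (default `1:10`).
#' @param n_per_cluster Plots taken per cluster; default
#'   `ceil(budget / k)` with `budget = length(cal_hybrids)` if given,
#'   else 10.
#' @param budget Target number of selected plots used to derive
#'   `n_per_cluster` (see above).
#' @param seed Integer seed.
#' @return A `selection_result` with per-cluster provenance (`cluster`,
#'   `distance` of each selected plot to its center) and the cluster
#'   `centers`.
#' @export
select_phenotype <- function(tensor, records, test_ids = character(0),
                             k = "auto", k_range = 1:10,
                             n_per_cluster = NULL, budget = NULL,
                             seed = 1L) {
  pool_ids <- setdiff(intersect(tensor$plot_ids, records$plot_id), test_ids)
  rows <- match(pool_ids, tensor$plot_ids)
  x <- flatten_tensor(tensor)[rows, , drop = FALSE]
  x <- scale(x)
  x[, !is.finite(colSums(x))] <- 0

  if (identical(k, "auto")) {
    k_range <- k_range[k_range <= nrow(x)]
    curve <- wcss_curve(x, k_range = k_range, seed = seed)
    k <- as.integer(elbow_select(curve))
  } else {
    curve <- NULL
    k <- as.integer(k)
  }
  if (nrow(x) < k) abort("pool smaller than the number of clusters")
  if (is.null(n_per_cluster)) {
    if (is.null(budget)) budget <- 10L * k
    n_per_cluster <- ceiling(budget / k)
  }

  km <- with_substream(seed, "phenoselect", best_kmeans(x, k, n_init = 10))
  d2 <- proxy_dist2(x, km$centers)
  picks <- vector("list", k)
  shortfall <- integer(0)
  for (cl in seq_len(k)) {
    members <- which(km$cluster == cl)
    if (length(members) < n_per_cluster) shortfall <- c(shortfall, cl)
    take <- members[order(d2[members, cl])][
      seq_len(min(n_per_cluster, length(members)))]
    picks[[cl]] <- tibble(
      plot_id = pool_ids[take],
      cluster = cl,
      distance = sqrt(pmax(d2[take, cl], 0))
    )
  }
  sel <- bind_rows(picks) %>%
    left_join(select(records, "plot_id", "hybrid_id"), by = "plot_id") %>%
    select("plot_id", "hybrid_id", "cluster", "distance")
  structure(
    list(strategy = "phenotype", selected = sel, k = k,
         centers = km$centers, pool_ids = pool_ids,
         cluster_of_pool = setNames(km$cluster, pool_ids),
         n_per_cluster = n_per_cluster, shortfall = shortfall,
         curve = curve, seed = seed),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s strategy: %d plots, %d hybrids\n",
              x$strategy, nrow(x$selected),
              dplyr::n_distinct(x$selected$hybrid_id)))
  invisible(x)
}

#' Tidy a selection result
#'
#' @param x A `selection_result`.
#' @param ... Unused.
#' @return The selected-plots tibble.
#' @export
tidy.selection_result <- function(x, ...) x$selected

#' Fine-tune a pre-trained model on selected target-domain plots
#'
#' Continues optimization from the pre-trained weights on the selected
#' plots only, with all layers trainable at a reduced learning rate.
#' Normalization statistics are refit on the selection (the target domain
#' may be shifted in feature space). A 10% validation split of the
#' selection defines the retained best-validation weights.
#'
#' @param pretrained A trained `rnng_model`.
#' @param tensor Target-domain feature tensor (same post-pruning catalog
#'   and date count as the source: fingerprint-checked).
#' @param outcome Target biomass tibble (`plot_id`, `fresh_biomass`).
#' @param selection A `selection_result` (or character vector of plot IDs).
#' @param static Genotype-cluster tibble if the model uses one.
#' @param learning_rate Fine-tuning rate (default 1e-4).
#' @param epochs Fine-tuning epochs (default 300). `epochs = 0` returns the
#'   pre-trained model unchanged.
#' @param val_frac Validation fraction of the selection (default 0.1).
#' @param seed Integer seed.
#' @return A fine-tuned `rnng_model`.
#' @export
fine_tune <- function(pretrained, tensor, outcome, selection,
                      static = NULL, learning_rate = 1e-4, epochs = 300,
                      val_frac = 0.1, seed = 1L) {
  ids <- if (inherits(selection, "selection_result")) {
    selection$selected$plot_id
  } else as.character(selection)
  check_fingerprint(pretrained, tensor, static)
  if (epochs == 0) return(pretrained)
  if (length(ids) < 10) {
    abort("selection has fewer than 10 plots: cannot form a validation split")
  }
  split <- with_substream(seed, "ftsplit", {
    perm <- ids[shuffle(length(ids))]
    n_val <- max(1L, round(val_frac * length(ids)))
    list(train = sort(perm[-seq_len(n_val)]),
         val = sort(perm[seq_len(n_val)]))
  })
  cfg <- pretrained$config
  cfg$seed <- seed
  tr_rows <- match(split$train, tensor$plot_ids)
  va_rows <- match(split$val, tensor$plot_ids)
  if (anyNA(c(tr_rows, va_rows))) {
    abort("selection refers to plots absent from the target tensor")
  }
  y <- outcome$fresh_biomass[match(tensor$plot_ids, outcome$plot_id)]
  stats <- fit_norm_stats(tensor, tr_rows)
  y_mu <- mean(y[tr_rows]); y_sd <- sd(y[tr_rows])
  if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  xtr <- tensor_to_xlist(tensor, tr_rows, stats)
  xva <- tensor_to_xlist(tensor, va_rows, stats)
  s_all <- encode_static(static, tensor$plot_ids,
                         pretrained$fingerprint$cluster_levels,
                         pretrained$fingerprint$static_encoding)
  attr(xtr, "static") <- s_all[tr_rows, , drop = FALSE]
  attr(xva, "static") <- s_all[va_rows, , drop = FALSE]
  fit <- train_core(pretrained$params, xtr, (y[tr_rows] - y_mu) / y_sd,
                    xva, (y[va_rows] - y_mu) / y_sd, cfg,
                    lr = learning_rate, epochs = as.integer(epochs),
                    stream = "finetune")
  out <- pretrained
  out$params <- fit$params
  out$norm <- c(stats, list(y_mu = y_mu, y_sd = y_sd))
  out$history <- fit$history
  out$best_epoch <- fit$best_epoch
  out$fine_tuned <- TRUE
  out$split <- split
  out
}

#' Run the four-model transfer-learning comparison
#'
#' Reproduces the standard experimental design for domain transfer between
#' a small source panel and a large target panel: (1) a source-only model
#' trained on the source trial, (2) a target-trained ceiling model using
#' the full target training pool, and (3, 4) the source model fine-tuned on
#' plots selected by the genomic and phenotype strategies. All four are
#' evaluated on one shared held-out target test third.
#'
#' @param source,target `trial_data` objects sharing the feature catalog.
#' @param clusters A `cluster_assignment` over the hybrid set (the shared
#'   genotype-cluster model), or `NULL` for genotype-free models.
#' @param catalog Feature catalog (post-pruning).
#' @param config An [rnng_config()] for pre-training and target training.
#' @param ft_learning_rate,ft_epochs Fine-tuning schedule (defaults 1e-4,
#'   300).
#' @param pheno_k,pheno_budget Phenotype-strategy knobs (defaults: elbow
#'   auto k; budget = number of calibration hybrids).
#' @param seed Integer seed (test split, selections, training).
#' @param source_tensor,target_tensor Optional pre-extracted tensors (to
#'   reuse cached extractions); extracted from the trials when `NULL`.
#' @return A `transfer_report`: per-model `rnng_eval`s, selection objects,
#'   sample/hybrid counts, and the shared test set.
#' @export
run_transfer_experiment <- function(source, target, clusters = NULL,
                                    catalog = default_catalog(),
                                    config = rnng_config(),
                                    ft_learning_rate = 1e-4, ft_epochs = 300,
                                    pheno_k = "auto", pheno_budget = NULL,
                                    seed = 1L,
                                    source_tensor = NULL,
                                    target_tensor = NULL) {
  if (is.null(source_tensor)) source_tensor <- extract_features(source, catalog)
  if (is.null(target_tensor)) target_tensor <- extract_features(target, catalog)
  if (!identical(source_tensor$features$name, target_tensor$features$name)) {
    abort("source and target do not share the feature catalog")
  }

  src_static <- if (is.null(clusters)) NULL else {
    plot_clusters(source$records, clusters)
  }
  tgt_static <- if (is.null(clusters)) NULL else {
    plot_clusters(target$records, clusters)
  }

  # shared held-out target test third
  tgt_ids <- target$records$plot_id
  test_ids <- with_substream(seed, "transfer_test", {
    sort(tgt_ids[shuffle(length(tgt_ids))][seq_len(round(length(tgt_ids) / 3))])
  })
  pool_ids <- setdiff(tgt_ids, test_ids)

  # source-only model: trained on the full source panel with a 10% val split
  src_split <- with_substream(seed, "src_split", {
    ids <- source$records$plot_id
    perm <- ids[shuffle(length(ids))]
    n_val <- max(1L, round(0.1 * length(ids)))
    list(train = sort(perm[-seq_len(n_val)]),
         val = sort(perm[seq_len(n_val)]))
  })
  cfg <- config
  cfg$seed <- substream_seed(seed, "pretrain")
  m_source <- rnng_train(source_tensor, source$biomass, src_split,
                         static = src_static, config = cfg)

  # target-trained ceiling model on the full non-test pool
  tgt_split <- with_substream(seed, "tgt_split", {
    perm <- pool_ids[shuffle(length(pool_ids))]
    n_val <- max(1L, round(0.1 * length(pool_ids)))
    list(train = sort(perm[-seq_len(n_val)]),
         val = sort(perm[seq_len(n_val)]))
  })
  cfg2 <- config
  cfg2$seed <- substream_seed(seed, "tgttrain")
  m_target <- rnng_train(target_tensor, target$biomass, tgt_split,
                         static = tgt_static, config = cfg2)

  # selections (drawn only from the non-test pool)
  cal_hybrids <- unique(source$records$hybrid_id)
  sel_g <- select_genomic(target$records, cal_hybrids, test_ids)
  if (is.null(pheno_budget)) pheno_budget <- length(cal_hybrids)
  sel_p <- select_phenotype(target_tensor, target$records, test_ids,
                            k = pheno_k, budget = pheno_budget,
                            seed = substream_seed(seed, "phenosel"))

  m_ftg <- fine_tune(m_source, target_tensor, target$biomass, sel_g,
                     static = tgt_static, learning_rate = ft_learning_rate,
                     epochs = ft_epochs, seed = substream_seed(seed, "ftg"))
  m_ftp <- fine_tune(m_source, target_tensor, target$biomass, sel_p,
                     static = tgt_static, learning_rate = ft_learning_rate,
                     epochs = ft_epochs, seed = substream_seed(seed, "ftp"))

  stopifnot(length(intersect(sel_g$selected$plot_id, test_ids)) == 0,
            length(intersect(sel_p$selected$plot_id, test_ids)) == 0)

  evl <- function(m) {
    evaluate_model(m, target_tensor, target$biomass, target$records,
                   test_ids = test_ids, static = tgt_static)
  }
  evals <- list(
    source_only = evl(m_source),
    fine_tuned_genomic = evl(m_ftg),
    fine_tuned_phenotype = evl(m_ftp),
    target_trained = evl(m_target)
  )
  counts <- tibble(
    model = names(evals),
    n_target_train = c(0L, nrow(sel_g$selected), nrow(sel_p$selected),
                       length(tgt_split$train)),
    n_target_hybrids = c(
      0L,
      dplyr::n_distinct(sel_g$selected$hybrid_id),
      dplyr::n_distinct(sel_p$selected$hybrid_id),
      dplyr::n_distinct(
        target$records$hybrid_id[target$records$plot_id %in%
                                   tgt_split$train]))
  )
  structure(
    list(evals = evals, counts = counts, test_ids = test_ids,
         pool_ids = pool_ids,
         selections = list(genomic = sel_g, phenotype = sel_p),
         models = list(source_only = m_source, target_trained = m_target,
                       fine_tuned_genomic = m_ftg,
                       fine_tuned_phenotype = m_ftp)),
    class = "transfer_report"
  )
}

#' Tidy a transfer report into a comparison table
#'
#' One row per model: target-domain sample/hybrid counts used for training,
#' prediction `R2_ref`, RMSE and ranking `R2_ref` on the shared test set.
#'
#' @param x A `transfer_report`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.transfer_report <- function(x, ...) {
  metrics <- purrr::imap_dfr(x$evals, function(e, nm) {
    mutate(e$metrics, model = nm, .before = 1)
  })
  left_join(x$counts, metrics, by = "model")
}

#' @export
print.transfer_report <- function(x, ...) {
  cat("<transfer_report>\n")
  print(as.data.frame(tidy(x)[, c("model", "n_target_train",
                                  "r2_prediction", "rmse", "r2_ranking")]),
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Bar plot of the four-model comparison
#'
#' @param object A `transfer_report`.
#' @param ... Unused.
#' @return A ggplot of test `R2_ref` per model.
#' @export
autoplot.transfer_report <- function(object, ...) {
  df <- tidy(object)
  df$model <- factor(df$model, levels = df$model)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$r2_prediction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "target test R2_ref") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}
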