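# PCA-loading feature importance and majority-vote redundancy pruning.
#
# Importance of feature i is the sum over the leading principal components
# of |loading| weighted by the component's explained-variance ratio:
#   I_i = sum_n |W_in| * V_n,  n = 1..n_pcs.
# Computed on column-standardized features (correlation-matrix PCA), since
# hyperspectral, LiDAR and weather features have incommensurate units.

#' PCA-loading feature importance for one plots x features matrix
#'
#' @param x Numeric matrix or data frame, plots in rows, features in
#'   columns (named).
#' @param n_pcs Number of leading principal components to aggregate over
#'   (default 5, which typically explains > 90% of the variance in
#'   plot-level remote-sensing feature sets).
#' @param standardize Standardize columns first (default TRUE). Constant
#'   columns cannot be standardized; they receive importance 0 and are
#'   flagged.
#' @return A `pca_importance` list: `importance` (tibble: feature,
#'   importance, constant flag), `loadings` (|W|, features x PCs, sign
#'   convention: largest-|loading| entry of each PC is positive),
#'   `variance_ratio` (per PC), `n_pcs`.
#' @examples
#' x <- matrix(rnorm(60), 10, 6, dimnames = list(NULL, paste0("f", 1:6)))
#' pca_importance(x, n_pcs = 3)$importance
#' @export
pca_importance <- function(x, n_pcs = 5, standardize = TRUE) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (nrow(x) < 2) abort("need at least 2 plots for PCA")
  if (n_pcs > ncol(x)) abort("n_pcs exceeds the number of features")
  const <- apply(x, 2, function(v) sd(v) == 0 || !all(is.finite(v)))
  xs <- x[, !const, drop = FALSE]
  if (ncol(xs) == 0) abort("all feature columns are constant")
  n_use <- min(n_pcs, ncol(xs), nrow(xs) - 1L)

  pc <- prcomp(xs, center = TRUE, scale. = standardize)
  rot <- pc$rotation
  # Deterministic sign convention: largest-|loading| entry positive.
  for (j in seq_len(ncol(rot))) {
    top <- which.max(abs(rot[, j]))
    if (rot[top, j] < 0) rot[, j] <- -rot[, j]
  }
  v_ratio <- pc$sdev^2 / sum(pc$sdev^2)

  imp_active <- abs(rot[, seq_len(n_use), drop = FALSE]) %*%
    v_ratio[seq_len(n_use)]
  imp <- setNames(numeric(ncol(x)), colnames(x))
  imp[colnames(xs)] <- imp_active[, 1]

  structure(
    list(
      importance = tibble(feature = colnames(x),
                          importance = unname(imp),
                          constant = unname(const)),
      loadings = abs(rot),
      signed_loadings = rot,
      variance_ratio = v_ratio,
      n_pcs = n_use
    ),
    class = "pca_importance"
  )
}

#' @export
print.pca_importance <- function(x, ...) {
  cat(sprintf("<pca_importance> %d features, top %d PCs (%.1f%% variance)\n",
              nrow(x$importance), x$n_pcs,
              100 * sum(x$variance_ratio[seq_len(x$n_pcs)])))
  invisible(x)
}

#' Per-date, per-source importance for a whole trial tensor
#'
#' Runs [pca_importance()] on each observation date of a feature tensor,
#' separately per feature source block (hyperspectral and LiDAR, as the
#' blocks have separate supplementary catalogs and the importance analysis
#' is conventionally run per sensor). Weather features are excluded: they
#' are constant across plots within a date and are never candidates for
#' pruning.
#'
#' @param tensor A `feature_tensor`.
#' @param n_pcs PCs to aggregate (default 5).
#' @param by_source Analyze hyperspectral and LiDAR blocks separately
#'   (default TRUE) or as one joint matrix.
#' @return A tibble: `date`, `source`, `feature`, `importance`.
#' @export
feature_importance <- function(tensor, n_pcs = 5, by_source = TRUE) {
  stopifnot(inherits(tensor, "feature_tensor"))
  feats <- filter(tensor$features, .data$source != "weather")
  groups <- if (by_source) split(feats$name, feats$source) else {
    list(rs = feats$name)
  }
  purrr::map_dfr(seq_len(nrow(tensor$dates)), function(d) {
    purrr::imap_dfr(groups, function(nms, src) {
      x <- tensor$values[, nms, d, drop = TRUE]
      pi <- pca_importance(x, n_pcs = min(n_pcs, length(nms)))
      mutate(pi$importance, date = tensor$dates$date[d], source = src,
             .before = 1)
    })
  }) %>% select("date", "source", "feature", "importance")
}

#' Flag features with low importance at every date of a trial
#'
#' A feature is flagged only if its importance falls in the bottom-`q`
#' quantile of its group's importances at *every* observation date — low at
#' one or two growth stages is not enough, since feature relevance is stage
#' dependent. A date whose importances are all equal contributes no low
#' set, so nothing can be flagged through it.
#'
#' @param importance Tibble from [feature_importance()] (columns `date`,
#'   `feature`, `importance`; an optional `source` column makes the
#'   quantile within-source).
#' @param q Bottom-quantile threshold in (0, 1) (default 0.25).
#' @return Tibble: `feature`, `flagged`.
#' @export
flag_low_within_trial <- function(importance, q = 0.25) {
  if (!(q > 0 && q < 1)) abort("`q` must lie in (0, 1)")
  if (!"source" %in% names(importance)) importance$source <- "all"
  per_date <- importance %>%
    group_by(.data$date, .data$source) %>%
    mutate(
      low = if (diff(range(.data$importance)) == 0) FALSE else {
        # bottom ceiling(q * n) by rank; ties take their maximum rank, so a
        # tie group straddling the cutoff is excluded (conservative)
        rank(.data$importance, ties.method = "max") <= ceiling(q * n())
      }
    ) %>%
    ungroup()
  per_date %>%
    group_by(.data$feature) %>%
    summarise(flagged = all(.data$low), .groups = "drop")
}

#' Majority vote of per-trial redundancy flags
#'
#' A feature enters the redundant set only if it was flagged in *strictly*
#' more than half of the trials.
#'
#' @param flags A list of per-trial flag tibbles from
#'   [flag_low_within_trial()]; all trials must share the feature catalog.
#' @return Character vector of redundant feature names.
#' @export
majority_vote_redundant <- function(flags) {
  stopifnot(length(flags) >= 1)
  ref <- sort(flags[[1]]$feature)
  for (f in flags[-1]) {
    if (!identical(sort(f$feature), ref)) {
      diffs <- c(setdiff(f$feature, ref), setdiff(ref, f$feature))
      abort(sprintf("trials disagree on the feature catalog: %s",
                    paste(diffs, collapse = ", ")))
    }
  }
  votes <- bind_rows(flags) %>%
    group_by(.data$feature) %>%
    summarise(n_flagged = sum(.data$flagged), .groups = "drop")
  sort(votes$feature[votes$n_flagged > length(flags) / 2])
}

#' Identify redundant features across multiple trials
#'
#' Full pruning pipeline: per-trial per-date importance, within-trial
#' "low at all dates" flagging, then strict-majority vote across trials.
#'
#' @param tensors List of `feature_tensor`s, one per trial.
#' @param n_pcs PCs to aggregate (default 5).
#' @param q Bottom-quantile threshold (default 0.25).
#' @param by_source Per-sensor-block analysis (default TRUE).
#' @return A `redundancy_report`: `redundant` (names), `flags` (per trial),
#'   `importance` (per trial).
#' @examples
#' \donttest{
#' cfg <- sim_config(n_hybrids = 30, n_markers = 300, n_cal_hybrids = 10,
#'                   points_per_plot = 80, seed = 1)
#' mk <- simulate_markers(cfg); wx <- simulate_weather(cfg)
#' tensors <- lapply(1:3, function(i)
#'   extract_features(simulate_trial(cfg, mk, wx, trial_id = paste0("T", i))))
#' redundant_features(tensors)$redundant
#' }
#' @export
redundant_features <- function(tensors, n_pcs = 5, q = 0.25,
                               by_source = TRUE) {
  imps <- purrr::map(tensors, feature_importance, n_pcs = n_pcs,
                     by_source = by_source)
  flags <- purrr::map(imps, flag_low_within_trial, q = q)
  structure(
    list(redundant = majority_vote_redundant(flags),
         flags = flags, importance = imps, q = q, n_pcs = n_pcs),
    class = "redundancy_report"
  )
}

#' @export
print.redundancy_report <- function(x, ...) {
  cat(sprintf("<redundancy_report> %d trials, q = %.2f, %d PCs\n",
              length(x$flags), x$q, x$n_pcs))
  if (length(x$redundant) == 0) {
    cat("  no redundant features\n")
  } else {
    cat("  redundant:", paste(x$redundant, collapse = ", "), "\n")
  }
  invisible(x)
}
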