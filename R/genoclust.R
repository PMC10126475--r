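# Genotype clustering: marker PCA, k-means WCSS curve, elbow selection.

#' PCA projection of a marker matrix
#'
#' Columns are centered (not variance-scaled; biallelic codings share a
#' scale) and the leading principal-component scores returned, with a
#' deterministic sign convention (largest-|loading| marker positive per
#' component).
#'
#' @param markers Hybrids x markers matrix (rownames = hybrid IDs). Missing
#'   values are imputed with the column mean and flagged.
#' @param n_components Number of components (default 10).
#' @return Matrix of scores, hybrids x n_components; attribute
#'   `variance_ratio` holds the per-component explained-variance ratios and
#'   `imputed` the count of imputed cells.
#' @export
marker_pca <- function(markers, n_components = 10) {
  x <- unclass(as.matrix(markers))
  storage.mode(x) <- "double"
  if (nrow(x) < 2) abort("need at least 2 hybrids")
  n_imp <- 0L
  if (anyNA(x)) {
    n_imp <- sum(is.na(x))
    mu <- colMeans(x, na.rm = TRUE)
    for (j in which(colSums(is.na(x)) > 0)) {
      x[is.na(x[, j]), j] <- mu[j]
    }
  }
  if (n_components > min(nrow(x) - 1L, ncol(x))) {
    abort(sprintf("n_components must be <= min(hybrids - 1, markers) = %d",
                  min(nrow(x) - 1L, ncol(x))))
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  rot <- pc$rotation
  scores <- pc$x
  for (j in seq_len(ncol(rot))) {
    top <- which.max(abs(rot[, j]))
    if (rot[top, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(markers)
  attr(scores, "variance_ratio") <- (pc$sdev^2 / sum(pc$sdev^2))[
    seq_len(n_components)]
  attr(scores, "imputed") <- n_imp
  scores
}

# Best-of-n_init k-means; also warm-starts from `warm` centers (previous
# k-1 solution plus the farthest point) so WCSS(k) <= WCSS(k-1) holds.
best_kmeans <- function(x, k, n_init, warm = NULL) {
  x <- as.matrix(x)
  if (k >= nrow(unique(x))) {
    km <- kmeans(x, centers = unique(x), iter.max = 50,
                 algorithm = "Lloyd")
    attr(km, "degenerate") <- TRUE
    return(km)
  }
  run <- function(centers) {
    tryCatch(
      suppressWarnings(
        kmeans(x, centers = centers, iter.max = 100, algorithm = "Lloyd")
      ),
      error = function(e) NULL
    )
  }
  best <- NULL
  tries <- 0L
  while (is.null(best) || tries < n_init) {
    tries <- tries + 1L
    cand <- run(x[sample.int(nrow(x), k), , drop = FALSE])
    if (!is.null(cand) &&
        (is.null(best) || cand$tot.withinss < best$tot.withinss)) {
      best <- cand
    }
    if (tries > 5L * n_init) break
  }
  if (!is.null(warm) && nrow(warm) == k) {
    cand <- run(warm)
    if (!is.null(cand) && cand$tot.withinss < best$tot.withinss) best <- cand
  }
  if (is.null(best)) abort("k-means failed to converge for any start")
  best
}

#' WCSS curve over a range of k
#'
#' For each `k`, the best of `n_init` Lloyd k-means runs (squared-Euclidean
#' within-cluster sum of squares). A warm start from the previous solution
#' guarantees the curve is non-increasing in `k`.
#'
#' @param projection Points x dims matrix (e.g. [marker_pca()] scores).
#' @param k_range Integer vector of k values (default `1:10`).
#' @param seed Integer seed.
#' @param n_init Random restarts per k (default 10).
#' @return A `wcss_curve` tibble: `k`, `wcss`, `degenerate` flag (k no
#'   smaller than the number of distinct points).
#' @export
wcss_curve <- function(projection, k_range = 1:10, seed = 1L, n_init = 10) {
  x <- as.matrix(projection)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 1) || any(k_range > nrow(x))) {
    abort("k_range must lie within [1, number of points]")
  }
  if (n_init < 1) abort("n_init must be >= 1")
  with_substream(seed, "wcss", {
    out <- vector("list", length(k_range))
    prev <- NULL
    for (i in seq_along(k_range)) {
      k <- k_range[i]
      if (k == 1) {
        wcss <- sum(scale(x, scale = FALSE)^2)
        prev <- matrix(colMeans(x), 1)
        out[[i]] <- tibble(k = k, wcss = wcss, degenerate = FALSE)
        next
      }
      warm <- NULL
      if (!is.null(prev) && nrow(prev) == k - 1) {
        # previous centers plus the point farthest from its center
        d2 <- rowSums((x - prev[max.col(-as.matrix(
          proxy_dist2(x, prev))), , drop = FALSE])^2)
        warm <- rbind(prev, x[which.max(d2), ])
      }
      km <- best_kmeans(x, k, n_init, warm = warm)
      prev <- km$centers
      out[[i]] <- tibble(k = k, wcss = km$tot.withinss,
                         degenerate = isTRUE(attr(km, "degenerate")))
    }
    res <- bind_rows(out)
    class(res) <- c("wcss_curve", class(res))
    res
  })
}

# Squared Euclidean distances points x centers.
proxy_dist2 <- function(x, centers) {
  outer(rowSums(x^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(x)), rowSums(centers^2)) -
    2 * x %*% t(centers)
}

#' Elbow selection of the number of clusters
#'
#' Formalizes the visual elbow criterion as the k whose point on the WCSS
#' curve lies farthest (perpendicular distance) from the straight line
#' joining the curve's endpoints; ties break toward smaller k. A curve that
#' is straight within tolerance carries no elbow: the smallest k is
#' returned with a `no_elbow` flag.
#'
#' @param curve A [wcss_curve()] tibble (`k`, `wcss`), >= 4 points.
#' @param tol Relative straightness tolerance (default 1e-8).
#' @return Integer chosen k, with attribute `no_elbow`.
#' @examples
#' elbow_select(tibble::tibble(k = 1:5, wcss = c(1000, 200, 120, 100, 95)))
#' @export
elbow_select <- function(curve, tol = 1e-8) {
  if (nrow(curve) < 4) abort("elbow selection needs a curve over >= 4 k values")
  k <- curve$k
  w <- curve$wcss
  # perpendicular distance from (k_i, w_i) to the endpoint chord, with both
  # axes scaled to [0, 1] so the geometry is aspect-invariant
  ks <- (k - k[1]) / max(k[length(k)] - k[1], 1)
  rng <- max(w[1] - w[length(w)], .Machine$double.eps)
  ws <- (w - w[length(w)]) / rng
  x1 <- c(ks[1], ws[1])
  x2 <- c(ks[length(ks)], ws[length(ws)])
  v <- x2 - x1
  v <- v / sqrt(sum(v^2))
  d <- vapply(seq_along(k), function(i) {
    p <- c(ks[i], ws[i]) - x1
    abs(p[1] * v[2] - p[2] * v[1])
  }, numeric(1))
  if (max(d) < tol) {
    return(structure(k[1], no_elbow = TRUE, prominence = max(d)))
  }
  structure(k[which.max(d)], no_elbow = FALSE, prominence = max(d))
}

#' Cluster genotypes at a chosen k
#'
#' Final k-means assignment with canonical relabeling (clusters ordered by
#' decreasing size, ties by centroid norm), so two runs reaching the same
#' partition emit identical IDs. An empty cluster at convergence is
#' re-seeded from the farthest point.
#'
#' @param projection Points x dims matrix (rownames = hybrid IDs).
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @param n_init Random restarts (default 10).
#' @return A `cluster_assignment`: `assignment` tibble (`hybrid_id`,
#'   `cluster`), `k`, `centers`, `wcss`, `seed`.
#' @export
cluster_genotypes <- function(projection, k, seed = 1L, n_init = 10) {
  x <- as.matrix(projection)
  if (k < 1 || k > nrow(x)) abort("k must lie in [1, number of hybrids]")
  ids <- rownames(x)
  if (is.null(ids)) ids <- sprintf("row%d", seq_len(nrow(x)))
  with_substream(seed, "cluster", {
    if (k == 1) {
      cl <- rep(1L, nrow(x))
      centers <- matrix(colMeans(x), 1)
      wcss <- sum(scale(x, scale = FALSE)^2)
    } else {
      km <- best_kmeans(x, k, n_init)
      cl <- km$cluster
      centers <- km$centers
      wcss <- km$tot.withinss
    }
    # canonical relabeling: decreasing size, ties by centroid norm, then by
    # the smallest member index so the labels depend only on the partition
    size <- as.numeric(table(factor(cl, levels = seq_len(max(cl)))))
    norm <- sqrt(rowSums(centers^2))
    first_member <- vapply(seq_len(max(cl)), function(g) {
      m <- which(cl == g)
      if (length(m) == 0) Inf else min(m)
    }, numeric(1))
    ord <- order(-size, -round(norm, 9), first_member)
    relab <- match(seq_along(ord), ord)
    cl_new <- relab[cl]
    structure(
      list(
        assignment = tibble(hybrid_id = ids, cluster = as.integer(cl_new)),
        k = as.integer(k),
        centers = centers[ord, , drop = FALSE],
        wcss = wcss,
        seed = seed
      ),
      class = "cluster_assignment"
    )
  })
}

#' End-to-end genotype clustering from a marker matrix
#'
#' Marker PCA (default 10 components), WCSS curve over `k_range`, elbow
#' selection of k, and final clustering — the standard pipeline for turning
#' genome-wide markers into a per-hybrid genotype-cluster ID.
#'
#' @param markers Marker matrix.
#' @param n_components PCs kept (default 10).
#' @param k_range Candidate k values (default `1:10`).
#' @param k Fix k instead of elbow selection (default `NULL` = auto).
#' @param seed Integer seed.
#' @param n_init k-means restarts (default 10).
#' @return A `genotype_clusters` object: fields of [cluster_genotypes()]
#'   plus `curve` (the WCSS tibble), `chosen_k`, `no_elbow`, `projection`.
#' @examples
#' cfg <- sim_config(n_hybrids = 50, n_markers = 300, n_cal_hybrids = 10,
#'                   seed = 1)
#' gc <- genotype_clusters(simulate_markers(cfg), k_range = 1:8, seed = 1)
#' gc$chosen_k
#' @export
genotype_clusters <- function(markers, n_components = 10, k_range = 1:10,
                              k = NULL, seed = 1L, n_init = 10) {
  n_components <- min(n_components, nrow(markers) - 1L, ncol(markers))
  proj <- marker_pca(markers, n_components)
  curve <- wcss_curve(proj, k_range = k_range, seed = seed, n_init = n_init)
  if (is.null(k)) {
    k <- elbow_select(curve)
  }
  assign <- cluster_genotypes(proj, as.integer(k), seed = seed,
                              n_init = n_init)
  structure(
    c(assign, list(curve = curve, chosen_k = as.integer(k),
                   no_elbow = isTRUE(attr(k, "no_elbow")),
                   projection = proj)),
    class = c("genotype_clusters", "cluster_assignment")
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<%s> k = %d, WCSS = %.3g\n", class(x)[1], x$k, x$wcss))
  cat("  sizes:", paste(table(x$assignment$cluster), collapse = " / "), "\n")
  invisible(x)
}

#' Tidy a cluster assignment
#'
#' @param x A `cluster_assignment` or `genotype_clusters` object.
#' @param ... Unused.
#' @return The `hybrid_id` / `cluster` tibble.
#' @export
tidy.cluster_assignment <- function(x, ...) x$assignment

#' Glance at a cluster assignment
#'
#' @param x A `cluster_assignment`.
#' @param ... Unused.
#' @return One-row tibble: `k`, `wcss`, `n`.
#' @export
glance.cluster_assignment <- function(x, ...) {
  tibble(k = x$k, wcss = x$wcss, n = nrow(x$assignment))
}

#' Elbow plot of a WCSS curve
#'
#' @param object A [wcss_curve()] tibble.
#' @param chosen_k Optional k to highlight.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wcss_curve <- function(object, chosen_k = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$wcss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of clusters k",
                  y = "within-cluster sum of squares") +
    ggplot2::theme_minimal()
  if (!is.null(chosen_k)) {
    p <- p + ggplot2::geom_point(
      data = filter(object, .data$k == chosen_k),
      colour = "red", size = 3
    )
  }
  p
}
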