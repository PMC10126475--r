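#' Simulate a structured genotype marker matrix
#'
#' Draws a hybrids x markers matrix of biallelic genotypes coded {0, 1, 2}
#' under a Balding-Nichols island model: each marker has an ancestral allele
#' frequency, each subpopulation perturbs it with differentiation
#' `marker_fst`, and each hybrid's genotype is binomial in its
#' subpopulation's frequency. The hidden subpopulation labels are attached
#' as ground truth for cluster-recovery checks.
#'
#' @param config A [sim_config()].
#' @return A `marker_matrix`: an integer matrix with hybrid IDs as rownames,
#'   marker names as colnames, and attributes `subpop` (hidden truth labels,
#'   integer per hybrid) and `seed`.
#' @examples
#' m <- simulate_markers(sim_config(n_hybrids = 20, n_markers = 100, seed = 1))
#' dim(m)
#' table(attr(m, "subpop"))
#' @export
simulate_markers <- function(config) {
  validate_sim_config(config)
  with_substream(config$seed, "markers", {
    n_v <- config$n_hybrids
    n_m <- config$n_markers
    n_s <- config$n_subpops
    fst <- config$marker_fst

    p_anc <- runif(n_m, 0.1, 0.9)
    # Subpopulation frequencies: Balding-Nichols beta draws around p_anc.
    freq <- if (n_s == 1L || fst == 0) {
      matrix(rep(p_anc, n_s), nrow = n_s, byrow = TRUE)
    } else {
      shape <- (1 - fst) / fst
      t(vapply(seq_len(n_s), function(s) {
        rbeta(n_m, shape1 = p_anc * shape, shape2 = (1 - p_anc) * shape)
      }, numeric(n_m)))
    }

    subpop <- rep(seq_len(n_s), length.out = n_v)
    geno <- matrix(0L, nrow = n_v, ncol = n_m)
    for (s in seq_len(n_s)) {
      idx <- which(subpop == s)
      geno[idx, ] <- matrix(
        rbinom(length(idx) * n_m, size = 2L,
               prob = rep(freq[s, ], each = length(idx))),
        nrow = length(idx)
      )
    }
    rownames(geno) <- hybrid_ids(n_v)
    colnames(geno) <- sprintf("m%05d", seq_len(n_m))
    structure(geno, subpop = subpop, seed = config$seed,
              class = c("marker_matrix", "matrix", "array"))
  })
}

hybrid_ids <- function(n) sprintf("H%04d", seq_len(n))

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("<marker_matrix> %d hybrids x %d markers\n", nrow(x), ncol(x)))
  sp <- attr(x, "subpop")
  if (!is.null(sp)) {
    cat("  hidden subpops:", paste(table(sp), collapse = " / "), "\n")
  }
  invisible(x)
}

#' Tidy a marker matrix into long format
#'
#' @param x A `marker_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `hybrid_id`, `marker`, `genotype`.
#' @export
tidy.marker_matrix <- function(x, ...) {
  tibble(
    hybrid_id = rep(rownames(x), times = ncol(x)),
    marker = rep(colnames(x), each = nrow(x)),
    genotype = as.integer(x)
  )
}
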