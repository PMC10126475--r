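# Shared small fixtures, built once per test run and cached.

fixture_env <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = fixture_env)) {
    assign(key, builder(), envir = fixture_env)
  }
  get(key, envir = fixture_env)
}

tiny_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_hybrids = 24, n_markers = 120, n_subpops = 3,
         n_cal_hybrids = 8, points_per_plot = 60, seed = seed),
    list(...)
  )
  do.call(sim_config, args)
}

# One small simulated trial plus its tensor, shared across test files.
tiny_trial <- function() {
  cached("tiny_trial", function() {
    cfg <- tiny_config(seed = 7)
    mk <- simulate_markers(cfg)
    wx <- simulate_weather(cfg)
    tr <- simulate_trial(cfg, mk, wx)
    list(cfg = cfg, markers = mk, weather = wx, trial = tr,
         tensor = extract_features(tr))
  })
}

# Independent eigendecomposition oracle for PCA importance: power iteration
# with deflation on the correlation matrix -- no LAPACK/SVD shared with the
# implementation path.
power_eigen <- function(S, n_vec, iters = 5000, tol = 1e-12) {
  p <- ncol(S)
  vals <- numeric(n_vec)
  vecs <- matrix(0, p, n_vec)
  A <- S
  for (k in seq_len(n_vec)) {
    # generic start vector: never orthogonal to an eigenvector by symmetry
    v <- seq_len(p) + 0.5
    v <- v / sqrt(sum(v^2))
    for (i in seq_len(iters)) {
      w <- A %*% v
      nw <- sqrt(sum(w^2))
      if (nw < 1e-300) break
      w <- as.numeric(w / nw)
      if (sum(abs(w - v)) < tol) {
        v <- w
        break
      }
      v <- w
    }
    lam <- as.numeric(t(v) %*% A %*% v)
    vals[k] <- lam
    vecs[, k] <- v
    A <- A - lam * (v %*% t(v))
  }
  list(values = vals, vectors = vecs)
}

# Oracle for Eq.-style PCA-loading importance on a raw matrix.
oracle_importance <- function(x, n_pcs) {
  S <- stats::cor(x)
  total <- ncol(x)  # correlation matrix: total variance = p
  eig <- power_eigen(S, n_pcs)
  v_ratio <- eig$values / total
  as.numeric(abs(eig$vectors) %*% v_ratio)
}

# Small trained model shared by the modeling and transfer tests.
trained_fixture <- function() {
  cached("trained_model", function() {
    tt <- tiny_trial()
    gc_fit <- genotype_clusters(tt$markers, n_components = 8, k_range = 1:6,
                                seed = 1)
    static <- plot_clusters(tt$trial$records, gc_fit)
    cfg <- rnng_config(hidden = 8, epochs = 40, batch_size = 16, seed = 11)
    split <- split_cv(tt$trial$records, seed = 11)[[1]]
    model <- rnng_train(tt$tensor, tt$trial$biomass, split, static = static,
                        config = cfg)
    list(tt = tt, static = static, cfg = cfg, split = split, model = model)
  })
}
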