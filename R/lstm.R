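# Stacked-LSTM regression engine: forward pass, backpropagation through
# time, and Adam. Written in vectorised base R (batch as matrix rows); at
# the problem sizes of plot-level phenotyping (hundreds of plots, 4 time
# steps, tens of features) the matrix products are tiny and this is fast.
#
# Gate layout in the combined weight matrices is [i | f | g | o]:
#   i = sigmoid(x W_i + h U_i + b_i)        input gate
#   f = sigmoid(x W_f + h U_f + b_f)        forget gate
#   g = tanh  (x W_g + h U_g + b_g)         cell candidate
#   o = sigmoid(x W_o + h U_o + b_o)        output gate
#   c = f * c_prev + i * g ;  h = o * tanh(c)
# The final hidden state is concatenated with the static genotype encoding
# and mapped to the scalar biomass output by one fully connected layer.

sigmoid <- function(x) 1 / (1 + exp(-x))

# Uniform(-1/sqrt(H), 1/sqrt(H)) init, forget-gate bias +1 (standard
# recurrent-net practice: start by remembering).
lstm_init <- function(n_features, hidden, n_static, n_layers, seed) {
  with_substream(seed, "init", {
    k <- 1 / sqrt(hidden)
    u <- function(r, c) matrix(runif(r * c, -k, k), r, c)
    layers <- vector("list", n_layers)
    for (l in seq_len(n_layers)) {
      d_in <- if (l == 1) n_features else hidden
      b <- runif(4 * hidden, -k, k)
      b[(hidden + 1):(2 * hidden)] <- 1
      layers[[l]] <- list(W = u(d_in, 4 * hidden),
                          U = u(hidden, 4 * hidden),
                          b = b)
    }
    list(layers = layers,
         w_h = runif(hidden, -k, k),
         w_s = if (n_static > 0) runif(n_static, -k, k) else numeric(0),
         b_out = 0)
  })
}

lstm_param_count <- function(params) {
  sum(vapply(params$layers, function(l) {
    length(l$W) + length(l$U) + length(l$b)
  }, numeric(1))) + length(params$w_h) + length(params$w_s) + 1
}

# Forward pass. xlist: list over time of B x D matrices; static: B x S.
# Returns yhat and (optionally) the caches needed for BPTT.
lstm_forward <- function(params, xlist, static, keep_cache = FALSE) {
  n_t <- length(xlist)
  B <- nrow(xlist[[1]])
  H <- length(params$w_h)
  inputs <- xlist
  caches <- if (keep_cache) vector("list", length(params$layers))
  for (l in seq_along(params$layers)) {
    p <- params$layers[[l]]
    h <- matrix(0, B, H)
    cc <- matrix(0, B, H)
    outs <- vector("list", n_t)
    cache_t <- if (keep_cache) vector("list", n_t)
    for (t in seq_len(n_t)) {
      x <- inputs[[t]]
      pre <- x %*% p$W + h %*% p$U
      pre <- sweep(pre, 2, p$b, `+`)
      i_g <- sigmoid(pre[, 1:H, drop = FALSE])
      f_g <- sigmoid(pre[, (H + 1):(2 * H), drop = FALSE])
      g_g <- tanh(pre[, (2 * H + 1):(3 * H), drop = FALSE])
      o_g <- sigmoid(pre[, (3 * H + 1):(4 * H), drop = FALSE])
      c_new <- f_g * cc + i_g * g_g
      tc <- tanh(c_new)
      h_new <- o_g * tc
      if (keep_cache) {
        cache_t[[t]] <- list(x = x, h_prev = h, c_prev = cc,
                             i = i_g, f = f_g, g = g_g, o = o_g, tc = tc)
      }
      h <- h_new
      cc <- c_new
      outs[[t]] <- h
    }
    if (keep_cache) caches[[l]] <- cache_t
    inputs <- outs
  }
  h_top <- inputs[[n_t]]
  yhat <- as.numeric(h_top %*% params$w_h) + params$b_out
  if (length(params$w_s) > 0) {
    yhat <- yhat + as.numeric(static %*% params$w_s)
  }
  list(yhat = yhat, h_top = h_top, caches = caches)
}

# Backpropagation through time. dy: dL/dyhat (length B). Returns gradients
# with the same shape as params.
lstm_backward <- function(params, fw, static, dy) {
  H <- length(params$w_h)
  n_layers <- length(params$layers)
  n_t <- length(fw$caches[[1]])
  B <- length(dy)

  grads <- list(
    layers = lapply(params$layers, function(p) {
      list(W = matrix(0, nrow(p$W), ncol(p$W)),
           U = matrix(0, H, 4 * H), b = numeric(4 * H))
    }),
    w_h = as.numeric(t(fw$h_top) %*% dy),
    w_s = if (length(params$w_s) > 0) as.numeric(t(static) %*% dy) else
      numeric(0),
    b_out = sum(dy)
  )

  # external dh per layer per time step; top layer only at the last step
  dh_ext <- rep(list(vector("list", n_t)), n_layers)
  dh_ext[[n_layers]][[n_t]] <- dy %o% params$w_h

  for (l in rev(seq_len(n_layers))) {
    p <- params$layers[[l]]
    g <- grads$layers[[l]]
    dh_rec <- matrix(0, B, H)
    dc_rec <- matrix(0, B, H)
    for (t in rev(seq_len(n_t))) {
      ca <- fw$caches[[l]][[t]]
      dh <- dh_rec
      if (!is.null(dh_ext[[l]][[t]])) dh <- dh + dh_ext[[l]][[t]]
      dc <- dc_rec + dh * ca$o * (1 - ca$tc^2)
      dpre_o <- (dh * ca$tc) * ca$o * (1 - ca$o)
      dpre_i <- (dc * ca$g) * ca$i * (1 - ca$i)
      dpre_f <- (dc * ca$c_prev) * ca$f * (1 - ca$f)
      dpre_g <- (dc * ca$i) * (1 - ca$g^2)
      dpre <- cbind(dpre_i, dpre_f, dpre_g, dpre_o)
      g$W <- g$W + t(ca$x) %*% dpre
      g$U <- g$U + t(ca$h_prev) %*% dpre
      g$b <- g$b + colSums(dpre)
      if (l > 1) {
        dx <- dpre %*% t(p$W)
        dh_ext[[l - 1]][[t]] <- if (is.null(dh_ext[[l - 1]][[t]])) dx else
          dh_ext[[l - 1]][[t]] + dx
      }
      dh_rec <- dpre %*% t(p$U)
      dc_rec <- dc * ca$f
    }
    grads$layers[[l]] <- g
  }
  grads
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else p * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t_ <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t_)
    vh <- v / (1 - beta2^t_)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t_))
}
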