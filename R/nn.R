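# Minimal feed-forward network machinery: He-initialised linear layers, ReLU
# activations, inverted dropout, hand-derived backpropagation and Adam.
# Parameter trees contain only numeric leaves (W/b matrices and vectors) so
# the optimizer and gradient checks can treat them generically; architecture
# flags live in the model config, not in the tree. Everything is
# deterministic given the R RNG state, which training seeds explicitly.

nn_linear_init <- function(n_in, n_out) {
  list(
    W = matrix(rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
    b = rep(0, n_out)
  )
}

# An MLP parameter set: a list of linear layers. Whether the final layer is
# passed through the activation is decided at call time (experts/trunk: yes,
# so the gate mixes a common nonneg representation; towers: no, they emit
# logits).
mlp_init <- function(n_in, hidden, n_out = NULL) {
  dims <- c(n_in, hidden, n_out)
  layers <- vector("list", length(dims) - 1L)
  for (i in seq_along(layers)) {
    layers[[i]] <- nn_linear_init(dims[i], dims[i + 1L])
  }
  layers
}

relu <- function(x) x * (x > 0)

# Forward pass. `dropout` is applied to activated hidden outputs when
# `training` is TRUE (inverted dropout, so eval mode needs no rescale).
mlp_forward <- function(layers, X, activate_last = TRUE, dropout = 0,
                        training = FALSE) {
  L <- length(layers)
  cache <- vector("list", L)
  A <- X
  for (i in seq_len(L)) {
    lay <- layers[[i]]
    Z <- A %*% lay$W
    Z <- sweep(Z, 2, lay$b, "+")
    act <- i < L || activate_last
    H <- if (act) relu(Z) else Z
    drop_mask <- NULL
    if (act && training && dropout > 0) {
      drop_mask <- matrix(
        rbinom(length(H), 1L, 1 - dropout) / (1 - dropout),
        nrow(H), ncol(H)
      )
      H <- H * drop_mask
    }
    cache[[i]] <- list(A = A, Z = Z, act = act, drop_mask = drop_mask)
    A <- H
  }
  list(out = A, cache = cache)
}

# Backward pass: returns gradient wrt the input and a grads structure
# congruent with `layers`.
mlp_backward <- function(layers, cache, dOut) {
  L <- length(layers)
  grads <- vector("list", L)
  dH <- dOut
  dZ <- dOut
  for (i in rev(seq_len(L))) {
    cc <- cache[[i]]
    if (!is.null(cc$drop_mask)) dH <- dH * cc$drop_mask
    dZ <- if (cc$act) dH * (cc$Z > 0) else dH
    grads[[i]] <- list(
      W = crossprod(cc$A, dZ),
      b = colSums(dZ)
    )
    if (i > 1L) dH <- tcrossprod(dZ, layers[[i]]$W)
  }
  list(dX = tcrossprod(dZ, layers[[1L]]$W), grads = grads)
}

# ---- generic parameter-tree utilities (Adam, gradient checks) ----

params_flatten <- function(p) {
  if (is.numeric(p)) return(as.numeric(p))
  unlist(lapply(p, params_flatten), use.names = FALSE)
}

params_unflatten <- function(template, v) {
  pos <- 0L
  rebuild <- function(p) {
    if (is.numeric(p)) {
      n <- length(p)
      out <- v[(pos + 1L):(pos + n)]
      pos <<- pos + n
      if (is.matrix(p)) dim(out) <- dim(p)
      return(out)
    }
    lapply(p, rebuild)
  }
  rebuild(template)
}

params_map2 <- function(a, b, f) {
  if (is.numeric(a)) return(f(a, b))
  out <- vector("list", length(a))
  names(out) <- names(a)
  for (i in seq_along(a)) out[[i]] <- params_map2(a[[i]], b[[i]], f)
  out
}

params_zero_like <- function(p) {
  if (is.numeric(p)) return(p * 0)
  lapply(p, params_zero_like)
}

adam_init <- function(params) {
  list(m = params_zero_like(params), v = params_zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- params_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- params_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- params_map2(state$m, state$v, function(m, v) {
    (m / bc1) / (sqrt(v / bc2) + eps)
  })
  list(params = params_map2(params, upd, function(p, u) p - lr * u), state = state)
}
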