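#' Network configuration for multitask models
#'
#' Describes the shared architecture used by both the single-encoder
#' multitask network and the mixture-of-experts (MoE) network: each encoder
#' feeds an expert MLP ending in a shared hidden width, a gate mixes expert
#' representations with convex weights, and a shared trunk feeds one small
#' tower per task, each emitting a single logit. For a single branch the
#' gate is omitted and the model reduces to the plain multitask network, so
#' encoder comparisons keep the number of non-input parameters fixed.
#'
#' @param n_tasks number of prediction tasks (towers).
#' @param branch_dims named integer vector: input width per branch/encoder.
#' @param expert_hidden hidden layer sizes of every expert; the final size is
#'   the shared representation width the gate mixes.
#' @param trunk_hidden hidden sizes of the shared trunk.
#' @param tower_hidden hidden sizes of each task tower.
#' @param dropout dropout fraction applied to hidden activations in training.
#' @param loss_mode `"mean"` (average of per-task masked balanced BCE) or
#'   `"uncertainty"` (learnable per-task homoscedastic uncertainty weights).
#' @param normalize_experts L2-normalize each expert's representation rows
#'   before the gate mixes them (default `TRUE` for multi-branch models)?
#'   Without normalization the network can silence an uninformative branch
#'   by shrinking its expert's output instead of down-weighting it through
#'   the gate, leaving the gate weights uninterpretable as branch
#'   importance.
#' @return An object of class `moe_config`.
#' @export
moe_config <- function(n_tasks, branch_dims,
                       expert_hidden = c(256, 128),
                       trunk_hidden = 128,
                       tower_hidden = 64,
                       dropout = 0.2,
                       loss_mode = c("mean", "uncertainty"),
                       normalize_experts = length(branch_dims) > 1) {
  loss_mode <- match.arg(loss_mode)
  if (is.null(names(branch_dims))) {
    names(branch_dims) <- paste0("branch", seq_along(branch_dims))
  }
  stopifnot(n_tasks >= 1, all(branch_dims > 0), all(expert_hidden > 0),
            all(trunk_hidden > 0), all(tower_hidden > 0),
            dropout >= 0, dropout < 1)
  structure(
    list(
      n_tasks = as.integer(n_tasks),
      task_names = paste0("task", seq_len(n_tasks)),
      branch_dims = branch_dims,
      expert_hidden = as.integer(expert_hidden),
      trunk_hidden = as.integer(trunk_hidden),
      tower_hidden = as.integer(tower_hidden),
      dropout = dropout,
      loss_mode = loss_mode,
      normalize_experts = isTRUE(normalize_experts)
    ),
    class = "moe_config"
  )
}

#' Initialise a multitask (MoE) model
#'
#' @param config a [moe_config()].
#' @param seed integer seed for the parameter draw (He initialisation).
#' @return An object of class `moe_model` holding the config and a parameter
#'   tree (experts, gate, trunk, towers, per-task `log_sigma`).
#' @export
moe_init <- function(config, seed = 1L) {
  stopifnot(inherits(config, "moe_config"))
  set.seed(derive_seed(seed, "init"))
  K <- length(config$branch_dims)
  rep_width <- utils::tail(config$expert_hidden, 1)
  experts <- lapply(config$branch_dims, function(d) {
    mlp_init(d, config$expert_hidden)
  })
  params <- list(
    experts = experts,
    trunk = mlp_init(rep_width, config$trunk_hidden),
    towers = stats::setNames(
      lapply(seq_len(config$n_tasks), function(i) {
        mlp_init(utils::tail(config$trunk_hidden, 1), config$tower_hidden, 1L)
      }),
      config$task_names
    ),
    log_sigma = rep(0, config$n_tasks)
  )
  if (K > 1) {
    params$gate <- nn_linear_init(sum(config$branch_dims), K)
  }
  structure(list(config = config, params = params), class = "moe_model")
}

softmax_rows <- function(Z) {
  E <- exp(Z - apply(Z, 1, max))
  E / rowSums(E)
}

check_branch_features <- function(config, features) {
  if (is.matrix(features)) features <- list(features)
  K <- length(config$branch_dims)
  if (length(features) != K) {
    abort(sprintf("expected %d branch feature matrices, got %d", K, length(features)))
  }
  if (!is.null(names(features)) &&
      setequal(names(features), names(config$branch_dims))) {
    features <- features[names(config$branch_dims)]
  }
  n <- unique(vapply(features, nrow, 1L))
  if (length(n) != 1L) abort("branch feature matrices disagree on row count")
  for (k in seq_len(K)) {
    if (ncol(features[[k]]) != config$branch_dims[k]) {
      abort(sprintf("branch '%s': expected %d columns, got %d",
                    names(config$branch_dims)[k], config$branch_dims[k],
                    ncol(features[[k]])))
    }
  }
  features
}

# Full forward pass. `features`: named list of branch matrices (or a single
# matrix for K = 1). `gate_override`: optional fixed gate weight vector
# (length K) or matrix (n x K), bypassing the learned gate.
moe_forward_full <- function(model, features, training = FALSE,
                             gate_override = NULL) {
  cfg <- model$config
  p <- model$params
  features <- check_branch_features(cfg, features)
  K <- length(features)
  n <- nrow(features[[1]])
  drop <- if (training) cfg$dropout else 0

  hk <- lapply(seq_len(K), function(k) {
    mlp_forward(p$experts[[k]], features[[k]], activate_last = TRUE,
                dropout = drop, training = training)
  })
  Hraw <- lapply(hk, `[[`, "out")
  norms <- NULL
  if (cfg$normalize_experts) {
    norms <- lapply(Hraw, function(h) sqrt(rowSums(h^2) + 1e-8))
    H <- lapply(seq_len(K), function(k) Hraw[[k]] / norms[[k]])
  } else {
    H <- Hraw
  }

  gate_cache <- NULL
  if (!is.null(gate_override)) {
    G <- if (is.matrix(gate_override)) gate_override else
      matrix(gate_override, n, K, byrow = TRUE)
  } else if (K > 1) {
    Xg <- do.call(cbind, features)
    Zg <- sweep(Xg %*% p$gate$W, 2, p$gate$b, "+")
    G <- softmax_rows(Zg)
    gate_cache <- list(Xg = Xg, G = G)
  } else {
    G <- matrix(1, n, 1)
  }

  colnames(G) <- names(cfg$branch_dims)[seq_len(ncol(G))]
  Mix <- G[, 1] * H[[1]]
  if (K > 1) for (k in 2:K) Mix <- Mix + G[, k] * H[[k]]

  tr <- mlp_forward(p$trunk, Mix, activate_last = TRUE,
                    dropout = drop, training = training)
  tw <- lapply(p$towers, function(tl) {
    mlp_forward(tl, tr$out, activate_last = FALSE,
                dropout = drop, training = training)
  })
  logits <- do.call(cbind, lapply(tw, `[[`, "out"))
  colnames(logits) <- cfg$task_names
  list(
    logits = logits, gate_weights = G,
    cache = list(hk = hk, H = H, Hraw = Hraw, norms = norms,
                 gate = gate_cache, tr = tr, tw = tw,
                 features = features, gate_override = !is.null(gate_override))
  )
}

# Backpropagate dLogits (n x T) through the cached forward pass; returns a
# grads tree congruent with model$params (log_sigma grads filled by caller).
moe_backward_full <- function(model, fw, dLogits) {
  cfg <- model$config
  p <- model$params
  K <- length(fw$cache$features)
  grads <- list(experts = vector("list", K))
  names(grads$experts) <- names(p$experts)

  dTr <- 0
  grads$towers <- vector("list", cfg$n_tasks)
  names(grads$towers) <- cfg$task_names
  for (t in seq_len(cfg$n_tasks)) {
    bt <- mlp_backward(p$towers[[t]], fw$cache$tw[[t]]$cache,
                       dLogits[, t, drop = FALSE])
    grads$towers[[t]] <- bt$grads
    dTr <- dTr + bt$dX
  }
  btr <- mlp_backward(p$trunk, fw$cache$tr$cache, dTr)
  grads$trunk <- btr$grads
  dMix <- btr$dX

  G <- fw$gate_weights
  dG <- matrix(0, nrow(dMix), K)
  for (k in seq_len(K)) {
    dHk <- G[, k] * dMix
    dG[, k] <- rowSums(dMix * fw$cache$H[[k]])
    if (cfg$normalize_experts) {
      # y = h / n, n = sqrt(sum h^2 + eps):
      # dL/dh = dY / n - h * (dY . h) / n^3
      h <- fw$cache$Hraw[[k]]
      nn <- fw$cache$norms[[k]]
      dHk <- dHk / nn - h * (rowSums(dHk * h) / nn^3)
    }
    be <- mlp_backward(p$experts[[k]], fw$cache$hk[[k]]$cache, dHk)
    grads$experts[[k]] <- be$grads
  }
  if (K > 1 && !fw$cache$gate_override) {
    # softmax backward: dZ = G * (dG - rowSums(dG * G))
    dZ <- G * (dG - rowSums(dG * G))
    grads$gate <- list(W = crossprod(fw$cache$gate$Xg, dZ), b = colSums(dZ))
  } else if (!is.null(p$gate)) {
    grads$gate <- params_zero_like(p$gate)
  }
  grads$log_sigma <- rep(0, cfg$n_tasks)
  grads[names(p)]
}

#' Forward pass of a single-branch multitask network
#'
#' Evaluation-mode forward pass (dropout off): one logit per task per row.
#'
#' @param model a `moe_model` with exactly one branch.
#' @param features numeric matrix, rows = molecules.
#' @return Logit matrix (batch x tasks).
#' @export
forward_single <- function(model, features) {
  stopifnot(inherits(model, "moe_model"))
  if (length(model$config$branch_dims) != 1L) {
    abort("`forward_single()` requires a single-branch model")
  }
  moe_forward_full(model, features, training = FALSE)$logits
}

#' Forward pass of a mixture-of-experts network
#'
#' Evaluation-mode forward pass. Each expert maps its branch features to a
#' shared-width representation; the gate maps the concatenated raw branch
#' inputs to convex weights on the simplex (softmax); the mixed
#' representation feeds the shared trunk and the per-task towers.
#'
#' @param model a `moe_model`.
#' @param features named list of branch feature matrices (shared row order).
#' @param gate_override optional fixed gate weights (length-K vector or
#'   n x K matrix) replacing the learned gate, e.g. a one-hot vector to
#'   inspect a single expert.
#' @return A list: `logits` (batch x tasks) and `gate_weights` (batch x K).
#' @export
forward_moe <- function(model, features, gate_override = NULL) {
  stopifnot(inherits(model, "moe_model"))
  fw <- moe_forward_full(model, features, training = FALSE,
                         gate_override = gate_override)
  list(logits = fw$logits, gate_weights = fw$gate_weights)
}

#' Predicted activity probabilities
#'
#' @param model a trained `moe_model`.
#' @param features branch feature matrix or named list of matrices.
#' @return Matrix of sigmoid probabilities (batch x tasks).
#' @export
predict_proba <- function(model, features) {
  sigmoid(moe_forward_full(model, features, training = FALSE)$logits)
}

#' Threshold probabilities into binary activity calls
#'
#' Ties at the threshold are called active (probability >= threshold), which
#' favours sensitivity — the screening-oriented reading.
#'
#' @param probabilities matrix of probabilities in `[0, 1]`.
#' @param threshold decision threshold in (0, 1); default 0.5.
#' @return Integer 0/1 matrix of the same shape.
#' @export
classify <- function(probabilities, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  out <- (probabilities >= threshold) * 1L
  dimnames(out) <- dimnames(probabilities)
  out
}

#' Save / load a model checkpoint
#'
#' Checkpoints store the config, parameter tree, task names and (optionally)
#' the encoder specs used to build the features. Loading validates the
#' structure.
#'
#' @param model a `moe_model`.
#' @param path file path.
#' @param task_names optional task names to store (defaults to the config's).
#' @return `save_checkpoint()` the path, invisibly; `load_checkpoint()` the
#'   restored `moe_model`.
#' @export
save_checkpoint <- function(model, path, task_names = NULL) {
  stopifnot(inherits(model, "moe_model"))
  if (!is.null(task_names)) model$config$task_names <- task_names
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "moe_model") ||
      length(model$config$task_names) != model$config$n_tasks) {
    abort("not a valid moetox checkpoint")
  }
  model
}
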