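#' Training configuration
#'
#' @param max_epochs maximum number of epochs.
#' @param patience epochs without validation improvement tolerated before
#'   stopping (`0` stops at the first non-improvement). Must be smaller than
#'   `max_epochs`.
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size (full rows; label sparsity is handled by
#'   the mask, not by row filtering).
#' @param loss_mode `"mean"` or `"uncertainty"`; `NULL` inherits the model
#'   config's mode.
#' @param balance use class-balance positive weights (negative/positive
#'   ratio on the training rows)? Default `TRUE`; set `FALSE` for plain BCE.
#' @param seed integer seed controlling shuffling, dropout and (via
#'   [moe_init()]) initialisation.
#' @return An object of class `train_config`.
#' @export
train_config <- function(max_epochs = 300, patience = 20,
                         learning_rate = 1e-3, batch_size = 128,
                         loss_mode = NULL, balance = TRUE, seed = 1L) {
  stopifnot(max_epochs >= 1, patience >= 0, patience < max_epochs,
            learning_rate > 0, batch_size >= 1)
  if (!is.null(loss_mode)) loss_mode <- match.arg(loss_mode, c("mean", "uncertainty"))
  structure(
    list(max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         loss_mode = loss_mode, balance = isTRUE(balance),
         seed = stopifnot_scalar_int(seed, "seed")),
    class = "train_config"
  )
}

as_feature_list <- function(features) {
  if (is.matrix(features)) list(features) else features
}

# loss + dLogits (+ dlog_sigma) for one batch under the configured mode
batch_loss_and_grad <- function(logits, Y, M, pos_w, loss_mode, log_sigma) {
  bce <- masked_mean_bce(logits, Y, M, pos_w)
  if (loss_mode == "mean") {
    list(loss = bce$loss,
         dLogits = masked_mean_bce_grad(logits, Y, M, pos_w),
         dlog_sigma = rep(0, length(log_sigma)),
         per_task = bce$per_task)
  } else {
    loss <- uncertainty_weighted_loss(bce$per_task, log_sigma)
    g_el <- bce_grad_elementwise(logits, Y, M, pos_w)
    n_obs <- pmax(colSums(M), 1)
    coef <- ifelse(is.na(bce$per_task), 0, exp(-2 * log_sigma) / n_obs)
    list(loss = loss,
         dLogits = sweep(g_el, 2, coef, "*"),
         dlog_sigma = uncertainty_loss_grad_log_sigma(bce$per_task, log_sigma),
         per_task = bce$per_task)
  }
}

#' Train a multitask (or MoE) network
#'
#' Minibatch Adam with early stopping on the validation loss: after each
#' epoch the loss is evaluated on the validation partition (dropout off) and
#' the parameters of the best epoch are returned once `patience`
#' non-improving epochs accumulate. Class-balance weights are computed on
#' the training rows only. Fully deterministic given the config seeds.
#'
#' @param table a [multitask_table()].
#' @param features branch feature matrix or named list of matrices,
#'   row-aligned with `table$molecules`.
#' @param split tibble from [stratified_multitask_split()] (or any tibble
#'   with `molecule` and `partition` columns; only train/validation rows are
#'   used).
#' @param config a [moe_config()].
#' @param train a [train_config()].
#' @return An object of class `moetox_fit`: the trained `model` (best-epoch
#'   parameters), a `history` tibble (epoch, train/validation loss, mean
#'   validation balanced accuracy), `best_epoch`, `pos_weight`, and the mean
#'   validation-set `gate_weights` at the best epoch (multi-branch models).
#' @export
train_mtnn <- function(table, features, split, config, train = train_config()) {
  stopifnot(inherits(table, "multitask_table"), inherits(config, "moe_config"),
            inherits(train, "train_config"))
  features <- as_feature_list(features)
  for (f in features) {
    if (nrow(f) != length(table$molecules)) {
      abort("features must be row-aligned with the table's molecules")
    }
  }
  loss_mode <- train$loss_mode %||% config$loss_mode
  idx <- match(split$molecule, table$molecules)
  rows_tr <- idx[split$partition == "train"]
  rows_va <- idx[split$partition == "validation"]
  if (!length(rows_tr) || !length(rows_va)) {
    abort("split must provide non-empty train and validation partitions")
  }
  if (length(intersect(rows_tr, rows_va))) abort("train and validation overlap")

  pos_w <- if (train$balance) {
    unname(class_balance_weights(table, rows_tr))
  } else {
    rep(1, config$n_tasks)
  }

  model <- moe_init(config, seed = train$seed)
  model$config$task_names <- table$tasks$name
  feats_tr <- lapply(features, function(f) f[rows_tr, , drop = FALSE])
  feats_va <- lapply(features, function(f) f[rows_va, , drop = FALSE])
  Ytr <- table$Y[rows_tr, , drop = FALSE]; Mtr <- table$M[rows_tr, , drop = FALSE]
  Yva <- table$Y[rows_va, , drop = FALSE]; Mva <- table$M[rows_va, , drop = FALSE]

  opt <- adam_init(model$params)
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  bad_epochs <- 0L
  hist <- vector("list", train$max_epochs)
  set.seed(derive_seed(train$seed, "trainloop"))
  n_tr <- length(rows_tr)

  for (epoch in seq_len(train$max_epochs)) {
    perm <- sample.int(n_tr)
    batch_starts <- seq(1, n_tr, by = train$batch_size)
    ep_loss <- 0
    for (s in batch_starts) {
      b <- perm[s:min(s + train$batch_size - 1L, n_tr)]
      if (sum(Mtr[b, ]) == 0) next
      fb <- lapply(feats_tr, function(f) f[b, , drop = FALSE])
      fw <- moe_forward_full(model, fb, training = TRUE)
      lg <- batch_loss_and_grad(fw$logits, Ytr[b, , drop = FALSE],
                                Mtr[b, , drop = FALSE], pos_w, loss_mode,
                                model$params$log_sigma)
      if (!is.finite(lg$loss)) {
        abort(sprintf("training diverged (non-finite loss) at epoch %d", epoch))
      }
      grads <- moe_backward_full(model, fw, lg$dLogits)
      grads$log_sigma <- lg$dlog_sigma
      step <- adam_step(model$params, grads, opt, lr = train$learning_rate)
      model$params <- step$params
      opt <- step$state
      ep_loss <- ep_loss + lg$loss * length(b)
    }
    ep_loss <- ep_loss / n_tr

    fw_va <- moe_forward_full(model, feats_va, training = FALSE)
    lv <- batch_loss_and_grad(fw_va$logits, Yva, Mva, pos_w, loss_mode,
                              model$params$log_sigma)
    pred_va <- classify(sigmoid(fw_va$logits))
    ba <- task_metrics(pred_va, Yva, Mva)$balanced_accuracy
    hist[[epoch]] <- tibble(
      epoch = epoch, train_loss = ep_loss, val_loss = lv$loss,
      val_balanced_accuracy = mean(ba, na.rm = TRUE)
    )
    if (lv$loss < best$loss - 1e-9) {
      best <- list(loss = lv$loss, params = model$params, epoch = epoch,
                   gate = colMeans(fw_va$gate_weights))
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs > train$patience) break
    }
  }
  model$params <- best$params
  structure(
    list(
      model = model,
      history = bind_rows(hist[!vapply(hist, is.null, TRUE)]),
      best_epoch = best$epoch,
      best_val_loss = best$loss,
      gate_weights = if (length(features) > 1) best$gate else NULL,
      pos_weight = stats::setNames(pos_w, table$tasks$name),
      loss_mode = loss_mode,
      train = train
    ),
    class = "moetox_fit"
  )
}

#' @export
print.moetox_fit <- function(x, ...) {
  cat(sprintf("<moetox_fit> %d tasks, loss mode '%s', best epoch %d (val loss %.4f)\n",
              x$model$config$n_tasks, x$loss_mode, x$best_epoch, x$best_val_loss))
  if (!is.null(x$gate_weights)) {
    cat("mean gate weights:",
        paste(sprintf("%s=%.3f", names(x$model$config$branch_dims), x$gate_weights),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Cross-validate a multitask model
#'
#' Rebuilds and retrains the model on each of `k` multitask-stratified
#' folds, collecting per-fold validation metrics and, for multi-branch
#' models, the per-fold mean gate weights (one simplex vector per fold,
#' ready for [gate_summary()]).
#'
#' @param table a [multitask_table()].
#' @param features branch feature matrix or named list.
#' @param k number of folds.
#' @param config a [moe_config()].
#' @param train a [train_config()]; fold `i` trains with seed
#'   `train$seed + i`.
#' @param seed seed for the fold assignment.
#' @return A list: `metrics` (tibble of per-fold, per-task metrics),
#'   `gate_weights` (k x K matrix or `NULL`), `folds`.
#' @export
cross_validate_mtnn <- function(table, features, k = 5L, config,
                                train = train_config(), seed = 1L) {
  folds <- make_folds(table, k = k, seed = seed)
  features <- as_feature_list(features)
  metrics <- vector("list", k)
  gates <- vector("list", k)
  for (i in seq_len(k)) {
    split <- tibble(
      molecule = folds$molecule,
      partition = factor(ifelse(folds$fold == i, "validation", "train"),
                         levels = c("train", "validation", "holdout"))
    )
    tr_i <- train
    tr_i$seed <- train$seed + i
    fit <- train_mtnn(table, features, split, config, tr_i)
    rows_va <- which(folds$fold == i)
    pv <- predict_proba(fit$model,
                        lapply(features, function(f) f[rows_va, , drop = FALSE]))
    m <- task_metrics(classify(pv), table$Y[rows_va, , drop = FALSE],
                      table$M[rows_va, , drop = FALSE])
    metrics[[i]] <- mutate(m, fold = i, .before = 1)
    gates[[i]] <- fit$gate_weights
  }
  gate_mat <- NULL
  if (!is.null(gates[[1]])) {
    gate_mat <- do.call(rbind, gates)
    rownames(gate_mat) <- paste0("fold", seq_len(k))
  }
  list(metrics = bind_rows(metrics), gate_weights = gate_mat, folds = folds)
}

#' Random-forest hyperparameter grid search
#'
#' The single-task baseline protocol: for every combination of number of
#' trees, maximum depth and minimum node size, run stratified k-fold
#' cross-validation, score each fold with the F1 of the positive class, and
#' select the combination with the highest median F1 (ties resolved by
#' deterministic grid order).
#'
#' @param features numeric matrix, rows = molecules.
#' @param labels 0/1 vector.
#' @param grid data frame with columns `num_trees`, `max_depth` (0 =
#'   unlimited), `min_node`; defaults to trees \{100, 300, 500\} x depth
#'   \{0, 10, 20\} x min-leaf \{1, 3, 5\}.
#' @param k folds for the inner cross-validation.
#' @param seed integer seed (fold assignment and forest seeds).
#' @return A list: `best` (one-row tibble), `results` (median F1 per
#'   combination).
#' @export
rf_grid_search <- function(features, labels, grid = NULL, k = 5L, seed = 1L) {
  grid <- grid %||% expand.grid(num_trees = c(100, 300, 500),
                                max_depth = c(0, 10, 20),
                                min_node = c(1, 3, 5))
  stopifnot(nrow(grid) >= 1, length(labels) == nrow(features),
            all(labels %in% c(0, 1)))
  tab <- multitask_table(matrix(labels, ncol = 1,
                                dimnames = list(NULL, "task")))
  folds <- make_folds(tab, k = k, seed = seed)
  f1s <- matrix(NA_real_, nrow(grid), k)
  for (i in seq_len(k)) {
    tr <- folds$fold != i
    for (g in seq_len(nrow(grid))) {
      fit <- ranger_fit(features[tr, , drop = FALSE], labels[tr],
                        grid$num_trees[g], grid$max_depth[g], grid$min_node[g],
                        seed = seed + g)
      pred <- ranger_predict(fit, features[!tr, , drop = FALSE])
      f1s[g, i] <- f1_score(as.integer(pred >= 0.5), labels[!tr])
    }
  }
  med <- apply(f1s, 1, median)
  best_i <- which.max(med)
  results <- as_tibble(grid)
  results$median_f1 <- med
  list(best = results[best_i, ], results = results)
}

f1_score <- function(pred, truth) {
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  if (sum(truth == 1) == 0) {
    warn("fold without positive labels; F1 set to 0")
    return(0)
  }
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

ranger_fit <- function(X, y, num_trees, max_depth, min_node, seed) {
  df <- as.data.frame(X)
  df$.y <- factor(y, levels = c(0, 1))
  ranger::ranger(
    dependent.variable.name = ".y", data = df,
    num.trees = num_trees, max.depth = max_depth, min.node.size = min_node,
    probability = TRUE, seed = seed, num.threads = 1
  )
}

ranger_predict <- function(fit, X) {
  p <- stats::predict(fit, data = as.data.frame(X), num.threads = 1)$predictions
  p[, "1"]
}

#' Train a single-task random-forest baseline
#'
#' Fitted by convention on the merged train+validation rows (baselines have
#' no use for a validation set, so they see more data than the networks).
#'
#' @param features numeric matrix.
#' @param labels 0/1 vector; both classes must be present.
#' @param params one-row data frame with `num_trees`, `max_depth`,
#'   `min_node` (e.g. `rf_grid_search()$best`).
#' @param seed integer seed.
#' @return An object of class `rf_baseline` with a `predict_proba` method
#'   via [predict_proba_rf()].
#' @export
train_rf_baseline <- function(features, labels, params = NULL, seed = 1L) {
  stopifnot(all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2) abort("training labels contain a single class")
  params <- params %||% tibble(num_trees = 300, max_depth = 0, min_node = 1)
  fit <- ranger_fit(features, labels, params$num_trees[1], params$max_depth[1],
                    params$min_node[1], seed = seed)
  structure(list(fit = fit, params = params), class = "rf_baseline")
}

#' Predicted positive-class probability of an RF baseline
#'
#' @param model an `rf_baseline`.
#' @param features numeric matrix.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba_rf <- function(model, features) {
  stopifnot(inherits(model, "rf_baseline"))
  ranger_predict(model$fit, features)
}
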