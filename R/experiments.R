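# Self-contained simulation studies exercising the method's headline
# properties on synthetic data. Each study fixes its generator conditions
# (sample sizes, imbalance, missingness) and varies only the replicate
# seed, so tests and reproduction scripts share one definition of the
# experiment.

#' Gate identifiability study
#'
#' Trains a two-branch mixture of experts on synthetic data where branch A
#' carries the full latent signal and branch B is pure noise, and records
#' the mean gate weight assigned to the informative branch. A working gate
#' should concentrate its weight on branch A, mirroring the way a gate
#' singles out the best encoder for an endpoint.
#'
#' Conditions: 2000 molecules, 4 tasks, latent dimension 4, 16 features per
#' branch, informativeness A = 1 / B = 0. Networks use experts (32, 16),
#' trunk 16, towers 8, dropout 0.2; training uses learning rate 3e-3,
#' patience 40, up to 300 epochs (the gate bias needs more optimizer steps
#' than the predictive layers, so the gate study trains faster and longer
#' than the package defaults).
#'
#' @param seeds integer vector of replicate seeds.
#' @return A tibble with one row per replicate: `seed`, `gate_informative`,
#'   `gate_noise`, `best_epoch`.
#' @export
run_gate_study <- function(seeds = 1:5) {
  rows <- lapply(seeds, function(s) {
    ds <- synth_generate(synth_config(
      n_molecules = 2000, n_tasks = 4, latent_dim = 4,
      branch_dims = c(A = 16, B = 16),
      branch_informativeness = c(A = 1, B = 0),
      task_prevalence = c(0.2, 0.3, 0.4, 0.25), missingness = 0.2,
      seed = 100 + s
    ))
    sp <- suppressWarnings(stratified_multitask_split(ds$table, seed = s))
    cfg <- moe_config(4, c(A = 16, B = 16), expert_hidden = c(32, 16),
                      trunk_hidden = 16, tower_hidden = 8, dropout = 0.2)
    fit <- train_mtnn(ds$table, ds$features, sp, cfg,
                      train_config(max_epochs = 300, patience = 40,
                                   learning_rate = 3e-3, batch_size = 128,
                                   seed = s))
    tibble(seed = s, gate_informative = fit$gate_weights[["A"]],
           gate_noise = fit$gate_weights[["B"]], best_epoch = fit$best_epoch)
  })
  bind_rows(rows)
}

#' Multitask benefit study
#'
#' Compares a multitask network against independent single-task random
#' forests (identical features) on the four most sparsely labelled of 12
#' tasks sharing a latent structure. The multitask model sees all tasks'
#' labels through the shared trunk, so it should beat the per-task
#' baselines exactly where labels are scarce.
#'
#' Conditions: 2000 molecules, 12 tasks, latent dimension 8, one 32-feature
#' branch; per-task missingness 40--80% (the four smallest tasks at 80%,
#' i.e. about 400 observed labels each); prevalence 10--40%. The RF
#' baselines are fitted on the merged train+validation rows of each task.
#'
#' @param seeds integer vector of replicate seeds.
#' @return A tibble per replicate: `seed`, `ba_mtnn`, `ba_rf` (means over
#'   the four smallest tasks, holdout rows) and `gain`.
#' @export
run_multitask_benefit_study <- function(seeds = 1:5) {
  rows <- lapply(seeds, function(s) {
    ds <- synth_generate(synth_config(
      n_molecules = 2000, n_tasks = 12, latent_dim = 8,
      branch_dims = c(A = 32),
      task_prevalence = rep(c(0.1, 0.2, 0.3, 0.4), 3),
      missingness = c(rep(0.8, 4), rep(0.5, 4), rep(0.4, 4)),
      seed = 200 + s
    ))
    sp <- suppressWarnings(stratified_multitask_split(ds$table, seed = s))
    X <- ds$features$A
    cfg <- moe_config(12, c(A = 32), expert_hidden = c(64, 32),
                      trunk_hidden = 32, tower_hidden = 16, dropout = 0.2)
    fit <- train_mtnn(ds$table, X, sp, cfg,
                      train_config(max_epochs = 300, patience = 20,
                                   batch_size = 128, seed = s))
    rows_ho <- which(sp$partition == "holdout")
    pv <- predict_proba(fit$model, X[rows_ho, , drop = FALSE])
    mt <- task_metrics(classify(pv), ds$table$Y[rows_ho, , drop = FALSE],
                       ds$table$M[rows_ho, , drop = FALSE])
    small <- order(ds$table$tasks$n_observed)[1:4]
    rf_ba <- vapply(small, function(t) {
      tr <- which(train_plus_validation(sp) & ds$table$M[, t] == 1)
      ho <- rows_ho[ds$table$M[rows_ho, t] == 1]
      rf <- train_rf_baseline(X[tr, , drop = FALSE], ds$table$Y[tr, t],
                              seed = s)
      p <- predict_proba_rf(rf, X[ho, , drop = FALSE])
      task_metrics(matrix(as.integer(p >= 0.5)),
                   matrix(ds$table$Y[ho, t]))$balanced_accuracy
    }, 1)
    tibble(seed = s,
           ba_mtnn = mean(mt$balanced_accuracy[small]),
           ba_rf = mean(rf_ba),
           gain = mean(mt$balanced_accuracy[small]) - mean(rf_ba))
  })
  bind_rows(rows)
}

#' Class-imbalance handling study
#'
#' Trains the same multitask network twice on strongly imbalanced synthetic
#' tasks (10% positives) — once with the class-balanced cross-entropy, once
#' with plain unweighted BCE — and measures the mean absolute
#' sensitivity--specificity gap at the 0.5 threshold on the holdout rows.
#' Balanced training should shrink the gap.
#'
#' Conditions: 1500 molecules, 4 tasks at 10% prevalence, latent dimension
#' 4, one 24-feature branch, 10% missingness.
#'
#' @param seeds integer vector of replicate seeds.
#' @return A tibble per replicate: `seed`, `gap_balanced`, `gap_unweighted`.
#' @export
run_imbalance_study <- function(seeds = 1:5) {
  rows <- lapply(seeds, function(s) {
    ds <- synth_generate(synth_config(
      n_molecules = 1500, n_tasks = 4, latent_dim = 4,
      branch_dims = c(A = 24), task_prevalence = 0.1, missingness = 0.1,
      seed = 300 + s
    ))
    sp <- suppressWarnings(stratified_multitask_split(ds$table, seed = s))
    X <- ds$features$A
    cfg <- moe_config(4, c(A = 24), expert_hidden = c(32, 16),
                      trunk_hidden = 16, tower_hidden = 8, dropout = 0.2)
    rows_ho <- which(sp$partition == "holdout")
    gaps <- vapply(c(TRUE, FALSE), function(bal) {
      fit <- train_mtnn(ds$table, X, sp, cfg,
                        train_config(max_epochs = 300, patience = 20,
                                     batch_size = 128, seed = s,
                                     balance = bal))
      pv <- predict_proba(fit$model, X[rows_ho, , drop = FALSE])
      mt <- task_metrics(classify(pv), ds$table$Y[rows_ho, , drop = FALSE],
                         ds$table$M[rows_ho, , drop = FALSE])
      gap_statistic(mt)
    }, 1)
    tibble(seed = s, gap_balanced = gaps[1], gap_unweighted = gaps[2])
  })
  bind_rows(rows)
}

#' Applicability-domain recovery study
#'
#' Fits the LOF applicability domain on synthetic training features and
#' scores (a) held-out points from the same distribution, which should
#' stay in-domain, and (b) injected gross outliers displaced by ten
#' training standard deviations, which should be flagged.
#'
#' @param n training points (default 2000).
#' @param n_outliers injected outliers (default 20).
#' @param seed integer seed.
#' @return A list: `outlier_recall`, `indomain_flag_rate`.
#' @export
run_ad_study <- function(n = 2000, n_outliers = 20, seed = 0) {
  set.seed(derive_seed(seed, "ad-study"))
  p <- 8
  Xtr <- matrix(rnorm(n * p), n, p)
  Xho <- matrix(rnorm(n * p), n, p)
  shift <- matrix(rnorm(n_outliers * p), n_outliers, p)
  shift <- shift / sqrt(rowSums(shift^2))
  Xout <- shift * 10 * mean(apply(Xtr, 2, sd)) * sqrt(p)
  m <- fit_ad(Xtr, n_neighbors = 20)
  list(
    outlier_recall = mean(flag_outliers(m, Xout)),
    indomain_flag_rate = mean(flag_outliers(m, Xho))
  )
}
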