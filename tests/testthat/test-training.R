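fast_config <- function(n_tasks, dims, dropout = 0) {
  moe_config(n_tasks, dims, expert_hidden = c(16, 8), trunk_hidden = 8,
             tower_hidden = 4, dropout = dropout)
}

test_that("the network can overfit a small separable multitask set", {
  ds <- separable_dataset(n = 50, seed = 0)
  sp <- tibble::tibble(
    molecule = ds$table$molecules,
    partition = factor(rep(c("train", "validation"), c(40, 10)),
                       levels = c("train", "validation", "holdout"))
  )
  fit <- train_mtnn(ds$table, ds$X, sp, fast_config(2, c(X = ncol(ds$X))),
                    train_config(max_epochs = 200, patience = 200 - 1,
                                 batch_size = 16, seed = 0))
  pred <- classify(predict_proba(fit$model, ds$X[1:40, ]))
  m <- task_metrics(pred, ds$table$Y[1:40, ])
  expect_gte(mean(m$balanced_accuracy), 0.95)
})

test_that("training is bit-reproducible and early stopping is optimal", {
  ds <- separable_dataset(n = 60, seed = 1)
  sp <- tibble::tibble(
    molecule = ds$table$molecules,
    partition = factor(rep(c("train", "validation"), c(45, 15)),
                       levels = c("train", "validation", "holdout"))
  )
  cfg <- fast_config(2, c(X = ncol(ds$X)), dropout = 0.1)
  tc <- train_config(max_epochs = 40, patience = 10, seed = 7)
  f1 <- train_mtnn(ds$table, ds$X, sp, cfg, tc)
  f2 <- train_mtnn(ds$table, ds$X, sp, cfg, tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
  # returned parameters are those of the minimum-validation-loss epoch
  expect_equal(f1$best_val_loss, min(f1$history$val_loss))
  expect_equal(f1$history$val_loss[f1$best_epoch], f1$best_val_loss)
  # patience 0 stops at the first non-improving epoch
  f0 <- train_mtnn(ds$table, ds$X, sp, cfg,
                   train_config(max_epochs = 40, patience = 0, seed = 7))
  stopped_early <- nrow(f0$history) < 40
  if (stopped_early) expect_equal(nrow(f0$history), f0$best_epoch + 1)
})

test_that("uncertainty-weighted training runs and learns task sigmas", {
  ds <- separable_dataset(n = 60, seed = 2)
  sp <- tibble::tibble(
    molecule = ds$table$molecules,
    partition = factor(rep(c("train", "validation"), c(45, 15)),
                       levels = c("train", "validation", "holdout"))
  )
  cfg <- moe_config(2, c(X = ncol(ds$X)), expert_hidden = c(16, 8),
                    trunk_hidden = 8, tower_hidden = 4, dropout = 0,
                    loss_mode = "uncertainty")
  fit <- train_mtnn(ds$table, ds$X, sp, cfg,
                    train_config(max_epochs = 60, patience = 15, seed = 3))
  expect_false(identical(fit$model$params$log_sigma, c(0, 0)))
  expect_true(all(tidy(fit)$sigma > 0))
  expect_equal(glance(fit)$loss_mode, "uncertainty")
})

test_that("cross-validation returns per-fold metrics and simplex gates", {
  ds <- synth_generate(synth_config(n_molecules = 240, n_tasks = 2,
                                    latent_dim = 3,
                                    branch_dims = c(A = 8, B = 8),
                                    branch_informativeness = c(A = 1, B = 0),
                                    missingness = 0.1, seed = 21))
  cv <- cross_validate_mtnn(ds$table, ds$features, k = 3,
                            fast_config(2, c(A = 8, B = 8)),
                            train_config(max_epochs = 15, patience = 5,
                                         batch_size = 64, seed = 1),
                            seed = 1)
  expect_equal(nrow(cv$metrics), 3 * 2)  # k folds x T tasks
  expect_equal(dim(cv$gate_weights), c(3, 2))
  expect_equal(unname(rowSums(cv$gate_weights)), rep(1, 3), tolerance = 1e-6)
  gs <- gate_summary(cv$gate_weights)
  expect_equal(nrow(gs), 2)
  expect_true(all(gs$ci_half_width >= 0))
})

test_that("RF grid search selects by median F1 deterministically", {
  set.seed(5)
  X <- matrix(rnorm(400), 200, 2)
  y <- as.integer(X[, 1] + 0.2 * rnorm(200) > 0)
  one <- rf_grid_search(X, y, grid = data.frame(num_trees = 50, max_depth = 0,
                                                min_node = 1), seed = 1)
  expect_equal(one$best$num_trees, 50)
  grid <- expand.grid(num_trees = c(50, 100), max_depth = c(0, 3),
                      min_node = c(1, 5))
  g1 <- rf_grid_search(X, y, grid = grid, seed = 2)
  g2 <- rf_grid_search(X, y, grid = grid, seed = 2)
  expect_identical(g1$best, g2$best)
  expect_gte(g1$best$median_f1, 0.9)  # separable task
})

test_that("the RF baseline fits, predicts probabilities and guards inputs", {
  set.seed(6)
  X <- matrix(rnorm(600), 300, 2)
  y <- as.integer(X[, 1] > 0)
  tr <- 1:240; ho <- 241:300
  rf <- train_rf_baseline(X[tr, ], y[tr], seed = 4)
  p <- predict_proba_rf(rf, X[ho, ])
  expect_true(all(p >= 0 & p <= 1))
  m <- task_metrics(matrix(as.integer(p >= 0.5)), matrix(y[ho]))
  expect_gte(m$balanced_accuracy, 0.9)
  rf2 <- train_rf_baseline(X[tr, ], y[tr], seed = 4)
  expect_identical(predict_proba_rf(rf2, X[ho, ]), p)
  expect_error(train_rf_baseline(X[tr, ], rep(1, 240)), "single class")
})
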