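make_toy_moe <- function(seed = 3, normalize = TRUE) {
  cfg <- moe_config(3, c(A = 5, B = 4), expert_hidden = c(6, 4),
                    trunk_hidden = 4, tower_hidden = 3, dropout = 0,
                    normalize_experts = normalize)
  moe_init(cfg, seed = seed)
}

toy_features <- function(n = 8, seed = 4) {
  set.seed(seed)
  list(A = matrix(rnorm(n * 5), n, 5), B = matrix(rnorm(n * 4), n, 4))
}

test_that("gate weights live on the probability simplex", {
  set.seed(10)
  for (i in 1:20) {
    model <- make_toy_moe(seed = i)
    X <- toy_features(n = 7, seed = 100 + i)
    fw <- forward_moe(model, X)
    expect_true(all(fw$gate_weights >= 0))
    expect_equal(rowSums(fw$gate_weights), rep(1, 7), tolerance = 1e-6)
  }
})

test_that("zero gate parameters give uniform mixing", {
  model <- make_toy_moe()
  model$params$gate$W[] <- 0
  model$params$gate$b[] <- 0
  fw <- forward_moe(model, toy_features())
  expect_equal(unname(fw$gate_weights), matrix(0.5, 8, 2), tolerance = 1e-12)
})

test_that("a one-hot gate reproduces the single-branch network exactly", {
  model <- make_toy_moe()
  X <- toy_features()
  for (k in 1:2) {
    onehot <- as.numeric(seq_len(2) == k)
    lg_moe <- forward_moe(model, X, gate_override = onehot)$logits
    # build the equivalent single-branch model sharing expert k + trunk/towers
    cfg1 <- moe_config(3, model$config$branch_dims[k],
                       expert_hidden = model$config$expert_hidden,
                       trunk_hidden = model$config$trunk_hidden,
                       tower_hidden = model$config$tower_hidden,
                       dropout = 0, normalize_experts = TRUE)
    single <- moe_init(cfg1, seed = 1)
    single$params$experts[[1]] <- model$params$experts[[k]]
    single$params$trunk <- model$params$trunk
    single$params$towers <- model$params$towers
    lg_single <- forward_single(single, X[[k]])
    expect_identical(unname(lg_moe), unname(lg_single))
  }
})

test_that("forward passes are deterministic and row-consistent in eval mode", {
  model <- make_toy_moe()
  X <- toy_features()
  expect_identical(forward_moe(model, X)$logits, forward_moe(model, X)$logits)
  # identical input rows produce identical logit rows
  X2 <- lapply(X, function(m) m[c(1, 1, 2), , drop = FALSE])
  lg <- forward_moe(model, X2)$logits
  expect_equal(lg[1, ], lg[2, ])
  # a zero-weight network outputs logit 0 -> probability 0.5
  zero <- make_toy_moe()
  zero$params <- moetox:::params_map2(zero$params, zero$params, function(a, b) a * 0)
  expect_equal(unname(predict_proba(zero, X)), matrix(0.5, 8, 3))
})

test_that("classification applies the >= threshold tie rule", {
  p <- matrix(c(0.5, 0.89, 0.9, 0.1), 1)
  expect_equal(unname(classify(p, 0.5)), matrix(c(1L, 1L, 1L, 0L), 1))
  expect_equal(unname(classify(p, 0.9)), matrix(c(0L, 0L, 1L, 0L), 1))
  expect_error(classify(p, 0), "threshold")
  # near-saturated logits map to probabilities near 0/1
  model <- make_toy_moe()
  expect_equal(unname(sigmoid(1e3)), 1)
})

test_that("shape mismatches are rejected with informative errors", {
  model <- make_toy_moe()
  X <- toy_features()
  Xbad <- X; Xbad$A <- Xbad$A[, 1:3]
  expect_error(forward_moe(model, Xbad), "columns")
  Xrow <- X; Xrow$B <- Xrow$B[1:3, ]
  expect_error(forward_moe(model, Xrow), "row count")
  expect_error(forward_single(model, X$A), "single-branch")
})

test_that("checkpoints round-trip through disk", {
  model <- make_toy_moe()
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path, task_names = c("hERG", "ahr", "stress"))
  back <- load_checkpoint(path)
  expect_equal(back$config$task_names, c("hERG", "ahr", "stress"))
  expect_identical(back$params, model$params)
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(1), bad)
  expect_error(load_checkpoint(bad), "checkpoint")
})
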