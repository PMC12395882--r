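test_that("per-task metrics match hand-computed confusion arithmetic", {
  pred <- matrix(c(rep(1, 8), rep(0, 2), rep(0, 6), rep(1, 4)))
  truth <- matrix(c(rep(1, 10), rep(0, 10)))
  m <- task_metrics(pred, truth)
  expect_equal(m$tp, 8); expect_equal(m$fn, 2)
  expect_equal(m$tn, 6); expect_equal(m$fp, 4)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.6)
  expect_equal(m$balanced_accuracy, 0.7)
  expect_equal(m$mcc, 40 / sqrt(9600), tolerance = 1e-12)
  # perfect predictions
  mp <- task_metrics(truth, truth)
  expect_equal(mp$sensitivity, 1); expect_equal(mp$mcc, 1)
})

test_that("undefined ratios propagate as NA, never as zero", {
  # no positives observed: sensitivity undefined
  m <- task_metrics(matrix(c(0, 0)), matrix(c(0, 0)))
  expect_true(is.na(m$sensitivity))
  expect_equal(m$specificity, 1)
  expect_true(is.na(m$balanced_accuracy))
  # fully masked task yields an all-NA row
  m2 <- task_metrics(matrix(0, 2, 1), matrix(0, 2, 1), mask = matrix(0, 2, 1))
  expect_true(all(is.na(m2[, c("tp", "sensitivity", "mcc")])))
})

test_that("metrics agree with brute-force confusion construction", {
  set.seed(8)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    pred <- rbinom(n, 1, 0.5); truth <- rbinom(n, 1, 0.5)
    m <- task_metrics(matrix(pred), matrix(truth))
    tp <- 0; fp <- 0; tn <- 0; fn <- 0
    for (j in seq_len(n)) {
      if (pred[j] == 1 && truth[j] == 1) tp <- tp + 1
      if (pred[j] == 1 && truth[j] == 0) fp <- fp + 1
      if (pred[j] == 0 && truth[j] == 0) tn <- tn + 1
      if (pred[j] == 0 && truth[j] == 1) fn <- fn + 1
    }
    expect_equal(c(m$tp, m$fp, m$tn, m$fn), c(tp, fp, tn, fn))
    if (tp + fn > 0) expect_equal(m$sensitivity, tp / (tp + fn))
    if (tn + fp > 0) expect_equal(m$specificity, tn / (tn + fp))
  }
})

test_that("pooled metrics sum counts before applying the formulas", {
  per_task <- tibble::tibble(
    task = c("t1", "t2"),
    tp = c(5L, 10L), fn = c(5L, 0L), tn = c(5L, 0L), fp = c(5L, 10L)
  )
  pooled <- pooled_metrics(per_task)
  expect_equal(c(pooled$tp, pooled$fn, pooled$tn, pooled$fp), c(15, 5, 5, 15))
  expect_equal(pooled$sensitivity, 0.75)
  expect_equal(pooled$specificity, 0.25)
  expect_equal(pooled$balanced_accuracy, 0.5)
  # single task: pooled equals per-task; order never matters
  single <- task_metrics(matrix(c(1, 0, 1)), matrix(c(1, 1, 0)))
  expect_equal(pooled_metrics(single)$mcc, single$mcc)
  expect_equal(pooled_metrics(per_task[2:1, ])[, -1], pooled[, -1])
})

test_that("the sensitivity-specificity gap averages absolute differences", {
  rep1 <- tibble::tibble(sensitivity = c(0.9, 0.6), specificity = c(0.5, 0.4))
  expect_equal(gap_statistic(rep1), 0.3)
  expect_equal(gap_statistic(tibble::tibble(sensitivity = 0.9,
                                            specificity = 0.5)), 0.4)
  same <- tibble::tibble(sensitivity = c(0.7, 0.8), specificity = c(0.7, 0.8))
  expect_equal(gap_statistic(same), 0)
  # undefined tasks are excluded, all-undefined errors
  withna <- tibble::tibble(sensitivity = c(0.9, NA), specificity = c(0.5, 0.2))
  expect_equal(gap_statistic(withna), 0.4)
  expect_error(gap_statistic(tibble::tibble(sensitivity = NA_real_,
                                            specificity = 0.3)), "defined")
})

test_that("gate summaries report t-based confidence intervals", {
  g <- matrix(rep(c(0.87, 0.08, 0.03, 0.02), each = 10), 10, 4)
  colnames(g) <- c("morgan", "cddd", "md", "bert")
  gs <- gate_summary(g)
  expect_equal(unname(gs$mean), c(0.87, 0.08, 0.03, 0.02))
  expect_equal(unname(gs$ci_half_width), rep(0, 4))
  expect_equal(gs$label[1], "87 ± 0%")
  expect_error(gate_summary(g[1, , drop = FALSE]), "two folds")
  # half-width formula against a direct t.test on one branch
  set.seed(9)
  g2 <- matrix(runif(20), 10, 2)
  gs2 <- gate_summary(g2)
  tt <- t.test(g2[, 1])
  expect_equal(unname(gs2$ci_half_width[1]), diff(tt$conf.int) / 2,
               tolerance = 1e-12)
})

test_that("t confidence intervals achieve nominal coverage", {
  set.seed(0)
  hits <- 0
  for (r in 1:1000) {
    x <- rnorm(10, mean = 0.5, sd = 0.1)
    m <- mean(x)
    hw <- qt(0.975, 9) * sd(x) / sqrt(10)
    if (abs(m - 0.5) <= hw) hits <- hits + 1
  }
  expect_equal(hits / 1000, 0.95, tolerance = 0.02)
})

test_that("group roll-up applies the any-active rule per molecule", {
  pred <- rbind(a = c(0, 0, 1), b = c(0, 0, 0), c = c(1, 1, 0))
  colnames(pred) <- c("t1", "t2", "t3")
  groups <- list(invitro = c("t1", "t2", "t3"), single = "t2")
  out <- group_rollup(pred, groups)
  expect_equal(out$invitro, c(1L, 0L, 1L))
  expect_equal(out$single, unname(pred[, "t2"]))
  expect_error(group_rollup(pred, list(empty = character(0))), "empty")
  expect_error(group_rollup(pred, list(g = "nope")), "unknown task")
})
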