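test_that("build_table assembles the union of molecules with a correct mask", {
  labels <- tibble::tibble(
    molecule = c("A", "B"),
    task = c("t1", "t2"),
    label = c(1, 0)
  )
  tab <- build_table(labels)
  expect_equal(length(tab$molecules), 2)
  expect_equal(unname(tab$M), matrix(c(1, 0, 0, 1), 2, 2))
  expect_equal(tab$Y["A", "t1"], 1)
  expect_equal(tab$tasks$n_observed, c(1L, 1L))
  # a fully observed table has an all-ones mask
  full <- build_table(tidyr::crossing(molecule = c("A", "B", "C"),
                                      task = c("t1", "t2")) |>
                        dplyr::mutate(label = 1 * (molecule == "A")))
  expect_true(all(full$M == 1))
})

test_that("task summary counts match an imbalanced endpoint profile", {
  # an aryl-hydrocarbon-receptor-like endpoint: 3282 observed, 1111 active
  set.seed(3)
  y <- sample(c(rep(1, 1111), rep(0, 3282 - 1111)))
  tab <- multitask_table(matrix(y, ncol = 1, dimnames = list(NULL, "ahr")))
  expect_equal(tab$tasks$n_observed, 3282L)
  expect_equal(tab$tasks$n_active, 1111L)
  expect_equal(round(100 * tab$tasks$n_active / tab$tasks$n_observed), 34)
  # tasks with no observed labels are rejected outright
  Y <- cbind(a = c(1, 0), b = c(0, 1)); M <- cbind(c(1, 1), c(0, 0))
  expect_error(multitask_table(Y, M), "zero observed")
})

test_that("single-task 8:1:1 split hits exact stratified quotas", {
  set.seed(7)
  y <- sample(c(rep(1, 300), rep(0, 700)))
  tab <- multitask_table(matrix(y, ncol = 1, dimnames = list(NULL, "t")))
  sp <- stratified_multitask_split(tab, c(0.8, 0.1, 0.1), seed = 0)
  expect_equal(unname(table(sp$partition)), c(800L, 100L, 100L),
               ignore_attr = TRUE)
  actives <- tapply(tab$Y[, 1], sp$partition, sum)
  expect_equal(as.numeric(actives), c(240, 30, 30))
})

test_that("splits are deterministic, disjoint and exhaustive", {
  ds <- synth_generate(synth_config(n_molecules = 500, n_tasks = 5,
                                    missingness = 0.4, seed = 9))
  s1 <- suppressWarnings(stratified_multitask_split(ds$table, seed = 5))
  s2 <- suppressWarnings(stratified_multitask_split(ds$table, seed = 5))
  expect_identical(s1, s2)
  s3 <- suppressWarnings(stratified_multitask_split(ds$table, seed = 6))
  expect_false(identical(s1$partition, s3$partition))
  expect_equal(sort(s1$molecule), sort(ds$table$molecules))
  expect_equal(anyDuplicated(s1$molecule), 0)
})

test_that("greedy split preserves per-task class balance on a nested design", {
  # task A's molecules are a subset of task B's: A (smaller) is split first,
  # then B's remaining molecules are stratified on B's labels
  set.seed(11)
  n <- 400
  M <- cbind(A = c(rep(1, 100), rep(0, 300)), B = rep(1, n))
  Y <- cbind(A = rbinom(n, 1, 0.3) * M[, "A"], B = rbinom(n, 1, 0.5))
  tab <- multitask_table(Y, M)
  sp <- stratified_multitask_split(tab, seed = 0)
  for (t in c("A", "B")) {
    obs <- tab$M[, t] == 1
    overall <- mean(tab$Y[obs, t])
    for (p in levels(sp$partition)) {
      rows <- obs & sp$partition == p
      expect_lt(abs(mean(tab$Y[rows, t]) - overall), 0.08)
    }
  }
})

test_that("folds partition every molecule exactly once with balanced classes", {
  # class sizes divisible by k: folds are exactly equal
  y100 <- sample(c(rep(1, 30), rep(0, 70)))
  tab100 <- multitask_table(matrix(y100, ncol = 1, dimnames = list(NULL, "t")))
  fd100 <- make_folds(tab100, k = 5, seed = 0)
  expect_equal(as.numeric(table(fd100$fold)), rep(20, 5))
  # general case: fold sizes within the largest-remainder rounding and the
  # union of validation folds is the full set
  set.seed(13)
  y <- rbinom(1000, 1, 0.3)
  y[1:2] <- c(0, 1)
  tab <- multitask_table(matrix(y, ncol = 1, dimnames = list(NULL, "t")))
  fd <- make_folds(tab, k = 5, seed = 0)
  expect_true(all(abs(as.numeric(table(fd$fold)) - 200) <= 2))
  expect_equal(sort(fd$molecule), sort(tab$molecules))
  frac <- tapply(tab$Y[, 1], fd$fold, mean)
  expect_true(all(abs(frac - mean(y)) <= 0.05))
  expect_warning(make_folds(tiny_table(n = 20, prevalence = 0.2), k = 15),
                 "smallest class")
})

test_that("class-balance weights are the neg/pos ratio on training rows", {
  Y <- cbind(rare = c(rep(1, 25), rep(0, 100)),
             balanced = rep(c(1, 0), length.out = 125))
  tab <- multitask_table(Y)
  w <- class_balance_weights(tab)
  expect_equal(unname(w["rare"]), 4)
  expect_equal(unname(w["balanced"]), 62 / 63)
  # weights respond to the row subset (per-split computation, no leakage)
  w_sub <- class_balance_weights(tab, rows = 1:50)
  expect_equal(unname(w_sub["rare"]), 1)
  M <- cbind(rep(1, 4)); Yz <- cbind(rep(0, 4))
  colnames(M) <- colnames(Yz) <- "t"
  expect_error(class_balance_weights(multitask_table(Yz + c(1, 0, 0, 0), M),
                                     rows = 2:4),
               "zero observed positives")
})
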