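#' Sparse multitask label table
#'
#' The central container: an ordered set of molecules, a 0/1 label matrix
#' `Y` (molecules x tasks) and an observed-mask `M` (1 = label present).
#' Labels are meaningful only where `M = 1`; every modelled task must have
#' at least one observed positive and one observed negative.
#'
#' @param Y numeric 0/1 matrix, molecules x tasks; entries at unobserved
#'   positions are ignored (stored as 0).
#' @param M 0/1 observed-mask matrix of the same shape. Defaults to all
#'   observed. `NA`s in `Y` may be used instead of `M`.
#' @param molecules character ids (canonical SMILES or synthetic ids);
#'   defaults to rownames of `Y`.
#' @param task_levels optional character vector of biological levels per
#'   task (e.g. MIE, KE, MOA, AdverseEffect).
#' @return An object of class `multitask_table` with components `molecules`,
#'   `tasks` (a tibble: name, level, n_observed, n_active), `Y` and `M`.
#' @export
multitask_table <- function(Y, M = NULL, molecules = NULL, task_levels = NULL) {
  Y <- as.matrix(Y)
  if (is.null(M)) {
    M <- (!is.na(Y)) * 1L
  } else {
    M <- as.matrix(M)
  }
  stopifnot(all(dim(Y) == dim(M)), all(M %in% c(0, 1)))
  Y[M == 0] <- 0
  if (!all(Y %in% c(0, 1))) abort("observed labels must be 0/1")
  molecules <- molecules %||% rownames(Y) %||% sprintf("mol%05d", seq_len(nrow(Y)))
  task_names <- colnames(Y) %||% paste0("task", seq_len(ncol(Y)))
  n_obs <- colSums(M)
  n_act <- colSums(Y * M)
  if (any(n_obs == 0)) {
    abort(sprintf("task(s) with zero observed labels: %s",
                  paste(task_names[n_obs == 0], collapse = ", ")))
  }
  dimnames(Y) <- dimnames(M) <- list(molecules, task_names)
  tasks <- tibble(
    name = task_names,
    level = task_levels %||% rep(NA_character_, length(task_names)),
    n_observed = as.integer(n_obs),
    n_active = as.integer(n_act)
  )
  structure(list(molecules = molecules, tasks = tasks, Y = Y, M = M),
            class = "multitask_table")
}

#' @export
print.multitask_table <- function(x, ...) {
  cat(sprintf("<multitask_table> %d molecules x %d tasks (%.1f%% observed)\n",
              length(x$molecules), nrow(x$tasks), 100 * mean(x$M)))
  print(x$tasks)
  invisible(x)
}

#' Build a multitask table from long-format labels
#'
#' Takes one row per (molecule, task) labelled pair and assembles the union
#' of molecules across tasks, with the observed-mask set to 0 wherever a
#' molecule lacks a label for a task.
#'
#' @param labels data frame with columns `molecule`, `task`, `label`
#'   (0/1). Column names can be remapped via the arguments.
#' @param molecule,task,label column names in `labels`.
#' @param task_levels optional named vector mapping task name to level.
#' @return A [multitask_table()].
#' @export
build_table <- function(labels, molecule = "molecule", task = "task",
                        label = "label", task_levels = NULL) {
  df <- tibble(
    molecule = as.character(labels[[molecule]]),
    task = as.character(labels[[task]]),
    label = as.numeric(labels[[label]])
  )
  if (!all(df$label %in% c(0, 1))) abort("labels must be 0/1")
  mols <- sort(unique(df$molecule))
  tks <- sort(unique(df$task))
  Y <- matrix(0, length(mols), length(tks), dimnames = list(mols, tks))
  M <- Y
  Y[cbind(match(df$molecule, mols), match(df$task, tks))] <- df$label
  M[cbind(match(df$molecule, mols), match(df$task, tks))] <- 1
  lv <- if (!is.null(task_levels)) unname(task_levels[tks]) else NULL
  multitask_table(Y, M, molecules = mols, task_levels = lv)
}

#' Greedy multitask stratified split
#'
#' Splits molecules into train/validation/holdout at the given ratios while
#' preserving, as far as possible, each task's class balance in every
#' partition. Tasks are visited from the least to the most numerous
#' (ties broken by name); within a task, molecules not yet assigned by an
#' earlier (smaller) task are shuffled with the seed and apportioned
#' class-stratified by largest-remainder quotas. Molecules observed only in
#' later tasks inherit their assignment from the first task that sees them,
#' so every molecule is assigned exactly once.
#'
#' @param table a [multitask_table()].
#' @param ratios length-3 numeric summing to 1 (train, validation, holdout).
#' @param seed integer; the split is reproducible from it.
#' @return A tibble (`molecule`, `partition`) with attributes `ratios` and
#'   `seed`; `partition` is a factor train/validation/holdout.
#' @export
stratified_multitask_split <- function(table, ratios = c(0.8, 0.1, 0.1),
                                       seed = 1L) {
  stopifnot(inherits(table, "multitask_table"), length(ratios) == 3)
  if (abs(sum(ratios) - 1) > 1e-8) abort("`ratios` must sum to 1")
  parts <- c("train", "validation", "holdout")
  assignment <- greedy_stratified_assign(table, length(parts), ratios, seed,
                                         small_to_first = TRUE)
  out <- tibble(
    molecule = table$molecules,
    partition = factor(parts[assignment], levels = parts)
  )
  attr(out, "ratios") <- ratios
  attr(out, "seed") <- seed
  out
}

#' Multitask-stratified cross-validation folds
#'
#' Applies the same greedy per-task stratification as
#' [stratified_multitask_split()] with `k` equal partitions; each molecule
#' lands in exactly one validation fold.
#'
#' @param table a [multitask_table()].
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return A tibble (`molecule`, `fold`) with `fold` in `1:k`.
#' @export
make_folds <- function(table, k = 5L, seed = 1L) {
  stopifnot(inherits(table, "multitask_table"))
  k <- stopifnot_scalar_int(k, "k")
  if (k < 2) abort("`k` must be at least 2")
  smallest <- min(pmin(table$tasks$n_active,
                       table$tasks$n_observed - table$tasks$n_active))
  if (k > smallest) {
    warn(sprintf("k = %d exceeds the smallest class size (%d); folds may be degenerate",
                 k, smallest))
  }
  assignment <- greedy_stratified_assign(table, k, rep(1 / k, k), seed,
                                         small_to_first = FALSE)
  tibble(molecule = table$molecules, fold = as.integer(assignment))
}

# Shared greedy pass. Returns an integer partition index per molecule.
#
# Tasks are visited from least to most numerous. For each task and class,
# the pass is deficit-aware: it first counts how many of the class's
# molecules earlier (smaller) tasks have already placed in each partition,
# then apportions the still-unassigned members so the class's TOTAL
# partition counts track the target ratios as closely as the existing
# assignments allow — maintaining each endpoint's stratification as far as
# possible rather than re-stratifying only the remainder.
#
# small_to_first: send whole undersized classes to partition 1 (train) with
# a warning, as the 8:1:1 split does; folds instead spread them as evenly
# as the quotas allow.
greedy_stratified_assign <- function(table, n_parts, props, seed,
                                     small_to_first = TRUE) {
  set.seed(derive_seed(seed, "split"))
  n <- length(table$molecules)
  assignment <- rep(NA_integer_, n)
  ord <- order(table$tasks$n_observed, table$tasks$name)
  for (t in ord) {
    obs_all <- which(table$M[, t] == 1)
    for (cls in c(1, 0)) {
      members <- obs_all[table$Y[obs_all, t] == cls]
      idx <- members[is.na(assignment[members])]
      if (!length(idx)) next
      idx <- idx[sample.int(length(idx))]
      if (small_to_first && length(members) < n_parts) {
        warn(sprintf(
          "task '%s' class %d has %d member(s), fewer than %d partitions; unassigned ones sent to the first partition",
          table$tasks$name[t], cls, length(members), n_parts))
        assignment[idx] <- 1L
        next
      }
      desired <- largest_remainder(length(members), props)
      placed <- tabulate(assignment[members], nbins = n_parts)
      deficit <- pmax(desired - placed, 0)
      n_u <- length(idx)
      alloc <- if (sum(deficit) >= n_u) {
        if (sum(deficit) > 0) {
          largest_remainder(n_u, deficit / sum(deficit))
        } else {
          largest_remainder(n_u, props)
        }
      } else {
        deficit + largest_remainder(n_u - sum(deficit), props)
      }
      assignment[idx] <- rep.int(seq_len(n_parts), alloc)
    }
  }
  # molecules with no observed labels at all cannot occur (table invariant),
  # but guard anyway
  assignment[is.na(assignment)] <- 1L
  assignment
}

#' Positive-class balance weights per task
#'
#' The balanced cross-entropy up-weights the positive class of each task by
#' the negative/positive count ratio, computed on the training rows only so
#' no information leaks from validation or holdout.
#'
#' @param table a [multitask_table()].
#' @param rows optional integer or logical index of training rows (default:
#'   all rows).
#' @return Named numeric vector of weights, one per task.
#' @export
class_balance_weights <- function(table, rows = NULL) {
  stopifnot(inherits(table, "multitask_table"))
  Y <- table$Y; M <- table$M
  if (!is.null(rows)) {
    Y <- Y[rows, , drop = FALSE]
    M <- M[rows, , drop = FALSE]
  }
  pos <- colSums(Y * M)
  neg <- colSums((1 - Y) * M)
  if (any(pos == 0)) {
    abort(sprintf("task(s) with zero observed positives in the training rows: %s",
                  paste(colnames(Y)[pos == 0], collapse = ", ")))
  }
  stats::setNames(neg / pos, colnames(Y))
}

#' Merge train and validation partitions
#'
#' Baseline learners that do not use a validation set are fitted on the
#' union of the train and validation partitions, so they see strictly more
#' data than the early-stopped networks.
#'
#' @param split a split tibble from [stratified_multitask_split()].
#' @return Logical vector marking rows in train or validation.
#' @export
train_plus_validation <- function(split) {
  split$partition %in% c("train", "validation")
}
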