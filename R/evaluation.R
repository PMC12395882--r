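#' Confusion counts for one task
#'
#' @param pred 0/1 predictions.
#' @param truth 0/1 labels.
#' @return A one-row tibble `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  tibble(
    tp = sum(pred == 1 & truth == 1),
    fp = sum(pred == 1 & truth == 0),
    tn = sum(pred == 0 & truth == 0),
    fn = sum(pred == 0 & truth == 1)
  )
}

# metric formulas from counts; zero-denominator ratios are NA, never 0
metrics_from_counts <- function(cts) {
  with(cts, {
    sens <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
    spec <- ifelse(tn + fp > 0, tn / (tn + fp), NA_real_)
    prec <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
    f1 <- ifelse(!is.na(prec) & !is.na(sens) & (prec + sens) > 0,
                 2 * prec * sens / (prec + sens), NA_real_)
    mcc_den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
    mcc <- ifelse(mcc_den > 0,
                  (as.numeric(tp) * tn - as.numeric(fp) * fn) / mcc_den,
                  NA_real_)
    tibble(
      sensitivity = sens, specificity = spec,
      balanced_accuracy = (sens + spec) / 2,
      f1 = f1, mcc = mcc
    )
  })
}

#' Per-task classification metrics
#'
#' Computes sensitivity, specificity, balanced accuracy, F1 and MCC for each
#' task over observed (mask = 1) entries only. Ratios with a zero
#' denominator are reported as `NA`, never coerced to 0, and a task with no
#' observed entries yields an all-`NA` row.
#'
#' @param predictions 0/1 matrix (molecules x tasks).
#' @param labels 0/1 matrix, same shape.
#' @param mask 0/1 observed mask, same shape (default: all observed).
#' @return A tibble with one row per task: `task`, the counts and metrics.
#' @export
task_metrics <- function(predictions, labels, mask = NULL) {
  predictions <- as.matrix(predictions); labels <- as.matrix(labels)
  mask <- if (is.null(mask)) matrix(1, nrow(labels), ncol(labels)) else as.matrix(mask)
  stopifnot(all(dim(predictions) == dim(labels)), all(dim(labels) == dim(mask)))
  tasks <- colnames(labels) %||% paste0("task", seq_len(ncol(labels)))
  rows <- map(seq_len(ncol(labels)), function(t) {
    obs <- mask[, t] == 1
    cts <- if (any(obs)) {
      confusion_counts(predictions[obs, t], labels[obs, t])
    } else {
      tibble(tp = NA_integer_, fp = NA_integer_, tn = NA_integer_, fn = NA_integer_)
    }
    met <- if (any(obs)) metrics_from_counts(cts) else
      tibble(sensitivity = NA_real_, specificity = NA_real_,
             balanced_accuracy = NA_real_, f1 = NA_real_, mcc = NA_real_)
    dplyr::bind_cols(tibble(task = tasks[t]), cts, met)
  })
  bind_rows(rows)
}

#' Pooled (global) metrics across tasks
#'
#' Sums the per-task confusion counts element-wise and applies the same
#' metric formulas to the combined counts, yielding one global row — the
#' aggregation used for headline multitask performance.
#'
#' @param per_task a tibble with `tp`, `fp`, `tn`, `fn` columns (e.g. from
#'   [task_metrics()]); rows with `NA` counts are dropped with a message in
#'   the `n_excluded` attribute.
#' @return A one-row tibble of pooled counts and metrics.
#' @export
pooled_metrics <- function(per_task) {
  stopifnot(nrow(per_task) >= 1)
  keep <- !is.na(per_task$tp)
  cts <- tibble(
    tp = sum(per_task$tp[keep]), fp = sum(per_task$fp[keep]),
    tn = sum(per_task$tn[keep]), fn = sum(per_task$fn[keep])
  )
  out <- dplyr::bind_cols(tibble(task = "pooled"), cts, metrics_from_counts(cts))
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Mean absolute sensitivity--specificity gap
#'
#' The imbalance diagnostic: the mean over tasks of
#' |sensitivity - specificity|. Balanced training should shrink it. Tasks
#' with an undefined sensitivity or specificity are excluded.
#'
#' @param report tibble with `sensitivity` and `specificity` columns.
#' @return Scalar mean absolute gap.
#' @export
gap_statistic <- function(report) {
  gaps <- abs(report$sensitivity - report$specificity)
  gaps <- gaps[!is.na(gaps)]
  if (!length(gaps)) abort("no task has both sensitivity and specificity defined")
  mean(gaps)
}

#' Gate-weight summary over cross-validation folds
#'
#' Mean per-branch gate weight with a 95% confidence interval based on the
#' t distribution with `n_folds - 1` degrees of freedom.
#'
#' @param fold_gate_weights numeric matrix, folds x branches (each row a
#'   simplex vector of mean gate weights from one rebuilt model).
#' @param conf_level confidence level (default 0.95).
#' @return An object of class `gate_summary`: a tibble `branch`, `mean`,
#'   `ci_half_width`, `label` (percent rendering, e.g. `"87 ± 5%"`).
#' @export
gate_summary <- function(fold_gate_weights, conf_level = 0.95) {
  m <- as.matrix(fold_gate_weights)
  if (nrow(m) < 2) abort("at least two folds are required for a confidence interval")
  branches <- colnames(m) %||% paste0("branch", seq_len(ncol(m)))
  tcrit <- qt(1 - (1 - conf_level) / 2, df = nrow(m) - 1)
  out <- tibble(
    branch = branches,
    mean = colMeans(m),
    ci_half_width = tcrit * apply(m, 2, sd) / sqrt(nrow(m))
  )
  out$label <- sprintf("%.0f ± %.0f%%", 100 * out$mean, 100 * out$ci_half_width)
  class(out) <- c("gate_summary", class(out))
  out
}

#' Endpoint-group activity roll-up
#'
#' Collapses per-task binary predictions into per-molecule group calls: a
#' molecule is active for a group if it is predicted active on at least one
#' task in the group (e.g. the in-vitro endpoints, or the in-vivo/human set
#' which additionally includes apical cardiotoxicity).
#'
#' @param predictions 0/1 matrix (molecules x tasks) with task column names.
#' @param task_groups named list mapping group name to a character vector of
#'   task names.
#' @return A tibble: `molecule` plus one 0/1 column per group.
#' @export
group_rollup <- function(predictions, task_groups) {
  predictions <- as.matrix(predictions)
  tasks <- colnames(predictions)
  if (is.null(tasks)) abort("`predictions` must have task column names")
  mols <- rownames(predictions) %||% sprintf("mol%05d", seq_len(nrow(predictions)))
  out <- tibble(molecule = mols)
  for (g in names(task_groups)) {
    members <- task_groups[[g]]
    if (!length(members)) abort(sprintf("group '%s' is empty", g))
    missing <- setdiff(members, tasks)
    if (length(missing)) {
      abort(sprintf("group '%s' references unknown task(s): %s",
                    g, paste(missing, collapse = ", ")))
    }
    out[[g]] <- as.integer(
      rowSums(predictions[, members, drop = FALSE]) >= 1
    )
  }
  out
}

# ---- broom-style methods ----

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a trained multitask fit
#'
#' One row per task: name, positive-class weight, and (for uncertainty
#' training) the learned task uncertainty sigma.
#'
#' @param x a `moetox_fit`.
#' @param ... unused.
#' @export
tidy.moetox_fit <- function(x, ...) {
  tibble(
    task = x$model$config$task_names,
    pos_weight = unname(x$pos_weight),
    sigma = exp(x$model$params$log_sigma)
  )
}

#' @rdname tidy.moetox_fit
#' @export
glance.moetox_fit <- function(x, ...) {
  tibble(
    n_tasks = x$model$config$n_tasks,
    n_branches = length(x$model$config$branch_dims),
    loss_mode = x$loss_mode,
    epochs_run = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss
  )
}

#' @export
tidy.gate_summary <- function(x, ...) as_tibble(unclass(x))
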