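#' Masked class-balanced binary cross-entropy
#'
#' The multitask training loss for sparse label matrices. Each observed
#' molecule--task pair contributes a weighted binary cross-entropy term
#' \deqn{l = w \, y \, (-\log \sigma(x)) + (1 - y)(-\log(1 - \sigma(x)))}
#' where \eqn{x} is the logit, \eqn{y \in \{0,1\}} the label, \eqn{\sigma}
#' the sigmoid and \eqn{w} the task's positive-class weight (typically the
#' negative/positive count ratio of the training split, see
#' [class_balance_weights()]). Unobserved pairs (mask 0) contribute nothing —
#' neither to the value nor to any gradient. The per-task loss is the mean
#' over that task's observed entries; the scalar loss is the mean over tasks
#' with at least one observed entry, so densely labelled tasks do not
#' dominate.
#'
#' @param logits numeric matrix, batch x tasks, raw (pre-sigmoid) outputs.
#' @param labels numeric matrix of 0/1, same shape; values at masked
#'   positions are ignored.
#' @param mask numeric matrix of 0/1, same shape; 1 marks an observed label.
#' @param pos_weight positive-class weight per task (length = n tasks, or a
#'   scalar recycled). Default 1 (plain BCE).
#' @return A list with elements `loss` (scalar), `per_task` (length-T vector,
#'   `NA` for tasks with no observed entry in the batch), and `n_observed`
#'   (observed entries per task).
#' @examples
#' masked_mean_bce(matrix(0), matrix(1), matrix(1))$loss  # log(2)
#' @export
masked_mean_bce <- function(logits, labels, mask, pos_weight = 1) {
  logits <- as.matrix(logits); labels <- as.matrix(labels); mask <- as.matrix(mask)
  stopifnot(all(dim(logits) == dim(labels)), all(dim(logits) == dim(mask)))
  if (!all(mask %in% c(0, 1))) abort("`mask` must be 0/1")
  obs <- mask == 1
  if (!any(obs)) abort("no observed labels: every entry of `mask` is 0")
  if (!all(labels[obs] %in% c(0, 1))) abort("observed `labels` must be 0/1")
  Tn <- ncol(logits)
  w <- rep_len(pos_weight, Tn)
  if (any(w <= 0)) abort("`pos_weight` must be positive")

  # stable elementwise loss: w*y*softplus(-x) + (1-y)*softplus(x)
  W <- matrix(w, nrow(logits), Tn, byrow = TRUE)
  el <- W * labels * softplus(-logits) + (1 - labels) * softplus(logits)
  el[!obs] <- 0
  n_obs <- colSums(mask)
  per_task <- ifelse(n_obs > 0, colSums(el) / pmax(n_obs, 1), NA_real_)
  list(
    loss = mean(per_task[!is.na(per_task)]),
    per_task = per_task,
    n_observed = as.integer(n_obs)
  )
}

# Gradient of the elementwise weighted BCE wrt logits, before any pooling:
# d l / d x = s (1 - y + w y) - w y,  s = sigmoid(x). Masked entries are 0.
bce_grad_elementwise <- function(logits, labels, mask, pos_weight) {
  Tn <- ncol(logits)
  W <- matrix(rep_len(pos_weight, Tn), nrow(logits), Tn, byrow = TRUE)
  s <- sigmoid(logits)
  g <- s * (1 - labels + W * labels) - W * labels
  g * mask
}

# Gradient of masked_mean_bce$loss wrt logits (per-task mean, then mean over
# observed tasks).
masked_mean_bce_grad <- function(logits, labels, mask, pos_weight = 1) {
  g <- bce_grad_elementwise(logits, labels, mask, pos_weight)
  n_obs <- colSums(mask)
  t_obs <- sum(n_obs > 0)
  coef <- ifelse(n_obs > 0, 1 / (t_obs * n_obs), 0)
  sweep(g, 2, coef, "*")
}

#' Uncertainty-weighted multitask loss
#'
#' Combines per-task losses with learnable homoscedastic task uncertainties
#' \eqn{\sigma_i}: \deqn{\mathrm{Loss} = \sum_i \frac{1}{\sigma_i^2} L_i +
#' \sum_i \log \sigma_i.} Tasks whose loss is `NA` (no observed labels in the
#' batch) are excluded from both sums. The \eqn{1/\sigma^2} factor lets the
#' model down-weight noisy tasks while the \eqn{\log \sigma} term stops the
#' weights from collapsing to zero. \eqn{\sigma_i = \exp(\mathrm{log\_sigma}_i)}
#' is positive by construction.
#'
#' @param per_task_losses numeric vector of per-task losses (`NA` allowed for
#'   tasks absent from the batch); must be finite and non-negative otherwise.
#' @param log_sigma numeric vector, same length: the log of each task's
#'   uncertainty parameter.
#' @return Scalar loss.
#' @examples
#' uncertainty_weighted_loss(c(1, 1), c(0, 0))  # sigma = 1 recovers the sum
#' @export
uncertainty_weighted_loss <- function(per_task_losses, log_sigma) {
  stopifnot(length(per_task_losses) == length(log_sigma))
  keep <- !is.na(per_task_losses)
  L <- per_task_losses[keep]
  if (any(!is.finite(L)) || any(L < 0)) {
    abort("per-task losses must be finite and non-negative")
  }
  ls <- log_sigma[keep]
  sum(L * exp(-2 * ls)) + sum(ls)
}

# d Loss / d log_sigma_i = -2 L_i exp(-2 ls_i) + 1 (0 for excluded tasks)
uncertainty_loss_grad_log_sigma <- function(per_task_losses, log_sigma) {
  g <- rep(0, length(log_sigma))
  keep <- !is.na(per_task_losses)
  g[keep] <- -2 * per_task_losses[keep] * exp(-2 * log_sigma[keep]) + 1
  g
}
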