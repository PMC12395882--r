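# Shared test fixtures and independent oracles.

# Brute-force per-element masked balanced BCE: explicit loops, no vectorised
# shortcuts, kept independent of the implementation it checks.
bce_brute_force <- function(logits, labels, mask, pos_weight) {
  Tn <- ncol(logits)
  w <- rep_len(pos_weight, Tn)
  per_task <- rep(NA_real_, Tn)
  for (t in seq_len(Tn)) {
    acc <- 0; n <- 0
    for (i in seq_len(nrow(logits))) {
      if (mask[i, t] == 1) {
        p <- 1 / (1 + exp(-logits[i, t]))
        acc <- acc + if (labels[i, t] == 1) -w[t] * log(p) else -log(1 - p)
        n <- n + 1
      }
    }
    if (n > 0) per_task[t] <- acc / n
  }
  list(loss = mean(per_task[!is.na(per_task)]), per_task = per_task)
}

# central finite differences over a parameter tree
numeric_gradient <- function(lossfun, params, indices, eps = 1e-5) {
  pv <- moetox:::params_flatten(params)
  out <- numeric(length(indices))
  for (j in seq_along(indices)) {
    i <- indices[j]
    p1 <- pv; p1[i] <- p1[i] + eps
    p2 <- pv; p2[i] <- p2[i] - eps
    out[j] <- (lossfun(moetox:::params_unflatten(params, p1)) -
                 lossfun(moetox:::params_unflatten(params, p2))) / (2 * eps)
  }
  out
}

# small deterministic multitask table: n molecules, T tasks, given prevalence
tiny_table <- function(n = 60, n_tasks = 2, prevalence = 0.4, missing = 0,
                       seed = 42) {
  set.seed(seed)
  Y <- matrix(rbinom(n * n_tasks, 1, prevalence), n, n_tasks)
  M <- matrix(rbinom(n * n_tasks, 1, 1 - missing), n, n_tasks)
  for (t in seq_len(n_tasks)) {
    M[1:2, t] <- 1; Y[1, t] <- 1; Y[2, t] <- 0
  }
  colnames(Y) <- colnames(M) <- paste0("task", seq_len(n_tasks))
  multitask_table(Y, M)
}

# a linearly separable 2-task dataset for overfit smoke tests
separable_dataset <- function(n = 50, p = 6, seed = 0) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  Y <- cbind(as.integer(X[, 1] > 0), as.integer(X[, 2] + X[, 3] > 0))
  colnames(Y) <- c("task1", "task2")
  rownames(X) <- sprintf("m%03d", seq_len(n))
  list(table = multitask_table(Y, molecules = rownames(X)), X = X)
}

cli_path <- function() {
  p <- system.file("cli", "moetox.R", package = "moetox")
  stopifnot(nzchar(p))
  p
}

run_cli <- function(...) {
  out <- system2("Rscript", c(cli_path(), ...), stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status")
  list(output = out, status = if (is.null(status)) 0L else status)
}
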