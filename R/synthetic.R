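#' Configuration for the synthetic multitask generator
#'
#' The generator emulates the statistical structure a multitask
#' cardiotoxicity table exhibits: many binary endpoints driven by shared
#' latent chemistry, strong class imbalance, and per-endpoint missingness
#' (each endpoint is only measured for a subset of chemicals). It does not
#' attempt realistic chemistry — features are linear read-outs of the latent
#' space plus noise, one block per encoder branch, with a tunable
#' informativeness per branch.
#'
#' @param n_molecules number of molecules.
#' @param n_tasks number of binary endpoints.
#' @param latent_dim dimension of the shared latent factor.
#' @param branch_dims named integer vector: feature width per branch.
#' @param branch_informativeness named numeric in `[0, 1]` per branch; 1 =
#'   features carry the full latent signal, 0 = pure noise.
#' @param task_prevalence per-task target positive rate in (0, 1); recycled.
#' @param missingness per-task probability that a label is unobserved, in
#'   `[0, 1)`; recycled.
#' @param noise_sd standard deviation of the logit noise (label noise).
#' @param signal_scale scale of the task logits before noise; larger values
#'   give cleaner (more separable) tasks.
#' @param seed integer seed; the dataset is fully reproducible from it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_molecules = 2000, n_tasks = 12, latent_dim = 8,
                         branch_dims = c(A = 32),
                         branch_informativeness = NULL,
                         task_prevalence = 0.3, missingness = 0.3,
                         noise_sd = 1, signal_scale = 3, seed = 1L) {
  if (is.null(names(branch_dims))) {
    names(branch_dims) <- LETTERS[seq_along(branch_dims)]
  }
  branch_informativeness <- branch_informativeness %||%
    stats::setNames(rep(1, length(branch_dims)), names(branch_dims))
  task_prevalence <- rep_len(task_prevalence, n_tasks)
  missingness <- rep_len(missingness, n_tasks)
  stopifnot(
    n_molecules > 0, n_tasks > 0, latent_dim > 0, all(branch_dims > 0),
    all(branch_informativeness >= 0), all(branch_informativeness <= 1),
    all(task_prevalence > 0), all(task_prevalence < 1),
    all(missingness >= 0), all(missingness < 1),
    noise_sd >= 0, signal_scale > 0
  )
  structure(
    list(
      n_molecules = as.integer(n_molecules), n_tasks = as.integer(n_tasks),
      latent_dim = as.integer(latent_dim), branch_dims = branch_dims,
      branch_informativeness = branch_informativeness[names(branch_dims)],
      task_prevalence = task_prevalence, missingness = missingness,
      noise_sd = noise_sd, signal_scale = signal_scale,
      seed = stopifnot_scalar_int(seed, "seed")
    ),
    class = "synth_config"
  )
}

#' Generate a synthetic multitask dataset
#'
#' Draws a shared latent factor \eqn{z \sim N(0, I)}, per-branch features as
#' an informativeness-scaled linear map of \eqn{z} plus unit noise, and
#' per-task labels from a Bernoulli-sigmoid model on a task-specific linear
#' read-out of \eqn{z}. Each task's intercept is calibrated by 1-D root
#' finding so the expected positive rate matches the configured prevalence.
#' Masks are missing-completely-at-random per task. Byte-identical output is
#' guaranteed for a fixed config (including the seed).
#'
#' @param config a [synth_config()].
#' @return An object of class `synth_dataset`: a list with `table` (a
#'   [multitask_table()]), `features` (named list of branch matrices),
#'   `latent`, `task_weights`, `intercepts` and `config`.
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(derive_seed(config$seed, "synth"))
  n <- config$n_molecules; Tn <- config$n_tasks; d <- config$latent_dim
  mols <- sprintf("syn%05d", seq_len(n))

  z <- matrix(rnorm(n * d), n, d)

  features <- imap(as.list(config$branch_dims), function(p, nm) {
    A <- matrix(rnorm(d * p, sd = 1 / sqrt(d)), d, p)
    alpha <- config$branch_informativeness[[nm]]
    X <- alpha * (z %*% A) + matrix(rnorm(n * p), n, p)
    rownames(X) <- mols
    colnames(X) <- sprintf("%s_f%03d", nm, seq_len(p))
    X
  })

  W <- matrix(rnorm(d * Tn, sd = 1 / sqrt(d)), d, Tn)
  raw_logit <- config$signal_scale * (z %*% W) +
    config$noise_sd * matrix(rnorm(n * Tn), n, Tn)

  intercepts <- vapply(seq_len(Tn), function(t) {
    target <- config$task_prevalence[t]
    f <- function(c) mean(sigmoid(raw_logit[, t] + c)) - target
    sol <- tryCatch(uniroot(f, c(-60, 60), tol = 1e-10), error = function(e) NULL)
    if (is.null(sol)) abort(sprintf("prevalence %.3f unreachable for task %d", target, t))
    sol$root
  }, 1)

  P <- sigmoid(sweep(raw_logit, 2, intercepts, "+"))
  Y <- matrix(rbinom(n * Tn, 1L, as.vector(P)), n, Tn)
  M <- matrix(rbinom(n * Tn, 1L, rep(1 - config$missingness, each = n)), n, Tn)
  # table invariant: each task needs an observed example of both classes
  for (t in seq_len(Tn)) {
    obs <- which(M[, t] == 1)
    if (!length(obs) || length(unique(Y[obs, t])) < 2) {
      need <- if (!length(obs)) c(0, 1) else setdiff(c(0, 1), unique(Y[obs, t]))
      for (cls in need) {
        cand <- which(Y[, t] == cls)
        if (!length(cand)) abort(sprintf("task %d produced a single class; raise n or adjust prevalence", t))
        M[cand[1], t] <- 1L
      }
    }
  }
  tnames <- sprintf("task%02d", seq_len(Tn))
  dimnames(Y) <- dimnames(M) <- list(mols, tnames)

  structure(
    list(
      table = multitask_table(Y, M, molecules = mols),
      features = features,
      latent = z, task_weights = W, intercepts = intercepts,
      config = config
    ),
    class = "synth_dataset"
  )
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf("<synth_dataset> %d molecules, %d tasks, %d branch(es)\n",
              x$config$n_molecules, x$config$n_tasks, length(x$features)))
  print(x$table)
  invisible(x)
}

#' Small deterministic SMILES fixtures
#'
#' Enumerates simple, valid, structurally distinct organic SMILES (alkanes,
#' alcohols, aromatics, ethers, amines) for end-to-end pipeline smoke tests.
#'
#' @param n how many SMILES to return (up to 40).
#' @return Character vector of `n` distinct parseable SMILES.
#' @export
generate_smiles_fixtures <- function(n = 10) {
  stopifnot(n >= 0)
  base <- c(
    "CC", "CCC", "CCCC", "CCCCC", "CCCCCC", "CCCCCCC",
    "CO", "CCO", "CCCO", "CC(C)O", "CC(C)CO", "OCCO",
    "c1ccccc1", "Cc1ccccc1", "CCc1ccccc1", "Oc1ccccc1", "Nc1ccccc1",
    "COC", "CCOC", "CCOCC", "CN", "CCN", "CC(C)N", "CNC",
    "CC(=O)O", "CCC(=O)O", "CC(=O)N", "CC(=O)C", "CCC(=O)C",
    "C1CCCCC1", "C1CCCC1", "C1CCOC1", "C1CCNC1",
    "Cc1ccccc1C", "Cc1ccc(C)cc1", "COc1ccccc1", "CC(C)(C)O",
    "C=C", "CC=C", "C#N"
  )
  if (n > length(base)) abort(sprintf("at most %d fixtures available", length(base)))
  base[seq_len(n)]
}
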