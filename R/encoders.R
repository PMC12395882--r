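# Molecular encoders behind a uniform registry: every encoder is a function
# from a character vector of (accepted, canonical) SMILES to a numeric
# matrix with one row per molecule and a fixed declared width. Circular
# (Morgan-style ECFP) fingerprints and a physicochemical descriptor battery
# are built in; learned embeddings (CDDD/ChemBERTa-like) plug in through
# register_encoder() without the package shipping any weights.

.moetox_registry <- new.env(parent = emptyenv())

#' Describe an encoder
#'
#' @param name unique encoder name.
#' @param dimension output feature width (positive integer).
#' @param kind `"binary_fingerprint"`, `"numeric_descriptors"` or
#'   `"embedding_plugin"`.
#' @param params named list of encoder parameters.
#' @return An object of class `encoder_spec`.
#' @export
encoder_spec <- function(name, dimension,
                         kind = c("binary_fingerprint", "numeric_descriptors",
                                  "embedding_plugin"),
                         params = list()) {
  kind <- match.arg(kind)
  stopifnot(nzchar(name), dimension > 0)
  structure(list(name = name, dimension = as.integer(dimension),
                 kind = kind, params = params),
            class = "encoder_spec")
}

#' Register an encoder
#'
#' Makes an encoder addressable by name in [encode_molecules()] and configs.
#' The function's output width is validated against the declared dimension
#' at first use.
#'
#' @param spec an [encoder_spec()].
#' @param fn function(smiles_vector) returning an n x dimension matrix.
#' @param overwrite replace an existing registration? Default `FALSE`
#'   (duplicate names error).
#' @return The spec, invisibly.
#' @export
register_encoder <- function(spec, fn, overwrite = FALSE) {
  stopifnot(inherits(spec, "encoder_spec"), is.function(fn))
  if (!overwrite && exists(spec$name, envir = .moetox_registry)) {
    abort(sprintf("encoder '%s' is already registered", spec$name))
  }
  assign(spec$name, list(spec = spec, fn = fn), envir = .moetox_registry)
  invisible(spec)
}

#' List registered encoders
#'
#' @return A tibble: `name`, `dimension`, `kind`.
#' @export
list_encoders <- function() {
  nms <- sort(ls(.moetox_registry))
  bind_rows(lapply(nms, function(nm) {
    s <- get(nm, envir = .moetox_registry)$spec
    tibble(name = s$name, dimension = s$dimension, kind = s$kind)
  }))
}

#' Encode molecules with a registered encoder
#'
#' @param smiles character vector of canonical SMILES.
#' @param encoder encoder name (see [list_encoders()]).
#' @return Numeric matrix (molecules x features) with the encoder spec in
#'   the `"encoder"` attribute.
#' @export
encode_molecules <- function(smiles, encoder = "morgan") {
  if (!exists(encoder, envir = .moetox_registry)) {
    abort(sprintf("unknown encoder '%s'", encoder))
  }
  entry <- get(encoder, envir = .moetox_registry)
  X <- entry$fn(smiles)
  if (!is.matrix(X) || nrow(X) != length(smiles)) {
    abort(sprintf("encoder '%s' returned a malformed matrix", encoder))
  }
  spec <- entry$spec
  if (ncol(X) != spec$dimension) {
    # descriptor batteries may legitimately shrink when a descriptor is
    # undefined for every molecule in the batch; anything else is a bug
    if (spec$kind == "numeric_descriptors" && ncol(X) < spec$dimension) {
      spec$dimension <- ncol(X)
    } else {
      abort(sprintf("encoder '%s' declared dimension %d but returned %d columns",
                    encoder, spec$dimension, ncol(X)))
    }
  }
  attr(X, "encoder") <- spec
  X
}

smiles_to_sdf <- function(smiles) {
  ids <- sprintf("m%05d", seq_along(smiles))
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, ids))),
    error = function(e) abort(sprintf("SMILES parsing failed: %s", conditionMessage(e)))
  )
  ok <- vapply(seq_along(smiles), function(i) {
    ab <- tryCatch(ChemmineR::atomblock(sdf[[i]]), error = function(e) NULL)
    !is.null(ab) && nrow(ab) > 0
  }, TRUE)
  bad <- which(!ok)
  if (length(bad)) {
    abort(sprintf("unparseable SMILES at row(s) %s — run standardize_smiles() first",
                  paste(bad, collapse = ", ")))
  }
  sdf
}

#' Circular (Morgan-style) fingerprints
#'
#' Extended-connectivity fingerprints: atom identifiers are iteratively
#' updated from each atom's neighbourhood up to the given radius and hashed
#' into a fixed-length binary vector (OpenBabel ECFP, folded from its 4096
#' native bits to `n_bits` by modular OR). Deterministic and independent of
#' the SMILES spelling.
#'
#' @param smiles character vector of canonical SMILES.
#' @param n_bits fingerprint length (default 1024; at most 4096).
#' @param radius neighbourhood radius (default 2, i.e. ECFP4).
#' @return Binary matrix, molecules x `n_bits`.
#' @export
morgan_encode <- function(smiles, n_bits = 1024, radius = 2) {
  stopifnot(n_bits > 0, n_bits <= 4096, radius >= 0)
  sdf <- smiles_to_sdf(smiles)
  fp <- ChemmineR::fingerprintOB(sdf, sprintf("ECFP%d", 2 * radius))@fpma
  n_native <- ncol(fp)
  out <- matrix(0, nrow(fp), n_bits)
  for (j in seq_len(n_native)) {
    tgt <- (j - 1) %% n_bits + 1
    out[, tgt] <- pmax(out[, tgt], fp[, j])
  }
  rownames(out) <- smiles
  colnames(out) <- sprintf("bit%04d", seq_len(n_bits))
  out
}

#' Physicochemical descriptor battery
#'
#' Computes a battery of 1-D/2-D descriptors per molecule: OpenBabel
#' physicochemical properties (MW, logP, TPSA, MR, H-bond donors/acceptors,
#' ...), element counts, bond-order counts, and ring descriptors. Ring
#' descriptors that are undefined for acyclic molecules (e.g. mean ring
#' size) are returned as `NA` and are meant to be imputed by
#' [fit_preprocessor()]. Column names are stable across calls.
#'
#' @param smiles character vector of canonical SMILES.
#' @return Numeric matrix, molecules x descriptors (may contain `NA`).
#' @export
descriptor_encode <- function(smiles) {
  sdf <- smiles_to_sdf(smiles)
  pr <- ChemmineR::propOB(sdf)
  num_cols <- c("HBA1", "HBA2", "HBD", "logP", "MR", "MW", "nF", "TPSA")
  P <- as.matrix(pr[, intersect(num_cols, colnames(pr)), drop = FALSE])

  elements <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")
  ac <- ChemmineR::atomcountMA(sdf, addH = FALSE)
  E <- matrix(0, length(smiles), length(elements),
              dimnames = list(NULL, paste0("n", elements)))
  for (e in intersect(elements, colnames(ac))) E[, paste0("n", e)] <- ac[, e]

  graph <- t(vapply(seq_along(smiles), function(i) {
    bb <- tryCatch(ChemmineR::bondblock(sdf[[i]]), error = function(e) NULL)
    ord <- if (!is.null(bb) && nrow(bb) > 0) bb[, 3] else integer(0)
    rg <- tryCatch(ChemmineR::rings(sdf[[i]], type = "all", arom = FALSE),
                   error = function(e) list())
    sizes <- lengths(rg)
    c(
      n_atoms = nrow(ChemmineR::atomblock(sdf[[i]])),
      n_bonds = length(ord),
      n_single = sum(ord == 1), n_double = sum(ord == 2),
      n_triple = sum(ord == 3),
      n_rings = length(sizes),
      mean_ring_size = if (length(sizes)) mean(sizes) else NA_real_
    )
  }, numeric(7)))

  X <- cbind(P, E, graph)
  rownames(X) <- smiles
  all_na <- apply(X, 2, function(col) all(is.na(col)))
  if (any(all_na)) {
    warn(sprintf("dropping all-missing descriptor column(s): %s",
                 paste(colnames(X)[all_na], collapse = ", ")))
    X <- X[, !all_na, drop = FALSE]
  }
  X
}

#' Fit feature preprocessing on the training rows
#'
#' Median imputation plus z-standardization, with all statistics estimated
#' on the training rows only (no leakage). Constant columns get sd fixed to
#' 1 (scaling is a no-op); columns entirely missing in the training rows
#' are dropped with a warning.
#'
#' @param X numeric feature matrix (may contain `NA`).
#' @param train_rows integer or logical index of training rows.
#' @param scale standardize columns? Default `TRUE`; binary fingerprints
#'   should be passed through ([preprocess] with `scale = FALSE` only
#'   imputes).
#' @return An object of class `feature_preprocessor`.
#' @export
fit_preprocessor <- function(X, train_rows, scale = TRUE) {
  X <- as.matrix(X)
  Xt <- X[train_rows, , drop = FALSE]
  if (nrow(Xt) == 0) abort("`train_rows` selects no rows")
  all_na <- apply(Xt, 2, function(col) all(is.na(col)))
  if (any(all_na)) {
    warn(sprintf("dropping column(s) with no observed training values: %s",
                 paste(colnames(Xt)[all_na], collapse = ", ")))
  }
  keep <- which(!all_na)
  Xt <- Xt[, keep, drop = FALSE]
  med <- apply(Xt, 2, median, na.rm = TRUE)
  Xi <- Xt
  for (j in seq_along(keep)) Xi[is.na(Xi[, j]), j] <- med[j]
  mu <- colMeans(Xi)
  sds <- apply(Xi, 2, sd)
  sds[!is.finite(sds) | sds < .Machine$double.eps] <- 1
  structure(
    list(keep = keep, keep_names = colnames(X)[keep], medians = med,
         means = if (scale) mu else rep(0, length(keep)),
         sds = if (scale) sds else rep(1, length(keep)),
         scale = scale),
    class = "feature_preprocessor"
  )
}

#' Apply a fitted preprocessor
#'
#' @param prep a `feature_preprocessor`.
#' @param X numeric matrix with the same columns the preprocessor was
#'   fitted on.
#' @return Imputed, scaled matrix with no missing values.
#' @export
apply_preprocessor <- function(prep, X) {
  stopifnot(inherits(prep, "feature_preprocessor"))
  X <- as.matrix(X)[, prep$keep, drop = FALSE]
  for (j in seq_along(prep$keep)) X[is.na(X[, j]), j] <- prep$medians[j]
  X <- sweep(X, 2, prep$means, "-")
  sweep(X, 2, prep$sds, "/")
}

register_builtin_encoders <- function() {
  if (!exists("morgan", envir = .moetox_registry)) {
    register_encoder(
      encoder_spec("morgan", 1024, "binary_fingerprint",
                   params = list(n_bits = 1024, radius = 2)),
      function(smiles) morgan_encode(smiles, n_bits = 1024, radius = 2)
    )
  }
  if (!exists("descriptors", envir = .moetox_registry)) {
    register_encoder(
      encoder_spec("descriptors", 24, "numeric_descriptors"),
      function(smiles) descriptor_encode(smiles)
    )
  }
}

.onLoad <- function(libname, pkgname) {
  register_builtin_encoders()
}
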