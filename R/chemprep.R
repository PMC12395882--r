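# SMILES curation: stereo removal, canonicalization (OpenBabel), filtering
# of inorganic/organometallic structures and mixtures, duplicate merging and
# assay-outcome collapsing. The element rules: a structure is inorganic if
# it has no carbon atom; organometallic if an element outside the allowed
# organic set is covalently bonded to carbon. Multi-fragment SMILES are
# rejected outright (no largest-fragment rescue).

ORGANIC_ELEMENTS <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S",
                      "Cl", "Se", "Br", "I")

strip_stereo <- function(smiles) {
  gsub("[@/\\\\]", "", smiles)
}

ob_canonical <- function(smiles) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", smiles),
    error = function(e) ""
  )
  trimws(out)
}

# element symbols from a canonical SMILES by tokenization (fallback for
# bond-less molecules whose SDF atom block is malformed)
smiles_elements <- function(smiles) {
  pat <- "\\[[^\\]]+\\]|Cl|Br|Si|Se|B|C|N|O|P|S|F|I|b|c|n|o|p|s"
  toks <- regmatches(smiles, gregexpr(pat, smiles))[[1]]
  vapply(toks, function(tk) {
    if (startsWith(tk, "[")) {
      el <- sub("^\\[[0-9]*([A-Za-z][a-z]?).*$", "\\1", tk)
    } else {
      el <- tk
    }
    paste0(toupper(substr(el, 1, 1)), substring(el, 2))
  }, "", USE.NAMES = FALSE)
}

# element symbols and bond pairs from a parsed single SMILES; NULL if the
# toolkit cannot parse it
parse_structure <- function(smiles) {
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(c(m = smiles))),
    error = function(e) NULL
  )
  if (is.null(sdf)) return(NULL)
  # validSDF() is deliberately not used: it rejects legitimate bond-less
  # structures (single atoms, ionic pairs) that we still need to classify
  ab <- tryCatch(ChemmineR::atomblock(sdf[[1]]), error = function(e) NULL)
  if (is.null(ab) || nrow(ab) == 0) return(NULL)
  bb <- tryCatch(ChemmineR::bondblock(sdf[[1]]), error = function(e) NULL)
  if (!all(grepl("_", rownames(ab)))) {
    # single-atom molecules get a degenerate atom block; recover the element
    # list from the canonical SMILES itself (no bonds exist)
    return(list(elements = smiles_elements(smiles), bonds = matrix(0L, 0, 2)))
  }
  elements <- sub("_.*$", "", rownames(ab))
  bonds <- if (!is.null(bb) && nrow(bb) > 0) {
    cbind(bb[, 1], bb[, 2])
  } else {
    matrix(0L, 0, 2)
  }
  list(elements = elements, bonds = bonds)
}

#' Standardize SMILES strings
#'
#' For each input SMILES: strips stereochemistry markers, canonicalizes with
#' OpenBabel, and rejects structures that are unparseable, carbon-free
#' (inorganic), have a non-organic element bonded to carbon
#' (organometallic), or contain multiple fragments (mixtures). When several
#' reasons apply the first in that order is reported. The operation is
#' idempotent: standardizing an accepted canonical SMILES returns it
#' unchanged, and any two spellings of the same molecule map to the same
#' canonical form. Never throws on bad input — failures are rows with
#' `status = "rejected"`.
#'
#' @param smiles character vector of SMILES.
#' @return A tibble with one row per input: `input`, `canonical_smiles`
#'   (`NA` when rejected), `status` (`"accepted"`/`"rejected"`) and
#'   `rejection_reason` (`"none"`, `"unparseable"`, `"inorganic"`,
#'   `"organometallic"`, `"mixture"`).
#' @examples
#' \donttest{
#' standardize_smiles(c("c1ccccc1", "[Na+].[Cl-]", "C[C@@H](O)C"))
#' }
#' @export
standardize_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  rows <- map(smiles, standardize_one)
  out <- bind_rows(rows)
  out$input <- smiles
  out[, c("input", "canonical_smiles", "status", "rejection_reason")]
}

standardize_one <- function(s) {
  rejected <- function(reason) {
    tibble(canonical_smiles = NA_character_, status = "rejected",
           rejection_reason = reason)
  }
  if (is.na(s) || !nzchar(trimws(s))) return(rejected("unparseable"))
  can <- ob_canonical(strip_stereo(trimws(s)))
  if (!nzchar(can)) return(rejected("unparseable"))
  st <- parse_structure(can)
  if (is.null(st)) return(rejected("unparseable"))
  if (!"C" %in% st$elements) return(rejected("inorganic"))
  if (nrow(st$bonds) > 0) {
    e1 <- st$elements[st$bonds[, 1]]
    e2 <- st$elements[st$bonds[, 2]]
    metal_c <- (e1 == "C" & !(e2 %in% ORGANIC_ELEMENTS)) |
      (e2 == "C" & !(e1 %in% ORGANIC_ELEMENTS))
    if (any(metal_c)) return(rejected("organometallic"))
  }
  if (grepl(".", can, fixed = TRUE)) return(rejected("mixture"))
  tibble(canonical_smiles = can, status = "accepted", rejection_reason = "none")
}

#' Collapse assay outcomes into an activity label
#'
#' A chemical is active for an endpoint if at least one of its assays for
#' that endpoint is positive, inactive if all observed assays are negative,
#' and missing if no assay was run. Adding a positive outcome can therefore
#' never turn an active call inactive.
#'
#' @param outcomes vector (possibly empty) of 0/1 assay outcomes.
#' @return `"active"`, `"inactive"` or `"missing"`.
#' @export
label_activity <- function(outcomes) {
  outcomes <- outcomes[!is.na(outcomes)]
  if (!length(outcomes)) return("missing")
  if (!all(outcomes %in% c(0, 1))) {
    abort("malformed assay table: outcomes must be 0/1")
  }
  if (any(outcomes == 1)) "active" else "inactive"
}

#' Merge duplicate structures
#'
#' Collapses records sharing a canonical SMILES into one row, merging their
#' per-endpoint labels with the same any-positive (OR) rule used for assay
#' collapsing: a duplicate group is active for an endpoint if any member
#' is, inactive if any member is observed and none is active, missing
#' otherwise.
#'
#' @param records data frame with a `canonical_smiles` column plus 0/1/`NA`
#'   label columns.
#' @param label_cols character vector naming the label columns (default:
#'   everything except `canonical_smiles`).
#' @return A tibble with one row per canonical SMILES, sorted by canonical
#'   SMILES.
#' @export
deduplicate <- function(records, label_cols = NULL) {
  stopifnot("canonical_smiles" %in% names(records))
  label_cols <- label_cols %||% setdiff(names(records), "canonical_smiles")
  if (!nrow(records)) {
    return(as_tibble(records[, c("canonical_smiles", label_cols)]))
  }
  or_merge <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) NA_real_ else as.numeric(any(x == 1))
  }
  records |>
    as_tibble() |>
    group_by(.data$canonical_smiles) |>
    summarise(dplyr::across(dplyr::all_of(label_cols), or_merge),
              .groups = "drop") |>
    arrange(.data$canonical_smiles)
}

#' Curate a raw chemical table end to end
#'
#' Standardizes the SMILES column, drops rejected structures (logging the
#' reason per input row), merges duplicates with the OR rule, and returns a
#' curated table in deterministic order (sorted by canonical SMILES).
#'
#' @param data data frame with an id column, a SMILES column and 0/1/empty
#'   endpoint label columns.
#' @param smiles_col,id_col column names (defaults `"smiles"`, `"id"`).
#' @return A list: `curated` (tibble: `canonical_smiles` + endpoint
#'   columns), `rejects` (tibble: `id`, `smiles`, `reason`).
#' @export
prep_chemicals <- function(data, smiles_col = "smiles", id_col = "id") {
  stopifnot(smiles_col %in% names(data))
  ids <- if (id_col %in% names(data)) as.character(data[[id_col]]) else
    sprintf("row%05d", seq_len(nrow(data)))
  std <- standardize_smiles(as.character(data[[smiles_col]]))
  label_cols <- setdiff(names(data), c(smiles_col, id_col))
  rejects <- tibble(
    id = ids[std$status == "rejected"],
    smiles = std$input[std$status == "rejected"],
    reason = std$rejection_reason[std$status == "rejected"]
  )
  keep <- std$status == "accepted"
  curated <- tibble(canonical_smiles = std$canonical_smiles[keep])
  for (cl in label_cols) {
    curated[[cl]] <- suppressWarnings(as.numeric(data[[cl]][keep]))
  }
  list(curated = deduplicate(curated, label_cols), rejects = rejects)
}
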