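test_that("standardization accepts organics and strips stereochemistry", {
  res <- standardize_smiles(c("c1ccccc1", "C[C@@H](O)C", "CC(C)O", "CC/C=C/CC"))
  expect_true(all(res$status == "accepted"))
  expect_equal(res$rejection_reason, rep("none", 4))
  # stereo marker removal: the chiral and achiral spellings collapse
  expect_identical(res$canonical_smiles[2], res$canonical_smiles[3])
  expect_false(any(grepl("[@/\\\\]", res$canonical_smiles)))
})

test_that("standardization rejects inorganics, organometallics and mixtures", {
  res <- standardize_smiles(c("[Na+].[Cl-]", "[OH2]", "C[Hg]C", "CCO.CC",
                              "not-a-smiles", "", NA))
  expect_true(all(res$status == "rejected"))
  expect_equal(res$rejection_reason,
               c("inorganic", "inorganic", "organometallic", "mixture",
                 "unparseable", "unparseable", "unparseable"))
  expect_true(all(is.na(res$canonical_smiles)))
})

test_that("standardization is idempotent and spelling-invariant", {
  spellings <- list(c("CCO", "OCC"), c("c1ccccc1", "C1=CC=CC=C1"),
                    c("CC(C)O", "OC(C)C"))
  for (pair in spellings) {
    res <- standardize_smiles(pair)
    expect_identical(res$canonical_smiles[1], res$canonical_smiles[2])
  }
  once <- standardize_smiles(generate_smiles_fixtures(15))
  twice <- standardize_smiles(once$canonical_smiles)
  expect_identical(twice$canonical_smiles, once$canonical_smiles)
  expect_true(all(twice$status == "accepted"))
})

test_that("label_activity applies the any-positive rule", {
  expect_identical(label_activity(c(1, 0, 0)), "active")
  expect_identical(label_activity(c(0, 0)), "inactive")
  expect_identical(label_activity(numeric(0)), "missing")
  # monotone: appending a positive can never deactivate
  set.seed(1)
  for (i in 1:20) {
    out <- rbinom(sample(1:5, 1), 1, 0.5)
    before <- label_activity(out)
    after <- label_activity(c(out, 1))
    expect_identical(after, "active")
    if (before == "active") expect_identical(after, before)
  }
  expect_error(label_activity(c(0, 2)), "malformed")
})

test_that("deduplicate OR-merges labels per canonical structure", {
  df <- tibble::tibble(
    canonical_smiles = c("CCO", "CCO", "CC", "CCC"),
    hERG = c(1, 0, NA, 0),
    ahr = c(NA, 0, 1, NA)
  )
  out <- deduplicate(df)
  expect_equal(nrow(out), 3)
  expect_equal(out$hERG[out$canonical_smiles == "CCO"], 1)  # 1 OR 0 -> 1
  expect_equal(out$ahr[out$canonical_smiles == "CCO"], 0)   # NA OR 0 -> 0
  expect_true(is.na(out$hERG[out$canonical_smiles == "CC"]))
  # distinct structures pass through unchanged in count
  distinct <- tibble::tibble(canonical_smiles = c("CC", "CCC"), y = c(1, 0))
  expect_equal(nrow(deduplicate(distinct)), 2)
  # empty input -> empty output
  expect_equal(nrow(deduplicate(df[0, ])), 0)
  # uniqueness invariant
  expect_equal(anyDuplicated(out$canonical_smiles), 0)
})

test_that("prep_chemicals curates a raw table end to end", {
  raw <- data.frame(
    id = paste0("c", 1:6),
    smiles = c("CCO", "OCC", "[Na+].[Cl-]", "c1ccccc1", "bogus", "C[C@@H](O)C"),
    hERG = c(1, 0, 1, 0, 1, NA),
    stress = c(NA, 1, 0, 0, 1, 1)
  )
  res <- prep_chemicals(raw)
  expect_equal(nrow(res$rejects), 2)
  expect_setequal(res$rejects$reason, c("inorganic", "unparseable"))
  # CCO and OCC merged with OR rule
  expect_equal(nrow(res$curated), 3)
  cco <- res$curated[res$curated$canonical_smiles == "CCO", ]
  expect_equal(cco$hERG, 1)
  expect_equal(cco$stress, 1)
  # deterministic order: sorted by canonical SMILES
  expect_identical(res$curated$canonical_smiles,
                   sort(res$curated$canonical_smiles))
})
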