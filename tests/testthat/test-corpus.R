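## Corpus ingestion, SOM labeling, dataset assembly and splitting.

write_tmp_corpus <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("parent_smiles\tproducts_smiles", rows), path)
  path
}

test_that("reaction tables parse and reject bad rows with a report", {
  path <- write_tmp_corpus(c(
    "CC(=O)Nc1ccccc1\tCC(=O)O.Nc1ccccc1",
    "C1CC\tCC",                                # unclosed ring: rejected
    "CCOC(=O)C\tCCOC(=O)C >> CC(=O)O.CCO"))    # '>>' prefix accepted
  corp <- parse_reaction_corpus(path)
  expect_length(corp, 2L)
  expect_identical(length(corp[[1]]$products), 2L)
  report <- attr(corp, "parse_report")
  expect_identical(report$row, 2L)
  expect_match(report$reason, "ring")
  expect_error(parse_reaction_corpus(write_tmp_corpus("C1CC\tC")), "no valid")
})

test_that("written corpora round-trip byte-identically through canonical SMILES", {
  corp <- generate_corpus(synth_config(n_molecules = 10L, seed = 7L),
                          hy_rules())
  path <- tempfile(fileext = ".tsv")
  write_reaction_table(corp$records, path)
  back <- parse_reaction_corpus(path)
  expect_identical(vapply(back, `[[`, character(1), "parent"),
                   vapply(corp$records, `[[`, character(1), "parent"))
  for (k in seq_along(back)) {
    expect_identical(back[[k]]$products, corp$records[[k]]$products)
  }
})

test_that("SOM labeling marks rule-explained atoms and only those", {
  rb <- hy_rules()
  rec <- hydrosite:::new_reaction_record(
    "ace", canonical_smiles("CC(=O)Nc1ccccc1"),
    c(canonical_smiles("CC(=O)O"), canonical_smiles("Nc1ccccc1")))
  lab <- label_som_atoms(rec, rb)
  expect_false(attr(lab, "unexplained"))
  pos <- lab[lab$label == "SOM+", ]
  expect_identical(nrow(pos), 1L)
  expect_identical(pos$element, "N")
  ## every other tracked atom is SOM-
  expect_identical(sum(lab$label == "SOM-"), nrow(lab) - 1L)
  ## labeling is idempotent: same input, same labels
  expect_identical(label_som_atoms(rec, rb), lab)
})

test_that("records whose products are unexplained are flagged", {
  rb <- hy_rules()
  parent <- canonical_smiles("CC(=O)Nc1ccccc1")
  rec <- hydrosite:::new_reaction_record("self", parent, parent)
  lab <- label_som_atoms(rec, rb)
  expect_true(attr(lab, "unexplained"))
  expect_true(all(lab$label == "SOM-"))
})

test_that("class tables partition the tracked atoms", {
  corp <- hy_corpus()
  ds <- build_atom_datasets(corp$records, hy_rules())
  n_by_class <- vapply(c("N", "O", "C", "S", "X"), function(cl) {
    sum(ds$labels$atom_class == cl)
  }, integer(1))
  expect_identical(nrow(ds$datasets[["Global-Hydrolysis"]]),
                   sum(n_by_class))
  expect_true(all(ds$datasets[["N-Hydrolysis"]]$element == "N"))
  expect_true(all(ds$datasets[["O-Hydrolysis"]]$element == "O"))
  expect_true(all(ds$datasets[["C-Hydrolysis"]]$element == "C"))
  ## single amide molecule: element-wise row counts
  rec <- hydrosite:::new_reaction_record(
    "ace", canonical_smiles("CC(=O)Nc1ccccc1"),
    canonical_smiles("CC(=O)O"))
  one <- build_atom_datasets(
    structure(list(rec), class = "hydro_corpus"), hy_rules())
  expect_identical(nrow(one$datasets[["N-Hydrolysis"]]), 1L)
  expect_identical(nrow(one$datasets[["C-Hydrolysis"]]), 8L)
  expect_identical(nrow(one$datasets[["O-Hydrolysis"]]), 1L)
})

test_that("splits are molecule-grouped, ratio-exact and deterministic", {
  corp <- hy_corpus()
  table <- corp$labels
  ## 10-molecule subset: exactly 8/2
  sub <- table[table$record_id %in% unique(table$record_id)[1:10], ]
  sp <- split_dataset(sub, 0.8, seed = 1L)
  expect_length(sp$train_ids, 8L)
  expect_length(sp$test_ids, 2L)
  ## determinism and disjointness on the full table
  s1 <- split_dataset(table, 0.8, seed = 1L)
  s2 <- split_dataset(table, 0.8, seed = 1L)
  expect_identical(s1$train_ids, s2$train_ids)
  expect_identical(s1$test, s2$test)
  expect_length(intersect(s1$train_ids, s1$test_ids), 0L)
  expect_length(intersect(unique(s1$train$record_id),
                          unique(s1$test$record_id)), 0L)
  expect_error(split_dataset(table[table$record_id == table$record_id[1], ]),
               "at least 2")
})

test_that("feature-joined tables carry 1032 feature columns", {
  corp <- generate_corpus(synth_config(n_molecules = 10L, seed = 11L),
                          hy_rules())
  parents <- stats::setNames(
    vapply(corp$records, `[[`, character(1), "parent"),
    vapply(corp$records, `[[`, character(1), "record_id"))
  fm <- hydrosite:::build_feature_matrix(corp$labels, parents)
  expect_identical(ncol(fm$X), 1032L)
  expect_identical(nrow(fm$X), nrow(corp$labels))
  ## CSV export carries the documented header
  path <- tempfile(fileext = ".csv")
  write_feature_table(corp$labels, parents, path)
  hdr <- strsplit(readLines(path, n = 1L), ",")[[1]]
  expect_identical(gsub("\"", "", hdr[1:3]),
                   c("record_id", "atom_index", "fp_0000"))
  expect_identical(gsub("\"", "", hdr[length(hdr)]), "label")
  expect_length(hdr, 1035L)
})
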