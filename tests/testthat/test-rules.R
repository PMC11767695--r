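## Rule base loading, site matching, transformation application, validation.

test_that("the shipped rule base loads and covers every atom class", {
  rb <- hy_rules()
  expect_gte(length(rb$rules), 12L)
  classes <- vapply(rb$rules, `[[`, character(1), "atom_class")
  expect_setequal(unique(classes), c("N", "O", "C", "S", "X"))
  families <- vapply(rb$rules, `[[`, character(1), "family")
  expect_true(all(c("amide", "nitrile", "urea", "carbamate", "ester",
                    "carbonate", "oxime", "phosphoester", "thioether",
                    "acyl_halide", "haloalkane") %in% families))
})

test_that("malformed rule bases fail atomically with named errors", {
  rb_raw <- jsonlite::fromJSON(system.file(
    "extdata", "rules", "hydrolysis_rules.json", package = "hydrosite"),
    simplifyVector = FALSE)
  dup <- rb_raw
  dup$rules[[2]]$rule_id <- dup$rules[[1]]$rule_id
  f1 <- tempfile(fileext = ".json")
  jsonlite::write_json(dup, f1, auto_unbox = TRUE)
  expect_error(load_rulebase(f1), "duplicate rule_id")

  bad <- rb_raw
  bad$rules[[3]]$smarts <- "C(=O"
  f2 <- tempfile(fileext = ".json")
  jsonlite::write_json(bad, f2, auto_unbox = TRUE)
  expect_error(load_rulebase(f2), bad$rules[[3]]$rule_id)
})

test_that("every shipped rule reproduces its golden reactant/product pair", {
  report <- validate_rulebase(hy_rules())
  expect_true(all(report$pass))
  expect_true(attr(report, "pass"))
})

test_that("a corrupted golden product fails exactly its own pair", {
  pairs <- utils::read.delim(system.file(
    "extdata", "rules", "golden_pairs.tsv", package = "hydrosite"),
    stringsAsFactors = FALSE)
  pairs$products_smiles[3] <- "CCCCCC"
  report <- validate_rulebase(hy_rules(), pairs)
  expect_identical(which(!report$pass), 3L)
})

test_that("heavy atoms balance to parent + water oxygen(s) for every rule", {
  bal <- audit_rule_balance(hy_rules())
  expect_true(all(bal$pass))
  expect_identical(bal$product_atoms, bal$parent_atoms + bal$expected_delta)
})

test_that("site matching finds the expected centers on known molecules", {
  rb <- hy_rules()
  ## flamprop-methyl: ester O and amide N, nothing else
  fla <- match_sites(SMI_FLAMPROP_METHYL, rb)
  expect_identical(nrow(fla), 2L)
  expect_setequal(fla$element, c("O", "N"))
  expect_setequal(fla$rule_id, c("ester_hydrolysis", "amide_hydrolysis"))
  ## methane: nothing
  expect_identical(nrow(match_sites("C", rb)), 0L)
  ## N-methylacetamide: a single amide match centered on N
  nma <- match_sites("CC(=O)NC", rb)
  nma <- nma[nma$rule_id == "amide_hydrolysis", ]
  expect_identical(nrow(nma), 1L)
  expect_identical(nma$element, "N")
})

test_that("rule application yields the textbook products", {
  rb <- hy_rules()
  nma <- match_sites("CC(=O)NC", rb)
  amide <- nma[nma$rule_id == "amide_hydrolysis", ]
  prods <- apply_rule("CC(=O)NC", "amide_hydrolysis", amide$atom_index, rb)
  expect_setequal(prods, c(canonical_smiles("CC(=O)O"), canonical_smiles("CN")))

  des <- match_sites(SMI_DESMEDIPHAM, rb)
  all_prods <- unique(unlist(des$products))
  expect_true(canonical_smiles("CCOC(=O)Nc1cccc(O)c1") %in% all_prods)
  expect_true(canonical_smiles("Nc1cccc(OC(=O)Nc2ccccc2)c1") %in% all_prods)
})

test_that("automorphic centers collapse to a single site match", {
  rb <- hy_rules()
  ## para-symmetric diester: the two acetate O centers are equivalent
  sym <- match_sites("CC(=O)Oc1ccc(OC(=O)C)cc1", rb)
  est <- sym[sym$rule_id == "ester_hydrolysis", ]
  expect_identical(nrow(est), 1L)
  ## without collapse both centers are reported
  sym2 <- match_sites("CC(=O)Oc1ccc(OC(=O)C)cc1", rb,
                      collapse_symmetric = FALSE)
  expect_identical(nrow(sym2[sym2$rule_id == "ester_hydrolysis", ]), 2L)
})

test_that("matching and application are deterministic pure functions", {
  rb <- hy_rules()
  a <- match_sites(SMI_CYANOPHOS, rb)
  b <- match_sites(SMI_CYANOPHOS, rb)
  expect_identical(a, b)
})
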