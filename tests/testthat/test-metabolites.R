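## Metabolite generation, ranking and product evaluation.

test_that("desmedipham yields exactly the two reported transformations", {
  des <- generate_metabolites(SMI_DESMEDIPHAM, hy_rules())
  expect_identical(attr(des, "n_transformations"), 2L)
  expect_true(canonical_smiles("CCOC(=O)Nc1cccc(O)c1") %in%
                des$product_smiles[des$fragment_role == "major"])
  expect_true(canonical_smiles("Nc1cccc(OC(=O)Nc2ccccc2)c1") %in%
                des$product_smiles[des$fragment_role == "major"])
})

test_that("cyanophos collapses to three distinct transformations", {
  cyn <- generate_metabolites(SMI_CYANOPHOS, hy_rules())
  expect_identical(attr(cyn, "n_transformations"), 3L)
  fams <- unique(cyn[, c("rank", "rule_id")])
  ## two phosphoester cleavages (symmetric methyls collapsed) + the nitrile
  expect_identical(sum(grepl("phosphoester", fams$rule_id)), 2L)
  expect_identical(sum(grepl("nitrile", fams$rule_id)), 1L)
})

test_that("a threshold above every score yields no products", {
  out <- generate_metabolites(SMI_DESMEDIPHAM, hy_rules(),
                              threshold = 1 + 1e-9)
  expect_identical(nrow(out), 0L)
  expect_identical(attr(out, "n_transformations"), 0L)
})

test_that("ranking is score-descending with lexicographic rule_id ties", {
  out <- generate_metabolites(SMI_FLAMPROP_METHYL, hy_rules())
  ranked <- rank_consistency(out)
  scores <- tapply(ranked$score, ranked$rank, unique)
  expect_true(all(diff(as.numeric(scores)) <= 0))
  ## flamprop-methyl under the reported site scores (ester O 0.9396,
  ## amide N 0.7582): the ester cleavage outranks the amide cleavage
  stub <- out
  stub$score <- ifelse(stub$rule_id == "ester_hydrolysis", 0.9396, 0.7582)
  stub <- rank_consistency(stub)
  first <- stub$rule_id[stub$rank == 1][1]
  expect_identical(first, "ester_hydrolysis")
  ## equal scores: rule_id lexicographic, stable across calls
  tie <- out
  tie$score <- 0.5
  t1 <- rank_consistency(tie); t2 <- rank_consistency(tie)
  expect_identical(t1, t2)
  expect_identical(unique(t1$rule_id), sort(unique(t1$rule_id)))
})

test_that("lowering the threshold never removes a predicted product", {
  corp <- hy_corpus()
  rb <- hy_rules()
  b <- hy_bundle()
  for (rec in corp$records[1:15]) {
    lo <- generate_metabolites(rec$parent, rb, b, threshold = 0.3)
    hi <- generate_metabolites(rec$parent, rb, b, threshold = 0.7)
    expect_true(all(hi$product_smiles %in% lo$product_smiles),
                label = rec$parent)
    expect_true(all(lo$score >= 0.3))
    expect_true(all(hi$score >= 0.7) || nrow(hi) == 0L)
  }
})

test_that("every product's provenance round-trips through its rule", {
  out <- generate_metabolites(SMI_CYANOPHOS, hy_rules())
  for (r in unique(out$rank)) {
    sub <- out[out$rank == r, ]
    prods <- apply_rule(SMI_CYANOPHOS, sub$rule_id[1], sub$site_atom_index[1],
                        hy_rules())
    expect_true(all(sub$product_smiles %in% prods))
  }
})

test_that("product evaluation counts hits by canonical structure", {
  ## identity
  ev <- evaluate_products(c("CC(=O)O", "CCO"), c("OCC", "OC(C)=O"))
  expect_identical(ev$hit_rate, 1)
  expect_identical(ev$false_positive_rate, 0)
  ## set arithmetic: reference {A, B}, predicted {A, C, D}
  ev2 <- evaluate_products(c("CC(=O)O", "CCC", "CCCC"), c("CC(=O)O", "CN"))
  expect_identical(ev2$n_hit, 1L)
  expect_identical(ev2$hit_rate, 0.5)
  expect_equal(ev2$false_positive_rate, 2 / 3, tolerance = 1e-12)
  ## unparsable reference is a named input error
  expect_error(evaluate_products("CC", c("C1CC")), "unparsable")
})

test_that("aggregate evaluation equals the sum of per-compound evaluations", {
  rb <- hy_rules()
  preds <- hydro_predict(c(a = SMI_DESMEDIPHAM, b = SMI_CYANOPHOS),
                         bundle = NULL, rules = rb)
  refs <- data.frame(
    parent_id = c("a", "a", "b"),
    product_smiles = c("CCOC(=O)Nc1cccc(O)c1", "CCCCC",
                       "Oc1ccc(C#N)cc1"),
    stringsAsFactors = FALSE)
  ev <- hydro_evaluate(preds, refs)
  expect_identical(ev$aggregate$n_hit, sum(ev$per_compound$n_hit))
  expect_identical(ev$aggregate$n_reference, sum(ev$per_compound$n_reference))
  expect_identical(ev$aggregate$n_predicted, sum(ev$per_compound$n_predicted))
  ## mismatching parent ids are a named error
  expect_error(hydro_evaluate(preds, data.frame(
    parent_id = "zzz", product_smiles = "CC")), "zzz")
})
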