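## Synthetic corpus generator: closure, determinism, statistics.

test_that("generated corpora are fully explained by the rule base", {
  corp <- hy_corpus()
  rb <- hy_rules()
  ## labeling (which shares only the rule base) recovers the generator's
  ## ground truth exactly, for every record
  for (rec in corp$records) {
    lab <- label_som_atoms(rec, rb)
    expect_false(attr(lab, "unexplained"))
    gt <- corp$labels[corp$labels$record_id == rec$record_id, ]
    expect_identical(lab$label, gt$label, label = rec$parent)
  }
})

test_that("generation is deterministic per seed and varies across seeds", {
  a <- generate_corpus(synth_config(n_molecules = 12L, seed = 3L), hy_rules())
  b <- generate_corpus(synth_config(n_molecules = 12L, seed = 3L), hy_rules())
  c <- generate_corpus(synth_config(n_molecules = 12L, seed = 4L), hy_rules())
  pa <- vapply(a$records, `[[`, character(1), "parent")
  pb <- vapply(b$records, `[[`, character(1), "parent")
  pc <- vapply(c$records, `[[`, character(1), "parent")
  expect_identical(pa, pb)
  expect_identical(a$labels, b$labels)
  expect_false(identical(pa, pc))
})

test_that("a decoy-only configuration is rejected", {
  gw <- rep(0, length(hydrosite:::SYNTH_GROUPS))
  names(gw) <- names(hydrosite:::SYNTH_GROUPS)
  expect_error(synth_config(group_weights = gw), "no SOM\\+")
  expect_error(synth_config(n_molecules = 5L), "at least 10")
})

test_that("corpus statistics are a bookkeeping identity and additive", {
  corp <- hy_corpus()
  stats <- corpus_statistics(corp$labels)
  expect_identical(
    stats$som_pos[stats$dataset == "Global-Hydrolysis"],
    sum(corp$labels$label == "SOM+"))
  ## merging two corpora adds the counts
  other <- generate_corpus(synth_config(n_molecules = 10L, seed = 21L),
                           hy_rules())
  merged <- corpus_statistics(rbind(corp$labels, other$labels))
  single <- corpus_statistics(other$labels)
  expect_identical(merged$som_pos, stats$som_pos + single$som_pos)
  expect_identical(merged$som_neg, stats$som_neg + single$som_neg)
  ## empty classes appear as zero rows, never dropped
  nconly <- corp$labels[corp$labels$atom_class == "C", ]
  st2 <- corpus_statistics(nconly)
  expect_true("S-atoms" %in% st2$dataset)
  expect_identical(st2$som_pos[st2$dataset == "S-atoms"], 0L)
})

test_that("the achieved Global SOM ratio sits near the configured target", {
  corp <- hy_corpus()
  expect_lt(abs(corp$achieved_global_ratio -
                  corp$config$target_global_ratio), 0.08)
})
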