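## Model families, cross-validation, tuning and serving.

test_that("every family beats the majority-class CV baseline on rule-determined sites", {
  d <- hy_model_data()
  baseline <- max(mean(d$ytr == "SOM+"), mean(d$ytr == "SOM-"))
  cv <- pretrain(d$Xtr, d$ytr, folds = 5L, seed = 11L)
  expect_identical(cv$family, hydrosite:::FAMILY_ORDER)
  expect_true(all(cv$cv_accuracy > baseline),
              label = paste(cv$family, round(cv$cv_accuracy, 3), collapse = "; "))
})

test_that("permuted labels drop every family to chance level", {
  d <- hy_model_data()
  yperm <- withr::with_seed(99, sample(d$ytr))
  baseline <- max(mean(yperm == "SOM+"), mean(yperm == "SOM-"))
  ## a fast representative subset of families
  cv <- pretrain(d$Xtr, yperm, families = c("dt", "lda"), folds = 5L,
                 seed = 11L)
  se <- sqrt(baseline * (1 - baseline) / length(yperm))
  expect_true(all(cv$cv_accuracy < baseline + 3 * se + 0.02))
})

test_that("select_top keeps the highest-scoring families with a fixed tie order", {
  tab <- data.frame(
    family = hydrosite:::FAMILY_ORDER,
    cv_accuracy = c(0.9, 0.5, 0.9, 0.5, 0.9, 0.9, 0.9, 0.5))
  expect_setequal(select_top(tab, 5), c("dt", "et", "hgb", "ada", "lda"))
  tab$cv_accuracy <- 0.7
  expect_identical(select_top(tab, 5), hydrosite:::FAMILY_ORDER[1:5])
})

test_that("tuning always contains the default configuration", {
  d <- hy_model_data()
  tn <- tune("dt", d$Xtr, d$ytr, n_configs = 4L, folds = 3L, seed = 11L)
  expect_identical(tn$log$params[1], "default")
  expect_gte(tn$cv_accuracy, tn$log$cv_accuracy[1])
  ## deterministic configuration sampling
  tn2 <- tune("dt", d$Xtr, d$ytr, n_configs = 4L, folds = 3L, seed = 11L)
  expect_identical(tn$log, tn2$log)
})

test_that("the gradient-boosting search space spans the documented range", {
  cfgs <- withr::with_seed(1, {
    replicate(400, hydrosite:::sample_family_config("gbc"),
              simplify = FALSE)
  })
  etas <- vapply(cfgs, `[[`, numeric(1), "eta")
  rounds <- vapply(cfgs, `[[`, numeric(1), "nrounds")
  expect_lt(min(etas), 0.15)
  expect_gte(max(rounds), 230)
})

test_that("finalize picks the test-MCC argmax and keeps all candidates", {
  d <- hy_model_data()
  bundle <- hy_bundle()
  mccs <- vapply(bundle$candidate_metrics, `[[`, numeric(1), "MCC")
  expect_identical(bundle$family, names(which.max(mccs)))
  expect_gte(bundle$test_metrics$MCC, max(mccs[names(mccs) != bundle$family]))
  ## single candidate wins trivially
  tuned <- list(tune("dt", d$Xtr, d$ytr, n_configs = 2L, folds = 3L,
                     seed = 11L))
  solo <- finalize(tuned, d$sel, d$Xtr_raw, d$ytr, d$Xte_raw, d$yte,
                   "Global-Hydrolysis", c("N", "O", "C", "S", "X"),
                   seed = 11L)
  expect_identical(solo$family, "dt")
})

test_that("fitted models never see test labels", {
  d <- hy_model_data()
  fit1 <- hydrosite:::fit_family("dt", d$Xtr, d$ytr, seed = 11L)
  fit2 <- hydrosite:::fit_family("dt", d$Xtr, d$ytr, seed = 11L)
  probe <- d$Xte[1:5, , drop = FALSE]
  expect_identical(hydrosite:::predict_prob(fit1, probe),
                   hydrosite:::predict_prob(fit2, probe))
})

test_that("predict_sites honours class scope and the probability contract", {
  b <- hy_bundle()
  ## no atoms of the class -> empty frame
  n_only <- b
  n_only$atom_classes <- "N"
  expect_identical(nrow(predict_sites(n_only, "CCO")), 0L)
  ## probabilities finite and in [0, 1] on random synthetic molecules
  small <- generate_corpus(synth_config(n_molecules = 10L, seed = 31L),
                           hy_rules())
  for (rec in small$records) {
    ps <- predict_sites(b, rec$parent)
    expect_true(all(is.finite(ps$probability)))
    expect_true(all(ps$probability >= 0 & ps$probability <= 1))
    expect_identical(ps$is_site, ps$probability >= b$threshold)
  }
})

test_that("bundles survive a save/load round trip and check versions", {
  b <- hy_bundle()
  dir <- tempfile("bundle")
  save_bundle(b, dir)
  b2 <- load_bundle(dir)
  expect_identical(b2$family, b$family)
  probe <- "CC(=O)Nc1ccc(OC)cc1"
  expect_identical(predict_sites(b2, probe), predict_sites(b, probe))
  ## version mismatch refused
  meta <- jsonlite::fromJSON(file.path(dir, "metadata.json"))
  meta$feature_version <- "other-dialect-0"
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE)
  expect_error(load_bundle(dir), "feature version")
})
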