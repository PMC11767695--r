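## Confusion-matrix metric identities.

test_that("canonical confusion cases give the expected metric values", {
  perfect <- compute_metrics(5, 5, 0, 0)
  expect_identical(c(perfect$ACC, perfect$Recall, perfect$Precision,
                     perfect$MCC), c(1, 1, 1, 1))
  chance <- compute_metrics(0, 5, 5, 0)
  expect_identical(chance$ACC, 0.5)
  expect_identical(chance$MCC, 0)
  m <- compute_metrics(2, 3, 1, 1)
  expect_equal(m$MCC, 5 / 12, tolerance = 1e-12)
})

test_that("zero denominators are reported as 0 and flagged", {
  ## all predictions wrong but every marginal non-zero: MCC is a valid -1
  worst <- compute_metrics(0, 0, 5, 5)
  expect_identical(worst$ACC, 0)
  expect_identical(worst$MCC, -1)
  expect_length(worst$undefined, 0L)
  ## nothing predicted positive: Precision and MCC denominators vanish
  m <- compute_metrics(0, 5, 0, 5)
  expect_identical(m$Precision, 0)
  expect_identical(m$MCC, 0)
  expect_true(all(c("Precision", "MCC") %in% m$undefined))
  expect_error(compute_metrics(0, 0, 0, 0), "zero")
  expect_error(compute_metrics(-1, 1, 1, 1), "non-negative")
})

test_that("metric identities hold against direct formula evaluation", {
  withr::with_seed(123, {
    for (k in 1:200) {
      cts <- as.numeric(sample(0:40, 4, replace = TRUE))
      if (sum(cts) == 0) cts[1] <- 1
      tp <- cts[1]; tn <- cts[2]; fp <- cts[3]; fn <- cts[4]
      m <- compute_metrics(tp, tn, fp, fn)
      expect_equal(m$ACC, (tp + tn) / (tp + tn + fp + fn), tolerance = 1e-12)
      if (tp + fn > 0) expect_equal(m$Recall, tp / (tp + fn), tolerance = 1e-12)
      if (tp + fp > 0) expect_equal(m$Precision, tp / (tp + fp), tolerance = 1e-12)
      den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
      if (den > 0) {
        expect_equal(m$MCC, (tp * tn - fp * fn) / sqrt(den), tolerance = 1e-12)
        expect_true(m$MCC >= -1 && m$MCC <= 1)
      }
    }
  })
})
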