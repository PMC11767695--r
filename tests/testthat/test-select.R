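## The variance / ANOVA-F / Welch-t feature-selection cascade.

test_that("degenerate columns are handled per stage definition", {
  withr::with_seed(42, {
    X <- cbind(const = rep(1, 100), noise = rnorm(100), label_copy = 0)
    y <- rep(c(0L, 1L), each = 50)
    X[, "label_copy"] <- y
    sel <- fit_selector(X, y)
    ## constant column removed at stage 1; label copy always survives
    expect_false(1L %in% sel$retained_indices)
    expect_true(3L %in% sel$retained_indices)
  })
})

test_that("the cascade agrees with the brute-force oracle", {
  withr::with_seed(3, {
    for (rep in 1:5) {
      n <- 200
      y <- rep(c(0L, 1L), each = n / 2)
      X <- matrix(rnorm(n * 20), n, 20)
      ## 2 strong separators, 1 constant
      X[, 3] <- X[, 3] + 2 * y
      X[, 17] <- X[, 17] - 1.5 * y
      X[, 9] <- 7
      sel <- fit_selector(X, y)
      oracle <- brute_force_selector(X, y)
      expect_identical(sel$retained_indices, oracle)
      expect_true(all(c(3L, 17L) %in% sel$retained_indices))
    }
  })
})

test_that("per-column statistics match independent recomputation to 1e-9", {
  withr::with_seed(5, {
    n <- 60
    y <- rep(c(0L, 1L), each = n / 2)
    X <- matrix(rnorm(n * 8), n, 8)
    f_mine <- hydrosite:::column_f_stats(X, y)
    f_ref <- vapply(seq_len(ncol(X)), function(j) {
      summary(stats::aov(X[, j] ~ factor(y)))[[1]][["F value"]][1]
    }, numeric(1))
    expect_lt(max(abs(f_mine - f_ref)), 1e-9)
    p_mine <- hydrosite:::column_t_pvalues(X, y, "welch")
    p_ref <- vapply(seq_len(ncol(X)), function(j) {
      stats::t.test(X[y == 1, j], X[y == 0, j])$p.value
    }, numeric(1))
    expect_lt(max(abs(p_mine - p_ref)), 1e-9)
  })
})

test_that("stage masks compose monotonically and order is fixed", {
  withr::with_seed(8, {
    X <- matrix(rnorm(100 * 30), 100, 30)
    y <- rep(c(0L, 1L), each = 50)
    X[, 1:4] <- X[, 1:4] + 1.2 * y
    sel <- fit_selector(X, y)
    s <- sel$stage_sizes
    expect_true(s[["variance"]] >= s[["f_test"]])
    expect_true(s[["f_test"]] >= s[["t_test"]])
    expect_identical(s[["f_test"]], as.integer(ceiling(0.5 * s[["variance"]])))
    expect_identical(sel$retained_indices, sort(sel$retained_indices))
  })
})

test_that("apply_selector enforces the fit-time feature contract", {
  withr::with_seed(9, {
    X <- matrix(rnorm(80 * 10), 80, 10)
    y <- rep(c(0L, 1L), each = 40)
    X[, 2] <- X[, 2] + 2 * y
    sel <- fit_selector(X, y)
    expect_identical(ncol(apply_selector(sel, X)),
                     length(sel$retained_indices))
    expect_error(apply_selector(sel, X[, 1:5]), "mismatch")
    ## all-noise features with tight alpha -> explicit error, not 0 columns
    Xn <- matrix(rnorm(80 * 5), 80, 5)
    expect_error(fit_selector(Xn, y, alpha = 1e-12), "no informative")
  })
})
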