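## Three-stage feature-selection cascade, fitted on training rows only:
## (1) drop zero-variance columns, (2) keep the top 50% of survivors by
## one-way ANOVA F value (ceiling on odd counts, ties to the lower column
## index), (3) keep survivors with two-sided Welch t-test p < 0.05.

#' Fit the variance / ANOVA-F / t-test selector cascade
#'
#' @param X numeric feature matrix (training rows only).
#' @param y labels: "SOM+"/"SOM-" character or 0/1.
#' @param keep_fraction fraction kept at the F-test stage (default 0.5).
#' @param alpha t-test significance threshold (default 0.05).
#' @param t_variant `"welch"` (default) or `"pooled"`.
#' @return a fitted `hydro_selector`.
#' @export
fit_selector <- function(X, y, keep_fraction = 0.5, alpha = 0.05,
                         t_variant = c("welch", "pooled")) {
  t_variant <- match.arg(t_variant)
  y <- as_binary_label(y)
  if (length(unique(y)) < 2L) stop("both classes must be present to fit the selector")
  if (min(table(y)) < 2L) stop("need at least 2 samples per class")
  if (any(!is.finite(X))) stop("features must be finite")
  n <- nrow(X)

  ## stage 1: zero variance
  v <- matrix_col_var(X)
  s1 <- which(v > 0)
  if (!length(s1)) stop("no informative features: all columns are constant")

  ## stage 2: top keep_fraction by F value
  stats_f <- column_f_stats(X[, s1, drop = FALSE], y)
  k <- ceiling(keep_fraction * length(s1))
  ## ties at the cutoff broken by lower column index: stable order sort
  ord <- order(-stats_f, seq_along(stats_f))
  s2 <- s1[sort(ord[seq_len(k)])]

  ## stage 3: t-test p < alpha
  p <- column_t_pvalues(X[, s2, drop = FALSE], y, t_variant)
  s3 <- s2[p < alpha]
  if (!length(s3)) stop("no informative features survive the t-test stage")

  structure(list(
    retained_indices = s3,
    stage_sizes = c(input = ncol(X), variance = length(s1),
                    f_test = length(s2), t_test = length(s3)),
    keep_fraction = keep_fraction, alpha = alpha, t_variant = t_variant,
    n_train = n, fitted = TRUE), class = "hydro_selector")
}

#' Apply a fitted selector
#'
#' @param selector a `hydro_selector`.
#' @param X feature matrix with the fit-time column count.
#' @return the reduced matrix (columns = retained indices, order preserved).
#' @export
apply_selector <- function(selector, X) {
  if (!isTRUE(selector$fitted)) stop("selector is not fitted")
  if (ncol(X) != selector$stage_sizes[["input"]]) {
    stop(sprintf("feature count mismatch: selector fitted on %d columns, got %d",
                 selector$stage_sizes[["input"]], ncol(X)))
  }
  X[, selector$retained_indices, drop = FALSE]
}

#' @export
print.hydro_selector <- function(x, ...) {
  s <- x$stage_sizes
  cat(sprintf(
    "<hydro_selector: %d -> %d (var) -> %d (F top %.0f%%) -> %d (t p<%g, %s)>\n",
    s[["input"]], s[["variance"]], s[["f_test"]], 100 * x$keep_fraction,
    s[["t_test"]], x$alpha, x$t_variant))
  invisible(x)
}

as_binary_label <- function(y) {
  if (is.character(y) || is.factor(y)) as.integer(as.character(y) == "SOM+")
  else as.integer(y)
}

matrix_col_var <- function(X) {
  n <- nrow(X)
  m <- colMeans(X)
  (colSums(X^2) - n * m^2) / (n - 1)
}

## One-way ANOVA F per column for a binary grouping.
column_f_stats <- function(X, y) {
  n <- nrow(X); n1 <- sum(y == 1L); n0 <- n - n1
  m <- colMeans(X)
  m1 <- colMeans(X[y == 1L, , drop = FALSE])
  m0 <- colMeans(X[y == 0L, , drop = FALSE])
  ssb <- n1 * (m1 - m)^2 + n0 * (m0 - m)^2
  sst <- colSums(X^2) - n * m^2
  ssw <- sst - ssb
  f <- (ssb / 1) / (ssw / (n - 2))
  f[ssw <= 0 & ssb > 0] <- Inf
  f[ssw <= 0 & ssb <= 0] <- 0
  f
}

column_t_pvalues <- function(X, y, t_variant = "welch") {
  X1 <- X[y == 1L, , drop = FALSE]; X0 <- X[y == 0L, , drop = FALSE]
  n1 <- nrow(X1); n0 <- nrow(X0)
  m1 <- colMeans(X1); m0 <- colMeans(X0)
  v1 <- matrix_col_var(X1); v0 <- matrix_col_var(X0)
  if (t_variant == "welch") {
    se2 <- v1 / n1 + v0 / n0
    t <- (m1 - m0) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    t <- (m1 - m0) / sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- rep(n1 + n0 - 2, ncol(X))
  }
  p <- 2 * stats::pt(-abs(t), df)
  ## zero within-group variance with distinct means: perfect separator
  p[!is.finite(t) | is.na(p)] <- ifelse(m1[!is.finite(t) | is.na(p)] !=
                                          m0[!is.finite(t) | is.na(p)], 0, 1)
  p
}
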