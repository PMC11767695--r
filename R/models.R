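## The eight classifier families, cross-validation, pre-training, tuning,
## finalisation and per-atom probability serving.
##
## Family roster (short id -> algorithm): dt = decision tree (rpart),
## rf = random forest (ranger), et = extremely randomised trees (ranger),
## gbc = gradient boosting (xgboost, exact splits), hgb = histogram-based
## gradient boosting (xgboost, hist splits), ada = adaptive boosting
## (SAMME over rpart stumps, implemented here), lda / qda = linear /
## quadratic discriminant analysis (MASS) on a PCA projection that keeps
## the discriminants well-posed on near-collinear binary fingerprints.

FAMILY_ORDER <- c("dt", "rf", "et", "gbc", "hgb", "ada", "lda", "qda")

FAMILY_LABELS <- c(
  dt = "decision-tree", rf = "random-forest", et = "extra-trees",
  gbc = "gradient-boosting", hgb = "histogram-gradient-boosting",
  ada = "adaptive-boosting", lda = "linear-discriminant",
  qda = "quadratic-discriminant")

## ---- family fit / predict -------------------------------------------------

fit_family <- function(family, X, y, params = list(), seed = 1L) {
  y <- as_binary_label(y)
  p <- function(name, default) params[[name]] %||% default
  model <- switch(family,
    dt = {
      df <- as.data.frame(X)
      df$.y <- factor(y, levels = c(0L, 1L))
      withr::with_seed(seed, rpart::rpart(
        .y ~ ., data = df, method = "class",
        control = rpart::rpart.control(
          cp = p("cp", 0.01), minsplit = p("minsplit", 20L),
          maxdepth = p("maxdepth", 30L), xval = 0L)))
    },
    rf = ranger::ranger(
      x = X, y = factor(y, levels = c(0L, 1L)), probability = TRUE,
      num.trees = p("num_trees", 100L),
      mtry = mtry_from(params, X),
      min.node.size = p("min_node_size", 10L),
      seed = seed, num.threads = 1L),
    et = ranger::ranger(
      x = X, y = factor(y, levels = c(0L, 1L)), probability = TRUE,
      splitrule = "extratrees",
      num.random.splits = p("num_random_splits", 1L),
      num.trees = p("num_trees", 100L),
      mtry = mtry_from(params, X),
      min.node.size = p("min_node_size", 10L),
      seed = seed, num.threads = 1L),
    gbc = fit_xgb(X, y, params, seed, tree_method = "exact"),
    hgb = fit_xgb(X, y, params, seed, tree_method = "hist"),
    ada = fit_adaboost(X, y,
                       n_rounds = p("n_rounds", 25L),
                       maxdepth = p("maxdepth", 1L),
                       learning_rate = p("learning_rate", 1.0), seed = seed),
    lda = fit_discriminant(X, y, MASS::lda, p("n_pca", 30L)),
    qda = fit_discriminant(X, y, MASS::qda, p("n_pca", 8L)),
    stop(sprintf("unknown model family '%s'", family)))
  structure(list(family = family, model = model, params = params,
                 colnames = colnames(X), seed = seed),
            class = "hydro_model")
}

mtry_from <- function(params, X) {
  mf <- params[["mtry_frac"]]
  if (is.null(mf)) max(1L, floor(sqrt(ncol(X))))
  else max(1L, floor(mf * ncol(X)))
}

fit_xgb <- function(X, y, params, seed, tree_method) {
  p <- function(name, default) params[[name]] %||% default
  dtrain <- xgboost::xgb.DMatrix(data = X, label = y, nthread = 1L)
  withr::with_seed(seed, xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  eta = p("eta", 0.3), max_depth = p("max_depth", 6L),
                  min_child_weight = p("min_child_weight", 1L),
                  max_bin = p("max_bin", 256L),
                  tree_method = tree_method, nthread = 1L,
                  seed = seed),
    data = dtrain, nrounds = p("nrounds", 100L), verbose = 0))
}

## SAMME adaptive boosting over shallow rpart learners.
fit_adaboost <- function(X, y, n_rounds = 50L, maxdepth = 1L,
                         learning_rate = 1.0, seed = 1L) {
  df <- as.data.frame(X)
  yy <- ifelse(y == 1L, 1, -1)
  df$.y <- factor(y, levels = c(0L, 1L))
  n <- nrow(df)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric()
  withr::with_seed(seed, {
    for (m in seq_len(n_rounds)) {
      fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                          control = rpart::rpart.control(
                            maxdepth = maxdepth, cp = -1, minsplit = 2L,
                            xval = 0L))
      pred <- ifelse(predict(fit, df, type = "class") == "1", 1, -1)
      err <- sum(w[pred != yy])
      if (err <= 1e-10) {
        stumps[[m]] <- fit; alphas[m] <- 10; break
      }
      if (err >= 0.5) break
      alphas[m] <- learning_rate * 0.5 * log((1 - err) / err)
      stumps[[m]] <- fit
      w <- w * exp(-alphas[m] * yy * pred)
      w <- w / sum(w)
    }
  })
  if (!length(stumps)) {
    ## degenerate: constant majority-class scorer
    stumps <- list(NULL); alphas <- 0
  }
  list(stumps = stumps, alphas = alphas,
       base_rate = mean(y), type = "adaboost")
}

fit_discriminant <- function(X, y, engine, n_pca) {
  keep <- which(matrix_col_var(X) > 0)
  if (!length(keep)) stop("all features constant; discriminant undefined")
  Xk <- X[, keep, drop = FALSE]
  min_class <- min(table(y))
  rank_max <- min(n_pca, min_class - 1L, nrow(Xk) - 1L, ncol(Xk))
  pc <- stats::prcomp(Xk, center = TRUE, scale. = FALSE, rank. = rank_max)
  ## guard against zero-variance trailing components
  good <- pc$sdev[seq_len(ncol(pc$rotation))] > 1e-8
  rot <- pc$rotation[, good, drop = FALSE]
  proj <- scale(Xk, center = pc$center, scale = FALSE) %*% rot
  fit <- engine(proj, grouping = factor(y, levels = c(0L, 1L)))
  list(fit = fit, keep = keep, center = pc$center, rotation = rot,
       type = "discriminant")
}

predict_prob <- function(object, X) {
  stopifnot(inherits(object, "hydro_model"))
  m <- object$model
  out <- switch(object$family,
    dt = {
      df <- as.data.frame(X)
      pr <- predict(m, df, type = "prob")
      if ("1" %in% colnames(pr)) pr[, "1"] else rep(0, nrow(df))
    },
    rf = ,
    et = {
      pr <- predict(m, data = X, num.threads = 1L)$predictions
      if ("1" %in% colnames(pr)) pr[, "1"] else rep(0, nrow(X))
    },
    gbc = ,
    hgb = as.numeric(predict(m, xgboost::xgb.DMatrix(X, nthread = 1L))),
    ada = {
      if (is.null(m$stumps[[1]])) rep(m$base_rate, nrow(X))
      else {
        df <- as.data.frame(X)
        score <- rep(0, nrow(df))
        for (k in seq_along(m$stumps)) {
          pk <- ifelse(predict(m$stumps[[k]], df, type = "class") == "1", 1, -1)
          score <- score + m$alphas[k] * pk
        }
        1 / (1 + exp(-2 * score / max(sum(abs(m$alphas)), 1e-12)))
      }
    },
    lda = ,
    qda = {
      proj <- scale(X[, m$keep, drop = FALSE], center = m$center,
                    scale = FALSE) %*% m$rotation
      pr <- predict(m$fit, proj)$posterior
      if ("1" %in% colnames(pr)) pr[, "1"] else rep(0, nrow(X))
    })
  pmin(pmax(as.numeric(out), 0), 1)
}

## ---- cross-validation -----------------------------------------------------

## Stratified fold assignment; every fold keeps both classes where possible.
make_folds <- function(y, k, seed) {
  y <- as_binary_label(y)
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  if (any(vapply(seq_len(k), function(f) length(unique(y[fold != f])) < 2L,
                 logical(1)))) {
    stop("stratification failed: a training fold lost a class")
  }
  fold
}

cv_accuracy <- function(family, X, y, folds = 10L, seed = 1L,
                        params = list(), fold_id = NULL) {
  y <- as_binary_label(y)
  if (is.null(fold_id)) fold_id <- make_folds(y, folds, seed)
  accs <- vapply(seq_len(max(fold_id)), function(f) {
    tr <- fold_id != f; te <- !tr
    fit <- fit_family(family, X[tr, , drop = FALSE], y[tr], params, seed)
    prob <- predict_prob(fit, X[te, , drop = FALSE])
    mean((prob >= 0.5) == (y[te] == 1L))
  }, numeric(1))
  mean(accs)
}

#' Pre-train all model families with cross-validated accuracy
#'
#' @param X selected feature matrix (training rows).
#' @param y SOM labels for the rows.
#' @param families families to evaluate (default all eight).
#' @param folds stratified CV folds (default 10).
#' @param seed integer seed (fold assignment and model seeds).
#' @return data frame (`family`, `label`, `cv_accuracy`) sorted as
#'   `FAMILY_ORDER`.
#' @export
pretrain <- function(X, y, families = FAMILY_ORDER, folds = 10L, seed = 1L) {
  fold_id <- make_folds(y, folds, seed)
  acc <- vapply(families, function(fam) {
    cv_accuracy(fam, X, y, folds, seed, list(), fold_id)
  }, numeric(1))
  data.frame(family = families, label = FAMILY_LABELS[families],
             cv_accuracy = as.numeric(acc), stringsAsFactors = FALSE)
}

#' Select the top families from a pre-training table
#'
#' @param cv_table output of [pretrain()].
#' @param n number of families to keep (default 5).
#' @return character vector of family ids, ties broken by the fixed
#'   `FAMILY_ORDER`.
#' @export
select_top <- function(cv_table, n = 5L) {
  if (nrow(cv_table) < n) stop("fewer families than requested")
  ord <- order(-cv_table$cv_accuracy, match(cv_table$family, FAMILY_ORDER))
  cv_table$family[ord][seq_len(n)]
}

## ---- hyperparameter search ------------------------------------------------

## Random configuration for one family (config 0 is always the default).
sample_family_config <- function(family) {
  switch(family,
    dt = list(cp = 10^stats::runif(1, -4, -1),
              minsplit = sample(5:40, 1), maxdepth = sample(3:30, 1)),
    rf = list(num_trees = sample(50:200, 1),
              mtry_frac = stats::runif(1, 0.05, 0.4),
              min_node_size = sample(1:10, 1)),
    et = list(num_trees = sample(50:200, 1),
              mtry_frac = stats::runif(1, 0.05, 0.4),
              min_node_size = sample(1:10, 1),
              num_random_splits = sample(1:5, 1)),
    gbc = list(nrounds = sample(50:300, 1),
               eta = stats::runif(1, 0.05, 1.0),
               max_depth = sample(2:6, 1),
               min_child_weight = sample(1:5, 1)),
    hgb = list(nrounds = sample(50:300, 1),
               eta = stats::runif(1, 0.05, 1.0),
               max_depth = sample(2:6, 1),
               min_child_weight = sample(1:5, 1),
               max_bin = sample(c(32L, 64L, 128L, 256L), 1)),
    ada = list(n_rounds = sample(10:35, 1), maxdepth = sample(1:2, 1),
               learning_rate = stats::runif(1, 0.3, 1.0)),
    lda = list(n_pca = sample(c(5L, 10L, 20L, 30L, 50L), 1)),
    qda = list(n_pca = sample(3:15, 1)),
    stop("unknown family"))
}

#' Tune one family over random hyperparameter configurations
#'
#' The default configuration is always candidate 0, so the tuned CV score
#' is never worse than the default's.
#'
#' @param family family id.
#' @param X,y selected training features and labels.
#' @param n_configs number of configurations (default 50, incl. default).
#' @param folds CV folds (default 10).
#' @param seed integer seed.
#' @return list: `family`, `params` (best), `cv_accuracy`, `log` (one row
#'   per configuration).
#' @export
tune <- function(family, X, y, n_configs = 50L, folds = 10L, seed = 1L) {
  if (n_configs < 1L) stop("n_configs must be at least 1")
  configs <- c(list(list()),
               withr::with_seed(seed + 1000L, {
                 lapply(seq_len(n_configs - 1L),
                        function(i) sample_family_config(family))
               }))
  fold_id <- make_folds(y, folds, seed)
  scores <- vapply(configs, function(cfg) {
    tryCatch(cv_accuracy(family, X, y, folds, seed, cfg, fold_id),
             error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(scores))) stop(sprintf("every configuration failed for '%s'", family))
  best <- which.max(ifelse(is.na(scores), -Inf, scores))
  log <- data.frame(config = seq_along(configs) - 1L,
                    cv_accuracy = scores,
                    params = vapply(configs, function(cfg) {
                      if (!length(cfg)) "default" else
                        paste(names(cfg), signif(unlist(cfg), 4),
                              sep = "=", collapse = ";")
                    }, character(1)), stringsAsFactors = FALSE)
  list(family = family, params = configs[[best]],
       cv_accuracy = scores[best], log = log)
}

## ---- finalisation and serving ---------------------------------------------

#' Finalize a model bundle from tuned candidates
#'
#' Refits every tuned candidate on the full training rows and evaluates on
#' the held-out test rows; the winner has the highest test MCC, ties broken
#' by test ACC, then by `FAMILY_ORDER`. All candidate metrics are retained
#' in the bundle metadata.
#'
#' @param candidates list of [tune()] results.
#' @param selector fitted `hydro_selector` (fitted on train rows only).
#' @param X_train,y_train,X_test,y_test raw (unselected) feature matrices
#'   and labels.
#' @param dataset_name e.g. `"Global-Hydrolysis"`.
#' @param atom_classes atom classes this bundle scores.
#' @param threshold site-call threshold tau (default 0.5).
#' @param seed integer seed.
#' @return a `hydro_bundle`.
#' @export
finalize <- function(candidates, selector, X_train, y_train, X_test, y_test,
                     dataset_name, atom_classes, threshold = 0.5, seed = 1L) {
  if (!length(candidates)) stop("no tuned candidates supplied")
  Xtr <- apply_selector(selector, X_train)
  Xte <- apply_selector(selector, X_test)
  fits <- list(); evals <- list()
  for (cand in candidates) {
    fit <- fit_family(cand$family, Xtr, y_train, cand$params, seed)
    met <- metrics_from_predictions(predict_prob(fit, Xte), y_test, threshold)
    fits[[cand$family]] <- fit
    evals[[cand$family]] <- met
  }
  mccs <- vapply(evals, `[[`, numeric(1), "MCC")
  accs <- vapply(evals, `[[`, numeric(1), "ACC")
  ord <- order(-mccs, -accs, match(names(evals), FAMILY_ORDER))
  winner <- names(evals)[ord[1]]
  structure(list(
    dataset_name = dataset_name, family = winner,
    selector = selector, model = fits[[winner]],
    params = candidates[[which(vapply(candidates, `[[`, character(1),
                                      "family") == winner)]]$params,
    threshold = threshold, atom_classes = atom_classes,
    test_metrics = evals[[winner]],
    candidate_metrics = evals,
    metadata = list(seed = seed,
                    feature_version = feature_version(),
                    package_version = hydrosite_version(),
                    n_train = nrow(X_train), n_test = nrow(X_test))),
    class = "hydro_bundle")
}

#' @export
print.hydro_bundle <- function(x, ...) {
  cat(sprintf("<hydro_bundle %s: %s (%s), %d features, test MCC %.3f>\n",
              x$dataset_name, x$family, FAMILY_LABELS[x$family],
              length(x$selector$retained_indices), x$test_metrics$MCC))
  invisible(x)
}

#' Per-atom hydrolysis site probabilities
#'
#' @param bundle a `hydro_bundle`.
#' @param molecule a `hymol` or SMILES string.
#' @param threshold tau for the `is_site` call (default: bundle threshold).
#' @return data frame: `atom_index` (0-based canonical), `element`,
#'   `atom_class`, `probability`, `is_site`. One row per heavy atom of the
#'   bundle's atom class(es); empty if the molecule has none.
#' @export
predict_sites <- function(bundle, molecule, threshold = NULL) {
  threshold <- threshold %||% bundle$threshold
  f <- featurize(molecule, bundle$atom_classes)
  out <- f$meta
  if (!nrow(out)) {
    out$probability <- numeric(0); out$is_site <- logical(0)
    return(out)
  }
  prob <- predict_prob(bundle$model, apply_selector(bundle$selector, f$X))
  out$probability <- prob
  out$is_site <- prob >= threshold
  out
}

#' Save / load a model bundle directory
#'
#' The bundle directory holds `selector.json`, `metadata.json` and the
#' serialized classifier; loading refuses a feature-version mismatch.
#'
#' @param bundle a `hydro_bundle`.
#' @param dir target directory.
#' @return the directory (`save_bundle`) or a `hydro_bundle` (`load_bundle`).
#' @export
save_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sel <- bundle$selector
  jsonlite::write_json(
    list(retained_indices = sel$retained_indices,
         stage_sizes = as.list(sel$stage_sizes),
         keep_fraction = sel$keep_fraction, alpha = sel$alpha,
         t_variant = sel$t_variant, n_train = sel$n_train),
    file.path(dir, "selector.json"), auto_unbox = TRUE, digits = NA)
  meta <- c(bundle$metadata,
            list(dataset_name = bundle$dataset_name, family = bundle$family,
                 threshold = bundle$threshold,
                 atom_classes = bundle$atom_classes,
                 params = bundle$params,
                 test_metrics = unclass(bundle$test_metrics)))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  saveRDS(bundle, file.path(dir, "bundle.rds"))
  invisible(dir)
}

#' @rdname save_bundle
#' @param dir bundle directory written by [save_bundle()].
#' @export
load_bundle <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "metadata.json"))
  if (!identical(meta$feature_version, feature_version())) {
    stop(sprintf("bundle feature version '%s' does not match this package ('%s')",
                 meta$feature_version, feature_version()))
  }
  readRDS(file.path(dir, "bundle.rds"))
}
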