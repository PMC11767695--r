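## End-to-end pipelines behind the command-line surface: train bundles from
## a reaction corpus, predict ranked metabolites for query molecules, and
## evaluate predictions against reference product lists.

DATASET_CLASSES <- list(
  "N-Hydrolysis" = "N", "O-Hydrolysis" = "O", "C-Hydrolysis" = "C",
  "Global-Hydrolysis" = c("N", "O", "C", "S", "X"))

#' Train hydrolysis site model bundles from a reaction corpus
#'
#' Runs corpus labeling, featurization, molecule-grouped splitting, the
#' feature-selection cascade, pre-training of all eight families,
#' hyperparameter tuning of the top families and final model selection by
#' held-out test MCC. Writes, per dataset, `cv_table.csv`,
#' `tuning_log.csv`, `metrics.json`, `confusion.json` and a bundle
#' directory, plus corpus-level `labels.csv`, `corpus_summary.json` and a
#' reproducibility `manifest.json`.
#'
#' @param corpus a corpus file path, a `hydro_corpus`, or the result of
#'   [generate_corpus()].
#' @param out_dir output directory.
#' @param datasets dataset names to train (default `"Global-Hydrolysis"`).
#' @param rules a `hydro_rulebase` (default: shipped base).
#' @param seed integer seed driving split, folds and model fits.
#' @param folds CV folds (default 10).
#' @param n_configs tuning configurations per family (default 50).
#' @param top_n families carried into tuning (default 5).
#' @param ratio train fraction of the molecule split (default 0.8).
#' @param threshold site-call tau stored in the bundles (default 0.5).
#' @param corpus_format corpus file format when `corpus` is a path.
#' @return named list of `hydro_bundle`s (invisibly).
#' @export
hydro_train <- function(corpus, out_dir, datasets = "Global-Hydrolysis",
                        rules = NULL, seed = 1L, folds = 10L,
                        n_configs = 50L, top_n = 5L, ratio = 0.8,
                        threshold = 0.5, corpus_format = "smiles-table") {
  if (is.null(rules)) rules <- load_rulebase()
  records <- if (is.character(corpus)) {
    parse_reaction_corpus(corpus, corpus_format)
  } else if (inherits(corpus, "hydro_corpus")) corpus
  else if (is.list(corpus) && !is.null(corpus$records)) corpus$records
  else stop("unsupported corpus argument")

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- build_atom_datasets(records, rules)
  utils::write.csv(ds$labels, file.path(out_dir, "labels.csv"),
                   row.names = FALSE)
  jsonlite::write_json(ds$summary, file.path(out_dir, "corpus_summary.json"),
                       dataframe = "rows", digits = NA)

  bundles <- list()
  for (name in datasets) {
    table <- ds$datasets[[name]]
    if (is.null(table)) stop(sprintf("unknown dataset '%s'", name))
    if (!nrow(table) || length(unique(table$label)) < 2L) {
      warning(sprintf("dataset %s lacks two classes; skipped", name))
      next
    }
    sub_dir <- file.path(out_dir, gsub("[^A-Za-z0-9]+", "_", name))
    dir.create(sub_dir, showWarnings = FALSE)

    split <- split_dataset(table, ratio, seed)
    ftr <- build_feature_matrix(split$train, ds$parents)
    fte <- build_feature_matrix(split$test, ds$parents)
    y_train <- split$train$label
    y_test <- split$test$label

    selector <- fit_selector(ftr$X, y_train)
    Xtr <- apply_selector(selector, ftr$X)

    cv_table <- pretrain(Xtr, y_train, folds = folds, seed = seed)
    utils::write.csv(cv_table, file.path(sub_dir, "cv_table.csv"),
                     row.names = FALSE)
    top <- select_top(cv_table, top_n)
    tuned <- lapply(top, function(fam) {
      tune(fam, Xtr, y_train, n_configs = n_configs, folds = folds,
           seed = seed)
    })
    tuning_log <- do.call(rbind, lapply(tuned, function(t) {
      cbind(family = t$family, t$log)
    }))
    utils::write.csv(tuning_log, file.path(sub_dir, "tuning_log.csv"),
                     row.names = FALSE)

    bundle <- finalize(tuned, selector, ftr$X, y_train, fte$X, y_test,
                       dataset_name = name,
                       atom_classes = DATASET_CLASSES[[name]],
                       threshold = threshold, seed = seed)
    jsonlite::write_json(
      lapply(bundle$candidate_metrics, unclass),
      file.path(sub_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      lapply(bundle$candidate_metrics, function(m) {
        m[c("TP", "TN", "FP", "FN")]
      }),
      file.path(sub_dir, "confusion.json"), auto_unbox = TRUE, digits = NA)
    save_bundle(bundle, file.path(sub_dir, "bundle"))
    bundles[[name]] <- bundle
  }

  manifest <- list(
    seed = seed, folds = folds, n_configs = n_configs, top_n = top_n,
    ratio = ratio, threshold = threshold, datasets = datasets,
    n_records = length(records), unexplained_records = ds$unexplained,
    rulebase_version = rules$version,
    feature_version = feature_version(),
    package_version = hydrosite_version(),
    r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(bundles)
}

#' Predict ranked hydrolysis metabolites for query molecules
#'
#' @param molecules character vector of SMILES, or a file path (`.smi`
#'   one-per-line with optional id column, or an SDF).
#' @param bundle a `hydro_bundle`, a bundle directory, or `NULL` for pure
#'   rule-based enumeration (every matched site scores 1).
#' @param rules a `hydro_rulebase` (default shipped).
#' @param threshold site probability threshold tau.
#' @param out_prefix optional path prefix; writes `<prefix>.json`,
#'   `<prefix>.csv` and `<prefix>.sdf`.
#' @return named list per molecule with `sites` (per-atom probabilities)
#'   and `products` (ranked metabolite table); parse failures are reported
#'   in attribute `"failed"`, valid molecules still processed.
#' @export
hydro_predict <- function(molecules, bundle = NULL, rules = NULL,
                          threshold = 0.5, out_prefix = NULL) {
  if (is.null(rules)) rules <- load_rulebase()
  if (is.character(bundle) && length(bundle) == 1L && dir.exists(bundle)) {
    bundle <- load_bundle(bundle)
  }
  if (is.character(molecules) && length(molecules) == 1L &&
      file.exists(molecules)) {
    molecules <- read_molecule_input(molecules)
  }
  if (is.null(names(molecules))) {
    names(molecules) <- sprintf("mol%04d", seq_along(molecules))
  }
  out <- list(); failed <- list()
  for (nm in names(molecules)) {
    mol <- tryCatch(mol_canonicalize(molecules[[nm]]), error = function(e) e)
    if (inherits(mol, "error")) {
      failed[[nm]] <- conditionMessage(mol)
      next
    }
    sites <- if (is.null(bundle)) {
      ms <- match_sites(mol, rules)
      if (nrow(ms)) data.frame(atom_index = sort(unique(ms$atom_index)),
                               probability = 1.0)
      else data.frame(atom_index = integer(), probability = numeric())
    } else predict_sites(bundle, mol, threshold = threshold)
    products <- generate_metabolites(mol, rules, bundle, threshold)
    out[[nm]] <- list(smiles = canonical_smiles(mol), sites = sites,
                      products = products)
  }
  attr(out, "failed") <- failed
  if (!is.null(out_prefix)) write_prediction_outputs(out, out_prefix)
  out
}

read_molecule_input <- function(path) {
  if (grepl("V2000", paste(readLines(path, n = 4L, warn = FALSE),
                           collapse = " ")) || grepl("\\.sdf$", path)) {
    entries <- read_sdf_entries(path)
    smis <- vapply(entries, function(e) {
      tryCatch(canonical_smiles(sdf_entry_to_mol(e)),
               error = function(err) NA_character_)
    }, character(1))
    nms <- vapply(seq_along(entries), function(k) {
      t <- trimws(entries[[k]][1])
      if (nzchar(t)) t else sprintf("sdf%04d", k)
    }, character(1))
    stats::setNames(smis, nms)
  } else {
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines)]
    toks <- strsplit(lines, "[ \t]+")
    smis <- vapply(toks, `[`, "", 1L)
    nms <- vapply(seq_along(toks), function(k) {
      if (length(toks[[k]]) > 1L) toks[[k]][2] else sprintf("mol%04d", k)
    }, character(1))
    stats::setNames(smis, nms)
  }
}

write_prediction_outputs <- function(out, prefix) {
  rows <- list()
  for (nm in names(out)) {
    p <- out[[nm]]$products
    if (nrow(p)) rows[[nm]] <- cbind(molecule = nm, p)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(molecule = character())
  utils::write.csv(tab, paste0(prefix, ".csv"), row.names = FALSE)
  payload <- list(
    manifest = list(package_version = hydrosite_version(),
                    feature_version = feature_version()),
    molecules = lapply(out, function(p) {
      list(smiles = p$smiles, sites = p$sites, products = p$products,
           n_transformations = attr(p$products, "n_transformations"))
    }))
  jsonlite::write_json(payload, paste0(prefix, ".json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  ## SDF of major products
  majors <- tab[tab$fragment_role %in% "major", , drop = FALSE]
  if (nrow(majors)) {
    write_sdf(stats::setNames(as.list(majors$product_smiles),
                              sprintf("%s_rank%d", majors$molecule, majors$rank)),
              paste0(prefix, ".sdf"),
              fields = list(RULE = majors$rule_id,
                            SCORE = sprintf("%.4f", majors$score)))
  }
  invisible(prefix)
}

#' Evaluate predictions against per-compound reference products
#'
#' @param predictions result of [hydro_predict()], or its CSV output path.
#' @param references data frame (or CSV path) with columns `parent_id`,
#'   `product_smiles`.
#' @return list with `per_compound` (data frame) and `aggregate`
#'   (`hydro_product_eval`-style totals; hit rate over all reference
#'   products).
#' @export
hydro_evaluate <- function(predictions, references) {
  if (is.character(references)) {
    references <- utils::read.csv(references, stringsAsFactors = FALSE)
  }
  need <- c("parent_id", "product_smiles")
  if (!all(need %in% names(references))) {
    stop("references need columns parent_id, product_smiles")
  }
  if (is.character(predictions)) {
    tab <- utils::read.csv(predictions, stringsAsFactors = FALSE)
    predictions <- lapply(split(tab, tab$molecule), function(df) {
      list(products = df)
    })
  }
  ids <- unique(references$parent_id)
  miss <- setdiff(ids, names(predictions))
  if (length(miss)) {
    stop(sprintf("no predictions for reference parent id(s): %s",
                 paste(miss, collapse = ", ")))
  }
  per <- lapply(ids, function(id) {
    ev <- evaluate_products(
      predictions[[id]]$products,
      references$product_smiles[references$parent_id == id])
    data.frame(parent_id = id, n_reference = ev$n_reference,
               n_predicted = ev$n_predicted, n_hit = ev$n_hit,
               n_extra = ev$n_extra, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  agg <- list(n_reference = sum(per$n_reference),
              n_predicted = sum(per$n_predicted),
              n_hit = sum(per$n_hit), n_extra = sum(per$n_extra))
  agg$hit_rate <- agg$n_hit / agg$n_reference
  agg$false_positive_rate <-
    if (agg$n_predicted) agg$n_extra / agg$n_predicted else 0
  list(per_compound = per, aggregate = agg)
}
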