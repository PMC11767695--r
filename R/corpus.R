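## Reaction corpus: parent -> observed hydrolysis products, per-atom SOM
## labeling by rule matching, and the four atom-class datasets.

new_reaction_record <- function(record_id, parent, products,
                                environment = "unspecified", source = "") {
  list(record_id = record_id, parent = parent, products = products,
       environment = environment, source = source)
}

## Largest organic fragment (salt stripping): most heavy atoms, preferring
## carbon-containing fragments; ties broken by canonical SMILES order.
keep_largest_fragment <- function(mol) {
  frags <- mol_fragments(mol)
  if (length(frags) == 1L) return(frags[[1]])
  has_c <- vapply(frags, function(f) any(f$atoms$element == "C"), logical(1))
  if (any(has_c)) frags <- frags[has_c]
  sizes <- vapply(frags, n_atoms, integer(1))
  cand <- frags[sizes == max(sizes)]
  smi <- vapply(cand, canonical_smiles, character(1))
  cand[[order(smi)[1]]]
}

#' Parse a hydrolysis reaction corpus
#'
#' `smiles-table` format: a delimited text file (tab or comma, sniffed from
#' the header) with columns `parent_smiles` and `products_smiles`
#' (`.`-separated fragments, an optional `parent >>` prefix is accepted) and
#' optional `record_id`, `environment`, `source`. `sdf` format: a V2000 SD
#' file whose entries carry a `PRODUCTS` property (`.`-separated SMILES).
#' Multi-fragment parents are reduced to their largest organic fragment;
#' structures are canonicalised on ingest. Rows that fail to parse are
#' reported in the `parse_report` attribute, never silently dropped.
#'
#' @param path input file.
#' @param format `"smiles-table"` or `"sdf"`.
#' @return a `hydro_corpus` (list of reaction records) with attribute
#'   `parse_report`.
#' @export
parse_reaction_corpus <- function(path, format = c("smiles-table", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("cannot read corpus file: %s", path))
  rows <- if (format == "smiles-table") read_reaction_table(path)
          else read_reaction_sdf(path)
  records <- list()
  report <- list()
  for (k in seq_len(nrow(rows))) {
    rec <- tryCatch({
      parent <- canonical_smiles(keep_largest_fragment(
        parse_smiles(rows$parent_smiles[k])))
      prods_raw <- rows$products_smiles[k]
      if (grepl(">>", prods_raw, fixed = TRUE)) {
        prods_raw <- trimws(strsplit(prods_raw, ">>", fixed = TRUE)[[1]][2])
      }
      prods <- vapply(trimws(strsplit(prods_raw, ".", fixed = TRUE)[[1]]),
                      canonical_smiles, character(1), USE.NAMES = FALSE)
      if (!length(prods)) stop("empty product list")
      new_reaction_record(rows$record_id[k], parent, unique(prods),
                          rows$environment[k], rows$source[k])
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      report[[length(report) + 1L]] <- data.frame(
        row = k, record_id = rows$record_id[k],
        reason = conditionMessage(rec), stringsAsFactors = FALSE)
    } else {
      records[[length(records) + 1L]] <- rec
    }
  }
  if (!length(records)) stop("corpus contains no valid records")
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(row = integer(), record_id = character(), reason = character())
  structure(records, class = "hydro_corpus", parse_report = report)
}

read_reaction_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  ## single-column "parent >> products" form
  if (!"parent_smiles" %in% names(df) && ncol(df) >= 1L &&
      any(grepl(">>", df[[1]], fixed = TRUE))) {
    halves <- strsplit(df[[1]], ">>", fixed = TRUE)
    df <- data.frame(parent_smiles = trimws(vapply(halves, `[`, "", 1L)),
                     products_smiles = trimws(vapply(halves, `[`, "", 2L)),
                     stringsAsFactors = FALSE)
  }
  need <- c("parent_smiles", "products_smiles")
  miss <- need[!need %in% names(df)]
  if (length(miss)) {
    stop(sprintf("corpus table lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  if (!"record_id" %in% names(df)) {
    df$record_id <- sprintf("rec%04d", seq_len(nrow(df)))
  }
  if (!"environment" %in% names(df)) df$environment <- "unspecified"
  if (!"source" %in% names(df)) df$source <- ""
  df
}

#' @export
print.hydro_corpus <- function(x, ...) {
  rep <- attr(x, "parse_report")
  cat(sprintf("<hydro_corpus: %d records%s>\n", length(x),
              if (nrow(rep)) sprintf(", %d rejected rows", nrow(rep)) else ""))
  invisible(x)
}

#' Label SOM+/SOM- atoms of one reaction record
#'
#' Every tracked heavy atom (classes N/O/C/S/X) of the parent receives
#' exactly one label. An atom is SOM+ when some rule applied at that atom
#' yields at least one product fragment that matches an observed product
#' (canonical, stereo-agnostic comparison); all other tracked atoms are
#' SOM-. When no rule application explains any observed product the record
#' is flagged unexplained (attribute `"unexplained"`) and should be
#' excluded from labeled data.
#'
#' @param record a reaction record from [parse_reaction_corpus()].
#' @param rules a `hydro_rulebase`.
#' @return data frame (`record_id`, `atom_index`, `element`, `atom_class`,
#'   `label`) with attribute `unexplained`.
#' @export
label_som_atoms <- function(record, rules) {
  mol <- parse_smiles(record$parent)      # parent stored canonical
  cls <- element_class(mol$atoms$element)
  tracked <- which(!is.na(cls))
  sites <- match_sites(mol, rules, collapse_symmetric = FALSE)
  explained_at <- integer()
  if (nrow(sites)) {
    for (k in seq_len(nrow(sites))) {
      if (length(intersect(sites$products[[k]], record$products))) {
        explained_at <- c(explained_at, sites$atom_index[k])
      }
    }
  }
  labels <- data.frame(
    record_id = record$record_id,
    atom_index = tracked - 1L,
    element = mol$atoms$element[tracked],
    atom_class = cls[tracked],
    label = ifelse((tracked - 1L) %in% explained_at, "SOM+", "SOM-"),
    stringsAsFactors = FALSE)
  attr(labels, "unexplained") <- length(explained_at) == 0L
  labels
}

#' Build the four atom-class datasets from a labeled corpus
#'
#' @param records a `hydro_corpus`.
#' @param rules a `hydro_rulebase`.
#' @return list with `labels` (all records pooled), `datasets` (named list
#'   `N-Hydrolysis`, `O-Hydrolysis`, `C-Hydrolysis`, `Global-Hydrolysis`),
#'   `summary` (SOM+/SOM- counts per dataset), `parents` (record_id ->
#'   canonical parent SMILES) and `unexplained` (excluded record ids).
#' @export
build_atom_datasets <- function(records, rules) {
  all_labels <- list(); unexplained <- character()
  for (rec in records) {
    lab <- label_som_atoms(rec, rules)
    if (isTRUE(attr(lab, "unexplained"))) {
      unexplained <- c(unexplained, rec$record_id)
      next
    }
    all_labels[[length(all_labels) + 1L]] <- lab
  }
  if (!length(all_labels)) stop("no record could be explained by the rule base")
  labels <- do.call(rbind, all_labels)
  datasets <- list(
    "N-Hydrolysis" = labels[labels$atom_class == "N", , drop = FALSE],
    "O-Hydrolysis" = labels[labels$atom_class == "O", , drop = FALSE],
    "C-Hydrolysis" = labels[labels$atom_class == "C", , drop = FALSE],
    "Global-Hydrolysis" = labels
  )
  for (nm in names(datasets)) {
    if (!nrow(datasets[[nm]])) {
      warning(sprintf("dataset %s contains no atoms", nm))
    }
  }
  parents <- stats::setNames(
    vapply(records, `[[`, character(1), "parent"),
    vapply(records, `[[`, character(1), "record_id"))
  parents <- parents[!names(parents) %in% unexplained]
  list(labels = labels, datasets = datasets,
       summary = corpus_statistics_from_labels(labels),
       parents = parents, unexplained = unexplained)
}

corpus_statistics_from_labels <- function(labels) {
  count <- function(df) c(som_pos = sum(df$label == "SOM+"),
                          som_neg = sum(df$label == "SOM-"))
  out <- rbind(
    "N-Hydrolysis" = count(labels[labels$atom_class == "N", ]),
    "O-Hydrolysis" = count(labels[labels$atom_class == "O", ]),
    "C-Hydrolysis" = count(labels[labels$atom_class == "C", ]),
    "S-atoms" = count(labels[labels$atom_class == "S", ]),
    "X-atoms" = count(labels[labels$atom_class == "X", ]),
    "Global-Hydrolysis" = count(labels))
  df <- data.frame(dataset = rownames(out), out, row.names = NULL,
                   stringsAsFactors = FALSE)
  df$ratio <- ifelse(df$som_neg > 0, df$som_pos / df$som_neg, NA_real_)
  df
}

#' Molecule-grouped train/test split
#'
#' Splits a labeled atom table at the molecule level: no molecule
#' contributes atoms to both sides. Deterministic for a fixed seed.
#'
#' @param table labeled atom data frame (needs `record_id`).
#' @param ratio train fraction (default 0.8).
#' @param seed integer seed.
#' @return a `hydro_split`: list with `train`, `test` (row subsets),
#'   `train_ids`, `test_ids`, `ratio`, `seed`.
#' @export
split_dataset <- function(table, ratio = 0.8, seed = 1L) {
  if (!nrow(table)) stop("cannot split an empty table")
  ids <- unique(table$record_id)
  if (length(ids) < 2L) stop("need at least 2 molecules to split")
  n_train <- max(1L, min(length(ids) - 1L, round(ratio * length(ids))))
  shuffled <- withr::with_seed(seed, sample(ids))
  train_ids <- sort(shuffled[seq_len(n_train)])
  test_ids <- sort(setdiff(ids, train_ids))
  structure(list(
    train = table[table$record_id %in% train_ids, , drop = FALSE],
    test = table[table$record_id %in% test_ids, , drop = FALSE],
    train_ids = train_ids, test_ids = test_ids,
    ratio = ratio, seed = as.integer(seed)), class = "hydro_split")
}
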