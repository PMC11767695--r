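## Synthetic hydrolysis reaction corpus with per-atom ground truth.
##
## Parents are small scaffolds (benzenoid, pyridine, alkyl, alicyclic)
## decorated with 1-3 hydrolyzable groups and 0-2 hydrolytically inert
## decoys. Ground-truth SOM+ atoms are the rule-matched reaction centers of
## the assembled molecule, and observed products are computed by applying
## the rule base at those centers — so corpus labeling can be validated
## end-to-end against the generator without sharing any site bookkeeping
## beyond the rule base itself.

## Scaffold templates; slot A always receives a hydrolyzable group, slots
## B/C receive groups, decoys or nothing.
SYNTH_SCAFFOLDS <- c(
  "c1ccc({A})cc1",
  "c1ccc({A})c({B})c1",
  "c1cc({A})cc({B})c1",
  "c1ccc({A})cc1{B}",
  "c1ccnc({A})c1",
  "c1ccc({A})nc1",
  "Cc1ccc({A})cc1",
  "Cc1cccc({A})c1",
  "c1cc({A})c({B})cc1{C}",
  "CC{A}",
  "CCC{A}",
  "CC(C){A}",
  "CC({A})C{B}",
  "C1CCC({A})CC1",
  "CC(C)({A}){B}",
  "c1cc2ccccc2c({A})c1"
)

## Hydrolyzable substituents (attach via their first atom) with sampling
## weights; weights shape the SOM+/SOM- balance of the corpus.
SYNTH_GROUPS <- list(
  amide_acyl   = list(frag = "C(=O)NC",        w = 1.2),
  amide_n      = list(frag = "NC(=O)C",        w = 1.2),
  ester_acyl   = list(frag = "C(=O)OC",        w = 1.4),
  ester_o      = list(frag = "OC(=O)C",        w = 1.4),
  carbamate_o  = list(frag = "OC(=O)NC",       w = 1.0),
  carbamate_n  = list(frag = "NC(=O)OC",       w = 1.0),
  urea         = list(frag = "NC(=O)NC",       w = 0.8),
  nitrile      = list(frag = "C#N",            w = 0.8),
  carbonate    = list(frag = "OC(=O)OC",       w = 0.6),
  oxime        = list(frag = "C(C)=NO",        w = 0.6),
  phosphoester = list(frag = "OP(=O)(OC)OC",   w = 0.8),
  phosphothio  = list(frag = "OP(=S)(OC)OC",   w = 0.6),
  thioether    = list(frag = "SC",             w = 0.7),
  chloromethyl = list(frag = "CCl",            w = 0.7),
  bromomethyl  = list(frag = "CBr",            w = 0.4),
  acid_cl      = list(frag = "C(=O)Cl",        w = 0.4),
  alkyne       = list(frag = "C#C",            w = 0.5)
)

## Hydrolytically inert decoys (contribute SOM- atoms only).
SYNTH_DECOYS <- list(
  methyl    = list(frag = "C",             w = 1.0),
  ethyl     = list(frag = "CC",            w = 0.8),
  methoxy   = list(frag = "OC",            w = 1.0),
  hydroxyl  = list(frag = "O",             w = 0.8),
  dimethylamino = list(frag = "N(C)C",     w = 0.8),
  fluoro    = list(frag = "F",             w = 0.6),
  nitro     = list(frag = "[N+](=O)[O-]",  w = 0.5),
  isopropyl = list(frag = "C(C)C",         w = 0.5)
)

#' Configuration for the synthetic corpus generator
#'
#' @param n_molecules number of distinct parent molecules (>= 10).
#' @param seed integer seed; the corpus is a pure function of the config.
#' @param p_extra_group probability that an available extra slot carries a
#'   second/third hydrolyzable group rather than a decoy or hydrogen.
#' @param p_decoy probability that a non-group extra slot carries a decoy.
#' @param group_weights named sampling weights over hydrolyzable families
#'   (default `SYNTH_GROUPS` weights).
#' @param decoy_weights named sampling weights over decoys.
#' @param target_global_ratio intended SOM+:SOM- ratio of the Global table
#'   (reported against the achieved ratio; generation is not re-tuned).
#' @param label_noise fraction of ground-truth labels to flip in the
#'   *reported* label table (testing machinery; the default 0 means the
#'   corpus is internally consistent).
#' @return a `hydro_synth_config`.
#' @export
synth_config <- function(n_molecules = 300L, seed = 7L,
                         p_extra_group = 0.45, p_decoy = 0.6,
                         group_weights = NULL, decoy_weights = NULL,
                         target_global_ratio = 0.24, label_noise = 0) {
  if (n_molecules < 10L) stop("n_molecules must be at least 10")
  gw <- vapply(SYNTH_GROUPS, `[[`, numeric(1), "w")
  if (!is.null(group_weights)) gw[names(group_weights)] <- group_weights
  dw <- vapply(SYNTH_DECOYS, `[[`, numeric(1), "w")
  if (!is.null(decoy_weights)) dw[names(decoy_weights)] <- decoy_weights
  if (any(gw < 0) || any(dw < 0)) stop("weights must be non-negative")
  if (all(gw == 0)) {
    stop("all hydrolyzable-group weights are zero: no SOM+ atom can be generated")
  }
  structure(list(n_molecules = as.integer(n_molecules), seed = as.integer(seed),
                 p_extra_group = p_extra_group, p_decoy = p_decoy,
                 group_weights = gw, decoy_weights = dw,
                 target_global_ratio = target_global_ratio,
                 label_noise = label_noise),
            class = "hydro_synth_config")
}

sample_weighted <- function(items, weights) {
  items[[sample.int(length(items), 1L, prob = weights)]]
}

assemble_parent <- function(config) {
  template <- SYNTH_SCAFFOLDS[[sample.int(length(SYNTH_SCAFFOLDS), 1L)]]
  gfrags <- vapply(SYNTH_GROUPS, `[[`, character(1), "frag")
  dfrags <- vapply(SYNTH_DECOYS, `[[`, character(1), "frag")
  smi <- template
  ## slot {A}: always a hydrolyzable group
  smi <- sub("{A}", sample_weighted(gfrags, config$group_weights), smi, fixed = TRUE)
  for (slot in c("{B}", "{C}")) {
    if (!grepl(slot, smi, fixed = TRUE)) next
    fill <- if (stats::runif(1) < config$p_extra_group) {
      sample_weighted(gfrags, config$group_weights)
    } else if (stats::runif(1) < config$p_decoy) {
      sample_weighted(dfrags, config$decoy_weights)
    } else ""
    if (nzchar(fill)) {
      smi <- sub(slot, fill, smi, fixed = TRUE)
    } else if (grepl(paste0("(", slot, ")"), smi, fixed = TRUE)) {
      smi <- sub(paste0("(", slot, ")"), "", smi, fixed = TRUE)
    } else {
      smi <- sub(slot, "", smi, fixed = TRUE)
    }
  }
  smi
}

#' Generate a synthetic hydrolysis corpus with ground truth
#'
#' @param config a [synth_config()].
#' @param rules a `hydro_rulebase` (default: shipped base).
#' @return list with `records` (a `hydro_corpus`), `labels` (ground-truth
#'   per-atom label table in the format of [label_som_atoms()]), `summary`
#'   (achieved SOM+/SOM- statistics) and `config`.
#' @export
generate_corpus <- function(config = synth_config(), rules = NULL) {
  if (is.null(rules)) rules <- load_rulebase()
  withr::with_seed(config$seed, {
    records <- list(); labels <- list(); seen <- character()
    attempts <- 0L
    while (length(records) < config$n_molecules) {
      attempts <- attempts + 1L
      if (attempts > 60L * config$n_molecules) {
        stop("generator failed to produce enough distinct explainable molecules")
      }
      smi <- assemble_parent(config)
      mol <- tryCatch(mol_canonicalize(parse_smiles(smi)),
                      error = function(e) NULL)
      if (is.null(mol)) next
      parent <- canonical_smiles(mol)
      if (parent %in% seen) next
      sites <- match_sites(mol, rules, collapse_symmetric = FALSE)
      if (!nrow(sites)) next
      products <- sort(unique(unlist(sites$products)))
      seen <- c(seen, parent)
      rid <- sprintf("syn%04d", length(records) + 1L)
      records[[length(records) + 1L]] <-
        new_reaction_record(rid, parent, products, source = "synthetic")
      cls <- element_class(mol$atoms$element)
      tracked <- which(!is.na(cls))
      lab <- data.frame(
        record_id = rid, atom_index = tracked - 1L,
        element = mol$atoms$element[tracked], atom_class = cls[tracked],
        label = ifelse((tracked - 1L) %in% sites$atom_index, "SOM+", "SOM-"),
        stringsAsFactors = FALSE)
      labels[[length(labels) + 1L]] <- lab
    }
    labels <- do.call(rbind, labels)
    if (config$label_noise > 0) {
      flip <- which(stats::runif(nrow(labels)) < config$label_noise)
      labels$label[flip] <- ifelse(labels$label[flip] == "SOM+", "SOM-", "SOM+")
    }
    summary <- corpus_statistics_from_labels(labels)
    achieved <- summary$ratio[summary$dataset == "Global-Hydrolysis"]
    list(records = structure(records, class = "hydro_corpus",
                             parse_report = data.frame()),
         labels = labels, summary = summary,
         achieved_global_ratio = achieved, config = config)
  })
}

#' Table-1-style SOM statistics of a labeled corpus
#'
#' @param labels per-atom label table.
#' @return data frame of SOM+/SOM- counts per atom-class dataset (empty
#'   classes are reported as zero rows, never omitted).
#' @export
corpus_statistics <- function(labels) corpus_statistics_from_labels(labels)

#' Write a corpus to the reaction-table interchange format
#'
#' @param records a `hydro_corpus`.
#' @param path output TSV path.
#' @export
write_reaction_table <- function(records, path) {
  df <- data.frame(
    record_id = vapply(records, `[[`, character(1), "record_id"),
    parent_smiles = vapply(records, `[[`, character(1), "parent"),
    products_smiles = vapply(records, function(r) paste(r$products, collapse = "."),
                             character(1)),
    environment = vapply(records, function(r) paste(r$environment, collapse = ";"),
                         character(1)),
    source = vapply(records, `[[`, character(1), "source"),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
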