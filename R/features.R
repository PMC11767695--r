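## Per-atom feature assembly: 1024-bit environment fingerprint + 8
## descriptors = 1032 columns, fixed order, versioned.

feature_version <- function() paste(FP_DIALECT, DESC_VERSION, sep = "+")

#' Featurize the atoms of a molecule
#'
#' One row per heavy atom of the requested atom class(es), in canonical
#' atom order. Columns: `fp_0000..fp_1023` then the 8 descriptors.
#'
#' @param molecule a `hymol` or SMILES string.
#' @param classes atom classes to keep (subset of N, O, C, S, X) or
#'   `"all"` for every tracked class.
#' @param radius fingerprint radius (default 3).
#' @param n_bits fingerprint length (default 1024).
#' @return list with `meta` (data frame: `atom_index` 0-based, `element`,
#'   `atom_class`) and `X` (numeric matrix, 1032 columns).
#' @export
featurize <- function(molecule, classes = "all", radius = 3L, n_bits = 1024L) {
  mol <- if (is.character(molecule)) mol_canonicalize(molecule) else molecule
  cls <- element_class(mol$atoms$element)
  keep <- if (identical(classes, "all")) !is.na(cls) else cls %in% classes
  idx <- which(keep)
  meta <- data.frame(atom_index = idx - 1L,
                     element = mol$atoms$element[idx],
                     atom_class = cls[idx],
                     stringsAsFactors = FALSE)
  if (!length(idx)) {
    X <- matrix(numeric(), 0, n_bits + 8L)
    colnames(X) <- c(sprintf("fp_%04d", seq_len(n_bits) - 1L), DESCRIPTOR_NAMES)
    return(list(meta = meta, X = X))
  }
  fp <- fingerprint_matrix(mol, radius, n_bits)
  dm <- descriptor_matrix(mol)
  X <- cbind(fp, dm)[idx, , drop = FALSE]
  rownames(X) <- NULL
  list(meta = meta, X = X)
}

#' Export a labeled feature matrix as CSV
#'
#' Header: `record_id, atom_index, fp_0000..fp_1023, d_*, label`.
#'
#' @param labels labeled atom table ([label_som_atoms()] format).
#' @param parents named vector: record_id -> canonical parent SMILES.
#' @param path output CSV path.
#' @export
write_feature_table <- function(labels, parents, path) {
  fm <- build_feature_matrix(labels, parents)
  out <- cbind(fm$meta[, c("record_id", "atom_index")],
               as.data.frame(fm$X), label = fm$meta$label)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

## Corpus-level feature table aligned to a labeled-atom table.
## labels: data.frame(record_id, atom_index, element, atom_class, label)
## parents: named character vector record_id -> canonical parent SMILES.
build_feature_matrix <- function(labels, parents, radius = 3L,
                                 n_bits = 1024L) {
  Xs <- vector("list", length(unique(labels$record_id)))
  metas <- vector("list", length(Xs))
  rid_levels <- unique(labels$record_id)
  for (k in seq_along(rid_levels)) {
    rid <- rid_levels[k]
    mol <- parse_smiles(parents[[rid]])   # parents stored canonical
    f <- featurize(mol, "all", radius, n_bits)
    sub <- labels[labels$record_id == rid, , drop = FALSE]
    pos <- match(sub$atom_index, f$meta$atom_index)
    if (anyNA(pos)) stop(sprintf("record %s: label atom not in feature rows", rid))
    Xs[[k]] <- f$X[pos, , drop = FALSE]
    metas[[k]] <- sub
  }
  list(meta = do.call(rbind, metas), X = do.call(rbind, Xs))
}
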