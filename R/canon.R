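## Canonical SMILES.
##
## Canonical atom ranks are obtained by iterative invariant refinement
## (element, charge, aromaticity, degree, H count seed; neighbour-rank
## multisets thereafter). Residual symmetry is resolved exactly: every atom
## of the first tied cell is individualised in turn, refinement re-run, and
## the lexicographically smallest emitted SMILES kept. Exponential only on
## pathologically symmetric graphs; molecules here are small.

atom_invariants <- function(mol) {
  deg <- mol_degree(mol)
  sprintf("%03d|%d|%+03d|%d|%d",
          ATOMIC_NUMBER[mol$atoms$element], as.integer(mol$atoms$aromatic),
          mol$atoms$charge, deg, mol$atoms$hcount)
}

dense_rank <- function(keys) as.integer(factor(keys, levels = sort(unique(keys))))

refine_ranks <- function(mol, ranks, adj) {
  repeat {
    keys <- character(n_atoms(mol))
    for (a in seq_len(n_atoms(mol))) {
      nb <- adj[[a]]
      nbk <- if (is.null(nb)) character() else {
        vapply(seq_len(nrow(nb)), function(k) {
          b <- mol$bonds[nb[k, 2], ]
          bt <- if (b$arom) 4L else b$order
          sprintf("%d:%05d", bt, ranks[nb[k, 1]])
        }, character(1))
      }
      keys[a] <- paste0(sprintf("%05d", ranks[a]), "|",
                        paste(sort(nbk), collapse = ","))
    }
    new <- dense_rank(keys)
    if (identical(new, ranks)) return(ranks)
    ranks <- new
  }
}

canon_component_smiles <- function(mol) {
  adj <- mol_adjacency(mol)
  search <- function(ranks) {
    ranks <- refine_ranks(mol, ranks, adj)
    if (length(unique(ranks)) == n_atoms(mol)) {
      return(write_smiles_ranked(mol, ranks, adj))
    }
    tab <- table(ranks)
    cell_rank <- as.integer(names(tab)[tab > 1][1])
    members <- which(ranks == cell_rank)
    best <- NULL
    for (a in members) {
      r2 <- ranks * 2L
      r2[a] <- r2[a] - 1L
      s <- search(dense_rank(sprintf("%06d", r2)))
      if (is.null(best) || s < best) best <- s
    }
    best
  }
  search(dense_rank(atom_invariants(mol)))
}

## Emit SMILES for one connected component under a complete atom ranking.
## Pass 1 classifies bonds into DFS-tree vs ring bonds under the canonical
## neighbour order; pass 2 emits, assigning ring-closure digits on first use.
write_smiles_ranked <- function(mol, ranks, adj) {
  n <- n_atoms(mol)
  bos <- bond_order_sum(mol)

  bond_token <- function(b) {
    if (b$arom) return("")
    if (b$order == 2L) return("=")
    if (b$order == 3L) return("#")
    if (mol$atoms$aromatic[b$i] && mol$atoms$aromatic[b$j]) return("-")
    ""
  }

  atom_token <- function(a) {
    at <- mol$atoms[a, ]
    implied <- {
      vals <- DEFAULT_VALENCES[[at$element]]
      if (is.null(vals) || at$charge != 0L) NA_integer_
      else if (at$aromatic) max(0L, as.integer(vals[1] - floor(bos[a])))
      else {
        ok <- vals[vals >= bos[a]]
        if (length(ok)) as.integer(ok[1] - floor(bos[a])) else 0L
      }
    }
    sym <- if (at$aromatic) tolower(at$element) else at$element
    plain <- at$charge == 0L && at$element %in% ORGANIC_SUBSET &&
      !is.na(implied) && implied == at$hcount &&
      !(at$aromatic && !at$element %in% c("B", "C", "N", "O", "P", "S"))
    if (plain) return(sym)
    h <- if (at$hcount == 0L) "" else if (at$hcount == 1L) "H" else
      paste0("H", at$hcount)
    chg <- if (at$charge == 0L) "" else if (at$charge == 1L) "+" else
      if (at$charge == -1L) "-" else sprintf("%+d", at$charge)
    paste0("[", sym, h, chg, "]")
  }

  digit_token <- function(d) if (d < 10L) as.character(d) else sprintf("%%%02d", d)

  root <- which.min(ranks)

  ## pass 1: tree/ring bond classification under canonical neighbour order
  is_tree <- logical(nrow(mol$bonds))
  is_ring <- logical(nrow(mol$bonds))
  seen <- logical(n)
  classify <- function(a) {
    seen[a] <<- TRUE
    nb <- adj[[a]]
    if (is.null(nb)) return(invisible())
    nb <- nb[order(ranks[nb[, 1]]), , drop = FALSE]
    for (k in seq_len(nrow(nb))) {
      tgt <- nb[k, 1]; bid <- nb[k, 2]
      if (is_tree[bid] || is_ring[bid]) next
      if (seen[tgt]) is_ring[bid] <<- TRUE
      else { is_tree[bid] <<- TRUE; classify(tgt) }
    }
  }
  classify(root)

  ## pass 2: emission with ring digits assigned on first encounter
  ring_digit <- rep(NA_integer_, nrow(mol$bonds))
  next_digit <- 0L
  emit <- function(a) {
    out <- atom_token(a)
    nb <- adj[[a]]
    if (is.null(nb)) return(out)
    nb <- nb[order(ranks[nb[, 1]]), , drop = FALSE]
    ## ring-closure digits first (opening or closing)
    for (k in seq_len(nrow(nb))) {
      bid <- nb[k, 2]
      if (!is_ring[bid]) next
      if (is.na(ring_digit[bid])) {
        next_digit <<- next_digit + 1L
        ring_digit[bid] <<- next_digit
      }
      out <- paste0(out, bond_token(mol$bonds[bid, ]),
                    digit_token(ring_digit[bid]))
    }
    children <- integer(); child_bonds <- integer()
    for (k in seq_len(nrow(nb))) {
      bid <- nb[k, 2]
      if (is_tree[bid] && !tree_done[bid]) {
        tree_done[bid] <<- TRUE
        children <- c(children, nb[k, 1])
        child_bonds <- c(child_bonds, bid)
      }
    }
    for (k in seq_along(children)) {
      sub <- paste0(bond_token(mol$bonds[child_bonds[k], ]), emit(children[k]))
      out <- if (k < length(children)) paste0(out, "(", sub, ")")
             else paste0(out, sub)
    }
    out
  }
  tree_done <- logical(nrow(mol$bonds))
  emit(root)
}

#' Canonical SMILES of a molecule
#'
#' Multi-fragment inputs are canonicalised per fragment and joined with `.`
#' in sorted order, so canonical equality is fragment-order independent.
#'
#' @param mol a `hymol` or a SMILES string.
#' @return character scalar canonical SMILES.
#' @examples
#' canonical_smiles("C(C)(=O)Nc1ccccc1")
#' @export
canonical_smiles <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  frags <- mol_fragments(mol)
  paste(sort(vapply(frags, canon_component_smiles, character(1))),
        collapse = ".")
}

#' Reorder a molecule into canonical atom order
#'
#' Atom index 0..n-1 over the returned molecule is the package's canonical
#' atom numbering (heavy atoms in canonical SMILES emission order).
#'
#' @param mol a `hymol` or SMILES string.
#' @return a `hymol` whose atom order matches its canonical SMILES.
#' @export
mol_canonicalize <- function(mol) {
  parse_smiles(canonical_smiles(mol))
}

mol_to_smiles <- function(mol) canonical_smiles(mol)
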