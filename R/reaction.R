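## Reaction SMARTS: one-reactant transformations with atom maps.
##
## The reactant side is a matchable pattern; the product side is a build
## template. Application semantics: bonds between mapped atom pairs are
## rewired to match the product template (deleted when absent there), new
## unmapped product atoms are created, unmapped reactant atoms are removed,
## and implicit hydrogens are recomputed on the edited graph. Everything a
## mapped atom carries outside the pattern (substituents, ring context) is
## preserved — this is what turns a functional-group rule into a whole-
## molecule transformation.

parse_reaction_smarts <- function(smarts) {
  halves <- strsplit(smarts, ">>", fixed = TRUE)[[1]]
  if (length(halves) != 2L) stop("reaction SMARTS must contain one '>>'")
  lhs <- trimws(halves[1]); rhs <- trimws(halves[2])
  ## strip one outer paren pair wrapping the whole product side
  if (grepl("^\\(", rhs) && grepl("\\)$", rhs)) {
    inner <- substring(rhs, 2L, nchar(rhs) - 1L)
    if (balanced_parens(inner)) rhs <- inner
  }
  prod_parts <- split_top_level(rhs, ".")
  reactant <- parse_smarts(gsub(" ", "", lhs))
  products <- lapply(prod_parts, function(p) parse_smarts(gsub(" ", "", p)))

  rmaps <- vapply(reactant$atoms, function(a) a$map %||% NA_integer_, integer(1))
  if (all(is.na(rmaps))) stop("reactant pattern carries no atom maps")
  if (anyDuplicated(rmaps[!is.na(rmaps)])) stop("duplicate atom map on reactant side")
  structure(list(reactant = reactant, products = products, smarts = smarts),
            class = "hyreaction")
}

balanced_parens <- function(s) {
  depth <- 0L
  for (ch in strsplit(s, "")[[1]]) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (depth < 0L) return(FALSE)
  }
  depth == 0L
}

split_top_level <- function(s, sep) {
  chars <- strsplit(s, "")[[1]]
  depth <- 0L; parts <- character(); cur <- ""
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (ch == sep && depth == 0L) { parts <- c(parts, cur); cur <- "" }
    else cur <- paste0(cur, ch)
  }
  c(parts, cur)
}

pattern_maps <- function(pattern) {
  vapply(pattern$atoms, function(a) a$map %||% NA_integer_, integer(1))
}

## Apply a parsed reaction at one embedding of its reactant pattern.
## `match` is an integer vector: reactant pattern atom -> molecule atom.
## Returns a list of product fragments (hymol), major organic first left to
## the caller; fragments are sanitized but not yet canonical-ordered.
apply_reaction <- function(mol, rxn, match) {
  rmaps <- pattern_maps(rxn$reactant)
  map_to_mol <- stats::setNames(match[!is.na(rmaps)], rmaps[!is.na(rmaps)])

  atoms <- mol$atoms
  bonds <- mol$bonds

  ## product-side bonds between mapped pairs, keyed "lo-hi" of map numbers
  prod_bond_type <- list()
  new_atoms <- list()      # per product component: specs of unmapped atoms
  new_bonds <- list()      # bonds touching unmapped atoms, resolved later
  for (pp in rxn$products) {
    pm <- pattern_maps(pp)
    local_id <- integer(length(pp$atoms))   # index into new_atoms for unmapped
    for (k in seq_along(pp$atoms)) {
      if (is.na(pm[k])) {
        spec <- pp$atoms[[k]]
        if (is.null(spec$allowed)) stop("unmapped product atom must name an element")
        new_atoms[[length(new_atoms) + 1L]] <- list(
          element = spec$allowed$element[1],
          aromatic = isTRUE(spec$allowed$aromatic[1]),
          charge = if (is.na(spec$charge)) 0L else spec$charge,
          hexp = spec$H)
        local_id[k] <- length(new_atoms)
      }
    }
    if (nrow(pp$bonds)) {
      for (b in seq_len(nrow(pp$bonds))) {
        pi <- pp$bonds$i[b]; pj <- pp$bonds$j[b]; ty <- pp$bonds$type[b]
        mi <- pm[pi]; mj <- pm[pj]
        if (!is.na(mi) && !is.na(mj)) {
          key <- paste(sort(c(mi, mj)), collapse = "-")
          prod_bond_type[[key]] <- ty
        } else {
          new_bonds[[length(new_bonds) + 1L]] <- list(
            i = if (is.na(mi)) -local_id[pi] else as.integer(mi),
            j = if (is.na(mj)) -local_id[pj] else as.integer(mj),
            type = ty)
        }
      }
    }
  }

  bond_order_from_type <- function(ty) switch(ty, "=" = 2L, "#" = 3L, 1L)

  ## rewire bonds between mapped pairs present in the reactant pattern
  rb <- rxn$reactant$bonds
  if (nrow(rb)) {
    for (b in seq_len(nrow(rb))) {
      mi <- rmaps[rb$i[b]]; mj <- rmaps[rb$j[b]]
      if (is.na(mi) || is.na(mj)) next
      a1 <- map_to_mol[[as.character(mi)]]
      a2 <- map_to_mol[[as.character(mj)]]
      key <- paste(sort(c(mi, mj)), collapse = "-")
      hit <- which((bonds$i == a1 & bonds$j == a2) |
                   (bonds$i == a2 & bonds$j == a1))
      if (is.null(prod_bond_type[[key]])) {
        bonds <- bonds[-hit, , drop = FALSE]        # bond cleaved
      } else {
        ty <- prod_bond_type[[key]]
        if (ty == "default") {
          ## unspecified product bond: single, or aromatic if it was
          if (!bonds$arom[hit]) { bonds$order[hit] <- 1L }
        } else if (ty != "~") {
          bonds$order[hit] <- bond_order_from_type(ty)
          bonds$arom[hit] <- identical(ty, ":")
        }
      }
      prod_bond_type[[key]] <- NULL
    }
  }
  ## product bonds between mapped pairs with no reactant-pattern bond: add
  for (key in names(prod_bond_type)) {
    mm <- as.integer(strsplit(key, "-")[[1]])
    ty <- prod_bond_type[[key]]
    bonds <- rbind(bonds, data.frame(
      i = map_to_mol[[as.character(mm[1])]],
      j = map_to_mol[[as.character(mm[2])]],
      order = bond_order_from_type(ty), arom = identical(ty, ":"),
      stringsAsFactors = FALSE))
  }

  ## create unmapped product atoms
  new_idx <- integer(length(new_atoms))
  for (k in seq_along(new_atoms)) {
    na_ <- new_atoms[[k]]
    atoms <- rbind(atoms, data.frame(
      element = na_$element, aromatic = na_$aromatic, charge = na_$charge,
      hexp = if (is.null(na_$hexp)) NA_integer_ else na_$hexp,
      hcount = NA_integer_, stringsAsFactors = FALSE))
    new_idx[k] <- nrow(atoms)
  }
  for (nb in new_bonds) {
    i <- if (nb$i < 0L) new_idx[-nb$i] else map_to_mol[[as.character(nb$i)]]
    j <- if (nb$j < 0L) new_idx[-nb$j] else map_to_mol[[as.character(nb$j)]]
    bonds <- rbind(bonds, data.frame(
      i = i, j = j, order = bond_order_from_type(nb$type),
      arom = identical(nb$type, ":"), stringsAsFactors = FALSE))
  }

  ## drop unmapped reactant atoms (none in the shipped base, but supported)
  drop_atoms <- match[is.na(rmaps)]
  edited <- new_hymol(atoms, bonds)
  if (length(drop_atoms)) {
    edited <- mol_subset(edited, setdiff(seq_len(nrow(atoms)), drop_atoms))
  }

  ## hydrogens: atoms written without explicit H stay implicit and adapt to
  ## the edited bonding; recompute across the board
  edited$atoms$hcount <- NA_integer_
  edited <- mol_sanitize(assign_implicit_h(edited))
  mol_fragments(edited)
}
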