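## Molecular graph container used throughout the package.
##
## A `hymol` is a light-weight molecular graph: a data frame of heavy atoms
## (element, aromatic flag, formal charge, explicit/implicit hydrogen count)
## and a data frame of bonds (endpoints, integer order, aromatic flag).
## Hydrogens are implicit; stereochemistry is not represented (hydrolysis
## rules and product matching are stereo-agnostic).

ATOMIC_NUMBER <- c(
  H = 1L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L, Si = 14L, P = 15L,
  S = 16L, Cl = 17L, Br = 35L, I = 53L, Se = 34L
)

## Default valence sets for implicit-hydrogen completion (organic subset).
DEFAULT_VALENCES <- list(
  B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L),
  S = c(2L, 4L, 6L), F = 1L, Cl = 1L, Br = 1L, I = 1L, Si = 4L,
  Se = c(2L, 4L, 6L)
)

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

new_hymol <- function(atoms, bonds) {
  structure(list(atoms = atoms, bonds = bonds), class = "hymol")
}

n_atoms <- function(mol) nrow(mol$atoms)

#' @export
print.hymol <- function(x, ...) {
  cat(sprintf("<hymol: %d heavy atoms, %d bonds> %s\n",
              nrow(x$atoms), nrow(x$bonds), mol_to_smiles(x)))
  invisible(x)
}

## Adjacency list: for each atom, integer vector of (neighbor, bond row) pairs.
mol_adjacency <- function(mol) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  if (nrow(mol$bonds)) {
    for (b in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[b]; j <- mol$bonds$j[b]
      adj[[i]] <- rbind(adj[[i]], c(j, b))
      adj[[j]] <- rbind(adj[[j]], c(i, b))
    }
  }
  adj
}

mol_degree <- function(mol) {
  n <- n_atoms(mol)
  deg <- integer(n)
  if (nrow(mol$bonds)) {
    t1 <- tabulate(mol$bonds$i, n)
    t2 <- tabulate(mol$bonds$j, n)
    deg <- t1 + t2
  }
  deg
}

## Bond order sum per atom with the usual SMILES aromatic convention:
## aromatic bonds count 1 and an aromatic atom carries one extra unit for
## its share of the delocalised pi system.
bond_order_sum <- function(mol) {
  n <- n_atoms(mol)
  s <- numeric(n)
  if (nrow(mol$bonds)) {
    ord <- ifelse(mol$bonds$arom, 1, mol$bonds$order)
    for (b in seq_len(nrow(mol$bonds))) {
      s[mol$bonds$i[b]] <- s[mol$bonds$i[b]] + ord[b]
      s[mol$bonds$j[b]] <- s[mol$bonds$j[b]] + ord[b]
    }
  }
  s + ifelse(mol$atoms$aromatic, 1, 0)
}

## Fill the hcount column: explicit bracket H counts are kept; others get
## the smallest default valence that accommodates the bond order sum.
assign_implicit_h <- function(mol) {
  bos <- bond_order_sum(mol)
  h <- mol$atoms$hexp
  for (a in seq_len(n_atoms(mol))) {
    if (!is.na(h[a])) next
    el <- mol$atoms$element[a]
    vals <- DEFAULT_VALENCES[[el]]
    if (is.null(vals) || mol$atoms$charge[a] != 0L) { h[a] <- 0L; next }
    if (mol$atoms$aromatic[a]) {
      ## aromatic atoms use their lowest valence state only
      h[a] <- max(0L, as.integer(vals[1] - floor(bos[a])))
    } else {
      ok <- vals[vals >= bos[a]]
      h[a] <- if (length(ok)) as.integer(ok[1] - floor(bos[a])) else 0L
    }
  }
  mol$atoms$hcount <- as.integer(h)
  mol
}

## Basic valence sanity check; returns the molecule or stops.
mol_sanitize <- function(mol) {
  bos <- bond_order_sum(mol)
  for (a in seq_len(n_atoms(mol))) {
    el <- mol$atoms$element[a]
    vmax <- max(DEFAULT_VALENCES[[el]] %||% 8L)
    tot <- bos[a] + mol$atoms$hcount[a]
    if (tot > vmax + abs(mol$atoms$charge[a]) + 0.5) {
      stop(sprintf("valence overflow on atom %d (%s): %.1f", a, el, tot))
    }
  }
  mol
}

`%||%` <- function(a, b) if (is.null(a)) b else a

hydrosite_version <- function() {
  tryCatch(as.character(utils::packageVersion("hydrosite")),
           error = function(e) "dev")
}

## Smallest ring size containing each atom (0 if acyclic). Shortest cycle
## through atom a = min over incident edges (a,b) of 1 + shortest a->b path
## avoiding that edge; molecules here are small so plain BFS is fine.
smallest_ring_sizes <- function(mol) {
  n <- n_atoms(mol)
  out <- integer(n)
  if (!nrow(mol$bonds)) return(out)
  adj <- mol_adjacency(mol)
  for (a in seq_len(n)) {
    best <- Inf
    nb <- adj[[a]]
    if (is.null(nb)) next
    for (k in seq_len(nrow(nb))) {
      b <- nb[k, 1]; skip_bond <- nb[k, 2]
      dist <- rep(NA_integer_, n); dist[a] <- 0L
      queue <- a
      while (length(queue)) {
        cur <- queue[1]; queue <- queue[-1]
        cn <- adj[[cur]]
        if (is.null(cn)) next
        for (m in seq_len(nrow(cn))) {
          if (cn[m, 2] == skip_bond) next
          nxt <- cn[m, 1]
          if (is.na(dist[nxt])) {
            dist[nxt] <- dist[cur] + 1L
            queue <- c(queue, nxt)
          }
        }
      }
      if (!is.na(dist[b])) best <- min(best, dist[b] + 1L)
    }
    out[a] <- if (is.finite(best)) as.integer(best) else 0L
  }
  out
}

## Connected components as a membership vector.
mol_components <- function(mol) {
  n <- n_atoms(mol)
  comp <- integer(n)
  adj <- mol_adjacency(mol)
  cid <- 0L
  for (a in seq_len(n)) {
    if (comp[a] != 0L) next
    cid <- cid + 1L
    queue <- a; comp[a] <- cid
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      nb <- adj[[cur]]
      if (is.null(nb)) next
      for (k in seq_len(nrow(nb))) {
        nxt <- nb[k, 1]
        if (comp[nxt] == 0L) { comp[nxt] <- cid; queue <- c(queue, nxt) }
      }
    }
  }
  comp
}

## Extract one fragment (induced subgraph) as a standalone hymol.
mol_subset <- function(mol, atom_idx) {
  atom_idx <- sort(atom_idx)
  remap <- match(seq_len(n_atoms(mol)), atom_idx)
  atoms <- mol$atoms[atom_idx, , drop = FALSE]
  rownames(atoms) <- NULL
  keep <- mol$bonds$i %in% atom_idx & mol$bonds$j %in% atom_idx
  bonds <- mol$bonds[keep, , drop = FALSE]
  if (nrow(bonds)) {
    bonds$i <- remap[bonds$i]
    bonds$j <- remap[bonds$j]
  }
  rownames(bonds) <- NULL
  new_hymol(atoms, bonds)
}

## Split a (possibly multi-fragment) molecule into its components.
mol_fragments <- function(mol) {
  comp <- mol_components(mol)
  lapply(seq_len(max(comp)), function(cc) mol_subset(mol, which(comp == cc)))
}

empty_atoms_df <- function() {
  data.frame(element = character(), aromatic = logical(), charge = integer(),
             hexp = integer(), hcount = integer(), stringsAsFactors = FALSE)
}

empty_bonds_df <- function() {
  data.frame(i = integer(), j = integer(), order = integer(),
             arom = logical(), stringsAsFactors = FALSE)
}
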