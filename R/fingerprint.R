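## Circular atomic-environment fingerprints (Morgan-style, ECFP-like).
##
## Each heavy atom receives an integer identifier from its local invariants;
## identifiers are then iteratively re-hashed together with the sorted
## (bond-type, neighbour-identifier) multiset up to the requested radius.
## The environment identifiers rooted at one atom (radii 0..r) are folded
## into an n_bits binary vector. The hashing dialect is the package's own
## (polynomial string hash, versioned below); bit positions are therefore
## not portable to other toolkits, which is recorded in model metadata.

FP_DIALECT <- "hydrosite-fp-1"

## Deterministic string hash onto [0, 2^31-2].
hy_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261 %% 2147483647
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  h
}

## Environment identifier codes for every atom at radii 0..radius.
## Returns a matrix [n_atoms x (radius+1)].
atom_environment_codes <- function(mol, radius = 3L) {
  n <- n_atoms(mol)
  deg <- mol_degree(mol)
  ring <- smallest_ring_sizes(mol)
  codes <- matrix(0, n, radius + 1L)
  init <- sprintf("%d|%d|%d|%d|%d|%d",
                  ATOMIC_NUMBER[mol$atoms$element], mol$atoms$charge,
                  mol$atoms$hcount, deg, as.integer(mol$atoms$aromatic),
                  as.integer(ring > 0L))
  codes[, 1L] <- vapply(init, hy_hash, numeric(1), USE.NAMES = FALSE)
  if (radius == 0L) return(codes)
  adj <- mol_adjacency(mol)
  for (r in seq_len(radius)) {
    for (a in seq_len(n)) {
      nb <- adj[[a]]
      nbk <- if (is.null(nb)) character() else {
        vapply(seq_len(nrow(nb)), function(k) {
          b <- mol$bonds[nb[k, 2], ]
          bt <- if (b$arom) 4L else b$order
          sprintf("%d:%.0f", bt, codes[nb[k, 1], r])
        }, character(1))
      }
      codes[a, r + 1L] <- hy_hash(paste0(
        r, "|", sprintf("%.0f", codes[a, r]), "|",
        paste(sort(nbk), collapse = ",")))
    }
  }
  codes
}

#' Atomic-environment fingerprint of one atom
#'
#' Binary vector whose set bits correspond to the circular environments
#' rooted at the given atom up to `radius` bonds (the radius-0 environment
#' always sets a bit, so the popcount is at least 1).
#'
#' @param molecule a `hymol` or SMILES string.
#' @param atom_index 0-based heavy-atom index (canonical order when a SMILES
#'   string is given).
#' @param radius maximum environment radius in bonds (default 3).
#' @param n_bits fingerprint length (default 1024).
#' @return integer vector of 0/1 of length `n_bits`.
#' @export
atom_environment_fingerprint <- function(molecule, atom_index, radius = 3L,
                                         n_bits = 1024L) {
  mol <- if (is.character(molecule)) mol_canonicalize(molecule) else molecule
  if (atom_index < 0L || atom_index >= n_atoms(mol)) {
    stop(sprintf("atom_index %d out of range [0, %d)", atom_index, n_atoms(mol)))
  }
  codes <- atom_environment_codes(mol, radius)
  fp <- integer(n_bits)
  fp[(codes[atom_index + 1L, ] %% n_bits) + 1L] <- 1L
  fp
}

## Fingerprint matrix for all atoms of a molecule (rows = atoms).
fingerprint_matrix <- function(mol, radius = 3L, n_bits = 1024L) {
  codes <- atom_environment_codes(mol, radius)
  fp <- matrix(0L, n_atoms(mol), n_bits)
  for (a in seq_len(n_atoms(mol))) fp[a, (codes[a, ] %% n_bits) + 1L] <- 1L
  colnames(fp) <- sprintf("fp_%04d", seq_len(n_bits) - 1L)
  fp
}
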