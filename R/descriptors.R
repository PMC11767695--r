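## Interpretable atomic descriptors.
##
## Eight per-atom descriptors complement the environment fingerprint:
## partial charge and sigma electronegativity from the iterative partial
## equalisation of orbital electronegativity (PEOE, Gasteiger-Marsili),
## a tabulated element polarizability, and five topological terms. The set
## is versioned (DESC_VERSION); swap `atom_descriptors` to change it.

DESC_VERSION <- "hydrosite-desc-1"

DESCRIPTOR_NAMES <- c("d_charge", "d_sigma_en", "d_polar", "d_degree",
                      "d_hcount", "d_aromatic", "d_ringsize", "d_pibonds")

## PEOE parameters (a, b, c) by element/hybridisation state.
PEOE_PARAMS <- list(
  "H"     = c(7.17, 6.24, -0.56),
  "C.sp3" = c(7.98, 9.18, 1.88),
  "C.sp2" = c(8.79, 9.32, 1.51),
  "C.sp"  = c(10.39, 9.45, 0.73),
  "N.sp3" = c(11.54, 10.82, 1.36),
  "N.sp2" = c(12.87, 11.15, 0.85),
  "N.sp"  = c(15.68, 11.70, -0.27),
  "O.sp3" = c(14.18, 12.92, 1.39),
  "O.sp2" = c(17.07, 13.79, 0.47),
  "F"     = c(14.66, 13.85, 2.31),
  "Cl"    = c(11.00, 9.69, 1.35),
  "Br"    = c(10.08, 8.47, 1.16),
  "I"     = c(9.90, 7.96, 0.96),
  "S"     = c(10.14, 9.13, 1.38),
  "P"     = c(8.90, 8.24, 0.96),
  "B"     = c(7.98, 9.18, 1.88),   # borderline cases borrow C sp3
  "Si"    = c(7.98, 9.18, 1.88),
  "Se"    = c(10.14, 9.13, 1.38)
)

## Static element polarizabilities (angstrom^3).
ELEMENT_POLARIZABILITY <- c(
  H = 0.667, B = 3.03, C = 1.76, N = 1.10, O = 0.802, F = 0.557,
  Si = 5.38, P = 3.63, S = 2.90, Cl = 2.18, Br = 3.05, I = 5.35, Se = 3.77
)

## Hybridisation proxy per heavy atom: "sp", "sp2" or "sp3".
atom_hybridization <- function(mol) {
  n <- n_atoms(mol)
  ndouble <- integer(n); ntriple <- integer(n)
  if (nrow(mol$bonds)) {
    for (b in seq_len(nrow(mol$bonds))) {
      if (mol$bonds$arom[b]) next
      if (mol$bonds$order[b] == 2L) {
        ndouble[mol$bonds$i[b]] <- ndouble[mol$bonds$i[b]] + 1L
        ndouble[mol$bonds$j[b]] <- ndouble[mol$bonds$j[b]] + 1L
      } else if (mol$bonds$order[b] == 3L) {
        ntriple[mol$bonds$i[b]] <- ntriple[mol$bonds$i[b]] + 1L
        ntriple[mol$bonds$j[b]] <- ntriple[mol$bonds$j[b]] + 1L
      }
    }
  }
  hyb <- rep("sp3", n)
  hyb[ndouble >= 1L | mol$atoms$aromatic] <- "sp2"
  hyb[ntriple >= 1L | ndouble >= 2L] <- "sp"
  attr(hyb, "pibonds") <- ndouble + 2L * ntriple + as.integer(mol$atoms$aromatic)
  hyb
}

peoe_key <- function(element, hyb) {
  ifelse(element %in% c("C", "N", "O"), paste(element, hyb, sep = "."), element)
}

#' PEOE (Gasteiger-Marsili) partial charges
#'
#' Iterative partial equalisation of orbital electronegativity over the
#' sigma framework, with implicit hydrogens expanded as pseudo-atoms and the
#' usual 0.5^k damping. Also returns each heavy atom's electronegativity at
#' convergence (`a + b q + c q^2`).
#'
#' @param molecule a `hymol` or SMILES string.
#' @param n_iter damping iterations (default 8; contributions decay as 2^-k).
#' @return list with numeric vectors `charge` and `electronegativity` over
#'   heavy atoms.
#' @export
gasteiger_charges <- function(molecule, n_iter = 8L) {
  mol <- if (is.character(molecule)) mol_canonicalize(molecule) else molecule
  n <- n_atoms(mol)
  hyb <- atom_hybridization(mol)
  key <- peoe_key(mol$atoms$element, hyb)
  bad <- is.na(match(key, names(PEOE_PARAMS)))
  if (any(bad)) {
    stop(sprintf("no PEOE parameters for atom type(s): %s",
                 paste(unique(key[bad]), collapse = ", ")))
  }
  ## extended atom list: heavy atoms then one pseudo-atom per implicit H
  keys <- key
  edges <- if (nrow(mol$bonds)) cbind(mol$bonds$i, mol$bonds$j) else
    matrix(integer(), 0, 2)
  hpar <- which(mol$atoms$hcount > 0L)
  for (a in hpar) {
    for (h in seq_len(mol$atoms$hcount[a])) {
      keys <- c(keys, "H")
      edges <- rbind(edges, c(a, length(keys)))
    }
  }
  par <- do.call(rbind, PEOE_PARAMS[keys])
  q <- c(as.numeric(mol$atoms$charge), rep(0, length(keys) - n))
  chiplus <- par[, 1] + par[, 2] + par[, 3]
  chiplus[keys == "H"] <- 20.02
  chi <- numeric(length(keys))
  for (k in seq_len(n_iter)) {
    chi <- par[, 1] + par[, 2] * q + par[, 3] * q^2
    damp <- 0.5^k
    if (nrow(edges)) {
      dq <- numeric(length(keys))
      for (e in seq_len(nrow(edges))) {
        i <- edges[e, 1]; j <- edges[e, 2]
        if (chi[i] == chi[j]) next
        lo <- if (chi[i] < chi[j]) i else j   # electron donor
        hi <- if (chi[i] < chi[j]) j else i
        t <- (chi[hi] - chi[lo]) / chiplus[lo] * damp
        dq[lo] <- dq[lo] + t
        dq[hi] <- dq[hi] - t
      }
      q <- q + dq
    }
    if (any(!is.finite(q))) stop("PEOE charge iteration diverged")
  }
  chi <- par[, 1] + par[, 2] * q + par[, 3] * q^2
  list(charge = q[seq_len(n)], electronegativity = chi[seq_len(n)])
}

## Descriptor matrix for all heavy atoms (rows = atoms, 8 columns).
descriptor_matrix <- function(mol) {
  peoe <- gasteiger_charges(mol)
  hyb <- atom_hybridization(mol)
  d <- cbind(
    d_charge = peoe$charge,
    d_sigma_en = peoe$electronegativity,
    d_polar = as.numeric(ELEMENT_POLARIZABILITY[mol$atoms$element]),
    d_degree = as.numeric(mol_degree(mol)),
    d_hcount = as.numeric(mol$atoms$hcount),
    d_aromatic = as.numeric(mol$atoms$aromatic),
    d_ringsize = as.numeric(smallest_ring_sizes(mol)),
    d_pibonds = as.numeric(attr(hyb, "pibonds"))
  )
  if (any(!is.finite(d))) stop("non-finite atomic descriptor")
  d
}

#' Interpretable atomic descriptors for one atom
#'
#' The 8-vector: PEOE partial charge, sigma electronegativity at
#' convergence (eV-scale), element polarizability (angstrom^3), heavy-atom
#' degree, attached-hydrogen count, aromaticity indicator, smallest ring
#' size (0 if acyclic) and pi-bond count.
#'
#' @param molecule a `hymol` or SMILES string.
#' @param atom_index 0-based heavy-atom index.
#' @return named numeric vector of length 8.
#' @export
atom_descriptors <- function(molecule, atom_index) {
  mol <- if (is.character(molecule)) mol_canonicalize(molecule) else molecule
  if (atom_index < 0L || atom_index >= n_atoms(mol)) {
    stop(sprintf("atom_index %d out of range [0, %d)", atom_index, n_atoms(mol)))
  }
  descriptor_matrix(mol)[atom_index + 1L, ]
}
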