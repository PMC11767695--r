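## Atomic-environment fingerprints and interpretable descriptors.

test_that("fingerprints reflect local environments and symmetry", {
  ## radius-0 environment always sets a bit
  fp <- atom_environment_fingerprint("CCO", 0L)
  expect_gte(sum(fp), 1L)
  expect_true(all(fp %in% c(0L, 1L)))
  expect_length(fp, 1024L)
  ## the two methyl carbons of propane are equivalent
  prop <- mol_canonicalize("CCC")
  methyls <- which(prop$atoms$element == "C" &
                     hydrosite:::mol_degree(prop) == 1L) - 1L
  expect_identical(atom_environment_fingerprint(prop, methyls[1]),
                   atom_environment_fingerprint(prop, methyls[2]))
  ## amide N and amine N have different radius-1 environments
  nma <- mol_canonicalize("CC(=O)NC")
  ma <- mol_canonicalize("CN")
  n1 <- which(nma$atoms$element == "N") - 1L
  n2 <- which(ma$atoms$element == "N") - 1L
  expect_false(identical(atom_environment_fingerprint(nma, n1),
                         atom_environment_fingerprint(ma, n2)))
})

test_that("environment bits grow monotonically with radius", {
  ## collision-free toy molecules: radius-2 bits subset of radius-3 bits
  for (s in c("CCCCO", "CC(=O)NCCC", "c1ccccc1CCl")) {
    mol <- mol_canonicalize(s)
    for (a in seq_len(nrow(mol$atoms)) - 1L) {
      f2 <- atom_environment_fingerprint(mol, a, radius = 2L)
      f3 <- atom_environment_fingerprint(mol, a, radius = 3L)
      expect_true(all(which(f2 == 1L) %in% which(f3 == 1L)),
                  label = sprintf("%s atom %d", s, a))
    }
  }
})

test_that("descriptors are counted and ordered as documented", {
  ## central carbon of neopentane: degree 4, no H
  neo <- mol_canonicalize("CC(C)(C)C")
  center <- which(hydrosite:::mol_degree(neo) == 4L) - 1L
  d <- atom_descriptors(neo, center)
  expect_named(d, c("d_charge", "d_sigma_en", "d_polar", "d_degree",
                    "d_hcount", "d_aromatic", "d_ringsize", "d_pibonds"))
  expect_identical(unname(d["d_degree"]), 4)
  expect_identical(unname(d["d_hcount"]), 0)
  ## methane C carries 4 hydrogens
  expect_identical(unname(atom_descriptors("C", 0L)["d_hcount"]), 4)
  ## benzene: aromatic flag and ring size 6
  benz <- atom_descriptors("c1ccccc1", 0L)
  expect_identical(unname(benz["d_aromatic"]), 1)
  expect_identical(unname(benz["d_ringsize"]), 6)
})

test_that("electron withdrawal orders the PEOE partial charges", {
  ## carbonyl C of acetic acid more positive than its methyl C
  aa <- mol_canonicalize("CC(=O)O")
  q <- gasteiger_charges(aa)$charge
  carbons <- which(aa$atoms$element == "C")
  carbonyl <- carbons[which.max(vapply(carbons, function(a) {
    sum(aa$bonds$order[aa$bonds$i == a | aa$bonds$j == a])
  }, numeric(1)))]
  methyl <- setdiff(carbons, carbonyl)
  expect_gt(q[carbonyl], q[methyl])
  ## oxygens carry negative charge
  expect_true(all(q[aa$atoms$element == "O"] < 0))
  ## heavy-atom charge sum stays near neutral (H atoms carry the rest)
  expect_lt(abs(sum(q)), 0.5)
})

test_that("featurize gives one 1032-long row per atom of the class", {
  f <- featurize("c1ccccc1", classes = "C")
  expect_identical(nrow(f$X), 6L)
  expect_identical(ncol(f$X), 1032L)
  ## all six benzene carbons identical
  expect_identical(max(apply(f$X, 2, function(col) diff(range(col)))), 0)
  ## cyanophos O rows
  fo <- featurize(SMI_CYANOPHOS, classes = "O")
  expect_identical(nrow(fo$X), 3L)
  ## permutation invariance: differently written inputs give the same
  ## multiset of feature rows
  a <- featurize("CC(=O)Nc1ccccc1")
  b <- featurize("O=C(C)Nc1ccccc1")
  key <- function(f) sort(apply(f$X, 1, function(r) paste(r, collapse = ",")))
  expect_identical(key(a), key(b))
  ## canonical round-trip leaves rows unchanged
  c1 <- featurize(canonical_smiles("CC(=O)Nc1ccccc1"))
  expect_identical(a$X, c1$X)
})
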