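## SMILES parsing and canonicalisation.

test_that("canonical SMILES round-trips byte-identically", {
  smis <- c("CC(=O)Nc1ccccc1", "c1ccccc1", "C1CCCCC1", "CC(C)(C)C",
            SMI_DESMEDIPHAM, SMI_CYANOPHOS, SMI_FLAMPROP_METHYL,
            "[O-][N+](=O)c1ccccc1", "c1ccc2ccccc2c1", "O=C=O", "CC#N",
            "CC(C)=NO", "COP(=O)(OC)Oc1ccccc1", "OCC1CCCCC1O")
  for (s in smis) {
    c1 <- canonical_smiles(s)
    expect_identical(canonical_smiles(c1), c1, label = s)
  }
})

test_that("canonicalisation is invariant to the input atom ordering", {
  ## alternative hand-written spellings of identical structures
  variants <- list(
    c("CC(=O)Nc1ccccc1", "O=C(C)Nc1ccccc1", "c1ccccc1NC(C)=O",
      "N(c1ccccc1)C(=O)C"),
    c("CCOC(=O)C", "CC(=O)OCC", "O=C(C)OCC"),
    c("c1ccc(Cl)cc1", "Clc1ccccc1"),
    c("COP(=S)(OC)Oc1ccc(C#N)cc1", "N#Cc1ccc(OP(=S)(OC)OC)cc1"),
    c("[O-][N+](=O)c1ccccc1", "c1ccccc1[N+](=O)[O-]"))
  for (v in variants) {
    cans <- vapply(v, canonical_smiles, character(1))
    expect_length(unique(cans), 1L)
  }
})

test_that("canonical equality agrees with VF2 graph isomorphism", {
  pairs <- list(
    c("CC(=O)OC", "COC(C)=O", TRUE),
    c("CC(=O)OC", "CCC(=O)O", FALSE),      # isomers, different graphs
    c("c1ccccc1", "C1CCCCC1", FALSE),
    c("CNC(=O)NC", "CN(C)C(N)=O", FALSE),
    c("Oc1ccccc1O", "Oc1ccccc1", FALSE))
  for (p in pairs) {
    same_canon <- canonical_smiles(p[1]) == canonical_smiles(p[2])
    expect_identical(same_canon, as.logical(p[3]), label = paste(p[1], p[2]))
    expect_identical(mols_isomorphic(p[1], p[2]), as.logical(p[3]),
                     label = paste("vf2", p[1], p[2]))
  }
})

test_that("canonical SMILES agree with OpenBabel on equality classes", {
  ## obabel as an independent canonicaliser: two spellings map to the same
  ## canonical form in both toolkits
  spellings <- c("CC(=O)Nc1ccccc1", "O=C(C)Nc1ccccc1",
                 "CCOC(=O)C", "CC(=O)OCC")
  ours <- vapply(spellings, canonical_smiles, character(1),
                 USE.NAMES = FALSE)
  tmp <- tempfile(fileext = ".smi")
  writeLines(spellings, tmp)
  theirs <- system2("obabel", c(tmp, "-ocan"), stdout = TRUE, stderr = FALSE)
  theirs <- vapply(strsplit(trimws(theirs), "\t"), `[`, "", 1L)
  expect_identical(ours[1] == ours[2], theirs[1] == theirs[2])
  expect_identical(ours[3] == ours[4], theirs[3] == theirs[4])
  expect_true(all(ours[1] == ours[2], theirs[1] == theirs[2]))
})

test_that("invalid SMILES are rejected with informative errors", {
  expect_error(parse_smiles("C1CC"), "ring")
  expect_error(parse_smiles("C(C"), "branch")
  expect_error(parse_smiles(""), "non-empty")
  expect_error(parse_smiles("C$C"), "unexpected")
  expect_error(parse_smiles("[Xx]"), "element|parse")
})

test_that("implicit hydrogen counts follow standard valence rules", {
  m <- parse_smiles("CC(=O)N")
  expect_identical(m$atoms$hcount, c(3L, 0L, 0L, 2L))
  m2 <- parse_smiles("c1ccncc1")
  expect_identical(sum(m2$atoms$hcount), 5L)
  m3 <- parse_smiles("OP(=O)(O)O")
  expect_identical(m3$atoms$hcount[m3$atoms$element == "P"], 0L)
})
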