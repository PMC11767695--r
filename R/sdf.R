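## Minimal V2000 SDF input/output.
##
## Reading: atom/bond blocks plus named data fields; bond type 4 or
## alternating Kekule rings are perceived as aromatic (Hueckel-lite, 5/6
## rings of C/N/O/S). Writing: aromatic systems are kekulized back to
## alternating bonds. Coordinates are zeroed (2D/3D information is neither
## used nor preserved).

read_sdf_entries <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ends <- which(trimws(lines) == "$$$$")
  if (!length(ends)) stop("no $$$$-terminated entries in SDF")
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_along(ends), function(k) lines[starts[k]:(ends[k] - 1L)])
}

sdf_entry_to_mol <- function(entry) {
  counts <- entry[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || is.na(nb)) stop("bad SDF counts line")
  atoms <- empty_atoms_df()
  for (k in seq_len(na)) {
    ln <- entry[4 + k]
    el <- trimws(substr(ln, 32, 34))
    chgcode <- suppressWarnings(as.integer(substr(ln, 37, 39)))
    chg <- switch(as.character(chgcode %||% 0L),
                  "1" = 3L, "2" = 2L, "3" = 1L, "5" = -1L, "6" = -2L,
                  "7" = -3L, 0L)
    atoms <- rbind(atoms, data.frame(element = el, aromatic = FALSE,
                                     charge = as.integer(chg),
                                     hexp = NA_integer_, hcount = NA_integer_,
                                     stringsAsFactors = FALSE))
  }
  bonds <- empty_bonds_df()
  for (k in seq_len(nb)) {
    ln <- entry[4 + na + k]
    i <- as.integer(substr(ln, 1, 3)); j <- as.integer(substr(ln, 4, 6))
    ty <- as.integer(substr(ln, 7, 9))
    bonds <- rbind(bonds, data.frame(
      i = i, j = j,
      order = if (ty %in% 1:3) ty else 1L,
      arom = ty == 4L, stringsAsFactors = FALSE))
  }
  ## M  CHG overrides
  for (ln in grep("^M  CHG", entry, value = TRUE)) {
    toks <- strsplit(trimws(sub("^M  CHG *[0-9]+", "", ln)), " +")[[1]]
    toks <- as.integer(toks)
    for (p in seq(1, length(toks), by = 2)) {
      atoms$charge[toks[p]] <- toks[p + 1]
    }
  }
  mol <- new_hymol(atoms, bonds)
  mol <- perceive_aromaticity(mol)
  mol_sanitize(assign_implicit_h(mol))
}

sdf_entry_fields <- function(entry) {
  idx <- grep("^> *<", entry)
  out <- list()
  for (i in idx) {
    nm <- sub("^> *<([^>]+)>.*$", "\\1", entry[i])
    val <- character()
    j <- i + 1L
    while (j <= length(entry) && nzchar(trimws(entry[j]))) {
      val <- c(val, entry[j]); j <- j + 1L
    }
    out[[nm]] <- paste(val, collapse = "\n")
  }
  out
}

read_reaction_sdf <- function(path) {
  entries <- read_sdf_entries(path)
  rows <- lapply(seq_along(entries), function(k) {
    e <- entries[[k]]
    fields <- sdf_entry_fields(e)
    smi <- tryCatch(canonical_smiles(sdf_entry_to_mol(e)),
                    error = function(err) NA_character_)
    data.frame(
      record_id = if (nzchar(trimws(e[1]))) trimws(e[1]) else sprintf("sdf%04d", k),
      parent_smiles = smi %||% NA_character_,
      products_smiles = fields$PRODUCTS %||% NA_character_,
      environment = fields$ENVIRONMENT %||% "unspecified",
      source = fields$SOURCE %||% "",
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## Hueckel-lite perception for kekulized input: 5/6-membered rings of
## C/N/O/S whose pi-electron count is 6 (ring double bonds contribute 2,
## saturated N/O/S lone pairs contribute 2) become aromatic.
perceive_aromaticity <- function(mol) {
  rings <- find_small_rings(mol, max_size = 6L)
  repeat {
    changed <- FALSE
    for (ring in rings) {
      ratoms <- ring$atoms; rbonds <- ring$bonds
      if (any(mol$atoms$aromatic[ratoms])) next
      if (!all(mol$atoms$element[ratoms] %in% c("C", "N", "O", "S"))) next
      dbl <- mol$bonds$order[rbonds] == 2L
      ## atoms already double-bonded within the ring
      in_dbl <- unique(c(mol$bonds$i[rbonds][dbl], mol$bonds$j[rbonds][dbl]))
      pi_e <- 2L * sum(dbl)
      lone <- setdiff(ratoms, in_dbl)
      ok_lone <- TRUE
      for (a in lone) {
        if (mol$atoms$element[a] %in% c("N", "O", "S")) pi_e <- pi_e + 2L
        else ok_lone <- FALSE   # sp3 ring carbon: not aromatic
      }
      if (ok_lone && pi_e == 6L) {
        mol$atoms$aromatic[ratoms] <- TRUE
        mol$bonds$arom[rbonds] <- TRUE
        mol$bonds$order[rbonds] <- 1L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  mol
}

## Small rings (<= max_size) as lists of atom and bond indices.
find_small_rings <- function(mol, max_size = 6L) {
  rings <- list(); seen <- character()
  adj <- mol_adjacency(mol)
  n <- n_atoms(mol)
  for (b in seq_len(nrow(mol$bonds))) {
    src <- mol$bonds$i[b]; dst <- mol$bonds$j[b]
    ## shortest path src->dst avoiding bond b (BFS with parents)
    parent <- rep(NA_integer_, n); parent_bond <- rep(NA_integer_, n)
    dist <- rep(NA_integer_, n); dist[src] <- 0L
    queue <- src
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      nb <- adj[[cur]]
      if (is.null(nb)) next
      for (k in seq_len(nrow(nb))) {
        if (nb[k, 2] == b) next
        nxt <- nb[k, 1]
        if (is.na(dist[nxt])) {
          dist[nxt] <- dist[cur] + 1L
          parent[nxt] <- cur; parent_bond[nxt] <- nb[k, 2]
          queue <- c(queue, nxt)
        }
      }
    }
    if (is.na(dist[dst]) || dist[dst] + 1L > max_size) next
    atoms <- dst; bonds <- b
    cur <- dst
    while (cur != src) {
      bonds <- c(bonds, parent_bond[cur])
      cur <- parent[cur]
      atoms <- c(atoms, cur)
    }
    key <- paste(sort(atoms), collapse = "-")
    if (key %in% seen) next
    seen <- c(seen, key)
    rings[[length(rings) + 1L]] <- list(atoms = atoms, bonds = bonds)
  }
  rings
}

## Assign alternating double bonds to aromatic systems (backtracking
## perfect matching over atoms that must carry one pi bond).
kekulize <- function(mol) {
  arom_bonds <- which(mol$bonds$arom)
  if (!length(arom_bonds)) return(mol)
  needs_pi <- function(a) {
    at <- mol$atoms[a, ]
    if (!at$aromatic) return(FALSE)
    if (at$element == "C") return(TRUE)
    if (at$element == "N") {
      deg <- sum(mol$bonds$i == a | mol$bonds$j == a)
      return(deg + at$hcount < 3L && at$charge == 0L)
    }
    FALSE   # aromatic O/S/pyrrole-type N contribute lone pairs
  }
  need <- which(vapply(seq_len(n_atoms(mol)), needs_pi, logical(1)))
  assign_dbl <- logical(length(arom_bonds))
  matched <- logical(n_atoms(mol))
  bt <- function(k) {
    if (k > length(need)) return(TRUE)
    a <- need[k]
    if (matched[a]) return(bt(k + 1L))
    for (bi in seq_along(arom_bonds)) {
      bb <- mol$bonds[arom_bonds[bi], ]
      other <- if (bb$i == a) bb$j else if (bb$j == a) bb$i else next
      if (matched[other] || !other %in% need) next
      if (assign_dbl[bi]) next
      assign_dbl[bi] <<- TRUE; matched[a] <<- TRUE; matched[other] <<- TRUE
      if (bt(k + 1L)) return(TRUE)
      assign_dbl[bi] <<- FALSE; matched[a] <<- FALSE; matched[other] <<- FALSE
    }
    FALSE
  }
  if (!bt(1L)) stop("kekulization failed")
  mol$bonds$order[arom_bonds] <- ifelse(assign_dbl, 2L, 1L)
  mol$bonds$arom[arom_bonds] <- FALSE
  mol$atoms$hexp <- mol$atoms$hcount    # freeze H counts before deflagging
  mol$atoms$aromatic <- FALSE
  mol
}

## Write molecules (named list/vector of SMILES or hymol) to a V2000 SDF.
write_sdf <- function(mols, path, fields = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  nms <- names(mols) %||% sprintf("mol%04d", seq_along(mols))
  for (k in seq_along(mols)) {
    m <- mols[[k]]
    if (is.character(m)) m <- parse_smiles(m)
    m <- kekulize(m)
    na <- n_atoms(m); nb <- nrow(m$bonds)
    writeLines(c(nms[k], "  hydrosite", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb), con)
    for (a in seq_len(na)) {
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         0, 0, 0, m$atoms$element[a]), con)
    }
    for (b in seq_len(nb)) {
      writeLines(sprintf("%3d%3d%3d  0", m$bonds$i[b], m$bonds$j[b],
                         m$bonds$order[b]), con)
    }
    chg <- which(m$atoms$charge != 0L)
    for (a in chg) {
      writeLines(sprintf("M  CHG  1 %3d %3d", a, m$atoms$charge[a]), con)
    }
    writeLines("M  END", con)
    if (!is.null(fields)) {
      for (fn in names(fields)) {
        writeLines(c(sprintf("> <%s>", fn), fields[[fn]][k], ""), con)
      }
    }
    writeLines("$$$$", con)
  }
  invisible(path)
}
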