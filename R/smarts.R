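## Restricted SMARTS patterns.
##
## Supports what the shipped hydrolysis rule base needs: element primitives
## (`#6`, aliphatic upper-case, aromatic lower-case, `*`), comma-OR between
## element primitives, total-connection (`X`) and hydrogen (`H`) counts,
## formal charge, atom maps, branches and the bond primitives - = # : ~
## (default bond = single-or-aromatic). Recursive SMARTS and logical
## operators beyond the element-level comma are deliberately out of scope.

parse_smarts <- function(smarts) {
  chars <- strsplit(smarts, "")[[1]]
  n <- length(chars)
  atoms <- list()
  bi <- integer(); bj <- integer(); btype <- character()
  prev <- NA_integer_; stack <- integer(); pending <- ""
  ring <- list()

  add_atom <- function(spec) {
    atoms[[length(atoms) + 1L]] <<- spec
    length(atoms)
  }
  add_bond <- function(a, b, type) {
    if (type == "") type <- "default"
    bi[length(bi) + 1L] <<- a
    bj[length(bj) + 1L] <<- b
    btype[length(btype) + 1L] <<- type
  }
  connect <- function(a) {
    if (!is.na(prev)) add_bond(prev, a, pending)
    pending <<- ""
    prev <<- a
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == " ") { i <- i + 1L; next }
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unterminated bracket in SMARTS")
      tok <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      connect(add_atom(parse_smarts_atom(tok)))
      i <- j + 1L
    } else if (ch %in% c("C", "N", "O", "P", "S", "F", "B", "I")) {
      el <- ch
      if (ch == "C" && i < n && chars[i + 1L] == "l") { el <- "Cl"; i <- i + 1L }
      if (ch == "B" && i < n && chars[i + 1L] == "r") { el <- "Br"; i <- i + 1L }
      connect(add_atom(smarts_atom_spec(el, FALSE)))
      i <- i + 1L
    } else if (ch %in% c("c", "n", "o", "p", "s")) {
      connect(add_atom(smarts_atom_spec(toupper(ch), TRUE)))
      i <- i + 1L
    } else if (ch == "*") {
      connect(add_atom(smarts_atom_spec(NULL, NA)))
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "~")) {
      pending <- ch
      i <- i + 1L
    } else if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      key <- ch
      if (is.null(ring[[key]])) ring[[key]] <- list(atom = prev, type = pending)
      else {
        add_bond(ring[[key]]$atom, prev,
                 if (nzchar(pending)) pending else ring[[key]]$type)
        ring[[key]] <- NULL
      }
      pending <- ""
      i <- i + 1L
    } else {
      stop(sprintf("unexpected character '%s' in SMARTS '%s'", ch, smarts))
    }
  }
  if (!length(atoms)) stop("empty SMARTS pattern")
  list(atoms = atoms,
       bonds = data.frame(i = bi, j = bj, type = btype,
                          stringsAsFactors = FALSE))
}

smarts_atom_spec <- function(elem, arom, charge = NA_integer_,
                             H = NA_integer_, X = NA_integer_,
                             map = NA_integer_) {
  allowed <- if (is.null(elem)) NULL else
    data.frame(element = elem, aromatic = arom, stringsAsFactors = FALSE)
  list(allowed = allowed, charge = charge, H = H, X = X, map = map)
}

## Bracket SMARTS atom, e.g. "#6:1", "CX4:1", "OX2H1", "Cl,Br,I:2", "N+".
parse_smarts_atom <- function(tok) {
  map <- NA_integer_
  mm <- regmatches(tok, regexpr(":[0-9]+$", tok))
  if (length(mm)) {
    map <- as.integer(substring(mm, 2L))
    tok <- sub(":[0-9]+$", "", tok)
  }
  H <- NA_integer_; X <- NA_integer_; charge <- NA_integer_
  parts <- strsplit(tok, ",", fixed = TRUE)[[1]]
  rows <- list()
  for (part in parts) {
    rest <- part
    xm <- regmatches(rest, regexpr("X[0-9]+", rest))
    if (length(xm)) { X <- as.integer(substring(xm, 2L)); rest <- sub("X[0-9]+", "", rest) }
    hm <- regmatches(rest, regexpr("H[0-9]*", rest))
    ## bare H after an element spec means H1 (hydrogen count primitive)
    if (length(hm) && !rest %in% c("H")) {
      H <- if (nchar(hm) == 1L) 1L else as.integer(substring(hm, 2L))
      rest <- sub("H[0-9]*", "", rest)
    }
    cm <- regmatches(rest, regexpr("[+-][0-9]*$", rest))
    if (length(cm) && nzchar(cm)) {
      sgn <- if (substring(cm, 1L, 1L) == "+") 1L else -1L
      num <- substring(cm, 2L)
      charge <- sgn * if (nzchar(num)) as.integer(num) else 1L
      rest <- sub("[+-][0-9]*$", "", rest)
    }
    if (rest == "*" || rest == "") {
      rows <- NULL
      next
    }
    if (grepl("^#[0-9]+$", rest)) {
      z <- as.integer(substring(rest, 2L))
      el <- names(ATOMIC_NUMBER)[match(z, ATOMIC_NUMBER)]
      if (is.na(el)) stop(sprintf("unknown atomic number %d in SMARTS", z))
      rows[[length(rows) + 1L]] <- data.frame(element = el, aromatic = NA,
                                              stringsAsFactors = FALSE)
    } else if (rest %in% c("c", "n", "o", "p", "s")) {
      rows[[length(rows) + 1L]] <- data.frame(element = toupper(rest),
                                              aromatic = TRUE,
                                              stringsAsFactors = FALSE)
    } else if (rest %in% names(ATOMIC_NUMBER)) {
      rows[[length(rows) + 1L]] <- data.frame(element = rest, aromatic = FALSE,
                                              stringsAsFactors = FALSE)
    } else {
      stop(sprintf("cannot parse SMARTS atom primitive '%s'", part))
    }
  }
  allowed <- if (is.null(rows) || !length(rows)) NULL else do.call(rbind, rows)
  list(allowed = allowed, charge = charge, H = H, X = X, map = map)
}

smarts_atom_matches <- function(spec, mol, a) {
  at <- mol$atoms[a, ]
  if (!is.null(spec$allowed)) {
    ok <- any(spec$allowed$element == at$element &
              (is.na(spec$allowed$aromatic) |
                 spec$allowed$aromatic == at$aromatic))
    if (!ok) return(FALSE)
  }
  if (!is.na(spec$charge) && spec$charge != at$charge) return(FALSE)
  if (!is.na(spec$H) && spec$H != at$hcount) return(FALSE)
  if (!is.na(spec$X)) {
    deg <- sum(mol$bonds$i == a | mol$bonds$j == a)
    if (deg + at$hcount != spec$X) return(FALSE)
  }
  TRUE
}

smarts_bond_matches <- function(type, bond) {
  switch(type,
    "default" = bond$arom || bond$order == 1L,
    "-" = !bond$arom && bond$order == 1L,
    "=" = !bond$arom && bond$order == 2L,
    "#" = !bond$arom && bond$order == 3L,
    ":" = bond$arom,
    "~" = TRUE,
    stop("unknown SMARTS bond type"))
}

## All embeddings of a connected pattern into a molecule. Returns an integer
## matrix: one row per match, column p = molecule atom matched by pattern
## atom p. Injective over atoms; duplicate rows removed.
match_pattern <- function(pattern, mol) {
  np <- length(pattern$atoms)
  pb <- pattern$bonds
  ## visit order: pattern atom 1 first, then atoms adjacent to placed ones
  order_idx <- 1L
  placed <- c(1L)
  while (length(placed) < np) {
    nxt <- NULL
    for (b in seq_len(nrow(pb))) {
      if (pb$i[b] %in% placed && !(pb$j[b] %in% placed)) { nxt <- pb$j[b]; break }
      if (pb$j[b] %in% placed && !(pb$i[b] %in% placed)) { nxt <- pb$i[b]; break }
    }
    if (is.null(nxt)) stop("disconnected SMARTS pattern cannot be matched")
    placed <- c(placed, nxt)
  }

  matches <- list()
  assign_vec <- rep(NA_integer_, np)
  mol_bond_lookup <- function(a, b) {
    hit <- which((mol$bonds$i == a & mol$bonds$j == b) |
                 (mol$bonds$i == b & mol$bonds$j == a))
    if (length(hit)) hit[1] else NA_integer_
  }

  extend <- function(k) {
    if (k > np) {
      matches[[length(matches) + 1L]] <<- assign_vec
      return(invisible())
    }
    p <- placed[k]
    cands <- if (k == 1L) seq_len(n_atoms(mol)) else {
      ## neighbours of an already-placed pattern neighbour
      anchor <- NULL
      for (b in seq_len(nrow(pb))) {
        other <- if (pb$i[b] == p) pb$j[b] else if (pb$j[b] == p) pb$i[b] else NA
        if (!is.na(other) && !is.na(assign_vec[other])) { anchor <- assign_vec[other]; break }
      }
      nb <- mol$bonds[mol$bonds$i == anchor | mol$bonds$j == anchor, ]
      unique(ifelse(nb$i == anchor, nb$j, nb$i))
    }
    for (a in cands) {
      if (a %in% assign_vec) next
      if (!smarts_atom_matches(pattern$atoms[[p]], mol, a)) next
      ok <- TRUE
      for (b in seq_len(nrow(pb))) {
        other <- if (pb$i[b] == p) pb$j[b] else if (pb$j[b] == p) pb$i[b] else NA
        if (is.na(other) || is.na(assign_vec[other])) next
        mb <- mol_bond_lookup(a, assign_vec[other])
        if (is.na(mb) || !smarts_bond_matches(pb$type[b], mol$bonds[mb, ])) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      assign_vec[p] <<- a
      extend(k + 1L)
      assign_vec[p] <<- NA_integer_
    }
  }
  extend(1L)
  if (!length(matches)) {
    return(matrix(integer(), nrow = 0, ncol = np))
  }
  m <- do.call(rbind, matches)
  unique(m)
}
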