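## SMILES reader.
##
## Supports the organic subset plus bracket atoms (isotope, charge, explicit
## H), aromatic lowercase atoms, ring closures (incl. %nn), branches and
## multi-fragment input. Stereo markers (/ \ @) are accepted and discarded:
## nothing downstream is stereo-aware.

#' Parse a SMILES string into a molecular graph
#'
#' @param smiles character scalar.
#' @return a `hymol` molecular graph (possibly multi-fragment).
#' @examples
#' parse_smiles("CC(=O)Nc1ccccc1")
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop("SMILES must be a non-empty character scalar")
  }
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)

  element <- character(); aromatic <- logical(); charge <- integer()
  hexp <- integer()
  bi <- integer(); bj <- integer(); border <- integer(); barom <- logical()

  prev <- NA_integer_          # atom to bond the next atom to
  stack <- integer()           # branch stack
  pending_bond <- ""           # bond symbol awaiting next atom
  ring <- list()               # closure label -> c(atom, bondchar)

  add_atom <- function(el, arom, chg = 0L, h = NA_integer_) {
    element[length(element) + 1L] <<- el
    aromatic[length(aromatic) + 1L] <<- arom
    charge[length(charge) + 1L] <<- as.integer(chg)
    hexp[length(hexp) + 1L] <<- as.integer(h)
    length(element)
  }

  add_bond <- function(a, b, sym) {
    if (a == b) stop("self-bond in SMILES")
    ord <- switch(sym, "=" = 2L, "#" = 3L, 1L)
    arom <- identical(sym, ":") ||
      (sym == "" && aromatic[a] && aromatic[b])
    if (arom) ord <- 1L
    bi[length(bi) + 1L] <<- a
    bj[length(bj) + 1L] <<- b
    border[length(border) + 1L] <<- ord
    barom[length(barom) + 1L] <<- arom
  }

  connect <- function(atom) {
    if (!is.na(prev)) add_bond(prev, atom, pending_bond)
    pending_bond <<- ""
    prev <<- atom
  }

  close_ring <- function(label, sym) {
    key <- as.character(label)
    if (is.null(ring[[key]])) {
      ring[[key]] <<- list(atom = prev, sym = sym)
    } else {
      open <- ring[[key]]
      use <- if (nzchar(sym)) sym else open$sym
      add_bond(open$atom, prev, use)
      ring[[key]] <<- NULL
    }
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unterminated bracket atom in SMILES")
      tok <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      at <- parse_bracket_atom(tok)
      a <- add_atom(at$element, at$aromatic, at$charge, at$hcount)
      connect(a)
      i <- j + 1L
    } else if (ch %in% c("C", "N", "O", "P", "S", "F", "B", "I")) {
      el <- ch
      if (ch == "C" && i < n && chars[i + 1L] == "l") { el <- "Cl"; i <- i + 1L }
      if (ch == "B" && i < n && chars[i + 1L] == "r") { el <- "Br"; i <- i + 1L }
      if (ch == "S" && i < n && chars[i + 1L] == "i") { el <- "Si"; i <- i + 1L }
      a <- add_atom(el, FALSE)
      connect(a)
      i <- i + 1L
    } else if (ch %in% c("c", "n", "o", "p", "s")) {
      a <- add_atom(toupper(ch), TRUE)
      connect(a)
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":")) {
      pending_bond <- ch
      i <- i + 1L
    } else if (ch %in% c("/", "\\")) {
      pending_bond <- ""           # stereo bond -> plain single
      i <- i + 1L
    } else if (ch == "(") {
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop("unbalanced ')' in SMILES")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      if (is.na(prev)) stop("ring closure before any atom")
      close_ring(ch, pending_bond)
      pending_bond <- ""
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) stop("bad %% ring closure")
      close_ring(paste0(chars[i + 1L], chars[i + 2L]), pending_bond)
      pending_bond <- ""
      i <- i + 3L
    } else if (ch == ".") {
      prev <- NA_integer_
      pending_bond <- ""
      i <- i + 1L
    } else {
      stop(sprintf("unexpected character '%s' in SMILES '%s'", ch, smiles))
    }
  }
  if (length(ring)) stop(sprintf("unclosed ring bond in SMILES '%s'", smiles))
  if (length(stack)) stop(sprintf("unclosed branch in SMILES '%s'", smiles))
  if (!length(element)) stop("SMILES contains no atoms")

  atoms <- data.frame(element = element, aromatic = aromatic, charge = charge,
                      hexp = hexp, hcount = NA_integer_,
                      stringsAsFactors = FALSE)
  bonds <- data.frame(i = bi, j = bj, order = border, arom = barom,
                      stringsAsFactors = FALSE)
  mol_sanitize(assign_implicit_h(new_hymol(atoms, bonds)))
}

## Contents of a bracket atom, e.g. "13CH3+", "nH", "O-", "N+2".
parse_bracket_atom <- function(tok) {
  rest <- tok
  rest <- sub("^[0-9]+", "", rest)              # isotope: parsed and dropped
  m <- regmatches(rest, regexpr("^([A-Z][a-z]?|[cnops])", rest))
  if (!length(m)) stop(sprintf("cannot parse bracket atom '[%s]'", tok))
  sym <- m
  rest <- substring(rest, nchar(sym) + 1L)
  aromatic <- sym %in% c("c", "n", "o", "p", "s")
  el <- if (aromatic) toupper(sym) else sym
  if (is.na(ATOMIC_NUMBER[el])) {
    stop(sprintf("unsupported element '%s' in bracket atom", el))
  }
  rest <- gsub("@", "", rest)                   # chirality dropped
  h <- 0L
  hm <- regmatches(rest, regexpr("H[0-9]*", rest))
  if (length(hm)) {
    h <- if (nchar(hm) == 1L) 1L else as.integer(substring(hm, 2L))
    rest <- sub("H[0-9]*", "", rest)
  }
  chg <- 0L
  cm <- regmatches(rest, regexpr("[+-][0-9]*", rest))
  if (length(cm) && nzchar(cm)) {
    sign <- if (substring(cm, 1L, 1L) == "+") 1L else -1L
    num <- substring(cm, 2L)
    mag <- if (nzchar(num)) as.integer(num) else {
      ## ++ / -- style
      as.integer(nchar(gsub("[^+-]", "", rest)))
    }
    chg <- sign * max(mag, 1L)
  }
  list(element = el, aromatic = aromatic, charge = chg, hcount = h)
}
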