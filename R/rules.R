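## Hydrolysis rule base: loading, site matching, application, validation.

TRACKED_CLASSES <- c("N", "O", "C", "S", "X")

#' Atom class of an element symbol
#'
#' Tracked classes are N, O, C, S and X (halogens F/Cl/Br/I); other elements
#' (notably P) return `NA` and are not scored by any site model.
#'
#' @param element character vector of element symbols.
#' @return character vector of classes or `NA`.
#' @export
element_class <- function(element) {
  out <- rep(NA_character_, length(element))
  out[element %in% c("N", "O", "C", "S")] <- element[element %in% c("N", "O", "C", "S")]
  out[element %in% c("F", "Cl", "Br", "I")] <- "X"
  out
}

#' Load a hydrolysis rule base
#'
#' Reads a JSON rule base (see the shipped default under
#' `system.file("extdata/rules/hydrolysis_rules.json", package = "hydrosite")`),
#' compiles every reaction SMARTS and fails atomically if any rule is
#' malformed.
#'
#' @param path path to a JSON rule base; `NULL` loads the shipped default.
#' @return a `hydro_rulebase` object.
#' @export
load_rulebase <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "rules", "hydrolysis_rules.json",
                        package = "hydrosite")
  }
  if (!file.exists(path)) stop(sprintf("rule base file not found: %s", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(raw$rules) || !length(raw$rules)) stop("rule base contains no rules")
  ids <- vapply(raw$rules, function(r) r$rule_id %||% "", character(1))
  if (any(!nzchar(ids))) stop("every rule needs a rule_id")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate rule_id in rule base: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  rules <- lapply(raw$rules, function(r) {
    required <- c("rule_id", "name", "smarts", "atom_class", "center_map")
    miss <- required[!required %in% names(r)]
    if (length(miss)) {
      stop(sprintf("rule '%s' is missing field(s): %s", r$rule_id %||% "?",
                   paste(miss, collapse = ", ")))
    }
    rxn <- tryCatch(parse_reaction_smarts(r$smarts), error = function(e) {
      stop(sprintf("rule '%s' has malformed SMARTS: %s",
                   r$rule_id, conditionMessage(e)))
    })
    maps <- pattern_maps(rxn$reactant)
    center_idx <- which(maps == as.integer(r$center_map))
    if (!length(center_idx)) {
      stop(sprintf("rule '%s': center_map %s not present in reactant pattern",
                   r$rule_id, r$center_map))
    }
    if (!r$atom_class %in% TRACKED_CLASSES) {
      stop(sprintf("rule '%s': unknown atom_class '%s'", r$rule_id, r$atom_class))
    }
    list(rule_id = r$rule_id, name = r$name,
         family = r$family %||% r$rule_id,
         smarts = r$smarts, rxn = rxn,
         atom_class = r$atom_class,
         center_map = as.integer(r$center_map),
         center_idx = center_idx,
         environments = unlist(r$environments %||%
                                 list("aquatic", "plant", "animal")),
         balance_mode = r$balance_mode %||% "hydrolysis",
         reference = r$reference %||% "")
  })
  classes <- vapply(rules, `[[`, character(1), "atom_class")
  missing_cls <- setdiff(TRACKED_CLASSES, classes)
  if (length(missing_cls)) {
    stop(sprintf("rule base lacks rules for atom class(es): %s",
                 paste(missing_cls, collapse = ", ")))
  }
  structure(list(rules = rules,
                 version = raw$version %||% "unversioned",
                 path = path),
            class = "hydro_rulebase")
}

#' @export
print.hydro_rulebase <- function(x, ...) {
  cat(sprintf("<hydro_rulebase '%s': %d rules>\n", x$version, length(x$rules)))
  for (r in x$rules) {
    cat(sprintf("  %-26s class %s  %s\n", r$rule_id, r$atom_class, r$name))
  }
  invisible(x)
}

rulebase_ids <- function(rules) vapply(rules$rules, `[[`, character(1), "rule_id")

get_rule <- function(rules, rule_id) {
  hit <- which(rulebase_ids(rules) == rule_id)
  if (!length(hit)) stop(sprintf("no such rule: '%s'", rule_id))
  rules$rules[[hit]]
}

#' Match hydrolysis sites in a molecule
#'
#' Finds every distinct (rule, center-atom) pair. Symmetric duplicates —
#' automorphism-equivalent centers of the same rule whose application yields
#' an identical canonical product set — are collapsed onto the
#' lowest-indexed center. Atom indices are 0-based over the canonical atom
#' order of the molecule (use [mol_canonicalize()] upstream or pass SMILES).
#'
#' @param molecule a `hymol` or SMILES string.
#' @param rules a `hydro_rulebase`.
#' @param collapse_symmetric collapse automorphic duplicate centers.
#' @return data frame with columns `rule_id`, `atom_index` (0-based),
#'   `element`, `atom_class`, and a list column `products` of canonical
#'   product SMILES character vectors.
#' @export
match_sites <- function(molecule, rules, collapse_symmetric = TRUE) {
  mol <- if (is.character(molecule)) mol_canonicalize(molecule) else
    mol_canonicalize(molecule)
  out <- list()
  for (rule in rules$rules) {
    m <- match_pattern(rule$rxn$reactant, mol)
    if (!nrow(m)) next
    centers <- unique(m[, rule$center_idx])
    entries <- list()
    for (ctr in centers) {
      rows <- which(m[, rule$center_idx] == ctr)
      prods <- unique(unlist(lapply(rows, function(r) {
        frags <- apply_reaction(mol, rule$rxn, m[r, ])
        list(sort(vapply(frags, canonical_smiles, character(1))))
      }), recursive = FALSE))
      ## distinct product sets at one center are merged into their union
      entries[[length(entries) + 1L]] <- list(
        center = ctr, products = sort(unique(unlist(prods))))
    }
    if (collapse_symmetric && length(entries) > 1L) {
      keys <- vapply(entries, function(e) paste(e$products, collapse = "|"),
                     character(1))
      keep <- !duplicated(keys)
      entries <- entries[keep]
    }
    for (e in entries) {
      out[[length(out) + 1L]] <- data.frame(
        rule_id = rule$rule_id,
        atom_index = e$center - 1L,
        element = mol$atoms$element[e$center],
        atom_class = rule$atom_class,
        stringsAsFactors = FALSE)
      attr(out[[length(out)]], "products") <- e$products
    }
  }
  if (!length(out)) {
    res <- data.frame(rule_id = character(), atom_index = integer(),
                      element = character(), atom_class = character(),
                      stringsAsFactors = FALSE)
    res$products <- list()
    return(res)
  }
  prods <- lapply(out, attr, "products")
  res <- do.call(rbind, out)
  res$products <- prods
  rownames(res) <- NULL
  res
}

#' Apply one rule at one site
#'
#' @param molecule a `hymol` or SMILES string (canonical atom order assumed
#'   for `atom_index`).
#' @param rule_id rule identifier in `rules`.
#' @param atom_index 0-based canonical index of the center atom.
#' @param rules a `hydro_rulebase`.
#' @return character vector of canonical product SMILES (one per fragment).
#' @export
apply_rule <- function(molecule, rule_id, atom_index, rules) {
  mol <- mol_canonicalize(molecule)
  rule <- get_rule(rules, rule_id)
  m <- match_pattern(rule$rxn$reactant, mol)
  rows <- which(m[, rule$center_idx] == atom_index + 1L)
  if (!length(rows)) {
    stop(sprintf("rule '%s' does not match at atom %d", rule_id, atom_index))
  }
  prods <- unlist(lapply(rows, function(r) {
    frags <- tryCatch(apply_reaction(mol, rule$rxn, m[r, ]),
                      error = function(e) {
      stop(sprintf("rule '%s' failed at atom %d: %s", rule_id, atom_index,
                   conditionMessage(e)))
    })
    vapply(frags, canonical_smiles, character(1))
  }))
  sort(unique(prods))
}

#' Validate a rule base against known reactant/product pairs
#'
#' Each pair names its designated rule; the pair passes when some
#' application of that rule reproduces the full expected product set
#' (canonical comparison).
#'
#' @param rules a `hydro_rulebase`.
#' @param pairs data frame with columns `rule_id`, `reactant_smiles`,
#'   `products_smiles` (`.`-separated fragments). `NULL` loads the shipped
#'   golden pairs.
#' @return data frame report with one row per pair (`pass`, `expected`,
#'   `observed`); overall pass as attribute `"pass"`.
#' @export
validate_rulebase <- function(rules, pairs = NULL) {
  if (is.null(pairs)) {
    pairs <- utils::read.delim(
      system.file("extdata", "rules", "golden_pairs.tsv", package = "hydrosite"),
      stringsAsFactors = FALSE)
  }
  if (!nrow(pairs)) stop("no validation pairs supplied")
  res <- lapply(seq_len(nrow(pairs)), function(k) {
    rid <- pairs$rule_id[k]
    expected <- sort(vapply(strsplit(pairs$products_smiles[k], ".", fixed = TRUE)[[1]],
                            canonical_smiles, character(1), USE.NAMES = FALSE))
    rule <- get_rule(rules, rid)
    mol <- mol_canonicalize(pairs$reactant_smiles[k])
    m <- match_pattern(rule$rxn$reactant, mol)
    observed <- character()
    pass <- FALSE
    if (nrow(m)) {
      for (r in seq_len(nrow(m))) {
        frags <- sort(vapply(apply_reaction(mol, rule$rxn, m[r, ]),
                             canonical_smiles, character(1)))
        observed <- union(observed, paste(frags, collapse = "."))
        if (identical(frags, expected)) pass <- TRUE
      }
    }
    data.frame(rule_id = rid, reactant = pairs$reactant_smiles[k],
               expected = paste(expected, collapse = "."),
               observed = paste(observed, collapse = " | "),
               pass = pass, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, res)
  attr(report, "pass") <- all(report$pass)
  report
}

#' Heavy-atom balance audit of a rule base
#'
#' Applies every rule to its golden reactant and checks that the heavy atoms
#' summed over all product fragments equal the parent's heavy atoms plus the
#' water-derived oxygen(s) implied by the rule's balance mode
#' (`hydration`/`hydrolysis`: +1, `double`: +2).
#'
#' @inheritParams validate_rulebase
#' @return data frame with per-rule `parent_atoms`, `product_atoms`,
#'   `expected_delta`, `pass`.
#' @export
audit_rule_balance <- function(rules, pairs = NULL) {
  if (is.null(pairs)) {
    pairs <- utils::read.delim(
      system.file("extdata", "rules", "golden_pairs.tsv", package = "hydrosite"),
      stringsAsFactors = FALSE)
  }
  res <- lapply(seq_len(nrow(pairs)), function(k) {
    rule <- get_rule(rules, pairs$rule_id[k])
    mol <- mol_canonicalize(pairs$reactant_smiles[k])
    m <- match_pattern(rule$rxn$reactant, mol)
    stopifnot(nrow(m) > 0)
    frags <- apply_reaction(mol, rule$rxn, m[1, ])
    np <- sum(vapply(frags, n_atoms, integer(1)))
    delta <- switch(rule$balance_mode, hydration = 1L, hydrolysis = 1L,
                    double = 2L, stop("unknown balance_mode"))
    data.frame(rule_id = rule$rule_id, parent_atoms = n_atoms(mol),
               product_atoms = np, expected_delta = delta,
               pass = np == n_atoms(mol) + delta, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
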