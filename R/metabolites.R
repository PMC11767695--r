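## Metabolite generation: combine per-atom site probabilities with the rule
## base; score, deduplicate, rank and evaluate hydrolysis products.
##
## A "transformation" is one cleavage event. Rules of the same reaction
## family applied at the same site (e.g. the two nitrile rules) or arriving
## at the same major product from different centers of one functional group
## (e.g. N-acyl vs O-acyl carbamate cleavage) describe the same chemical
## event, so transformations are merged within a family when they share
## either the site atom or the major organic fragment; the highest-scoring
## representative (ties: rule-base order) is reported.

## CO2 and carbon-free fragments (halides, ammonia, H2S, hydroxylamine...)
## are inorganic by-products, never "major" metabolites.
is_inorganic_fragment <- function(smiles) {
  vapply(smiles, function(s) {
    !grepl("[Cc]", gsub("Cl", "", s)) || s == "C(=O)=O"
  }, logical(1), USE.NAMES = FALSE)
}

major_fragment <- function(products) {
  org <- products[!is_inorganic_fragment(products)]
  if (!length(org)) org <- products
  sizes <- vapply(org, function(s) n_atoms(parse_smiles(s)), integer(1))
  cand <- sort(org[sizes == max(sizes)])
  cand[1]
}

#' Generate ranked hydrolysis metabolites for a molecule
#'
#' Applies every rule whose center-atom probability reaches `threshold`,
#' merges duplicate transformations (automorphic sites; same family at the
#' same site or with the same major fragment), and ranks by site
#' probability (descending; ties by `rule_id`).
#'
#' With `bundle = NULL` every matched site scores 1.0, which reduces the
#' engine to pure rule-based enumeration.
#'
#' @param molecule a `hymol` or SMILES string.
#' @param rules a `hydro_rulebase`.
#' @param bundle optional `hydro_bundle` for site probabilities.
#' @param threshold site probability threshold tau in `[0, 1]`.
#' @return data frame, one row per product fragment: `rank`,
#'   `product_smiles`, `score`, `rule_id`, `rule_name`, `site_atom_index`,
#'   `environments`, `fragment_role`; attribute `n_transformations`.
#' @export
generate_metabolites <- function(molecule, rules, bundle = NULL,
                                 threshold = 0.5) {
  mol <- mol_canonicalize(molecule)
  sites <- match_sites(mol, rules, collapse_symmetric = TRUE)
  empty <- data.frame(rank = integer(), product_smiles = character(),
                      score = numeric(), rule_id = character(),
                      rule_name = character(), site_atom_index = integer(),
                      environments = character(), fragment_role = character(),
                      stringsAsFactors = FALSE)
  attr(empty, "n_transformations") <- 0L
  if (!nrow(sites)) return(empty)

  prob_of <- if (is.null(bundle)) {
    function(atom_index) 1.0
  } else {
    preds <- predict_sites(bundle, mol, threshold = 0)
    function(atom_index) {
      hit <- preds$probability[preds$atom_index == atom_index]
      if (length(hit)) hit[1] else NA_real_
    }
  }

  rule_pos <- stats::setNames(seq_along(rules$rules), rulebase_ids(rules))
  entries <- list()
  for (k in seq_len(nrow(sites))) {
    p <- prob_of(sites$atom_index[k])
    if (is.na(p) || p < threshold) next
    rule <- get_rule(rules, sites$rule_id[k])
    prods <- sites$products[[k]]
    entries[[length(entries) + 1L]] <- list(
      rule_id = rule$rule_id, rule_name = rule$name, family = rule$family,
      pos = rule_pos[[rule$rule_id]],
      environments = paste(rule$environments, collapse = ";"),
      site = sites$atom_index[k], score = p,
      products = prods, major = major_fragment(prods))
  }
  if (!length(entries)) return(empty)

  ## merge within family: shared site or shared major fragment (union-find)
  ne <- length(entries)
  parent <- seq_len(ne)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(ne)) for (j in seq_len(ne)) {
    if (j <= i) next
    ei <- entries[[i]]; ej <- entries[[j]]
    if (ei$family != ej$family) next
    if (ei$site == ej$site || ei$major == ej$major) {
      parent[find(j)] <- find(i)
    }
  }
  groups <- split(seq_len(ne), vapply(seq_len(ne), find, integer(1)))
  merged <- lapply(groups, function(idx) {
    es <- entries[idx]
    scores <- vapply(es, `[[`, numeric(1), "score")
    pos <- vapply(es, `[[`, numeric(1), "pos")
    es[[order(-scores, pos)[1]]]
  })

  ord <- order(-vapply(merged, `[[`, numeric(1), "score"),
               vapply(merged, `[[`, character(1), "rule_id"))
  merged <- merged[ord]
  rows <- list()
  for (r in seq_along(merged)) {
    e <- merged[[r]]
    roles <- ifelse(is_inorganic_fragment(e$products), "inorganic",
                    ifelse(e$products == e$major, "major", "minor"))
    for (f in seq_along(e$products)) {
      rows[[length(rows) + 1L]] <- data.frame(
        rank = r, product_smiles = e$products[f], score = e$score,
        rule_id = e$rule_id, rule_name = e$rule_name,
        site_atom_index = e$site, environments = e$environments,
        fragment_role = roles[f], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_transformations") <- length(merged)
  out
}

#' Re-sort a metabolite table by score
#'
#' Stable sort, score descending, ties by `rule_id` (lexicographic), as used
#' for reporting; ranks are renumbered by transformation.
#'
#' @param predictions output of [generate_metabolites()].
#' @return the reordered data frame.
#' @export
rank_consistency <- function(predictions) {
  if (!nrow(predictions)) return(predictions)
  key <- unique(predictions[, c("rank", "score", "rule_id")])
  key <- key[order(-key$score, key$rule_id), , drop = FALSE]
  key$new_rank <- seq_len(nrow(key))
  predictions$new_rank <- key$new_rank[match(predictions$rank, key$rank)]
  predictions <- predictions[order(predictions$new_rank), , drop = FALSE]
  predictions$rank <- predictions$new_rank
  predictions$new_rank <- NULL
  rownames(predictions) <- NULL
  predictions
}

#' Evaluate predicted metabolites against a reference product list
#'
#' A hit is a canonical-structure match (stereo-stripped, largest organic
#' fragment) between a predicted major fragment and a reference product.
#'
#' @param predicted output of [generate_metabolites()] or a character
#'   vector of product SMILES.
#' @param reference character vector of reference product SMILES.
#' @return a `hydro_product_eval` list: `n_reference`, `n_predicted`,
#'   `n_hit`, `n_extra`, `hit_rate`, `false_positive_rate`.
#' @export
evaluate_products <- function(predicted, reference) {
  if (!length(reference)) stop("reference product list is empty")
  norm <- function(s) canonical_smiles(keep_largest_fragment(parse_smiles(s)))
  ref <- unique(vapply(reference, function(s) {
    tryCatch(norm(s), error = function(e) {
      stop(sprintf("unparsable reference structure '%s': %s", s,
                   conditionMessage(e)))
    })
  }, character(1), USE.NAMES = FALSE))
  pred <- if (is.data.frame(predicted)) {
    unique(predicted$product_smiles[predicted$fragment_role == "major"])
  } else {
    unique(vapply(predicted, norm, character(1), USE.NAMES = FALSE))
  }
  n_hit <- length(intersect(pred, ref))
  n_extra <- length(setdiff(pred, ref))
  structure(list(
    n_reference = length(ref), n_predicted = length(pred),
    n_hit = n_hit, n_extra = n_extra,
    hit_rate = n_hit / length(ref),
    false_positive_rate = if (length(pred)) n_extra / length(pred) else 0),
    class = "hydro_product_eval")
}

#' @export
print.hydro_product_eval <- function(x, ...) {
  cat(sprintf("products: %d predicted, %d/%d reference hit (hit rate %.1f%%), %d extra (FPR %.1f%%)\n",
              x$n_predicted, x$n_hit, x$n_reference, 100 * x$hit_rate,
              x$n_extra, 100 * x$false_positive_rate))
  invisible(x)
}
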