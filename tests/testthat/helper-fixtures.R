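## Shared fixtures: the shipped rule base and a small cached synthetic
## corpus. Everything is generated in code at test time.

hy_rules <- function() {
  if (is.null(.hy_cache$rules)) .hy_cache$rules <- load_rulebase()
  .hy_cache$rules
}

## 40-molecule corpus, seed 11: large enough to split and train tiny models.
hy_corpus <- function() {
  if (is.null(.hy_cache$corpus)) {
    .hy_cache$corpus <- generate_corpus(
      synth_config(n_molecules = 40L, seed = 11L), hy_rules())
  }
  .hy_cache$corpus
}

.hy_cache <- new.env(parent = emptyenv())

## Selected features + split of the 40-molecule corpus (lazy, cached).
hy_model_data <- function() {
  if (!is.null(.hy_cache$model_data)) return(.hy_cache$model_data)
  corp <- hy_corpus()
  parents <- stats::setNames(
    vapply(corp$records, `[[`, character(1), "parent"),
    vapply(corp$records, `[[`, character(1), "record_id"))
  split <- split_dataset(corp$labels, 0.8, seed = 11L)
  ftr <- hydrosite:::build_feature_matrix(split$train, parents)
  fte <- hydrosite:::build_feature_matrix(split$test, parents)
  sel <- fit_selector(ftr$X, split$train$label)
  .hy_cache$model_data <- list(
    split = split, sel = sel,
    Xtr_raw = ftr$X, Xte_raw = fte$X,
    Xtr = apply_selector(sel, ftr$X), Xte = apply_selector(sel, fte$X),
    ytr = split$train$label, yte = split$test$label)
  .hy_cache$model_data
}

## A small finalized Global bundle over two cheap families (lazy, cached).
hy_bundle <- function() {
  if (!is.null(.hy_cache$bundle)) return(.hy_cache$bundle)
  d <- hy_model_data()
  tuned <- lapply(c("dt", "lda"), function(f) {
    tune(f, d$Xtr, d$ytr, n_configs = 2L, folds = 3L, seed = 11L)
  })
  .hy_cache$bundle <- finalize(
    tuned, d$sel, d$Xtr_raw, d$ytr, d$Xte_raw, d$yte,
    dataset_name = "Global-Hydrolysis",
    atom_classes = c("N", "O", "C", "S", "X"), seed = 11L)
  .hy_cache$bundle
}

## Reference agrochemical structures used across tests.
SMI_DESMEDIPHAM <- "CCOC(=O)Nc1cccc(OC(=O)Nc2ccccc2)c1"
SMI_CYANOPHOS <- "COP(=S)(OC)Oc1ccc(C#N)cc1"
SMI_FLAMPROP_METHYL <- "COC(=O)C(C)N(C(=O)c1ccccc1)c1ccc(F)c(Cl)c1"
SMI_ACETANILIDE <- "CC(=O)Nc1ccccc1"

## Independent structure-equality oracle: VF2 isomorphism on colored graphs
## (igraph), used to cross-check canonical-SMILES equality.
mols_isomorphic <- function(smi1, smi2) {
  m1 <- hydrosite:::parse_smiles(smi1)
  m2 <- hydrosite:::parse_smiles(smi2)
  if (nrow(m1$atoms) != nrow(m2$atoms) || nrow(m1$bonds) != nrow(m2$bonds)) {
    return(FALSE)
  }
  to_graph <- function(m) {
    g <- igraph::graph_from_data_frame(
      m$bonds[, c("i", "j")], directed = FALSE,
      vertices = data.frame(name = seq_len(nrow(m$atoms))))
    vcol <- as.integer(factor(
      paste(m$atoms$element, m$atoms$aromatic, m$atoms$charge, m$atoms$hcount),
      levels = sort(unique(c(
        paste(m1$atoms$element, m1$atoms$aromatic, m1$atoms$charge, m1$atoms$hcount),
        paste(m2$atoms$element, m2$atoms$aromatic, m2$atoms$charge, m2$atoms$hcount))))))
    ecol <- ifelse(m$bonds$arom, 4L, m$bonds$order)
    list(g = g, vcol = vcol, ecol = ecol)
  }
  g1 <- to_graph(m1); g2 <- to_graph(m2)
  igraph::isomorphic(g1$g, g2$g, method = "vf2",
                     vertex.color1 = g1$vcol, vertex.color2 = g2$vcol,
                     edge.color1 = g1$ecol, edge.color2 = g2$ecol)
}

## Independent brute-force oracle: per-column variance, F and Welch p
## computed with base R primitives (var, aov-free closed forms via t.test).
brute_force_selector <- function(X, y, keep_fraction = 0.5, alpha = 0.05) {
  y <- as.integer(y)
  s1 <- which(apply(X, 2, stats::var) > 0)
  fvals <- vapply(s1, function(j) {
    summary(stats::aov(X[, j] ~ factor(y)))[[1]][["F value"]][1]
  }, numeric(1))
  k <- ceiling(keep_fraction * length(s1))
  ord <- order(-fvals, seq_along(fvals))
  s2 <- s1[sort(ord[seq_len(k)])]
  pvals <- vapply(s2, function(j) {
    if (stats::var(X[y == 1, j]) == 0 && stats::var(X[y == 0, j]) == 0) {
      return(if (mean(X[y == 1, j]) != mean(X[y == 0, j])) 0 else 1)
    }
    stats::t.test(X[y == 1, j], X[y == 0, j])$p.value
  }, numeric(1))
  s2[pvals < alpha]
}

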