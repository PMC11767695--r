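# hydrosite

Atom-level hydrolysis site-of-metabolism (SOM) prediction and metabolite
generation for environmental organic chemicals.

Hydrolysis — reaction with water, enzymatic or abiotic — is a principal
degradation route of agrochemicals and related organics. `hydrosite`
predicts *where* a molecule hydrolyzes and *what* it becomes by coupling
two components:

- **Per-atom classifiers** (N-, O-, C- and Global-Hydrolysis). Every heavy
  atom of a tracked class (N, O, C, S, halogens) is encoded as a 1024-bit
  circular atomic-environment fingerprint (Morgan-style, radius 3) plus 8
  interpretable atomic descriptors (PEOE partial charge, sigma
  electronegativity, polarizability, topology). Features pass a
  variance → ANOVA-F (top 50%) → Welch-t (p < 0.05) selection cascade;
  eight model families (decision tree, random forest, extra trees,
  gradient boosting, histogram gradient boosting, adaptive boosting, LDA,
  QDA) are pre-trained with stratified k-fold CV, the top five tuned over
  random hyperparameter configurations, and the winner chosen by held-out
  test MCC,

  MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN)).

- **A reaction-SMARTS rule base** of 14 hydrolysis transformations
  (amides, nitriles, ureas, carbamates, esters, carbonates, oximes,
  phosphoesters, thioethers, acid chlorides, haloalkanes, alkynes), each
  with a mapped reaction center, atom class, environment tags
  (aquatic/plant/animal), mass-balance mode and a golden validation pair.

Prediction: candidate sites come from SMARTS matching, each site receives
the classifier probability, rules fire at sites with probability ≥ τ
(default 0.5), and each product is ranked by its site's score. Symmetric
sites and equivalent cleavages of one functional group are collapsed so
transformation counts are chemically meaningful.

Because the published hydrolysis corpora compiled from the agrochemical
metabolism literature are not redistributable, the package includes a
synthetic corpus generator with per-atom ground truth
(`generate_corpus()`), which makes the entire pipeline testable
end-to-end offline.

## Worked example

```r
library(hydrosite)
rules <- load_rulebase()

## the herbicide desmedipham: two carbamate groups
products <- generate_metabolites("CCOC(=O)Nc1cccc(OC(=O)Nc2ccccc2)c1", rules)
attr(products, "n_transformations")
#> [1] 2
subset(products, fragment_role == "major",
       select = c(rank, product_smiles, rule_id))
#>   rank               product_smiles              rule_id
#> 2    1 C(Nc1ccccc1)(=O)Oc2cccc(c2)N carbamate_N_cleavage
#> 6    2         CCOC(Nc1cccc(c1)O)=O carbamate_N_cleavage
```

The two major products are 3-aminophenyl phenylcarbamate (hydrolysis of
the ethyl carbamate) and ethyl (3-hydroxyphenyl)carbamate (hydrolysis of
the phenyl carbamate) — the documented hydrolysis chemistry of
desmedipham.

Training on the default synthetic corpus:

```r
corp <- generate_corpus(synth_config(n_molecules = 300, seed = 7))
bundles <- hydro_train(corp, out_dir = "run", datasets = "Global-Hydrolysis",
                       seed = 7, folds = 5, n_configs = 10)
bundles[["Global-Hydrolysis"]]
#> <hydro_bundle Global-Hydrolysis: rf (random-forest), 320 features, test MCC 1.000>
```

With no model bundle every matched site scores 1.0 (pure rule-based
enumeration). After training, `predict_sites(bundle, smiles)` returns one
row per tracked heavy atom with the classifier probability and the
`is_site` call at τ, and `generate_metabolites(smiles, rules, bundle)`
ranks the products by those probabilities.

A thin command-line front end ships at `inst/scripts/hydrosite`
(subcommands `generate-fixtures`, `train`, `predict`, `evaluate`,
`validate-rules`).

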