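---
title: "Predicting hydrolysis sites and metabolites with hydrosite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting hydrolysis sites and metabolites with hydrosite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Hydrolysis — biotic or abiotic reaction with water — is a dominant
degradation route for environmental organic chemicals such as
agrochemicals: esters, amides, carbamates, ureas, nitriles,
organophosphates and related linkages are cleaved in soil water, plants
and animals. Knowing *where* a molecule will hydrolyze (the site of
metabolism, SOM) and *what* it will turn into is central to environmental
fate assessment. Exhaustive application of transformation rules
over-generates products combinatorially; hydrosite instead scores every
candidate atom with a machine-learned probability and only applies
transformation rules at sites that pass a threshold, so products arrive
ranked by plausibility.

## The model

hydrosite couples two components:

1. **Per-atom hydrolysis-site classifiers.** Every heavy atom of a tracked
   class — N, O, C, S, or halogen (X) — is represented by a 1032-long
   feature vector: a 1024-bit circular atomic-environment fingerprint
   (Morgan-style iterative neighbourhood hashing rooted at the atom, radius
   3) concatenated with 8 interpretable atomic descriptors. Atoms observed
   to react are labeled SOM+, all other tracked atoms SOM−. Four datasets
   are assembled: N-, O- and C-Hydrolysis (single-element) and
   Global-Hydrolysis (all tracked classes; S and halogen atoms are folded
   into the global set because they are sparse). Class imbalance is kept
   as-is — the rarity of reactive atoms is a property of the chemistry,
   and resampling it away would miscalibrate the scores.

2. **A knowledge-based reaction rule base.** Fourteen reaction-SMARTS
   transformation rules cover the classic hydrolyzable families (amide,
   nitrile to amide and to acid, urea, carbamate N- and O-acyl cleavage,
   carboxylic ester, carbonate, oxime, phosphoester, thioether, acid
   chloride, haloalkane substitution, terminal alkyne hydration). Each rule
   names the atom-map of its reaction center, the atom class that scores
   it, the environments it is reported from, and a mass-balance mode. The
   rule base is a user-replaceable JSON file; every shipped rule has a
   golden reactant-product pair and is validated on load
   (`validate_rulebase()`, `audit_rule_balance()`).

Prediction combines the two: candidate sites come from SMARTS matching,
each site gets the classifier's probability, rules fire at sites above the
threshold tau, and each resulting metabolite inherits its site's score.

## The modelling pipeline

Training (`hydro_train()`) proceeds dataset by dataset:

* **Molecule-grouped 8:2 split.** The train/test split is at the molecule
  level, never the atom level: atoms of one molecule share near-duplicate
  environments, and an atom-wise split would leak them across the
  boundary.
* **Three-stage feature selection**, fitted on training rows only and
  frozen: (i) remove zero-variance columns, (ii) keep the top 50% of
  survivors by one-way ANOVA F value (ceiling on odd counts; ties broken
  toward the lower column index so the result is deterministic),
  (iii) keep survivors with a two-sided Welch t-test p < 0.05. Welch
  rather than pooled variance is the default because the SOM classes are
  strongly imbalanced; a `t_variant` switch restores the pooled test.
  Binary fingerprint columns pass through the same numeric tests.
* **Pre-training of eight families** with stratified cross-validation:
  decision tree (`rpart`), random forest and extremely randomised trees
  (`ranger`), gradient boosting with exact and with histogram split
  finding (`xgboost`), adaptive boosting (a SAMME loop over shallow
  `rpart` learners implemented in the package), and linear and quadratic
  discriminant analysis (`MASS`) on a PCA projection. The projection keeps
  the discriminants well-posed on near-collinear binary fingerprints; its
  dimension is capped at one less than the smaller class.
* **Tuning** of the top five families by mean CV accuracy over randomly
  sampled configurations; the default configuration is always candidate 0,
  so tuning can never select something worse than the default. The
  gradient-boosting space spans learning rates from 0.05 to 1.0 and tree
  counts from 50 to 300 — deliberately bracketing the regime where a lower
  learning rate with more trees beats the defaults.
* **Finalisation** by held-out test MCC, with ACC and then a fixed family
  order as tie-breaks. MCC is the primary criterion because it is the one
  confusion-matrix summary that stays informative under the imbalance of
  these datasets. All candidate metrics are retained in the bundle.

Default ensemble sizes (200 trees for the forests, 30 boosting rounds for
the SAMME learner, search ranges around them) are sized for the
desk-scale corpora this package targets — hundreds of molecules, a few
thousand atom rows — where learning curves for these data are flat well
below the conventional 500-tree defaults.

## Scoring and ranking metabolites

`generate_metabolites()` defines a *transformation* as one cleavage event
and reports one ranked entry per transformation, with every product
fragment attached and classified as `major` (largest organic fragment),
`minor`, or `inorganic` (CO2, halide, ammonia and other carbon-free
leaving species). Three deduplication layers keep the counts chemically
meaningful:

* automorphism collapse: rule centers that are symmetry-equivalent (they
  produce identical canonical product sets) are reported once;
* within a reaction family, applications sharing a site are one event
  (the two nitrile rules describe alternative outcomes of attacking the
  same C≡N group);
* within a family, applications sharing the major product are one event
  (N-acyl and O-acyl carbamate cleavage both decompose the same carbamate
  to the same alcohol + amine + CO2).

The representative of a merged group is the highest-scoring application,
with rule-base order as the tie-break. Ranking is a stable sort by score
descending, ties by rule id. Product-set behaviour is monotone in tau:
lowering the threshold can only add transformations. Hit-matching against
reference products is canonical-SMILES equality after stereo stripping
and salt reduction to the largest organic fragment.

Multi-step degradation sequences are intentionally out of scope: the
engine predicts single hydrolysis steps, and a pathway is explored by
re-running prediction on a chosen product. This avoids the combinatorial
explosion that unprioritised rule systems suffer from.

## The chemistry layer

No chemistry toolkit with atom-mapped reaction transformations is
available to R in this package's dependency footprint, so hydrosite
carries its own compact molecular-graph core: a SMILES reader (organic
subset, bracket atoms, aromatic lower-case, ring closures; stereochemistry
is parsed and discarded), a canonical SMILES writer, a restricted SMARTS
matcher (element primitives with `#n`, comma-OR, `H`/`X` counts, charge,
atom maps; no recursive SMARTS), a reaction engine, and Morgan-style
atom-rooted fingerprint hashing. Design points that matter for results:

* **Canonical ranking** is iterative invariant refinement with exact
  symmetry resolution: when refinement stalls with tied atoms, each member
  of the first tied cell is individualised in turn and the
  lexicographically smallest emitted SMILES wins. This is exponential only
  on pathological symmetry and exact on everything: canonical equality is
  the package's structure-identity relation, and the test suite
  cross-checks it against VF2 graph isomorphism (igraph) and OpenBabel's
  independent canonicaliser.
* **Implicit hydrogens** follow standard SMILES valence rules; aromatic
  atoms use their lowest valence state.
* **Atom indexing** in every user-facing table is 0-based over the
  canonical atom order of the molecule, so indices are reproducible across
  any input spelling of the same structure.
* **The fingerprint hashing dialect is package-specific** (a versioned
  polynomial string hash). Bit positions are not portable to other
  toolkits; the dialect id travels with every model bundle and
  `load_bundle()` refuses a mismatch.
* **PEOE charges** (Gasteiger-Marsili partial equalisation of orbital
  electronegativity) run over the sigma framework with implicit hydrogens
  expanded and 0.5^k damping for 8 iterations. The 8-descriptor set is
  partial charge, sigma electronegativity at convergence, tabulated
  element polarizability, heavy degree, attached-H count, aromatic flag,
  smallest ring size, and pi-bond count. Effective (neighbourhood-damped)
  polarizability and a separate pi electronegativity were considered and
  dropped: their parameterisations are not reproducible from any source
  available to this package, and the shipped set covers the same
  chemistry (charge distribution, polarizability, topology) with
  documented, testable definitions. The set is versioned so an
  alternative can be swapped in without silently mixing feature spaces.

## The synthetic corpus

Real hydrolysis corpora are compiled from the agrochemical metabolism
literature and are not redistributable, so the package ships a generator
(`generate_corpus()`) that emulates their structure: small scaffolds
(benzenoid, pyridine, alkyl, alicyclic) decorated with 1-3 hydrolyzable
groups and 0-2 inert decoys (ethers, amines, alcohols, nitro, halogenated
aromatics). Ground-truth SOM+ atoms are the rule-matched centers of the
assembled molecule and the observed products are computed by applying the
rule base there, which gives the generator a closure property the tests
lean on: corpus labeling, which shares only the rule base with the
generator, must recover the ground truth exactly. Group and decoy
frequencies are chosen so the Global dataset lands near the 0.24 SOM+:SOM−
imbalance characteristic of curated hydrolysis data; the achieved ratio is
reported with every corpus and the generator refuses configurations that
cannot produce positives. An optional label-flip rate exists purely as
robustness-testing machinery and defaults to 0.

What the synthetic corpus does *not* emulate: realistic agrochemical
property distributions, competing reaction kinetics, unexplained or
missing product reports, and sites whose reactivity depends on long-range
electronics rather than the local functional group. Because ground truth
is a deterministic function of local substructure, classifier metrics on
this corpus (test MCC above 0.9) demonstrate that the pipeline is wired
correctly — featurization is informative, selection keeps the signal,
no leakage across the molecule split — not that comparable accuracy would
be reached on experimental data, where the paper-scale corpora show
substantially harder behaviour.

## Worked checks

Three agrochemicals serve as fast structural regression points, chosen
because their hydrolysis chemistry is well documented: desmedipham (two
carbamate groups; exactly two predicted transformations, including ethyl
(3-hydroxyphenyl)carbamate and 3-aminophenyl phenylcarbamate), cyanophos
(a phosphorothioate triester plus an aryl nitrile; three transformations
after the two symmetric O-methyl cleavages collapse), and flamprop-methyl
(exactly two matched sites: the ester oxygen and the amide nitrogen).
These depend only on the rule engine and the structures, not on any
trained model.

## Numerical and degenerate-input choices

* Metrics with a zero denominator are reported as 0 and flagged rather
  than NaN; the all-wrong confusion matrix still yields its legitimate
  MCC of −1.
* An empty retained-feature set is an explicit error, never a 0-column
  matrix.
* Splits, fold assignments, configuration sampling and every model fit are
  seeded; two runs with the same corpus, seed and configuration produce
  byte-identical metric files.
* Records whose observed products no rule can reproduce are flagged
  `unexplained`, excluded from labeled data, and reported — never
  silently dropped. A record whose product list is only the parent is the
  canonical example.
* Multi-fragment parents are reduced to the largest organic fragment
  before labeling (rules are written against the organic core).

## Known limitations

* The rule base is a reconstruction: it covers the hydrolyzable families
  named in the agrochemical metabolism literature with one or two rules
  each, not an exhaustive curated list. It is versioned and replaceable.
* Kinetics, pH and temperature dependence are not modelled; environment
  tags (aquatic/plant/animal) are qualitative provenance, not rates.
* The SMARTS subset excludes recursive patterns and logical operators
  beyond element-level OR; rules requiring them would need the matcher to
  grow.
* Only single-step hydrolysis; non-hydrolytic phase I/II chemistry is out
  of scope.
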