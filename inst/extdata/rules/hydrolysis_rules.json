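{
  "version": "hydrosite-rules-1.0",
  "comment": "Reconstructed hydrolysis transformation rule base covering the classic hydrolyzable functional-group families of agrochemical degradation chemistry (amides, nitriles, ureas, carbamates, esters, carbonates, oximes, phosphoesters, thioethers, acyl halides, haloalkanes, alkynes). User-replaceable; see load_rulebase().",
  "rules": [
    {
      "rule_id": "amide_hydrolysis",
      "name": "Carboxylic amide hydrolysis to acid + amine",
      "family": "amide",
      "smarts": "[#6:1][C:2](=[O:3])[N:4]>>([#6:1][C:2](=[O:3])[OH1].[N:4])",
      "atom_class": "N",
      "center_map": 4,
      "environments": ["aquatic", "plant", "animal"],
      "balance_mode": "hydrolysis",
      "reference": "classic amide bond cleavage (amidases; alkaline hydrolysis)"
    },
    {
      "rule_id": "nitrile_to_amide",
      "name": "Nitrile hydration to primary amide",
      "family": "nitrile",
      "smarts": "[#6:1][C:2]#[N:3]>>[#6:1][C:2](=[O])[N:3]",
      "atom_class": "N",
      "center_map": 3,
      "environments": ["aquatic", "plant", "animal"],
      "balance_mode": "hydration",
      "reference": "nitrile hydratase-type hydration; first step of nitrile degradation"
    },
    {
      "rule_id": "nitrile_to_acid",
      "name": "Nitrile hydrolysis to carboxylic acid + ammonia",
      "family": "nitrile",
      "smarts": "[#6:1][C:2]#[N:3]>>([#6:1][C:2](=[O])[OH1].[N:3])",
      "atom_class": "N",
      "center_map": 3,
      "environments": ["aquatic", "plant", "animal"],
      "balance_mode": "double",
      "reference": "nitrilase-type full hydrolysis"
    },
    {
      "rule_id": "urea_hydrolysis",
      "name": "Urea hydrolysis to two amines + CO2",
      "family": "urea",
      "smarts": "[NX3:1][C:2](=[O:3])[NX3:4]>>([NX3:1].[O:3]=[C:2]=[O].[NX3:4])",
      "atom_class": "N",
      "center_map": 1,
      "environments": ["aquatic", "plant", "animal"],
      "balance_mode": "hydrolysis",
      "reference": "phenylurea herbicide degradation via carbamic acid decomposition"
    },
    {
      "rule_id": "carbamate_N_cleavage",
      "name": "Carbamate hydrolysis, amine release (N-acyl cleavage)",
      "family": "carbamate",
      "smarts": "[#6:1][O:2][C:3](=[O:4])[NX3:5]>>([#6:1][O:2].[O:4]=[C:3]=[O].[NX3:5])",
      "atom_class": "N",
      "center_map": 5,
      "environments": ["aquatic", "plant", "animal"],
      "balance_mode": "hydrolysis",
      "reference": "carbamate decomposition to alcohol + amine + CO2"
    },
    {
      "rule_id": "carbamate_O_cleavage",
      "name": "Carbamate hydrolysis, alcohol release (O-acyl cleavage)",
      "family": "carbamate",
      "smarts": "[#6:1][O:2][C:3](=[O:4])[NX3:5]>>([#6:1][O:2].[O:4]=[C:3]=[O].[NX3:5])",
      "atom_class": "O",
      "center_map": 2,
      "environments": ["aquatic", "plant", "animal"],
      "balance_mode": "hydrolysis",
      "reference": "carbamate decomposition to alcohol + amine + CO2"
    },
    {
      "rule_id": "ester_hydrolysis",
      "name": "Carboxylic ester hydrolysis to acid + alcohol",
      "family": "ester",
      "smarts": "[#6:1][C:2](=[O:3])[O:4][#6:5]>>([#6:1][C:2](=[O:3])[OH1].[O:4][#6:5])",
      "atom_class": "O",
      "center_map": 4,
      "environments": ["aquatic", "plant", "animal"],
      "balance_mode": "hydrolysis",
      "reference": "carboxylesterase / alkaline ester cleavage"
    },
    {
      "rule_id": "carbonate_hydrolysis",
      "name": "Carbonate ester hydrolysis to two alcohols + CO2",
      "family": "carbonate",
      "smarts": "[#6:1][O:2][C:3](=[O:4])[O:5][#6:6]>>([#6:1][O:2].[O:4]=[C:3]=[O].[O:5][#6:6])",
      "atom_class": "O",
      "center_map": 2,
      "environments": ["aquatic", "plant", "animal"],
      "balance_mode": "hydrolysis",
      "reference": "carbonic acid diester decomposition"
    },
    {
      "rule_id": "oxime_hydrolysis",
      "name": "Oxime hydrolysis to carbonyl + hydroxylamine",
      "family": "oxime",
      "smarts": "[C:1]=[N:2][OX2H1:3]>>([C:1]=[O].[N:2][OX2:3])",
      "atom_class": "O",
      "center_map": 3,
      "environments": ["aquatic", "plant"],
      "balance_mode": "hydrolysis",
      "reference": "acid-catalysed oxime deoximation"
    },
    {
      "rule_id": "phosphoester_hydrolysis",
      "name": "Phosphoester hydrolysis (P-O cleavage, hydroxide substitution at P)",
      "family": "phosphoester",
      "smarts": "[#6:1][O:2][P:3]=[O,S:4]>>([#6:1][O:2].[OH1][P:3]=[*:4])",
      "atom_class": "O",
      "center_map": 2,
      "environments": ["aquatic", "plant", "animal"],
      "balance_mode": "hydrolysis",
      "reference": "SN2-at-phosphorus: hydroxide attack at P expels the alkoxy/aryloxy leaving group"
    },
    {
      "rule_id": "thioether_hydrolysis",
      "name": "Thioether hydrolysis to alcohol + thiol",
      "family": "thioether",
      "smarts": "[#6:1][SX2:2][#6:3]>>([#6:1][OH1].[SX2:2][#6:3])",
      "atom_class": "S",
      "center_map": 2,
      "environments": ["aquatic", "animal"],
      "balance_mode": "hydrolysis",
      "reference": "C-S bond displacement by water"
    },
    {
      "rule_id": "acid_chloride_hydrolysis",
      "name": "Acid chloride hydrolysis to acid + HCl",
      "family": "acyl_halide",
      "smarts": "[#6:1][C:2](=[O:3])[Cl:4]>>([#6:1][C:2](=[O:3])[OH1].[Cl:4])",
      "atom_class": "X",
      "center_map": 4,
      "environments": ["aquatic"],
      "balance_mode": "hydrolysis",
      "reference": "fast abiotic acyl halide hydrolysis"
    },
    {
      "rule_id": "haloalkane_substitution",
      "name": "Haloalkane hydrolytic substitution to alcohol + halide",
      "family": "haloalkane",
      "smarts": "[CX4:1][Cl,Br,I:2]>>([CX4:1][OH1].[*:2])",
      "atom_class": "X",
      "center_map": 2,
      "environments": ["aquatic", "plant", "animal"],
      "balance_mode": "hydrolysis",
      "reference": "nucleophilic substitution / haloalkane dehalogenase"
    },
    {
      "rule_id": "alkyne_hydration",
      "name": "Terminal alkyne hydration to methyl ketone",
      "family": "alkyne",
      "smarts": "[#6:1][C:2]#[CH1:3]>>[#6:1][C:2](=[O])[C:3]",
      "atom_class": "C",
      "center_map": 2,
      "environments": ["aquatic"],
      "balance_mode": "hydration",
      "reference": "Markovnikov hydration of terminal acetylenes"
    }
  ]
}
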