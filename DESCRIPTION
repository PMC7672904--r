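Package: retroplan
Title: Retrosynthetic Route Planning by Monte Carlo Tree Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A retrosynthetic planning engine that recursively breaks a
    target molecule into purchasable precursors. Search is Monte Carlo tree
    search with upper-confidence-bound selection, guided by a pluggable
    reaction-template ranking policy; stop conditions are supplied by a
    composable stock of purchasable compounds. The package includes
    retro-template application on SMILES/SMARTS chemistry (via an RDKit
    worker process), tabular and fingerprint-classifier policies with a
    desk-scale trainer, route extraction and scoring, per-target search
    statistics, a toy-chemistry fixture generator with a brute-force route
    enumeration oracle, and a YAML-configured batch command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite, yaml, glmnet, Matrix
Suggests: testthat (>= 3.0.0), withr
SystemRequirements: Python (>= 3.8) with the rdkit package, on PATH as
    'python'
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'bridge.R'
    'chem.R'
    'stock.R'
    'policy.R'
    'training.R'
    'search.R'
    'analysis.R'
    'synthetic.R'
    'cli.R'
    'zzz.R'
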