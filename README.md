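# retroplan

Retrosynthetic route planning by Monte Carlo tree search, in R.

Given a target molecule, retrosynthesis asks which simpler precursors it
could be made from, applied recursively until every open compound is
purchasable. `retroplan` implements the full planning stack for this
problem:

* **chem** — molecule parsing/canonicalization (canonical SMILES + InChI-key
  identity), and application of retro-direction reaction-SMARTS templates to
  enumerate precursor sets (RDKit does the pattern matching, driven through a
  persistent worker process; see `SystemRequirements`).
* **stock** — the stop condition: an OR-composition of pluggable
  purchasability queries (in-memory identity-key sets loaded from SMILES
  files, and rule queries such as "fewer than seven carbon atoms").
* **policy** — the template-ranking engine: given a molecule, a probability
  distribution over the template library, shortlisted by cumulative
  probability and count. Built in: a deterministic tabular policy and a
  fingerprint classifier (Morgan fingerprints into a multinomial softmax).
* **training** — fits the fingerprint policy from
  `(product, template_id)` pairs.
* **search** — the planner itself: Monte Carlo tree search over sets of open
  molecules, with upper-confidence-bound selection

  `U = Q + C * sqrt(2 ln n_parent / n_child)`,

  policy-guided expansion, rollout to terminal states, and backpropagation
  of the state score

  `score = 0.95 * f + 0.05 * max(0, 1 - d / d_max)`

  where `f` is the fraction of state molecules in stock and `d` the deepest
  retro depth. A solved state scores at least 0.95; a state with at most
  half its molecules purchasable stays below 0.8.
* **analysis** — route extraction and ranking from a finished tree, route
  JSON serialization, per-target and aggregate search statistics.
* **synthetic** — a toy-chemistry world generator (ester/amide/ether
  couplings over real small-molecule SMILES) with known ground-truth routes,
  plus a brute-force route-enumeration oracle used for validation.
* **cli** — a YAML-configured batch planner (`exec/retroplan` with `plan`,
  `train` and `fixtures` subcommands).

## Worked example

```r
library(retroplan)

world  <- generateToyWorld(nBlocks = 6, depth = 2, seed = 3, nTargets = 3)
stock  <- worldStock(world)
policy <- uniformPolicy(worldTemplates(world))

tree <- mctsSearch(worldTargets(world)$target_smiles[2], policy, stock,
                   searchConfig(iterationLimit = 300))
tree
#> SearchTree for CC(C)OCC(=O)OC(C)C: 300 iterations, first solution at iteration 3 (0.10 s)

extractRoutes(tree, topN = 1)[[1]]
#> Route for CC(C)OCC(=O)OC(C)C: 2 step(s), score 0.983, solved
#>   CC(C)OCC(=O)OC(C)C =[t_ester]=> CC(C)O + CC(C)OCC(=O)O
#>   CC(C)OCC(=O)O =[t_ether]=> CC(C)O + O=C(O)CO

computeStatistics(tree)
#> SearchStatistics for CC(C)OCC(=O)OC(C)C: solved, top route 2 step(s), 3/3 precursors in stock, 300 iterations
```

The target (an isopropyl ester ether) is broken in two retro steps — ester
hydrolysis, then ether cleavage — into three purchasable building blocks;
the route score 0.983 reflects a fully solved state (`f = 1`) two
transforms deep (`0.95 + 0.05 * (1 - 2/6)`). The generator recorded this
target as requiring exactly 2 steps, which the search recovered.

Batch planning from the shell:

```sh
Rscript exec/retroplan fixtures --out fix --seed 1 --depth 2
Rscript exec/retroplan plan --config config.yml --smiles targets.smi --output out
```

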