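---
title: "Planning retrosynthetic routes with Monte Carlo tree search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning retrosynthetic routes with Monte Carlo tree search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The planning problem

Retrosynthesis inverts synthesis: starting from a target molecule, apply
formal reverse reactions (retro-templates) until every remaining compound
is purchasable. `retroplan` treats this as tree search. A *state* is the
set of molecules still on the bench — some already in stock, some open
problems. Applying one retro-template to one open molecule replaces it by a
precursor set and yields a child state. A state is *terminal* when it is
solved (every molecule in stock), when its deepest molecule has consumed
the transform budget, or when no template applies to any expandable
molecule (a dead end).

Three pluggable components close the loop:

* a **stock** answers "is this molecule purchasable" — an OR over
  membership queries (identity-key sets, or rules such as a carbon-count
  bound with a *strict* inequality: fewer than `maxCarbons` carbons);
* a **policy** ranks the template library per molecule and returns a
  probability distribution, shortlisted to the smallest prefix reaching a
  cumulative-probability cutoff and capped in length;
* the **search** explores the state tree under a fixed iteration or
  wall-clock budget.

## The search and its accounting

Selection descends from the root by the UCT rule
`U = Q + C * sqrt(2 ln n_parent / n_child)` over instantiated children
(an unvisited child has infinite bonus; ties fall back to policy rank),
stopping at a terminal node or one that still has untried candidate
reactions. Expansion applies the highest-prior untried template to the
node's expansion molecule; every distinct precursor set becomes its own
concrete candidate (same prior, ordered by canonical SMILES), instantiated
one child per call. Rollout repeats top-prior expansion from the new child
down to a terminal state, and every node created along the way is retained
in the tree; there is no separate rollout policy.

The backpropagated value is the state score

```
score = w_stock * f + w_len * max(0, 1 - d / d_max),   w_stock = 0.95, w_len = 0.05
```

with `f` the in-stock fraction of state molecules and `d` the deepest
retro depth, clamped to [0, 1]. The weights are a design choice anchored to
two qualitative requirements: a fully solved state must score near 1
(at least 0.95 at any admissible depth, exactly 1 for a purchasable target
at depth 0), an unpromising state (at most half solved) must stay below
0.8, and among solved states shorter routes must score strictly higher.

**Visit accounting.** Every node receives exactly one backpropagation at
the moment it is created — its own state score, propagated to the root —
and terminal nodes receive one more each time selection reaches them. Each
backpropagation counts as one iteration. This makes three bookkeeping
identities hold exactly, and the test suite checks them on every tree: the
root's visit count equals the number of iterations; every internal node
satisfies `n = 1 + sum(children n)`; and no molecule in the tree exceeds
`maxTransforms`. A rollout chain of k nodes therefore consumes k
iterations — the iteration budget counts node creations, which also makes
budgets comparable across shallow and deep searches.

**Determinism.** All default tie-breaks are lexicographic: the expansion
molecule is the deepest open molecule with ties by ascending identity key;
equal-probability templates sort by ascending template id; precursor sets
sort by their canonical SMILES. No random draws are made, so an
iteration-limited run is bit-reproducible; the seed is recorded in the
configuration for provenance and for stochastic extensions. Wall-clock
termination (checked once per iteration, and during rollouts) is the one
non-reproducible mode and is excluded from determinism guarantees —
correspondingly, the batch statistics CSV contains only deterministic
columns, and timings live in the per-target route JSON.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `C` | 1.4 | exploration constant; 0 is greedy exploitation |
| `maxTransforms` | 6 | retro-depth budget `d_max` (reactions, longest branch) |
| `iterationLimit` | 100 | iteration budget (one backpropagation each) |
| `timeLimitS` | 120 | wall-clock cap in seconds; first limit reached stops |
| `cutoffNumber` | 50 | policy shortlist length cap |
| `cutoffCumulative` | 0.995 | shortlist probability-mass threshold |

The UCB formula, the exploration constant, the score weights and the
shortlist defaults are this package's own choices; they are configurable
precisely because nothing in the problem fixes them.

## Policies and training

`tabularPolicy` is an explicit molecule-to-distribution table (unknown
molecules fall back to uniform, which keeps a search alive on
intermediates the table never anticipated) and is the reference policy for
reproducibility tests. `fingerprintPolicy` is the learned ranker: folded
Morgan fingerprints (radius 2, 2048 bits) into an L2-regularized
multinomial softmax, fitted by `fitPolicy` via `glmnet` (ridge path,
prediction at lambda = 1e-3). A linear softmax is the smallest model that
honors the policy contract — a sorted probability distribution over the
full library — and on the toy chemistry the classes are separable by
functional group, so it trains in seconds on a desk machine. The fit has
no stochastic component; the `seed` argument is recorded for interface
stability. Deep-network policies are an extension point, not included.

## The synthetic world and what it does (not) show

`generateToyWorld` builds planning problems with known answers from real
chemistry: monofunctional alcohols, amines and carboxylic acids from a
fixed catalogue, composed forward through three valence-safe couplings
(esterification, amide coupling, Williamson-style etherification);
bifunctional linkers (e.g. ethanolamine, glycolic acid, beta-alanine)
carry chains to depth 2 and 3 while keeping exactly one reactive group
free at each step, so forward matches are unambiguous. Because the blocks
are monofunctional and no block contains an ester/amide/ether motif, the
number of cleavable linkages in a target equals its construction depth,
and the recorded `true_min_steps` is the true minimum — independently
confirmed by `oracleEnumerate`, an exhaustive depth-bounded decomposition
with identity-key memoization and an application budget.

Defaults (6 blocks, depth up to 3, 3 targets per world) keep each world
small enough for the oracle to be exhaustive while exercising every
production code path: SMARTS matching, canonicalization, identity keys,
multi-set template outcomes, stock lookups. What passing these tests does
*not* show: performance on drug-like molecules, on noisy
template libraries extracted from reaction corpora, or with
million-compound stocks — the toy templates are clean, never conflict,
and always regenerate their forward couplings, none of which holds for
real reaction data.

## Numerical and degenerate-input choices

* Template outcomes failing sanitization are dropped silently and counted
  (`chemDiagnostics`); off-target matches routinely produce invalid
  valences and must not abort a search.
* Precursor sets containing the target itself are discarded (self-loop
  guard); symmetric match sites are deduplicated by identity-key sets.
* Stereochemistry is left to the generic reaction engine; templates that
  create or destroy stereocenters are applied as written, with no
  chirality propagation. The toy chemistry is achiral.
* A target already in stock terminates the search after one iteration with
  score 1; `iterationLimit = 0` returns the unexpanded root. An inert
  target (no matching template) becomes a terminal dead end scoring only
  the depth term.
* A molecule's identity key is its InChI key; if the InChI backend is
  unavailable the canonical SMILES (prefixed) is used instead, preserving
  exact-membership semantics.
* One `RetroReaction` may carry several alternative precursor sets; the
  search tree splits each set into its own child so that visit statistics
  attach to concrete outcomes.

## Implementation note: the chemistry worker

No R package applies reaction SMARTS, so the chem module drives RDKit — the
toolkit of record for template chemistry — through a persistent local
worker process speaking line-delimited JSON over a localhost socket,
started lazily and restarted transparently. Round trips are microseconds;
results are memoized in R, so search-scale call volumes are cheap. All
chemistry results consumed by the planner pass through this one interface.

## Known limitations

No transposition handling (identical states reached via different template
orders are distinct children); no reaction-feasibility filter; no separate
rollout policy; single-threaded search; Mongo-style database stock queries
are an interface point only. Problem sizes in the tests and the acceptance
script (20 worlds, depth 3, 500 iterations) are the package's validation
scale, chosen so the brute-force oracle remains exhaustive.
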