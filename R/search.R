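#' @include training.R
NULL

# ---- configuration --------------------------------------------------------

#' Search configuration
#'
#' @param C Exploration constant of the upper-confidence-bound rule
#'   (non-negative; 0 is pure exploitation).
#' @param maxTransforms Maximum retro-reaction depth; a state whose deepest
#'   molecule reaches this depth is terminal.
#' @param iterationLimit Maximum number of search iterations (one
#'   backpropagation each).
#' @param timeLimitS Wall-clock cap in seconds, checked once per iteration;
#'   the search stops at whichever limit is hit first.
#' @param seed RNG seed, recorded with the run. Default tie-breaks are all
#'   lexicographic, so iteration-limited runs are seed-independent.
#' @param policyConfig A [policyConfig()] controlling template
#'   shortlisting at each expansion.
#' @return A `SearchConfig` object.
#' @export
searchConfig <- function(C = 1.4, maxTransforms = 6L, iterationLimit = 100L,
                         timeLimitS = 120, seed = 1L,
                         policyConfig = retroplan::policyConfig()) {
  stopifnot(C >= 0, maxTransforms >= 1L, iterationLimit >= 0L, timeLimitS > 0)
  new("SearchConfig", explorationConstant = C,
      maxTransforms = as.integer(maxTransforms),
      iterationLimit = as.integer(iterationLimit), timeLimitS = timeLimitS,
      seed = as.integer(seed), policyConfig = policyConfig)
}

#' @rdname searchConfig
#' @slot explorationConstant Exploration constant of the UCB rule.
#' @slot maxTransforms Maximum retro-reaction depth.
#' @slot iterationLimit Iteration cap.
#' @slot timeLimitS Wall-clock cap (seconds).
#' @slot seed Recorded RNG seed.
#' @slot policyConfig Shortlist settings.
#' @export
setClass("SearchConfig", representation(
  explorationConstant = "numeric", maxTransforms = "integer",
  iterationLimit = "integer",
  timeLimitS = "numeric", seed = "integer", policyConfig = "PolicyConfig"))

# ---- state score ----------------------------------------------------------

#' Score of a search state
#'
#' The state value that is backpropagated: a weighted sum of the fraction
#' of state molecules that are in stock and a depth penalty,
#' `0.95 * f + 0.05 * max(0, 1 - d / maxTransforms)`, clamped to `[0, 1]`.
#' A purchasable target at depth 0 scores exactly 1; a fully solved state at
#' any admissible depth scores at least 0.95; states with at most half the
#' molecules in stock stay below 0.8.
#'
#' @param inStockFraction Fraction `f` of state molecules in stock, in
#'   `[0, 1]`.
#' @param depth Number of retro-reactions on the deepest branch of the
#'   state.
#' @param maxTransforms The search's maximum depth `d_max`.
#' @return A score in `[0, 1]`.
#' @export
stateScore <- function(inStockFraction, depth, maxTransforms) {
  stopifnot(maxTransforms >= 1)
  s <- 0.95 * inStockFraction + 0.05 * pmax(0, 1 - depth / maxTransforms)
  pmin(1, pmax(0, s))
}

.scoreState <- function(state, maxTransforms) {
  stateScore(mean(state$inStock), state$maxDepth, maxTransforms)
}

# ---- node internals -------------------------------------------------------

# A search node is a mutable environment:
#   state    list(smiles, keys, depths, inStock, solved, maxDepth)
#   n, W     visit count and accumulated value
#   parent   parent node env or NULL
#   children list of node envs, in creation (= policy-rank) order
#   cand     candidate list (NULL until first expansion), each candidate
#            list(templateId, prior, status, reactants?) with status
#            "untried" (template not yet applied), "ready" (one concrete
#            precursor set awaiting instantiation), "dead", "done"
#   candMolIdx index of the state molecule the candidates apply to
#   terminal / deadEnd flags
#   reaction list(templateId, productSmiles, productKey, precursors) that
#            created this node (NULL at root)

.makeState <- function(smiles, keys, depths, inStock) {
  list(smiles = smiles, keys = keys, depths = as.integer(depths),
       inStock = inStock, solved = all(inStock),
       maxDepth = if (length(depths)) max(as.integer(depths)) else 0L)
}

.stateTerminal <- function(state, maxTransforms) {
  if (state$solved) return(TRUE)
  if (state$maxDepth >= maxTransforms) return(TRUE)
  # dead by construction: nothing expandable below the depth cap
  !any(!state$inStock & state$depths < maxTransforms)
}

.makeNode <- function(state, parent, config, reaction = NULL) {
  node <- new.env(parent = emptyenv())
  node$state <- state
  node$n <- 0L
  node$W <- 0
  node$parent <- parent
  node$children <- list()
  node$cand <- NULL
  node$candMolIdx <- NA_integer_
  node$terminal <- .stateTerminal(state, config@maxTransforms)
  node$deadEnd <- FALSE
  node$reaction <- reaction
  class(node) <- c("SearchNode", "environment")
  node
}

#' Node accessors
#'
#' Read-only views of a search node: visit count, accumulated value, mean
#' value, children, terminal flag and state summary.
#'
#' @param node A `SearchNode` (as found in a [SearchTree-class]).
#' @return `nodeVisits`/`nodeValue` scalars; `nodeMeanValue` W/n (NA when
#'   unvisited); `nodeChildren` list of child nodes; `nodeIsTerminal`
#'   logical; `nodeState` the state record (SMILES, depths, in-stock
#'   flags, solved flag).
#' @export
nodeVisits <- function(node) node$n

#' @rdname nodeVisits
#' @export
nodeValue <- function(node) node$W

#' @rdname nodeVisits
#' @export
nodeMeanValue <- function(node) if (node$n >= 1L) node$W / node$n else NA_real_

#' @rdname nodeVisits
#' @export
nodeChildren <- function(node) node$children

#' @rdname nodeVisits
#' @export
nodeIsTerminal <- function(node) node$terminal

#' @rdname nodeVisits
#' @export
nodeState <- function(node) node$state

# which state molecule does this node expand? deepest expandable, ties by
# ascending identity key; NA when none
.expansionMolIdx <- function(state, maxTransforms) {
  ok <- which(!state$inStock & state$depths < maxTransforms)
  if (!length(ok)) return(NA_integer_)
  ok <- ok[order(-state$depths[ok], state$keys[ok], method = "radix")]
  ok[[1]]
}

.ensureCandidates <- function(node, policy, config) {
  if (!is.null(node$cand)) return(invisible(NULL))
  idx <- .expansionMolIdx(node$state, config@maxTransforms)
  if (is.na(idx)) { node$cand <- list(); return(invisible(NULL)) }
  node$candMolIdx <- idx
  pred <- predictTemplates(policy, parseMolecule(node$state$smiles[idx]))
  short <- shortlistPrediction(pred, config@policyConfig)
  node$cand <- lapply(seq_len(nrow(short)), function(i) {
    list(templateId = short$templateId[i], prior = short$probability[i],
         status = "untried")
  })
  invisible(NULL)
}

.hasUntriedCandidates <- function(node) {
  if (is.null(node$cand)) return(TRUE)  # not yet computed
  any(vapply(node$cand, function(c) c$status %in% c("untried", "ready"), logical(1)))
}

# instantiate the child for one concrete (template, precursor-set) candidate
.instantiateChild <- function(node, ci, policy, stock, config) {
  cand <- node$cand[[ci]]
  idx <- node$candMolIdx
  st <- node$state
  precs <- cand$reactants                 # list of Molecule
  pSmiles <- vapply(precs, smiles, character(1))
  pKeys <- vapply(precs, identityKey, character(1))
  pDepth <- rep(st$depths[idx] + 1L, length(precs))
  pStock <- vapply(precs, function(m) inStock(stock, m), logical(1))
  keep <- setdiff(seq_along(st$smiles), idx)
  state <- .makeState(c(st$smiles[keep], pSmiles),
                      c(st$keys[keep], pKeys),
                      c(st$depths[keep], pDepth),
                      c(st$inStock[keep], pStock))
  reaction <- list(templateId = cand$templateId,
                   productSmiles = st$smiles[idx], productKey = st$keys[idx],
                   precursorSmiles = pSmiles, precursorKeys = pKeys,
                   prior = cand$prior)
  child <- .makeNode(state, node, config, reaction)
  node$cand[[ci]]$status <- "done"
  node$children[[length(node$children) + 1L]] <- child
  child
}

#' Expand a search node by one child
#'
#' Walks the node's shortlisted candidate reactions in priority order
#' (prior descending, shortlist order): the first untried template is
#' applied to the node's expansion molecule (the deepest not-in-stock
#' molecule, ties by ascending identity key); each resulting precursor set
#' becomes a concrete candidate, and the highest-priority one is
#' instantiated as a new child node with zero visits. Templates that yield
#' no outcome are marked dead and skipped. When every candidate is dead and
#' the node has no children, it is marked terminal (a dead end).
#'
#' @param node A non-terminal `SearchNode`.
#' @param policy A loaded [Policy-class].
#' @param stock A [Stock-class].
#' @param config A [searchConfig()].
#' @return The new child node, or `NULL` when no child could be created.
#' @export
expandNode <- function(node, policy, stock, config) {
  if (node$terminal) return(NULL)
  .ensureCandidates(node, policy, config)
  if (!length(node$cand)) {
    if (!length(node$children)) { node$terminal <- TRUE; node$deadEnd <- TRUE }
    return(NULL)
  }
  tmplById <- policy@templates
  repeat {
    stat <- vapply(node$cand, function(c) c$status, character(1))
    ci <- which(stat %in% c("untried", "ready"))[1]
    if (is.na(ci)) {
      if (!length(node$children)) { node$terminal <- TRUE; node$deadEnd <- TRUE }
      return(NULL)
    }
    cand <- node$cand[[ci]]
    if (cand$status == "ready") return(.instantiateChild(node, ci, policy, stock, config))
    # untried template: apply it now
    tmpl <- tmplById[[cand$templateId]]
    target <- parseMolecule(node$state$smiles[node$candMolIdx])
    sets <- applyTemplate(tmpl, target)
    if (!length(sets)) {
      node$cand[[ci]]$status <- "dead"
      next
    }
    # one concrete candidate per precursor set, deterministic order
    sig <- vapply(sets, function(s) paste(vapply(s, smiles, character(1)), collapse = "."),
                  character(1))
    sets <- sets[order(sig, method = "radix")]
    concrete <- lapply(sets, function(s) {
      list(templateId = cand$templateId, prior = cand$prior,
           status = "ready", reactants = s)
    })
    node$cand <- append(node$cand[-ci], concrete, after = ci - 1L)
  }
}

# ---- selection ------------------------------------------------------------

.ucbScore <- function(parentN, child, C) {
  if (child$n == 0L) return(Inf)
  q <- child$W / child$n
  if (C == 0 || parentN <= 0L) return(q)
  q + C * sqrt(2 * log(parentN) / child$n)
}

#' Select the most promising leaf by upper confidence bound
#'
#' Descends from the root, at each step moving to the instantiated child
#' maximizing `U = Q + C * sqrt(2 * ln(n_parent) / n_child)` (an unvisited
#' child has `U = +Inf`; ties are broken by creation order, i.e. policy
#' rank). Descent stops at a node that is terminal or still has untried
#' candidate reactions.
#'
#' @param tree A [SearchTree-class] or a root `SearchNode`.
#' @param C Exploration constant.
#' @return The selected `SearchNode`.
#' @export
selectLeaf <- function(tree, C = 1.4) {
  node <- if (is(tree, "SearchTree")) tree@root else tree
  repeat {
    if (node$terminal) return(node)
    if (.hasUntriedCandidates(node)) return(node)
    kids <- node$children
    if (!length(kids)) return(node)
    best <- 1L; bestU <- -Inf
    for (i in seq_along(kids)) {
      u <- .ucbScore(node$n, kids[[i]], C)
      if (u > bestU) { bestU <- u; best <- i }
      if (is.infinite(bestU)) break       # first unvisited wins ties
    }
    node <- kids[[best]]
  }
}

# ---- backpropagation ------------------------------------------------------

#' Backpropagate a leaf score to the root
#'
#' Increments the visit count and adds `score` to the accumulated value of
#' every node on the leaf-to-root path.
#'
#' @param leaf A `SearchNode`.
#' @param score A value in `[0, 1]`.
#' @return Invisibly, the number of nodes updated.
#' @export
backpropagate <- function(leaf, score) {
  stopifnot(score >= 0, score <= 1)
  node <- leaf
  k <- 0L
  while (!is.null(node)) {
    node$n <- node$n + 1L
    node$W <- node$W + score
    node <- node$parent
    k <- k + 1L
  }
  invisible(k)
}

# ---- rollout --------------------------------------------------------------

#' Roll out from a node to a terminal state
#'
#' Repeatedly expands the current node along its top-prior applicable
#' reaction (the same policy as expansion — there is no separate rollout
#' policy) until the state is terminal: solved, at the depth cap, or a dead
#' end. All nodes created during the rollout are retained in the tree.
#'
#' @param node Starting `SearchNode`.
#' @param policy,stock,config As in [mctsSearch()].
#' @param onStep Optional callback invoked with each newly created node
#'   (used by the search loop to backpropagate and count iterations);
#'   returning `FALSE` stops the rollout early.
#' @return The terminal (or last-created) `SearchNode`.
#' @export
rolloutNode <- function(node, policy, stock, config, onStep = NULL) {
  cur <- node
  while (!cur$terminal) {
    nxt <- expandNode(cur, policy, stock, config)
    if (is.null(nxt)) break                # dead end: cur flagged terminal
    if (!is.null(onStep) && identical(onStep(nxt), FALSE)) return(nxt)
    cur <- nxt
  }
  cur
}

# ---- the search -----------------------------------------------------------

#' SearchTree: a finished Monte Carlo tree search
#'
#' @slot root The root `SearchNode` (mutable environment; traverse with
#'   [nodeChildren()]).
#' @slot target The target [Molecule-class].
#' @slot config The [searchConfig()] used.
#' @slot iterationsRun Completed iterations (equals the root's visit
#'   count).
#' @slot firstSolutionIteration Iteration at which the first solved state
#'   appeared (`NA` when unsolved).
#' @slot firstSolutionTimeS Wall-clock seconds to the first solved state
#'   (`NA` when unsolved).
#' @slot elapsedS Total wall-clock seconds of the search.
#' @export
setClass("SearchTree", representation(
  root = "ANY", target = "Molecule", config = "SearchConfig",
  iterationsRun = "integer", firstSolutionIteration = "integer",
  firstSolutionTimeS = "numeric", elapsedS = "numeric"))

#' @describeIn mctsSearch Number of completed iterations of a finished
#'   search.
#' @param tree A `SearchTree`.
#' @export
iterationsRun <- function(tree) tree@iterationsRun

#' @describeIn mctsSearch Was any solved state found?
#' @export
isSolved <- function(tree) !is.na(tree@firstSolutionIteration)

setMethod("show", "SearchTree", function(object) {
  cat(sprintf("SearchTree for %s: %d iterations, %s (%.2f s)\n",
              object@target@smiles, object@iterationsRun,
              if (isSolved(object))
                sprintf("first solution at iteration %d", object@firstSolutionIteration)
              else "unsolved",
              object@elapsedS))
})

#' Plan retrosynthetic routes with Monte Carlo tree search
#'
#' Runs the full search for one target: iterated leaf selection by upper
#' confidence bound, expansion through the template-ranking policy, rollout
#' to a terminal state, and backpropagation of the state score, until the
#' iteration limit or the wall-clock limit is reached. Every created node
#' is backpropagated exactly once at creation (its own state score) and
#' terminal nodes are re-scored each time selection reaches them; each
#' backpropagation counts as one iteration, so the root's visit count
#' equals the number of iterations and visit counts are conserved across
#' the tree.
#'
#' With a deterministic policy and iteration-limited termination the search
#' is fully reproducible: all tie-breaks are lexicographic and no random
#' draws are made.
#'
#' @param target A [Molecule-class] or SMILES string.
#' @param policy A loaded [Policy-class].
#' @param stock A [Stock-class].
#' @param config A [searchConfig()].
#' @return A [SearchTree-class].
#' @export
mctsSearch <- function(target, policy, stock, config = searchConfig()) {
  if (is.character(target)) target <- parseMolecule(target)
  stopifnot(is(target, "Molecule"), is(policy, "Policy"), is(stock, "Stock"))
  .checkLoaded(policy)
  t0 <- Sys.time()
  rootState <- .makeState(target@smiles, target@key, 0L, inStock(stock, target))
  root <- .makeNode(rootState, NULL, config)
  iter <- 0L
  firstIter <- NA_integer_
  firstTime <- NA_real_
  limit <- config@iterationLimit
  bump <- function(node) {
    backpropagate(node, .scoreState(node$state, config@maxTransforms))
    iter <<- iter + 1L
    if (node$state$solved && is.na(firstIter)) {
      firstIter <<- iter
      firstTime <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    }
    iter < limit
  }
  timeOk <- function() as.numeric(difftime(Sys.time(), t0, units = "secs")) < config@timeLimitS
  if (limit >= 1L) {
    bump(root)
    # a terminal root (in stock, or inert) cannot be explored further
    while (iter < limit && timeOk() && !root$terminal) {
      leaf <- selectLeaf(root, config@explorationConstant)
      if (leaf$terminal) { bump(leaf); next }
      child <- expandNode(leaf, policy, stock, config)
      if (is.null(child)) {
        # leaf just became a childless dead end, or exhausted its last
        # candidate while keeping children; only the former is an endpoint
        if (leaf$terminal) bump(leaf)
        next
      }
      if (!bump(child)) break
      rolloutNode(child, policy, stock, config,
                  onStep = function(n) bump(n) && timeOk())
    }
  }
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  new("SearchTree", root = root, target = target, config = config,
      iterationsRun = iter, firstSolutionIteration = firstIter,
      firstSolutionTimeS = firstTime, elapsedS = elapsed)
}
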