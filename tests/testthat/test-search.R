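test_that("the state score blends stock fraction and depth penalty", {
  expect_equal(stateScore(1, 0, 6), 1.0)
  expect_equal(stateScore(1, 3, 6), 0.975)   # 0.95 + 0.05 * 0.5
  expect_equal(stateScore(0, 6, 6), 0)
  expect_equal(stateScore(0.5, 8, 6), 0.475) # penalty floors at zero
  grid <- expand.grid(f = seq(0, 1, 0.1), d = 0:8)
  s <- stateScore(grid$f, grid$d, 6)
  expect_true(all(s >= 0 & s <= 1))
})

test_that("UCB selection trades off value and visits", {
  mkNode <- function(n, W, parent = NULL) {
    e <- new.env(); e$n <- n; e$W <- W; e$parent <- parent
    e$children <- list(); e$cand <- list(); e$terminal <- FALSE
    e$state <- list(); e
  }
  parent <- mkNode(11L, 0)
  a <- mkNode(10L, 8)   # Q = 0.8, heavily visited
  b <- mkNode(1L, 0.5)  # Q = 0.5, barely visited
  parent$children <- list(a, b)
  a$terminal <- TRUE; b$terminal <- TRUE
  # U(a) = 0.8 + 1.4 * sqrt(2 ln 11 / 10) = 1.77 < U(b) = 3.57
  expect_identical(selectLeaf(parent, C = 1.4), b)
  # C = 0 is pure exploitation
  expect_identical(selectLeaf(parent, C = 0), a)
  # an unvisited child has infinite bonus
  c0 <- mkNode(0L, 0); c0$terminal <- TRUE
  parent$children <- list(a, c0)
  expect_identical(selectLeaf(parent, C = 1.4), c0)
})

test_that("backpropagation increments the whole path", {
  mk <- function(parent) {
    e <- new.env(); e$n <- 0L; e$W <- 0; e$parent <- parent; e$children <- list(); e
  }
  root <- mk(NULL); mid <- mk(root); leaf <- mk(mid)
  backpropagate(leaf, 0.9)
  for (nd in list(root, mid, leaf)) {
    expect_equal(nd$n, 1L)
    expect_equal(nd$W, 0.9)
  }
  backpropagate(root, 0.5)
  expect_equal(root$n, 2L)
  expect_equal(root$W, 1.4)
  expect_equal(nodeMeanValue(root), 0.7)
})

test_that("expansion follows prior order and discards dead candidates", {
  w <- toyWorldCached(seed = 2, depth = 1, nTargets = 2)
  stock <- worldStock(w)
  cfg <- searchConfig(iterationLimit = 10)
  target <- worldTargets(w)$target_smiles[1]
  trueTid <- w@routes[[1]][[1]]$templateId
  # bias the policy towards the correct template
  probs <- stats::setNames(rep(0.05, 3), names(worldTemplates(w)))
  probs[trueTid] <- 0.9
  pol <- tabularPolicy(worldTemplates(w), stats::setNames(list(probs), target))
  root <- retroplan:::.makeNode(
    retroplan:::.makeState(smiles(parseMolecule(target)),
                           identityKey(parseMolecule(target)), 0L, FALSE),
    NULL, cfg)
  child <- expandNode(root, pol, stock, cfg)
  expect_false(is.null(child))
  expect_identical(child$reaction$templateId, trueTid)
  expect_equal(child$n, 0L)
})

test_that("a target matched by no template becomes a terminal dead end", {
  w <- toyWorldCached()
  pol <- uniformPolicy(worldTemplates(w))
  stock <- worldStock(w)
  cfg <- searchConfig(iterationLimit = 10)
  tree <- mctsSearch("c1ccccc1CCCCCCCl", pol, stock, cfg)  # inert target
  expect_false(isSolved(tree))
  expect_true(tree@root$terminal)
  expect_length(nodeChildren(tree@root), 0)
  # dead-end score: f = 0, d = 0 -> only the length term
  expect_equal(nodeMeanValue(tree@root), stateScore(0, 0, cfg@maxTransforms))
})

test_that("rollout walks top-prior reactions down to a terminal state", {
  w <- toyWorldCached(seed = 6, depth = 2, nTargets = 3)
  pol <- uniformPolicy(worldTemplates(w))
  stock <- worldStock(w)
  cfg <- searchConfig(iterationLimit = 100)
  i <- which(worldTargets(w)$true_min_steps == 2)[1]
  target <- parseMolecule(worldTargets(w)$target_smiles[i])
  root <- retroplan:::.makeNode(
    retroplan:::.makeState(smiles(target), identityKey(target), 0L,
                           inStock(stock, target)),
    NULL, cfg)
  end <- rolloutNode(root, pol, stock, cfg)
  expect_true(end$terminal)
  # a rollout from an already-terminal node returns it unchanged
  expect_identical(rolloutNode(end, pol, stock, cfg), end)
})

test_that("an in-stock target terminates immediately with score 1", {
  w <- toyWorldCached()
  pol <- uniformPolicy(worldTemplates(w))
  stock <- worldStock(w)
  tree <- mctsSearch(w@stockSmiles[1], pol, stock,
                     searchConfig(iterationLimit = 50))
  expect_true(isSolved(tree))
  expect_equal(tree@firstSolutionIteration, 1L)
  expect_length(nodeChildren(tree@root), 0)
  expect_equal(nodeMeanValue(tree@root), 1.0)
})

test_that("a zero-iteration run returns the unexpanded root", {
  w <- toyWorldCached()
  pol <- uniformPolicy(worldTemplates(w))
  stock <- worldStock(w)
  tree <- mctsSearch(worldTargets(w)$target_smiles[1], pol, stock,
                     searchConfig(iterationLimit = 0))
  expect_equal(iterationsRun(tree), 0L)
  expect_equal(nodeVisits(tree@root), 0L)
  expect_false(isSolved(tree))
  expect_length(nodeChildren(tree@root), 0)
})

test_that("searches solve toy targets at the oracle's minimum depth", {
  w <- toyWorldCached(seed = 11, depth = 2, nTargets = 3)
  pol <- uniformPolicy(worldTemplates(w))
  stock <- worldStock(w)
  cfg <- searchConfig(iterationLimit = 200)
  for (i in seq_len(nrow(worldTargets(w)))) {
    target <- worldTargets(w)$target_smiles[i]
    tree <- mctsSearch(target, pol, stock, cfg)
    expect_true(isSolved(tree))
    top <- extractRoutes(tree, 1)[[1]]
    oracle <- oracleEnumerate(target, worldTemplates(w), stock, maxDepth = 3)
    expect_true(routeIsSolved(top))
    expect_equal(routeLength(top), oracle[[1]]$nSteps)
  }
})

test_that("visit counts are conserved and the depth bound holds", {
  cfg <- searchConfig(iterationLimit = 300, maxTransforms = 3)
  for (seed in c(3, 9)) {
    w <- toyWorldCached(seed = seed, depth = 3, nTargets = 2)
    pol <- uniformPolicy(worldTemplates(w))
    stock <- worldStock(w)
    for (target in worldTargets(w)$target_smiles) {
      tree <- mctsSearch(target, pol, stock, cfg)
      expect_equal(nodeVisits(tree@root), iterationsRun(tree))
      expect_true(visitConservationHolds(tree@root))
      expect_lte(maxTreeMoleculeDepth(tree@root), cfg@maxTransforms)
      if (isSolved(tree))
        expect_lte(tree@firstSolutionIteration, iterationsRun(tree))
    }
  }
})

test_that("iteration-limited searches are reproducible node for node", {
  w <- toyWorldCached(seed = 8, depth = 2, nTargets = 2)
  pol <- uniformPolicy(worldTemplates(w))
  stock <- worldStock(w)
  cfg <- searchConfig(iterationLimit = 150, seed = 123)
  t1 <- mctsSearch(worldTargets(w)$target_smiles[1], pol, stock, cfg)
  t2 <- mctsSearch(worldTargets(w)$target_smiles[1], pol, stock, cfg)
  expect_true(treesIdentical(t1@root, t2@root))
})

test_that("shorter solved routes score strictly higher", {
  expect_true(stateScore(1, 1, 6) > stateScore(1, 2, 6))
  expect_true(stateScore(1, 2, 6) > stateScore(1, 5, 6))
})
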