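test_that("an in-stock target yields a single zero-step route", {
  w <- toyWorldCached()
  pol <- uniformPolicy(worldTemplates(w))
  stock <- worldStock(w)
  tree <- mctsSearch(w@stockSmiles[1], pol, stock, searchConfig(iterationLimit = 20))
  routes <- extractRoutes(tree, 5)
  expect_length(routes, 1)
  expect_equal(routeLength(routes[[1]]), 0)
  expect_equal(routeScore(routes[[1]]), 1.0)
  expect_true(routeIsSolved(routes[[1]]))
  stats <- computeStatistics(tree)
  expect_equal(stats@nSteps, 0L)
  expect_equal(stats@nPrecursors, 1L)
  expect_equal(stats@nPrecursorsInStock, 1L)
})

test_that("a solved two-step tree ranks a solved two-step route first", {
  w <- toyWorldCached(seed = 6, depth = 2, nTargets = 3)
  pol <- uniformPolicy(worldTemplates(w))
  stock <- worldStock(w)
  i <- which(worldTargets(w)$true_min_steps == 2)[1]
  tree <- mctsSearch(worldTargets(w)$target_smiles[i], pol, stock,
                     searchConfig(iterationLimit = 300))
  routes <- extractRoutes(tree, 10)
  top <- routes[[1]]
  expect_true(routeIsSolved(top))
  expect_equal(routeLength(top), 2)
  expect_true(all(routePrecursors(top)$inStock))
  # ranking is by score, best first
  scores <- vapply(routes, routeScore, numeric(1))
  expect_true(all(diff(scores) <= 1e-12))
  # truncation
  expect_length(extractRoutes(tree, 1), 1)
})

test_that("routes reconstruct: re-applying each step recovers its precursors", {
  w <- toyWorldCached(seed = 12, depth = 2, nTargets = 2)
  pol <- uniformPolicy(worldTemplates(w))
  stock <- worldStock(w)
  tree <- mctsSearch(worldTargets(w)$target_smiles[1], pol, stock,
                     searchConfig(iterationLimit = 200))
  for (route in extractRoutes(tree, 3)) {
    for (step in route@steps) {
      sets <- applyTemplate(worldTemplates(w)[[step$templateId]],
                            step$productSmiles)
      sigs <- vapply(sets, function(s)
        paste(sort(vapply(s, smiles, character(1))), collapse = "."),
        character(1))
      expect_true(paste(sort(step$precursorSmiles), collapse = ".") %in% sigs)
    }
  }
})

test_that("the top route's score is the best end-node state score", {
  w <- toyWorldCached(seed = 13, depth = 2, nTargets = 2)
  pol <- uniformPolicy(worldTemplates(w))
  stock <- worldStock(w)
  tree <- mctsSearch(worldTargets(w)$target_smiles[2], pol, stock,
                     searchConfig(iterationLimit = 250))
  ends <- retroplan:::.collectEndNodes(tree@root)
  best <- max(vapply(ends, function(n)
    retroplan:::.scoreState(n$state, tree@config@maxTransforms), numeric(1)))
  expect_equal(routeScore(extractRoutes(tree, 1)[[1]]), best)
})

test_that("route serialization nests molecules and reactions", {
  w <- toyWorldCached(seed = 6, depth = 2, nTargets = 3)
  pol <- uniformPolicy(worldTemplates(w))
  stock <- worldStock(w)
  tree <- mctsSearch(worldTargets(w)$target_smiles[1], pol, stock,
                     searchConfig(iterationLimit = 150))
  top <- extractRoutes(tree, 1)[[1]]
  lst <- routeToList(top, stock)
  expect_equal(lst$type, "mol")
  expect_equal(lst$smiles, tree@target@smiles)
  countReactions <- function(node) {
    if (node$type == "reaction")
      return(1L + sum(vapply(node$children, countReactions, integer(1))))
    if (length(node$children))
      return(sum(vapply(node$children, countReactions, integer(1))))
    0L
  }
  expect_equal(countReactions(lst), routeLength(top))
})

test_that("statistics distinguish unsolved runs and aggregate correctly", {
  w <- toyWorldCached()
  pol <- uniformPolicy(worldTemplates(w))
  stock <- worldStock(w)
  bad <- mctsSearch("c1ccccc1CCCCCCCl", pol, stock, searchConfig(iterationLimit = 5))
  s <- computeStatistics(bad)
  expect_false(s@isSolved)
  expect_true(is.na(s@firstSolutionIteration))
  good <- computeStatistics(
    mctsSearch(worldTargets(w)$target_smiles[1], pol, stock,
               searchConfig(iterationLimit = 150)))
  df <- rbind(statisticsRow(s), statisticsRow(good))
  agg <- aggregateStatistics(df)
  expect_equal(agg$n_targets, 2)
  expect_equal(agg$n_solved, 1)
  expect_equal(agg$solved_fraction, 0.5)
  # success-conditional means use the solved subset only
  expect_equal(agg$mean_steps_solved, good@nSteps)
  expect_lte(df$n_precursors_in_stock[1], df$n_precursors[1])
})
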