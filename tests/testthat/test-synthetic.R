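test_that("depth-1 worlds are solvable in exactly one retro step", {
  w <- toyWorldCached(seed = 21, depth = 1, nTargets = 4)
  expect_true(all(worldTargets(w)$true_min_steps == 1L))
  stock <- worldStock(w)
  for (i in seq_len(nrow(worldTargets(w)))) {
    oracle <- oracleEnumerate(worldTargets(w)$target_smiles[i],
                              worldTemplates(w), stock, maxDepth = 2)
    expect_equal(oracle[[1]]$nSteps, 1L)
  }
})

test_that("world generation is deterministic per seed", {
  a <- generateToyWorld(nBlocks = 6, depth = 3, seed = 17, nTargets = 3)
  b <- generateToyWorld(nBlocks = 6, depth = 3, seed = 17, nTargets = 3)
  expect_identical(worldTargets(a), worldTargets(b))
  expect_identical(a@stockSmiles, b@stockSmiles)
  expect_identical(a@routes, b@routes)
  c <- generateToyWorld(nBlocks = 6, depth = 3, seed = 18, nTargets = 3)
  expect_false(identical(worldTargets(a), worldTargets(c)))
})

test_that("recorded minimum steps stay within the requested depth", {
  w <- toyWorldCached(seed = 22, depth = 3, nTargets = 5)
  expect_true(all(worldTargets(w)$true_min_steps >= 1L))
  expect_true(all(worldTargets(w)$true_min_steps <= 3L))
})

test_that("the oracle agrees with the generator's recorded minimum", {
  for (seed in c(1, 5, 14)) {
    w <- toyWorldCached(seed = seed, depth = 3, nTargets = 3)
    stock <- worldStock(w)
    for (i in seq_len(nrow(worldTargets(w)))) {
      oracle <- oracleEnumerate(worldTargets(w)$target_smiles[i],
                                worldTemplates(w), stock, maxDepth = 4)
      expect_gt(length(oracle), 0)
      expect_equal(oracle[[1]]$nSteps, worldTargets(w)$true_min_steps[i])
    }
  }
})

test_that("retro templates recover every recorded forward coupling", {
  for (seed in c(2, 7)) {
    w <- toyWorldCached(seed = seed, depth = 3, nTargets = 3)
    for (step in worldTriples(w)) {
      sets <- applyTemplate(worldTemplates(w)[[step$templateId]],
                            step$productSmiles)
      sigs <- vapply(sets, function(s)
        paste(sort(vapply(s, smiles, character(1))), collapse = "."),
        character(1))
      expect_true(paste(sort(step$precursorSmiles), collapse = ".") %in% sigs)
    }
  }
})

test_that("the oracle returns nothing for unreachable molecules", {
  w <- toyWorldCached()
  oracle <- oracleEnumerate("c1ccccc1", worldTemplates(w), worldStock(w),
                            maxDepth = 3)
  expect_length(oracle, 0)
})

test_that("the oracle honors its application budget", {
  w <- toyWorldCached(seed = 22, depth = 3, nTargets = 5)
  deep <- worldTargets(w)$target_smiles[which.max(worldTargets(w)$true_min_steps)]
  expect_error(
    oracleEnumerate(deep, worldTemplates(w), worldStock(w), maxDepth = 4,
                    nodeCap = 2),
    class = "oracleBudgetError")
})

test_that("an in-stock target has one zero-step oracle route", {
  w <- toyWorldCached()
  oracle <- oracleEnumerate(w@stockSmiles[1], worldTemplates(w), worldStock(w),
                            maxDepth = 2)
  expect_length(oracle, 1)
  expect_equal(oracle[[1]]$nSteps, 0L)
})

test_that("world files round-trip through the planner's loaders", {
  dir <- withr::local_tempdir()
  w <- toyWorldCached(seed = 5)
  paths <- writeWorldFiles(w, dir)
  lib <- loadTemplateLibrary(paths$templates)
  expect_named(lib, names(worldTemplates(w)))
  q <- smilesFileQuery(paths$stock)
  expect_equal(q@size, length(w@stockSmiles))
  tg <- read.csv(paths$targets)
  expect_equal(tg$target_smiles, worldTargets(w)$target_smiles)
})
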