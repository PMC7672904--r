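# Shared fixtures, memoized across test files to keep the suite fast.

.fixtures <- new.env(parent = emptyenv())

toyWorldCached <- function(seed = 1L, depth = 2L, nBlocks = 6L, nTargets = 3L) {
  key <- sprintf("world-%d-%d-%d-%d", seed, depth, nBlocks, nTargets)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generateToyWorld(nBlocks = nBlocks, depth = depth,
                                         seed = seed, nTargets = nTargets)
  .fixtures[[key]]
}

toyTemplatesCached <- function() {
  worldTemplates(toyWorldCached())
}

amideTemplate <- function() {
  if (is.null(.fixtures$amide))
    .fixtures$amide <- retroTemplate(
      "t_amide",
      "[C:1](=[O:2])[NX3;H1:3][CX4:4]>>[C:1](=[O:2])[OH].[NX3;H2:3][C:4]")
  .fixtures$amide
}

trainedPolicyCached <- function() {
  if (is.null(.fixtures$trained)) {
    pairs <- toyTrainingPairs(nPerClass = 30, seed = 1)
    ts <- buildTrainingSet(pairs, toyTemplatesCached())
    .fixtures$trained <- list(ts = ts, policy = fitPolicy(ts, seed = 42))
  }
  .fixtures$trained
}

# recursive node-for-node tree comparison
treesIdentical <- function(a, b) {
  sameState <- identical(a$state, b$state)
  sameStats <- a$n == b$n && isTRUE(all.equal(a$W, b$W)) &&
    identical(a$terminal, b$terminal) &&
    identical(a$reaction$templateId, b$reaction$templateId) &&
    identical(a$reaction$precursorSmiles, b$reaction$precursorSmiles)
  if (!sameState || !sameStats) return(FALSE)
  if (length(a$children) != length(b$children)) return(FALSE)
  for (i in seq_along(a$children))
    if (!treesIdentical(a$children[[i]], b$children[[i]])) return(FALSE)
  TRUE
}

# visit-count conservation: every internal node has n = 1 + sum(children n)
visitConservationHolds <- function(node) {
  if (length(node$children)) {
    if (node$n != 1L + sum(vapply(node$children, function(c) c$n, integer(1))))
      return(FALSE)
    for (ch in node$children)
      if (!visitConservationHolds(ch)) return(FALSE)
  }
  TRUE
}

maxTreeMoleculeDepth <- function(node) {
  d <- max(node$state$depths)
  for (ch in node$children) d <- max(d, maxTreeMoleculeDepth(ch))
  d
}
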