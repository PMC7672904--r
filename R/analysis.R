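#' @include search.R
NULL

#' Route: an extracted synthesis plan
#'
#' A route records, top-down, the retro-reactions leading from the target
#' to a set of leaf precursors. It is solved when every precursor is in
#' stock; its score is the state score of the corresponding search node.
#'
#' @slot steps List of steps, each `list(productSmiles, templateId,
#'   precursorSmiles)`, ordered from the target downwards.
#' @slot score State score of the route's end state.
#' @slot nSteps Number of reactions in the route.
#' @slot precursors `data.frame` with columns `smiles`, `inStock`: the leaf
#'   molecules of the route.
#' @slot isSolved `TRUE` when every precursor is in stock.
#' @slot targetSmiles The route's target.
#' @export
setClass("Route", representation(
  steps = "list", score = "numeric", nSteps = "integer",
  precursors = "data.frame", isSolved = "logical", targetSmiles = "character"))

#' @describeIn extractRoutes Number of reactions in a route.
#' @param route A `Route`.
#' @export
routeLength <- function(route) route@nSteps

#' @describeIn extractRoutes Score of a route.
#' @export
routeScore <- function(route) route@score

#' @describeIn extractRoutes Is the route solved (all precursors in
#'   stock)?
#' @export
routeIsSolved <- function(route) route@isSolved

#' @describeIn extractRoutes Leaf precursors of a route with in-stock
#'   flags.
#' @export
routePrecursors <- function(route) route@precursors

setMethod("show", "Route", function(object) {
  cat(sprintf("Route for %s: %d step(s), score %.3f, %s\n",
              object@targetSmiles, object@nSteps, object@score,
              if (object@isSolved) "solved" else "unsolved"))
  for (s in object@steps)
    cat(sprintf("  %s =[%s]=> %s\n", s$productSmiles, s$templateId,
                paste(s$precursorSmiles, collapse = " + ")))
})

# signature of a route = sorted set of its reaction signatures
.routeSignature <- function(steps) {
  sig <- vapply(steps, function(s)
    paste(s$productKey, s$templateId, paste(sort(s$precursorKeys), collapse = "."),
          sep = ">"), character(1))
  paste(sort(sig), collapse = "|")
}

.nodeRoute <- function(node, tree) {
  steps <- list()
  cur <- node
  while (!is.null(cur$parent)) {
    steps <- c(list(cur$reaction), steps)
    cur <- cur$parent
  }
  st <- node$state
  new("Route",
      steps = steps,
      score = .scoreState(st, tree@config@maxTransforms),
      nSteps = length(steps),
      precursors = data.frame(smiles = st$smiles, inStock = st$inStock,
                              stringsAsFactors = FALSE),
      isSolved = st$solved,
      targetSmiles = tree@target@smiles)
}

.collectEndNodes <- function(root) {
  out <- list()
  stack <- list(root)
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (node$terminal || !length(node$children))
      out[[length(out) + 1L]] <- node
    for (ch in node$children) stack[[length(stack) + 1L]] <- ch
  }
  out
}

#' Extract ranked routes from a finished search
#'
#' Collects the root-to-node reaction sequence of every terminal or leaf
#' node, drops duplicate routes (identical reaction sets), and ranks by
#' score (descending), then number of steps (ascending), then
#' lexicographically on the reaction strings.
#'
#' @param tree A [SearchTree-class] from [mctsSearch()].
#' @param topN Maximum number of routes returned.
#' @return A list of [Route-class] objects, best first.
#' @export
extractRoutes <- function(tree, topN = 5L) {
  stopifnot(is(tree, "SearchTree"))
  nodes <- .collectEndNodes(tree@root)
  routes <- lapply(nodes, .nodeRoute, tree = tree)
  sigs <- vapply(routes, function(r) .routeSignature(r@steps), character(1))
  routes <- routes[!duplicated(sigs)]
  lex <- vapply(routes, function(r)
    paste(vapply(r@steps, function(s)
      paste(s$productSmiles, s$templateId,
            paste(s$precursorSmiles, collapse = "."), sep = ">"),
      character(1)), collapse = "|"), character(1))
  ord <- order(-vapply(routes, routeScore, numeric(1)),
               vapply(routes, routeLength, integer(1)),
               lex, method = "radix")
  routes <- routes[ord]
  routes[seq_len(min(topN, length(routes)))]
}

#' Serialize a route as a molecule/reaction tree
#'
#' Produces the nested representation used in the on-disc route JSON:
#' alternating `mol` and `reaction` nodes, molecules carrying their
#' in-stock flag, reactions their template id.
#'
#' @param route A [Route-class].
#' @param stock Optional [Stock-class] used to flag intermediate
#'   molecules; leaf flags always come from the route itself.
#' @return A nested list (convert with [jsonlite::toJSON()]).
#' @export
routeToList <- function(route, stock = NULL) {
  used <- rep(FALSE, length(route@steps))
  leafStock <- stats::setNames(route@precursors$inStock, route@precursors$smiles)
  build <- function(smi) {
    ri <- which(!used & vapply(route@steps, function(s)
      s$productSmiles == smi, logical(1)))[1]
    if (!is.na(ri)) {
      used[ri] <<- TRUE
      step <- route@steps[[ri]]
      inS <- if (!is.null(stock)) inStock(stock, smi) else FALSE
      list(type = "mol", smiles = smi, in_stock = inS,
           children = list(list(
             type = "reaction", template_id = step$templateId,
             children = lapply(step$precursorSmiles, build))))
    } else {
      inS <- if (smi %in% names(leafStock)) unname(leafStock[[smi]])
             else if (!is.null(stock)) inStock(stock, smi) else FALSE
      list(type = "mol", smiles = smi, in_stock = inS, children = list())
    }
  }
  build(route@targetSmiles)
}

# ---- statistics -----------------------------------------------------------

#' SearchStatistics: per-target summary of a finished search
#'
#' @slot targetSmiles Canonical target SMILES.
#' @slot isSolved Whether any solved route was found.
#' @slot nSteps Steps of the top route.
#' @slot nPrecursors Leaf precursors of the top route.
#' @slot nPrecursorsInStock How many of those are purchasable.
#' @slot iterationsRun Iterations completed.
#' @slot firstSolutionIteration Iteration of the first solved state (NA
#'   when unsolved).
#' @slot elapsedS Total search wall time (seconds).
#' @slot firstSolutionTimeS Wall time to first solution (NA when
#'   unsolved).
#' @slot topScore Score of the top route.
#' @export
setClass("SearchStatistics", representation(
  targetSmiles = "character", isSolved = "logical", nSteps = "integer",
  nPrecursors = "integer", nPrecursorsInStock = "integer",
  iterationsRun = "integer", firstSolutionIteration = "integer",
  elapsedS = "numeric", firstSolutionTimeS = "numeric", topScore = "numeric"))

setMethod("show", "SearchStatistics", function(object) {
  cat(sprintf("SearchStatistics for %s: %s, top route %d step(s), %d/%d precursors in stock, %d iterations\n",
              object@targetSmiles,
              if (object@isSolved) "solved" else "unsolved",
              object@nSteps, object@nPrecursorsInStock, object@nPrecursors,
              object@iterationsRun))
})

#' Compute per-target search statistics
#'
#' Populates a [SearchStatistics-class] from a finished tree and its top
#' route: solved flag, steps and precursor counts of the top route,
#' iteration and timing counters.
#'
#' @param tree A [SearchTree-class].
#' @return A [SearchStatistics-class].
#' @export
computeStatistics <- function(tree) {
  stopifnot(is(tree, "SearchTree"))
  top <- extractRoutes(tree, topN = 1L)[[1]]
  new("SearchStatistics",
      targetSmiles = tree@target@smiles,
      isSolved = isSolved(tree),
      nSteps = top@nSteps,
      nPrecursors = nrow(top@precursors),
      nPrecursorsInStock = as.integer(sum(top@precursors$inStock)),
      iterationsRun = tree@iterationsRun,
      firstSolutionIteration = tree@firstSolutionIteration,
      elapsedS = tree@elapsedS,
      firstSolutionTimeS = tree@firstSolutionTimeS,
      topScore = top@score)
}

#' One-row data frame of the deterministic statistics fields
#'
#' Wall-clock fields are deliberately excluded so that re-running an
#' iteration-limited batch reproduces the statistics table byte for byte;
#' timings are written to the per-target route JSON instead.
#'
#' @param stats A [SearchStatistics-class].
#' @return A one-row `data.frame`.
#' @export
statisticsRow <- function(stats) {
  data.frame(
    target_smiles = stats@targetSmiles,
    is_solved = stats@isSolved,
    n_steps = stats@nSteps,
    n_precursors = stats@nPrecursors,
    n_precursors_in_stock = stats@nPrecursorsInStock,
    iterations_run = stats@iterationsRun,
    first_solution_iteration = stats@firstSolutionIteration,
    top_score = stats@topScore,
    stringsAsFactors = FALSE)
}

#' Aggregate a batch statistics table
#'
#' Means that depend on success (steps, precursors, time to first
#' solution) are taken over the solved subset; search effort means over all
#' targets.
#'
#' @param df A `data.frame` of [statisticsRow()] rows (optionally with an
#'   `elapsed_s` column).
#' @return A named list of aggregate statistics.
#' @export
aggregateStatistics <- function(df) {
  solved <- df[df$is_solved %in% TRUE, , drop = FALSE]
  list(
    n_targets = nrow(df),
    n_solved = nrow(solved),
    solved_fraction = if (nrow(df)) nrow(solved) / nrow(df) else NA_real_,
    mean_steps_solved = if (nrow(solved)) mean(solved$n_steps) else NA_real_,
    mean_precursors_solved = if (nrow(solved)) mean(solved$n_precursors) else NA_real_,
    mean_first_solution_iteration =
      if (nrow(solved)) mean(solved$first_solution_iteration) else NA_real_,
    mean_elapsed_s = if ("elapsed_s" %in% names(df)) mean(df$elapsed_s) else NA_real_)
}
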