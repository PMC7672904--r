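#' @include chem.R
NULL

#' StockQuery: pluggable purchasability membership test
#'
#' Virtual base class. A concrete query answers, deterministically and
#' without side effects, whether a molecule counts as purchasable. Queries
#' are composed into a [Stock-class], where a molecule is in stock as soon
#' as any one query contains it.
#'
#' @slot name Human-readable label for the query.
#' @export
setClass("StockQuery", representation("VIRTUAL", name = "character"))

#' Does a stock query contain a molecule?
#'
#' @param query A [StockQuery-class].
#' @param molecule A [Molecule-class] (or SMILES string, parsed on the fly).
#' @return A single logical.
#' @export
setGeneric("queryContains", function(query, molecule) standardGeneric("queryContains"))

# ---- in-memory identity-key set ------------------------------------------

#' @rdname smilesFileQuery
#' @slot keys Environment used as a hash set of identity keys.
#' @slot size Number of distinct compounds held.
#' @export
setClass("InMemoryStockQuery", contains = "StockQuery",
         representation(keys = "environment", size = "integer"))

#' In-memory stock query from a SMILES file
#'
#' Reads one SMILES per line (blank lines and lines starting with `#`
#' ignored), canonicalizes each and stores the set of identity keys in
#' memory; membership is then an exact key lookup, so it is invariant to how
#' the query molecule's SMILES was written. Unparsable lines are skipped
#' with a warning and counted.
#'
#' @param path Path to the SMILES file.
#' @param name Label for the query (defaults to the file name).
#' @return An `InMemoryStockQuery`. Raises `stockLoadError` when the file is
#'   missing or contains no valid molecule.
#' @export
smilesFileQuery <- function(path, name = basename(path)) {
  if (!file.exists(path))
    .chemError("stockLoadError", sprintf("stock file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  keys <- new.env(parent = emptyenv())
  nBad <- 0L
  for (sm in lines) {
    mol <- tryCatch(parseMolecule(sm), error = function(e) NULL)
    if (is.null(mol)) nBad <- nBad + 1L else assign(mol@key, TRUE, envir = keys)
  }
  size <- length(ls(keys, all.names = TRUE))
  if (size == 0L)
    .chemError("stockLoadError", sprintf("no valid molecules in stock file: %s", path))
  if (nBad > 0L)
    warning(sprintf("skipped %d unparsable line(s) in %s", nBad, path))
  new("InMemoryStockQuery", name = name, keys = keys, size = size)
}

#' In-memory stock query from molecules already in R
#'
#' @param molecules List of [Molecule-class] objects or character vector of
#'   SMILES.
#' @param name Label for the query.
#' @return An `InMemoryStockQuery`.
#' @rdname smilesFileQuery
#' @export
inMemoryQuery <- function(molecules, name = "in-memory") {
  if (is.character(molecules)) molecules <- lapply(molecules, parseMolecule)
  keys <- new.env(parent = emptyenv())
  for (m in molecules) assign(identityKey(m), TRUE, envir = keys)
  size <- length(ls(keys, all.names = TRUE))
  if (size == 0L) .chemError("stockLoadError", "no molecules given")
  new("InMemoryStockQuery", name = name, keys = keys, size = size)
}

setMethod("queryContains", signature("InMemoryStockQuery", "Molecule"),
  function(query, molecule) {
    !is.null(query@keys[[molecule@key]])
  })

setMethod("show", "InMemoryStockQuery", function(object) {
  cat(sprintf("InMemoryStockQuery '%s': %d compounds\n", object@name, object@size))
})

# ---- rule-based query -----------------------------------------------------

#' @rdname carbonRuleQuery
#' @slot maxCarbons Exclusive carbon-count bound.
#' @export
setClass("CarbonRuleQuery", contains = "StockQuery",
         representation(maxCarbons = "integer"))

#' Carbon-count purchasability rule
#'
#' Treats every compound with strictly fewer than `maxCarbons` carbon atoms
#' as purchasable — the classic stand-in for "small enough to buy". With
#' `maxCarbons = 7`, ethanol (2 C) is in stock, toluene (7 C) is not.
#'
#' @param maxCarbons Non-negative integer; a molecule is in stock iff its
#'   carbon count is `< maxCarbons`.
#' @param name Label for the query.
#' @return A `CarbonRuleQuery`.
#' @export
carbonRuleQuery <- function(maxCarbons = 7L, name = sprintf("carbon<%d", maxCarbons)) {
  maxCarbons <- as.integer(maxCarbons)
  stopifnot(length(maxCarbons) == 1L, !is.na(maxCarbons), maxCarbons >= 0L)
  new("CarbonRuleQuery", name = name, maxCarbons = maxCarbons)
}

setMethod("queryContains", signature("CarbonRuleQuery", "Molecule"),
  function(query, molecule) {
    molecule@nCarbons < query@maxCarbons
  })

setMethod("show", "CarbonRuleQuery", function(object) {
  cat(sprintf("CarbonRuleQuery '%s': fewer than %d carbons\n",
              object@name, object@maxCarbons))
})

# string convenience for any query
setMethod("queryContains", signature("StockQuery", "character"),
  function(query, molecule) queryContains(query, parseMolecule(molecule)))

# ---- Stock ----------------------------------------------------------------

#' Stock: OR-composition of purchasability queries
#'
#' The stop-condition of the tree search: a molecule is in stock iff at
#' least one member query contains it. A stock with no queries contains
#' nothing.
#'
#' @slot queries Ordered list of [StockQuery-class] objects.
#' @export
setClass("Stock", representation(queries = "list"),
  validity = function(object) {
    if (!all(vapply(object@queries, function(q) is(q, "StockQuery"), logical(1))))
      return("all elements of queries must be StockQuery objects")
    TRUE
  })

#' Build a Stock from queries
#'
#' @param ... [StockQuery-class] objects (or a single list of them).
#' @return A [Stock-class].
#' @export
makeStock <- function(...) {
  qs <- list(...)
  if (length(qs) == 1L && is.list(qs[[1]]) && !is(qs[[1]], "StockQuery"))
    qs <- qs[[1]]
  new("Stock", queries = qs)
}

#' Is a molecule in stock?
#'
#' Evaluates member queries in order, short-circuiting on the first hit.
#'
#' @param stock A [Stock-class].
#' @param molecule A [Molecule-class] or SMILES string.
#' @return A single logical.
#' @export
inStock <- function(stock, molecule) {
  stopifnot(is(stock, "Stock"))
  if (is.character(molecule)) molecule <- parseMolecule(molecule)
  for (q in stock@queries) {
    if (queryContains(q, molecule)) return(TRUE)
  }
  FALSE
}

setMethod("show", "Stock", function(object) {
  cat(sprintf("Stock with %d query(ies): %s\n", length(object@queries),
              paste(vapply(object@queries, function(q) q@name, character(1)),
                    collapse = ", ")))
})
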