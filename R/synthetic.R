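#' @include analysis.R
NULL

# Toy chemistry: real small-molecule SMILES/SMARTS so that the production
# code paths (pattern matching, canonicalization, identity keys) are
# exercised end to end. Three valence-safe condensations:
#   ester  : carboxylic acid + alcohol -> ester
#   amide  : carboxylic acid + primary amine -> secondary amide
#   ether  : alcohol + alcohol -> dialkyl ether
# Retro templates are the exact inverses, so every generated product is
# recoverable by applyTemplate (forward/retro closure).

.toySmarts <- list(
  t_ester = list(
    retro = "[C:1](=[O:2])[O:3][CX4:4]>>[C:1](=[O:2])[OH].[OH:3][C:4]",
    forward = "[C:1](=[O:2])[OX2H1].[OX2H1:3][CX4:4]>>[C:1](=[O:2])[O:3][C:4]",
    name = "ester condensation (retro: ester hydrolysis)"),
  t_amide = list(
    retro = "[C:1](=[O:2])[NX3;H1:3][CX4:4]>>[C:1](=[O:2])[OH].[NX3;H2:3][C:4]",
    forward = "[C:1](=[O:2])[OX2H1].[NX3;H2:3][CX4:4]>>[C:1](=[O:2])[N:3][C:4]",
    name = "amide coupling (retro: amide hydrolysis)"),
  t_ether = list(
    retro = "[CX4:1][OX2:2][CX4:3]>>[CX4:1][OX2:2].[OX2][CX4:3]",
    forward = "[CX4:1][OX2H1:2].[OX2H1][CX4:3]>>[C:1][O:2][C:3]",
    name = "ether synthesis (retro: ether cleavage)"))

# monofunctional building blocks, by functional group
.toyCatalogue <- list(
  alcohol = c("CO", "CCO", "CCCO", "CC(C)O", "CCCCO"),
  amine = c("CN", "CCN", "CCCN", "CC(C)N", "CCCCN"),
  acid = c("CC(=O)O", "CCC(=O)O", "CC(C)C(=O)O", "O=C(O)c1ccccc1",
           "CCCC(=O)O"))

# bifunctional linkers keep a free group after one coupling
.toyLinkers <- list(
  list(smiles = "OCCN", groups = c("OH", "NH2")),
  list(smiles = "OCCCN", groups = c("OH", "NH2")),
  list(smiles = "OCC(=O)O", groups = c("OH", "COOH")),
  list(smiles = "NCCC(=O)O", groups = c("NH2", "COOH")))

#' ToyWorld: synthetic planning fixtures with known ground truth
#'
#' A self-contained toy planning problem: a retro-template library with
#' matching forward transforms, a stock of building blocks, and targets
#' composed forward from those blocks so that the true minimum number of
#' retro steps of every target is known by construction.
#'
#' @slot templates Named list of [RetroTemplate-class] (the library).
#' @slot forwardSmarts Named character: forward reaction SMARTS per
#'   template id.
#' @slot stockSmiles Character vector of purchasable building blocks
#'   (canonical SMILES).
#' @slot targets `data.frame` with columns `target_smiles`,
#'   `true_min_steps`.
#' @slot routes List (parallel to targets) of recorded ground-truth retro
#'   routes; each route is a list of steps `list(productSmiles,
#'   templateId, precursorSmiles)`.
#' @slot seed The generator seed.
#' @export
setClass("ToyWorld", representation(
  templates = "list", forwardSmarts = "character", stockSmiles = "character",
  targets = "data.frame", routes = "list", seed = "integer"))

setMethod("show", "ToyWorld", function(object) {
  cat(sprintf("ToyWorld (seed %d): %d templates, %d stock compounds, %d targets (min steps %s)\n",
              object@seed, length(object@templates), length(object@stockSmiles),
              nrow(object@targets),
              paste(object@targets$true_min_steps, collapse = ",")))
})

#' @describeIn generateToyWorld The world's template library.
#' @param world A `ToyWorld`.
#' @export
worldTemplates <- function(world) world@templates

#' @describeIn generateToyWorld The world's stock as a [Stock-class].
#' @export
worldStock <- function(world) {
  makeStock(inMemoryQuery(world@stockSmiles, name = "toy-blocks"))
}

#' @describeIn generateToyWorld Targets with recorded minimum steps.
#' @export
worldTargets <- function(world) world@targets

#' @describeIn generateToyWorld All `(product, template, precursors)`
#'   triples recorded while composing the world's targets.
#' @export
worldTriples <- function(world) {
  out <- list()
  for (route in world@routes) for (s in route)
    out[[length(out) + 1L]] <- s
  out
}

.toyTemplateLibrary <- function() {
  out <- lapply(names(.toySmarts), function(id)
    retroTemplate(id, .toySmarts[[id]]$retro,
                  metadata = list(name = .toySmarts[[id]]$name)))
  names(out) <- names(.toySmarts)
  out
}

# run body with a local RNG stream, restoring the caller's state
.withSeed <- function(seed, body) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  body()
}

# one forward coupling; returns canonical product SMILES
.toyCouple <- function(template, first, second) {
  prods <- .applyForward(.toySmarts[[template]]$forward, c(first, second))
  if (!length(prods))
    stop(sprintf("toy forward '%s' produced nothing for %s + %s",
                 template, first, second))
  # unique by construction for monovalent couplings; take the sorted first
  # for determinism
  smiles(parseMolecule(prods[[1]]))
}

# options to react a free group with a linker, keeping a chain going:
# returns list of list(template, linkerIdx, usedGroup, nextGroup)
.linkerOptions <- function(freeGroup, linkers) {
  opts <- list()
  for (i in seq_along(linkers)) {
    g <- linkers[[i]]$groups
    add <- function(template, used) {
      opts[[length(opts) + 1L]] <<- list(template = template, linkerIdx = i,
                                         usedGroup = used,
                                         nextGroup = setdiff(g, used)[1])
    }
    if (freeGroup == "COOH" && "OH" %in% g) add("t_ester", "OH")
    if (freeGroup == "COOH" && "NH2" %in% g) add("t_amide", "NH2")
    if (freeGroup == "OH" && "COOH" %in% g) add("t_ester", "COOH")
    if (freeGroup == "OH" && "OH" %in% g) add("t_ether", "OH")
    if (freeGroup == "NH2" && "COOH" %in% g) add("t_amide", "COOH")
  }
  opts
}

# capping reactions consuming the free group with a monofunctional block
.capOptions <- function(freeGroup) {
  switch(freeGroup,
         COOH = list(list(template = "t_ester", pool = "alcohol"),
                     list(template = "t_amide", pool = "amine")),
         OH = list(list(template = "t_ester", pool = "acid"),
                   list(template = "t_ether", pool = "alcohol")),
         NH2 = list(list(template = "t_amide", pool = "acid")))
}

# forward-react scaffold (free group g) with partner via template; the acid
# always goes first in the forward reactant tuple
.toyStep <- function(template, scaffold, g, partner, partnerUsedGroup) {
  if (template == "t_ester") {
    if (g == "COOH") .toyCouple(template, scaffold, partner)
    else .toyCouple(template, partner, scaffold)
  } else if (template == "t_amide") {
    if (g == "COOH") .toyCouple(template, scaffold, partner)
    else .toyCouple(template, partner, scaffold)
  } else {
    .toyCouple(template, scaffold, partner)
  }
}

#' Generate a toy retrosynthesis world
#'
#' Samples monofunctional building blocks (alcohols, amines, carboxylic
#' acids) from a fixed catalogue, composes targets forward through ester,
#' amide and ether couplings (bifunctional linkers carry chains deeper than
#' one step), and records each target's retro route. Every target is
#' decomposable back to stock in exactly the recorded number of steps; the
#' stock holds the sampled blocks and linkers. Deterministic per seed.
#'
#' @param nBlocks Number of monofunctional blocks to sample (at least one
#'   of each functional class; minimum 3 enforced).
#' @param depth Maximum forward composition depth (target min steps are
#'   1..depth).
#' @param seed Integer seed.
#' @param nTargets Number of targets to compose.
#' @return A [ToyWorld-class].
#' @export
generateToyWorld <- function(nBlocks = 6L, depth = 2L, seed = 1L, nTargets = 3L) {
  stopifnot(nBlocks >= 2L, depth >= 1L, nTargets >= 1L)
  nBlocks <- max(3L, as.integer(nBlocks))
  templates <- .toyTemplateLibrary()
  .withSeed(as.integer(seed), function() {
    # stratified block sample: one of each class, remainder at random
    pools <- list(alcohol = sample(.toyCatalogue$alcohol, 1),
                  amine = sample(.toyCatalogue$amine, 1),
                  acid = sample(.toyCatalogue$acid, 1))
    extraPool <- setdiff(unlist(.toyCatalogue), unlist(pools))
    nExtra <- min(nBlocks - 3L, length(extraPool))
    if (nExtra > 0L) {
      for (sm in sample(extraPool, nExtra)) {
        cls <- names(.toyCatalogue)[vapply(.toyCatalogue, function(p) sm %in% p, logical(1))]
        pools[[cls]] <- c(pools[[cls]], sm)
      }
    }
    linkers <- .toyLinkers[sample(seq_along(.toyLinkers), 2L)]
    targets <- data.frame(target_smiles = character(), true_min_steps = integer(),
                          stringsAsFactors = FALSE)
    routes <- list()
    for (t in seq_len(nTargets)) {
      dT <- sample.int(depth, 1L)
      steps <- list()   # forward order; reversed at the end
      if (dT == 1L) {
        cap <- .capOptions(sample(c("COOH", "OH", "NH2"), 1L))
        cap <- cap[[sample.int(length(cap), 1L)]]
        # draw the two partners
        if (cap$template == "t_ester") {
          a <- sample(pools$acid, 1); b <- sample(pools$alcohol, 1)
          prod <- .toyCouple("t_ester", a, b)
          pre <- c(a, b); tid <- "t_ester"
        } else if (cap$template == "t_amide") {
          a <- sample(pools$acid, 1); b <- sample(pools$amine, 1)
          prod <- .toyCouple("t_amide", a, b)
          pre <- c(a, b); tid <- "t_amide"
        } else {
          ab <- sample(pools$alcohol, 2, replace = length(pools$alcohol) < 2)
          prod <- .toyCouple("t_ether", ab[1], ab[2])
          pre <- ab; tid <- "t_ether"
        }
        steps[[1]] <- list(productSmiles = prod, templateId = tid,
                           precursorSmiles = vapply(pre, function(s) smiles(parseMolecule(s)), character(1)))
        scaffold <- prod
      } else {
        # step 1: mono block x linker, leaving the linker's other group free
        startOpts <- list()
        for (g0 in c("COOH", "OH", "NH2")) {
          pool <- switch(g0, COOH = pools$acid, OH = pools$alcohol, NH2 = pools$amine)
          for (o in .linkerOptions(g0, linkers))
            startOpts[[length(startOpts) + 1L]] <- c(o, list(g0 = g0, pool = pool))
        }
        repeat {
          o <- startOpts[[sample.int(length(startOpts), 1L)]]
          # continuation must exist when more linker steps remain
          if (dT == 2L || length(.linkerOptions(o$nextGroup, linkers)) > 0L) break
        }
        block <- sample(o$pool, 1)
        linker <- linkers[[o$linkerIdx]]$smiles
        prod <- .toyStep(o$template, block, o$g0, linker, o$usedGroup)
        steps[[1]] <- list(productSmiles = prod, templateId = o$template,
                           precursorSmiles = vapply(c(block, linker), function(s)
                             smiles(parseMolecule(s)), character(1)))
        scaffold <- prod
        g <- o$nextGroup
        # middle steps: scaffold x linker
        for (k in seq_len(dT - 2L)) {
          opts <- .linkerOptions(g, linkers)
          if ((dT - 2L) > k)  # one-step lookahead keeps the chain alive
            opts <- Filter(function(o2) length(.linkerOptions(o2$nextGroup, linkers)) > 0L, opts)
          o2 <- opts[[sample.int(length(opts), 1L)]]
          linker <- linkers[[o2$linkerIdx]]$smiles
          prod <- .toyStep(o2$template, scaffold, g, linker, o2$usedGroup)
          steps[[length(steps) + 1L]] <- list(
            productSmiles = prod, templateId = o2$template,
            precursorSmiles = vapply(c(scaffold, linker), function(s)
              smiles(parseMolecule(s)), character(1)))
          scaffold <- prod
          g <- o2$nextGroup
        }
        # final step: cap with a monofunctional block
        caps <- .capOptions(g)
        cap <- caps[[sample.int(length(caps), 1L)]]
        partner <- sample(pools[[cap$pool]], 1)
        prod <- .toyStep(cap$template, scaffold, g, partner, NA)
        steps[[length(steps) + 1L]] <- list(
          productSmiles = prod, templateId = cap$template,
          precursorSmiles = vapply(c(scaffold, partner), function(s)
            smiles(parseMolecule(s)), character(1)))
        scaffold <- prod
      }
      targets[t, ] <- list(smiles(parseMolecule(scaffold)), dT)
      routes[[t]] <- rev(steps)   # retro order: target first
    }
    stockSmiles <- vapply(
      unique(c(unlist(pools), vapply(linkers, `[[`, character(1), "smiles"))),
      function(s) smiles(parseMolecule(s)), character(1))
    new("ToyWorld", templates = templates,
        forwardSmarts = vapply(.toySmarts, `[[`, character(1), "forward"),
        stockSmiles = unname(stockSmiles), targets = targets, routes = routes,
        seed = as.integer(seed))
  })
}

#' Training pairs for the toy chemistry
#'
#' Enumerates single-coupling products over the full catalogue (plus
#' linkers) for each template class and samples a balanced set of
#' `(product_smiles, template_id)` pairs — one linkage type per product, so
#' the classes are separable by their functional groups.
#'
#' @param nPerClass Examples per template class.
#' @param seed Integer seed.
#' @return A `data.frame` with columns `product_smiles`, `template_id`.
#' @export
toyTrainingPairs <- function(nPerClass = 30L, seed = 1L) {
  linkSmi <- vapply(.toyLinkers, `[[`, character(1), "smiles")
  acids <- c(.toyCatalogue$acid, linkSmi[grepl("C\\(=O\\)O", linkSmi)])
  alcohols <- c(.toyCatalogue$alcohol, linkSmi[startsWith(linkSmi, "O")])
  amines <- c(.toyCatalogue$amine, linkSmi[grepl("N", linkSmi)])
  .withSeed(as.integer(seed), function() {
    draw <- function(template, firsts, seconds) {
      combos <- expand.grid(a = firsts, b = seconds, stringsAsFactors = FALSE)
      combos <- combos[sample.int(nrow(combos)), , drop = FALSE]
      out <- character(0)
      for (i in seq_len(nrow(combos))) {
        if (length(out) >= nPerClass) break
        prod <- tryCatch(.toyCouple(template, combos$a[i], combos$b[i]),
                         error = function(e) NA_character_)
        if (!is.na(prod) && !(prod %in% out)) out <- c(out, prod)
      }
      data.frame(product_smiles = out,
                 template_id = rep(template, length(out)),
                 stringsAsFactors = FALSE)
    }
    rbind(draw("t_ester", acids, alcohols),
          draw("t_amide", acids, amines),
          draw("t_ether", alcohols, alcohols))
  })
}

# ---- oracle ---------------------------------------------------------------

#' Exhaustively enumerate solved routes (brute-force oracle)
#'
#' Depth-bounded exhaustive decomposition: applies every template to every
#' intermediate molecule, pruning repeated molecules by identity key
#' (memoized per remaining depth), and combines sub-solutions into complete
#' routes. Intended for small instances; raises `oracleBudgetError` beyond
#' `nodeCap` template applications.
#'
#' @param target A [Molecule-class] or SMILES string.
#' @param templates Template library (named list of
#'   [RetroTemplate-class]).
#' @param stock A [Stock-class].
#' @param maxDepth Maximum route depth (longest branch).
#' @param nodeCap Budget on template applications.
#' @param maxRoutesPerMol Cap on sub-routes kept per molecule (smallest
#'   first), bounding combinatorial blow-up while preserving minimality.
#' @return A list of solved routes, minimal step count first; each route is
#'   `list(nSteps, steps)` with steps as in [ToyWorld-class]. Empty list
#'   when the target is unreachable.
#' @export
oracleEnumerate <- function(target, templates, stock, maxDepth = 4L,
                            nodeCap = 1e5, maxRoutesPerMol = 25L) {
  if (is.character(target)) target <- parseMolecule(target)
  budget <- new.env(parent = emptyenv()); budget$n <- 0L
  memo <- new.env(parent = emptyenv())
  solve <- function(mol, depthRem) {
    key <- paste(mol@key, depthRem, sep = "@")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    routes <- list()
    if (inStock(stock, mol)) {
      routes[[1]] <- list(nSteps = 0L, steps = list())
      memo[[key]] <- routes
      return(routes)
    }
    if (depthRem > 0L) {
      for (tmpl in templates) {
        budget$n <- budget$n + 1L
        if (budget$n > nodeCap)
          .chemError("oracleBudgetError",
                     sprintf("oracle exceeded %g template applications", nodeCap))
        sets <- applyTemplate(tmpl, mol)
        for (set in sets) {
          subLists <- lapply(set, solve, depthRem = depthRem - 1L)
          if (any(vapply(subLists, length, integer(1)) == 0L)) next
          # cartesian combination of sub-routes
          combos <- list(list(nSteps = 1L, steps = list(list(
            productSmiles = mol@smiles, templateId = templateId(tmpl),
            precursorSmiles = vapply(set, smiles, character(1)),
            productKey = mol@key,
            precursorKeys = vapply(set, identityKey, character(1))))))
          for (sub in subLists) {
            combos <- unlist(lapply(combos, function(cmb) {
              lapply(sub, function(sr) list(
                nSteps = cmb$nSteps + sr$nSteps,
                steps = c(cmb$steps, sr$steps)))
            }), recursive = FALSE)
            if (length(combos) > maxRoutesPerMol) {
              ord <- order(vapply(combos, `[[`, integer(1), "nSteps"))
              combos <- combos[ord[seq_len(maxRoutesPerMol)]]
            }
          }
          routes <- c(routes, combos)
        }
      }
      if (length(routes) > maxRoutesPerMol) {
        ord <- order(vapply(routes, `[[`, integer(1), "nSteps"))
        routes <- routes[ord[seq_len(maxRoutesPerMol)]]
      }
    }
    memo[[key]] <- routes
    routes
  }
  routes <- solve(target, as.integer(maxDepth))
  routes[order(vapply(routes, `[[`, integer(1), "nSteps"))]
}

#' Write a toy world's files to disk
#'
#' Emits the template library (TSV), stock (SMILES list) and targets (CSV
#' with recorded minimum steps) in the formats the planner loads.
#'
#' @param world A [ToyWorld-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the three file paths.
#' @export
writeWorldFiles <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tf <- file.path(dir, "templates.tsv")
  meta <- vapply(world@templates, function(t)
    if (!is.null(t@metadata$name)) t@metadata$name else "", character(1))
  utils::write.table(
    data.frame(template_id = vapply(world@templates, templateId, character(1)),
               retro_smarts = vapply(world@templates, retroSmarts, character(1)),
               name = meta, stringsAsFactors = FALSE),
    tf, sep = "\t", quote = FALSE, row.names = FALSE)
  sf <- file.path(dir, "stock.smi")
  writeLines(c("# toy world stock", world@stockSmiles), sf)
  gf <- file.path(dir, "targets.csv")
  utils::write.csv(world@targets, gf, row.names = FALSE, quote = FALSE)
  invisible(list(templates = tf, stock = sf, targets = gf))
}
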