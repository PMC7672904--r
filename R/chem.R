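#' @include bridge.R
NULL

# ---- conditions -----------------------------------------------------------

.chemError <- function(class, msg) {
  stop(structure(
    class = c(class, "retroplanError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# running diagnostics (sanitization drops during template application)
.chemDiag <- new.env(parent = emptyenv())
.chemDiag$n_sanitize_failed <- 0L

#' Template-application diagnostics counters
#'
#' Reaction templates routinely match off-target sites and produce precursor
#' sets with invalid valences; those outcomes are dropped silently during
#' [applyTemplate()] and counted here.
#'
#' @param reset If `TRUE`, zero the counters after reading.
#' @return A named list with `n_sanitize_failed`, the number of outcome sets
#'   dropped because a precursor failed sanitization.
#' @export
chemDiagnostics <- function(reset = FALSE) {
  out <- list(n_sanitize_failed = .chemDiag$n_sanitize_failed)
  if (reset) .chemDiag$n_sanitize_failed <- 0L
  out
}

# ---- Molecule -------------------------------------------------------------

#' Molecule: a canonical structure with an identity key
#'
#' A `Molecule` stores the canonical SMILES of a parsed structure together
#' with a hashed identity key (the InChI key). Two molecules entered with
#' different atom orderings canonicalize to the same SMILES and the same
#' key, so equality is structural, not textual.
#'
#' @slot smiles Canonical SMILES string.
#' @slot key Identity key (InChI key) used for fast exact-compound
#'   comparisons, e.g. stock membership.
#' @slot nCarbons Number of carbon atoms (cached for rule-based stock
#'   queries).
#' @slot nAtoms Number of heavy atoms.
#' @export
setClass("Molecule", representation(
  smiles = "character",
  key = "character",
  nCarbons = "integer",
  nAtoms = "integer"
), validity = function(object) {
  if (length(object@smiles) != 1L || !nzchar(object@smiles))
    return("smiles must be a single non-empty string")
  if (length(object@key) != 1L || !nzchar(object@key))
    return("key must be a single non-empty string")
  TRUE
})

#' Parse a SMILES string into a Molecule
#'
#' @param smiles A single SMILES string.
#' @return A [Molecule-class] object with canonical SMILES and identity key.
#'   Raises a `moleculeParseError` if the input cannot be parsed.
#' @examples
#' \dontrun{
#' m <- parseMolecule("OCC")
#' smiles(m)  # "CCO"
#' }
#' @export
parseMolecule <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) || !nzchar(smiles))
    .chemError("moleculeParseError", "smiles must be a single non-empty string")
  resp <- .bridgeCached("parse", smiles, list(op = "parse", smiles = smiles))
  if (!isTRUE(resp$ok))
    .chemError("moleculeParseError", sprintf("cannot parse SMILES '%s': %s", smiles, resp$error))
  new("Molecule",
      smiles = resp$smiles, key = resp$key,
      nCarbons = as.integer(resp$n_carbons), nAtoms = as.integer(resp$n_atoms))
}

#' @describeIn parseMolecule Canonical SMILES of a Molecule.
#' @param x A `Molecule`.
#' @export
smiles <- function(x) {
  stopifnot(is(x, "Molecule"))
  x@smiles
}

#' @describeIn parseMolecule Identity key of a Molecule.
#' @export
identityKey <- function(x) {
  stopifnot(is(x, "Molecule"))
  x@key
}

#' @describeIn parseMolecule Number of carbon atoms.
#' @export
carbonCount <- function(x) {
  stopifnot(is(x, "Molecule"))
  x@nCarbons
}

setMethod("show", "Molecule", function(object) {
  cat("Molecule:", object@smiles, "(", object@key, ")\n")
})

#' Structural equality of molecules
#'
#' @param e1,e2 `Molecule` objects.
#' @return `TRUE` when both molecules have the same identity key.
#' @export
setMethod("==", signature("Molecule", "Molecule"), function(e1, e2) {
  e1@key == e2@key
})

# ---- TreeMolecule ---------------------------------------------------------

#' TreeMolecule: a molecule at a depth in the search tree
#'
#' Wraps a [Molecule-class] with the number of retro-reactions applied from
#' the root target to produce it. The root target has `transformDepth` 0; a
#' precursor created by applying a retro-reaction to a molecule at depth d
#' sits at depth d + 1.
#'
#' @slot molecule The underlying [Molecule-class].
#' @slot transformDepth Non-negative integer retro-reaction count from the
#'   root.
#' @export
setClass("TreeMolecule", representation(
  molecule = "Molecule",
  transformDepth = "integer"
), validity = function(object) {
  if (object@transformDepth < 0L) return("transformDepth must be >= 0")
  TRUE
})

#' Construct a TreeMolecule
#'
#' @param molecule A [Molecule-class] or a SMILES string.
#' @param transformDepth Retro-reaction depth from the root target.
#' @return A [TreeMolecule-class].
#' @export
treeMolecule <- function(molecule, transformDepth = 0L) {
  if (is.character(molecule)) molecule <- parseMolecule(molecule)
  new("TreeMolecule", molecule = molecule, transformDepth = as.integer(transformDepth))
}

#' @describeIn treeMolecule Retro-reaction depth of a TreeMolecule.
#' @param x A `TreeMolecule`.
#' @export
transformDepth <- function(x) {
  stopifnot(is(x, "TreeMolecule"))
  x@transformDepth
}

setMethod("show", "TreeMolecule", function(object) {
  cat("TreeMolecule:", object@molecule@smiles,
      "(depth", object@transformDepth, ")\n")
})

# ---- RetroTemplate --------------------------------------------------------

#' RetroTemplate: a retro-direction reaction template
#'
#' A reaction SMARTS written in the retro direction, `product >> reactants`:
#' the left-hand side is a single product pattern matched against the target
#' molecule, the right-hand side the precursor patterns the match is
#' rewritten to.
#'
#' @slot templateId Template identifier (unique within a library).
#' @slot retroSmarts Reaction SMARTS, retro direction, exactly one
#'   product-side pattern.
#' @slot metadata Free-form named list (e.g. a human-readable name).
#' @export
setClass("RetroTemplate", representation(
  templateId = "character",
  retroSmarts = "character",
  metadata = "list"
))

#' Construct (and validate) a RetroTemplate
#'
#' @param templateId Identifier string (numbers are accepted and converted).
#' @param retroSmarts Reaction SMARTS, retro direction.
#' @param metadata Optional named list of metadata.
#' @return A [RetroTemplate-class]. Raises `templateParseError` if the
#'   SMARTS does not parse or has more than one product-side pattern.
#' @export
retroTemplate <- function(templateId, retroSmarts, metadata = list()) {
  templateId <- as.character(templateId)
  resp <- .bridgeCached("parse_rxn", retroSmarts,
                        list(op = "parse_rxn", smarts = retroSmarts))
  if (!isTRUE(resp$ok))
    .chemError("templateParseError",
               sprintf("template '%s': %s", templateId, resp$error))
  if (resp$n_reactant_templates != 1L)
    .chemError("templateParseError",
               sprintf("template '%s': retro SMARTS must have exactly one product-side pattern, found %d",
                       templateId, resp$n_reactant_templates))
  new("RetroTemplate", templateId = templateId,
      retroSmarts = retroSmarts, metadata = metadata)
}

#' @describeIn retroTemplate Identifier of a template.
#' @param x A `RetroTemplate`.
#' @export
templateId <- function(x) {
  stopifnot(is(x, "RetroTemplate"))
  x@templateId
}

#' @describeIn retroTemplate Retro-direction reaction SMARTS of a template.
#' @export
retroSmarts <- function(x) {
  stopifnot(is(x, "RetroTemplate"))
  x@retroSmarts
}

setMethod("show", "RetroTemplate", function(object) {
  cat("RetroTemplate", object@templateId, ":", object@retroSmarts, "\n")
})

# ---- template library -----------------------------------------------------

#' Load a template library from a delimited file
#'
#' The file must have a header with columns `template_id` and `retro_smarts`
#' (any further columns become per-template metadata). The delimiter (tab or
#' comma) is auto-detected from the header line.
#'
#' @param path Path to the template file.
#' @return A named list of [RetroTemplate-class] objects, ordered as in the
#'   file, names being the template ids.
#' @export
loadTemplateLibrary <- function(path) {
  if (!file.exists(path))
    .chemError("templateParseError", sprintf("template file not found: %s", path))
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          quote = "\"")
  if (!all(c("template_id", "retro_smarts") %in% names(df)))
    .chemError("templateParseError",
               "template file must have columns 'template_id' and 'retro_smarts'")
  extra <- setdiff(names(df), c("template_id", "retro_smarts"))
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    meta <- as.list(df[i, extra, drop = FALSE])
    out[[i]] <- retroTemplate(df$template_id[i], df$retro_smarts[i], meta)
  }
  names(out) <- vapply(out, templateId, character(1))
  if (anyDuplicated(names(out)))
    .chemError("templateParseError", "duplicate template_id in template file")
  out
}

# ---- template application -------------------------------------------------

#' Apply a retro-template to a target molecule
#'
#' Matches the template's product-side pattern against the target and
#' rewrites every match site, returning all distinct precursor sets. Each
#' precursor is canonicalized; outcome sets that fail sanitization are
#' dropped silently (counted in [chemDiagnostics()]); sets containing a
#' molecule identical to the target are discarded (they would be trivial
#' self-loops); duplicate sets arising from symmetric match sites are
#' collapsed by their set of identity keys.
#'
#' @param template A [RetroTemplate-class].
#' @param target A [Molecule-class], [TreeMolecule-class] or SMILES string.
#' @return A list of precursor sets; each set is a list of
#'   [Molecule-class] objects. Empty list when the template does not match.
#' @export
applyTemplate <- function(template, target) {
  stopifnot(is(template, "RetroTemplate"))
  if (is(target, "TreeMolecule")) target <- target@molecule
  if (is.character(target)) target <- parseMolecule(target)
  stopifnot(is(target, "Molecule"))
  key <- paste(template@retroSmarts, target@smiles, sep = "\r")
  resp <- .bridgeCached("apply", key,
                        list(op = "apply", smarts = template@retroSmarts,
                             smiles = target@smiles))
  if (!isTRUE(resp$ok))
    .chemError("templateParseError",
               sprintf("template '%s': %s", template@templateId, resp$error))
  if (resp$n_failed > 0L)
    .chemDiag$n_sanitize_failed <- .chemDiag$n_sanitize_failed + as.integer(resp$n_failed)
  sets <- list()
  seen <- character()
  for (raw in resp$sets) {
    mols <- lapply(unlist(raw, use.names = FALSE), parseMolecule)
    keys <- sort(vapply(mols, identityKey, character(1)))
    if (target@key %in% keys) next          # self-loop guard
    sig <- paste(keys, collapse = "|")
    if (sig %in% seen) next                 # symmetric-match duplicate
    seen <- c(seen, sig)
    # deterministic within-set order: by canonical SMILES
    mols <- mols[order(vapply(mols, smiles, character(1)))]
    sets[[length(sets) + 1L]] <- mols
  }
  sets
}

# forward application used by the synthetic world generator (n reactants)
.applyForward <- function(forwardSmarts, smilesList) {
  key <- paste(forwardSmarts, paste(smilesList, collapse = "."), sep = "\r")
  resp <- .bridgeCached("apply_fwd", key,
                        list(op = "apply_multi", smarts = forwardSmarts,
                             smiles_list = as.list(smilesList)))
  if (!isTRUE(resp$ok))
    .chemError("templateParseError", resp$error)
  out <- unique(vapply(resp$sets, function(s) paste(unlist(s), collapse = "."),
                       character(1)))
  sort(out)
}

# Morgan fingerprint on-bit indices (1-based), used by the policy module
.moleculeFingerprint <- function(mol, radius = 2L, nbits = 2048L) {
  stopifnot(is(mol, "Molecule"))
  key <- paste(mol@smiles, radius, nbits, sep = "\r")
  resp <- .bridgeCached("fp", key,
                        list(op = "fingerprint", smiles = mol@smiles,
                             radius = radius, nbits = nbits))
  if (!isTRUE(resp$ok)) .chemError("moleculeParseError", resp$error)
  as.integer(unlist(resp$bits))
}
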