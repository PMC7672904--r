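#' @include stock.R
NULL

#' Policy shortlist configuration
#'
#' After the full template distribution is predicted, the search keeps only
#' the smallest prefix whose cumulative probability reaches
#' `cutoffCumulative`, further truncated to at most `cutoffNumber` entries
#' (always at least one).
#'
#' @param cutoffNumber Maximum number of templates kept (positive integer).
#' @param cutoffCumulative Probability-mass threshold in (0, 1].
#' @return A `PolicyConfig` object.
#' @export
policyConfig <- function(cutoffNumber = 50L, cutoffCumulative = 0.995) {
  cutoffNumber <- as.integer(cutoffNumber)
  stopifnot(cutoffNumber >= 1L, cutoffCumulative > 0, cutoffCumulative <= 1)
  new("PolicyConfig", cutoffNumber = cutoffNumber,
      cutoffCumulative = cutoffCumulative)
}

#' @rdname policyConfig
#' @slot cutoffNumber Maximum number of templates kept.
#' @slot cutoffCumulative Probability-mass threshold.
#' @export
setClass("PolicyConfig", representation(
  cutoffNumber = "integer", cutoffCumulative = "numeric"))

#' Policy: template-recommendation engine
#'
#' Virtual base class. A policy is loaded with a template library; given a
#' molecule it returns the full library ranked by probability (see
#' [predictTemplates()]), which the search then shortlists.
#'
#' @slot templates Named list of [RetroTemplate-class] objects (the loaded
#'   library, in library order).
#' @export
setClass("Policy", representation("VIRTUAL", templates = "list"))

#' @describeIn predictTemplates Template library a policy was loaded with.
#' @export
policyTemplates <- function(policy) {
  stopifnot(is(policy, "Policy"))
  policy@templates
}

.checkLoaded <- function(policy) {
  if (length(policy@templates) == 0L)
    .chemError("policyNotLoadedError", "policy has no template library loaded")
}

#' Rank reaction templates for a molecule
#'
#' Returns the policy's probability for every template in its library,
#' sorted by probability (descending; ties broken by ascending template
#' id). Probabilities form a distribution over the full library (sum 1)
#' before any shortlisting.
#'
#' @param policy A [Policy-class].
#' @param molecule A [Molecule-class] or SMILES string.
#' @return A `data.frame` with columns `templateId` (character) and
#'   `probability` (numeric), one row per library template, sorted.
#' @export
setGeneric("predictTemplates", function(policy, molecule) standardGeneric("predictTemplates"))

setMethod("predictTemplates", signature("Policy", "character"),
  function(policy, molecule) predictTemplates(policy, parseMolecule(molecule)))

# sort + package a named probability vector into the prediction frame
.predictionFrame <- function(probs) {
  ids <- names(probs)
  ord <- order(-probs, ids, method = "radix")
  data.frame(templateId = ids[ord], probability = unname(probs[ord]),
             stringsAsFactors = FALSE)
}

#' Shortlist a template prediction
#'
#' Keeps the smallest prefix of the sorted prediction whose cumulative
#' probability reaches `config@cutoffCumulative`, truncated to
#' `config@cutoffNumber` rows; at least one row is always kept. The result
#' is a prefix — rows are never reordered or skipped.
#'
#' @param prediction A prediction frame from [predictTemplates()].
#' @param config A [policyConfig()].
#' @return The shortlisted prediction frame.
#' @export
shortlistPrediction <- function(prediction, config = policyConfig()) {
  stopifnot(is.data.frame(prediction), nrow(prediction) >= 1L)
  cum <- cumsum(prediction$probability)
  k <- which(cum >= config@cutoffCumulative - 1e-12)[1]
  if (is.na(k)) k <- nrow(prediction)
  k <- max(1L, min(k, config@cutoffNumber))
  prediction[seq_len(k), , drop = FALSE]
}

# ---- TabularPolicy --------------------------------------------------------

#' @rdname tabularPolicy
#' @slot table Named list mapping molecule identity keys to named numeric
#'   probability vectors (names = template ids).
#' @export
setClass("TabularPolicy", contains = "Policy", representation(table = "list"))

#' Tabular (lookup) policy
#'
#' An explicit molecule-to-distribution table, the deterministic policy used
#' for reproducible runs and tests. Molecules absent from the table fall
#' back to the uniform distribution over the library, which keeps a search
#' alive on unanticipated intermediates.
#'
#' @param templates Template library (named list of
#'   [RetroTemplate-class]).
#' @param table Named list: molecule identity key (or SMILES, converted) to
#'   named probability vector over template ids. May be empty, giving a
#'   uniform policy.
#' @return A `TabularPolicy`.
#' @export
tabularPolicy <- function(templates, table = list()) {
  keys <- names(table)
  if (length(table)) {
    # accept SMILES keys for convenience; normalize to identity keys
    looksLikeKey <- grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$|^SMI:", keys)
    for (i in which(!looksLikeKey)) keys[i] <- identityKey(parseMolecule(keys[i]))
    names(table) <- keys
    tids <- vapply(templates, templateId, character(1))
    for (k in keys) {
      p <- table[[k]]
      if (is.null(names(p)) || !all(names(p) %in% tids))
        stop("table probabilities must be named by template ids from the library")
    }
  }
  new("TabularPolicy", templates = templates, table = table)
}

setMethod("predictTemplates", signature("TabularPolicy", "Molecule"),
  function(policy, molecule) {
    .checkLoaded(policy)
    tids <- vapply(policy@templates, templateId, character(1))
    probs <- stats::setNames(rep(0, length(tids)), tids)
    row <- policy@table[[molecule@key]]
    if (is.null(row)) {
      probs[] <- 1 / length(tids)          # uniform fallback
    } else {
      probs[names(row)] <- row
      s <- sum(probs)
      if (abs(s - 1) > 1e-6) probs <- probs / s
    }
    .predictionFrame(probs)
  })

setMethod("show", "TabularPolicy", function(object) {
  cat(sprintf("TabularPolicy: %d templates, %d tabulated molecules\n",
              length(object@templates), length(object@table)))
})

#' Uniform policy over a template library
#'
#' Convenience: a [tabularPolicy()] with an empty table, i.e. every molecule
#' gets the uniform distribution.
#'
#' @param templates Template library.
#' @return A `TabularPolicy`.
#' @export
uniformPolicy <- function(templates) tabularPolicy(templates, list())

# ---- FingerprintPolicy ----------------------------------------------------

#' @rdname fingerprintPolicy
#' @slot model Fitted multinomial glmnet model.
#' @slot classIds Template ids corresponding to the model's classes.
#' @slot radius Morgan fingerprint radius.
#' @slot nbits Folded fingerprint length.
#' @slot lambda Regularization strength used at prediction.
#' @export
setClass("FingerprintPolicy", contains = "Policy", representation(
  model = "ANY", classIds = "character", radius = "integer",
  nbits = "integer", lambda = "numeric"))

#' Fingerprint-classifier policy
#'
#' Ranks templates with a multinomial softmax classifier over folded Morgan
#' (circular) fingerprints — the desk-scale counterpart of a template-
#' prioritization network, honoring the same contract: a probability
#' distribution over the library, sorted. Construct it with
#' [fitPolicy()]; this constructor assembles the object from its parts.
#'
#' @param templates Template library (named list of
#'   [RetroTemplate-class]).
#' @param model A fitted `glmnet` multinomial model.
#' @param classIds Template ids for the model's response classes.
#' @param radius,nbits Fingerprint parameters used at training time.
#' @param lambda Regularization strength at which to predict.
#' @return A `FingerprintPolicy`.
#' @export
fingerprintPolicy <- function(templates, model, classIds,
                              radius = 2L, nbits = 2048L, lambda = 1e-3) {
  new("FingerprintPolicy", templates = templates, model = model,
      classIds = as.character(classIds), radius = as.integer(radius),
      nbits = as.integer(nbits), lambda = lambda)
}

.fingerprintMatrix <- function(molecules, radius, nbits) {
  i <- integer(0); j <- integer(0)
  for (r in seq_along(molecules)) {
    bits <- .moleculeFingerprint(molecules[[r]], radius, nbits)
    i <- c(i, rep.int(r, length(bits)))
    j <- c(j, bits)
  }
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(length(molecules), nbits))
}

setMethod("predictTemplates", signature("FingerprintPolicy", "Molecule"),
  function(policy, molecule) {
    .checkLoaded(policy)
    X <- .fingerprintMatrix(list(molecule), policy@radius, policy@nbits)
    p <- stats::predict(policy@model, newx = X, type = "response",
                        s = policy@lambda)
    p <- drop(p)                            # named by class labels
    tids <- vapply(policy@templates, templateId, character(1))
    probs <- stats::setNames(rep(0, length(tids)), tids)
    probs[policy@classIds] <- p[policy@classIds]
    .predictionFrame(probs)
  })

setMethod("show", "FingerprintPolicy", function(object) {
  cat(sprintf("FingerprintPolicy: %d templates, %d trained classes, radius %d, %d bits\n",
              length(object@templates), length(object@classIds),
              object@radius, object@nbits))
})

# ---- serialization --------------------------------------------------------

#' Save / load a fitted policy
#'
#' Serializes a policy to a single file (RDS with a format-version field).
#'
#' @param policy A [Policy-class].
#' @param path Destination file.
#' @return `loadPolicy` returns the policy; `savePolicy` the path,
#'   invisibly.
#' @export
savePolicy <- function(policy, path) {
  stopifnot(is(policy, "Policy"))
  saveRDS(list(format_version = 1L, policy = policy), path)
  invisible(path)
}

#' @rdname savePolicy
#' @export
loadPolicy <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$format_version))
    stop("not a retroplan policy file (missing format_version)")
  obj$policy
}
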