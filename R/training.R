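#' @include policy.R
NULL

#' TrainingSet: (product, template) pairs for policy fitting
#'
#' @slot molecules List of [Molecule-class] products (deduplicated jointly
#'   with their template id).
#' @slot templateIds Character vector, parallel to `molecules`.
#' @slot templates The template library the ids refer to.
#' @export
setClass("TrainingSet", representation(
  molecules = "list", templateIds = "character", templates = "list"))

setMethod("show", "TrainingSet", function(object) {
  tab <- table(object@templateIds)
  cat(sprintf("TrainingSet: %d pairs over %d template class(es)\n",
              length(object@molecules), length(tab)))
  print(tab)
})

#' @describeIn buildTrainingSet Number of (product, template) pairs.
#' @param x A `TrainingSet`.
#' @export
trainingSize <- function(x) {
  stopifnot(is(x, "TrainingSet"))
  length(x@molecules)
}

#' Build a training set from (product, template) records
#'
#' Canonicalizes products, checks every template id against the library and
#' drops exact duplicates (same product structure and same template id).
#'
#' @param reactions A `data.frame` with columns `product_smiles` and
#'   `template_id` (or a list of two-element vectors).
#' @param templates Template library (named list of
#'   [RetroTemplate-class]).
#' @return A [TrainingSet-class]. Raises `trainingDataError` on empty
#'   input, unparsable products, or unknown template ids.
#' @export
buildTrainingSet <- function(reactions, templates) {
  if (is.list(reactions) && !is.data.frame(reactions)) {
    reactions <- data.frame(
      product_smiles = vapply(reactions, function(r) as.character(r[[1]]), character(1)),
      template_id = vapply(reactions, function(r) as.character(r[[2]]), character(1)),
      stringsAsFactors = FALSE)
  }
  if (!is.data.frame(reactions) ||
      !all(c("product_smiles", "template_id") %in% names(reactions)))
    .chemError("trainingDataError",
               "reactions must have columns product_smiles and template_id")
  if (nrow(reactions) == 0L)
    .chemError("trainingDataError", "no training reactions given")
  libIds <- vapply(templates, templateId, character(1))
  tid <- as.character(reactions$template_id)
  unknown <- setdiff(unique(tid), libIds)
  if (length(unknown))
    .chemError("trainingDataError",
               sprintf("unknown template id(s): %s", paste(unknown, collapse = ", ")))
  mols <- vector("list", nrow(reactions))
  for (i in seq_len(nrow(reactions))) {
    mols[[i]] <- tryCatch(parseMolecule(reactions$product_smiles[i]),
      error = function(e) .chemError("trainingDataError",
        sprintf("unparsable product SMILES '%s'", reactions$product_smiles[i])))
  }
  sig <- paste(vapply(mols, identityKey, character(1)), tid, sep = "\r")
  keep <- !duplicated(sig)
  new("TrainingSet", molecules = mols[keep], templateIds = tid[keep],
      templates = templates)
}

#' Fit a fingerprint-classifier policy
#'
#' Trains the multinomial softmax ranker of [fingerprintPolicy()]: folded
#' Morgan fingerprints (default radius 2, 2048 bits) into an
#' L2-regularized multinomial logistic model. The fit is deterministic; the
#' `seed` argument is recorded for provenance and reserved for future
#' stochastic options (e.g. held-out splits).
#'
#' @param ts A [TrainingSet-class] with at least two distinct template
#'   classes.
#' @param seed Integer seed (recorded; the default fit is deterministic).
#' @param radius,nbits Fingerprint parameters.
#' @param lambda L2 regularization strength.
#' @param maxit Maximum optimizer iterations.
#' @return A [fingerprintPolicy()] over the training set's library.
#' @export
fitPolicy <- function(ts, seed = 1L, radius = 2L, nbits = 2048L,
                      lambda = 1e-3, maxit = 500L) {
  stopifnot(is(ts, "TrainingSet"))
  classes <- sort(unique(ts@templateIds))
  if (length(classes) < 2L)
    .chemError("trainingDataError",
               "need at least two distinct template classes to fit a policy")
  X <- .fingerprintMatrix(ts@molecules, as.integer(radius), as.integer(nbits))
  y <- factor(ts@templateIds, levels = classes)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  fit <- glmnet::glmnet(X, y, family = "multinomial", alpha = 0,
                        lambda = lambda * c(100, 10, 1), standardize = FALSE,
                        maxit = as.integer(maxit))
  fingerprintPolicy(ts@templates, fit, classes,
                    radius = radius, nbits = nbits, lambda = lambda)
}

#' Top-1 accuracy of a policy on a training set
#'
#' @param policy A [Policy-class].
#' @param ts A [TrainingSet-class].
#' @return Fraction of pairs whose true template is ranked first.
#' @export
policyAccuracy <- function(policy, ts) {
  stopifnot(is(policy, "Policy"), is(ts, "TrainingSet"))
  hits <- vapply(seq_along(ts@molecules), function(i) {
    pred <- predictTemplates(policy, ts@molecules[[i]])
    pred$templateId[1] == ts@templateIds[i]
  }, logical(1))
  mean(hits)
}
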