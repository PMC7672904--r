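test_that("tabular policy returns its table rows, sorted with id tie-break", {
  tmpls <- toyTemplatesCached()
  m <- parseMolecule("CCOC(C)=O")
  pol <- tabularPolicy(tmpls, stats::setNames(
    list(c(t_ester = 0.7, t_amide = 0.3, t_ether = 0)), smiles(m)))
  pred <- predictTemplates(pol, m)
  expect_identical(pred$templateId[1:2], c("t_ester", "t_amide"))
  expect_equal(pred$probability, c(0.7, 0.3, 0), tolerance = 1e-12)
  expect_equal(sum(pred$probability), 1, tolerance = 1e-6)
  # exact ties are broken by ascending template id
  tiePol <- tabularPolicy(tmpls, stats::setNames(
    list(c(t_ether = 0.4, t_amide = 0.4, t_ester = 0.2)), smiles(m)))
  tie <- predictTemplates(tiePol, m)
  expect_identical(tie$templateId, c("t_amide", "t_ether", "t_ester"))
})

test_that("unknown molecules fall back to the uniform distribution", {
  pol <- uniformPolicy(toyTemplatesCached())
  pred <- predictTemplates(pol, "c1ccccc1")
  expect_equal(pred$probability, rep(1 / 3, 3))
  expect_identical(pred$templateId, sort(pred$templateId))
})

test_that("prediction is deterministic for a fixed policy", {
  pol <- uniformPolicy(toyTemplatesCached())
  expect_identical(predictTemplates(pol, "CCO"), predictTemplates(pol, "CCO"))
})

test_that("an empty library raises policyNotLoadedError", {
  pol <- tabularPolicy(list())
  expect_error(predictTemplates(pol, "CCO"), class = "policyNotLoadedError")
})

test_that("shortlisting keeps the smallest sufficient prefix", {
  mk <- function(p) data.frame(
    templateId = sprintf("t%02d", seq_along(p)), probability = p,
    stringsAsFactors = FALSE)
  # cumulative sums 0.6, 0.9 >= 0.9 after two entries
  s <- shortlistPrediction(mk(c(0.6, 0.3, 0.08, 0.02)),
                           policyConfig(cutoffNumber = 10, cutoffCumulative = 0.9))
  expect_equal(nrow(s), 2)
  # count cap dominates
  s2 <- shortlistPrediction(mk(c(0.6, 0.3, 0.1)), policyConfig(cutoffNumber = 1))
  expect_equal(nrow(s2), 1)
  # a single certain item survives any config
  s3 <- shortlistPrediction(mk(1), policyConfig(cutoffNumber = 50,
                                                cutoffCumulative = 0.5))
  expect_equal(nrow(s3), 1)
})

test_that("a shortlist is always a prefix of the sorted prediction", {
  pol <- uniformPolicy(toyTemplatesCached())
  trained <- trainedPolicyCached()$policy
  mols <- c("CCOC(C)=O", "CNC(=O)C", "CCOCC", "c1ccccc1")
  for (m in mols) for (p in list(pol, trained)) {
    pred <- predictTemplates(p, m)
    for (cc in c(0.3, 0.9, 0.995)) {
      s <- shortlistPrediction(pred, policyConfig(cutoffNumber = 2,
                                                  cutoffCumulative = cc))
      expect_identical(s, pred[seq_len(nrow(s)), ])
      expect_lte(nrow(s), 2)
      expect_gte(nrow(s), 1)
    }
  }
})

test_that("fingerprint policy probabilities form a distribution", {
  trained <- trainedPolicyCached()$policy
  for (m in c("CCOC(C)=O", "CCNC(=O)CC", "COC")) {
    pred <- predictTemplates(trained, m)
    expect_true(all(pred$probability >= 0))
    expect_equal(sum(pred$probability), 1, tolerance = 1e-6)
    expect_true(all(diff(pred$probability) <= 1e-12))
  }
})

test_that("policies round-trip through serialization", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "policy.bin")
  trained <- trainedPolicyCached()$policy
  savePolicy(trained, p)
  back <- loadPolicy(p)
  expect_identical(predictTemplates(back, "CCOC(C)=O"),
                   predictTemplates(trained, "CCOC(C)=O"))
  saveRDS(list(no = "version"), p)
  expect_error(loadPolicy(p), "format_version")
})
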