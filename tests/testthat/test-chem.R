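test_that("parsing canonicalizes and keys are atom-order independent", {
  m <- parseMolecule("OCC")
  expect_s4_class(m, "Molecule")
  expect_equal(smiles(m), "CCO")
  expect_equal(identityKey(parseMolecule("CCO")), identityKey(m))
  expect_true(parseMolecule("C(O)C") == m)
  expect_equal(carbonCount(m), 2L)
  # canonicalization is idempotent over a mixed fixture panel
  panel <- c("OCC", "c1ccccc1C", "CC(=O)OCC", "N(C)C(=O)c1ccccc1",
             "OCCN", "CC(C)C(=O)O")
  for (sm in panel) {
    once <- smiles(parseMolecule(sm))
    expect_identical(smiles(parseMolecule(once)), once)
  }
})

test_that("unparsable SMILES raise moleculeParseError", {
  expect_error(parseMolecule("C1CC"), class = "moleculeParseError")
  expect_error(parseMolecule(""), class = "moleculeParseError")
  expect_error(parseMolecule("not_a_smiles"), class = "moleculeParseError")
})

test_that("retro templates validate their reaction SMARTS", {
  expect_s4_class(amideTemplate(), "RetroTemplate")
  expect_error(retroTemplate("bad", "this is not smarts"),
               class = "templateParseError")
  # two product-side patterns are rejected (retro direction needs one)
  expect_error(
    retroTemplate("two", "[C:1].[C:2]>>[C:1][C:2]"),
    class = "templateParseError")
})

test_that("amide cleavage recovers precursors that recompose the target", {
  sets <- applyTemplate(amideTemplate(), "CNC(=O)c1ccccc1")
  expect_length(sets, 1)
  got <- sort(vapply(sets[[1]], smiles, character(1)))
  expect_identical(got, sort(c("CN", "O=C(O)c1ccccc1")))
  # forward recomposition regenerates the target
  fwd <- retroplan:::.applyForward(
    "[C:1](=[O:2])[OX2H1].[NX3;H2:3][CX4:4]>>[C:1](=[O:2])[N:3][C:4]",
    c("O=C(O)c1ccccc1", "CN"))
  expect_identical(fwd, smiles(parseMolecule("CNC(=O)c1ccccc1")))
})

test_that("non-matching targets give an empty list, never an error", {
  expect_identical(applyTemplate(amideTemplate(), "c1ccccc1"), list())
})

test_that("a bis-amide yields two distinct precursor sets", {
  sets <- applyTemplate(amideTemplate(), "CNC(=O)CCC(=O)NCC")
  expect_length(sets, 2)
  sigs <- vapply(sets, function(s)
    paste(sort(vapply(s, identityKey, character(1))), collapse = "|"),
    character(1))
  expect_length(unique(sigs), 2)
})

test_that("template application is invariant to target atom ordering", {
  a <- applyTemplate(amideTemplate(), "CNC(=O)c1ccccc1")
  b <- applyTemplate(amideTemplate(), "c1ccccc1C(=O)NC")
  expect_equal(lapply(a, function(s) vapply(s, smiles, character(1))),
               lapply(b, function(s) vapply(s, smiles, character(1))))
})

test_that("self-loop outcomes are discarded", {
  noop <- retroTemplate("noop", "[OX2H1:1][CX4:2]>>[OX2H1:1][C:2]")
  expect_identical(applyTemplate(noop, "CCO"), list())
})

test_that("sanitization failures are dropped silently and counted", {
  chemDiagnostics(reset = TRUE)
  boom <- retroTemplate("boom", "[CX4;H3:1][CX4:2]>>[C:1](=C)(=C)C.[C:2]")
  expect_identical(applyTemplate(boom, "CCO"), list())
  expect_gte(chemDiagnostics()$n_sanitize_failed, 1L)
})

test_that("template libraries load from tab and comma separated files", {
  tmpls <- toyTemplatesCached()
  dir <- withr::local_tempdir()
  df <- data.frame(template_id = vapply(tmpls, templateId, character(1)),
                   retro_smarts = vapply(tmpls, retroSmarts, character(1)),
                   name = "toy")
  tsv <- file.path(dir, "lib.tsv")
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  csv <- file.path(dir, "lib.csv")
  write.table(df, csv, sep = ",", quote = FALSE, row.names = FALSE)
  for (p in c(tsv, csv)) {
    lib <- loadTemplateLibrary(p)
    expect_named(lib, names(tmpls))
    expect_identical(vapply(lib, retroSmarts, character(1)),
                     vapply(tmpls, retroSmarts, character(1)))
    expect_equal(lib[[1]]@metadata$name, "toy")
  }
  expect_error(loadTemplateLibrary(file.path(dir, "missing.tsv")),
               class = "templateParseError")
})

test_that("tree molecules track transform depth", {
  tm <- treeMolecule("OCC")
  expect_equal(transformDepth(tm), 0L)
  deeper <- treeMolecule(parseMolecule("CN"), transformDepth = 3L)
  expect_equal(transformDepth(deeper), 3L)
  expect_error(treeMolecule("CCO", -1L))
})
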