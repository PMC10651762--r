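# internal graph kernel: SMILES round trips, sanitization, ring perception

test_that("parsed and rewritten SMILES round-trip to the same canonical key", {
  panel <- c("CCO", "Cc1ccccc1", "c1ccc(-c2ccccc2)cc1", "O=c1ccccn1C",
             "c1cc[nH]c1", "CC(=O)[O-]", "C[N+](C)(C)C", "c1ccsc1",
             "c1ccncc1", "CC1SC(=O)[N-]C1=O", "OCC(O)CO", "C#CC#C",
             "CC(C)(C)c1ccc(O)cc1", "O=[N+]([O-])c1ccccc1")
  for (smi in panel) {
    g <- ChemLibDesign:::.sanitizeMol(ChemLibDesign:::.parseSmiles(smi))
    written <- ChemLibDesign:::.writeSmiles(g)
    expect_identical(obcan(written), obcan(smi), label = smi)
  }
})

test_that("valence and aromaticity violations are rejected with typed errors", {
  expect_error(
    ChemLibDesign:::.sanitizeMol(ChemLibDesign:::.parseSmiles("C(C)(C)(C)(C)C")),
    class = "chem_valence_error")
  expect_error(
    ChemLibDesign:::.sanitizeMol(ChemLibDesign:::.parseSmiles("cc")),
    class = "chem_sanitize_error")
  expect_error(ChemLibDesign:::.parseSmiles("C1CC"),   # unclosed ring
               class = "chem_parse_error")
  expect_error(ChemLibDesign:::.parseSmiles("C(C"),
               class = "chem_parse_error")
  expect_error(ChemLibDesign:::.parseSmiles(""),
               class = "chem_parse_error")
})

test_that("implicit hydrogen assignment follows standard valence rules", {
  g <- ChemLibDesign:::.sanitizeMol(ChemLibDesign:::.parseSmiles("Cc1ccccc1"))
  expect_identical(g$hcount, c(3L, 0L, 1L, 1L, 1L, 1L, 1L))
  g2 <- ChemLibDesign:::.sanitizeMol(ChemLibDesign:::.parseSmiles("c1cc[nH]c1"))
  expect_identical(sum(g2$hcount[g2$elem == "N"]), 1L)
  g3 <- ChemLibDesign:::.sanitizeMol(ChemLibDesign:::.parseSmiles("CS(=O)(=O)C"))
  expect_identical(g3$hcount[g3$elem == "S"], 0L)
})

test_that("ring perception distinguishes ring from acyclic bonds", {
  g <- ChemLibDesign:::.sanitizeMol(
    ChemLibDesign:::.parseSmiles("CC1CCCCC1c1ccccc1"))
  ringb <- ChemLibDesign:::.ringBonds(g)
  expect_identical(sum(ringb), 12L)          # two 6-rings
  sssr <- ChemLibDesign:::.sssr(g)
  expect_identical(sort(vapply(sssr, length, integer(1))), c(6L, 6L))
  # naphthalene: 2 SSSR rings from 11 ring bonds
  gn <- ChemLibDesign:::.sanitizeMol(
    ChemLibDesign:::.parseSmiles("c1ccc2ccccc2c1"))
  expect_identical(length(ChemLibDesign:::.sssr(gn)), 2L)
})

test_that("molecular weight matches reference values", {
  mw <- function(s) ChemLibDesign:::.molWeight(
    ChemLibDesign:::.sanitizeMol(ChemLibDesign:::.parseSmiles(s)))
  expect_equal(mw("c1ccccc1"), 78.112, tolerance = 1e-3)
  expect_equal(mw("CC(=O)O"), 60.052, tolerance = 1e-3)
  expect_equal(mw("O"), 18.015, tolerance = 1e-3)
})

test_that("SMARTS primitives match their definitions", {
  feat <- ChemLibDesign:::.molFeatures(
    ChemLibDesign:::.sanitizeMol(ChemLibDesign:::.parseSmiles("Cc1ccccc1")))
  count <- function(p) length(ChemLibDesign:::.matchSmarts(
    feat, ChemLibDesign:::.parseSmarts(p)))
  expect_identical(count("[cD2]"), 5L)     # unsubstituted aromatic CH
  expect_identical(count("[cD3]"), 1L)     # ipso carbon
  expect_identical(count("[CX4H3]"), 1L)   # methyl
  expect_identical(count("[R]"), 6L)       # ring atoms
  expect_identical(count("[r6]"), 6L)
  expect_identical(count("[r5]"), 0L)
  expect_identical(count("a"), 6L)
  expect_identical(count("[!#6]"), 0L)
  # recursive and negated forms
  expect_identical(count("[c;$(c(c)c)]"), 6L)
  expect_identical(count("[C;!R]"), 1L)
})
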