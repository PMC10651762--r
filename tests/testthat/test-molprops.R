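# descriptors, QED drug-likeness, synthetic-accessibility score

test_that("profile descriptors match hand-checkable values", {
  prof <- as.data.frame(computeProfile(
    c("c1ccccc1", "CC(N)C(=O)O", "CC(=O)O", "CCOCC", "CC(=O)NC")))
  rownames(prof) <- prof$canonicalKey
  benz <- prof[obcan("c1ccccc1"), ]
  expect_identical(benz$TPSA, 0)
  expect_identical(benz$HBD, 0L)
  expect_identical(benz$RotB, 0L)
  expect_identical(benz$AROM, 1L)
  ala <- prof[obcan("CC(N)C(=O)O"), ]
  expect_identical(ala$nChiral, 1L)
  expect_identical(ala$HBA, 3L)
  expect_identical(ala$HBD, 2L)
  acid <- prof[obcan("CC(=O)O"), ]
  expect_equal(acid$TPSA, 37.3, tolerance = 1e-6)
  ether <- prof[obcan("CCOCC"), ]
  expect_identical(ether$RotB, 2L)
  amide <- prof[obcan("CC(=O)NC"), ]
  expect_identical(amide$RotB, 0L)   # amide C-N excluded
})

test_that("identical canonical keys give identical profiles", {
  p1 <- as.data.frame(computeProfile("c1ccccc1CC(N)C(=O)O"))
  p2 <- as.data.frame(computeProfile("OC(=O)C(N)Cc1ccccc1"))
  expect_identical(p1, p2)
})

test_that("QED equals the weighted geometric mean of its desirabilities", {
  props <- data.frame(MW = 250, ALOGP = 2.2, HBA = 3, HBD = 1, PSA = 60,
                      ROTB = 4, AROM = 1, ALERTS = 0)
  d <- vapply(names(ChemLibDesign:::.QED_ADS), function(ch)
    ChemLibDesign:::.qedADS(props[[ch]], ChemLibDesign:::.QED_ADS[[ch]]),
    numeric(1))
  w <- ChemLibDesign:::.QED_WEIGHTS[names(ChemLibDesign:::.QED_ADS)]
  expect_equal(qedFromProperties(props),
               exp(sum(w * log(d)) / sum(w)), tolerance = 1e-12)
  # unit weights: plain geometric mean; equal desirabilities d return d
  expect_equal(qedFromProperties(props, weights = stats::setNames(
    rep(1, 8), names(w))), exp(mean(log(d))), tolerance = 1e-12)
})

test_that("QED desirability math reproduces the reference implementation", {
  oracle <- loadOracle("qed_oracle.csv")
  mine <- qedFromProperties(oracle[, c("MW", "ALOGP", "HBA", "HBD", "PSA",
                                       "ROTB", "AROM", "ALERTS")])
  # same property vector in, same score out (the desirability machinery)
  expect_equal(mine, oracle$qed, tolerance = 1e-6)
})

test_that("molecule-level QED tracks the reference within descriptor drift", {
  oracle <- loadOracle("qed_oracle.csv")
  mine <- qedScore(oracle$smiles)
  # different toolkits count acceptors/alerts differently; agreement is
  # expected at the distribution level, not the third decimal
  expect_lt(stats::median(abs(mine - oracle$qed)), 0.1)
  expect_gt(stats::cor(mine, oracle$qed), 0.85)
})

test_that("QED lies in (0, 1] and decreases in the alerts channel", {
  lib <- makeReferenceLibrary(30, seed = 5)
  q <- qedScore(lib)
  expect_true(all(q > 0 & q <= 1))
  base <- data.frame(MW = 300, ALOGP = 2.5, HBA = 3, HBD = 1, PSA = 70,
                     ROTB = 4, AROM = 2, ALERTS = 0:4)
  q2 <- qedFromProperties(base)
  expect_true(all(diff(q2) < 0))
})

test_that("SA scores stay in [1, 10] and rank ethane near the easy end", {
  panel <- c("CC", "CCO", "Cc1ccccc1", "CC(=O)Oc1ccccc1C(=O)O",
             "CC12CC(O)C3C(CCC4=CC(=O)CCC34C)C1CCC2C(=O)CO",
             "C1CCCCCCCCCCCCCCCCCCC1", "CCCCCCCCCCCCCCCCCCCC",
             "CC1SC(=O)NC1=O", "CN(C)C12CC(C1)C2")
  s <- saScore(panel)
  expect_true(all(s >= 1 & s <= 10))
  expect_lt(saScore("CC"), 3)
})

test_that("the macrocycle penalty term is present for rings larger than 8", {
  scores <- ChemLibDesign:::.defaultFragmentScores()
  gRing <- ChemLibDesign:::.sanitizeMol(
    ChemLibDesign:::.parseSmiles("C1CCCCCCCCCCCCCCCCCCC1"))
  gChain <- ChemLibDesign:::.sanitizeMol(
    ChemLibDesign:::.parseSmiles("CCCCCCCCCCCCCCCCCCCC"))
  cRing <- ChemLibDesign:::.saScoreComponents(gRing, scores)
  cChain <- ChemLibDesign:::.saScoreComponents(gChain, scores)
  expect_equal(cRing$macrocyclePenalty, log10(2))
  expect_identical(cChain$macrocyclePenalty, 0)
  # an 8-ring is not a macrocycle
  g8 <- ChemLibDesign:::.sanitizeMol(
    ChemLibDesign:::.parseSmiles("C1CCCCCCC1"))
  expect_identical(
    ChemLibDesign:::.saScoreComponents(g8, scores)$macrocyclePenalty, 0)
})

test_that("stereo, spiro and bridge penalties respond to the right features", {
  scores <- ChemLibDesign:::.defaultFragmentScores()
  comp <- function(s) ChemLibDesign:::.saScoreComponents(
    ChemLibDesign:::.sanitizeMol(ChemLibDesign:::.parseSmiles(s)), scores)
  expect_gt(comp("CC(N)C(=O)O")$stereoPenalty, 0)       # one stereocenter
  expect_identical(comp("CCC(=O)O")$stereoPenalty, 0)
  expect_gt(comp("C1CCC2(CC1)CCCC2")$spiroPenalty, 0)   # spiro decane
  expect_gt(comp("C1C2CC3CC1CC(C2)C3")$bridgePenalty, 0) # adamantane
  expect_identical(comp("c1ccc2ccccc2c1")$bridgePenalty, 0) # fused, no bridge
})

test_that("a user-supplied fragment table is honored and stays in range", {
  tab <- buildFragmentScores(c("CCO", "CCC", "CCN"))
  s <- saScore("CCO", fragmentScores = tab)
  expect_true(s >= 1 && s <= 10)
  # in a table built from tiny polar molecules, ethanol's environments are
  # all known and common, so it scores easier than under a mismatched table
  expect_lte(s, saScore("c1ccsc1", fragmentScores = tab))
})
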