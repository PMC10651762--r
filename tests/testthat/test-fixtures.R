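# built-in rules, seed sets, reference-library emulator

test_that("the built-in compendium carries all printed rules with metadata", {
  rules <- builtinRules()
  expect_identical(length(rules), 7L)
  expect_identical(rules[["phenyl_to_cyclohexyl"]]@transformationType,
                   "ring substitution")
  expect_identical(rules[["phenyl_to_cyclohexyl"]]@group, "Phenyl")
  expect_true("Bioisosteric replacement" %in%
                rules[["phenyl_to_cyclohexyl"]]@notes)
  gc <- groupCounts(rules)
  expect_identical(unname(gc["Phenyl"]), 3L)
  expect_identical(sum(gc), 7L)
  expect_true(all(ruleStatus(rules) == "parsed"))
})

test_that("every built-in rule fires on its motif probe", {
  rep <- validateRules(builtinRules())
  expect_true(all(rep@perRule$status == "parsed"))
  expect_true(all(rep@perRule$nProducts >= 1L))
})

test_that("seed sets are deterministic, motif-bearing and curation-stable", {
  s1 <- makeSeedSet(c("carboxylic-acid", "phenyl"), countPerMotif = 2L,
                    seed = 4L)
  s2 <- makeSeedSet(c("carboxylic-acid", "phenyl"), countPerMotif = 2L,
                    seed = 4L)
  expect_identical(canonicalKeys(s1), canonicalKeys(s2))
  expect_identical(length(s1), 4L)
  # carboxyl seeds are matched by the carboxyl rule's reactant pattern
  rule <- builtinRules()[["carboxyl_to_thiazolidinedione"]]
  acid <- makeSeedSet("carboxylic-acid", countPerMotif = 1L)
  expect_true(ChemLibDesign:::.hasSubstructure(
    acid@graphs[[1]], rule@compiled$reactant))
  # curation-stable: re-curating the keys changes nothing
  re <- curateLibrary(canonicalKeys(s1))
  expect_identical(canonicalKeys(re$set), canonicalKeys(s1))
})

test_that("empty counts and unknown motifs are handled explicitly", {
  expect_identical(length(makeSeedSet("phenyl", countPerMotif = 0L)), 0L)
  expect_error(makeSeedSet("no-such-motif"), "unknown motif")
})

test_that("the reference-library emulator hits requested property targets", {
  one <- makeReferenceLibrary(1, seed = 2)
  expect_identical(length(one), 1L)
  lib <- makeReferenceLibrary(50, propertyTargets = c(MW = 350), seed = 3)
  mw <- mean(computeProfile(lib)$MW)
  expect_lt(abs(mw - 350), 50)
})

test_that("libraries built on disjoint scaffolds separate in property PCA", {
  small <- curateLibrary(sapply(2:13, function(k)
    paste(rep("C", k), collapse = "")))$set
  polar <- curateLibrary(paste0(
    sapply(2:13, function(k) paste(rep("C", k), collapse = "")),
    "C(=O)NC(=O)NC(=O)O"))$set
  dm <- descriptorMatrix(apolar = small, polar = polar)
  emb <- pcaEmbed(dm)
  pc1 <- emb$coords[, 1]
  gap <- range(pc1[dm$labels == "apolar"])
  expect_true(all(pc1[dm$labels == "polar"] > gap[2]) ||
                all(pc1[dm$labels == "polar"] < gap[1]))
})
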