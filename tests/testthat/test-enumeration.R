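# property gates, single-step expansion, iterative enumeration

test_that("gate boundaries: MW strict, TPSA inclusive", {
  fake <- S4Vectors::DataFrame(MW = c(630, 400, 629.99, 400),
                               TPSA = c(100, 40, 150, 39.99))
  cfg <- enumerationConfig()
  set <- curateLibrary(c("CCO", "CCC", "CCN", "CCS"))$set
  expect_identical(propertyGate(set, cfg, profile = fake),
                   c(FALSE, TRUE, TRUE, FALSE))
  # benzene sits below the TPSA floor
  expect_false(propertyGate("c1ccccc1", cfg))
})

test_that("expandOnce applies every rule once per site with provenance", {
  rules <- builtinRules()
  res <- expandOnce(curateLibrary("Cc1ccccc1")$set,
                    rules["phenyl_to_cyclohexyl"])
  expect_identical(canonicalKeys(res$set), obcan("CC1CCCCC1"))
  expect_identical(res$parents$ruleId, "phenyl_to_cyclohexyl")
  expect_identical(res$parents$parentKey, obcan("Cc1ccccc1"))
  # no matching motif -> empty expansion
  res2 <- expandOnce(curateLibrary("C1CCCCC1")$set,
                     rules["phenyl_to_cyclohexyl"])
  expect_identical(length(res2$set), 0L)
})

test_that("coinciding products keep the first rule's provenance", {
  f <- withr::local_tempfile(fileext = ".tsv")
  smirks <- paste0("[c; x2:2]1[c; x2:3][c; x2:4][c; x2:5][c; x2:6]",
                   "[c; x2:1]1>>[#6:5]-1-[#6:6]-[#6:1]-[#6:2]-[#6:3]-[#6:4]-1")
  writeLines(c(paste(ChemLibDesign:::.COMPENDIUM_COLUMNS, collapse = "\t"),
               paste("rA", "Phenyl", "first", "ring substitution", smirks,
                     "", "x", sep = "\t"),
               paste("rB", "Phenyl", "second", "ring substitution", smirks,
                     "", "x", sep = "\t")), f)
  comp <- readRuleCompendium(f)
  res <- expandOnce(curateLibrary("Cc1ccccc1")$set, comp)
  expect_identical(length(res$set), 1L)
  expect_identical(res$parents$ruleId, "rA")
})

test_that("a single-rule enumeration terminates after exhausting its motif", {
  lib <- enumerateLibrary("Cc1ccccc1",
                          builtinRules()["phenyl_to_cyclohexyl"],
                          openConfig(2L))
  expect_identical(length(lib), 1L)
  expect_identical(canonicalKeys(lib), obcan("CC1CCCCC1"))
  expect_identical(lib@iterationCounts, c(1L, 0L))
  expect_identical(lib@provenance$iterationBorn, 1L)
})

test_that("zero iterations yield an empty library, or seeds when configured", {
  lib0 <- enumerateLibrary("Cc1ccccc1", builtinRules(), openConfig(0L))
  expect_identical(length(lib0), 0L)
  cfgSeeds <- enumerationConfig(nIterations = 0L, mwMax = Inf,
                                tpsaMin = -Inf, tpsaMax = Inf,
                                includeSeeds = TRUE)
  libS <- enumerateLibrary("Cc1ccccc1", builtinRules(), cfgSeeds)
  expect_identical(length(libS), 1L)
  expect_identical(libS@provenance$iterationBorn, 0L)
})

test_that("distinct phenyl sites yield at most one product per distinct outcome", {
  # two equivalent rings -> 1 product; two distinguishable rings -> 2
  libSym <- enumerateLibrary("c1ccc(-c2ccccc2)cc1",
                             builtinRules()["phenyl_to_cyclohexyl"],
                             openConfig(1L))
  expect_identical(length(libSym), 1L)
  libAsym <- enumerateLibrary("Cc1ccccc1-c1ccccc1",
                              builtinRules()["phenyl_to_cyclohexyl"],
                              openConfig(1L))
  expect_identical(length(libAsym), 2L)
})

test_that("library size is monotone in iterations and gate tightness", {
  seeds <- makeSeedSet(c("phenyl", "carboxylic-acid"), countPerMotif = 1L)
  rules <- builtinRules()
  n1 <- length(enumerateLibrary(seeds, rules, openConfig(1L)))
  n2 <- length(enumerateLibrary(seeds, rules, openConfig(2L)))
  expect_lte(n1, n2)
  wide <- enumerationConfig(nIterations = 1L, mwMax = Inf,
                            tpsaMin = -Inf, tpsaMax = Inf)
  tight <- enumerationConfig(nIterations = 1L, mwMax = 200,
                             tpsaMin = 40, tpsaMax = 150)
  expect_gte(length(enumerateLibrary(seeds, rules, wide)),
             length(enumerateLibrary(seeds, rules, tight)))
})

test_that("no emitted record violates the property gate", {
  seeds <- makeSeedSet(countPerMotif = 1L)
  cfg <- enumerationConfig(nIterations = 1L)
  lib <- enumerateLibrary(seeds, builtinRules(), cfg)
  if (length(lib)) {
    expect_true(all(propertyGate(lib, cfg)))
  }
})

test_that("two runs on identical inputs are byte-identical", {
  seeds <- makeSeedSet(c("phenyl", "benzoylphenyl"), countPerMotif = 2L)
  rules <- builtinRules()
  cfg <- enumerationConfig(nIterations = 2L)
  libA <- enumerateLibrary(seeds, rules, cfg)
  libB <- enumerateLibrary(seeds, rules, cfg)
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  writeEnumerated(libA, fa); writeEnumerated(libB, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("every record's rule chain replays to its canonical key", {
  seeds <- makeSeedSet(c("carboxylic-acid", "phenyl"), countPerMotif = 1L)
  rules <- builtinRules()
  lib <- enumerateLibrary(seeds, rules, openConfig(2L))
  expect_gt(length(lib), 0L)
  for (i in seq_len(length(lib))) {
    expect_true(replayProvenance(lib, i, seeds, rules),
                label = canonicalKeys(lib)[i])
  }
})

test_that("an empty seed set is an error", {
  empty <- curateLibrary(character(0))$set
  expect_error(enumerateLibrary(empty, builtinRules()), "empty")
})
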