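# SMIRKS parsing, compendium IO, rule application vs the frozen rewrite oracle

test_that("parseSmirks compiles the phenyl ring swap with six mapped atoms", {
  rw <- parseSmirks(paste0(
    "[c;x2:2]1[c;x2:3][c;x2:4][c;x2:5][c;x2:6][c;x2:1]1>>",
    "[#6:5]-1-[#6:6]-[#6:1]-[#6:2]-[#6:3]-[#6:4]-1"))
  expect_s3_class(rw, "CompiledSmirks")
  expect_identical(sum(!is.na(rw$rmap)), 6L)
  expect_identical(sort(rw$rmap), sort(rw$pmap))
  expect_length(rw$newProductMaps, 0)
})

test_that("malformed SMIRKS and duplicate maps raise typed errors", {
  expect_error(parseSmirks("CCO"), class = "chem_smirks_malformed")
  expect_error(parseSmirks("CC>>"), class = "chem_smirks_malformed")
  expect_error(parseSmirks("[C:1][C:1]>>[C:1]"),
               class = "chem_smirks_mapping")
})

test_that("extension blocks are stripped and recorded as metadata", {
  smk <- paste0("[#8; D1][#6; A; !R:2]([*:1]) = O>>",
                "[*:1]-[#6:2]-1-[#16]-[#6](=O)-[#7-]-[#6]-1 = O |s:0:1|")
  rw <- parseSmirks(smk)
  expect_identical(rw$extensions, "|s:0:1|")
  # and the rule still fires
  rules <- builtinRules()
  r <- rules[["carboxyl_to_thiazolidinedione"]]
  expect_identical(r@extensions, "|s:0:1|")
  prods <- applyRule(r, "CC(=O)O")
  expect_identical(canonicalKeys(prods), obcan("CC1SC(=O)[N-]C1=O"))
})

test_that("applyRule reproduces the independent rewrite oracle on all probes", {
  oracle <- loadOracle("applyrule_oracle.csv")
  rules <- builtinRules()
  for (i in seq_len(nrow(oracle))) {
    row <- oracle[i, ]
    got <- canonicalKeys(applyRule(rules[[row$rule_id]], row$probe))
    expect_identical(got, oracleProducts(row),
                     label = paste(row$rule_id, "on", row$probe))
  }
})

test_that("zero-match molecules give an empty set, never an error", {
  rules <- builtinRules()
  prods <- applyRule(rules[["phenyl_to_cyclohexyl"]], "C1CCCCC1")
  expect_identical(length(prods), 0L)
  expect_identical(attr(prods, "nMatches"), 0L)
})

test_that("product count never exceeds match count and reapplication is stable", {
  rules <- builtinRules()
  probes <- c("Cc1ccccc1", "c1ccc(-c2ccccc2)cc1", "CC(=O)O",
              "CN(C)c1ccccc1", "O=C(c1ccccc1)c1ccccc1")
  for (p in probes) {
    for (rid in names(rules)) {
      out1 <- applyRule(rules[[rid]], p)
      expect_lte(length(out1), attr(out1, "nMatches"))
      out2 <- applyRule(rules[[rid]], p)
      expect_identical(canonicalKeys(out1), canonicalKeys(out2))
    }
  }
})

test_that("symmetric sites collapse to one product under canonical dedup", {
  rules <- builtinRules()
  prods <- applyRule(rules[["phenyl_to_cyclohexyl"]],
                     "c1ccc(-c2ccccc2)cc1")
  expect_identical(length(prods), 1L)
  expect_identical(canonicalKeys(prods), obcan("C1CCC(CC1)c1ccccc1"))
})

test_that("unsanitizable input molecules are rejected as invalid input", {
  rules <- builtinRules()
  expect_error(applyRule(rules[["phenyl_to_cyclohexyl"]], "C(C)(C)(C)(C)C"),
               class = "chem_invalid_input")
})

test_that("compendium loading enforces schema and id uniqueness", {
  comp <- builtinRules()
  expect_identical(length(comp), 7L)
  expect_identical(comp[["phenyl_to_cyclohexyl"]]@transformationType,
                   "ring substitution")
  # header-only file -> empty compendium
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(ChemLibDesign:::.COMPENDIUM_COLUMNS, collapse = "\t"), f)
  expect_identical(length(readRuleCompendium(f)), 0L)
  # missing column -> schema error
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rule_id\tgroup", "a\tb"), f2)
  expect_error(readRuleCompendium(f2), "missing required column")
  # duplicate id -> duplicate-id error
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(ChemLibDesign:::.COMPENDIUM_COLUMNS, collapse = "\t"),
               "r1\tg\tn\tother\tCC>>CC\t\tref",
               "r1\tg\tn\tother\tCC>>CC\t\tref"), f3)
  expect_error(readRuleCompendium(f3), "duplicate rule_id")
})

test_that("rows with failing SMIRKS are retained with parse-error status", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(ChemLibDesign:::.COMPENDIUM_COLUMNS, collapse = "\t"),
               "ok\tPhenyl\tn\tother\t[c:1]>>[#7:1]\tnote\tref",
               "bad\tPhenyl\tn\tother\tnot-a-smirks\tnote\tref"), f)
  comp <- readRuleCompendium(f)
  expect_identical(length(comp), 2L)
  st <- ruleStatus(comp)
  expect_identical(unname(st[c("ok", "bad")]), c("parsed", "parse-error"))
})

test_that("the compendium writer round-trips the packaged table byte-identically", {
  src <- system.file("extdata", "table2_rules.tsv",
                     package = "ChemLibDesign")
  comp <- readRuleCompendium(src)
  out <- withr::local_tempfile(fileext = ".tsv")
  writeRuleCompendium(comp, out)
  expect_identical(readLines(out), readLines(src))
})

test_that("validateRules audits the compendium with partitioning statuses", {
  comp <- builtinRules()
  rep <- validateRules(comp)
  expect_identical(nrow(rep@perRule), length(comp))
  expect_true(all(rep@perRule$status == "parsed"))
  expect_true(all(rep@perRule$nProducts >= 1L))
  expect_identical(sum(rep@groupCounts), length(comp))
  expect_identical(sum(rep@typeCounts), length(comp))
  # a probe panel lacking every motif yields no-probe-match
  rep2 <- validateRules(comp["phenyl_to_cyclohexyl"], probes = "CCO")
  expect_identical(rep2@perRule$status, "no-probe-match")
})
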