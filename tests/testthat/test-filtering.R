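# structural alerts and the filter cascade

test_that("known alert bearers are flagged and clean molecules are not", {
  hits <- structuralAlerts("Oc1ccccc1O", catalogs = "pains")
  expect_gte(nrow(hits), 1L)
  expect_true("catechol" %in% hits$patternId)
  expect_identical(nrow(structuralAlerts("C")), 0L)
  expect_identical(nrow(structuralAlerts("CCCC")), 0L)
  # vacuous screen with no catalogs
  expect_identical(nrow(structuralAlerts("Oc1ccccc1O",
                                         catalogs = character(0))), 0L)
})

test_that("reactive functionality is caught by the unwanted catalog", {
  hits <- structuralAlerts(c("CC(=O)Cl", "C1CO1", "CCOO"),
                           catalogs = "unwanted")
  expect_true(all(c("acyl_halide", "epoxide", "peroxide") %in%
                    hits$patternId))
})

test_that("unknown catalog names are a configuration error", {
  expect_error(structuralAlerts("CC", catalogs = "nonexistent"),
               "unknown alert catalog")
})

test_that("cascade attrition equals brute-force set arithmetic at the boundaries", {
  # ten molecules with hand-assigned scores straddling every threshold
  set <- curateLibrary(c("CC", "CCC", "CCCC", "CCCCC", "CCCCCC",
                         "CCO", "CCCO", "CCCCO", "CCN", "CCCN"))$set
  sa   <- c(2, 6.0, 6.01, 3, 9.9, 1, 6.0, 2, 4, 5)
  qed  <- c(0.8, 0.67, 0.9, 0.66, 0.95, 0.68, 0.2, 0.671, 0.67, 0.9)
  alrt <- c(0L, 0L, 0L, 0L, 0L, 1L, 0L, 0L, 2L, 0L)
  spec <- filterSpec()
  res <- runFilterCascade(set, spec,
                          scores = list(sa = sa, qed = qed, alerts = alrt))
  passSa <- sa <= 6          # 6.0 passes (inclusive)
  passQed <- qed > 0.67      # 0.67 fails (strict)
  passAl <- alrt <= 0L
  expect_identical(unname(res$report@surviving),
                   c(10L, sum(passSa), sum(passSa & passQed),
                     sum(passSa & passQed & passAl)))
  expect_identical(length(res$survivors), sum(passSa & passQed & passAl))
  # boundary semantics, explicitly
  expect_true(passSa[2])       # SAScore exactly 6 passes
  expect_false(passQed[2])     # QED exactly 0.67 fails
})

test_that("survivors are order-invariant though per-stage attrition is not", {
  set <- curateLibrary(c("CC", "CCC", "CCCC", "CCCCC"))$set
  sc <- list(sa = c(2, 7, 3, 2), qed = c(0.9, 0.9, 0.5, 0.8),
             alerts = c(0L, 0L, 3L, 3L))
  o1 <- runFilterCascade(set, filterSpec(), scores = sc)
  o2 <- runFilterCascade(set, filterSpec(
    stageOrder = c("alerts", "qed", "sascore")), scores = sc)
  expect_identical(canonicalKeys(o1$survivors), canonicalKeys(o2$survivors))
  expect_false(identical(unname(o1$report@surviving[2]),
                         unname(o2$report@surviving[2])))
})

test_that("an empty library and a stage-free spec behave as identities", {
  empty <- curateLibrary(character(0))$set
  res <- runFilterCascade(empty, filterSpec())
  expect_identical(length(res$survivors), 0L)
  expect_identical(unname(res$report@surviving), c(0L, 0L, 0L, 0L))
  set <- curateLibrary(c("CC", "CCO"))$set
  res2 <- runFilterCascade(set, filterSpec(stageOrder = character(0)))
  expect_identical(canonicalKeys(res2$survivors), canonicalKeys(set))
})

test_that("the synthetic-feasibility stage is pluggable and strict at 0.5", {
  set <- curateLibrary(c("CC", "CCO", "CCC"))$set
  scorer <- function(mols) c(0.4, 0.5, 0.6)
  spec <- filterSpec(synthMin = 0.5, synthScorer = scorer,
                     stageOrder = c("synth"))
  res <- runFilterCascade(set, spec)
  expect_identical(length(res$survivors), 1L)   # only 0.6 > 0.5
  expect_error(filterSpec(synthMin = 0.5, stageOrder = "synth"),
               "no synthScorer")
})

test_that("first-failing stages partition the rejected set", {
  set <- curateLibrary(c("CC", "CCC", "CCCC"))$set
  sc <- list(sa = c(9, 2, 2), qed = c(0.9, 0.1, 0.9), alerts = c(0L, 0L, 5L))
  res <- runFilterCascade(set, filterSpec(), scores = sc)
  ff <- res$report@firstFailing$stage
  expect_identical(ff, c("sascore", "qed", "alerts"))
  expect_identical(sum(is.na(ff)) + sum(!is.na(ff)), 3L)
})
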