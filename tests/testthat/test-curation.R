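# standardization cascade and library curation

test_that("salts are split, charges neutralized, and the key is stereo-free", {
  rec <- standardizeMolecule("CC(=O)[O-].[Na+]")
  expect_true(rec$ok)
  expect_identical(rec$canonicalKey, obcan("CC(=O)O"))
  expect_true(all(c("multi-component-split", "neutralized") %in% rec$flags))
})

test_that("the element whitelist excludes non-allowed elements", {
  expect_identical(standardizeMolecule("C[As](C)C")$reason, "element")
  expect_identical(standardizeMolecule("[Zn]")$reason, "element")
  expect_identical(standardizeMolecule("CC[Fe]CC")$reason, "element")
  # all 13 allowed elements pass
  ok <- c("CB(O)O", "CC", "CN", "CO", "CF", "C[SiH3]", "CP", "CS",
          "CCl", "C[SeH]", "CBr", "CI")
  for (s in ok) expect_true(standardizeMolecule(s)$ok, label = s)
})

test_that("enantiomer spellings share one canonical key", {
  k1 <- standardizeMolecule("C[C@H](N)C(=O)O")$canonicalKey
  k2 <- standardizeMolecule("C[C@@H](N)C(=O)O")$canonicalKey
  k3 <- standardizeMolecule("CC(N)C(=O)O")$canonicalKey
  expect_identical(k1, k2)
  expect_identical(k1, k3)
})

test_that("rejections carry exactly one first-failing reason", {
  res <- curateLibrary(c("CCO", "not a smiles", "C[As](C)C",
                         "C(C)(C)(C)(C)C"))
  rej <- as.data.frame(res$report@rejections)
  expect_identical(nrow(rej), 3L)
  expect_identical(rej$reason[match(c("id2", "id3", "id4"), rej$sourceId)],
                   c("parse", "element", "valence"))
})

test_that("curation deduplicates stereo-blind and keeps first occurrence", {
  res <- curateLibrary(c("CCO", "OCC", "CC(=O)O"),
                       ids = c("a", "b", "c"))
  expect_identical(length(res$set), 2L)
  expect_identical(moleculeRecords(res$set)$sourceId, c("a", "c"))
  expect_identical(res$report@nInput, 3L)
  expect_identical(res$report@nAfterDedup, 2L)
})

test_that("curating an empty library yields an all-zero report", {
  res <- curateLibrary(character(0))
  expect_identical(length(res$set), 0L)
  expect_identical(res$report@nInput, 0L)
  expect_identical(res$report@nAfterDedup, 0L)
})

test_that("curation is idempotent on its own output", {
  input <- c("CC(=O)[O-].[Na+]", "C[C@H](N)C(=O)O", "OCC", "CCO",
             "CN(=O)=O", "Cc1ccccc1", "OC=C", "c1cc[nH]c1")
  first <- curateLibrary(input)
  second <- curateLibrary(canonicalKeys(first$set))
  expect_identical(canonicalKeys(second$set), canonicalKeys(first$set))
  expect_identical(second$report@nInput, second$report@nAfterDedup)
})

test_that("nitro spellings unify through reionization", {
  k1 <- standardizeMolecule("CN(=O)=O")$canonicalKey
  k2 <- standardizeMolecule("C[N+](=O)[O-]")$canonicalKey
  expect_identical(k1, k2)
})

test_that("the tautomer canonicalizer shifts acyclic enols but spares aromatics", {
  expect_identical(standardizeMolecule("OC=C")$canonicalKey, obcan("CC=O"))
  expect_true("tautomer-canonicalized" %in% standardizeMolecule("OC=C")$flags)
  expect_identical(standardizeMolecule("Oc1ccccc1")$canonicalKey,
                   obcan("Oc1ccccc1"))
  # stable: canonical tautomer of the canonical tautomer is itself
  k <- standardizeMolecule("OC=CC")$canonicalKey
  expect_identical(standardizeMolecule(k)$canonicalKey, k)
})

test_that("compound readers handle .smi, CSV and SDF", {
  smi <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO ethanol", "c1ccccc1 benzene"), smi)
  tab <- readCompounds(smi)
  expect_identical(tab$smiles, c("CCO", "c1ccccc1"))
  expect_identical(tab$id, c("ethanol", "benzene"))

  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,SMILES", "ethanol,CCO", "toluene,Cc1ccccc1"), csv)
  tab2 <- readCompounds(csv, idColumn = "name")
  expect_identical(tab2$smiles, c("CCO", "Cc1ccccc1"))

  sdf <- withr::local_tempfile(fileext = ".sdf")
  sdfText <- ChemmineOB::convertFormat("SMI", "SDF", "CCO ethanol\n")
  writeLines(sdfText, sdf)
  tab3 <- readCompounds(sdf)
  expect_identical(nrow(tab3), 1L)
  expect_identical(obcan(tab3$smiles), obcan("CCO"))
})

test_that("curated sets export with key and flag columns", {
  res <- curateLibrary(c("CC(=O)[O-].[Na+]", "CCO"))
  out <- withr::local_tempfile(fileext = ".csv")
  writeCurated(res$set, out)
  back <- utils::read.csv(out, stringsAsFactors = FALSE)
  expect_identical(colnames(back),
                   c("id", "input_smiles", "canonical_key", "flags"))
  expect_identical(back$canonical_key, canonicalKeys(res$set))
})
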