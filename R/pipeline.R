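#' @include AllClasses.R
NULL

#' Run the end-to-end library-design workflow
#'
#' Curate the seeds, enumerate the library through the rule compendium
#' under the property gates, profile the products, run the
#' medicinal-chemistry filter cascade, and embed the survivors alongside
#' the seeds in property space (PCA; t-SNE when enough compounds). Every
#' stage writes its table under \code{outDir} and the run closes with a
#' JSON manifest (package version, seeds, per-stage counts, file
#' checksums, full configuration) so a run can be audited and repeated.
#'
#' @param seeds character vector of SMILES or a path to a compound file
#'   (see \code{\link{readCompounds}}).
#' @param rules a \linkS4class{RuleCompendium} or a path readable by
#'   \code{\link{readRuleCompendium}}; default: the built-in rule set.
#' @param outDir output directory (created if needed).
#' @param config an \code{\link{enumerationConfig}}.
#' @param filter a \code{\link{filterSpec}}.
#' @param seed global seed for the stochastic embedding stage.
#' @param doTsne run the t-SNE view when the library is large enough
#'   (default \code{TRUE}).
#' @return the manifest (a list), invisibly; also written as
#'   \code{manifest.json}.
#' @export
runPipeline <- function(seeds, rules = builtinRules(),
                        outDir = tempfile("chemlib_run_"),
                        config = enumerationConfig(),
                        filter = filterSpec(), seed = 7L, doTsne = TRUE) {
  # validate configuration before any stage runs
  if (is.character(rules)) {
    if (!file.exists(rules)) stop("validation error: rules file not found: ",
                                  rules)
    rules <- readRuleCompendium(rules)
  }
  if (is.character(seeds) && length(seeds) == 1L && file.exists(seeds)) {
    tab <- readCompounds(seeds)
    seedSmiles <- tab$smiles; seedIds <- tab$id
  } else if (is.character(seeds)) {
    seedSmiles <- seeds; seedIds <- paste0("seed", seq_along(seeds))
  } else stop("validation error: seeds must be SMILES or a file path")
  if (!length(seedSmiles)) stop("validation error: no seed compounds")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           " (partial outputs kept in ", outDir, ")", call. = FALSE)
    })
  }
  counts <- list()
  # curate
  cur <- stage("curate", curateLibrary(seedSmiles, seedIds))
  counts$seedsIn <- cur$report@nInput
  counts$seedsCurated <- cur$report@nAfterDedup
  writeCurated(cur$set, file.path(outDir, "seeds_curated.csv"))
  curationReportJson(cur$report, file.path(outDir, "curation_report.json"))
  # enumerate
  lib <- stage("enumerate", enumerateLibrary(cur$set, rules, config))
  counts$enumerated <- length(lib)
  counts$perIteration <- as.list(lib@iterationCounts)
  counts$gateRejected <- as.list(lib@gateRejected)
  writeEnumerated(lib, file.path(outDir, "library.csv"))
  # profile
  prof <- stage("profile", computeProfile(lib))
  profDf <- as.data.frame(prof)
  profDf$QED <- if (length(lib)) qedScore(lib, profile = prof) else numeric(0)
  profDf$SAScore <- if (length(lib)) saScore(lib) else numeric(0)
  utils::write.csv(profDf, file.path(outDir, "profile.csv"),
                   row.names = FALSE)
  # filter
  fres <- stage("filter", runFilterCascade(
    lib, filter, scores = list(sa = profDf$SAScore, qed = profDf$QED)))
  counts$cascade <- as.list(fres$report@surviving)
  counts$survivors <- length(fres$survivors)
  cascadeReportJson(fres$report, file.path(outDir, "filter_report.json"))
  writeCurated(fres$survivors, file.path(outDir, "survivors.csv"))
  # chemical space: seeds vs enumerated library
  if (length(lib) >= 2L) {
    stage("chemspace", {
      dm <- descriptorMatrix(seeds = cur$set, library = lib)
      emb <- pcaEmbed(dm)
      coords <- data.frame(canonicalKey = dm$keys,
                           library = as.character(dm$labels),
                           pc1 = emb$coords[, 1], pc2 = emb$coords[, 2])
      if (doTsne && nrow(dm$x) >= 12L) {
        ts <- tsneEmbed(dm, perplexity = min(30, floor(nrow(dm$x) / 3)),
                        seed = seed)
        coords$tsne1 <- ts$coords[, 1]
        coords$tsne2 <- ts$coords[, 2]
      }
      utils::write.csv(coords, file.path(outDir, "chemspace.csv"),
                       row.names = FALSE)
      counts$pcaExplainedVariance <- as.list(emb$explainedVariance)
    })
  }
  files <- list.files(outDir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package = as.character(utils::packageVersion("ChemLibDesign")),
    rVersion = R.version.string,
    seed = seed,
    nRules = length(rules),
    enumeration = unclass(config),
    filter = filter[setdiff(names(filter), "synthScorer")],
    counts = counts,
    checksums = as.list(tools::md5sum(files))
  )
  names(manifest$checksums) <- basename(files)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(outDir, "manifest.json"))
  invisible(manifest)
}
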