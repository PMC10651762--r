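#' @include AllClasses.R
NULL

#' Medicinal-chemistry filter settings
#'
#' Thresholds and stage order of the filter cascade. Defaults are the
#' published criteria: QED strictly greater than 0.67, synthetic
#' accessibility score at most 6 (inclusive), optional synthetic
#' feasibility strictly greater than 0.5 (requires a pluggable scorer;
#' skipped by default since the reference scorer is a proprietary
#' ligand-based method), and zero structural alerts against the configured
#' catalogs.
#'
#' @param qedMin QED threshold, strict \code{>} (default 0.67).
#' @param saMax SA-score threshold, inclusive \code{<=} (default 6).
#' @param synthMin optional synthetic-feasibility threshold, strict
#'   \code{>} (default \code{NULL}: stage disabled).
#' @param synthScorer optional function \code{(MoleculeSet) -> numeric in
#'   [0,1]}; required when \code{synthMin} is set.
#' @param maxAlerts maximum allowed structural-alert hits (default 0).
#' @param alertCatalogs catalogs for the alert stage (default
#'   \code{c("pains", "unwanted")}).
#' @param stageOrder permutation of the enabled stages; default
#'   \code{c("sascore", "synth", "qed", "alerts")} (the conventional
#'   attrition-report row order). The \code{"synth"} entry is ignored when
#'   the stage is disabled.
#' @return a list of class \code{FilterSpec}.
#' @export
filterSpec <- function(qedMin = 0.67, saMax = 6, synthMin = NULL,
                       synthScorer = NULL, maxAlerts = 0L,
                       alertCatalogs = c("pains", "unwanted"),
                       stageOrder = c("sascore", "synth", "qed", "alerts")) {
  stopifnot(is.finite(qedMin), is.finite(saMax), maxAlerts >= 0L)
  known <- c("sascore", "synth", "qed", "alerts")
  bad <- setdiff(stageOrder, known)
  if (length(bad)) stop("unknown cascade stage(s): ",
                        paste(bad, collapse = ", "))
  if (anyDuplicated(stageOrder)) stop("stageOrder must not repeat stages")
  # stages are enabled by listing them; the synth stage additionally
  # requires both a threshold and a pluggable scorer
  if (is.null(synthMin)) {
    stageOrder <- setdiff(stageOrder, "synth")
  } else {
    if (!("synth" %in% stageOrder))
      stop("synthMin is set but 'synth' is not in stageOrder")
    if (is.null(synthScorer))
      stop("synthMin is set but no synthScorer is configured")
  }
  structure(list(qedMin = qedMin, saMax = saMax, synthMin = synthMin,
                 synthScorer = synthScorer, maxAlerts = as.integer(maxAlerts),
                 alertCatalogs = alertCatalogs, stageOrder = stageOrder),
            class = "FilterSpec")
}

#' Run the medicinal-chemistry filter cascade
#'
#' Applies the stages of \code{spec} in \code{stageOrder} and reports the
#' per-stage surviving counts (attrition-table style), each compound's
#' first failing stage, and the individual alert hits. Because the stages
#' are independent predicates, the final survivor set does not depend on
#' the stage order — only the per-stage attrition numbers do.
#'
#' @param mols a \linkS4class{MoleculeSet} or character vector of SMILES.
#' @param spec a \code{\link{filterSpec}}.
#' @param scores optional precomputed data.frame with any of \code{sa},
#'   \code{qed}, \code{synth}, \code{alerts} columns (bypasses
#'   computation; used for threshold testing and when scores are already
#'   available).
#' @return list with \code{survivors} (a \linkS4class{MoleculeSet}) and
#'   \code{report} (a \linkS4class{FilterCascadeReport}).
#' @export
runFilterCascade <- function(mols, spec = filterSpec(), scores = NULL) {
  set <- .asMoleculeSet(mols)
  n <- length(set)
  keys <- canonicalKeys(set)
  needSa <- "sascore" %in% spec$stageOrder
  needQed <- "qed" %in% spec$stageOrder
  needAlerts <- "alerts" %in% spec$stageOrder
  sa <- if (!is.null(scores$sa)) scores$sa else if (needSa && n)
    saScore(set) else numeric(n)
  qed <- if (!is.null(scores$qed)) scores$qed else if (needQed && n)
    qedScore(set) else numeric(n)
  alertHits <- data.frame(index = integer(0), canonicalKey = character(0),
                          catalog = character(0), patternId = character(0))
  if (!is.null(scores$alerts)) {
    nAlerts <- scores$alerts
  } else if (needAlerts && n) {
    alertHits <- structuralAlerts(set, catalogs = spec$alertCatalogs)
    nAlerts <- as.integer(table(factor(alertHits$index, levels = seq_len(n))))
  } else nAlerts <- integer(n)
  synth <- if (!is.null(scores$synth)) scores$synth else if
    ("synth" %in% spec$stageOrder && n) spec$synthScorer(set) else
      rep(NA_real_, n)
  pass <- list(
    sascore = if (n) sa <= spec$saMax else logical(0),
    qed = if (n) qed > spec$qedMin else logical(0),
    alerts = if (n) nAlerts <= spec$maxAlerts else logical(0),
    synth = if (n && !is.null(spec$synthMin)) synth > spec$synthMin else
      rep(TRUE, n)
  )
  surviving <- c(input = n)
  alive <- rep(TRUE, n)
  firstFail <- rep(NA_character_, n)
  for (stage in spec$stageOrder) {
    failNow <- alive & !pass[[stage]]
    firstFail[failNow] <- stage
    alive <- alive & pass[[stage]]
    surviving <- c(surviving, stats::setNames(sum(alive), stage))
  }
  specMeta <- list(qedMin = spec$qedMin, saMax = spec$saMax,
                   synthMin = spec$synthMin,
                   maxAlerts = spec$maxAlerts,
                   alertCatalogs = spec$alertCatalogs,
                   stageOrder = spec$stageOrder)
  report <- new("FilterCascadeReport",
                stages = spec$stageOrder,
                surviving = surviving,
                firstFailing = DataFrame(canonicalKey = keys,
                                         stage = firstFail),
                alertHits = DataFrame(
                  canonicalKey = if (nrow(alertHits))
                    alertHits$canonicalKey else character(0),
                  catalog = if (nrow(alertHits)) alertHits$catalog else
                    character(0),
                  patternId = if (nrow(alertHits)) alertHits$patternId else
                    character(0)),
                spec = specMeta)
  list(survivors = set[alive], report = report)
}

#' Serialize a filter-cascade report to JSON
#'
#' @param report a \linkS4class{FilterCascadeReport}.
#' @param path optional output path.
#' @export
cascadeReportJson <- function(report, path = NULL) {
  obj <- list(stages = report@stages,
              surviving = as.list(report@surviving),
              spec = report@spec[setdiff(names(report@spec), "synthScorer")],
              alertHits = as.data.frame(report@alertHits))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
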