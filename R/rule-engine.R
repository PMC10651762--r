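#' @include AllClasses.R methods.R
NULL

#' Parse a SMIRKS transformation into a compiled rewrite
#'
#' Splits the string on \code{">>"}, compiles the reactant side as a
#' substructure pattern and the product side as a rewrite template, strips
#' any CXSMILES-style extension blocks (\code{"|s:0:1|"},
#' \code{"|rb:..."}) into metadata, and checks the atom-map bookkeeping.
#' Product-side map classes with no reactant counterpart are legal and
#' denote atoms created by the rewrite (they are listed in
#' \code{$newProductMaps}).
#'
#' @param smirks a single SMIRKS string.
#' @return an object of class \code{CompiledSmirks}: a list with elements
#'   \code{reactant}, \code{product}, \code{rmap}, \code{pmap},
#'   \code{newProductMaps}, \code{extensions} and \code{smirks}.
#' @examples
#' rw <- parseSmirks(
#'   "[c;x2:2]1[c;x2:3][c;x2:4][c;x2:5][c;x2:6][c;x2:1]1>>[#6:5]-1-[#6:6]-[#6:1]-[#6:2]-[#6:3]-[#6:4]-1")
#' length(rw$rmap)
#' @export
parseSmirks <- function(smirks) {
  stopifnot(is.character(smirks), length(smirks) == 1L, nzchar(smirks))
  out <- .compileSmirks(smirks)
  class(out) <- "CompiledSmirks"
  out
}

#' @export
print.CompiledSmirks <- function(x, ...) {
  cat("CompiledSmirks\n")
  cat("  reactant atoms:", length(x$reactant$atoms),
      " product atoms:", length(x$pmap), "\n")
  cat("  mapped classes:", paste(sort(x$rmap[!is.na(x$rmap)]), collapse = " "),
      "\n")
  if (length(x$newProductMaps))
    cat("  new product maps:", paste(x$newProductMaps, collapse = " "), "\n")
  if (length(x$extensions))
    cat("  stripped extensions:", paste(x$extensions, collapse = " "), "\n")
  invisible(x)
}

#' Construct a TransformationRule
#'
#' Compiles the SMIRKS; a rule whose SMIRKS fails to compile is returned
#' with \code{status = "parse-error"} rather than raising, so compendium
#' loading can retain bad rows for auditing.
#'
#' @param ruleId unique identifier.
#' @param group functional-group family.
#' @param name rule name.
#' @param transformationType transformation category.
#' @param smirks SMIRKS string.
#' @param notes character vector of rationale tags.
#' @param reference literature citation.
#' @return a \linkS4class{TransformationRule}.
#' @export
makeTransformationRule <- function(ruleId, group = "", name = ruleId,
                                   transformationType = "other",
                                   smirks, notes = character(0),
                                   reference = "") {
  compiled <- tryCatch(.compileSmirks(smirks), error = function(e) e)
  if (inherits(compiled, "error")) {
    return(new("TransformationRule",
               ruleId = ruleId, group = group, name = name,
               transformationType = transformationType, smirks = smirks,
               notes = notes, reference = reference, compiled = list(),
               status = "parse-error",
               statusMessage = conditionMessage(compiled),
               extensions = character(0), newProductMaps = integer(0)))
  }
  new("TransformationRule",
      ruleId = ruleId, group = group, name = name,
      transformationType = transformationType, smirks = smirks,
      notes = notes, reference = reference, compiled = compiled,
      status = "parsed", statusMessage = "",
      extensions = compiled$extensions,
      newProductMaps = as.integer(compiled$newProductMaps))
}

.COMPENDIUM_COLUMNS <- c("rule_id", "group", "name", "transformation_type",
                         "smirks", "notes", "reference")

#' Read a transformation-rule compendium from delimited text
#'
#' Expects a header row with the columns \code{rule_id, group, name,
#' transformation_type, smirks, notes, reference}; \code{notes} is a
#' semicolon-separated tag list. Tab- or comma-separated files are detected
#' from the first line. Rows whose SMIRKS fail to compile are retained with
#' \code{"parse-error"} status, never dropped silently.
#'
#' @param path file path.
#' @return a \linkS4class{RuleCompendium}.
#' @export
readRuleCompendium <- function(path) {
  if (!file.exists(path)) stop("rule file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", quote = "\"",
                           check.names = FALSE, comment.char = "",
                           stringsAsFactors = FALSE)
  missing <- setdiff(.COMPENDIUM_COLUMNS, colnames(tab))
  if (length(missing)) {
    stop("rule table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(tab$rule_id)) {
    dup <- unique(tab$rule_id[duplicated(tab$rule_id)])
    stop("duplicate rule_id: ", paste(dup, collapse = ", "))
  }
  rules <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    notes <- strsplit(tab$notes[i], ";", fixed = TRUE)[[1]]
    notes <- trimws(notes[nzchar(trimws(notes))])
    rules[[i]] <- makeTransformationRule(
      ruleId = trimws(tab$rule_id[i]), group = trimws(tab$group[i]),
      name = trimws(tab$name[i]),
      transformationType = tolower(trimws(tab$transformation_type[i])),
      smirks = tab$smirks[i], notes = notes,
      reference = trimws(tab$reference[i]))
  }
  names(rules) <- vapply(rules, function(r) r@ruleId, character(1))
  new("RuleCompendium", rules = rules, source = path)
}

#' Write a compendium back to tab-separated text
#'
#' Inverse of \code{\link{readRuleCompendium}}: the packaged rule table
#' round-trips byte-identically.
#'
#' @param compendium a \linkS4class{RuleCompendium}.
#' @param path output file path.
#' @export
writeRuleCompendium <- function(compendium, path) {
  header <- paste(.COMPENDIUM_COLUMNS, collapse = "\t")
  rows <- vapply(compendium@rules, function(r) {
    paste(c(r@ruleId, r@group, r@name, r@transformationType, r@smirks,
            paste(r@notes, collapse = ";"), r@reference), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Apply one transformation rule to one molecule
#'
#' The reactant pattern is matched at every site of the molecule and the
#' rewrite applied once per match (single-site application). Products are
#' valence-sanitized; products failing sanitization are dropped and counted.
#' The product set is deduplicated by stereo-stripped canonical SMILES, the
#' input molecule itself is never returned, and products are ordered
#' lexicographically by canonical key for determinism.
#'
#' @param rule a \linkS4class{TransformationRule}, a \code{CompiledSmirks},
#'   or a SMIRKS string.
#' @param mol a SMILES string or a \linkS4class{MoleculeSet} of length 1.
#' @return a \linkS4class{MoleculeSet} of unique products, with attributes
#'   \code{nMatches} (match sites) and \code{nDropped} (failed sanitization).
#' @examples
#' \donttest{
#' rules <- builtinRules()
#' applyRule(rules[["phenyl_to_cyclohexyl"]], "Cc1ccccc1")
#' }
#' @export
applyRule <- function(rule, mol) {
  compiled <- .resolveRule(rule)
  g <- .resolveMolGraph(mol)
  res <- .applyCompiledRule(g, compiled)
  inputKey <- .obCanonical(.writeSmiles(g))
  keys <- .obCanonical(res$smiles)
  keys <- sort(unique(keys[!is.na(keys)]))
  keys <- setdiff(keys, inputKey)
  out <- .moleculeSetFromKeys(keys)
  attr(out, "nMatches") <- res$nMatches
  attr(out, "nDropped") <- res$nDropped
  out
}

.resolveRule <- function(rule) {
  if (is(rule, "TransformationRule")) {
    if (rule@status != "parsed") {
      stop("rule '", rule@ruleId, "' did not compile: ", rule@statusMessage)
    }
    return(rule@compiled)
  }
  if (inherits(rule, "CompiledSmirks")) return(unclass(rule))
  if (is.character(rule) && length(rule) == 1L) return(.compileSmirks(rule))
  stop("rule must be a TransformationRule, CompiledSmirks or SMIRKS string")
}

.resolveMolGraph <- function(mol) {
  if (is(mol, "MoleculeSet")) {
    if (length(mol) != 1L) stop("expected a single molecule")
    return(mol@graphs[[1]])
  }
  if (is.character(mol) && length(mol) == 1L) {
    rec <- standardizeMolecule(mol)
    if (!rec$ok) {
      .chemError(paste0("input molecule rejected (", rec$reason, ")"),
                 "chem_invalid_input")
    }
    return(rec$graph)
  }
  stop("mol must be a SMILES string or a MoleculeSet of length 1")
}

# Build a MoleculeSet from canonical keys (products of a rewrite: already
# sanitized; graphs are re-parsed from the canonical form).
.moleculeSetFromKeys <- function(keys, sourceIds = keys) {
  graphs <- lapply(keys, function(k) {
    tryCatch(.sanitizeMol(.parseSmiles(k)), error = function(e) NULL)
  })
  keep <- !vapply(graphs, is.null, logical(1))
  new("MoleculeSet",
      records = DataFrame(sourceId = sourceIds[keep],
                          smilesIn = keys[keep],
                          canonicalKey = keys[keep],
                          flags = rep("", sum(keep))),
      graphs = graphs[keep])
}

#' Audit a rule compendium against probe molecules
#'
#' Every parsed rule is applied to probe molecules; the first probe whose
#' structure contains the rule's reactant motif determines the rule's
#' status: \code{"parsed"} when at least one sanitized product results,
#' \code{"produced-invalid-product"} when all products failed sanitization,
#' \code{"no-probe-match"} when no probe carries the motif, and
#' \code{"parse-error"} as recorded at load time. Statuses partition the
#' compendium. Group and transformation-type histograms are attached.
#'
#' @param compendium a \linkS4class{RuleCompendium}.
#' @param probes optional \linkS4class{MoleculeSet} or character vector of
#'   SMILES; defaults to the built-in motif probe panel
#'   (\code{\link{makeSeedSet}} over all known motifs).
#' @return a \linkS4class{RuleValidationReport}.
#' @export
validateRules <- function(compendium, probes = NULL) {
  if (is.null(probes)) {
    # the full variant pool: strict patterns (e.g. exactly-1,4-disubstituted
    # rings) need their precise motif bearer present
    probes <- makeSeedSet(motifs = names(.FIXTURE_MOTIFS), countPerMotif = 5L)
  }
  if (is.character(probes)) {
    probes <- curateLibrary(probes)$set
  }
  n <- length(compendium)
  status <- character(n); nProducts <- integer(n); probeUsed <- character(n)
  for (i in seq_len(n)) {
    r <- compendium@rules[[i]]
    if (r@status != "parsed") {
      status[i] <- "parse-error"; nProducts[i] <- 0L; probeUsed[i] <- ""
      next
    }
    status[i] <- "no-probe-match"; nProducts[i] <- 0L; probeUsed[i] <- ""
    for (j in seq_len(length(probes))) {
      g <- probes@graphs[[j]]
      feat <- .molFeatures(g)
      if (!.hasSubstructure(g, r@compiled$reactant, feat)) next
      probeUsed[i] <- canonicalKeys(probes)[j]
      res <- .applyCompiledRule(g, r@compiled)
      keys <- unique(.obCanonical(res$smiles))
      keys <- keys[!is.na(keys)]
      if (length(keys)) {
        status[i] <- "parsed"; nProducts[i] <- length(keys)
      } else {
        status[i] <- "produced-invalid-product"
      }
      break
    }
  }
  groups <- vapply(compendium@rules, function(r) r@group, character(1))
  types <- vapply(compendium@rules, function(r) r@transformationType,
                  character(1))
  gtab <- table(groups); ttab <- table(types)
  gc <- as.integer(gtab); names(gc) <- names(gtab)
  tc <- as.integer(ttab); names(tc) <- names(ttab)
  new("RuleValidationReport",
      perRule = DataFrame(ruleId = names(compendium),
                          group = unname(groups),
                          transformationType = unname(types),
                          status = status, nProducts = nProducts,
                          probe = probeUsed),
      groupCounts = gc, typeCounts = tc)
}

#' Serialize a validation report to JSON
#'
#' @param report a \linkS4class{RuleValidationReport}.
#' @param path optional output path; when omitted the JSON string returns.
#' @export
validationReportJson <- function(report, path = NULL) {
  obj <- list(
    perRule = as.data.frame(report@perRule),
    groupCounts = as.list(report@groupCounts),
    typeCounts = as.list(report@typeCounts),
    statusCounts = as.list(table(report@perRule$status))
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
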