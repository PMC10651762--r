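#' @include AllClasses.R
NULL

# ---- RuleCompendium ---------------------------------------------------------

#' @describeIn RuleCompendium number of rules
#' @param x a \code{RuleCompendium}
#' @export
setMethod("length", "RuleCompendium", function(x) length(x@rules))

#' @describeIn RuleCompendium rule ids
#' @export
setMethod("names", "RuleCompendium", function(x) names(x@rules))

#' Extract a rule by id or position
#'
#' @param x a \code{RuleCompendium}
#' @param i rule id (character) or position (numeric)
#' @export
setMethod("[[", "RuleCompendium", function(x, i) x@rules[[i]])

#' Subset a compendium
#'
#' @param x a \code{RuleCompendium}
#' @param i character ids or positions
#' @param j,drop,... ignored
#' @export
setMethod("[", "RuleCompendium", function(x, i, j, ..., drop = FALSE) {
  new("RuleCompendium", rules = x@rules[i], source = x@source)
})

setMethod("show", "RuleCompendium", function(object) {
  cat(sprintf("RuleCompendium with %d rules (source: %s)\n",
              length(object), object@source))
  if (length(object)) {
    st <- ruleStatus(object)
    cat(sprintf("  parsed: %d, parse-error: %d\n",
                sum(st == "parsed"), sum(st != "parsed")))
    gc <- table(vapply(object@rules, function(r) r@group, character(1)))
    cat("  groups:", paste(sprintf("%s (%d)", names(gc), gc), collapse = ", "),
        "\n")
  }
})

setMethod("show", "TransformationRule", function(object) {
  cat(sprintf("TransformationRule '%s' [%s / %s]\n", object@ruleId,
              object@group, object@transformationType))
  cat("  ", object@smirks, "\n", sep = "")
  cat(sprintf("  status: %s%s\n", object@status,
              if (nzchar(object@statusMessage))
                paste0(" (", object@statusMessage, ")") else ""))
})

#' Per-rule parse status of a compendium
#'
#' @param compendium a \code{RuleCompendium}
#' @return named character vector (\code{"parsed"} / \code{"parse-error"}).
#' @export
ruleStatus <- function(compendium) {
  vapply(compendium@rules, function(r) r@status, character(1))
}

#' Rules per functional-group family
#'
#' @param compendium a \code{RuleCompendium}
#' @return named integer vector of group counts.
#' @export
groupCounts <- function(compendium) {
  g <- vapply(compendium@rules, function(r) r@group, character(1))
  tab <- table(g)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

# ---- MoleculeSet ------------------------------------------------------------

#' @describeIn MoleculeSet number of molecules
#' @param x a \code{MoleculeSet}
#' @export
setMethod("length", "MoleculeSet", function(x) nrow(x@records))

#' Stereo-agnostic canonical SMILES keys
#'
#' @param x a \code{MoleculeSet}
#' @return character vector of canonical keys.
#' @export
canonicalKeys <- function(x) x@records$canonicalKey

#' Record table of a molecule set
#'
#' @param x a \code{MoleculeSet}
#' @return the records \code{DataFrame}.
#' @export
moleculeRecords <- function(x) x@records

#' Subset a MoleculeSet
#'
#' @param x a \code{MoleculeSet}
#' @param i positions or logical mask
#' @param j,drop,... ignored
#' @export
setMethod("[", "MoleculeSet", function(x, i, j, ..., drop = FALSE) {
  initialize(x, records = x@records[i, , drop = FALSE],
             graphs = x@graphs[i])
})

#' Subset an EnumeratedLibrary (provenance kept in step)
#'
#' @param x an \code{EnumeratedLibrary}
#' @param i positions or logical mask
#' @param j,drop,... ignored
#' @export
setMethod("[", "EnumeratedLibrary", function(x, i, j, ..., drop = FALSE) {
  initialize(x, records = x@records[i, , drop = FALSE],
             graphs = x@graphs[i],
             provenance = x@provenance[i, , drop = FALSE])
})

setMethod("show", "MoleculeSet", function(object) {
  cat(sprintf("MoleculeSet with %d molecules\n", length(object)))
  if (length(object)) {
    k <- utils::head(canonicalKeys(object), 3L)
    cat("  ", paste(k, collapse = ", "),
        if (length(object) > 3L) ", ..." else "", "\n", sep = "")
  }
})

setMethod("show", "EnumeratedLibrary", function(object) {
  cat(sprintf("EnumeratedLibrary with %d molecules over %d iteration(s)\n",
              length(object), length(object@iterationCounts)))
  if (length(object@iterationCounts)) {
    cat("  accepted per iteration:",
        paste(object@iterationCounts, collapse = ", "), "\n")
    cat("  gate-rejected per iteration:",
        paste(object@gateRejected, collapse = ", "), "\n")
  }
})

setMethod("show", "CurationReport", function(object) {
  cat("CurationReport\n")
  cat(sprintf("  input: %d; after split: %d; removed (element/valence): %d; after dedup: %d\n",
              object@nInput, object@nAfterSplit,
              object@nRemovedElementOrValence, object@nAfterDedup))
  if (nrow(object@rejections)) {
    tab <- table(object@rejections$reason)
    cat("  rejections:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
})

setMethod("show", "RuleValidationReport", function(object) {
  cat("RuleValidationReport\n")
  tab <- table(object@perRule$status)
  cat("  status:", paste(sprintf("%s (%d)", names(tab), tab),
                         collapse = ", "), "\n")
  cat("  groups:", paste(sprintf("%s (%d)", names(object@groupCounts),
                                 object@groupCounts), collapse = ", "), "\n")
})

setMethod("show", "FilterCascadeReport", function(object) {
  cat("FilterCascadeReport\n")
  for (i in seq_along(object@surviving)) {
    cat(sprintf("  %-28s %d\n", names(object@surviving)[i],
                object@surviving[i]))
  }
})
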