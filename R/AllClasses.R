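#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' TransformationRule: one SMIRKS rewrite with medicinal-chemistry metadata
#'
#' A single chemical transformation (e.g. a bioisosteric phenyl-to-cyclohexyl
#' replacement) encoded as a SMIRKS string, together with the annotation
#' columns of a rule compendium: functional-group family, human-readable
#' name, transformation type, rationale tags and literature reference.
#' The compiled rewrite (reactant pattern + product template) is stored in
#' the \code{compiled} slot when the SMIRKS parsed; rules that failed to
#' compile are retained with \code{status != "parsed"} so a compendium audit
#' can report them rather than silently dropping rows.
#'
#' @slot ruleId opaque unique identifier.
#' @slot group functional-group family (e.g. \code{"Phenyl"}).
#' @slot name rule name (e.g. \code{"Phenyl_to_cyclohexyl"}).
#' @slot transformationType one of the recognised transformation categories.
#' @slot smirks the SMIRKS string as read (extension blocks included).
#' @slot notes character vector of rationale tags.
#' @slot reference free-text literature citation.
#' @slot compiled compiled rewrite (internal representation) or empty list.
#' @slot status \code{"parsed"} or \code{"parse-error"}.
#' @slot statusMessage parse diagnostics, empty when parsed.
#' @slot extensions stripped CXSMILES-style extension blocks (e.g.
#'   \code{"|s:0:1|"}), kept as metadata.
#' @slot newProductMaps atom-map classes that appear only on the product
#'   side and therefore create new atoms.
#' @export
setClass("TransformationRule", representation(
  ruleId = "character",
  group = "character",
  name = "character",
  transformationType = "character",
  smirks = "character",
  notes = "character",
  reference = "character",
  compiled = "list",
  status = "character",
  statusMessage = "character",
  extensions = "character",
  newProductMaps = "integer"
))

.TRANSFORMATION_TYPES <- c(
  "ring substitution", "ring modification", "ring addition",
  "linker modification", "functional group change", "addition",
  "removal", "cyclization", "other")

setValidity("TransformationRule", function(object) {
  msgs <- character(0)
  if (length(object@ruleId) != 1L || !nzchar(object@ruleId))
    msgs <- c(msgs, "ruleId must be a single non-empty string")
  if (!(object@status %in% c("parsed", "parse-error")))
    msgs <- c(msgs, "status must be 'parsed' or 'parse-error'")
  if (object@status == "parsed" && !length(object@compiled))
    msgs <- c(msgs, "a parsed rule must carry its compiled rewrite")
  if (length(msgs)) msgs else TRUE
})

#' RuleCompendium: an ordered, id-keyed collection of transformation rules
#'
#' @slot rules list of \linkS4class{TransformationRule}, names = rule ids.
#' @slot source provenance text (file path or \code{"builtin"}).
#' @export
setClass("RuleCompendium", representation(
  rules = "list",
  source = "character"
))

setValidity("RuleCompendium", function(object) {
  msgs <- character(0)
  if (length(object@rules)) {
    ok <- vapply(object@rules, is, logical(1), "TransformationRule")
    if (!all(ok)) msgs <- c(msgs, "all elements must be TransformationRule")
    ids <- unname(vapply(object@rules, function(r) r@ruleId, character(1)))
    if (anyDuplicated(ids)) msgs <- c(msgs, "rule ids must be unique")
    if (!identical(names(object@rules), ids))
      msgs <- c(msgs, "rules must be named by their ruleId")
  }
  if (length(msgs)) msgs else TRUE
})

#' MoleculeSet: standardized molecules with stereo-agnostic canonical keys
#'
#' The central compound container. Each record carries the raw input SMILES,
#' the standardized structure (internal graph), the stereo-stripped canonical
#' SMILES used as the deduplication key, and the standardization flags.
#'
#' @slot records a \code{DataFrame} with columns \code{sourceId},
#'   \code{smilesIn}, \code{canonicalKey} and \code{flags}
#'   (CharacterList-style comma-joined flag strings).
#' @slot graphs list of internal molecular graphs, parallel to
#'   \code{records}.
#' @export
setClass("MoleculeSet", representation(
  records = "DataFrame",
  graphs = "list"
))

setValidity("MoleculeSet", function(object) {
  msgs <- character(0)
  need <- c("sourceId", "smilesIn", "canonicalKey", "flags")
  if (!all(need %in% colnames(object@records)))
    msgs <- c(msgs, paste("records must have columns",
                          paste(need, collapse = ", ")))
  if (nrow(object@records) != length(object@graphs))
    msgs <- c(msgs, "graphs must parallel records")
  if (length(msgs)) msgs else TRUE
})

#' EnumeratedLibrary: products of iterative rule application with provenance
#'
#' A \linkS4class{MoleculeSet} whose records additionally carry a provenance
#' tag (seed id, the ordered chain of rule ids that produced the record, and
#' the iteration at which it was born) plus per-iteration bookkeeping.
#'
#' @slot provenance \code{DataFrame} with \code{seedId}, \code{ruleChain}
#'   (semicolon-joined rule ids) and \code{iterationBorn}.
#' @slot iterationCounts integer vector: new molecules accepted per iteration.
#' @slot gateRejected integer vector: gate-rejected candidates per iteration.
#' @slot config the \code{EnumerationConfig} used.
#' @export
setClass("EnumeratedLibrary", contains = "MoleculeSet", representation(
  provenance = "DataFrame",
  iterationCounts = "integer",
  gateRejected = "integer",
  config = "list"
))

setValidity("EnumeratedLibrary", function(object) {
  msgs <- character(0)
  if (nrow(object@provenance) != nrow(object@records))
    msgs <- c(msgs, "provenance must parallel records")
  need <- c("seedId", "ruleChain", "iterationBorn")
  if (!all(need %in% colnames(object@provenance)))
    msgs <- c(msgs, "provenance needs seedId, ruleChain, iterationBorn")
  if (nrow(object@provenance)) {
    chainLen <- vapply(strsplit(object@provenance$ruleChain, ";", fixed = TRUE),
                       function(x) length(x[nzchar(x)]), integer(1))
    if (!all(chainLen == object@provenance$iterationBorn))
      msgs <- c(msgs, "rule-chain length must equal iterationBorn")
  }
  if (length(msgs)) msgs else TRUE
})

#' CurationReport: attrition bookkeeping of the standardization cascade
#'
#' @slot nInput number of raw records presented.
#' @slot nAfterSplit records surviving parsing + largest-component split.
#' @slot nRemovedElementOrValence records rejected by the element whitelist
#'   or valence check.
#' @slot nAfterDedup final record count after stereo-agnostic deduplication.
#' @slot rejections \code{DataFrame} (sourceId, reason) with one first-failing
#'   reason per rejected record.
#' @export
setClass("CurationReport", representation(
  nInput = "integer",
  nAfterSplit = "integer",
  nRemovedElementOrValence = "integer",
  nAfterDedup = "integer",
  rejections = "DataFrame"
))

#' RuleValidationReport: per-rule audit of a compendium
#'
#' @slot perRule \code{DataFrame}: ruleId, group, transformationType, status,
#'   nProducts (on the probe), probe SMILES used.
#' @slot groupCounts named integer vector (rules per group).
#' @slot typeCounts named integer vector (rules per transformation type).
#' @export
setClass("RuleValidationReport", representation(
  perRule = "DataFrame",
  groupCounts = "integer",
  typeCounts = "integer"
))

#' FilterCascadeReport: per-stage attrition of the medicinal-chemistry cascade
#'
#' @slot stages character vector, the stage order actually applied.
#' @slot surviving named integer vector: compounds remaining after each stage
#'   (first element = input size).
#' @slot firstFailing \code{DataFrame}: canonicalKey, stage (NA = survivor).
#' @slot alertHits \code{DataFrame}: canonicalKey, catalog, patternId.
#' @slot spec the \code{FilterSpec} settings used (list, stamped into JSON).
#' @export
setClass("FilterCascadeReport", representation(
  stages = "character",
  surviving = "integer",
  firstFailing = "DataFrame",
  alertHits = "DataFrame",
  spec = "list"
))

setValidity("FilterCascadeReport", function(object) {
  s <- object@surviving
  if (length(s) > 1L && any(diff(s) > 0L))
    return("surviving counts must be non-increasing along the cascade")
  TRUE
})
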