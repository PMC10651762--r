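# Bridge to OpenBabel (via ChemmineOB) for the standard cheminformatics
# steps the package buys rather than authors: canonical SMILES, logP
# (Wildman-Crippen atomic contributions), TPSA (Ertl fragment
# contributions), and format conversion. OpenBabel aborts a batch at the
# first unreadable record, so both helpers realign results by index title
# and retry stragglers one at a time; failures surface as NA, never aborts.

.obCanonical <- function(smiles) {
  if (!length(smiles)) return(character(0))
  out <- rep(NA_character_, length(smiles))
  parseBatch <- function(res) {
    if (!nzchar(res)) return()
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    for (ln in lines[nzchar(lines)]) {
      fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(fields) < 2L) next
      idx <- suppressWarnings(as.integer(sub("^m", "", fields[2])))
      if (!is.na(idx) && idx >= 1L && idx <= length(smiles)) {
        out[idx] <<- fields[1]
      }
    }
  }
  src <- paste0(paste(smiles, paste0("m", seq_along(smiles)), sep = "\t"),
                collapse = "\n")
  parseBatch(tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN",
                                               paste0(src, "\n"))),
    error = function(e) ""))
  # a failed record truncates the batch: retry the gaps individually
  for (i in which(is.na(out))) {
    parseBatch(tryCatch(
      suppressWarnings(ChemmineOB::convertFormat(
        "SMI", "CAN", paste0(smiles[i], "\tm", i, "\n"))),
      error = function(e) ""))
  }
  out
}

# Batch physicochemical properties from OpenBabel: Wildman-Crippen logP,
# Ertl TPSA, and average-mass MW. NA rows mark molecules OpenBabel rejected.
.obProperties <- function(smiles) {
  out <- data.frame(logP = rep(NA_real_, length(smiles)),
                    TPSA = rep(NA_real_, length(smiles)),
                    MW = rep(NA_real_, length(smiles)))
  if (!length(smiles)) return(out)
  fill <- function(props) {
    if (is.null(props) || !nrow(props)) return()
    idx <- suppressWarnings(as.integer(sub("^m", "", props$title)))
    keep <- which(!is.na(idx) & idx >= 1L & idx <= length(smiles))
    out$logP[idx[keep]] <<- props$logP[keep]
    out$TPSA[idx[keep]] <<- props$TPSA[keep]
    out$MW[idx[keep]] <<- props$MW[keep]
  }
  propBatch <- function(src) {
    mols <- tryCatch(suppressWarnings(
      ChemmineOB::forEachMol("SMILES", src, identity)),
      error = function(e) NULL)
    if (is.null(mols)) return(NULL)
    if (!is.list(mols)) mols <- list(mols)
    rows <- lapply(mols, function(m) {
      tryCatch(suppressWarnings(ChemmineOB::prop_OB(m)),
               error = function(e) NULL)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows)) return(NULL)
    do.call(rbind, rows)
  }
  src <- paste0(paste(smiles, paste0("m", seq_along(smiles)), sep = "\t"),
                collapse = "\n")
  fill(propBatch(paste0(src, "\n")))
  for (i in which(is.na(out$MW))) {
    fill(propBatch(paste0(smiles[i], "\tm", i, "\n")))
  }
  out
}

# Convert SDF text to SMILES records (smiles + title), for the SDF reader.
.obSdfToSmiles <- function(sdfText) {
  res <- tryCatch(suppressWarnings(
    ChemmineOB::convertFormat("SDF", "SMI", sdfText)),
    error = function(e) "")
  if (!nzchar(res)) {
    return(data.frame(smiles = character(0), id = character(0)))
  }
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    smiles = vapply(fields, `[`, character(1), 1L),
    id = vapply(fields, function(f) if (length(f) > 1L) f[2] else NA_character_,
                character(1)),
    stringsAsFactors = FALSE)
}
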