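#' @include AllClasses.R
NULL

# Packaged structural-alert catalogs.
#
# "pains" is a curated subset of well-known pan-assay interference
# chemotype families (catechols, quinones, rhodanines, azo/hydrazone dyes,
# Michael-acceptor enones, ...); "unwanted" is a curated set of reactive or
# pharmacokinetically problematic functionality (acyl halides, epoxides,
# peroxides, isocyanates, ...). Both are deliberately compact, documented
# subsets of the much larger published collections, shipped as editable
# TSV (pattern_id, smarts, description) and extensible via user files; the
# catalog names used for a filtering run are stamped into every report so
# near-threshold counts are always attributable to a specific catalog.
.ALERT_CATALOG_FILES <- c(
  pains = "alerts_pains_subset.tsv",
  unwanted = "alerts_unwanted.tsv"
)

#' Load a structural-alert catalog
#'
#' @param catalog a packaged catalog name (\code{"pains"},
#'   \code{"unwanted"}) or a path to a TSV file with columns
#'   \code{pattern_id}, \code{smarts} and optional \code{description}.
#' @return data.frame with \code{pattern_id}, \code{smarts},
#'   \code{description} and a \code{compiled} list-column.
#' @export
loadAlertCatalog <- function(catalog) {
  path <- if (catalog %in% names(.ALERT_CATALOG_FILES)) {
    .extdata(.ALERT_CATALOG_FILES[[catalog]])
  } else if (file.exists(catalog)) {
    catalog
  } else {
    stop("unknown alert catalog: ", catalog)
  }
  .cached(paste0("alerts:", path), function() {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             colClasses = "character", quote = "",
                             comment.char = "", stringsAsFactors = FALSE)
    if (!all(c("pattern_id", "smarts") %in% colnames(tab))) {
      stop("alert catalog needs pattern_id and smarts columns: ", path)
    }
    if (!"description" %in% colnames(tab)) tab$description <- ""
    tab$compiled <- lapply(tab$smarts, .parseSmarts)
    tab
  })
}

#' Match molecules against structural-alert catalogs
#'
#' @param mols a \linkS4class{MoleculeSet} or character vector of SMILES.
#' @param catalogs character vector of catalog names and/or TSV paths
#'   (default: the packaged \code{"pains"} + \code{"unwanted"} sets). An
#'   empty vector returns no hits (vacuous screen).
#' @return data.frame of hits: \code{index} (position in \code{mols}),
#'   \code{canonicalKey}, \code{catalog}, \code{patternId}. Zero rows mean
#'   every molecule is clean.
#' @examples
#' \donttest{
#' structuralAlerts("Oc1ccc(O)cc1O")        # catechol: >= 1 hit
#' structuralAlerts("C")                    # methane: clean
#' }
#' @export
structuralAlerts <- function(mols, catalogs = c("pains", "unwanted")) {
  set <- .asMoleculeSet(mols)
  out <- data.frame(index = integer(0), canonicalKey = character(0),
                    catalog = character(0), patternId = character(0),
                    stringsAsFactors = FALSE)
  if (!length(catalogs)) return(out)
  loaded <- lapply(catalogs, loadAlertCatalog)
  names(loaded) <- catalogs
  for (i in seq_len(length(set))) {
    g <- set@graphs[[i]]
    feat <- .molFeatures(g)
    for (cat in catalogs) {
      tab <- loaded[[cat]]
      for (k in seq_len(nrow(tab))) {
        if (length(.matchSmarts(feat, tab$compiled[[k]], maxMatches = 1L))) {
          out <- rbind(out, data.frame(
            index = i, canonicalKey = canonicalKeys(set)[i],
            catalog = cat, patternId = tab$pattern_id[k],
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  out
}
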