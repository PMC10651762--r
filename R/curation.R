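#' @include AllClasses.R
NULL

# Tautomer normalization pattern: aliphatic enol -> keto. Compiled once.
.enolPattern <- function() {
  .cached("enolPattern", function() .parseSmarts("[C;A]=[C;A]-[O;D1;H1]"))
}

#' Standardize one raw SMILES into a molecule record
#'
#' Fixed-order cascade: (1) parse; (2) split components, keeping the
#' largest by heavy-atom count (ties: molecular weight, then canonical
#' key); (3) reject on elements outside H, B, C, N, O, F, Si, P, S, Cl,
#' Se, Br, I, or on valence/kekulization errors; (4) neutralize charges
#' that can be balanced by (de)protonation, then reionize (charge-separated
#' normalization of nitro-type groups); (5) deterministic rule-based
#' canonical tautomer (aliphatic enol-to-keto, applied to fixpoint);
#' (6) stereo-stripped canonical SMILES as the record key. Stereochemistry
#' is discarded at parse time throughout the package.
#'
#' @param smiles raw SMILES string.
#' @param id source identifier carried into the record.
#' @return a list: \code{ok} (logical); on success \code{graph},
#'   \code{canonicalKey}, \code{flags}; on rejection \code{reason}
#'   (\code{"parse"}, \code{"element"} or \code{"valence"}).
#' @examples
#' \donttest{
#' standardizeMolecule("CC(=O)[O-].[Na+]")$canonicalKey
#' }
#' @export
standardizeMolecule <- function(smiles, id = smiles) {
  rec <- .standardizeGraph(smiles, id)
  if (!rec$ok) return(rec)
  fin <- .finalizeRecords(list(rec))[[1]]
  fin
}

# Stage B of standardization, batched: re-aromatize every stage-A graph
# through a canonical round-trip (so rings written in Kekulé form are
# recognized as aromatic), apply the tautomer canonicalizer on the
# aromatized graph, and compute the final stereo-stripped canonical key.
# Takes/returns lists of records as produced by .standardizeGraph.
.finalizeRecords <- function(recs) {
  okIdx <- which(vapply(recs, function(r) isTRUE(r$ok), logical(1)))
  if (!length(okIdx)) return(recs)
  keys <- .obCanonical(vapply(recs[okIdx], function(r)
    .writeSmiles(r$graph), character(1)))
  redo <- integer(0)
  for (k in seq_along(okIdx)) {
    i <- okIdx[k]
    if (is.na(keys[k])) {
      recs[[i]] <- list(ok = FALSE, id = recs[[i]]$id, reason = "parse")
      next
    }
    # re-aromatized graph from the canonical form (fall back to the
    # stage-A graph when the canonical spelling uses unsupported syntax)
    g2 <- tryCatch(.sanitizeMol(.parseSmiles(keys[k])),
                   error = function(e) NULL)
    if (!is.null(g2)) recs[[i]]$graph <- g2
    taut <- .canonicalTautomer(recs[[i]]$graph)
    if (taut$changed) {
      recs[[i]]$graph <- taut$g
      recs[[i]]$flags <- union(recs[[i]]$flags, "tautomer-canonicalized")
      redo <- c(redo, i)
    } else {
      recs[[i]]$canonicalKey <- keys[k]
    }
  }
  if (length(redo)) {
    keys2 <- .obCanonical(vapply(recs[redo], function(r)
      .writeSmiles(r$graph), character(1)))
    for (k in seq_along(redo)) {
      i <- redo[k]
      if (is.na(keys2[k])) {
        recs[[i]] <- list(ok = FALSE, id = recs[[i]]$id, reason = "parse")
      } else {
        recs[[i]]$canonicalKey <- keys2[k]
      }
    }
  }
  recs
}

# standardization up to (but excluding) OB canonicalization, so library
# curation can batch the canonicalization call.
.standardizeGraph <- function(smiles, id = smiles) {
  reject <- function(reason) list(ok = FALSE, id = id, reason = reason)
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(trimws(smiles)))
    return(reject("parse"))
  g <- tryCatch(.parseSmiles(trimws(smiles)), error = function(e) e)
  if (inherits(g, "error")) return(reject("parse"))
  flags <- character(0)
  # largest component (on the raw graph: heavy atoms, then MW, then key)
  comp <- .components(g)
  if (max(comp) > 1L) {
    flags <- c(flags, "multi-component-split")
    sizes <- tabulate(comp)
    best <- which(sizes == max(sizes))
    if (length(best) > 1L) {
      mw <- vapply(best, function(ci)
        sum(.ATOMIC_WEIGHTS[g$elem[comp == ci]], na.rm = TRUE), numeric(1))
      best <- best[mw == max(mw)]
      if (length(best) > 1L) {
        keys <- vapply(best, function(ci)
          paste(sort(g$elem[comp == ci]), collapse = ""), character(1))
        best <- best[order(keys)]
      }
    }
    g <- .subgraph(g, which(comp == best[1]))
  }
  # element whitelist
  badElem <- setdiff(unique(g$elem), c(.ELEMENT_WHITELIST, "H"))
  if (length(badElem)) return(reject("element"))
  g <- tryCatch(.sanitizeMol(g), error = function(e) e)
  if (inherits(g, "error")) {
    return(reject(if (inherits(g, "chem_valence_error") ||
                      inherits(g, "chem_sanitize_error")) "valence" else
                    "parse"))
  }
  neut <- .neutralizeCharges(g)
  g <- neut$g
  if (neut$changed) flags <- c(flags, "neutralized")
  g <- .reionize(g)
  # tautomer canonicalization happens in .finalizeRecords, after the
  # canonical round-trip has re-aromatized Kekulé-written rings
  list(ok = TRUE, id = id, graph = g, flags = flags)
}

# Add/remove protons to bring formal charges to zero where a plain
# (de)protonation balances them. Zwitterionic pairs (a charged atom with an
# oppositely charged neighbour, e.g. nitro written charge-separated) are
# left alone.
.neutralizeCharges <- function(g) {
  changed <- FALSE
  adj <- .bondIndex(g)
  for (i in seq_len(.nAtoms(g))) {
    ch <- g$charge[i]
    if (ch == 0L) next
    nbr <- .neighbors(g, adj, i)
    if (ch > 0L && any(g$charge[nbr] < 0L)) next
    if (ch < 0L && any(g$charge[nbr] > 0L)) next
    if (ch > 0L && g$elem[i] %in% c("N", "O", "S", "P") && g$hcount[i] > 0L) {
      take <- min(ch, g$hcount[i])
      g$charge[i] <- ch - take
      g$hcount[i] <- g$hcount[i] - take
      g$hfixed[i] <- TRUE
      changed <- TRUE
    } else if (ch < 0L && g$elem[i] %in% c("O", "N", "S", "C", "Se")) {
      g$hcount[i] <- g$hcount[i] - ch
      g$charge[i] <- 0L
      g$hfixed[i] <- TRUE
      changed <- TRUE
    }
  }
  list(g = g, changed = changed)
}

# Normalize uncharged hypervalent nitro N(=O)=O to the charge-separated
# form so both spellings share one canonical key.
.reionize <- function(g) {
  adj <- .bondIndex(g)
  for (i in seq_len(.nAtoms(g))) {
    if (g$elem[i] != "N" || g$charge[i] != 0L) next
    dblO <- integer(0)
    for (b in adj[[i]]) {
      j <- if (g$bond$a1[b] == i) g$bond$a2[b] else g$bond$a1[b]
      if (g$elem[j] == "O" && g$bond$order[b] == 2L && !g$bond$arom[b] &&
          sum(g$bond$a1 == j | g$bond$a2 == j) == 1L && g$charge[j] == 0L) {
        dblO <- c(dblO, b)
      }
    }
    if (length(dblO) >= 2L) {
      b <- dblO[1]
      j <- if (g$bond$a1[b] == i) g$bond$a2[b] else g$bond$a1[b]
      g$bond$order[b] <- 1L
      g$charge[j] <- -1L
      g$charge[i] <- 1L
    }
  }
  g
}

# Deterministic rule-based canonical tautomer: shift aliphatic enols to the
# keto form, lowest-numbered match first, repeated to fixpoint.
.canonicalTautomer <- function(g, maxIter = 20L) {
  changed <- FALSE
  pat <- .enolPattern()
  for (iter in seq_len(maxIter)) {
    feat <- .molFeatures(g)
    ms <- .matchSmarts(feat, pat, maxMatches = 50L)
    if (!length(ms)) break
    ord <- order(vapply(ms, function(m) paste(sprintf("%04d", m),
                                              collapse = ""), character(1)))
    m <- ms[[ord[1]]]
    cA <- m[1]; cB <- m[2]; o <- m[3]
    bAB <- which(g$bond$a1 == min(cA, cB) & g$bond$a2 == max(cA, cB))
    bBO <- which(g$bond$a1 == min(cB, o) & g$bond$a2 == max(cB, o))
    g$bond$order[bAB] <- 1L
    g$bond$order[bBO] <- 2L
    g$hcount[o] <- 0L; g$hfixed[o] <- TRUE
    g$hcount[cA] <- g$hcount[cA] + 1L; g$hfixed[cA] <- TRUE
    changed <- TRUE
  }
  list(g = g, changed = changed)
}

#' Curate a compound library
#'
#' Applies \code{\link{standardizeMolecule}} to every record, removes
#' duplicates by stereo-agnostic canonical key (first occurrence kept, to
#' preserve input provenance) and reports the attrition.
#'
#' @param smiles character vector of raw SMILES.
#' @param ids optional identifiers (defaults to \code{id1..idn}).
#' @return list with \code{set} (a \linkS4class{MoleculeSet}) and
#'   \code{report} (a \linkS4class{CurationReport}).
#' @examples
#' \donttest{
#' res <- curateLibrary(c("CCO", "OCC", "CC(=O)O"))
#' length(res$set)   # 2: the two ethanol spellings merge
#' }
#' @export
curateLibrary <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("id%d", seq_along(smiles))
  stopifnot(length(ids) == length(smiles))
  n <- length(smiles)
  recs <- vector("list", n)
  for (i in seq_len(n)) recs[[i]] <- .standardizeGraph(smiles[i], ids[i])
  recs <- .finalizeRecords(recs)
  okIdx <- which(vapply(recs, function(r) isTRUE(r$ok), logical(1)))
  keys <- vapply(recs[okIdx], function(r) r$canonicalKey, character(1))
  # rejection log (one first-failing reason per record)
  rej <- !vapply(recs, function(r) r$ok, logical(1))
  rejections <- DataFrame(
    sourceId = ids[rej],
    reason = vapply(recs[rej], function(r) r$reason, character(1)))
  nParsed <- sum(vapply(recs, function(r)
    r$ok || r$reason %in% c("element", "valence"), logical(1)))
  nElemVal <- sum(vapply(recs[rej], function(r)
    r$reason %in% c("element", "valence"), logical(1)))
  keep <- !duplicated(keys)
  sel <- okIdx[keep]
  set <- new("MoleculeSet",
             records = DataFrame(
               sourceId = ids[sel],
               smilesIn = smiles[sel],
               canonicalKey = keys[keep],
               flags = vapply(recs[sel], function(r)
                 paste(r$flags, collapse = ","), character(1))),
             graphs = lapply(recs[sel], function(r) r$graph))
  report <- new("CurationReport",
                nInput = n,
                nAfterSplit = as.integer(nParsed),
                nRemovedElementOrValence = as.integer(nElemVal),
                nAfterDedup = length(sel),
                rejections = rejections)
  list(set = set, report = report)
}

#' Read compounds from .smi, CSV/TSV or SDF
#'
#' \code{.smi}/\code{.smiles}/\code{.txt}: one SMILES per line with an
#' optional whitespace-separated id. \code{.csv}/\code{.tsv}: a column
#' named like \code{smiles} (case-insensitive, or given explicitly) plus an
#' optional id column. \code{.sdf}: converted via OpenBabel.
#'
#' @param path input file.
#' @param smilesColumn column name for tabular input (default: first column
#'   whose lower-cased name contains \code{"smiles"}).
#' @param idColumn optional id column name.
#' @return data.frame with \code{smiles} and \code{id}.
#' @export
readCompounds <- function(path, smilesColumn = NULL, idColumn = NULL) {
  if (!file.exists(path)) stop("compound file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("smi", "smiles", "txt", "")) {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    parts <- strsplit(lines, "[[:space:]]+")
    return(data.frame(
      smiles = vapply(parts, `[`, character(1), 1L),
      id = vapply(seq_along(parts), function(i)
        if (length(parts[[i]]) > 1L) parts[[i]][2] else paste0("id", i),
        character(1)),
      stringsAsFactors = FALSE))
  }
  if (ext %in% c("csv", "tsv")) {
    tab <- utils::read.table(path, sep = if (ext == "csv") "," else "\t",
                             header = TRUE, colClasses = "character",
                             check.names = FALSE, quote = "\"",
                             comment.char = "", stringsAsFactors = FALSE)
    if (is.null(smilesColumn)) {
      hit <- which(grepl("smiles", tolower(colnames(tab))))
      if (!length(hit)) stop("no SMILES column found in ", path)
      smilesColumn <- colnames(tab)[hit[1]]
    }
    if (!smilesColumn %in% colnames(tab))
      stop("column '", smilesColumn, "' not present in ", path)
    idv <- if (!is.null(idColumn) && idColumn %in% colnames(tab))
      tab[[idColumn]] else paste0("id", seq_len(nrow(tab)))
    return(data.frame(smiles = tab[[smilesColumn]], id = idv,
                      stringsAsFactors = FALSE))
  }
  if (ext == "sdf") {
    res <- .obSdfToSmiles(paste(readLines(path, warn = FALSE),
                                collapse = "\n"))
    res$id[is.na(res$id) | !nzchar(res$id)] <-
      paste0("id", which(is.na(res$id) | !nzchar(res$id)))
    return(res)
  }
  stop("unsupported compound format: .", ext)
}

#' Write a curated set as CSV
#'
#' Columns: \code{id}, \code{input_smiles}, \code{canonical_key},
#' \code{flags}.
#'
#' @param set a \linkS4class{MoleculeSet}.
#' @param path output path.
#' @export
writeCurated <- function(set, path) {
  df <- data.frame(id = set@records$sourceId,
                   input_smiles = set@records$smilesIn,
                   canonical_key = set@records$canonicalKey,
                   flags = set@records$flags)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Serialize a curation report to JSON
#'
#' @param report a \linkS4class{CurationReport}.
#' @param path optional output path.
#' @export
curationReportJson <- function(report, path = NULL) {
  obj <- list(nInput = report@nInput,
              nAfterSplit = report@nAfterSplit,
              nRemovedElementOrValence = report@nRemovedElementOrValence,
              nAfterDedup = report@nAfterDedup,
              rejections = as.data.frame(report@rejections))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
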