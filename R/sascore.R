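#' @include AllClasses.R
NULL

#' Build a fragment-contribution score table from a compound collection
#'
#' Counts circular-environment identifiers (radius 0-2, as in
#' \code{\link{morganFingerprint}}) over all atoms of the collection and
#' scores each fragment by its log10 frequency relative to the median
#' fragment, clamped to [-4, 2.5]. Common fragments score high (positive),
#' rare fragments low (negative), which is the contribution scheme the
#' synthetic-accessibility score consumes. The packaged default table is
#' SYNTHETIC: it is built, with this function, from the package's own
#' generated reference library rather than from a large vendor catalog,
#' and its provenance is stamped into results that depend on it.
#'
#' @param mols a \linkS4class{MoleculeSet} or character vector of SMILES.
#' @return data.frame with \code{env_id} and \code{score}.
#' @export
buildFragmentScores <- function(mols) {
  set <- .asMoleculeSet(mols)
  counts <- new.env(parent = emptyenv())
  for (g in set@graphs) {
    ids <- as.vector(.morganEnvironments(g, radius = 2L))
    for (id in ids) {
      key <- as.character(id)
      prev <- if (exists(key, envir = counts, inherits = FALSE))
        get(key, envir = counts) else 0
      assign(key, prev + 1, envir = counts)
    }
  }
  keys <- ls(counts)
  cnt <- vapply(keys, function(k) get(k, envir = counts), numeric(1))
  # anchor at the lower quartile: ordinary environments score positive,
  # emulating the abundance skew of large-catalog frequency analyses
  anchor <- stats::quantile(cnt, 0.25)
  score <- pmin(pmax(log10(cnt / anchor), -4), 2.5)
  out <- data.frame(env_id = keys, score = round(score, 6),
                    stringsAsFactors = FALSE)
  out[order(out$env_id), , drop = FALSE]
}

.defaultFragmentScores <- function() {
  .cached("saFragmentTable", function() {
    path <- .extdata("sa_fragment_scores_synthetic.tsv")
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             colClasses = c("character", "numeric"),
                             stringsAsFactors = FALSE)
    scores <- tab$score
    names(scores) <- tab$env_id
    scores
  })
}

#' Synthetic-accessibility score (1 = easy, 10 = hard)
#'
#' Fragment-contribution synthetic accessibility: the mean frequency score
#' of the molecule's circular fragments (unknown fragments contribute the
#' floor value -4) minus complexity penalties for size
#' (\eqn{n^{1.005} - n}), stereocenters, spiro atoms, bridgehead atoms and
#' macrocycles (ring size > 8), plus a symmetry bonus when few distinct
#' fragments cover many atoms; the raw value is mapped onto [1, 10] with a
#' compression of the hard tail.
#'
#' @param mols a \linkS4class{MoleculeSet} or character vector of SMILES.
#' @param fragmentScores named numeric vector (names = environment ids) or
#'   a data.frame as from \code{\link{buildFragmentScores}}; defaults to
#'   the packaged synthetic table.
#' @return numeric vector of scores in [1, 10]; values \eqn{\le 6} are the
#'   conventional "synthesizable in principle" region.
#' @export
saScore <- function(mols, fragmentScores = NULL) {
  set <- .asMoleculeSet(mols)
  if (is.null(fragmentScores)) {
    fragmentScores <- .defaultFragmentScores()
  } else if (is.data.frame(fragmentScores)) {
    v <- fragmentScores$score
    names(v) <- fragmentScores$env_id
    fragmentScores <- v
  }
  vapply(set@graphs, function(g) .saScoreOne(g, fragmentScores), numeric(1))
}

.saScoreOne <- function(g, scores) {
  .saScoreComponents(g, scores)$sa
}

# component breakdown, used by the term-level tests
.saScoreComponents <- function(g, scores) {
  nAtoms <- .nAtoms(g)
  ids <- as.vector(.morganEnvironments(g, radius = 2L))
  idChr <- as.character(ids)
  hit <- scores[idChr]
  hit[is.na(hit)] <- -4
  score1 <- sum(hit) / length(ids)
  rc <- .ringComplexity(g)
  sizePenalty <- nAtoms^1.005 - nAtoms
  stereoPenalty <- log10(.countChiral(g) + 1)
  spiroPenalty <- log10(rc$nSpiro + 1)
  bridgePenalty <- log10(rc$nBridgehead + 1)
  macroPenalty <- if (rc$hasMacrocycle) log10(2) else 0
  score2 <- -sizePenalty - stereoPenalty - spiroPenalty - bridgePenalty -
    macroPenalty
  nUnique <- length(unique(ids))
  score3 <- if (nAtoms > nUnique) 0.5 * log(nAtoms / nUnique) else 0
  raw <- score1 + score2 + score3
  minv <- -4; maxv <- 2.5
  sa <- 11 - (raw - minv + 1) / (maxv - minv) * 9
  if (sa > 8) sa <- 8 + log(sa + 1 - 9)
  list(sa = min(max(sa, 1), 10), fragmentScore = score1,
       sizePenalty = sizePenalty, stereoPenalty = stereoPenalty,
       spiroPenalty = spiroPenalty, bridgePenalty = bridgePenalty,
       macrocyclePenalty = macroPenalty, symmetryBonus = score3)
}
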