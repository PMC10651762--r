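#' @include AllClasses.R
NULL

#' Circular substructure fingerprints (ECFP4-style)
#'
#' Hashed circular fingerprints of radius 2 folded to a fixed length:
#' each atom's environment identifier is built from its invariants
#' (element, degree, H count, charge, ring membership, aromaticity) and
#' iteratively extended with neighbour identifiers; all identifiers from
#' radius 0 to \code{radius} are folded modulo \code{nBits}. Deterministic
#' by construction.
#'
#' @param mols a \linkS4class{MoleculeSet} or character vector of SMILES.
#' @param radius neighbourhood radius (default 2, the ECFP4 convention).
#' @param nBits folded length (default 2048).
#' @return list of sorted integer vectors of set bit positions
#'   (\code{0}-based), named by canonical key.
#' @export
morganFingerprint <- function(mols, radius = 2L, nBits = 2048L) {
  set <- .asMoleculeSet(mols)
  out <- lapply(set@graphs, function(g) {
    ids <- .morganEnvironments(g, radius = radius)
    sort(unique(as.integer(as.vector(ids) %% nBits)))
  })
  names(out) <- canonicalKeys(set)
  out
}

#' Tanimoto similarity between bit-set fingerprints
#'
#' @param a,b integer vectors of set bit positions (as returned by
#'   \code{\link{morganFingerprint}}).
#' @return similarity in [0, 1]; two empty fingerprints count as 1.
#' @export
tanimotoSimilarity <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

#' Pairwise Tanimoto distance matrix
#'
#' @param fps list of bit-set fingerprints.
#' @return symmetric matrix of \code{1 - Tanimoto}.
#' @export
tanimotoDistanceMatrix <- function(fps) {
  n <- length(fps)
  d <- matrix(0, n, n)
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- 1 - tanimotoSimilarity(fps[[i]], fps[[j]])
    }
  }
  rownames(d) <- colnames(d) <- names(fps)
  d
}
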