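#' @include AllClasses.R
NULL

#' Principal-moments-of-inertia shape profile
#'
#' Generates a low-energy 3-D conformer per molecule (OpenBabel
#' \code{--gen3d} with force-field minimization, optionally refined by a
#' conformer search of breadth \code{nConformers} scored by energy),
#' computes the principal moments of inertia \eqn{I_1 \le I_2 \le I_3}
#' (amu \eqn{\mathrm{\AA}^2}, hydrogens included) and the normalized
#' ratios \eqn{npr_1 = I_1/I_3}, \eqn{npr_2 = I_2/I_3} that place each
#' molecule in the rod (0,1) - disc (0.5,0.5) - sphere (1,1) triangle.
#' Molecules whose conformer generation fails are skipped with a warning
#' (their rows carry NA). The backend exposes no RNG seed; the requested
#' \code{seed} is recorded in the output for provenance, and shapes of
#' rigid molecules are reproducible because their minimized geometry is
#' unique.
#'
#' @param mols a \linkS4class{MoleculeSet} or character vector of SMILES
#'   (each with at least 2 heavy atoms).
#' @param nConformers conformer-search breadth (default 50; 1 skips the
#'   refinement pass).
#' @param seed recorded generation seed.
#' @return a \code{DataFrame}: \code{canonicalKey}, \code{I1}, \code{I2},
#'   \code{I3}, \code{npr1}, \code{npr2}, \code{nConformers}, \code{seed}.
#' @examples
#' \donttest{
#' shapeTriple("c1ccccc1", nConformers = 1)   # disc: npr1 = npr2 = 0.5
#' }
#' @export
shapeTriple <- function(mols, nConformers = 50L, seed = 7L) {
  if (!nzchar(Sys.which("obabel"))) {
    stop("shape-unavailable: obabel not found on PATH")
  }
  set <- .asMoleculeSet(mols)
  n <- length(set)
  keys <- canonicalKeys(set)
  heavy <- vapply(set@graphs, .nAtoms, integer(1))
  if (any(heavy < 2L)) {
    stop("shape-unavailable: molecules need at least 2 heavy atoms")
  }
  smi <- tempfile(fileext = ".smi")
  sdf1 <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(smi, sdf1)), add = TRUE)
  writeLines(paste(keys, paste0("m", seq_len(n)), sep = "\t"), smi)
  suppressWarnings(system2("obabel", c(smi, "-O", sdf1, "--gen3d", "best"),
                           stdout = FALSE, stderr = FALSE))
  sdfFile <- sdf1
  if (nConformers > 1L) {
    sdf2 <- tempfile(fileext = ".sdf")
    on.exit(unlink(sdf2), add = TRUE)
    status <- suppressWarnings(system2(
      "obabel", c(sdf1, "-O", sdf2, "--conformer", "--nconf",
                  as.character(nConformers), "--score", "energy"),
      stdout = FALSE, stderr = FALSE))
    if (identical(status, 0L) && file.exists(sdf2) &&
        file.info(sdf2)$size > 0) {
      sdfFile <- sdf2
    }
  }
  mols3d <- if (file.exists(sdfFile)) .readSdfCoords(sdfFile) else list()
  byTitle <- stats::setNames(mols3d,
                             vapply(mols3d, function(m) m$title, character(1)))
  I1 <- I2 <- I3 <- npr1 <- npr2 <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    m <- byTitle[[paste0("m", i)]]
    if (is.null(m)) next
    mi <- .principalMoments(m$elements, m$coords)
    if (is.null(mi)) next
    I1[i] <- mi[1]; I2[i] <- mi[2]; I3[i] <- mi[3]
    npr1[i] <- mi[1] / mi[3]; npr2[i] <- mi[2] / mi[3]
  }
  failed <- which(is.na(npr1))
  if (length(failed)) {
    warning("conformer generation failed for ", length(failed),
            " molecule(s); rows carry NA")
  }
  DataFrame(canonicalKey = keys, I1 = I1, I2 = I2, I3 = I3,
            npr1 = npr1, npr2 = npr2,
            nConformers = rep(as.integer(nConformers), n),
            seed = rep(as.integer(seed), n))
}

# Minimal V2000 SDF coordinate reader (title, elements, coords).
.readSdfCoords <- function(path) {
  txt <- readLines(path, warn = FALSE)
  out <- list()
  i <- 1L
  while (i <= length(txt)) {
    # molecule block: title line, two header lines, counts line
    if (i + 3L > length(txt)) break
    title <- trimws(txt[i])
    counts <- txt[i + 3L]
    na <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
    nb <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
    if (is.na(na)) break
    atomLines <- txt[(i + 4L):(i + 3L + na)]
    coords <- matrix(0, na, 3L)
    elements <- character(na)
    for (k in seq_len(na)) {
      l <- atomLines[k]
      coords[k, ] <- c(as.numeric(substr(l, 1L, 10L)),
                       as.numeric(substr(l, 11L, 20L)),
                       as.numeric(substr(l, 21L, 30L)))
      elements[k] <- trimws(substr(l, 31L, 34L))
    }
    out[[length(out) + 1L]] <- list(title = title, elements = elements,
                                    coords = coords)
    # advance to end-of-record marker
    j <- i + 4L + na + max(nb, 0L)
    while (j <= length(txt) && !startsWith(txt[j], "$$$$")) j <- j + 1L
    i <- j + 1L
  }
  out
}

# sorted eigenvalues of the mass-weighted inertia tensor
.principalMoments <- function(elements, coords) {
  m <- .ATOMIC_WEIGHTS[elements]
  if (anyNA(m)) return(NULL)
  com <- colSums(coords * m) / sum(m)
  x <- sweep(coords, 2, com)
  I <- matrix(0, 3, 3)
  for (k in seq_along(m)) {
    v <- x[k, ]
    I <- I + m[k] * (diag(sum(v^2), 3) - tcrossprod(v))
  }
  ev <- sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values)
  if (ev[3] <= 0) return(NULL)
  pmax(ev, 0)
}
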