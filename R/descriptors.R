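# Native graph descriptors. Conventions:
#   HBA / HBD  Lipinski counting (N+O atoms; N/O atoms bearing >= 1 H)
#   RotB       single non-ring bonds between non-terminal heavy atoms,
#              excluding amide C-N and bonds at triple-bond carbons
#   nChiral    potential stereocenters: sp3 carbons whose four
#              substituents (implicit H included) fall in distinct
#              symmetry classes of an iterative-refinement partition;
#              assigned and unassigned centers count alike because the
#              whole pipeline is stereo-agnostic
#   AROM       SSSR rings whose atoms are all aromatic

.countHBA <- function(g) sum(g$elem %in% c("N", "O"))

.countHBD <- function(g) sum(g$elem %in% c("N", "O") & g$hcount > 0L)

.countRotB <- function(g) {
  if (!nrow(g$bond)) return(0L)
  ringb <- .ringBonds(g)
  deg <- .degree(g)
  tripleAtom <- logical(.nAtoms(g))
  tb <- which(g$bond$order == 3L)
  tripleAtom[c(g$bond$a1[tb], g$bond$a2[tb])] <- TRUE
  isAmide <- function(c_, n_) {
    if (!(g$elem[c_] == "C" && g$elem[n_] == "N")) return(FALSE)
    hits <- which((g$bond$a1 == c_ | g$bond$a2 == c_) & g$bond$order == 2L &
                  !g$bond$arom)
    for (b in hits) {
      o <- if (g$bond$a1[b] == c_) g$bond$a2[b] else g$bond$a1[b]
      if (g$elem[o] == "O") return(TRUE)
    }
    FALSE
  }
  n <- 0L
  for (b in seq_len(nrow(g$bond))) {
    if (g$bond$order[b] != 1L || g$bond$arom[b] || ringb[b]) next
    u <- g$bond$a1[b]; v <- g$bond$a2[b]
    if (deg[u] < 2L || deg[v] < 2L) next
    if (tripleAtom[u] || tripleAtom[v]) next
    if (isAmide(u, v) || isAmide(v, u)) next
    n <- n + 1L
  }
  n
}

# iterative refinement symmetry classes (Morgan-style)
.symmetryClasses <- function(g) {
  n <- .nAtoms(g)
  adj <- .bondIndex(g)
  inv <- paste(g$elem, g$arom, g$charge, g$hcount, .degree(g))
  rank <- as.integer(factor(inv, levels = sort(unique(inv))))
  for (iter in seq_len(n)) {
    sig <- vapply(seq_len(n), function(i) {
      nb <- vapply(adj[[i]], function(b) {
        j <- if (g$bond$a1[b] == i) g$bond$a2[b] else g$bond$a1[b]
        code <- if (isTRUE(g$bond$arom[b])) 4L else g$bond$order[b]
        sprintf("%d:%d", code, rank[j])
      }, character(1))
      paste(rank[i], paste(sort(nb), collapse = ","))
    }, character(1))
    newRank <- as.integer(factor(sig, levels = sort(unique(sig))))
    if (length(unique(newRank)) == length(unique(rank))) break
    rank <- newRank
  }
  rank
}

.countChiral <- function(g) {
  n <- .nAtoms(g)
  if (n < 4L) return(0L)
  adj <- .bondIndex(g)
  deg <- .degree(g)
  cls <- .symmetryClasses(g)
  cnt <- 0L
  for (i in seq_len(n)) {
    if (g$elem[i] != "C" || g$arom[i]) next
    multi <- any(vapply(adj[[i]], function(b) g$bond$order[b] > 1L, logical(1)))
    if (multi) next
    if (deg[i] + g$hcount[i] != 4L) next
    if (g$hcount[i] > 1L) next
    nbrCls <- cls[.neighbors(g, adj, i)]
    if (anyDuplicated(nbrCls)) next
    cnt <- cnt + 1L
  }
  cnt
}

.countAromaticRings <- function(g, sssr = NULL) {
  if (is.null(sssr)) sssr <- .sssr(g)
  if (!length(sssr)) return(0L)
  sum(vapply(sssr, function(cyc) all(g$arom[cyc]), logical(1)))
}

# ring-complexity counts for the synthetic-accessibility penalty terms:
# spiro atoms (two rings sharing exactly one atom), bridgehead atoms
# (>= 3 ring bonds within a bridged pair: rings sharing >= 3 atoms), and
# macrocycles (any SSSR ring larger than 8).
.ringComplexity <- function(g) {
  sssr <- .sssr(g)
  spiro <- integer(0); bridge <- integer(0)
  if (length(sssr) >= 2L) {
    x <- .ringBondCount(g)
    for (i in seq_len(length(sssr) - 1L)) {
      for (j in (i + 1L):length(sssr)) {
        shared <- intersect(sssr[[i]], sssr[[j]])
        if (length(shared) == 1L) spiro <- c(spiro, shared)
        if (length(shared) >= 3L) {
          bridge <- c(bridge, shared[x[shared] >= 3L])
        }
      }
    }
  }
  list(nSpiro = length(unique(spiro)),
       nBridgehead = length(unique(bridge)),
       hasMacrocycle = any(vapply(sssr, length, integer(1)) > 8L))
}

# ECFP-style circular identifiers per atom and radius.
# Returns an integer matrix n x (radius+1): environment ids.
.morganEnvironments <- function(g, radius = 2L) {
  n <- .nAtoms(g)
  adj <- .bondIndex(g)
  ringb <- .ringBonds(g)
  inRing <- logical(n)
  if (nrow(g$bond)) {
    rb <- which(ringb)
    inRing[c(g$bond$a1[rb], g$bond$a2[rb])] <- TRUE
  }
  ids <- matrix(0, nrow = n, ncol = radius + 1L)
  for (i in seq_len(n)) {
    ids[i, 1] <- .hashInts(c(
      .ELEMENT_NUMBERS[[g$elem[i]]], .degree(g)[i], g$hcount[i],
      g$charge[i] + 10L, as.integer(inRing[i]), as.integer(g$arom[i])))
  }
  if (radius >= 1L) {
    for (r in seq_len(radius)) {
      for (i in seq_len(n)) {
        nb <- vapply(adj[[i]], function(b) {
          j <- if (g$bond$a1[b] == i) g$bond$a2[b] else g$bond$a1[b]
          code <- if (isTRUE(g$bond$arom[b])) 4L else g$bond$order[b]
          code * 2147483647 + ids[j, r]
        }, numeric(1))
        nb <- sort(nb)
        flat <- as.vector(rbind(floor(nb / 2147483647), nb %% 2147483647))
        ids[i, r + 1L] <- .hashInts(c(r, ids[i, r], flat))
      }
    }
  }
  ids
}
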