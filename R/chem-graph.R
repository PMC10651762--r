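# Internal molecular-graph model.
#
# A molgraph is a list with:
#   elem    character  element symbols (capitalized; aromaticity is a flag)
#   arom    logical    atom aromatic flags
#   charge  integer    formal charges
#   hcount  integer    hydrogen counts (filled by .sanitizeMol)
#   hfixed  logical    TRUE when the H count was given explicitly ([nH], [NH2])
#   iso     integer    isotope labels (NA = natural)
#   bond    data.frame(a1, a2, order, arom)   1-based atom indices, a1 < a2
#
# Bonds of kekulized aromatic systems keep order 1/2 AND arom = TRUE, so
# valence arithmetic always sees definite orders while matching and SMILES
# output still see aromaticity.

.newMolgraph <- function() {
  list(
    elem = character(0), arom = logical(0), charge = integer(0),
    hcount = integer(0), hfixed = logical(0), iso = integer(0),
    bond = data.frame(a1 = integer(0), a2 = integer(0),
                      order = integer(0), arom = logical(0))
  )
}

.nAtoms <- function(g) length(g$elem)

.chemError <- function(msg, class) {
  stop(structure(class = c(class, "chem_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# adjacency: list of integer vectors of bond row indices per atom
.bondIndex <- function(g) {
  n <- .nAtoms(g)
  adj <- vector("list", n)
  if (nrow(g$bond) == 0L) return(lapply(seq_len(n), function(i) integer(0)))
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  for (b in seq_len(nrow(g$bond))) {
    adj[[g$bond$a1[b]]] <- c(adj[[g$bond$a1[b]]], b)
    adj[[g$bond$a2[b]]] <- c(adj[[g$bond$a2[b]]], b)
  }
  adj
}

.neighbors <- function(g, adj, i) {
  vapply(adj[[i]], function(b) {
    if (g$bond$a1[b] == i) g$bond$a2[b] else g$bond$a1[b]
  }, integer(1))
}

.degree <- function(g) {
  n <- .nAtoms(g)
  d <- integer(n)
  if (nrow(g$bond)) {
    t1 <- tabulate(g$bond$a1, n); t2 <- tabulate(g$bond$a2, n)
    d <- t1 + t2
  }
  d
}

.bondOrderSum <- function(g) {
  n <- .nAtoms(g)
  s <- numeric(n)
  if (nrow(g$bond)) {
    for (b in seq_len(nrow(g$bond))) {
      s[g$bond$a1[b]] <- s[g$bond$a1[b]] + g$bond$order[b]
      s[g$bond$a2[b]] <- s[g$bond$a2[b]] + g$bond$order[b]
    }
  }
  s
}

# Ring bonds via bridge finding (a bond is in a ring iff it is not a bridge).
.ringBonds <- function(g) {
  n <- .nAtoms(g)
  nb <- nrow(g$bond)
  if (nb == 0L) return(logical(0))
  adj <- .bondIndex(g)
  disc <- integer(n); low <- integer(n); visited <- logical(n)
  isBridge <- logical(nb)
  timer <- 0L
  for (root in seq_len(n)) {
    if (visited[root]) next
    # iterative DFS with explicit stack: entries (atom, parent bond, next ptr)
    stack <- list(list(a = root, pb = 0L, k = 1L))
    visited[root] <- TRUE; timer <- timer + 1L
    disc[root] <- low[root] <- timer
    while (length(stack)) {
      top <- stack[[length(stack)]]
      a <- top$a
      if (top$k <= length(adj[[a]])) {
        b <- adj[[a]][top$k]
        stack[[length(stack)]]$k <- top$k + 1L
        if (b == top$pb) next
        w <- if (g$bond$a1[b] == a) g$bond$a2[b] else g$bond$a1[b]
        if (!visited[w]) {
          visited[w] <- TRUE; timer <- timer + 1L
          disc[w] <- low[w] <- timer
          stack[[length(stack) + 1L]] <- list(a = w, pb = b, k = 1L)
        } else {
          low[a] <- min(low[a], disc[w])
        }
      } else {
        stack[[length(stack)]] <- NULL
        if (length(stack)) {
          p <- stack[[length(stack)]]$a
          low[p] <- min(low[p], low[a])
          if (low[a] > disc[p]) isBridge[top$pb] <- TRUE
        }
      }
    }
  }
  !isBridge
}

# Smallest set of smallest rings (pragmatic): shortest cycle through every
# ring bond, deduplicated, then greedily selected by size until the
# cyclomatic number of the ring subgraph is reached.
.sssr <- function(g, ringb = NULL) {
  if (is.null(ringb)) ringb <- .ringBonds(g)
  nb <- which(ringb)
  if (!length(nb)) return(list())
  adj <- .bondIndex(g)
  cycles <- list()
  for (b in nb) {
    u <- g$bond$a1[b]; v <- g$bond$a2[b]
    # BFS from u to v avoiding bond b, restricted to ring bonds
    prev <- rep(NA_integer_, .nAtoms(g))
    prev[u] <- 0L
    queue <- u
    while (length(queue) && is.na(prev[v])) {
      a <- queue[1]; queue <- queue[-1]
      for (bb in adj[[a]]) {
        if (bb == b || !ringb[bb]) next
        w <- if (g$bond$a1[bb] == a) g$bond$a2[bb] else g$bond$a1[bb]
        if (is.na(prev[w])) { prev[w] <- a; queue <- c(queue, w) }
      }
    }
    if (is.na(prev[v])) next
    path <- v
    while (path[1] != u) path <- c(prev[path[1]], path)
    key <- paste(sort(path), collapse = ",")
    if (is.null(cycles[[key]])) cycles[[key]] <- path
  }
  cycles <- cycles[order(vapply(cycles, length, integer(1)),
                         names(cycles))]
  # target ring count: cyclomatic number of ring subgraph
  ringAtoms <- sort(unique(c(g$bond$a1[nb], g$bond$a2[nb])))
  compCount <- .countComponents(ringAtoms, g$bond[nb, , drop = FALSE])
  target <- length(nb) - length(ringAtoms) + compCount
  chosen <- list()
  covered <- logical(nrow(g$bond))
  for (cyc in cycles) {
    if (length(chosen) >= target) break
    cycBonds <- .cycleBonds(g, cyc)
    if (any(!covered[cycBonds])) {
      covered[cycBonds] <- TRUE
      chosen[[length(chosen) + 1L]] <- cyc
    }
  }
  chosen
}

.cycleBonds <- function(g, cyc) {
  k <- length(cyc)
  pairs1 <- cyc
  pairs2 <- c(cyc[-1], cyc[1])
  lo <- pmin(pairs1, pairs2); hi <- pmax(pairs1, pairs2)
  match(paste(lo, hi), paste(g$bond$a1, g$bond$a2))
}

.countComponents <- function(atoms, bonds) {
  if (!length(atoms)) return(0L)
  idx <- seq_along(atoms)
  names(idx) <- atoms
  parent <- idx
  findp <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(bonds)) for (b in seq_len(nrow(bonds))) {
    i <- findp(idx[as.character(bonds$a1[b])])
    j <- findp(idx[as.character(bonds$a2[b])])
    if (i != j) parent[i] <- j
  }
  length(unique(vapply(idx, findp, integer(1))))
}

# Connected components over atoms; returns integer component id per atom.
.components <- function(g) {
  n <- .nAtoms(g)
  comp <- rep(NA_integer_, n)
  adj <- .bondIndex(g)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s; comp[s] <- cid
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      for (w in .neighbors(g, adj, a)) {
        if (is.na(comp[w])) { comp[w] <- cid; queue <- c(queue, w) }
      }
    }
  }
  comp
}

# Extract the induced subgraph on a set of atoms (renumbers atoms).
.subgraph <- function(g, atoms) {
  atoms <- sort(atoms)
  map <- match(seq_len(.nAtoms(g)), atoms)
  keep <- !is.na(map[g$bond$a1]) & !is.na(map[g$bond$a2])
  out <- list(
    elem = g$elem[atoms], arom = g$arom[atoms], charge = g$charge[atoms],
    hcount = g$hcount[atoms], hfixed = g$hfixed[atoms], iso = g$iso[atoms],
    bond = data.frame(a1 = map[g$bond$a1[keep]], a2 = map[g$bond$a2[keep]],
                      order = g$bond$order[keep], arom = g$bond$arom[keep])
  )
  if (nrow(out$bond)) {
    lo <- pmin(out$bond$a1, out$bond$a2); hi <- pmax(out$bond$a1, out$bond$a2)
    out$bond$a1 <- lo; out$bond$a2 <- hi
  }
  out
}

# Kekulize aromatic systems in place: every aromatic atom must need 0 or 1
# ring double bond; a perfect matching over the atoms needing one must exist
# within the aromatic bond subgraph, otherwise the structure is rejected.
.kekulize <- function(g) {
  aromAtoms <- which(g$arom)
  if (!length(aromAtoms)) return(g)
  aromBonds <- which(g$bond$arom)
  # every aromatic atom must carry at least two aromatic bonds (ring member)
  cnt <- integer(.nAtoms(g))
  for (b in aromBonds) {
    cnt[g$bond$a1[b]] <- cnt[g$bond$a1[b]] + 1L
    cnt[g$bond$a2[b]] <- cnt[g$bond$a2[b]] + 1L
  }
  if (any(cnt[aromAtoms] < 2L)) {
    .chemError("aromatic atom outside an aromatic ring", "chem_sanitize_error")
  }
  # valence demand: does the atom need one double bond within the system?
  needs <- rep(NA, .nAtoms(g))
  for (i in aromAtoms) {
    target <- .aromTargetValence(g$elem[i], g$charge[i])
    if (is.na(target)) {
      .chemError(sprintf("element %s cannot be aromatic", g$elem[i]),
                 "chem_sanitize_error")
    }
    nonArom <- sum(g$bond$order[setdiff(which(g$bond$a1 == i | g$bond$a2 == i),
                                        aromBonds)])
    h <- g$hcount[i]
    need <- target - h - nonArom - cnt[i]
    if (is.na(need) || need < 0L || need > 1L) {
      .chemError("unkekulizable aromatic system (valence demand)",
                 "chem_sanitize_error")
    }
    needs[i] <- need
  }
  # exact matching by backtracking over each aromatic component
  mustMatch <- aromAtoms[vapply(aromAtoms, function(i) needs[i] == 1L, logical(1))]
  matchedBond <- .matchAromatic(g, aromBonds, mustMatch)
  if (is.null(matchedBond)) {
    .chemError("unkekulizable aromatic system (no perfect matching)",
               "chem_sanitize_error")
  }
  g$bond$order[aromBonds] <- 1L
  g$bond$order[matchedBond] <- 2L
  g
}

.matchAromatic <- function(g, aromBonds, mustMatch) {
  if (!length(mustMatch)) return(integer(0))
  # candidate bonds: aromatic bonds joining two must-match atoms
  cand <- aromBonds[g$bond$a1[aromBonds] %in% mustMatch &
                    g$bond$a2[aromBonds] %in% mustMatch]
  matched <- integer(0)
  used <- logical(.nAtoms(g))
  order <- mustMatch[order(vapply(mustMatch, function(i) {
    sum(g$bond$a1[cand] == i | g$bond$a2[cand] == i)
  }, integer(1)))]
  recurse <- function(k) {
    if (k > length(order)) return(TRUE)
    a <- order[k]
    if (used[a]) return(recurse(k + 1L))
    for (b in cand) {
      u <- g$bond$a1[b]; v <- g$bond$a2[b]
      if (u != a && v != a) next
      w <- if (u == a) v else u
      if (used[w]) next
      used[a] <<- TRUE; used[w] <<- TRUE
      matched <<- c(matched, b)
      if (recurse(k + 1L)) return(TRUE)
      used[a] <<- FALSE; used[w] <<- FALSE
      matched <<- matched[-length(matched)]
    }
    FALSE
  }
  if (!recurse(1L)) return(NULL)
  matched
}

# Fill implicit hydrogens and validate valences. Returns the graph with
# hcount complete, or signals chem_valence_error / chem_sanitize_error.
.sanitizeMol <- function(g) {
  n <- .nAtoms(g)
  if (n == 0L) .chemError("empty molecule", "chem_parse_error")
  ringb <- .ringBonds(g)
  # resolve default bonds flagged NA: aromatic iff both atoms aromatic and in ring
  und <- which(is.na(g$bond$arom))
  for (b in und) {
    both <- g$arom[g$bond$a1[b]] && g$arom[g$bond$a2[b]]
    g$bond$arom[b] <- both && ringb[b]
  }
  if (any(g$bond$arom & !ringb)) {
    .chemError("aromatic bond outside a ring", "chem_sanitize_error")
  }
  # aromatic implicit hydrogens (organic-subset convention)
  deg <- .degree(g)
  for (i in seq_len(n)) {
    if (!is.na(g$hcount[i])) next
    if (g$arom[i]) {
      g$hcount[i] <- if (g$elem[i] == "C" && deg[i] == 2L) 1L else 0L
    }
  }
  g <- .kekulize(g)
  bos <- .bondOrderSum(g)
  for (i in seq_len(n)) {
    allowed <- .allowedValences(g$elem[i], g$charge[i])
    if (!length(allowed)) {
      .chemError(sprintf("no valence model for %s charge %+d",
                         g$elem[i], g$charge[i]), "chem_valence_error")
    }
    if (is.na(g$hcount[i])) {
      fit <- allowed[allowed >= bos[i]]
      g$hcount[i] <- if (length(fit)) as.integer(fit[1] - bos[i]) else
        .chemError(sprintf("valence %d too high for %s", bos[i], g$elem[i]),
                   "chem_valence_error")
    } else {
      tot <- bos[i] + g$hcount[i]
      # explicit-H atoms: overvalence is an error; sub-valence (radicals)
      # is tolerated
      if (tot > max(allowed)) {
        .chemError(sprintf("valence %d exceeds maximum for %s%+d",
                           tot, g$elem[i], g$charge[i]), "chem_valence_error")
      }
      if (g$arom[i] && !(tot %in% allowed) && tot > min(allowed)) {
        # aromatic kekulization already validated; leave as-is
      }
    }
  }
  g
}

.molWeight <- function(g) {
  w <- .ATOMIC_WEIGHTS[g$elem]
  if (anyNA(w)) .chemError("atomic weight unknown", "chem_element_error")
  sum(w) + sum(g$hcount) * .ATOMIC_WEIGHTS[["H"]]
}

# number of ring bonds incident to each atom (SMARTS 'x' primitive)
.ringBondCount <- function(g, ringb = NULL) {
  if (is.null(ringb)) ringb <- .ringBonds(g)
  n <- .nAtoms(g)
  cnt <- integer(n)
  for (b in which(ringb)) {
    cnt[g$bond$a1[b]] <- cnt[g$bond$a1[b]] + 1L
    cnt[g$bond$a2[b]] <- cnt[g$bond$a2[b]] + 1L
  }
  cnt
}
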