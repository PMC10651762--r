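#' @include AllClasses.R
NULL

# Motif variant pools for the synthetic seed generator. Every SMILES here
# parses, passes curation unchanged (curation-stable by construction) and
# contains the motif its pool is named after, so each built-in rule can be
# probed against a seed that carries its reactant pattern.
.FIXTURE_MOTIFS <- list(
  "carboxylic-acid" = c("CC(=O)O", "CCC(=O)O", "CC(C)C(=O)O",
                        "OC(=O)Cc1ccccc1", "CCCCC(=O)O"),
  "phenyl" = c("Cc1ccccc1", "CCc1ccccc1", "CCCc1ccccc1",
               "CC(C)c1ccccc1", "CCCCc1ccccc1"),
  "amide" = c("CC(=O)NC", "CCC(=O)NC", "CC(=O)NCC",
              "CC(=O)N(C)C", "CCC(=O)NCC"),
  "aminophenyl" = c("CN(C)c1ccccc1", "CCN(C)c1ccccc1", "CCN(CC)c1ccccc1",
                    "CN(CC)c1ccccc1", "CCCN(C)c1ccccc1"),
  "benzoylphenyl" = c("O=C(c1ccccc1)c1ccccc1", "CC(=O)c1ccccc1C(=O)c1ccccc1",
                      "O=C(c1ccccc1)c1ccc(C)cc1", "O=C(c1ccccc1)c1cccc(C)c1",
                      "O=C(c1ccccc1)c1ccc(CC)cc1"),
  "1,4-diaminophenyl" = c("Nc1ccc(N)cc1", "CCc1cc(N)ccc1N",
                          "Nc1ccc(N)c(C)c1", "CCCc1cc(N)ccc1N",
                          "Nc1ccc(N)c(CC)c1")
)

#' The built-in transformation-rule compendium
#'
#' Seven literature transformation rules spanning the main rule families
#' (phenyl bioisosteres, carboxyl ring addition, aminophenyl ring
#' substitution, diaminophenyl ring modification, benzoylphenyl linker
#' modification), with their groups, transformation types, SMIRKS
#' (extension blocks intact), rationale tags and references, read from the
#' packaged rule table. Serves as the no-download stand-in for the full
#' published 280-rule compendium, which \code{\link{readRuleCompendium}}
#' loads from its delimited file when available.
#'
#' @return a \linkS4class{RuleCompendium}.
#' @examples
#' rules <- builtinRules()
#' length(rules)
#' @export
builtinRules <- function() {
  comp <- readRuleCompendium(.extdata("table2_rules.tsv"))
  comp@source <- "builtin"
  comp
}

#' Generate a deterministic synthetic seed set
#'
#' Draws curation-stable molecules from per-motif variant pools. Intended
#' as probe/seed material for rule validation, enumeration tests and
#' pipeline demonstrations; reproducible under \code{seed}.
#'
#' @param motifs character vector of motif names (see
#'   \code{names(ChemLibDesign:::.FIXTURE_MOTIFS)}).
#' @param countPerMotif molecules per motif (0 allowed; capped at the pool
#'   size of 5 per motif).
#' @param seed integer seed controlling which variants are drawn.
#' @return a \linkS4class{MoleculeSet}.
#' @examples
#' \donttest{
#' makeSeedSet(c("phenyl", "carboxylic-acid"), countPerMotif = 2)
#' }
#' @export
makeSeedSet <- function(motifs = names(.FIXTURE_MOTIFS), countPerMotif = 1L,
                        seed = 1L) {
  unknown <- setdiff(motifs, names(.FIXTURE_MOTIFS))
  if (length(unknown)) {
    stop("unknown motif(s): ", paste(unknown, collapse = ", "))
  }
  countPerMotif <- as.integer(countPerMotif)
  if (countPerMotif < 0L) stop("countPerMotif must be >= 0")
  smiles <- character(0); ids <- character(0)
  rng <- .lcg(seed)
  for (m in motifs) {
    pool <- .FIXTURE_MOTIFS[[m]]
    k <- min(countPerMotif, length(pool))
    if (k == 0L) next
    ord <- .lcgSample(rng, length(pool))
    pick <- pool[ord[seq_len(k)]]
    smiles <- c(smiles, pick)
    ids <- c(ids, paste0(gsub("[^a-z0-9]+", "_", m), "_", seq_len(k)))
  }
  if (!length(smiles)) {
    return(new("MoleculeSet",
               records = DataFrame(sourceId = character(0),
                                   smilesIn = character(0),
                                   canonicalKey = character(0),
                                   flags = character(0)),
               graphs = list()))
  }
  curateLibrary(smiles, ids)$set
}

# tiny deterministic linear congruential generator so fixture generation
# never disturbs (or depends on) the session RNG state
.lcg <- function(seed) {
  state <- new.env(parent = emptyenv())
  state$x <- (as.numeric(seed) %% 2147483647) + 1
  state
}

.lcgNext <- function(rng) {
  rng$x <- (rng$x * 48271) %% 2147483647
  rng$x
}

.lcgSample <- function(rng, n) {
  # deterministic permutation of 1..n
  keys <- vapply(seq_len(n), function(i) .lcgNext(rng), numeric(1))
  order(keys)
}

# scaffold/substituent pools for the reference-library emulator
# scaffolds as token templates: substituent branches may follow any token
# marked TRUE (one branch per position keeps every product valence-legal)
.REF_SCAFFOLDS <- list(
  benzene = list(tokens = c("c1", "c", "c", "c", "c", "c1"),
                 open = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)),
  pyridine = list(tokens = c("c1", "c", "c", "c", "c", "n1"),
                  open = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)),
  furan = list(tokens = c("c1", "c", "c", "c", "o1"),
               open = c(TRUE, TRUE, TRUE, TRUE, FALSE)),
  thiophene = list(tokens = c("c1", "c", "c", "c", "s1"),
                   open = c(TRUE, TRUE, TRUE, TRUE, FALSE)),
  cyclohexane = list(tokens = c("C1", "C", "C", "C", "C", "C1"),
                     open = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)),
  piperidine = list(tokens = c("C1", "C", "C", "C", "C", "N1"),
                    open = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)),
  naphthalene = list(tokens = c("c1", "c", "c", "c2", "c", "c", "c", "c",
                                "c2", "c1"),
                     open = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE,
                              TRUE, FALSE, FALSE)),
  oxolane = list(tokens = c("C1", "C", "C", "C", "O1"),
                 open = c(TRUE, TRUE, TRUE, TRUE, FALSE))
)
.REF_SUBSTITUENTS <- c("C", "CC", "CCC", "O", "OC", "N", "F", "Cl",
                       "C(=O)O", "C(=O)NC", "CO", "C(C)C", "OCC", "C#N",
                       "S(=O)(=O)C", "CCN", "c1ccccc1", "Cc1ccccc1",
                       "OCc1ccccc1", "C(=O)Nc1ccccc1", "C(F)(F)F",
                       "S(=O)(=O)Nc1ccccc1", "OCCOC", "N(CC)CC",
                       "C(=O)Oc1ccccc1", "CCCCCC")

#' Generate a synthetic reference compound library
#'
#' Emulates an external reference collection by decorating ring scaffolds
#' with random substituents; when \code{propertyTargets} supplies a target
#' mean (currently \code{MW}, \code{TPSA} and/or \code{logP}), candidates
#' are over-sampled and a subset is greedily selected whose mean best
#' approaches the target. Reproducible under \code{seed}. This generator
#' produces plausible drug-like decorated scaffolds; it does not reproduce
#' any real database's content.
#'
#' @param n number of molecules (>= 1).
#' @param propertyTargets optional named list/vector of target means, e.g.
#'   \code{c(MW = 350)}; a warning is issued when the achieved mean misses
#'   a target by more than \code{tolerance}.
#' @param seed integer seed.
#' @param tolerance acceptable absolute deviation of achieved means
#'   (default 50 for MW, 15 for TPSA, 0.75 for logP).
#' @return a \linkS4class{MoleculeSet} with an attribute
#'   \code{achievedMeans}.
#' @export
makeReferenceLibrary <- function(n, propertyTargets = NULL, seed = 1L,
                                 tolerance = NULL) {
  stopifnot(n >= 1L)
  rng <- .lcg(seed + 7L)
  nCand <- if (is.null(propertyTargets)) n * 2L else n * 10L
  smiles <- character(0)
  guard <- 0L
  while (length(smiles) < nCand && guard < nCand * 20L) {
    guard <- guard + 1L
    sc <- .REF_SCAFFOLDS[[(.lcgNext(rng) %% length(.REF_SCAFFOLDS)) + 1L]]
    nSub <- (.lcgNext(rng) %% 5L)
    subs <- vapply(seq_len(nSub), function(i) {
      .REF_SUBSTITUENTS[(.lcgNext(rng) %% length(.REF_SUBSTITUENTS)) + 1L]
    }, character(1))
    smi <- .decorateScaffold(sc, subs, rng)
    if (!is.null(smi)) smiles <- c(smiles, smi)
  }
  cur <- curateLibrary(unique(smiles))
  set <- cur$set
  if (length(set) > n) {
    if (!is.null(propertyTargets)) {
      prof <- computeProfile(set)
      sel <- .selectTowardTargets(prof, propertyTargets, n)
      set <- set[sel]
    } else {
      set <- set[seq_len(n)]
    }
  }
  prof <- computeProfile(set)
  achieved <- c(MW = mean(prof$MW), TPSA = mean(prof$TPSA),
                logP = mean(prof$logP))
  if (!is.null(propertyTargets)) {
    defTol <- c(MW = 50, TPSA = 15, logP = 0.75)
    for (p in names(propertyTargets)) {
      tol <- if (!is.null(tolerance)) tolerance else defTol[[p]]
      if (abs(achieved[[p]] - propertyTargets[[p]]) > tol) {
        warning(sprintf(
          "reference library %s mean %.1f misses target %.1f (best effort)",
          p, achieved[[p]], as.numeric(propertyTargets[[p]])))
      }
    }
  }
  attr(set, "achievedMeans") <- achieved
  set
}

# attach each substituent as a branch at a distinct open template position
.decorateScaffold <- function(scaffold, subs, rng) {
  open <- which(scaffold$open)
  if (length(subs) > length(open)) subs <- subs[seq_along(open)]
  slots <- open[.lcgSample(rng, length(open))][seq_along(subs)]
  parts <- scaffold$tokens
  for (k in seq_along(subs)) {
    parts[slots[k]] <- paste0(parts[slots[k]], "(", subs[k], ")")
  }
  smi <- paste(parts, collapse = "")
  ok <- tryCatch({
    .sanitizeMol(.parseSmiles(smi)); TRUE
  }, error = function(e) FALSE)
  if (ok) smi else NULL
}

# greedy forward selection of n rows whose running means approach targets
.selectTowardTargets <- function(prof, targets, n) {
  cols <- intersect(names(targets), c("MW", "TPSA", "logP"))
  if (!length(cols)) return(seq_len(n))
  scale <- c(MW = 100, TPSA = 40, logP = 2)[cols]
  vals <- as.matrix(as.data.frame(prof)[, cols, drop = FALSE])
  tgt <- as.numeric(targets[cols])
  chosen <- integer(0)
  left <- seq_len(nrow(vals))
  for (k in seq_len(n)) {
    if (!length(left)) break
    cost <- vapply(left, function(i) {
      m <- colMeans(vals[c(chosen, i), , drop = FALSE])
      sum(abs(m - tgt) / scale)
    }, numeric(1))
    pick <- left[which.min(cost)]
    chosen <- c(chosen, pick)
    left <- setdiff(left, pick)
  }
  sort(chosen)
}
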