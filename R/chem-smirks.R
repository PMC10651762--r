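# SMIRKS compilation and single-site graph rewriting.
#
# Semantics follow the conventions of widely used reaction-transform
# engines, which are what make the published rule compendia behave as
# their authors intended:
#   * matched reactant atoms whose map class appears on the product side
#     are kept (element/aromaticity/charge updated from the template);
#   * matched reactant atoms with no surviving map class are deleted with
#     their bonds;
#   * product atoms whose map class is absent from the reactant side — and
#     unmapped product atoms — are created fresh;
#   * bonds written in the reactant pattern are removed, bonds written in
#     the product template are installed (replacing any existing bond);
#   * each match site yields one product (single-site application);
#   * hydrogen counts are recomputed from valence unless the template pins
#     them, and products failing kekulization or valence checks are
#     dropped and counted, never fatal.
# Atom maps written inside recursive SMARTS alternatives are NOT treated
# as reactant maps (matching the behaviour of the reference engines):
# product atoms carrying such a map class are created fresh, which is what
# produces the intended product for rules printed that way (the departing
# atom's substituents that must not survive leave with the deleted atom).

.compileSmirks <- function(text) {
  raw <- text
  ext <- regmatches(text, gregexpr("\\|[^|]*\\|", text))[[1]]
  text <- gsub("\\|[^|]*\\|", "", text)
  text <- gsub("[[:space:]]+", "", text)
  parts <- strsplit(text, ">>", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !nzchar(parts[1]) || !nzchar(parts[2])) {
    .chemError("SMIRKS must contain exactly one '>>' separating non-empty reactant and product sides",
               "chem_smirks_malformed")
  }
  reactant <- .parseSmarts(parts[1])
  product <- .parseSmiles(parts[2], mode = "template")
  rmap <- vapply(reactant$atoms, function(a) a$map, integer(1))
  pmap <- product$map
  if (anyDuplicated(rmap[!is.na(rmap)])) {
    .chemError("duplicate atom-map class on the reactant side",
               "chem_smirks_mapping")
  }
  if (anyDuplicated(pmap[!is.na(pmap)])) {
    .chemError("duplicate atom-map class on the product side",
               "chem_smirks_mapping")
  }
  newMaps <- setdiff(pmap[!is.na(pmap)], rmap[!is.na(rmap)])
  droppedMaps <- setdiff(rmap[!is.na(rmap)], pmap[!is.na(pmap)])
  list(reactant = reactant, product = product,
       rmap = rmap, pmap = pmap,
       newProductMaps = newMaps, droppedMaps = droppedMaps,
       extensions = ext, smirks = raw)
}

.removeAtoms <- function(g, atoms) {
  if (!length(atoms)) return(g)
  keep <- setdiff(seq_len(.nAtoms(g)), atoms)
  map <- match(seq_len(.nAtoms(g)), keep)
  bkeep <- !(g$bond$a1 %in% atoms) & !(g$bond$a2 %in% atoms)
  out <- g
  for (fld in c("elem", "arom", "charge", "hcount", "hfixed", "iso", "map")) {
    if (!is.null(out[[fld]])) out[[fld]] <- out[[fld]][keep]
  }
  out$bond <- g$bond[bkeep, , drop = FALSE]
  if (nrow(out$bond)) {
    out$bond$a1 <- map[out$bond$a1]
    out$bond$a2 <- map[out$bond$a2]
    lo <- pmin(out$bond$a1, out$bond$a2); hi <- pmax(out$bond$a1, out$bond$a2)
    out$bond$a1 <- lo; out$bond$a2 <- hi
    rownames(out$bond) <- NULL
  }
  out
}

# Apply a compiled SMIRKS at one match; returns a raw (unsanitized) product
# graph or NULL when the edit is structurally impossible.
.rewriteAtMatch <- function(g, compiled, match) {
  ng <- g
  ng$map <- NULL
  np <- .nAtoms(ng)
  rmap <- compiled$rmap; pmap <- compiled$pmap
  prod <- compiled$product
  # product template atom -> molecule atom (NA = to be created)
  prodTarget <- rep(NA_integer_, length(pmap))
  for (j in seq_along(pmap)) {
    if (!is.na(pmap[j]) && pmap[j] %in% rmap) {
      prodTarget[j] <- match[which(rmap == pmap[j])]
    }
  }
  # remove reactant-pattern bonds
  if (nrow(compiled$reactant$bonds)) {
    for (b in seq_len(nrow(compiled$reactant$bonds))) {
      u <- match[compiled$reactant$bonds$a1[b]]
      v <- match[compiled$reactant$bonds$a2[b]]
      hit <- which(ng$bond$a1 == min(u, v) & ng$bond$a2 == max(u, v))
      if (length(hit)) ng$bond <- ng$bond[-hit[1], , drop = FALSE]
    }
  }
  # update kept atoms from the template
  for (j in seq_along(pmap)) {
    t <- prodTarget[j]
    if (is.na(t)) next
    if (prod$elem[j] != "*") {
      ng$elem[t] <- prod$elem[j]
      ng$arom[t] <- prod$arom[j]
      ng$charge[t] <- prod$charge[j]
    }
    if (prod$hfixed[j]) {
      ng$hcount[t] <- prod$hcount[j]; ng$hfixed[t] <- TRUE
    } else {
      ng$hcount[t] <- NA_integer_; ng$hfixed[t] <- FALSE
    }
  }
  # create new product atoms
  for (j in seq_along(pmap)) {
    if (!is.na(prodTarget[j])) next
    if (prod$elem[j] == "*") return(NULL)  # cannot instantiate a wildcard
    ng$elem <- c(ng$elem, prod$elem[j])
    ng$arom <- c(ng$arom, prod$arom[j])
    ng$charge <- c(ng$charge, prod$charge[j])
    ng$hcount <- c(ng$hcount, if (prod$hfixed[j]) prod$hcount[j] else NA_integer_)
    ng$hfixed <- c(ng$hfixed, prod$hfixed[j])
    ng$iso <- c(ng$iso, NA_integer_)
    np <- np + 1L
    prodTarget[j] <- np
  }
  # install product-template bonds
  if (nrow(prod$bond)) {
    for (b in seq_len(nrow(prod$bond))) {
      u <- prodTarget[prod$bond$a1[b]]
      v <- prodTarget[prod$bond$a2[b]]
      hit <- which(ng$bond$a1 == min(u, v) & ng$bond$a2 == max(u, v))
      if (length(hit)) ng$bond <- ng$bond[-hit, , drop = FALSE]
      ng$bond <- rbind(ng$bond, data.frame(
        a1 = min(u, v), a2 = max(u, v),
        order = prod$bond$order[b], arom = prod$bond$arom[b]))
    }
  }
  # delete matched atoms whose map class did not survive
  kept <- prodTarget[!is.na(prodTarget)]
  del <- setdiff(match, kept)
  ng <- .removeAtoms(ng, del)
  # recompute implicit hydrogens outside pinned atoms
  ng$hcount[!ng$hfixed] <- NA_integer_
  if (.nAtoms(ng) == 0L) return(NULL)
  # keep the largest component (heavy atoms, then MW, then atom order)
  comp <- .components(ng)
  if (max(comp) > 1L) {
    sizes <- tabulate(comp)
    best <- which(sizes == max(sizes))
    if (length(best) > 1L) {
      mw <- vapply(best, function(ci) {
        sum(.ATOMIC_WEIGHTS[ng$elem[comp == ci]], na.rm = TRUE)
      }, numeric(1))
      best <- best[order(-mw, best)][1]
    }
    ng <- .subgraph(ng, which(comp == best[1]))
  }
  ng
}

# Full single-rule application: one product per match site, sanitized,
# written as (stereo-agnostic) SMILES. Returns list(smiles=..., nMatches=,
# nDropped=). Deduplication and canonicalization happen in the caller.
.applyCompiledRule <- function(g, compiled, maxMatches = 10000L) {
  feat <- .molFeatures(g)
  matches <- .matchSmarts(feat, compiled$reactant, maxMatches = maxMatches)
  smiles <- character(0)
  dropped <- 0L
  for (m in matches) {
    pg <- .rewriteAtMatch(g, compiled, m)
    if (is.null(pg)) { dropped <- dropped + 1L; next }
    pg <- tryCatch(.sanitizeMol(pg), error = function(e) NULL)
    if (is.null(pg)) { dropped <- dropped + 1L; next }
    smiles <- c(smiles, .writeSmiles(pg))
  }
  list(smiles = smiles, nMatches = length(matches), nDropped = dropped)
}
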