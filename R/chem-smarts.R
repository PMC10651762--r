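# SMARTS subset: parser and subgraph matcher.
#
# Supported atom primitives: '*', 'A'/'a', element symbols (aliphatic
# uppercase / aromatic lowercase), '#n', 'D'/'X'/'x'/'H'/'h'/'R'/'r'/'v'
# with optional counts, charges, '@' (accepted, ignored: stereo-agnostic),
# recursive '$(...)', negation '!', conjunctions '&'/';'/implicit and
# disjunction ','. Bond primitives: default (single-or-aromatic), '-', '=',
# '#', ':', '~', '@', '/', '\' (as single), with '!', '&'/';', ','.
# Atom maps ':n' are recorded. This covers the transformation-rule
# compendium format and the packaged structural-alert catalogs.

.parseSmarts <- function(s) {
  s <- gsub("[[:space:]]+", "", s)
  if (!nzchar(s)) .chemError("empty SMARTS", "chem_parse_error")
  atoms <- list()          # each: list(alts=..., map=...)
  bonds <- data.frame(a1 = integer(0), a2 = integer(0), expr = I(list()))
  prev <- NA_integer_
  pending <- NULL
  stack <- integer(0)
  rings <- list()
  addAtom <- function(spec) {
    atoms[[length(atoms) + 1L]] <<- spec
    length(atoms)
  }
  addBond <- function(a, b, expr) {
    bonds <<- rbind(bonds, data.frame(a1 = a, a2 = b, expr = I(list(expr))))
  }
  connect <- function(idx) {
    if (!is.na(prev)) addBond(prev, idx, .compileBondExpr(pending))
    pending <<- NULL
    prev <<- idx
  }
  i <- 1L; nc <- nchar(s)
  bondChars <- c("-", "=", "#", ":", "~", "@", "!", "/", "\\")
  while (i <= nc) {
    ch <- substr(s, i, i)
    ch2 <- if (i < nc) substr(s, i, i + 1L) else ""
    if (ch == "(") { stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) .chemError("unbalanced ')' in SMARTS", "chem_parse_error")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch %in% bondChars) {
      # collect a bond expression run (may be multi-char, e.g. '!@', '-,=')
      j <- i
      while (j <= nc && substr(s, j, j) %in% c(bondChars, ",", ";", "&")) {
        j <- j + 1L
      }
      pending <- substr(s, i, j - 1L)
      i <- j
    } else if (grepl("^[0-9]$", ch) || ch == "%") {
      if (ch == "%") {
        id <- substr(s, i + 1L, i + 2L); i <- i + 3L
      } else { id <- ch; i <- i + 1L }
      if (!is.null(rings[[id]])) {
        open <- rings[[id]]
        expr <- open$expr
        if (is.null(expr)) expr <- .compileBondExpr(pending)
        addBond(open$atom, prev, expr)
        rings[[id]] <- NULL
      } else {
        rings[[id]] <- list(atom = prev,
                            expr = if (is.null(pending)) NULL else
                              .compileBondExpr(pending))
      }
      pending <- NULL
    } else if (ch == "[") {
      close <- .findBracketEnd(s, i)
      spec <- .parseSmartsAtom(substr(s, i + 1L, close - 1L))
      connect(addAtom(spec))
      i <- close + 1L
    } else if (ch == "*") {
      connect(addAtom(list(alts = list(list()), map = NA_integer_)))
      i <- i + 1L
    } else if (ch2 %in% c("Cl", "Br")) {
      connect(addAtom(list(alts = list(list(
        list(type = "elem", value = ch2, neg = FALSE),
        list(type = "arom", value = FALSE, neg = FALSE))),
        map = NA_integer_)))
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I", "A")) {
      con <- if (ch == "A") {
        list(list(type = "arom", value = FALSE, neg = FALSE))
      } else {
        list(list(type = "elem", value = ch, neg = FALSE),
             list(type = "arom", value = FALSE, neg = FALSE))
      }
      connect(addAtom(list(alts = list(con), map = NA_integer_)))
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s", "a")) {
      con <- if (ch == "a") {
        list(list(type = "arom", value = TRUE, neg = FALSE))
      } else {
        list(list(type = "elem", value = toupper(ch), neg = FALSE),
             list(type = "arom", value = TRUE, neg = FALSE))
      }
      connect(addAtom(list(alts = list(con), map = NA_integer_)))
      i <- i + 1L
    } else {
      .chemError(sprintf("unexpected character '%s' in SMARTS", ch),
                 "chem_parse_error")
    }
  }
  if (length(stack)) .chemError("unbalanced '(' in SMARTS", "chem_parse_error")
  if (length(rings)) .chemError("unclosed ring bond in SMARTS", "chem_parse_error")
  list(atoms = atoms, bonds = bonds)
}

# Parse one bracket atom expression into OR-of-AND constraint lists.
.parseSmartsAtom <- function(inner) {
  map <- NA_integer_
  m <- regmatches(inner, regexpr(":[0-9]+$", inner))
  if (length(m)) {
    map <- as.integer(substr(m, 2L, nchar(m)))
    inner <- sub(":[0-9]+$", "", inner)
  }
  alts <- lapply(.splitTopLevel(inner, ","), function(part) {
    cons <- list()
    i <- 1L; nc <- nchar(part)
    neg <- FALSE
    grab <- function(pattern) {
      mm <- regmatches(substr(part, i, nc),
                       regexpr(paste0("^", pattern), substr(part, i, nc)))
      if (length(mm)) { i <<- i + nchar(mm); mm } else NULL
    }
    push <- function(type, value) {
      cons[[length(cons) + 1L]] <<- list(type = type, value = value, neg = neg)
      neg <<- FALSE
    }
    while (i <= nc) {
      ch <- substr(part, i, i)
      if (ch %in% c("&", ";")) { i <- i + 1L; next }
      if (ch == "!") { neg <- TRUE; i <- i + 1L; next }
      if (ch == "$") {
        if (substr(part, i + 1L, i + 1L) != "(")
          .chemError("bad recursive SMARTS", "chem_parse_error")
        depth <- 0L; j <- i + 1L
        while (j <= nc) {
          cj <- substr(part, j, j)
          if (cj == "(") depth <- depth + 1L
          if (cj == ")") { depth <- depth - 1L; if (depth == 0L) break }
          j <- j + 1L
        }
        if (depth != 0L) .chemError("unbalanced recursive SMARTS",
                                    "chem_parse_error")
        push("rec", .parseSmarts(substr(part, i + 2L, j - 1L)))
        i <- j + 1L
        next
      }
      if (!is.null(v <- grab("#[0-9]+"))) {
        num <- as.integer(sub("#", "", v))
        hit <- names(.ELEMENT_NUMBERS)[match(num, .ELEMENT_NUMBERS)]
        if (is.na(hit)) .chemError(sprintf("unknown atomic number %d", num),
                                   "chem_parse_error")
        push("elem", hit)
      } else if (!is.null(v <- grab("se"))) {
        push("elem", "Se"); push("arom", TRUE)
      } else if (!is.null(v <- grab("Cl|Br|Si|Se|Na|Mg|Ca|Fe|Zn|As"))) {
        push("elem", v); push("arom", FALSE)
      } else if (!is.null(v <- grab("D[0-9]*"))) {
        push("D", if (nchar(v) == 1L) 1L else as.integer(substring(v, 2L)))
      } else if (!is.null(v <- grab("H[0-9]*"))) {
        push("H", if (nchar(v) == 1L) 1L else as.integer(substring(v, 2L)))
      } else if (!is.null(v <- grab("h[0-9]*"))) {
        push("H", if (nchar(v) == 1L) 1L else as.integer(substring(v, 2L)))
      } else if (!is.null(v <- grab("X[0-9]*"))) {
        push("X", if (nchar(v) == 1L) 1L else as.integer(substring(v, 2L)))
      } else if (!is.null(v <- grab("x[0-9]*"))) {
        push("x", if (nchar(v) == 1L) NA_integer_ else
          as.integer(substring(v, 2L)))
      } else if (!is.null(v <- grab("R[0-9]*"))) {
        push("R", if (nchar(v) == 1L) NA_integer_ else
          as.integer(substring(v, 2L)))
      } else if (!is.null(v <- grab("r[0-9]*"))) {
        push("r", if (nchar(v) == 1L) NA_integer_ else
          as.integer(substring(v, 2L)))
      } else if (!is.null(v <- grab("v[0-9]*"))) {
        push("v", if (nchar(v) == 1L) 1L else as.integer(substring(v, 2L)))
      } else if (!is.null(v <- grab("\\+[0-9]+"))) {
        push("charge", as.integer(substring(v, 2L)))
      } else if (!is.null(v <- grab("\\++"))) {
        push("charge", nchar(v))
      } else if (!is.null(v <- grab("-[0-9]+"))) {
        push("charge", -as.integer(substring(v, 2L)))
      } else if (!is.null(v <- grab("-+"))) {
        push("charge", -nchar(v))
      } else if (!is.null(grab("@@|@"))) {
        # chirality constraint ignored
      } else if (!is.null(grab("\\*"))) {
        # wildcard: no constraint
      } else if (!is.null(v <- grab("[A-Z]"))) {
        if (!(v %in% names(.ELEMENT_NUMBERS))) {
          if (v == "A") { push("arom", FALSE) } else
            .chemError(sprintf("unknown SMARTS token '%s'", v),
                       "chem_parse_error")
        } else {
          push("elem", v); push("arom", FALSE)
        }
      } else if (!is.null(v <- grab("[bcnops]"))) {
        push("elem", toupper(v)); push("arom", TRUE)
      } else if (!is.null(grab("a"))) {
        push("arom", TRUE)
      } else {
        .chemError(sprintf("cannot parse SMARTS atom '[%s]' near '%s'",
                           inner, substr(part, i, nc)), "chem_parse_error")
      }
    }
    cons
  })
  list(alts = alts, map = map)
}

# split on a separator at top level (outside parentheses/brackets)
.splitTopLevel <- function(s, sep) {
  depth <- 0L
  parts <- character(0)
  cur <- ""
  for (j in seq_len(nchar(s))) {
    ch <- substr(s, j, j)
    if (ch %in% c("(", "[")) depth <- depth + 1L
    if (ch %in% c(")", "]")) depth <- depth - 1L
    if (ch == sep && depth == 0L) { parts <- c(parts, cur); cur <- "" }
    else cur <- paste0(cur, ch)
  }
  c(parts, cur)
}

# Bond expression compiler: returns list of OR-alternatives, each a list of
# (prim, neg) conjuncts. NULL input = default single-or-aromatic.
.compileBondExpr <- function(sym) {
  if (is.null(sym)) return(list(list(list(prim = "default", neg = FALSE))))
  alts <- lapply(.splitTopLevel(sym, ","), function(part) {
    out <- list()
    neg <- FALSE
    for (j in seq_len(nchar(part))) {
      ch <- substr(part, j, j)
      if (ch %in% c("&", ";")) next
      if (ch == "!") { neg <- TRUE; next }
      prim <- switch(ch,
        "-" = "single", "/" = "single", "\\" = "single",
        "=" = "double", "#" = "triple", ":" = "aromatic",
        "~" = "any", "@" = "ring",
        .chemError(sprintf("unsupported bond primitive '%s'", ch),
                   "chem_parse_error"))
      out[[length(out) + 1L]] <- list(prim = prim, neg = neg)
      neg <- FALSE
    }
    if (!length(out)) list(list(prim = "default", neg = FALSE)) else out
  })
  alts
}

# ---- matching ---------------------------------------------------------------

# Precompute per-molecule features used by constraints.
.molFeatures <- function(g) {
  ringb <- .ringBonds(g)
  sssr <- .sssr(g, ringb)
  n <- .nAtoms(g)
  ringSizes <- vector("list", n)
  ringCount <- integer(n)
  for (cyc in sssr) {
    for (a in cyc) {
      ringSizes[[a]] <- c(ringSizes[[a]], length(cyc))
      ringCount[a] <- ringCount[a] + 1L
    }
  }
  deg <- .degree(g)
  list(
    g = g, ringb = ringb, sssr = sssr,
    deg = deg,
    x = .ringBondCount(g, ringb),
    inRing = ringCount > 0L,
    ringCount = ringCount,
    ringSizes = ringSizes,
    valence = .bondOrderSum(g) + g$hcount,
    adj = .bondIndex(g)
  )
}

.atomMatches <- function(feat, ai, spec) {
  for (alt in spec$alts) {
    ok <- TRUE
    for (con in alt) {
      val <- switch(con$type,
        elem = feat$g$elem[ai] == con$value,
        arom = feat$g$arom[ai] == con$value,
        D = feat$deg[ai] == con$value,
        H = feat$g$hcount[ai] == con$value,
        X = (feat$deg[ai] + feat$g$hcount[ai]) == con$value,
        x = if (is.na(con$value)) feat$x[ai] > 0L else
          feat$x[ai] == con$value,
        R = if (is.na(con$value)) feat$inRing[ai] else
          if (con$value == 0L) !feat$inRing[ai] else
            feat$ringCount[ai] >= con$value,
        r = if (is.na(con$value)) feat$inRing[ai] else
          con$value %in% feat$ringSizes[[ai]],
        v = feat$valence[ai] == con$value,
        charge = feat$g$charge[ai] == con$value,
        rec = length(.matchSmarts(feat, con$value, anchor = ai,
                                  maxMatches = 1L)) > 0L,
        .chemError(sprintf("unknown constraint '%s'", con$type),
                   "chem_parse_error"))
      if (con$neg) val <- !val
      if (!val) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

.bondMatches <- function(feat, bi, expr) {
  ord <- feat$g$bond$order[bi]
  arom <- isTRUE(feat$g$bond$arom[bi])
  inRing <- feat$ringb[bi]
  for (alt in expr) {
    ok <- TRUE
    for (con in alt) {
      val <- switch(con$prim,
        default = arom || (ord == 1L && !arom),
        single = ord == 1L && !arom,
        double = ord == 2L && !arom,
        triple = ord == 3L && !arom,
        aromatic = arom,
        any = TRUE,
        ring = inRing)
      if (con$neg) val <- !val
      if (!val) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

# Backtracking subgraph matcher. Returns list of integer vectors mapping
# pattern atom index -> molecule atom index. anchor (optional) pins pattern
# atom 1 to a specific molecule atom (recursive SMARTS semantics).
.matchSmarts <- function(feat, pattern, anchor = NULL, maxMatches = 10000L) {
  np <- length(pattern$atoms)
  if (np == 0L) return(list())
  n <- .nAtoms(feat$g)
  # order pattern atoms so each (after the first) touches an earlier one
  order <- 1L
  placed <- c(TRUE, rep(FALSE, np - 1L))
  edges <- pattern$bonds
  repeat {
    nxt <- NA_integer_
    if (nrow(edges)) {
      for (b in seq_len(nrow(edges))) {
        a1 <- edges$a1[b]; a2 <- edges$a2[b]
        if (placed[a1] && !placed[a2]) { nxt <- a2; break }
        if (placed[a2] && !placed[a1]) { nxt <- a1; break }
      }
    }
    if (is.na(nxt)) {
      rest <- which(!placed)
      if (!length(rest)) break
      nxt <- rest[1]   # disconnected pattern component
    }
    placed[nxt] <- TRUE
    order <- c(order, nxt)
  }
  # bonds to check when placing the k-th pattern atom
  checkBonds <- vector("list", np)
  for (k in seq_along(order)) {
    pa <- order[k]
    before <- order[seq_len(k - 1L)]
    if (nrow(edges)) {
      hits <- which((edges$a1 == pa & edges$a2 %in% before) |
                    (edges$a2 == pa & edges$a1 %in% before))
      checkBonds[[k]] <- hits
    } else checkBonds[[k]] <- integer(0)
  }
  # mol bond lookup
  bondAt <- function(u, v) {
    lo <- min(u, v); hi <- max(u, v)
    which(feat$g$bond$a1 == lo & feat$g$bond$a2 == hi)[1]
  }
  results <- list()
  assign <- rep(NA_integer_, np)
  used <- logical(n)
  recurse <- function(k) {
    if (length(results) >= maxMatches) return()
    if (k > np) {
      results[[length(results) + 1L]] <<- assign
      return()
    }
    pa <- order[k]
    cands <- if (k == 1L && !is.null(anchor)) anchor else seq_len(n)
    for (ai in cands) {
      if (used[ai]) next
      if (!.atomMatches(feat, ai, pattern$atoms[[pa]])) next
      ok <- TRUE
      for (pb in checkBonds[[k]]) {
        other <- if (edges$a1[pb] == pa) edges$a2[pb] else edges$a1[pb]
        mb <- bondAt(ai, assign[other])
        if (is.na(mb) || !.bondMatches(feat, mb, edges$expr[[pb]])) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      assign[pa] <<- ai; used[ai] <<- TRUE
      recurse(k + 1L)
      assign[pa] <<- NA_integer_; used[ai] <<- FALSE
      if (length(results) >= maxMatches) return()
    }
  }
  recurse(1L)
  results
}

# Convenience: does the molecule contain the pattern?
.hasSubstructure <- function(g, pattern, feat = NULL) {
  if (is.null(feat)) feat <- .molFeatures(g)
  length(.matchSmarts(feat, pattern, maxMatches = 1L)) > 0L
}
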