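# SMILES reading and writing for the internal graph model.
#
# The parser covers the organic subset, bracket atoms (isotope, aromatic
# symbols, H counts, charges, atom maps), branches, ring closures (incl.
# %nn and bonds preceding closure digits), components ('.') and directional
# or chiral decorations, which are accepted and discarded: the package works
# with stereo-agnostic structures throughout. In "template" mode (SMIRKS
# product side) bracket atoms may additionally carry SMARTS decorations
# (D/X/x/R/A/a/@, '&'/';') which constrain matching but are ignored when
# instantiating products.

.parseSmiles <- function(s, mode = c("smiles", "template")) {
  mode <- match.arg(mode)
  s <- gsub("[[:space:]]+", "", s)
  if (!nzchar(s)) .chemError("empty SMILES", "chem_parse_error")
  g <- .newMolgraph()
  map <- integer(0)
  prev <- NA_integer_
  pending <- NULL           # pending bond symbol
  stack <- integer(0)
  rings <- list()           # open ring closures: id -> list(atom, sym)
  addAtom <- function(elem, arom, charge = 0L, h = NA_integer_,
                      hfix = FALSE, iso = NA_integer_, m = NA_integer_) {
    g$elem <<- c(g$elem, elem); g$arom <<- c(g$arom, arom)
    g$charge <<- c(g$charge, as.integer(charge))
    g$hcount <<- c(g$hcount, as.integer(h))
    g$hfixed <<- c(g$hfixed, hfix)
    g$iso <<- c(g$iso, as.integer(iso))
    map <<- c(map, as.integer(m))
    length(g$elem)
  }
  addBond <- function(a, b, sym) {
    if (a == b) .chemError("self-bond in SMILES", "chem_parse_error")
    spec <- .bondFromSymbol(sym, g$arom[a], g$arom[b])
    g$bond <<- rbind(g$bond, data.frame(
      a1 = min(a, b), a2 = max(a, b), order = spec$order, arom = spec$arom))
  }
  connect <- function(idx) {
    if (!is.na(prev)) addBond(prev, idx, pending)
    pending <<- NULL
    prev <<- idx
  }
  i <- 1L
  nc <- nchar(s)
  while (i <= nc) {
    ch <- substr(s, i, i)
    ch2 <- if (i < nc) substr(s, i, i + 1L) else ""
    if (ch == "(") {
      if (is.na(prev)) .chemError("branch before any atom", "chem_parse_error")
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) .chemError("unbalanced ')'", "chem_parse_error")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\", "~")) {
      if (ch == "~") .chemError("'~' is not a SMILES bond", "chem_parse_error")
      pending <- if (ch %in% c("/", "\\")) "-" else ch
      i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_; pending <- NULL; i <- i + 1L
    } else if (grepl("^[0-9]$", ch) || ch == "%") {
      if (ch == "%") {
        id <- substr(s, i + 1L, i + 2L)
        if (!grepl("^[0-9]{2}$", id))
          .chemError("bad %nn ring closure", "chem_parse_error")
        i <- i + 3L
      } else { id <- ch; i <- i + 1L }
      if (is.na(prev)) .chemError("ring closure before atom", "chem_parse_error")
      if (!is.null(rings[[id]])) {
        open <- rings[[id]]
        sym <- open$sym
        if (is.null(sym)) sym <- pending
        if (!is.null(open$sym) && !is.null(pending) &&
            !identical(open$sym, pending))
          .chemError("conflicting ring-closure bond symbols", "chem_parse_error")
        addBond(open$atom, prev, sym)
        rings[[id]] <- NULL
      } else {
        rings[[id]] <- list(atom = prev, sym = pending)
      }
      pending <- NULL
    } else if (ch == "[") {
      close <- .findBracketEnd(s, i)
      inner <- substr(s, i + 1L, close - 1L)
      at <- .parseBracketAtom(inner, mode)
      idx <- addAtom(at$elem, at$arom, at$charge, at$h, at$hfix, at$iso, at$map)
      connect(idx)
      i <- close + 1L
    } else if (ch == "*") {
      idx <- addAtom("*", FALSE)
      connect(idx); i <- i + 1L
    } else if (ch2 %in% c("Cl", "Br")) {
      idx <- addAtom(ch2, FALSE)
      connect(idx); i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      idx <- addAtom(ch, FALSE)
      connect(idx); i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      idx <- addAtom(toupper(ch), TRUE)
      connect(idx); i <- i + 1L
    } else {
      .chemError(sprintf("unexpected character '%s' in SMILES", ch),
                 "chem_parse_error")
    }
  }
  if (length(stack)) .chemError("unbalanced '('", "chem_parse_error")
  if (length(rings)) .chemError("unclosed ring bond", "chem_parse_error")
  g$map <- map
  g
}

.findBracketEnd <- function(s, i) {
  depth <- 0L
  for (j in i:nchar(s)) {
    ch <- substr(s, j, j)
    if (ch == "[") depth <- depth + 1L
    if (ch == "]") {
      depth <- depth - 1L
      if (depth == 0L) return(j)
    }
  }
  .chemError("unterminated '['", "chem_parse_error")
}

.bondFromSymbol <- function(sym, arom1, arom2) {
  if (is.null(sym)) {
    # default bond: aromatic iff both atoms aromatic AND the bond turns out
    # to lie in a ring (resolved during sanitization; NA marks "maybe")
    if (arom1 && arom2) return(list(order = 1L, arom = NA))
    return(list(order = 1L, arom = FALSE))
  }
  switch(sym,
    "-" = list(order = 1L, arom = FALSE),
    "=" = list(order = 2L, arom = FALSE),
    "#" = list(order = 3L, arom = FALSE),
    ":" = list(order = 1L, arom = TRUE),
    .chemError(sprintf("unsupported bond '%s'", sym), "chem_parse_error"))
}

.parseBracketAtom <- function(inner, mode) {
  out <- list(elem = NA_character_, arom = FALSE, charge = 0L,
              h = NA_integer_, hfix = FALSE, iso = NA_integer_,
              map = NA_integer_)
  i <- 1L; nc <- nchar(inner)
  grab <- function(pattern) {
    m <- regmatches(substr(inner, i, nc),
                    regexpr(paste0("^", pattern), substr(inner, i, nc)))
    if (length(m)) { i <<- i + nchar(m); m } else NULL
  }
  if (!is.null(iso <- grab("[0-9]+")) ) out$iso <- as.integer(iso)
  # element: #n, two-letter, aromatic lowercase, one-letter, or wildcard
  if (!is.null(v <- grab("#[0-9]+"))) {
    num <- as.integer(sub("#", "", v))
    hit <- names(.ELEMENT_NUMBERS)[match(num, .ELEMENT_NUMBERS)]
    if (is.na(hit)) .chemError(sprintf("unknown atomic number %d", num),
                               "chem_parse_error")
    out$elem <- hit
  } else if (!is.null(v <- grab("se"))) {
    out$elem <- "Se"; out$arom <- TRUE
  } else if (!is.null(v <- grab("[A-Z][a-z]?")) &&
             v %in% names(.ELEMENT_NUMBERS)) {
    out$elem <- v
  } else if (!is.null(v) ) {
    # single uppercase letter element like N followed by lowercase token:
    # retry with one letter
    i <- i - nchar(v)
    v1 <- grab("[A-Z]")
    if (is.null(v1) || !(v1 %in% names(.ELEMENT_NUMBERS)))
      .chemError(sprintf("unknown element '%s'", v), "chem_parse_error")
    out$elem <- v1
  } else if (!is.null(v <- grab("[bcnops]"))) {
    out$elem <- toupper(v); out$arom <- TRUE
  } else if (!is.null(grab("\\*"))) {
    out$elem <- "*"
  } else {
    .chemError(sprintf("cannot parse bracket atom '[%s]'", inner),
               "chem_parse_error")
  }
  while (i <= nc) {
    if (!is.null(v <- grab("H[0-9]*"))) {
      out$h <- if (nchar(v) == 1L) 1L else as.integer(substr(v, 2L, nchar(v)))
      out$hfix <- TRUE
    } else if (!is.null(v <- grab("\\+[0-9]+"))) {
      out$charge <- as.integer(substr(v, 2L, nchar(v)))
    } else if (!is.null(v <- grab("\\++"))) {
      out$charge <- nchar(v)
    } else if (!is.null(v <- grab("-[0-9]+"))) {
      out$charge <- -as.integer(substr(v, 2L, nchar(v)))
    } else if (!is.null(v <- grab("-+"))) {
      out$charge <- -nchar(v)
    } else if (!is.null(v <- grab(":[0-9]+"))) {
      out$map <- as.integer(substr(v, 2L, nchar(v)))
    } else if (!is.null(grab("@@|@"))) {
      # chirality parsed and discarded (stereo-agnostic model)
    } else if (mode == "template" && !is.null(grab("a"))) {
      out$arom <- TRUE
    } else if (mode == "template" && !is.null(grab("A"))) {
      out$arom <- FALSE
    } else if (mode == "template" &&
               !is.null(grab("[DXxRrvh][0-9]*|[;&!]"))) {
      # SMARTS matching decorations carry no meaning when instantiating
      # product atoms and are tolerated silently
    } else {
      .chemError(sprintf("cannot parse bracket atom '[%s]'", inner),
                 "chem_parse_error")
    }
  }
  out
}

# ---- writing ----------------------------------------------------------------

.writeSmiles <- function(g) {
  n <- .nAtoms(g)
  if (n == 0L) return("")
  adj <- .bondIndex(g)
  comp <- .components(g)
  visited <- logical(n)
  ringNum <- 0L
  ringLabel <- list()     # bond index -> label
  treeBond <- logical(nrow(g$bond))
  # first pass: DFS to classify tree vs ring-closure bonds
  order <- integer(0)
  parentBond <- rep(NA_integer_, n)
  for (root in order(comp)[!duplicated(sort(comp))]) NULL
  emit <- character(0)
  closures <- vector("list", n)   # per atom: list of (label, bondidx)
  for (root in seq_len(n)) {
    if (visited[root]) next
    stack <- list(root)
    visited[root] <- TRUE
    while (length(stack)) {
      a <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (b in adj[[a]]) {
        w <- if (g$bond$a1[b] == a) g$bond$a2[b] else g$bond$a1[b]
        if (!visited[w] && !treeBond[b]) {
          if (is.na(parentBond[w])) { parentBond[w] <- b; treeBond[b] <- TRUE
            visited[w] <- TRUE; stack[[length(stack) + 1L]] <- w }
        }
      }
    }
  }
  # ring-closure bonds get labels at both end atoms
  for (b in seq_len(nrow(g$bond))) {
    if (treeBond[b]) next
    ringNum <- ringNum + 1L
    lbl <- if (ringNum < 10L) as.character(ringNum) else
      sprintf("%%%02d", ringNum)
    for (a in c(g$bond$a1[b], g$bond$a2[b])) {
      closures[[a]] <- c(closures[[a]], list(list(label = lbl, bond = b)))
    }
  }
  visited <- logical(n)
  bondSym <- function(b, first) {
    if (isTRUE(g$bond$arom[b])) return("")
    if (g$bond$order[b] == 2L) return("=")
    if (g$bond$order[b] == 3L) return("#")
    # explicit single between two aromatic atoms (e.g. biphenyl)
    if (g$arom[g$bond$a1[b]] && g$arom[g$bond$a2[b]]) return("-")
    ""
  }
  atomToken <- function(i) {
    elem <- g$elem[i]
    if (elem == "*") return("*")
    sym <- if (g$arom[i]) tolower(elem) else elem
    needBracket <- g$charge[i] != 0L || !is.na(g$iso[i]) ||
      !(elem %in% .ORGANIC_SUBSET)
    if (!needBracket) {
      defH <- .defaultHCount(g, i)
      if (!identical(defH, g$hcount[i])) needBracket <- TRUE
    }
    if (!needBracket) return(sym)
    h <- g$hcount[i]
    hTok <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
    c0 <- g$charge[i]
    cTok <- if (c0 == 0L) "" else if (c0 > 0L) {
      if (c0 == 1L) "+" else paste0("+", c0)
    } else {
      if (c0 == -1L) "-" else as.character(c0)
    }
    iTok <- if (is.na(g$iso[i])) "" else as.character(g$iso[i])
    paste0("[", iTok, sym, hTok, cTok, "]")
  }
  writeAtom <- function(i, inBond) {
    visited[i] <<- TRUE
    tok <- atomToken(i)
    for (cl in closures[[i]]) {
      b <- cl$bond
      sym <- bondSym(b, FALSE)
      tok <- paste0(tok, sym, cl$label)
      closures[[i]] <- NULL
    }
    kids <- list()
    for (b in adj[[i]]) {
      if (!treeBond[b]) next
      w <- if (g$bond$a1[b] == i) g$bond$a2[b] else g$bond$a1[b]
      if (visited[w] || parentBond[w] != b) next
      kids[[length(kids) + 1L]] <- list(w = w, b = b)
    }
    sub <- character(0)
    if (length(kids)) {
      for (k in seq_along(kids)) {
        child <- paste0(bondSym(kids[[k]]$b, TRUE),
                        writeAtom(kids[[k]]$w, TRUE))
        sub <- c(sub, if (k < length(kids)) paste0("(", child, ")") else child)
      }
    }
    paste0(tok, paste(sub, collapse = ""))
  }
  parts <- character(0)
  for (root in seq_len(n)) {
    if (visited[root]) next
    parts <- c(parts, writeAtom(root, FALSE))
  }
  paste(parts, collapse = ".")
}

# H count the parser would infer for a bare organic-subset atom written in
# this bonding environment; used to decide whether brackets are required.
.defaultHCount <- function(g, i) {
  if (g$arom[i]) {
    deg <- sum(g$bond$a1 == i | g$bond$a2 == i)
    return(if (g$elem[i] == "C" && deg == 2L) 1L else 0L)
  }
  bos <- sum(g$bond$order[g$bond$a1 == i | g$bond$a2 == i])
  allowed <- .allowedValences(g$elem[i], 0L)
  fit <- allowed[allowed >= bos]
  if (!length(fit)) return(NA_integer_)
  as.integer(fit[1] - bos)
}
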