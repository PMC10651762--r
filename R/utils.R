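# package-level cache for lazily compiled patterns and tables
.pkgCache <- new.env(parent = emptyenv())

.cached <- function(key, maker) {
  if (!exists(key, envir = .pkgCache, inherits = FALSE)) {
    assign(key, maker(), envir = .pkgCache)
  }
  get(key, envir = .pkgCache, inherits = FALSE)
}

# deterministic polynomial hash of an integer vector onto [0, 2^31-2]
.hashInts <- function(xs) {
  h <- 17
  for (x in xs) {
    h <- (h * 31 + (x %% 2147483647)) %% 2147483647
  }
  h
}

# resolve a MoleculeSet or character vector of SMILES into a MoleculeSet
.asMoleculeSet <- function(mols) {
  if (is(mols, "MoleculeSet")) return(mols)
  if (is.character(mols)) return(curateLibrary(mols)$set)
  stop("expected a MoleculeSet or a character vector of SMILES")
}

.extdata <- function(...) {
  system.file("extdata", ..., package = "ChemLibDesign", mustWork = TRUE)
}
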