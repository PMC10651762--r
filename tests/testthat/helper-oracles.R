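# shared helpers: canonicalization shortcut and frozen oracle tables

obcan <- function(s) ChemLibDesign:::.obCanonical(s)

loadOracle <- function(name) {
  utils::read.csv(test_path("fixtures", name), stringsAsFactors = FALSE)
}

# expected product set of the independent rewrite oracle, expressed in the
# package's own canonical key space
oracleProducts <- function(row) {
  prods <- strsplit(row$expected_products, "|", fixed = TRUE)[[1]]
  prods <- prods[nzchar(prods)]
  if (!length(prods)) return(character(0))
  sort(unique(obcan(prods)))
}

# gates-off enumeration settings used across enumeration tests
openConfig <- function(nIterations = 1L) {
  enumerationConfig(nIterations = nIterations, mwMax = Inf,
                    tpsaMin = -Inf, tpsaMax = Inf)
}
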