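#' @include AllClasses.R
NULL

#' Physicochemical property profile
#'
#' Computes, for every molecule, the seven descriptors used throughout the
#' library-design workflow: molecular weight (MW, Da), octanol-water
#' partition coefficient (logP, Wildman-Crippen atomic contributions),
#' Lipinski hydrogen-bond acceptor and donor counts (HBA, HBD), topological
#' polar surface area (TPSA, Ertl fragment contributions, \eqn{\mathrm{\AA}^2}),
#' amide-excluded rotatable bonds (RotB) and the number of potential
#' stereocenters (nChiral, assigned plus unassigned). logP and TPSA come
#' from OpenBabel's implementations of the published contribution schemes;
#' the count descriptors are computed on the internal graph.
#'
#' @param mols a \linkS4class{MoleculeSet} or character vector of SMILES.
#' @return a \code{DataFrame} with columns \code{canonicalKey}, \code{MW},
#'   \code{logP}, \code{HBA}, \code{HBD}, \code{TPSA}, \code{RotB},
#'   \code{nChiral} (plus \code{AROM}, the aromatic ring count, used by the
#'   drug-likeness scoring).
#' @examples
#' \donttest{
#' computeProfile(c("c1ccccc1", "CC(N)C(=O)O"))
#' }
#' @export
computeProfile <- function(mols) {
  set <- .asMoleculeSet(mols)
  keys <- canonicalKeys(set)
  ob <- .obProperties(keys)
  n <- length(set)
  HBA <- integer(n); HBD <- integer(n); RotB <- integer(n)
  nChiral <- integer(n); AROM <- integer(n); MWn <- numeric(n)
  for (i in seq_len(n)) {
    g <- set@graphs[[i]]
    HBA[i] <- .countHBA(g)
    HBD[i] <- .countHBD(g)
    RotB[i] <- .countRotB(g)
    nChiral[i] <- .countChiral(g)
    AROM[i] <- .countAromaticRings(g)
    MWn[i] <- .molWeight(g)
  }
  MW <- ifelse(is.na(ob$MW), MWn, ob$MW)
  DataFrame(canonicalKey = keys, MW = MW, logP = ob$logP,
            HBA = HBA, HBD = HBD, TPSA = ob$TPSA,
            RotB = RotB, nChiral = nChiral, AROM = AROM)
}

# -- QED ----------------------------------------------------------------------

# Published asymmetric-double-sigmoid desirability parameters
# (a, b, c, d, e, f, dmax) for the eight QED property channels.
.QED_ADS <- list(
  MW     = c(2.817065973, 392.5754953, 290.7489764, 2.419764353,
             49.22325677, 65.37051707, 104.9805561),
  ALOGP  = c(3.172690585, 137.8624751, 2.534937431, 4.581497897,
             0.822739154, 0.576295591, 131.3186604),
  HBA    = c(2.948620388, 160.4605972, 3.615294657, 4.435986202,
             0.290141953, 1.300669958, 148.7763046),
  HBD    = c(1.618662227, 1010.051101, 0.985094388, 0.000000001,
             0.713820843, 0.920922555, 258.1632616),
  PSA    = c(1.876861559, 125.2232657, 62.90773554, 87.83366614,
             12.01999824, 28.51324732, 104.5686167),
  ROTB   = c(0.010000000, 272.4121427, 2.558379970, 1.565547684,
             1.271567166, 2.758063707, 105.4420403),
  AROM   = c(3.217788970, 957.7374108, 2.274627939, 0.000000001,
             1.317690384, 0.375760881, 312.3372610),
  ALERTS = c(0.010000000, 1199.094025, -0.09002883, 0.000000001,
             0.185904477, 0.875193782, 417.7253140)
)

# Published channel weights (the "mean-weight" scheme underlying the
# 0.67 attractive / 0.49 unattractive reference cut-points).
.QED_WEIGHTS <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
                  PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

# asymmetric double sigmoid desirability in (0, 1]
.qedADS <- function(x, p) {
  a <- p[1]; b <- p[2]; c <- p[3]; d <- p[4]; e <- p[5]; f <- p[6]; dmax <- p[7]
  val <- a + b / (1 + exp(-(x - c + d / 2) / e)) *
    (1 - 1 / (1 + exp(-(x - c - d / 2) / f)))
  pmax(val / dmax, 1e-9)
}

#' QED drug-likeness from a property table
#'
#' The quantitative estimate of drug-likeness: the weighted geometric mean
#' of eight desirability values, each an asymmetric double sigmoid of one
#' property channel (MW, ALOGP, HBA, HBD, PSA, ROTB, AROM, ALERTS), using
#' the published parameterization and channel weights.
#'
#' @param props data.frame-like with columns \code{MW}, \code{ALOGP} (or
#'   \code{logP}), \code{HBA}, \code{HBD}, \code{PSA} (or \code{TPSA}),
#'   \code{ROTB} (or \code{RotB}), \code{AROM}, \code{ALERTS}.
#' @param weights named channel weights; defaults to the published
#'   mean-weight scheme.
#' @return numeric vector of QED values in (0, 1].
#' @export
qedFromProperties <- function(props, weights = .QED_WEIGHTS) {
  props <- as.data.frame(props)
  alias <- c(ALOGP = "logP", PSA = "TPSA", ROTB = "RotB")
  for (nm in names(alias)) {
    if (!nm %in% colnames(props) && alias[[nm]] %in% colnames(props)) {
      props[[nm]] <- props[[alias[[nm]]]]
    }
  }
  need <- names(.QED_ADS)
  missing <- setdiff(need, colnames(props))
  if (length(missing)) stop("missing QED channels: ",
                            paste(missing, collapse = ", "))
  weights <- weights[need]
  if (!nrow(props)) return(numeric(0))
  d <- vapply(need, function(ch) .qedADS(props[[ch]], .QED_ADS[[ch]]),
              numeric(nrow(props)))
  d <- matrix(d, nrow = nrow(props))
  as.vector(exp((log(d) %*% weights) / sum(weights)))
}

#' QED drug-likeness of molecules
#'
#' Computes the eight property channels (descriptors via
#' \code{\link{computeProfile}}; ALERTS as the hit count against a
#' structural-alert catalog) and applies
#' \code{\link{qedFromProperties}}. Values of 0.67 and 0.49 are the
#' published reference cut-points for attractive and unattractive
#' compounds.
#'
#' @param mols a \linkS4class{MoleculeSet} or character vector of SMILES.
#' @param weights channel weights (see \code{\link{qedFromProperties}}).
#' @param alertCatalog catalog name(s) used for the ALERTS channel.
#' @param profile optional precomputed \code{\link{computeProfile}} result.
#' @return numeric vector of QED values in (0, 1].
#' @export
qedScore <- function(mols, weights = .QED_WEIGHTS,
                     alertCatalog = "unwanted", profile = NULL) {
  set <- .asMoleculeSet(mols)
  if (is.null(profile)) profile <- computeProfile(set)
  hits <- structuralAlerts(set, catalogs = alertCatalog)
  nAlerts <- integer(length(set))
  if (nrow(hits)) {
    tab <- table(factor(hits$index, levels = seq_len(length(set))))
    nAlerts <- as.integer(tab)
  }
  props <- data.frame(MW = profile$MW, ALOGP = profile$logP,
                      HBA = profile$HBA, HBD = profile$HBD,
                      PSA = profile$TPSA, ROTB = profile$RotB,
                      AROM = profile$AROM, ALERTS = nAlerts)
  qedFromProperties(props, weights = weights)
}
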