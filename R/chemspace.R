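#' @include AllClasses.R
NULL

#' Standardized six-property descriptor matrix
#'
#' Builds the property-space matrix used by the PCA and t-SNE views of the
#' chemical multiverse: columns HBD, HBA, logP, MW, RotB, TPSA,
#' standardized to zero mean and unit variance over the pooled libraries
#' (columns with zero variance are left centred at 0).
#'
#' @param ... named \linkS4class{MoleculeSet}s (or character SMILES
#'   vectors), one per library; names become the row labels.
#' @return list with \code{x} (standardized matrix), \code{labels}
#'   (factor of library names) and \code{keys} (canonical keys).
#' @export
descriptorMatrix <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !is(sets[[1]], "MoleculeSet"))
    sets <- sets[[1]]
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- paste0("lib", seq_along(sets))
  cols <- c("HBD", "HBA", "logP", "MW", "RotB", "TPSA")
  mats <- list(); labels <- character(0); keys <- character(0)
  for (nm in names(sets)) {
    set <- .asMoleculeSet(sets[[nm]])
    prof <- as.data.frame(computeProfile(set))
    mats[[nm]] <- as.matrix(prof[, cols, drop = FALSE])
    labels <- c(labels, rep(nm, nrow(prof)))
    keys <- c(keys, prof$canonicalKey)
  }
  x <- do.call(rbind, mats)
  if (anyNA(x)) stop("descriptor matrix contains missing values")
  ctr <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  sds[sds == 0 | is.na(sds)] <- 1
  x <- sweep(sweep(x, 2, ctr), 2, sds, "/")
  list(x = x, labels = factor(labels, levels = names(sets)), keys = keys)
}

#' PCA embedding of the property space
#'
#' Top two principal components of the standardized descriptor matrix,
#' with a fixed sign convention (the largest-magnitude loading of each
#' component is positive) so embeddings are reproducible across runs and
#' row orders.
#'
#' @param dm a \code{\link{descriptorMatrix}} result (or a plain numeric
#'   matrix, already standardized).
#' @return list of class \code{Embedding2D}: \code{coords} (n x 2),
#'   \code{explainedVariance} (fractions for PC1, PC2), \code{method},
#'   \code{labels}.
#' @export
pcaEmbed <- function(dm) {
  x <- if (is.list(dm)) dm$x else dm
  if (nrow(x) < 3L) stop("PCA embedding needs at least 3 rows")
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  k <- min(2L, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  coords <- x %*% rot
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(coords = coords[, 1:2, drop = FALSE],
                 explainedVariance = ev[seq_len(k)],
                 method = "pca",
                 labels = if (is.list(dm)) dm$labels else NULL),
            class = "Embedding2D")
}

#' t-SNE embedding of the property space
#'
#' Exact (quadratic-cost) t-distributed stochastic neighbour embedding
#' with per-point precision calibrated to the requested perplexity, early
#' exaggeration and momentum gradient descent. Deterministic under
#' \code{seed}; intended for the library sizes of diversity analyses
#' (hundreds to a few thousand compounds).
#'
#' @param dm a \code{\link{descriptorMatrix}} result or numeric matrix.
#' @param perplexity effective neighbourhood size; must be < number of
#'   rows (default 30).
#' @param seed integer seed for the random initialization.
#' @param nIter gradient-descent iterations (default 400).
#' @return an \code{Embedding2D} list (\code{coords}, \code{method},
#'   \code{perplexity}, \code{seed}, \code{labels}).
#' @export
tsneEmbed <- function(dm, perplexity = 30, seed = 7L, nIter = 400L) {
  x <- if (is.list(dm)) dm$x else dm
  n <- nrow(x)
  if (perplexity >= n) stop("perplexity must be smaller than the number of rows")
  if (perplexity < 2) stop("perplexity must be at least 2")
  P <- .tsneAffinities(x, perplexity)
  oldSeed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv())
  })
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), ncol = 2)
  dY <- matrix(0, n, 2); gains <- matrix(1, n, 2)
  eta <- 100; momentum <- 0.5
  Pex <- P * 4   # early exaggeration
  for (iter in seq_len(nIter)) {
    Pit <- if (iter <= 100L) Pex else P
    if (iter == 251L) momentum <- 0.8
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- num / sum(num)
    Q[Q < 1e-12] <- 1e-12
    L <- (Pit - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  structure(list(coords = Y, method = "tsne", perplexity = perplexity,
                 seed = seed,
                 labels = if (is.list(dm)) dm$labels else NULL),
            class = "Embedding2D")
}

# symmetric affinities with per-point precision found by bisection
.tsneAffinities <- function(x, perplexity) {
  n <- nrow(x)
  D2 <- as.matrix(stats::dist(x))^2
  targetH <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; betaMin <- -Inf; betaMax <- Inf
    Di <- D2[i, -i]
    for (tries in seq_len(50)) {
      p <- exp(-Di * beta)
      s <- sum(p)
      if (s == 0) { H <- 0; p[] <- 1 / length(p) } else {
        p <- p / s
        H <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(H - targetH) < 1e-5) break
      if (H > targetH) { betaMin <- beta
        beta <- if (is.finite(betaMax)) (beta + betaMax) / 2 else beta * 2
      } else { betaMax <- beta
        beta <- if (is.finite(betaMin)) (beta + betaMin) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P[P < 1e-12] <- 1e-12
  P
}

#' Tree embedding of fingerprint space (kNN + minimum spanning tree)
#'
#' Builds the k-nearest-neighbour graph under Tanimoto distance on ECFP4
#' fingerprints, connects components by their cheapest bridging edges when
#' needed, extracts the minimum spanning tree and lays the tree out in 2-D
#' (seeded force-directed layout). This reproduces the analytical role of
#' published tree-map embeddings — a spanning tree over fingerprint
#' similarity space — with an exactly testable MST; an alternative tree
#' construction can be swapped in via \code{treeBuilder}.
#'
#' @param fps list of fingerprints (from \code{\link{morganFingerprint}})
#'   or a \linkS4class{MoleculeSet}/character SMILES vector.
#' @param kNeighbors neighbours per node (default 10).
#' @param seed layout seed.
#' @param treeBuilder optional function \code{(distanceMatrix) -> igraph}
#'   returning a spanning tree, replacing the kNN+MST construction.
#' @return an \code{Embedding2D} list with \code{coords}, \code{edges}
#'   (data.frame from, to, weight), \code{method = "tree"}.
#' @export
treeEmbed <- function(fps, kNeighbors = 10L, seed = 7L, treeBuilder = NULL) {
  if (!is.list(fps) || is(fps, "MoleculeSet")) {
    fps <- morganFingerprint(fps)
  }
  n <- length(fps)
  if (n < 2L) stop("tree embedding needs at least 2 compounds")
  D <- tanimotoDistanceMatrix(fps)
  if (!is.null(treeBuilder)) {
    tree <- treeBuilder(D)
  } else {
    k <- min(kNeighbors, n - 1L)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      nbrs <- setdiff(order(D[i, ]), i)[seq_len(k)]
      adj[i, nbrs] <- TRUE
    }
    adj <- adj | t(adj)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    igraph::E(g)$weight <- D[igraph::as_edgelist(g, names = FALSE)]
    comp <- igraph::components(g)
    while (comp$no > 1L) {
      best <- c(Inf, NA, NA)
      for (ca in seq_len(comp$no - 1L)) {
        ia <- which(comp$membership == ca)
        ib <- which(comp$membership > ca)
        sub <- D[ia, ib, drop = FALSE]
        m <- which(sub == min(sub), arr.ind = TRUE)[1, ]
        if (sub[m[1], m[2]] < best[1]) {
          best <- c(sub[m[1], m[2]], ia[m[1]], ib[m[2]])
        }
      }
      g <- igraph::add_edges(g, c(best[2], best[3]),
                             attr = list(weight = best[1]))
      comp <- igraph::components(g)
    }
    tree <- igraph::mst(g, weights = igraph::E(g)$weight)
  }
  el <- igraph::as_edgelist(tree, names = FALSE)
  edges <- data.frame(from = el[, 1], to = el[, 2],
                      weight = igraph::E(tree)$weight)
  oldSeed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv())
  })
  set.seed(seed)
  # zero-distance edges (duplicate fingerprints) are legal in the tree;
  # the layout treats edges uniformly
  coords <- igraph::layout_with_fr(tree, weights = NA)
  structure(list(coords = coords, edges = edges, method = "tree",
                 seed = seed, labels = names(fps)),
            class = "Embedding2D")
}

#' @export
print.Embedding2D <- function(x, ...) {
  cat(sprintf("Embedding2D (%s): %d points\n", x$method, nrow(x$coords)))
  if (x$method == "pca")
    cat("  explained variance:",
        paste(sprintf("%.1f%%", 100 * x$explainedVariance), collapse = ", "),
        "\n")
  invisible(x)
}

#' Per-library summary statistics for rain-cloud-style comparisons
#'
#' Mean, median, quartiles and the 95 percent confidence interval of the
#' mean (t-based) for one property across libraries.
#'
#' @param values numeric vector of property values.
#' @param groups factor/character of library labels, parallel to
#'   \code{values}.
#' @return data.frame with one row per library: \code{n}, \code{mean},
#'   \code{median}, \code{q1}, \code{q3}, \code{ciLow}, \code{ciHigh}.
#' @export
diversitySummary <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- as.factor(groups)
  out <- lapply(levels(groups), function(gl) {
    v <- values[groups == gl]
    n <- length(v)
    m <- mean(v)
    se <- stats::sd(v) / sqrt(n)
    ci <- if (n > 1L && is.finite(se) && se > 0)
      m + c(-1, 1) * stats::qt(0.975, n - 1L) * se else c(m, m)
    data.frame(library = gl, n = n, mean = m, median = stats::median(v),
               q1 = unname(stats::quantile(v, 0.25)),
               q3 = unname(stats::quantile(v, 0.75)),
               ciLow = ci[1], ciHigh = ci[2])
  })
  do.call(rbind, out)
}
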