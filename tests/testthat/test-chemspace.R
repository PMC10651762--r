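# fingerprints, embeddings, tree maps, diversity summaries

test_that("fingerprints are deterministic and Tanimoto behaves", {
  fp1 <- morganFingerprint("c1ccccc1CC(N)C(=O)O")
  fp2 <- morganFingerprint("OC(=O)C(N)Cc1ccccc1")
  expect_identical(fp1[[1]], fp2[[1]])
  expect_identical(tanimotoSimilarity(fp1[[1]], fp2[[1]]), 1)
  # methane vs a large heteroaromatic: near-zero similarity
  fps <- morganFingerprint(c("C", "c1ccc2nc3ccccc3cc2c1"))
  expect_identical(length(fps), 2L)
  expect_lt(tanimotoSimilarity(fps[[1]], fps[[2]]), 0.1)
})

test_that("Tanimoto similarity is symmetric on random fixture pairs", {
  lib <- makeReferenceLibrary(12, seed = 9)
  fps <- morganFingerprint(lib)
  for (i in 1:5) {
    a <- fps[[i]]; b <- fps[[13L - i]]
    expect_identical(tanimotoSimilarity(a, b), tanimotoSimilarity(b, a))
  }
})

test_that("a rank-1 descriptor matrix loads entirely on PC1", {
  x <- cbind(seq(-2, 2, length.out = 10), 0, 0, 0, 0, 0)
  colnames(x) <- c("HBD", "HBA", "logP", "MW", "RotB", "TPSA")
  emb <- pcaEmbed(x)
  expect_equal(emb$explainedVariance[1], 1, tolerance = 1e-12)
  expect_equal(unname(emb$coords[, 2]), rep(0, 10), tolerance = 1e-12)
})

test_that("PCA coordinates equal the eigendecomposition oracle within 1e-8", {
  set.seed(42)
  x <- matrix(rnorm(50 * 6), 50, 6)
  x <- scale(x)
  emb <- pcaEmbed(x)
  # oracle: eigenvectors of the covariance matrix
  ev <- eigen(stats::cov(x), symmetric = TRUE)
  for (j in 1:2) {
    v <- ev$vectors[, j]
    i <- which.max(abs(v))
    if (v[i] < 0) v <- -v
    expect_equal(unname(emb$coords[, j]), unname(as.vector(x %*% v)),
                 tolerance = 1e-8)
  }
  # explained variance fractions agree too
  expect_equal(emb$explainedVariance[1:2],
               (ev$values / sum(ev$values))[1:2], tolerance = 1e-8)
})

test_that("duplicated rows map to identical PCA coordinates", {
  set.seed(1)
  x <- matrix(rnorm(8 * 6), 8, 6)
  x <- rbind(x, x[3, ])
  emb <- pcaEmbed(scale(x, scale = FALSE))
  expect_equal(emb$coords[9, ], emb$coords[3, ], tolerance = 1e-12)
  expect_error(pcaEmbed(x[1:2, ]), "at least 3")
})

test_that("PCA embedding is invariant to row order (up to nothing: signs fixed)", {
  set.seed(7)
  x <- scale(matrix(rnorm(30 * 6), 30, 6))
  perm <- sample(30)
  e1 <- pcaEmbed(x)
  e2 <- pcaEmbed(x[perm, ])
  expect_equal(e2$coords, e1$coords[perm, ], tolerance = 1e-8)
})

test_that("t-SNE is deterministic under a fixed seed and rejects bad perplexity", {
  set.seed(3)
  x <- scale(matrix(rnorm(40 * 6), 40, 6))
  e1 <- tsneEmbed(x, perplexity = 10, seed = 11, nIter = 120)
  e2 <- tsneEmbed(x, perplexity = 10, seed = 11, nIter = 120)
  expect_identical(e1$coords, e2$coords)
  expect_error(tsneEmbed(x, perplexity = 40), "perplexity")
  expect_error(tsneEmbed(x, perplexity = 45), "perplexity")
})

test_that("t-SNE preserves the co-membership of well-separated clusters", {
  set.seed(5)
  a <- matrix(rnorm(30 * 6, mean = 0), 30, 6)
  b <- matrix(rnorm(30 * 6, mean = 8), 30, 6)
  x <- scale(rbind(a, b))
  lab <- rep(c(1, 2), each = 30)
  emb <- tsneEmbed(x, perplexity = 10, seed = 2, nIter = 300)
  d <- as.matrix(stats::dist(emb$coords))
  ok <- 0L
  for (i in seq_len(60)) {
    nn <- order(d[i, ])[2:11]
    if (mean(lab[nn] == lab[i]) >= 0.9) ok <- ok + 1L
  }
  expect_gte(ok / 60, 0.9)
})

test_that("tree embedding yields a spanning tree with n-1 edges", {
  fps <- morganFingerprint(c("CC", "CCC", "CCCC"))
  emb <- treeEmbed(fps, kNeighbors = 2, seed = 1)
  expect_identical(nrow(emb$edges), 2L)
  expect_error(treeEmbed(fps[1]), "at least 2")
})

test_that("the kNN+MST tree weight equals the brute-force MST on <= 25 nodes", {
  primWeight <- function(D) {
    n <- nrow(D)
    inTree <- c(TRUE, rep(FALSE, n - 1))
    total <- 0
    for (step in seq_len(n - 1)) {
      sub <- D[inTree, !inTree, drop = FALSE]
      total <- total + min(sub)
      j <- which(!inTree)[which(sub == min(sub), arr.ind = TRUE)[1, 2]]
      inTree[j] <- TRUE
    }
    total
  }
  for (seed in c(2, 3)) {
    lib <- makeReferenceLibrary(20, seed = seed)
    fps <- morganFingerprint(lib)
    D <- tanimotoDistanceMatrix(fps)
    emb <- treeEmbed(fps, kNeighbors = 19, seed = 1)
    expect_equal(sum(emb$edges$weight), primWeight(D), tolerance = 1e-12)
  }
})

test_that("two scaffold families are joined by exactly one MST cross-edge", {
  alkanes <- sapply(3:12, function(k) paste(rep("C", k), collapse = ""))
  aromatics <- paste0(sapply(1:10, function(k)
    paste(rep("C", k), collapse = "")), "c1ccc2ccccc2c1")
  fps <- morganFingerprint(c(alkanes, aromatics))
  emb <- treeEmbed(fps, kNeighbors = 19, seed = 1)
  fam <- rep(c(1, 2), each = 10)
  cross <- sum(fam[emb$edges$from] != fam[emb$edges$to])
  expect_identical(cross, 1L)
})

test_that("duplicate fingerprints contribute zero-weight edges to the tree", {
  fps <- morganFingerprint(c("CCO", "CCC", "CCCC"))
  fps <- c(fps, fps[1])   # an exact duplicate entry
  emb <- treeEmbed(fps, kNeighbors = 3, seed = 1)
  expect_identical(nrow(emb$edges), 3L)
  expect_true(any(emb$edges$weight == 0))
})

test_that("diversity summaries report exact statistics and honest CIs", {
  s <- diversitySummary(rep(4.2, 10), rep("a", 10))
  expect_identical(s$mean, 4.2)
  expect_identical(s$median, 4.2)
  expect_identical(s$ciLow, s$ciHigh)
  s2 <- diversitySummary(c(1, 2, 3, 4, 5), rep("x", 5))
  expect_identical(s2$median, 3)
  expect_identical(s2$mean, 3)
})

test_that("the t-based CI agrees with a bootstrap CI on normal data", {
  set.seed(11)
  v <- rnorm(1000, mean = 5, sd = 2)
  s <- diversitySummary(v, rep("n", 1000))
  boots <- replicate(400, mean(sample(v, replace = TRUE)))
  bootCI <- stats::quantile(boots, c(0.025, 0.975))
  widthT <- s$ciHigh - s$ciLow
  widthB <- unname(bootCI[2] - bootCI[1])
  expect_lt(abs(widthT - widthB) / widthB, 0.1)
})
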