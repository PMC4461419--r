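# hand-built genotype helper: rows of c(a, b) allele pairs at one locus
oneLocus <- function(...) {
  pairs <- list(...)
  a1 <- matrix(vapply(pairs, `[`, 0L, 1), ncol = 1)
  a2 <- matrix(vapply(pairs, `[`, 0L, 2), ncol = 1)
  genotypeMatrix(a1, a2)
}

test_that("gene diversity matches the unbiased estimator by hand", {
  # monomorphic locus
  g <- oneLocus(c(1L, 1L), c(1L, 1L))
  expect_equal(unname(geneDiversity(g, c("a", "a"))$multilocus), 0)

  # {AA, BB}: p = 0.5/0.5, n = 2 -> (4/3) * 0.5
  g <- oneLocus(c(1L, 1L), c(2L, 2L))
  expect_equal(unname(geneDiversity(g, c("a", "a"))$multilocus),
               (4 / 3) * 0.5, tolerance = 1e-12)

  # k equifrequent alleles at large n -> 1 - 1/k
  k <- 5; n <- 500
  a <- rep(seq_len(k), each = 2 * n / k)
  g <- genotypeMatrix(matrix(a[seq(1, 2 * n, 2)], ncol = 1),
                      matrix(a[seq(2, 2 * n, 2)], ncol = 1))
  expect_equal(unname(geneDiversity(g, rep("a", n))$multilocus),
               1 - 1 / k, tolerance = 2e-3)

  expect_error(geneDiversity(oneLocus(c(NA_integer_, NA_integer_)), "a"),
               "no genotyped")
})

test_that("allelic richness rarefies hypergeometrically", {
  # copies {A: 3, B: 1}, g = 2 -> 1 + (1 - C(3,2)/C(4,2)) = 1.5
  g <- oneLocus(c(1L, 1L), c(1L, 2L))
  ar <- allelicRichness(g, c("a", "a"), rarefyTo = 2)
  expect_equal(unname(ar$multilocus), 1.5, tolerance = 1e-12)

  # rarefying to the full sample returns the observed allele count
  ar4 <- allelicRichness(g, c("a", "a"), rarefyTo = 4)
  expect_equal(unname(ar4$multilocus), 2, tolerance = 1e-12)

  # monotone non-decreasing in g
  g2 <- oneLocus(c(1L, 2L), c(3L, 3L), c(1L, 1L), c(2L, 4L))
  vals <- vapply(2:8, function(gg)
    unname(allelicRichness(g2, rep("a", 4), rarefyTo = gg)$multilocus), 0)
  expect_true(all(diff(vals) >= -1e-12))
  expect_error(allelicRichness(g, c("a", "a"), rarefyTo = 1), "at least 2")
})

test_that("FIS matches known cases and the null", {
  # all heterozygotes at a 2-allele locus -> -1
  g <- oneLocus(c(1L, 2L), c(1L, 2L), c(1L, 2L), c(1L, 2L))
  expect_equal(unname(inbreedingCoefficient(g, rep("a", 4))), -1)

  # Hardy-Weinberg null, n = 500: FIS within +/- 0.05 of 0
  set.seed(7)
  n <- 500
  a1 <- matrix(sample.int(4L, n * 5, TRUE), n, 5)
  a2 <- matrix(sample.int(4L, n * 5, TRUE), n, 5)
  g <- genotypeMatrix(a1, a2)
  expect_lt(abs(inbreedingCoefficient(g, rep("a", n))), 0.05)

  expect_warning(
    fis <- inbreedingCoefficient(oneLocus(c(1L, 1L), c(1L, 1L)),
                                 c("a", "a")),
    "monomorphic")
  expect_true(is.nan(fis))
})

test_that("Weir-Cockerham theta handles fixed, null and hand instances", {
  # two groups fixed for alternative alleles -> theta = 1
  a1 <- matrix(rep(c(1L, 2L), each = 4), 8, 2)
  g <- genotypeMatrix(a1, a1)
  expect_equal(wcFst(g, rep(c("a", "b"), each = 4))$theta, 1)

  # same frequencies, large n -> |theta| < 0.02
  set.seed(11)
  n <- 1000
  a1 <- matrix(sample.int(3L, n * 4, TRUE), n, 4)
  a2 <- matrix(sample.int(3L, n * 4, TRUE), n, 4)
  g <- genotypeMatrix(a1, a2)
  expect_lt(abs(wcFst(g, rep(c("a", "b"), each = n / 2))$theta), 0.02)

  # 2 pops x 2 inds, pop1 = {AA, AA}, pop2 = {AA, AB}: vs literal oracle
  a1 <- matrix(c(1L, 1L, 1L, 1L), 4, 1)
  a2 <- matrix(c(1L, 1L, 1L, 2L), 4, 1)
  g <- genotypeMatrix(a1, a2)
  grp <- c("a", "a", "b", "b")
  oracle <- wcOracle(g@allele1, g@allele2, grp)
  expect_equal(wcFst(g, grp)$theta, oracle$theta, tolerance = 1e-12)

  expect_error(wcFst(g, rep("a", 4)), "two groups")
})

test_that("theta and FIS equal the literal-formula oracle on random instances", {
  set.seed(101)
  for (i in 1:60) {
    inst <- randomInstance()
    res <- wcFst(inst$g, inst$groups)
    oracle <- wcOracle(inst$a1, inst$a2, inst$groups)
    expect_equal(res$theta, oracle$theta, tolerance = 1e-12)
    # per-group FIS against the single-population literal formulas
    for (p in unique(inst$groups)) {
      sel <- inst$groups == p
      expect_equal(
        unname(inbreedingCoefficient(inst$g[sel, ], rep(p, sum(sel)))),
        fisOracle(inst$a1[sel, , drop = FALSE],
                  inst$a2[sel, , drop = FALSE]),
        tolerance = 1e-12)
    }
  }
})

test_that("statistics are invariant to allele relabeling and row order", {
  set.seed(3)
  inst <- randomInstance(nPops = 2, maxInd = 6, nLoci = 3)
  g <- inst$g
  # relabel alleles at locus 1 (a bijection)
  perm <- c(3L, 4L, 1L, 2L)
  a1 <- g@allele1; a2 <- g@allele2
  a1[, 1] <- perm[a1[, 1]]; a2[, 1] <- perm[a2[, 1]]
  g2 <- genotypeMatrix(a1, a2)
  expect_equal(geneDiversity(g, inst$groups)$multilocus,
               geneDiversity(g2, inst$groups)$multilocus)
  expect_equal(wcFst(g, inst$groups)$theta, wcFst(g2, inst$groups)$theta)

  ord <- sample(nInd(g))
  expect_equal(wcFst(g[ord, ], inst$groups[ord])$theta,
               wcFst(g, inst$groups)$theta)
})

test_that("genotypic distances follow the codominant squared scheme", {
  d <- function(p1, p2) {
    g <- oneLocus(p1, p2)
    genotypicDistanceMatrix(g)[1, 2]
  }
  expect_equal(d(c(1L, 1L), c(1L, 1L)), 0)   # identical
  expect_equal(d(c(1L, 1L), c(2L, 2L)), 4)   # AA vs BB
  expect_equal(d(c(1L, 1L), c(1L, 2L)), 1)   # AA vs AB
  expect_equal(d(c(1L, 1L), c(2L, 3L)), 3)   # AA vs BC
  expect_equal(d(c(1L, 2L), c(1L, 3L)), 1)   # AB vs AC
  expect_equal(d(c(1L, 2L), c(3L, 4L)), 2)   # AB vs CD

  # missing loci: pairwise-complete with rescaling to the locus count
  a1 <- cbind(c(1L, 2L), c(1L, NA))
  a2 <- cbind(c(1L, 2L), c(1L, NA))
  g <- genotypeMatrix(a1, a2)
  expect_equal(genotypicDistanceMatrix(g)[1, 2], 4 * 2 / 1)

  # symmetry, zero diagonal, triangle inequality on square roots
  set.seed(5)
  inst <- randomInstance(nPops = 2, maxInd = 5, nLoci = 3,
                         missingProb = 0)
  D <- genotypicDistanceMatrix(inst$g)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, nrow(D)))
  S <- sqrt(D)
  n <- nrow(S)
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    expect_lte(S[i, j], S[i, k] + S[k, j] + 1e-9)

  # a pair with no commonly genotyped locus is an error
  a1 <- cbind(c(1L, NA), c(NA, 2L))
  g <- genotypeMatrix(a1, a1)
  expect_error(genotypicDistanceMatrix(g), "no genotyped locus")
})

test_that("PCoA recovers planted configurations", {
  # 3 collinear points: axis 1 explains 100% of positive variance
  x <- c(0, 1, 3)
  d2 <- outer(x, x, function(a, b) (a - b)^2)
  res <- pcoa(d2)
  expect_equal(res$percentVariance[1], 100, tolerance = 1e-8)

  # planted 2-D configuration: recovered up to rotation/reflection
  set.seed(9)
  X <- matrix(rnorm(20), 10, 2)
  d2 <- as.matrix(dist(X))^2
  res <- pcoa(d2, k = 2)
  Y <- res$coordinates
  # procrustes via SVD of cross-product (centering is already implied)
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  sv <- svd(t(Yc) %*% Xc)
  rot <- sv$u %*% t(sv$v)
  expect_lt(max(abs(Yc %*% rot - Xc)), 1e-8)

  # duplicated individuals get identical coordinates
  d2dup <- as.matrix(dist(X[c(1, 1, 2:10), ]))^2
  cd <- pcoa(d2dup, k = 2)$coordinates
  expect_equal(cd[1, ], cd[2, ], tolerance = 1e-9)

  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})
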