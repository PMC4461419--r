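mkSchedule <- function(rows, dates, lineage) {
  v <- do.call(rbind, rows)
  rownames(v) <- paste0("i", seq_len(nrow(v)))
  floweringSchedule(v, dates, lineage)
}

test_that("flowering synchrony matches hand-computed Pearson means", {
  d <- c(1, 2, 3, 4)
  # identical non-constant series: mean r = 1
  s <- mkSchedule(list(c(0, .5, 1, .2), c(0, .5, 1, .2), c(0, .5, 1, .2)),
                  d, rep("a", 3))
  expect_equal(floweringSynchrony(s, "overall")$meanR, 1)

  # anti-phase pair: r = -1
  x <- c(.1, .4, .8, .2)
  s <- mkSchedule(list(x, 1 - x), d, rep("a", 2))
  expect_equal(floweringSynchrony(s, "overall")$meanR, -1)

  # 3 individuals: mean of the three pairwise coefficients
  rows <- list(c(0, .2, .9, .1), c(.1, .5, .4, 0), c(.8, .2, 0, .4))
  s <- mkSchedule(rows, d, rep("a", 3))
  hand <- mean(c(cor(rows[[1]], rows[[2]]), cor(rows[[1]], rows[[3]]),
                 cor(rows[[2]], rows[[3]])))
  expect_equal(floweringSynchrony(s, "overall")$meanR, hand,
               tolerance = 1e-12)

  # zero-variance series are excluded pairwise and counted
  s <- mkSchedule(c(rows, list(rep(.3, 4))), d, rep("a", 4))
  res <- floweringSynchrony(s, "overall")
  expect_equal(res$meanR, hand, tolerance = 1e-12)
  expect_equal(res$excludedPairs, 3)
  expect_equal(res$nPairs, 3)
})

test_that("within and between modes partition the pairs", {
  d <- c(1, 2, 3)
  rows <- list(c(0, 1, 0), c(.1, .9, 0), c(0, .2, 1), c(0, .1, .8))
  s <- mkSchedule(rows, d, c("a", "a", "b", "b"))
  w <- floweringSynchrony(s, "within")
  b <- floweringSynchrony(s, "between")
  o <- floweringSynchrony(s, "overall")
  expect_named(w$meanR, c("a", "b"))
  expect_equal(unname(w$nPairs), c(1, 1))
  expect_equal(b$nPairs, 4)
  expect_equal(o$nPairs, 6)
  # overall mean r lies between the extremes of the pairwise r values
  C <- cor(t(scheduleValues(s)))
  rng <- range(C[upper.tri(C)])
  expect_gte(o$meanR, rng[1]); expect_lte(o$meanR, rng[2])
})

test_that("hybrid formation probability follows the reconstruction", {
  d <- c(1, 2, 3)
  # fully disjoint schedules: P = 0 for both lineages
  s <- mkSchedule(list(c(1, 0, 0), c(0, 0, 1)), d, c("a", "b"))
  P <- hybridFormationProbability(s, "a", "b", 10, 10)$P
  expect_equal(unname(P), c(0, 0))

  # identical schedules and equal N: symmetry forces 1/2
  s <- mkSchedule(list(c(.2, .8, .1), c(.2, .8, .1)), d, c("a", "b"))
  P <- hybridFormationProbability(s, "a", "b", 7, 7)$P
  expect_equal(unname(P), c(0.5, 0.5))

  # 3-census toy with hand-set means and N_i = 2 N_j
  xi <- c(.6, .4, 0); xj <- c(0, .2, .5)
  s <- mkSchedule(list(xi, xj), d, c("a", "b"))
  Ni <- 20; Nj <- 10
  mij <- ifelse(xi * Ni + xj * Nj > 0, xj * Nj / (xi * Ni + xj * Nj), 0)
  handPi <- sum(xi / sum(xi) * mij)
  res <- hybridFormationProbability(s, "a", "b", Ni, Nj)
  expect_equal(unname(res$P["a"]), handPi, tolerance = 1e-12)

  # per-census mating probabilities sum to 1 where defined
  pc <- res$perCensus
  defined <- pc$xbar_i + pc$xbar_j > 0
  expect_equal(pc$m_ij[defined] + pc$m_ji[defined],
               rep(1, sum(defined)))

  # a lineage that never flowers is flagged, not silently zero
  s <- mkSchedule(list(c(.1, .2, 0), c(0, 0, 0)), d, c("a", "b"))
  expect_warning(P <- hybridFormationProbability(s, "a", "b", 5, 5)$P,
                 "never flowers")
  expect_true(is.nan(P[["b"]]))
})

test_that("statistics ignore census-date relabeling that preserves order", {
  d1 <- c(1, 2, 3, 4); d2 <- c(100, 150, 151, 300)
  rows <- list(c(0, .2, .9, .1), c(.1, .5, .4, 0))
  s1 <- mkSchedule(rows, d1, c("a", "b"))
  s2 <- mkSchedule(rows, d2, c("a", "b"))
  expect_equal(floweringSynchrony(s1, "overall")$meanR,
               floweringSynchrony(s2, "overall")$meanR)
  expect_equal(hybridFormationProbability(s1, "a", "b", 3, 3)$P,
               hybridFormationProbability(s2, "a", "b", 3, 3)$P)
})

test_that("the stratified bootstrap is deterministic and handles degeneracy", {
  set.seed(71)
  cfg <- simulationConfig()
  s <- generateFloweringSchedule(cfg, rep(c("eff1", "eff2"), each = 10),
                                 seed = 3)
  stat <- function(x) floweringSynchrony(x, "overall")$meanR
  ci1 <- bootstrapCi(stat, s, replicates = 200, seed = 99)
  ci2 <- bootstrapCi(stat, s, replicates = 200, seed = 99)
  expect_identical(ci1[c("lower", "upper")], ci2[c("lower", "upper")])
  expect_lte(ci1$lower, ci1$upper)

  # identical individuals: zero-width interval at the point estimate
  v <- matrix(rep(c(0, .5, 1, .2), each = 4), 4)
  rownames(v) <- paste0("i", 1:4)
  sd0 <- floweringSchedule(v, 1:4, rep("a", 4))
  ci <- bootstrapCi(stat, sd0, replicates = 50, seed = 1)
  expect_equal(ci$lower, 1); expect_equal(ci$upper, 1)
  expect_equal(ci$estimate, 1)

  expect_error(bootstrapCi(stat, s, replicates = 1), "replicates")
})
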