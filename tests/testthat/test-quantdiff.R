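test_that("one-way ANOVA matches hand-computed sums of squares", {
  y <- c(3, 5, 4, 8, 9, 10)
  grp <- rep(c("a", "b"), each = 3)
  a <- anovaOneway(y, grp)
  # by hand: group means 4 and 9, grand 6.5; SSB = 3*(2.5^2)*2 = 37.5
  # SSW = (1+1+0) + (1+0+1) = 4; F = 37.5 / (4/4) = 37.5
  expect_equal(a$F, 37.5, tolerance = 1e-10)
  expect_equal(a$MSW, 1, tolerance = 1e-10)
  expect_equal(a$sigma2B, (37.5 - 1) / 3, tolerance = 1e-10)
  expect_equal(a$p, pf(37.5, 1, 4, lower.tail = FALSE), tolerance = 1e-10)

  # unbalanced n0
  y2 <- c(y, 11); grp2 <- c(grp, "b")
  a2 <- anovaOneway(y2, grp2)
  nk <- c(3, 4); N <- 7
  expect_equal(a2$n0, (N - sum(nk^2) / N) / 1, tolerance = 1e-12)

  # no group effect: sigma2B truncated to 0 when MSB < MSW
  set.seed(41)
  yn <- rnorm(40)
  an <- anovaOneway(yn, rep(c("a", "b"), 20))
  if (an$sigma2B_raw < 0) expect_equal(an$sigma2B, 0)

  expect_error(anovaOneway(1:5, rep("a", 5)), "2 groups")
  expect_warning(anovaOneway(rep(c(1, 2), each = 3),
                             rep(c("a", "b"), each = 3)), "zero within")
})

test_that("ANOVA F is invariant under affine trait rescaling", {
  set.seed(42)
  y <- rnorm(30, rep(c(0, 1, 3), each = 10))
  grp <- rep(letters[1:3], each = 10)
  a1 <- anovaOneway(y, grp)
  a2 <- anovaOneway(5 + 2.7 * y, grp)
  expect_equal(a1$F, a2$F, tolerance = 1e-10)
})

test_that("Tukey letters separate planted effects and join nulls", {
  set.seed(43)
  y <- rnorm(60, rep(c(0, 10, 20), each = 20))
  grp <- rep(c("lo", "mid", "hi"), each = 20)
  lt <- tukeyHsd(y, grp)$letters
  expect_equal(length(unique(lt)), 3)

  y0 <- rnorm(60)
  lt0 <- tukeyHsd(y0, grp)$letters
  expect_equal(length(unique(lt0)), 1)
})

test_that("PST follows the variance-component algebra", {
  expect_equal(pst(0, 1)$pst, 0)
  expect_equal(pst(2, 0)$pst, 1)
  # c = 1, h2 = 0.5, equal components -> exactly 1/2
  expect_equal(pst(3, 3, c = 1, h2 = 0.5)$pst, 0.5)
  expect_error(pst(1, 1, h2 = 0), "positive")

  # invariance under trait rescaling
  set.seed(44)
  y <- rnorm(45, rep(c(0, 2, 4), each = 15))
  df <- data.frame(individual = 1:45, lineage = rep(letters[1:3], each = 15),
                   tr = y)
  p1 <- pstFromTrait(df, "tr")$pst
  df$tr <- df$tr * 13 - 2
  expect_equal(pstFromTrait(df, "tr")$pst, p1, tolerance = 1e-10)
})

test_that("trait PCA standardizes, drops constants and orders axes", {
  set.seed(45)
  n <- 50
  f <- rnorm(n)
  df <- data.frame(individual = 1:n, lineage = "x",
                   t1 = f + rnorm(n, 0, .1), t2 = -f + rnorm(n, 0, .1),
                   t3 = rnorm(n), t4 = 1)
  expect_warning(res <- traitPca(df, c("t1", "t2", "t3", "t4")),
                 "constant")
  expect_equal(res$dropped, "t4")
  # planted 1-factor structure dominates axis 1
  expect_gt(res$percentVariance[1], 55)
  expect_true(all(diff(res$percentVariance) <= 1e-12))

  # duplicated trait column loads equally (up to sign) on the shared axis
  df$t5 <- df$t1
  expect_equal(abs(traitPca(df, c("t1", "t5", "t3"))$loadings["t1", 1]),
               abs(traitPca(df, c("t1", "t5", "t3"))$loadings["t5", 1]),
               tolerance = 1e-10)
})

test_that("LDA separates separable groups and flags diagnostic traits", {
  set.seed(46)
  n <- 60
  grp <- rep(c("p", "q"), each = n / 2)
  diagT <- ifelse(grp == "p", 0, 8) + rnorm(n, 0, .5)
  noise1 <- rnorm(n); noise2 <- rnorm(n)
  df <- data.frame(individual = 1:n, lineage = grp,
                   diagT = diagT, noise1 = noise1, noise2 = noise2)
  res <- ldaClassify(df, c("diagT", "noise1", "noise2"))
  expect_equal(unname(res$correctRate["overall"]), 1)
  cors <- abs(res$traitPosteriorCor[, 1])
  expect_equal(names(which.max(cors)), "diagT")

  # chance level for identical distributions
  set.seed(47)
  df2 <- data.frame(individual = 1:400,
                    lineage = rep(c("p", "q"), each = 200),
                    a = rnorm(400), b = rnorm(400))
  r2 <- ldaClassify(df2, c("a", "b"))
  expect_lt(abs(r2$correctRate[["overall"]] - 0.5), 0.12)
})

test_that("quasibinomial GLM reproduces saturated logits and dispersion", {
  # 2x2 counts {10/20 vs 15/20}: coefficient = log((15*10)/(5*10))
  res <- quasibinomialGlm(c(10, 15), c(20, 20), c("a", "b"))
  expect_equal(res$coefficients$estimate[2], log(3), tolerance = 1e-6)
  expect_equal(res$contrasts$estimate[1], log(3), tolerance = 1e-6)

  # identical success proportions: coefficient ~ 0, |t| small
  set.seed(48)
  tot <- rep(30, 40)
  suc <- rbinom(40, 30, 0.3)
  grp <- rep(c("a", "b"), 20)
  r0 <- quasibinomialGlm(suc, tot, grp)
  expect_lt(abs(r0$coefficients$t[2]), 2)

  # pure binomial data: dispersion close to 1
  set.seed(49)
  tot <- rep(25, 200)
  suc <- rbinom(200, 25, rep(c(0.2, 0.4), 100))
  phi <- quasibinomialGlm(suc, tot, rep(c("a", "b"), 100))$dispersion
  expect_gt(phi, 0.7); expect_lt(phi, 1.3)

  # beta-binomial data: dispersion well above 1
  p <- rbeta(200, 2, 5)
  sucOD <- rbinom(200, 25, p)
  phiOD <- quasibinomialGlm(sucOD, rep(25, 200),
                            rep(c("a", "b"), 100))$dispersion
  expect_gt(phiOD, 1.5)

  # complete separation is flagged with finite estimates
  expect_warning(
    rs <- quasibinomialGlm(c(0, 20), c(20, 20), c("a", "b")),
    "separation")
  expect_true(rs$separation)
  expect_true(all(is.finite(rs$coefficients$estimate)))

  expect_error(quasibinomialGlm(c(5, 25), c(20, 20), c("a", "b")))
})
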