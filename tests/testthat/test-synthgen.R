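smallConfig <- function(...) {
  simulationConfig(nIndividuals = c(cong = 40, eff1 = 40, eff2 = 40), ...)
}

test_that("generators are deterministic under a fixed seed", {
  cfg <- smallConfig()
  s1 <- generateStudySystem(cfg, seed = 5)
  s2 <- generateStudySystem(cfg, seed = 5)
  expect_identical(s1$genotypes@allele1, s2$genotypes@allele1)
  expect_identical(as.character(haplotypeSequences(s1$haplotypes)),
                   as.character(haplotypeSequences(s2$haplotypes)))
  expect_identical(scheduleValues(s1$schedule),
                   scheduleValues(s2$schedule))
  expect_identical(s1$traits, s2$traits)
  s3 <- generateStudySystem(cfg, seed = 6)
  expect_false(identical(s1$genotypes@allele1, s3$genotypes@allele1))
})

test_that("config validation rejects invalid settings", {
  expect_error(smallConfig(selfingF = 1.3), "proportions")
  expect_error(smallConfig(censusDates = c(3, 2, 1)), "increasing")
  expect_error(smallConfig(floweringDuration = c(cong = -1, eff1 = 2,
                                                 eff2 = 2)), "positive")
  expect_error(smallConfig(allelesPerLocus = 1), "2 alleles")
  tf <- matrix(0.2, 3, 3); diag(tf) <- 0; tf[1, 2] <- 0.3
  expect_error(smallConfig(targetFst = tf), "symmetric")
  # a differentiation pattern implying drift outside (0,1) is refused
  tfBad <- matrix(c(0, .98, .02, .98, 0, .98, .02, .98, 0), 3, 3)
  expect_error(smallConfig(targetFst = tfBad), "unattainable")
})

test_that("realized differentiation and inbreeding match their targets", {
  cfg <- simulationConfig(
    nIndividuals = c(cong = 100, eff1 = 100, eff2 = 100))
  gg <- generateGenotypes(cfg, seed = 17)
  pw <- wcFst(gg$genotypes, gg$lineage)$pairwise
  expect_lt(abs(pw["cong", "eff1"] - 0.57), 0.08)
  expect_lt(abs(pw["cong", "eff2"] - 0.57), 0.08)
  expect_lt(abs(pw["eff1", "eff2"] - 0.72), 0.08)
  fis <- inbreedingCoefficient(gg$genotypes, gg$lineage)
  expect_true(all(fis > 0.8 & fis < 0.97))
})

test_that("hybrid gamete sampling obeys Mendelian expectations", {
  L <- 9
  pools <- list(matrix(c(1, 0), L, 2, byrow = TRUE),
                matrix(c(0, 1), L, 2, byrow = TRUE))
  # fixed pools, F1: heterozygous at every locus
  f1 <- generateHybridGenotypes(pools, "F1", 30, seed = 2)
  expect_true(all(f1@allele1 != f1@allele2))

  # F2: genotype proportions tend to 1/4 : 1/2 : 1/4
  f2 <- generateHybridGenotypes(pools, "F2", 800, seed = 3)
  het <- mean(f2@allele1 != f2@allele2)
  homA <- mean(f2@allele1 == 1 & f2@allele2 == 1)
  expect_lt(abs(het - 0.5), 0.03)
  expect_lt(abs(homA - 0.25), 0.03)

  # BC_A: expected heterozygosity 1/2 per locus
  bc <- generateHybridGenotypes(pools, "BC_A", 800, seed = 4)
  expect_lt(abs(mean(bc@allele1 != bc@allele2) - 0.5), 0.03)

  expect_error(generateHybridGenotypes(pools, "F3", 5))
})

test_that("haplotype sequences realize the configured step pattern", {
  cfg <- smallConfig()
  seqs <- cryptolin:::.haplotypeTreeSequences(cfg$haplotypeTree,
                                              cfg$seqLength, seed = 8)
  h <- haplotypeSet(seqs)
  D <- pairwiseSteps(h)
  # two haplotypes specified 1+1 steps apart through the root
  expect_equal(D["h1", "h3"], 1L)
  expect_equal(D["h1", "h2"], 2L)
  # the eff1-like clade sits 3-6 steps from every cong/eff2 haplotype
  clade <- c("h4", "h5", "h6", "h7"); rest <- c("h1", "h2", "h3")
  expect_true(all(D[clade, rest] >= 3 & D[clade, rest] <= 6))
  # additivity along the tree: h5 is one step beyond h4
  expect_equal(D["h5", "h3"], D["h4", "h3"] + 1L)

  # step pattern too long for the sequence is refused
  tree <- data.frame(id = c("r", "x"), parent = c(NA, "r"),
                     steps = c(0L, 50L))
  expect_error(cryptolin:::.haplotypeTreeSequences(tree, 10),
               "not realizable")
})

test_that("hybrids inherit their maternal parent's haplotype", {
  cfg <- smallConfig(hybridFraction = 0.2)
  sys <- generateStudySystem(cfg, seed = 9)
  hap <- haplotypeAssignment(sys$haplotypes)
  # check via sequences (ids are renumbered by frequency): a hybrid's
  # haplotype sequence must be one drawn by its maternal lineage's pool
  seqOf <- as.character(haplotypeSequences(sys$haplotypes))
  indSeq <- seqOf[hap]
  names(indSeq) <- names(hap)
  for (lin in cfg$lineages) {
    pureSeqs <- unique(indSeq[sys$truth$individual[
      sys$truth$type == "pure" & sys$truth$lineage == lin]])
    hy <- sys$truth$individual[sys$truth$type == "hybrid" &
                                 sys$truth$maternal == lin]
    if (length(hy) && length(pureSeqs))
      expect_true(all(indSeq[hy] %in% pureSeqs))
  }
})

test_that("flowering schedules respect offsets, jitter and durations", {
  cfg <- smallConfig()
  lin <- rep(c("cong", "eff1", "eff2"), each = 25)
  s <- generateFloweringSchedule(cfg, lin, seed = 12)
  v <- scheduleValues(s); d <- censusDates(s)
  firstDay <- apply(v, 1, function(r) d[which(r > 0)[1]])
  m <- tapply(firstDay, lin, mean)
  expect_true(m[["cong"]] < m[["eff1"]] && m[["eff1"]] < m[["eff2"]])

  # no jitter + identical offsets: identical series
  cfg0 <- smallConfig(floweringJitterSd = 0,
                      floweringOffsets = c(cong = 5, eff1 = 5, eff2 = 5),
                      floweringDuration = c(cong = 18, eff1 = 18,
                                            eff2 = 18))
  s0 <- generateFloweringSchedule(cfg0, lin, seed = 13)
  v0 <- scheduleValues(s0)
  expect_true(all(apply(v0, 2, function(col) max(col) - min(col)) == 0))

  # configured durations are reproduced within one census interval
  cfgD <- smallConfig(floweringJitterSd = 0)
  sD <- generateFloweringSchedule(cfgD, lin, seed = 14)
  vD <- scheduleValues(sD); dD <- censusDates(sD)
  span <- apply(vD, 1, function(r) diff(range(dD[r > 0])))
  interval <- max(diff(dD))
  for (l in unique(lin)) {
    expect_lt(abs(mean(span[lin == l]) - cfg$floweringDuration[[l]]),
              interval + 1e-9)
  }
})

test_that("trait tables carry the configured herbivory and moisture", {
  cfg <- simulationConfig(nIndividuals = c(cong = 90, eff1 = 90,
                                           eff2 = 90))
  lin <- rep(c("cong", "eff1", "eff2"), each = 90)
  tt <- generateTraitTable(cfg, lin, seed = 15)
  prop <- tapply(tt$herbivory_damaged / tt$herbivory_total, lin, mean)
  expect_lt(abs(prop[["cong"]] - 0.19), 0.05)
  expect_lt(abs(prop[["eff1"]] - 0.17), 0.05)
  expect_lt(abs(prop[["eff2"]] - 0.04), 0.05)
  expect_true(all(tt$soil_moisture >= 0.07 & tt$soil_moisture <= 0.29))
  expect_true(all(tt$herbivory_damaged <= tt$herbivory_total))
})

test_that("null traits reject at close to the nominal ANOVA rate", {
  # identical trait means across lineages: type-I error near 0.05,
  # and soil moisture (independent of lineage by construction) likewise
  set.seed(16)
  nRep <- 400
  pTrait <- pMoist <- numeric(nRep)
  lin <- rep(c("a", "b", "c"), each = 10)
  for (r in seq_len(nRep)) {
    y <- rnorm(30, 5, 2)
    pTrait[r] <- anovaOneway(y, lin)$p
    moist <- runif(30, 0.07, 0.29)
    pMoist[r] <- anovaOneway(moist, lin)$p
  }
  expect_gt(mean(pTrait < 0.05), 0.01); expect_lt(mean(pTrait < 0.05), 0.10)
  expect_gt(mean(pMoist < 0.05), 0.01); expect_lt(mean(pMoist < 0.05), 0.10)
})

test_that("a written study system round-trips through the readers", {
  cfg <- smallConfig()
  sys <- generateStudySystem(cfg, seed = 20)
  dir <- tempfile("sys_")
  writeStudySystem(sys, dir)
  gp <- readGenepop(file.path(dir, "genotypes.gen"))
  expect_equal(gp$genotypes@allele1, sys$genotypes@allele1)
  hp <- readHaplotypeFasta(file.path(dir, "haplotypes.fa"))
  expect_equal(sort(unname(haplotypeFrequencies(hp))),
               sort(unname(haplotypeFrequencies(sys$haplotypes))))
  sc <- readScheduleCsv(file.path(dir, "schedule.csv"))
  expect_equal(scheduleValues(sc), scheduleValues(sys$schedule),
               tolerance = 1e-12)
  tr <- readTraitCsv(file.path(dir, "traits.csv"))
  expect_equal(tr$herbivory_damaged, sys$traits$herbivory_damaged)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(nrow(truth$truth), nInd(sys$genotypes))
  expect_equal(truth$config$selfingF, cfg$selfingF)
})

test_that("the hybrid fraction and class mix follow the configuration", {
  cfg <- smallConfig(hybridFraction = 0.07)
  sys <- generateStudySystem(cfg, seed = 21)
  frac <- mean(sys$truth$type == "hybrid")
  expect_lt(abs(frac - 0.07), 0.02)
  expect_true(all(sys$truth$class[sys$truth$type == "hybrid"] %in%
                    c("F1", "F2", "BC_A", "BC_B")))
})
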