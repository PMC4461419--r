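# Synthetic study-system generator.
#
# Emulates a three-lineage, highly selfing study system: strongly
# differentiated microsatellite lineages, a small fraction of hybrids of
# mixed genotype frequency classes, a small set of organellar haplotypes
# with a lineage-sharing pattern, staggered unimodal flowering curves,
# and quantitative traits with lineage-specific herbivory pressure.
# Every generator is deterministic under a fixed seed, and defaults are
# the calibration of the study system the analyses are designed for.

.rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha, rate = 1),
              n, length(alpha), byrow = TRUE)
  x / rowSums(x)
}

.defaultHaplotypeTree <- function() {
  # h3 is the central shared haplotype; h1-h2 are its close neighbours
  # (1-2 steps apart); h4-h7 form a distinct clade 3-6 steps from the rest
  data.frame(
    id     = c("h3", "h1", "h2", "h4", "h5", "h6", "h7"),
    parent = c(NA, "h3", "h3", "h3", "h4", "h4", "h4"),
    steps  = c(0L, 1L, 1L, 3L, 1L, 1L, 2L),
    stringsAsFactors = FALSE)
}

.defaultHaplotypeWeights <- function() {
  list(cong = c(h1 = 0.35, h2 = 0.25, h3 = 0.40),
       eff2 = c(h3 = 1),
       eff1 = c(h4 = 0.40, h5 = 0.25, h6 = 0.20, h7 = 0.15))
}

#' Configuration of a synthetic study system
#'
#' Assembles and validates all generator parameters.  The defaults are
#' the calibration of a three-lineage selfing system: pairwise
#' differentiation targets of 0.57/0.57/0.72, inbreeding coefficient
#' 0.9, about 7% hybrids, seven organellar haplotypes with one shared
#' central haplotype and a distinct clade 3-6 steps away, lineage
#' first-flowering offsets of 0/7/19 days with durations around 17-21
#' days, herbivory means of 19/17/4%, and soil moisture uniform on
#' 7-29% independent of lineage.
#'
#' @param lineages lineage names.
#' @param nIndividuals named counts of pure individuals per lineage.
#' @param nLoci,allelesPerLocus marker panel dimensions.
#' @param targetFst symmetric matrix of pairwise differentiation targets
#'   in \[0, 1) with zero diagonal.
#' @param selfingF inbreeding coefficient in \[0, 1\] used when drawing
#'   genotypes (homozygote excess \eqn{P(aa) = p^2 + F p(1-p)}).
#' @param hybridFraction proportion of hybrids among all samples.
#' @param hybridClassWeights proportions over classes F1, F2, BC_A, BC_B.
#' @param hybridPairWeights proportions over parental lineage pairs
#'   (named `i:j`).
#' @param maternalBias optional named vector: for a pair `i:j`, the
#'   probability that the maternal parent is lineage `i` (default 0.5).
#' @param haplotypeTree data.frame (`id`, `parent`, `steps`) of mutation
#'   steps on a reference sequence; the root has `parent = NA`.
#' @param haplotypeWeights per-lineage named weights over haplotype ids.
#' @param seqLength aligned haplotype sequence length.
#' @param censusDates strictly increasing ordinal census days.
#' @param floweringStart ordinal day at which the earliest lineage starts.
#' @param floweringOffsets per-lineage mean first-flowering offsets (days).
#' @param floweringDuration per-lineage flowering duration (days).
#' @param floweringJitterSd SD of the individual start-date jitter.
#' @param floweringPeak peak proportion of flowering stems.
#' @param herbivoryMeans per-lineage mean damaged-capsule proportions.
#' @param herbivoryDispersion beta-binomial concentration (smaller =
#'   more overdispersed).
#' @param capsuleMean mean capsule count per inflorescence.
#' @param traitMeans matrix (lineages x traits) of trait means.
#' @param traitSds named per-trait SDs (shared across lineages; used to
#'   build diagonal covariances).
#' @param firstFloweringSd SD of the ordinal first-flowering date trait.
#' @param soilMoistureRange range of soil moisture proportions.
#' @param seed integer seed.
#' @return a validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(
    lineages = c("cong", "eff1", "eff2"),
    nIndividuals = c(cong = 110, eff1 = 120, eff2 = 100),
    nLoci = 11, allelesPerLocus = 8,
    targetFst = matrix(c(0, 0.57, 0.57,
                         0.57, 0, 0.72,
                         0.57, 0.72, 0), 3, 3,
                       dimnames = list(lineages, lineages)),
    selfingF = 0.9,
    hybridFraction = 0.07,
    hybridClassWeights = c(F1 = 0.30, F2 = 0.40, BC_A = 0.15, BC_B = 0.15),
    hybridPairWeights = c("cong:eff1" = 0.68, "eff1:eff2" = 0.24,
                          "cong:eff2" = 0.08),
    maternalBias = NULL,
    haplotypeTree = .defaultHaplotypeTree(),
    haplotypeWeights = .defaultHaplotypeWeights(),
    seqLength = 600,
    censusDates = seq(148, 205, by = 3),
    floweringStart = 152,
    floweringOffsets = c(cong = 0, eff1 = 7, eff2 = 19),
    floweringDuration = c(cong = 17, eff1 = 21, eff2 = 18),
    floweringJitterSd = 3,
    floweringPeak = 0.9,
    herbivoryMeans = c(cong = 0.19, eff1 = 0.17, eff2 = 0.04),
    herbivoryDispersion = 15,
    capsuleMean = 40,
    traitMeans = rbind(cong = c(stem_height = 650, spathe_length = 120,
                                cataphyll_length = 60),
                       eff1 = c(stem_height = 780, spathe_length = 180,
                                cataphyll_length = 40),
                       eff2 = c(stem_height = 820, spathe_length = 200,
                                cataphyll_length = 55)),
    traitSds = c(stem_height = 90, spathe_length = 30,
                 cataphyll_length = 12),
    firstFloweringSd = 4,
    soilMoistureRange = c(0.07, 0.29),
    seed = 1L) {
  cfg <- list(lineages = lineages, nIndividuals = nIndividuals,
              nLoci = nLoci, allelesPerLocus = allelesPerLocus,
              targetFst = targetFst, selfingF = selfingF,
              hybridFraction = hybridFraction,
              hybridClassWeights = hybridClassWeights,
              hybridPairWeights = hybridPairWeights,
              maternalBias = maternalBias,
              haplotypeTree = haplotypeTree,
              haplotypeWeights = haplotypeWeights,
              seqLength = seqLength, censusDates = censusDates,
              floweringStart = floweringStart,
              floweringOffsets = floweringOffsets,
              floweringDuration = floweringDuration,
              floweringJitterSd = floweringJitterSd,
              floweringPeak = floweringPeak,
              herbivoryMeans = herbivoryMeans,
              herbivoryDispersion = herbivoryDispersion,
              capsuleMean = capsuleMean,
              traitMeans = traitMeans, traitSds = traitSds,
              firstFloweringSd = firstFloweringSd,
              soilMoistureRange = soilMoistureRange,
              seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  validateSimulationConfig(cfg)
  cfg
}

#' Validate a SimulationConfig
#' @param cfg a `SimulationConfig`.
#' @return `cfg`, invisibly; stops on violation.
#' @export
validateSimulationConfig <- function(cfg) {
  L <- length(cfg$lineages)
  inUnit <- function(x) all(x >= 0 & x <= 1)
  if (!inUnit(c(cfg$selfingF, cfg$hybridFraction, cfg$hybridClassWeights,
                cfg$hybridPairWeights, cfg$herbivoryMeans,
                cfg$floweringPeak, cfg$soilMoistureRange)))
    stop("all proportions must lie in [0, 1]")
  if (cfg$hybridFraction >= 1) stop("hybridFraction must be < 1")
  tf <- cfg$targetFst
  if (!is.matrix(tf) || nrow(tf) != L || ncol(tf) != L ||
      max(abs(tf - t(tf))) > 1e-12 || any(diag(tf) != 0) ||
      any(tf < 0) || any(tf >= 1))
    stop("targetFst must be a symmetric matrix in [0, 1) with zero diagonal")
  if (length(cfg$censusDates) > 1 && any(diff(cfg$censusDates) <= 0))
    stop("census dates must be strictly increasing")
  if (any(cfg$floweringDuration <= 0))
    stop("flowering durations must be positive")
  if (cfg$allelesPerLocus < 2)
    stop("at least 2 alleles per locus are required")
  if (!setequal(names(cfg$nIndividuals), cfg$lineages))
    stop("nIndividuals must be named by lineage")
  .fModelParams(tf)  # errors if targets unattainable
  invisible(cfg)
}

# Solve per-lineage drift parameters f of the F-model so that the
# expected pairwise Weir-Cockerham theta, (f_i + f_j) / 2, hits each
# pairwise target: a linear system in the f_i, solved by least squares.
.fModelParams <- function(targetFst) {
  L <- nrow(targetFst)
  prs <- utils::combn(L, 2)
  A <- matrix(0, ncol(prs), L)
  for (k in seq_len(ncol(prs))) A[k, prs[, k]] <- 1
  f <- drop(stats::coef(stats::lm.fit(A, 2 * targetFst[t(prs)])))
  f[is.na(f)] <- mean(f, na.rm = TRUE)
  if (any(f <= 0) || any(f >= 1))
    stop("targetFst pattern is unattainable: implied drift parameters ",
         paste(sprintf("%.2f", f), collapse = ", "),
         " must lie strictly in (0, 1)")
  stats::setNames(f, rownames(targetFst))
}

# Draw diploid genotypes from allele frequencies with homozygote excess
# P(aa) = p_a^2 + F p_a (1 - p_a): with probability F both gene copies
# are the same draw, otherwise two independent draws.
.drawGenotypes <- function(freqs, n, F) {
  L <- nrow(freqs)
  a1 <- matrix(0L, n, L); a2 <- matrix(0L, n, L)
  for (l in seq_len(L)) {
    p <- freqs[l, ]
    g1 <- sample.int(length(p), n, replace = TRUE, prob = p)
    g2 <- sample.int(length(p), n, replace = TRUE, prob = p)
    ibd <- stats::runif(n) < F
    g2[ibd] <- g1[ibd]
    a1[, l] <- g1; a2[, l] <- g2
  }
  list(a1 = a1, a2 = a2)
}

# Parametric (infinite-sample) multilocus pairwise Weir-Cockerham theta
# of a drawn frequency set, with observed heterozygosity reduced by the
# inbreeding coefficient F.  Used to calibrate the drift parameters on
# the realized frequency draw.
.parametricTheta <- function(freqs, F) {
  lineages <- names(freqs)
  L <- nrow(freqs[[1]])
  pw <- matrix(0, length(lineages), length(lineages),
               dimnames = list(lineages, lineages))
  for (i in seq_along(lineages)[-1]) for (j in seq_len(i - 1)) {
    pi <- freqs[[i]]; pj <- freqs[[j]]
    num <- den <- 0
    for (l in seq_len(L)) {
      pbar <- (pi[l, ] + pj[l, ]) / 2
      s2 <- (pi[l, ] - pj[l, ])^2 / 2
      hbar <- (1 - F) * (2 * pi[l, ] * (1 - pi[l, ]) +
                         2 * pj[l, ] * (1 - pj[l, ])) / 2
      a <- s2
      bc <- pbar * (1 - pbar) - s2 / 2 - hbar / 4 + hbar / 2
      num <- num + sum(a); den <- den + sum(a + bc)
    }
    pw[i, j] <- pw[j, i] <- num / den
  }
  pw
}

#' Generate lineage allele frequencies and pure genotypes
#'
#' Hierarchical F-model: ancestral allele frequencies per locus are
#' Dirichlet; each lineage's frequencies are Dirichlet with
#' concentration \eqn{p_{anc}(1-f)/f}.  The per-lineage drift parameters
#' \eqn{f} are first solved from the pairwise relation
#' \eqn{E[\theta_{ij}] = (f_i+f_j)/2} and then refined by a fixed-point
#' iteration on the parametric \eqn{\theta} of the realized frequency
#' draw (holding the underlying uniform variates fixed), so the drawn
#' frequency set itself carries the target differentiation and the
#' remaining error is individual-sampling noise only.  Genotypes are
#' drawn with homozygote excess controlled by `selfingF`.
#'
#' @param cfg a [simulationConfig()].
#' @param seed integer seed (default `cfg$seed`).
#' @return list with `genotypes` (a [GenotypeMatrix-class] of pure
#'   individuals), `lineage` (true labels) and `freqs` (per-lineage list
#'   of loci x alleles frequency matrices).
#' @export
generateGenotypes <- function(cfg, seed = cfg$seed) {
  validateSimulationConfig(cfg)
  set.seed(seed)
  f <- .fModelParams(cfg$targetFst)
  k <- cfg$allelesPerLocus
  nL <- cfg$nLoci
  prs <- utils::combn(length(cfg$lineages), 2)
  A <- matrix(0, ncol(prs), length(cfg$lineages))
  for (kk in seq_len(ncol(prs))) A[kk, prs[, kk]] <- 1
  target <- cfg$targetFst[t(prs)]
  f0 <- f
  freqs <- NULL
  for (attempt in seq_len(10)) {
    pAnc <- .rdirichlet(nL, rep(2, k))
    # fixed uniforms per (lineage, locus, allele): frequencies respond
    # smoothly to the drift parameters via the gamma quantile function
    u <- lapply(cfg$lineages,
                function(lin) matrix(stats::runif(nL * k), nL, k))
    names(u) <- cfg$lineages
    freqsOf <- function(fv) {
      out <- lapply(cfg$lineages, function(lin) {
        conc <- pAnc * (1 - fv[lin]) / fv[lin]
        x <- matrix(stats::qgamma(u[[lin]], shape = conc, rate = 1), nL, k)
        x[x < 1e-12] <- 1e-12
        x / rowSums(x)
      })
      names(out) <- cfg$lineages
      out
    }
    f <- f0
    converged <- FALSE
    for (it in seq_len(40)) {
      freqs <- freqsOf(f)
      th <- .parametricTheta(freqs, cfg$selfingF)[t(prs)]
      if (max(abs(th - target)) < 0.005) { converged <- TRUE; break }
      delta <- drop(stats::coef(stats::lm.fit(A, 2 * (target - th))))
      delta[is.na(delta)] <- 0
      f <- pmax(pmin(f + 0.6 * delta, 0.99), 0.01)
    }
    if (converged) break
    # an unlucky uniform draw can make the target pattern unreachable;
    # redraw (still within the seeded stream) and recalibrate
  }
  if (!converged)
    warning("drift calibration did not converge to the target ",
            "differentiation pattern; realized FST may deviate")
  a1 <- NULL; a2 <- NULL; lineage <- character()
  for (lin in cfg$lineages) {
    n <- cfg$nIndividuals[[lin]]
    gg <- .drawGenotypes(freqs[[lin]], n, cfg$selfingF)
    a1 <- rbind(a1, gg$a1); a2 <- rbind(a2, gg$a2)
    lineage <- c(lineage, rep(lin, n))
  }
  rownames(a1) <- paste0(lineage, "_", stats::ave(seq_along(lineage),
                                                  lineage, FUN = seq_along))
  colnames(a1) <- paste0("loc", seq_len(cfg$nLoci))
  list(genotypes = genotypeMatrix(a1, a2), lineage = lineage,
       freqs = freqs)
}

#' Generate hybrid genotypes by explicit gamete sampling
#'
#' F1: one gamete from each parental pool.  F2: one gamete from each of
#' two independently simulated F1 individuals.  BC_A / BC_B: one F1
#' gamete plus one gamete from the respective parental pool.
#'
#' @param parentFreqs list of two loci x alleles frequency matrices
#'   (pools A and B).
#' @param class one of `F1`, `F2`, `BC_A`, `BC_B`.
#' @param n number of hybrids to draw.
#' @param seed optional integer seed; `NULL` continues the RNG stream.
#' @return a [GenotypeMatrix-class].
#' @export
generateHybridGenotypes <- function(parentFreqs, class, n, seed = NULL) {
  class <- match.arg(class, c("F1", "F2", "BC_A", "BC_B"))
  if (!is.null(seed)) set.seed(seed)
  fA <- parentFreqs[[1]]; fB <- parentFreqs[[2]]
  L <- nrow(fA)
  poolGamete <- function(freqs, n)
    vapply(seq_len(L), function(l)
      sample.int(ncol(freqs), n, replace = TRUE, prob = freqs[l, ]),
      integer(n))
  f1Individual <- function(n)  # n x L allele pairs as a list of matrices
    list(a1 = poolGamete(fA, n), a2 = poolGamete(fB, n))
  f1Gamete <- function(n) {
    ind <- f1Individual(n)
    pick <- matrix(stats::runif(n * L) < 0.5, n, L)
    ifelse(pick, ind$a1, ind$a2)
  }
  gam <- switch(class,
    F1 = list(poolGamete(fA, n), poolGamete(fB, n)),
    F2 = list(f1Gamete(n), f1Gamete(n)),
    BC_A = list(f1Gamete(n), poolGamete(fA, n)),
    BC_B = list(f1Gamete(n), poolGamete(fB, n)))
  a1 <- matrix(as.integer(gam[[1]]), n, L)
  a2 <- matrix(as.integer(gam[[2]]), n, L)
  rownames(a1) <- paste0("hyb_", class, "_", seq_len(n))
  colnames(a1) <- paste0("loc", seq_len(L))
  genotypeMatrix(a1, a2)
}

# build aligned haplotype sequences whose pairwise Hamming distances
# equal the path lengths of the mutation tree: each branch mutates fresh
# positions, so no position is hit twice
.haplotypeTreeSequences <- function(tree, seqLength, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (sum(tree$steps) > seqLength)
    stop("step pattern not realizable on sequence length ", seqLength)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, seqLength, replace = TRUE)
  avail <- sample.int(seqLength)  # positions used at most once globally
  used <- 0L
  seqs <- list()
  pending <- tree
  done <- is.na(pending$parent)
  seqs[[tree$id[done][1]]] <- ref
  while (any(!done)) {
    ready <- which(!done & tree$parent %in% names(seqs))
    if (!length(ready)) stop("haplotype tree is not connected")
    for (r in ready) {
      s <- seqs[[tree$parent[r]]]
      k <- tree$steps[r]
      if (k > 0) {
        pos <- avail[used + seq_len(k)]
        used <- used + k
        for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1)
      }
      seqs[[tree$id[r]]] <- s
      done[r] <- TRUE
    }
  }
  out <- Biostrings::DNAStringSet(vapply(seqs, paste, "", collapse = ""))
  names(out) <- names(seqs)
  out[tree$id]
}

#' Generate haplotype sequences and maternal assignments
#'
#' Builds aligned sequences realizing the configured mutation-tree step
#' pattern exactly (each branch mutates previously untouched positions),
#' then assigns each individual a haplotype by drawing from its maternal
#' lineage's haplotype weights.
#'
#' @param cfg a [simulationConfig()].
#' @param maternalLineage character vector: the maternal lineage of each
#'   individual (for hybrids, the simulated maternal parent's lineage).
#' @param individuals individual names (default generated).
#' @param seed integer seed (default `cfg$seed`).
#' @return a [HaplotypeSet-class]; note only haplotypes observed in the
#'   sample are retained.
#' @export
generateHaplotypeSequences <- function(cfg, maternalLineage,
                                       individuals = NULL,
                                       seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  seqs <- .haplotypeTreeSequences(cfg$haplotypeTree, cfg$seqLength)
  if (is.null(individuals))
    individuals <- paste0("ind", seq_along(maternalLineage))
  hap <- vapply(maternalLineage, function(lin) {
    w <- cfg$haplotypeWeights[[lin]]
    if (is.null(w)) stop("no haplotype weights for lineage ", lin)
    sample(names(w), 1, prob = w)
  }, "")
  names(hap) <- individuals
  keep <- names(seqs) %in% unique(hap)
  obs <- seqs[keep]
  # renumber observed haplotypes by decreasing frequency for stable ids,
  # keeping the original tree ids as a map attribute
  counts <- table(factor(hap, levels = names(obs)))
  ord <- order(-as.integer(counts), seq_along(obs))
  obs <- obs[ord]
  haplotypeSet(obs, hap)
}

#' Generate a flowering schedule
#'
#' Each individual's proportion of flowering stems follows a truncated
#' Gaussian curve over its flowering window: the window starts at the
#' lineage offset plus an individual jitter, lasts the lineage duration,
#' and the curve is scaled to `floweringPeak` at mid-window (SD =
#' duration / 4, zero outside the window), sampled at the census dates.
#'
#' @param cfg a [simulationConfig()].
#' @param lineage lineage label per individual (must index
#'   `floweringOffsets`).
#' @param individuals individual names (default generated).
#' @param seed integer seed (default `cfg$seed`).
#' @return a [FloweringSchedule-class].
#' @export
generateFloweringSchedule <- function(cfg, lineage, individuals = NULL,
                                      seed = cfg$seed) {
  if (any(cfg$floweringDuration <= 0)) stop("durations must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(individuals))
    individuals <- paste0("ind", seq_along(lineage))
  n <- length(lineage)
  dates <- cfg$censusDates
  v <- matrix(0, n, length(dates),
              dimnames = list(individuals, as.character(dates)))
  for (i in seq_len(n)) {
    lin <- lineage[i]
    start <- cfg$floweringStart + cfg$floweringOffsets[[lin]] +
      stats::rnorm(1, 0, cfg$floweringJitterSd)
    dur <- cfg$floweringDuration[[lin]]
    mid <- start + dur / 2
    sdv <- dur / 4
    y <- cfg$floweringPeak * exp(-0.5 * ((dates - mid) / sdv)^2)
    y[dates < start | dates > start + dur] <- 0
    v[i, ] <- pmin(1, y)
  }
  floweringSchedule(v, dates, lineage)
}

#' Generate a quantitative trait table
#'
#' Multivariate-normal traits per lineage (diagonal covariance from
#' `traitSds`), an ordinal first-flowering date consistent with the
#' configured lineage offsets, beta-binomial damaged-capsule counts with
#' lineage-specific means, and soil moisture uniform on
#' `soilMoistureRange` independent of lineage.
#'
#' @param cfg a [simulationConfig()].
#' @param lineage lineage label per individual (must index the trait
#'   parameter tables).
#' @param individuals individual names (default generated).
#' @param seed integer seed (default `cfg$seed`).
#' @return a data.frame (see [readTraitCsv()] for the layout).
#' @export
generateTraitTable <- function(cfg, lineage, individuals = NULL,
                               seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(individuals))
    individuals <- paste0("ind", seq_along(lineage))
  n <- length(lineage)
  traits <- colnames(cfg$traitMeans)
  Sigma <- diag(cfg$traitSds[traits]^2, length(traits))
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("trait covariance must be positive definite")
  X <- matrix(NA_real_, n, length(traits), dimnames = list(NULL, traits))
  for (lin in unique(lineage)) {
    sel <- lineage == lin
    X[sel, ] <- MASS::mvrnorm(sum(sel), cfg$traitMeans[lin, traits], Sigma)
  }
  ff <- cfg$floweringStart +
    vapply(lineage, function(l) cfg$floweringOffsets[[l]], 0) +
    stats::rnorm(n, 0, cfg$firstFloweringSd)
  total <- stats::rpois(n, cfg$capsuleMean - 1) + 1L
  m <- vapply(lineage, function(l) cfg$herbivoryMeans[[l]], 0)
  th <- cfg$herbivoryDispersion
  pDam <- stats::rbeta(n, m * th, (1 - m) * th)
  damaged <- stats::rbinom(n, total, pDam)
  data.frame(individual = individuals, lineage = lineage,
             as.data.frame(X),
             first_flowering = ff,
             herbivory_damaged = damaged, herbivory_total = total,
             soil_moisture = stats::runif(n, cfg$soilMoistureRange[1],
                                          cfg$soilMoistureRange[2]),
             row.names = NULL)
}

# hybrid parameter helpers: mean of the two parental lineages
.hybridOffsets <- function(cfg) {
  prs <- names(cfg$hybridPairWeights)
  out <- lapply(prs, function(pr) {
    p <- strsplit(pr, ":")[[1]]
    list(offset = mean(c(cfg$floweringOffsets[[p[1]]],
                         cfg$floweringOffsets[[p[2]]])),
         duration = mean(c(cfg$floweringDuration[[p[1]]],
                           cfg$floweringDuration[[p[2]]])),
         herbivory = mean(c(cfg$herbivoryMeans[[p[1]]],
                            cfg$herbivoryMeans[[p[2]]])),
         traitMeans = colMeans(cfg$traitMeans[p, , drop = FALSE]))
  })
  names(out) <- prs
  out
}

#' Generate a complete labelled study system
#'
#' Orchestrates all generators into one coherent sample: pure
#' individuals of each lineage, hybrids of configured pair and class mix
#' (with maternally inherited haplotypes), a flowering schedule and a
#' trait table (hybrids receive the mean of their parents' flowering and
#' trait parameters).  The number of hybrids is chosen so they make up
#' `hybridFraction` of the full sample.
#'
#' @param cfg a [simulationConfig()].
#' @param seed integer seed (default `cfg$seed`); stage seeds are derived
#'   deterministically from it.
#' @return list with `config`, `genotypes` (all individuals), `truth`
#'   (data.frame: individual, type, lineage, class, pair, maternal),
#'   `haplotypes`, `schedule`, `traits` and `freqs`.
#' @export
generateStudySystem <- function(cfg, seed = cfg$seed) {
  validateSimulationConfig(cfg)
  stageSeed <- function(k) (seed * 131L + k) %% .Machine$integer.max

  pure <- generateGenotypes(cfg, seed = stageSeed(1))
  nPure <- nInd(pure$genotypes)
  nHyb <- round(cfg$hybridFraction / (1 - cfg$hybridFraction) * nPure)

  set.seed(stageSeed(2))
  g <- pure$genotypes
  truth <- data.frame(individual = individualNames(g), type = "pure",
                      lineage = pure$lineage, class = NA_character_,
                      pair = NA_character_, maternal = pure$lineage,
                      stringsAsFactors = FALSE)
  if (nHyb > 0) {
    prs <- sample(names(cfg$hybridPairWeights), nHyb, replace = TRUE,
                  prob = cfg$hybridPairWeights)
    cls <- sample(names(cfg$hybridClassWeights), nHyb, replace = TRUE,
                  prob = cfg$hybridClassWeights)
    hybNo <- 0L
    for (pr in unique(prs)) {
      p <- strsplit(pr, ":")[[1]]
      bias <- if (!is.null(cfg$maternalBias) &&
                  pr %in% names(cfg$maternalBias))
        cfg$maternalBias[[pr]] else 0.5
      for (cl in unique(cls[prs == pr])) {
        nn <- sum(prs == pr & cls == cl)
        hg <- generateHybridGenotypes(
          list(pure$freqs[[p[1]]], pure$freqs[[p[2]]]), cl, nn)
        ids <- paste0("hyb", hybNo + seq_len(nn))
        hybNo <- hybNo + nn
        rownames(hg@allele1) <- ids; rownames(hg@allele2) <- ids
        g <- rbind2(g, hg)
        # maternal parent: pool A with probability `bias`; backcrosses
        # to a parental pool inherit maternally from either parent of
        # the F1 or the recurrent parent -- resolved by the same draw
        mat <- ifelse(stats::runif(nn) < bias, p[1], p[2])
        truth <- rbind(truth, data.frame(
          individual = ids, type = "hybrid", lineage = pr, class = cl,
          pair = pr, maternal = mat, stringsAsFactors = FALSE))
      }
    }
  }

  haplotypes <- generateHaplotypeSequences(
    cfg, truth$maternal, individuals = truth$individual,
    seed = stageSeed(3))

  # flowering/trait parameters: pure lineages plus per-pair hybrid means
  hybPar <- .hybridOffsets(cfg)
  cfg2 <- cfg
  for (pr in names(hybPar)) {
    cfg2$floweringOffsets[[pr]] <- hybPar[[pr]]$offset
    cfg2$floweringDuration[[pr]] <- hybPar[[pr]]$duration
    cfg2$herbivoryMeans[[pr]] <- hybPar[[pr]]$herbivory
    cfg2$traitMeans <- rbind(
      cfg2$traitMeans,
      matrix(hybPar[[pr]]$traitMeans, 1,
             dimnames = list(pr, colnames(cfg2$traitMeans))))
  }
  schedLabel <- ifelse(truth$type == "pure", truth$lineage, truth$pair)
  schedule <- generateFloweringSchedule(cfg2, schedLabel,
                                        individuals = truth$individual,
                                        seed = stageSeed(4))
  traits <- generateTraitTable(cfg2, schedLabel,
                               individuals = truth$individual,
                               seed = stageSeed(5))
  list(config = cfg, genotypes = g, truth = truth,
       haplotypes = haplotypes, schedule = schedule, traits = traits,
       freqs = pure$freqs)
}

#' Write a study system to disk
#'
#' Writes `genotypes.gen` (GenePop, 3-digit codes, one POP block per
#' truth label), `haplotypes.fa` (aligned FASTA, one record per
#' individual), `schedule.csv`, `traits.csv` and `truth.json` (truth
#' labels plus a config echo).
#'
#' @param sys result of [generateStudySystem()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeStudySystem <- function(sys, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeGenepop(sys$genotypes, file.path(dir, "genotypes.gen"),
               pop = ifelse(sys$truth$type == "pure", sys$truth$lineage,
                            "hybrid"))
  writeHaplotypeFasta(sys$haplotypes, file.path(dir, "haplotypes.fa"))
  writeScheduleCsv(sys$schedule, file.path(dir, "schedule.csv"))
  utils::write.csv(sys$traits, file.path(dir, "traits.csv"),
                   row.names = FALSE)
  cfgEcho <- unclass(sys$config)
  cfgEcho$haplotypeTree <- as.list(cfgEcho$haplotypeTree)
  jsonlite::write_json(
    list(truth = sys$truth, config = cfgEcho),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}
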