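# Posterior classification into genotype frequency classes: pure
# individuals of either parental population, F1, F2 and first-generation
# backcrosses -- the six classes that can arise within two generations of
# crossing between two parental populations.

#' Ancestry-pair weights of the six genotype frequency classes
#'
#' For each class, the expected proportions of locus gene-copy-pair
#' origins (both copies from pool A, one from each, both from pool B).
#'
#' @return a 6 x 3 numeric matrix, rows named by class.
#' @export
hybridClassWeights <- function() {
  w <- rbind(Pure_A = c(1, 0, 0), Pure_B = c(0, 0, 1), F1 = c(0, 1, 0),
             F2 = c(1/4, 1/2, 1/4), BC_A = c(1/2, 1/2, 0),
             BC_B = c(0, 1/2, 1/2))
  colnames(w) <- c("AA", "AB", "BB")
  w
}

#' Single-locus genotype likelihood under a genotype frequency class
#'
#' \eqn{P(\mathrm{genotype} \mid \mathrm{class})} at one locus, mixing the
#' three gene-copy origin categories with the class's ancestry-pair
#' weights.  Within-pool categories contribute Hardy-Weinberg genotype
#' probabilities (\eqn{p_a^2} or \eqn{2 p_a p_b}); the cross-pool category
#' contributes \eqn{p_{Aa} p_{Bb} + p_{Ab} p_{Ba}} for heterozygotes and
#' \eqn{p_{Aa} p_{Ba}} for homozygotes.
#'
#' @param genotype integer vector of length 2 (allele indices into the
#'   frequency vectors), or `NA` for a missing genotype (probability 1).
#' @param class one of `Pure_A`, `Pure_B`, `F1`, `F2`, `BC_A`, `BC_B`.
#' @param pA,pB allele-frequency vectors of the two parental pools at
#'   this locus; each must sum to 1.
#' @return the genotype probability.
#' @examples
#' classGenotypeLikelihood(c(1, 2), "F2", c(0.8, 0.2), c(0.1, 0.9))
#' @export
classGenotypeLikelihood <- function(genotype, class, pA, pB) {
  class <- match.arg(class, HYBRID_CLASSES)
  if (abs(sum(pA) - 1) > 1e-6 || abs(sum(pB) - 1) > 1e-6)
    stop("pool allele frequencies must sum to 1")
  if (any(is.na(genotype))) return(1)
  x <- genotype[1]; y <- genotype[2]
  het <- x != y
  catProb <- c(
    AA = if (het) 2 * pA[x] * pA[y] else pA[x]^2,
    AB = if (het) pA[x] * pB[y] + pA[y] * pB[x] else pA[x] * pB[x],
    BB = if (het) 2 * pB[x] * pB[y] else pB[x]^2)
  unname(sum(hybridClassWeights()[class, ] * catProb))
}

#' Classify individuals into genotype frequency classes
#'
#' Gibbs sampler alternating (i) the class of each individual given the
#' two pool allele-frequency sets, (ii) the pool of origin of each gene
#' copy given the class, and (iii) pool frequencies from their
#' Dirichlet(1) full conditional.  The class prior is uniform over the
#' six classes.  By default the run is unsupervised: the two pools are
#' initialised from a deterministic split of the first principal
#' coordinate of the genotypic distance matrix.  Known pure individuals
#' can instead anchor the pools via `pureRef`.
#'
#' @param g a [GenotypeMatrix-class].
#' @param burnin,sweeps burn-in and retained sweeps.
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#' @param pureRef optional list with integer/logical index vectors `A`
#'   and `B`: individuals held fixed in `Pure_A` / `Pure_B`.
#' @return a [HybridPosterior-class].
#' @export
classifyHybrids <- function(g, burnin = 5000, sweeps = 20000, seed = NULL,
                            pureRef = NULL) {
  stopifnot(methods::is(g, "GenotypeMatrix"), sweeps > 0)
  if (!is.null(seed)) set.seed(seed)
  rc <- .recodeAlleles(g)
  if (all(rc$nAlleles == 1L))
    warning("all loci are monomorphic; the posterior equals the prior")
  n <- nInd(g)
  fixed <- integer(n)
  if (!is.null(pureRef)) {
    idx <- function(v) if (is.logical(v)) which(v) else as.integer(v)
    fixed[idx(pureRef$A)] <- 1L
    fixed[idx(pureRef$B)] <- 2L
    init <- ifelse(fixed > 0L, fixed, 1L)
    free <- which(fixed == 0L)
    if (length(free)) {
      # seed free individuals with the nearer anchored pool
      d <- genotypicDistanceMatrix(g)
      dA <- rowMeans(d[, fixed == 1L, drop = FALSE])
      dB <- rowMeans(d[, fixed == 2L, drop = FALSE])
      init[free] <- ifelse(dA[free] <= dB[free], 1L, 2L)
    }
  } else {
    d2 <- genotypicDistanceMatrix(g)
    if (max(d2) == 0) {
      init <- rep_len(c(1L, 2L), n)  # no signal: arbitrary split
    } else {
      ax <- pcoa(d2, k = 1)$coordinates[, 1]
      init <- ifelse(ax <= stats::median(ax), 1L, 2L)
      if (length(unique(init)) == 1L) init[1] <- 3L - init[1]
    }
  }
  post <- .gibbs_hybrids_cpp(rc$a1, rc$a2, rc$nAlleles,
                             as.integer(init), as.integer(fixed),
                             as.integer(burnin), as.integer(sweeps))
  dimnames(post) <- list(individualNames(g), HYBRID_CLASSES)
  methods::new("HybridPosterior", posterior = post,
               mcmc = list(burnin = burnin, sweeps = sweeps, seed = seed))
}

#' Call hybrid status from a class posterior
#'
#' Assigns each individual its maximum-posterior class when that
#' posterior clears the threshold, and `unassigned` otherwise.  The
#' default threshold of 0.95 is the conventional posterior cutoff for
#' confident hybrid calls.
#'
#' @param hp a [HybridPosterior-class].
#' @param threshold minimum posterior probability for a call.
#' @return data.frame with `individual`, `call`, `posterior` (of the
#'   modal class) and the six class posteriors.
#' @export
hybridCalls <- function(hp, threshold = 0.95) {
  stopifnot(methods::is(hp, "HybridPosterior"))
  post <- posteriorMatrix(hp)
  best <- apply(post, 1, which.max)
  pmax <- post[cbind(seq_len(nrow(post)), best)]
  call <- ifelse(pmax >= threshold, colnames(post)[best], "unassigned")
  data.frame(individual = rownames(post), call = call, posterior = pmax,
             post, row.names = NULL, check.names = FALSE)
}
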