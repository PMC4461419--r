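#' @import methods
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet width
#' @importFrom stats aov anova cor cov lm pf pt ptukey qnorm quantile rbeta
#'   rbinom rmultinom rnorm runif sd setNames var prcomp glm quasibinomial
#'   coef residuals fitted TukeyHSD as.formula binomial dnorm pnorm
#'   cmdscale complete.cases
#' @importFrom utils read.csv write.csv head combn
#' @useDynLib cryptolin, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Diploid codominant genotypes for a set of individuals
#'
#' `GenotypeMatrix` stores unordered diploid allele pairs for a set of
#' individuals scored at a set of codominant loci (typically nuclear
#' microsatellites).  Alleles are positive integer labels; a missing
#' genotype is represented by `NA` in both allele slots.  The two allele
#' matrices share dimensions and dimnames (individuals in rows, loci in
#' columns) and the order of alleles within a genotype carries no meaning.
#'
#' @slot allele1 integer matrix, first allele of each genotype.
#' @slot allele2 integer matrix, second allele of each genotype.
#'
#' @seealso [genotypeMatrix()] for the user constructor, [readGenepop()] /
#'   [writeGenepop()] for file exchange.
#' @export
setClass("GenotypeMatrix",
  representation(allele1 = "matrix", allele2 = "matrix"))

setValidity("GenotypeMatrix", function(object) {
  a1 <- object@allele1; a2 <- object@allele2
  msg <- character()
  if (!identical(dim(a1), dim(a2)))
    msg <- c(msg, "allele matrices must share dimensions")
  if (!identical(dimnames(a1), dimnames(a2)))
    msg <- c(msg, "allele matrices must share dimnames")
  if (!is.integer(a1) || !is.integer(a2))
    msg <- c(msg, "allele matrices must be integer")
  if (identical(dim(a1), dim(a2)) && !identical(is.na(a1), is.na(a2)))
    msg <- c(msg, "a genotype must have 0 or 2 allele calls, never 1")
  if (any(a1 <= 0L, na.rm = TRUE) || any(a2 <= 0L, na.rm = TRUE))
    msg <- c(msg, "allele labels must be positive integers")
  if (is.null(rownames(a1)) || is.null(colnames(a1)))
    msg <- c(msg, "individual and locus names are required")
  if (length(msg)) msg else TRUE
})

#' Aligned haplotype sequences with individual assignments
#'
#' Unique aligned sequences (IUPAC DNA plus `-` gaps, equal width) with a
#' stable haplotype identifier each, and a map from individual to
#' haplotype.  Haplotype frequencies are the individual counts and are
#' derived from the assignment, so they always sum to the number of
#' individuals.
#'
#' @slot sequences `DNAStringSet`, one entry per haplotype, named by
#'   haplotype id.
#' @slot assignment named character vector mapping individual id to
#'   haplotype id.
#'
#' @seealso [collapseHaplotypes()], [haplotypeFrequencies()],
#'   [buildParsimonyNetwork()].
#' @export
setClass("HaplotypeSet",
  representation(sequences = "ANY", assignment = "character"))

setValidity("HaplotypeSet", function(object) {
  msg <- character()
  if (!methods::is(object@sequences, "DNAStringSet"))
    msg <- c(msg, "sequences must be a DNAStringSet")
  else {
    if (length(unique(Biostrings::width(object@sequences))) > 1)
      msg <- c(msg, "all sequences must have equal aligned length")
    if (length(object@sequences) && is.null(names(object@sequences)))
      msg <- c(msg, "sequences must be named by haplotype id")
    if (length(object@assignment) &&
        !all(object@assignment %in% names(object@sequences)))
      msg <- c(msg, "assignment refers to unknown haplotype ids")
  }
  if (length(object@assignment) && is.null(names(object@assignment)))
    msg <- c(msg, "assignment must be named by individual id")
  if (length(msg)) msg else TRUE
})

#' Per-individual flowering time series
#'
#' Proportion of flowering stems per individual and census date, with a
#' lineage label per individual.  The substrate for flowering synchrony
#' and probability-of-hybrid-formation statistics.
#'
#' @slot values numeric matrix (individuals x censuses) of proportions in
#'   \[0, 1\].
#' @slot dates numeric vector of strictly increasing census dates
#'   (ordinal days).
#' @slot lineage character vector of lineage labels, one per individual.
#'
#' @seealso [floweringSchedule()], [floweringSynchrony()],
#'   [hybridFormationProbability()].
#' @export
setClass("FloweringSchedule",
  representation(values = "matrix", dates = "numeric", lineage = "character"))

setValidity("FloweringSchedule", function(object) {
  msg <- character()
  v <- object@values
  if (ncol(v) != length(object@dates))
    msg <- c(msg, "number of value columns must match number of censuses")
  if (nrow(v) != length(object@lineage))
    msg <- c(msg, "one lineage label per individual is required")
  if (any(v < 0 | v > 1, na.rm = TRUE))
    msg <- c(msg, "flowering proportions must lie in [0, 1]")
  if (length(object@dates) > 1 && any(diff(object@dates) <= 0))
    msg <- c(msg, "census dates must be strictly increasing")
  if (is.null(rownames(v)))
    msg <- c(msg, "individual names are required")
  if (length(msg)) msg else TRUE
})

#' Result of no-admixture Bayesian genotype clustering
#'
#' Posterior cluster-membership probabilities (post-burn-in occupancy
#' frequencies of a collapsed Gibbs sampler), together with the pairwise
#' co-assignment matrix, which is invariant to cluster label switching.
#'
#' @slot K number of clusters.
#' @slot posterior numeric matrix (individuals x K), rows sum to 1.
#' @slot coassignment numeric matrix (individuals x individuals),
#'   posterior probability that two individuals share a cluster.
#' @slot meanLogLik mean post-burn-in log-likelihood of the data.
#' @slot mcmc list with `burnin`, `sweeps` and `seed`.
#' @export
setClass("ClusterResult",
  representation(K = "integer", posterior = "matrix",
                 coassignment = "matrix", meanLogLik = "numeric",
                 mcmc = "list"))

setValidity("ClusterResult", function(object) {
  msg <- character()
  if (ncol(object@posterior) != object@K)
    msg <- c(msg, "posterior must have K columns")
  rs <- rowSums(object@posterior)
  if (length(rs) && max(abs(rs - 1)) > 1e-9)
    msg <- c(msg, "posterior rows must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Posterior over genotype frequency classes
#'
#' Per-individual posterior probabilities over the six genotype frequency
#' classes that can arise within two generations of crossing between two
#' parental populations: pure individuals of either population, F1, F2,
#' and the two backcrosses.
#'
#' @slot posterior numeric matrix (individuals x 6) with columns
#'   `Pure_A`, `Pure_B`, `F1`, `F2`, `BC_A`, `BC_B`; rows sum to 1.
#' @slot mcmc list with `burnin`, `sweeps` and `seed`.
#' @export
setClass("HybridPosterior",
  representation(posterior = "matrix", mcmc = "list"))

#' Class labels of the six genotype frequency classes
#' @keywords internal
HYBRID_CLASSES <- c("Pure_A", "Pure_B", "F1", "F2", "BC_A", "BC_B")

setValidity("HybridPosterior", function(object) {
  msg <- character()
  if (!identical(colnames(object@posterior), HYBRID_CLASSES))
    msg <- c(msg, "posterior columns must be the six genotype frequency classes")
  rs <- rowSums(object@posterior)
  if (length(rs) && max(abs(rs - 1)) > 1e-9)
    msg <- c(msg, "posterior rows must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Fixed-limit statistical parsimony haplotype network
#'
#' Haplotypes connected by single mutational steps; connections longer
#' than one step are expanded through inferred intermediate nodes of
#' frequency zero.  Pairs farther apart than the connection limit are
#' never joined, so the network may be a forest.
#'
#' @slot nodes data.frame with columns `id`, `frequency`, `inferred`.
#' @slot edges data.frame of single-step edges (`from`, `to`) after
#'   intermediate-node expansion.
#' @slot links data.frame of haplotype-level connections (`from`, `to`,
#'   `steps`, `loop`); `loop` marks retained equal-length alternatives.
#' @slot components named integer vector: connected component per
#'   observed haplotype.
#' @slot limit the connection limit (steps) used.
#' @export
setClass("ParsimonyNetwork",
  representation(nodes = "data.frame", edges = "data.frame",
                 links = "data.frame", components = "integer",
                 limit = "integer"))
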