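# Model-based clustering of multilocus genotypes: a no-admixture Gibbs
# sampler with uniform cluster prior and Dirichlet(1) allele-frequency
# prior, plus the Evanno delta-K heuristic for choosing K.

# remap allele labels to 1..J per locus; 0 = missing
.recodeAlleles <- function(g) {
  a1 <- g@allele1; a2 <- g@allele2
  r1 <- matrix(0L, nrow(a1), ncol(a1))
  r2 <- matrix(0L, nrow(a1), ncol(a1))
  nAll <- integer(ncol(a1))
  for (l in seq_len(ncol(a1))) {
    alleles <- sort(unique(c(a1[, l], a2[, l])))
    alleles <- alleles[!is.na(alleles)]
    nAll[l] <- max(length(alleles), 1L)
    m1 <- match(a1[, l], alleles); m2 <- match(a2[, l], alleles)
    r1[, l] <- ifelse(is.na(m1), 0L, m1)
    r2[, l] <- ifelse(is.na(m2), 0L, m2)
  }
  list(a1 = r1, a2 = r2, nAlleles = nAll)
}

#' No-admixture Bayesian clustering of genotypes
#'
#' Collapsed Gibbs sampler over cluster assignments under a no-admixture
#' model: each individual belongs wholly to one of `K` clusters, cluster
#' allele frequencies carry a Dirichlet(1) prior and are integrated out,
#' and the cluster prior is uniform.  Posterior membership probabilities
#' are post-burn-in occupancy frequencies.  Because cluster labels can
#' switch between runs, the label-invariant pairwise co-assignment
#' matrix is also returned.
#'
#' @param g a [GenotypeMatrix-class].
#' @param K number of clusters (`1 <= K <=` number of individuals).
#' @param burnin,sweeps burn-in and retained Gibbs sweeps.
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#' @param thin interval (in sweeps) for recording the log-likelihood and
#'   co-assignment accumulators.
#' @return a [ClusterResult-class].
#' @export
clusterNoAdmixture <- function(g, K, burnin = 5000, sweeps = 20000,
                               seed = NULL, thin = 10) {
  stopifnot(methods::is(g, "GenotypeMatrix"), K >= 1, sweeps > 0)
  if (K > nInd(g)) stop("K cannot exceed the number of individuals")
  if (!is.null(seed)) set.seed(seed)
  rc <- .recodeAlleles(g)
  res <- .gibbs_cluster_cpp(rc$a1, rc$a2, rc$nAlleles, as.integer(K),
                            as.integer(burnin), as.integer(sweeps),
                            as.integer(thin))
  post <- res$posterior
  dimnames(post) <- list(individualNames(g), paste0("cluster", seq_len(K)))
  co <- res$coassignment
  dimnames(co) <- list(individualNames(g), individualNames(g))
  methods::new("ClusterResult", K = as.integer(K), posterior = post,
               coassignment = co, meanLogLik = res$meanLogLik,
               mcmc = list(burnin = burnin, sweeps = sweeps, seed = seed,
                           thin = thin))
}

#' Replicate clustering runs over a range of K
#'
#' Runs [clusterNoAdmixture()] for each value of `K` and each replicate
#' (with seeds derived deterministically from `seed`) and collects the
#' per-run mean log-likelihoods, the input expected by [evannoDeltaK()].
#'
#' @inheritParams clusterNoAdmixture
#' @param Ks integer vector of cluster numbers to try.
#' @param reps replicate runs per K.
#' @return list with `logLik` (matrix, rows = K, cols = replicates) and
#'   `results` (nested list of [ClusterResult-class] objects).
#' @export
clusterKSeries <- function(g, Ks, reps = 5, burnin = 5000, sweeps = 20000,
                           seed = 1, thin = 10) {
  ll <- matrix(NA_real_, length(Ks), reps,
               dimnames = list(Ks, paste0("rep", seq_len(reps))))
  results <- vector("list", length(Ks))
  names(results) <- as.character(Ks)
  for (ki in seq_along(Ks)) {
    results[[ki]] <- vector("list", reps)
    for (r in seq_len(reps)) {
      s <- (seed * 1000L + Ks[ki] * 100L + r) %% .Machine$integer.max
      cr <- clusterNoAdmixture(g, Ks[ki], burnin, sweeps, seed = s,
                               thin = thin)
      ll[ki, r] <- cr@meanLogLik
      results[[ki]][[r]] <- cr
    }
  }
  list(logLik = ll, results = results)
}

#' Evanno delta-K statistic
#'
#' The rate-of-change heuristic for choosing the number of clusters:
#' \eqn{\Delta K = |\bar L(K+1) - 2\bar L(K) + \bar L(K-1)| / \mathrm{sd}\,L(K)},
#' computed for every interior K of a table of per-run mean
#' log-likelihoods.  A replicate-constant L (zero standard deviation) is
#' flagged with an infinite \eqn{\Delta K} rather than an error.
#'
#' @param logLik numeric matrix of mean log-likelihoods, rows = K values
#'   (consecutive, rownames = K), columns = replicate runs.
#' @return data.frame with `K`, `meanL`, `sdL`, `curvature` (the absolute
#'   second difference of the mean likelihood) and `deltaK` (`NA` for the
#'   boundary K values).
#' @seealso [selectK()] for picking the peak, including the degenerate
#'   zero-variance case.
#' @export
evannoDeltaK <- function(logLik) {
  logLik <- as.matrix(logLik)
  if (nrow(logLik) < 3)
    stop("delta-K needs at least 3 consecutive K values")
  if (ncol(logLik) < 2)
    stop("delta-K needs at least 2 replicates per K")
  Ks <- as.integer(rownames(logLik))
  if (any(is.na(Ks))) Ks <- seq_len(nrow(logLik))
  if (any(diff(Ks) != 1L))
    stop("K values must be consecutive")
  meanL <- rowMeans(logLik)
  sdL <- apply(logLik, 1, stats::sd)
  curvature <- deltaK <- rep(NA_real_, length(Ks))
  for (i in seq_along(Ks)[-c(1, length(Ks))]) {
    curvature[i] <- abs(meanL[i + 1] - 2 * meanL[i] + meanL[i - 1])
    deltaK[i] <- if (sdL[i] == 0) {
      if (curvature[i] == 0) 0 else Inf
    } else curvature[i] / sdL[i]
  }
  data.frame(K = Ks, meanL = meanL, sdL = sdL, curvature = curvature,
             deltaK = deltaK, row.names = NULL)
}

#' Pick the number of clusters from a delta-K table
#'
#' The K with the largest \eqn{\Delta K}.  When replicate runs agree
#' exactly (zero standard deviation) at more than one K, every such K
#' has an infinite \eqn{\Delta K}; in the limit of equal vanishing
#' variance the \eqn{\Delta K} ordering reduces to the ordering of the
#' likelihood curvatures, so ties are broken by the largest absolute
#' second difference.
#'
#' @param dk result of [evannoDeltaK()].
#' @return the selected K (integer), or `NA` if no interior K is usable.
#' @export
selectK <- function(dk) {
  ok <- which(!is.na(dk$deltaK))
  if (!length(ok)) return(NA_integer_)
  best <- ok[order(-dk$deltaK[ok], -dk$curvature[ok])][1]
  dk$K[best]
}
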