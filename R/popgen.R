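# Diversity and differentiation statistics on codominant genotypes.
#
# All estimators handle missing data by per-locus exclusion: an individual
# missing a genotype at a locus simply does not contribute to that locus.

# per-group, per-locus summaries used by several estimators:
# counts of gene copies per allele, genotyped n, observed heterozygote
# frequency per allele
.locusGroupStats <- function(g, groups, locus) {
  a1 <- g@allele1[, locus]; a2 <- g@allele2[, locus]
  ok <- !is.na(a1)
  alleles <- sort(unique(c(a1[ok], a2[ok])))
  grps <- unique(groups)
  out <- lapply(grps, function(gr) {
    sel <- ok & groups == gr
    n <- sum(sel)
    counts <- stats::setNames(numeric(length(alleles)), alleles)
    het <- stats::setNames(numeric(length(alleles)), alleles)
    if (n > 0) {
      tab <- table(factor(c(a1[sel], a2[sel]), levels = alleles))
      counts[] <- as.numeric(tab)
      isHet <- a1[sel] != a2[sel]
      for (a in alleles[counts > 0]) {
        het[as.character(a)] <-
          sum(isHet & (a1[sel] == a | a2[sel] == a)) / n
      }
    }
    list(n = n, counts = counts, het = het)
  })
  names(out) <- grps
  attr(out, "alleles") <- alleles
  out
}

#' Unbiased gene diversity per group
#'
#' Nei's unbiased expected heterozygosity
#' \eqn{H_E = \frac{2n}{2n-1}\left(1 - \sum_a p_a^2\right)} per locus,
#' where \eqn{n} is the number of genotyped individuals; the multilocus
#' value is the mean over loci with data.
#'
#' @param g a [GenotypeMatrix-class].
#' @param groups character/factor of group labels, one per individual.
#' @return list with `perLocus` (groups x loci matrix of \eqn{H_E}) and
#'   `multilocus` (named vector of per-group means over loci).
#' @examples
#' g <- genotypeMatrix(matrix(c(1L, 2L), 2), matrix(c(1L, 2L), 2))
#' geneDiversity(g, c("a", "a"))$multilocus  # {AA, BB}: 4/3 * 0.5
#' @export
geneDiversity <- function(g, groups) {
  groups <- as.character(groups)
  stopifnot(length(groups) == nInd(g))
  grps <- unique(groups)
  he <- matrix(NA_real_, length(grps), nLoc(g),
               dimnames = list(grps, lociNames(g)))
  for (l in lociNames(g)) {
    st <- .locusGroupStats(g, groups, l)
    for (gr in grps) {
      n <- st[[gr]]$n
      if (n >= 1) {
        p <- st[[gr]]$counts / (2 * n)
        he[gr, l] <- if (n > 0) (2 * n / (2 * n - 1)) * (1 - sum(p^2)) else NA
      }
    }
  }
  bad <- rowSums(!is.na(he)) == 0
  if (any(bad))
    stop("group(s) with no genotyped individuals at any locus: ",
         paste(grps[bad], collapse = ", "))
  list(perLocus = he, multilocus = rowMeans(he, na.rm = TRUE))
}

#' Rarefied allelic richness per group
#'
#' Hypergeometric rarefaction of allele counts to a common number of gene
#' copies \eqn{g}:
#' \eqn{A_R = \sum_a \left[1 - \binom{N - N_a}{g} / \binom{N}{g}\right]},
#' where \eqn{N} is the total number of gene copies sampled in the group
#' at the locus and \eqn{N_a} the copies of allele \eqn{a}.
#'
#' @inheritParams geneDiversity
#' @param rarefyTo number of gene copies to rarefy to.  Default: twice
#'   the smallest per-group per-locus genotyped sample size across all
#'   analyzed groups and loci (the global minimum).
#' @return list with `perLocus` matrix, `multilocus` per-group means, and
#'   `rarefyTo` actually used.
#' @export
allelicRichness <- function(g, groups, rarefyTo = NULL) {
  groups <- as.character(groups)
  stopifnot(length(groups) == nInd(g))
  grps <- unique(groups)
  statsByLocus <- lapply(lociNames(g), function(l)
    .locusGroupStats(g, groups, l))
  names(statsByLocus) <- lociNames(g)
  if (is.null(rarefyTo)) {
    ns <- unlist(lapply(statsByLocus, function(st)
      vapply(st, function(x) x$n, 0)))
    rarefyTo <- 2L * min(ns)
  }
  if (rarefyTo < 2) stop("rarefyTo must be at least 2 gene copies")
  ar <- matrix(NA_real_, length(grps), nLoc(g),
               dimnames = list(grps, lociNames(g)))
  for (l in lociNames(g)) {
    st <- statsByLocus[[l]]
    for (gr in grps) {
      N <- 2 * st[[gr]]$n
      if (N >= rarefyTo) {
        Na <- st[[gr]]$counts
        Na <- Na[Na > 0]
        ar[gr, l] <- sum(1 - exp(lchoose(N - Na, rarefyTo) -
                                 lchoose(N, rarefyTo)))
      }
    }
  }
  list(perLocus = ar, multilocus = rowMeans(ar, na.rm = TRUE),
       rarefyTo = rarefyTo)
}

# Weir & Cockerham (1984) variance components per locus and allele.
# With r sampled groups, returns the summed components:
#   a (among groups), b (among individuals within groups),
#   c (within individuals)
# For r = 1 only b and c are defined (a = 0).
.wcComponents <- function(g, groups, locus) {
  st <- .locusGroupStats(g, groups, locus)
  alleles <- attr(st, "alleles")
  keep <- vapply(st, function(x) x$n >= 1, TRUE)
  st <- st[keep]
  r <- length(st)
  if (r == 0 || length(alleles) == 0)
    return(c(a = 0, b = 0, c = 0))
  n <- vapply(st, function(x) x$n, 0)
  if (r == 1) {
    nn <- n[1]
    if (nn < 2) return(c(a = 0, b = 0, c = 0))
    p <- st[[1]]$counts / (2 * nn)
    h <- st[[1]]$het
    b <- (nn / (nn - 1)) * (p * (1 - p) - (2 * nn - 1) / (4 * nn) * h)
    return(c(a = 0, b = sum(b), c = sum(h) / 2))
  }
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  aTot <- bTot <- cTot <- 0
  for (al in as.character(alleles)) {
    p <- vapply(st, function(x) x$counts[al] / (2 * x$n), 0)
    h <- vapply(st, function(x) x$het[al], 0)
    pbar <- sum(n * p) / (r * nbar)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    aTot <- aTot + a; bTot <- bTot + b; cTot <- cTot + cc
  }
  c(a = aTot, b = bTot, c = cTot)
}

#' Weir-Cockerham inbreeding coefficient per group
#'
#' The small-\eqn{f} estimator of Weir & Cockerham (1984), computed per
#' group from the within-group variance components and combined across
#' loci as a ratio of summed components:
#' \eqn{\hat f = 1 - \sum c / \sum (b + c)}.
#'
#' @inheritParams geneDiversity
#' @return named numeric vector of per-group multilocus \eqn{F_{IS}};
#'   `NaN` for a group monomorphic at every locus (flagged by warning).
#' @export
inbreedingCoefficient <- function(g, groups) {
  groups <- as.character(groups)
  stopifnot(length(groups) == nInd(g))
  grps <- unique(groups)
  out <- stats::setNames(numeric(length(grps)), grps)
  for (gr in grps) {
    sel <- groups == gr
    comp <- rowSums(vapply(lociNames(g), function(l)
      .wcComponents(g[sel, ], rep(gr, sum(sel)), l), c(a = 0, b = 0, c = 0)))
    denom <- comp["b"] + comp["c"]
    if (denom == 0) {
      warning("group '", gr, "' is monomorphic at every locus; ",
              "F_IS undefined")
      out[gr] <- NaN
    } else out[gr] <- unname(1 - comp["c"] / denom)
  }
  out
}

#' Weir-Cockerham \eqn{\theta} (FST)
#'
#' Multilocus and pairwise \eqn{\theta} of Weir & Cockerham (1984),
#' combining loci as the ratio of summed variance components
#' \eqn{\hat\theta = \sum a / \sum (a + b + c)}.  Negative multilocus
#' estimates are reported as computed, without truncation at zero.
#'
#' @inheritParams geneDiversity
#' @return list with `theta` (multilocus, all groups), `pairwise`
#'   (symmetric groups x groups matrix) and `components` (summed a, b, c).
#' @export
wcFst <- function(g, groups) {
  groups <- as.character(groups)
  stopifnot(length(groups) == nInd(g))
  grps <- unique(groups)
  if (length(grps) < 2) stop("at least two groups are required")
  nOk <- vapply(grps, function(gr) {
    sel <- groups == gr
    max(colSums(!is.na(g@allele1[sel, , drop = FALSE])))
  }, 0)
  if (any(nOk < 2))
    stop("group(s) with fewer than 2 genotyped individuals at every locus: ",
         paste(grps[nOk < 2], collapse = ", "))

  thetaOf <- function(sel, labs) {
    comp <- rowSums(vapply(lociNames(g), function(l)
      .wcComponents(g[sel, ], labs, l), c(a = 0, b = 0, c = 0)))
    denom <- sum(comp)
    list(theta = if (denom == 0) NaN else unname(comp["a"] / denom),
         components = comp)
  }
  all <- thetaOf(rep(TRUE, nInd(g)), groups)
  pw <- matrix(NA_real_, length(grps), length(grps),
               dimnames = list(grps, grps))
  diag(pw) <- 0
  if (length(grps) >= 2)
    for (i in seq_along(grps)[-1]) for (j in seq_len(i - 1)) {
      sel <- groups %in% grps[c(i, j)]
      pw[i, j] <- pw[j, i] <- thetaOf(sel, groups[sel])$theta
    }
  list(theta = all$theta, pairwise = pw, components = all$components)
}

#' Pairwise squared genotypic distances
#'
#' Codominant squared genotypic distance of Smouse & Peakall: per locus,
#' half the squared Euclidean distance between allele-count vectors
#' (identical genotypes 0; homozygote vs heterozygote sharing one allele
#' 1; two different homozygotes 4; no shared allele hom vs het 3; two
#' heterozygotes sharing one allele 1, sharing none 2), summed over loci.
#' Pairs with missing loci are compared over commonly genotyped loci and
#' rescaled to the full locus count.
#'
#' @param g a [GenotypeMatrix-class].
#' @return symmetric numeric matrix of summed squared distances.
#' @export
genotypicDistanceMatrix <- function(g) {
  n <- nInd(g); L <- nLoc(g)
  acc <- matrix(0, n, n)
  cnt <- matrix(0L, n, n)
  for (l in seq_len(L)) {
    a1 <- g@allele1[, l]; a2 <- g@allele2[, l]
    ok <- which(!is.na(a1))
    if (length(ok) < 2) next
    alleles <- sort(unique(c(a1[ok], a2[ok])))
    C <- matrix(0, length(ok), length(alleles))
    C[cbind(seq_along(ok), match(a1[ok], alleles))] <-
      C[cbind(seq_along(ok), match(a1[ok], alleles))] + 1
    C[cbind(seq_along(ok), match(a2[ok], alleles))] <-
      C[cbind(seq_along(ok), match(a2[ok], alleles))] + 1
    d2 <- 0.5 * as.matrix(stats::dist(C))^2
    acc[ok, ok] <- acc[ok, ok] + d2
    cnt[ok, ok] <- cnt[ok, ok] + 1L
  }
  offdiag <- cnt[upper.tri(cnt)]
  if (any(offdiag == 0))
    stop("some individual pairs share no genotyped locus")
  d <- acc * (L / cnt)
  diag(d) <- 0
  dimnames(d) <- list(individualNames(g), individualNames(g))
  d
}

#' Principal coordinate analysis of a squared-distance matrix
#'
#' Gower double-centering of the squared-distance matrix followed by
#' eigendecomposition.  Axes are ordered by decreasing eigenvalue and the
#' percent variance of an axis is its eigenvalue relative to the sum of
#' positive eigenvalues; negative eigenvalues are reported, not dropped.
#'
#' @param d2 symmetric matrix of squared distances with zero diagonal.
#' @param k number of axes to return (default: all with positive
#'   eigenvalue).
#' @return list with `coordinates` (n x k), `eigenvalues` (all n) and
#'   `percentVariance` per returned axis.
#' @export
pcoa <- function(d2, k = NULL) {
  d2 <- as.matrix(d2)
  if (max(abs(d2 - t(d2))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(abs(diag(d2)) > 1e-12)) stop("diagonal must be zero")
  n <- nrow(d2)
  G <- -0.5 * d2
  G <- sweep(G, 1, rowMeans(G))
  G <- sweep(G, 2, colMeans(G))   # leaves B = (I-11'/n)(-D2/2)(I-11'/n)
  ee <- eigen((G + t(G)) / 2, symmetric = TRUE)
  eig <- ee$values
  pos <- which(eig > max(eig) * 1e-12 & eig > 0)
  if (is.null(k)) k <- length(pos)
  k <- min(k, length(pos))
  coords <- ee$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(eig[pos[seq_len(k)]]), k)
  rownames(coords) <- rownames(d2)
  colnames(coords) <- paste0("Axis", seq_len(k))
  list(coordinates = coords, eigenvalues = eig,
       percentVariance = 100 * eig[pos[seq_len(k)]] / sum(eig[pos]))
}

#' Combined diversity summary table
#'
#' Convenience wrapper assembling per-group multilocus \eqn{H_E},
#' rarefied \eqn{A_R} and \eqn{F_{IS}} into one data.frame.
#'
#' @inheritParams allelicRichness
#' @return data.frame with one row per group.
#' @export
diversitySummary <- function(g, groups, rarefyTo = NULL) {
  he <- geneDiversity(g, groups)
  ar <- allelicRichness(g, groups, rarefyTo)
  fis <- inbreedingCoefficient(g, groups)
  data.frame(group = names(he$multilocus),
             HE = unname(he$multilocus),
             AR = unname(ar$multilocus[names(he$multilocus)]),
             FIS = unname(fis[names(he$multilocus)]),
             row.names = NULL)
}
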