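# Independent oracles used across the suite.  Each one is a deliberately
# plain, literal transcription of the published formulas (or a direct
# enumeration), kept free of any code shared with the package internals.

# Weir & Cockerham (1984) theta and small f, written exactly as the
# per-allele formulas read, looping over everything.  `a1`, `a2` are
# integer allele matrices (individuals x loci), `groups` a label vector.
wcOracle <- function(a1, a2, groups) {
  groups <- as.character(groups)
  sumA <- sumB <- sumC <- 0
  for (l in seq_len(ncol(a1))) {
    x1 <- a1[, l]; x2 <- a2[, l]
    ok <- !is.na(x1)
    pops <- unique(groups[ok])
    r <- length(pops)
    if (r < 2) next
    alleles <- unique(c(x1[ok], x2[ok]))
    n <- sapply(pops, function(p) sum(ok & groups == p))
    if (any(n < 1)) next
    nbar <- mean(n)
    if (nbar <= 1) next
    nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
    for (al in alleles) {
      p <- sapply(pops, function(pp) {
        sel <- ok & groups == pp
        (sum(x1[sel] == al) + sum(x2[sel] == al)) / (2 * sum(sel))
      })
      h <- sapply(pops, function(pp) {
        sel <- ok & groups == pp
        sum(x1[sel] != x2[sel] & (x1[sel] == al | x2[sel] == al)) / sum(sel)
      })
      pbar <- sum(n * p) / (r * nbar)
      s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n * h) / (r * nbar)
      a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
             (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
      b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) -
             ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
      cc <- hbar / 2
      sumA <- sumA + a; sumB <- sumB + b; sumC <- sumC + cc
    }
  }
  list(theta = sumA / (sumA + sumB + sumC),
       f = 1 - sumC / (sumB + sumC))
}

# single-population Weir-Cockerham small f, literal per-allele formulas
fisOracle <- function(a1, a2) {
  sumB <- sumC <- 0
  for (l in seq_len(ncol(a1))) {
    x1 <- a1[, l]; x2 <- a2[, l]
    ok <- !is.na(x1)
    n <- sum(ok)
    if (n < 2) next
    for (al in unique(c(x1[ok], x2[ok]))) {
      p <- (sum(x1[ok] == al) + sum(x2[ok] == al)) / (2 * n)
      h <- sum(x1[ok] != x2[ok] & (x1[ok] == al | x2[ok] == al)) / n
      b <- (n / (n - 1)) * (p * (1 - p) - ((2 * n - 1) / (4 * n)) * h)
      sumB <- sumB + b; sumC <- sumC + h / 2
    }
  }
  1 - sumC / (sumB + sumC)
}

# random small genotype instance for property tests
randomInstance <- function(nPops = 3, maxInd = 6, nLoci = 2,
                           maxAlleles = 4, missingProb = 0.1) {
  nInd <- sample(2:maxInd, nPops, replace = TRUE)
  groups <- rep(paste0("p", seq_len(nPops)), nInd)
  n <- sum(nInd)
  a1 <- matrix(sample.int(maxAlleles, n * nLoci, TRUE), n, nLoci)
  a2 <- matrix(sample.int(maxAlleles, n * nLoci, TRUE), n, nLoci)
  miss <- matrix(runif(n * nLoci) < missingProb, n, nLoci)
  # keep at least 2 genotyped individuals per pop and locus
  for (l in seq_len(nLoci)) for (p in unique(groups)) {
    sel <- which(groups == p)
    if (sum(!miss[sel, l]) < 2) miss[sel[1:2], l] <- FALSE
  }
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  colnames(a1) <- paste0("L", seq_len(nLoci))
  list(g = genotypeMatrix(a1, a2), groups = groups,
       a1 = a1, a2 = a2)
}

# exact collapsed posterior for 2 individuals, 1 locus, K = 2: the
# sequential Dirichlet(1) predictive, enumerated over assignments
enumTwoIndCoassignment <- function(g1, g2, J) {
  predictive <- function(genos) {
    counts <- numeric(J); N <- 0; pr <- 1
    for (g in genos) {
      x <- g[1]; y <- g[2]
      if (x == y)
        pr <- pr * (counts[x] + 1) * (counts[x] + 2) /
          ((N + J) * (N + J + 1))
      else
        pr <- pr * 2 * (counts[x] + 1) * (counts[y] + 1) /
          ((N + J) * (N + J + 1))
      counts[x] <- counts[x] + 1; counts[y] <- counts[y] + 1
      N <- N + 2
    }
    pr
  }
  pz <- c(together = predictive(list(g1, g2)),          # z = (1,1)
          apart = predictive(list(g1)) * predictive(list(g2)))
  # two labelled configurations each for together/apart; factors cancel
  pz["together"] / (pz["together"] + pz["apart"])
}

# direct class posterior for one focal individual given pinned pool
# frequencies: uniform class prior times the product over loci of the
# genotype likelihood, enumerated over origin categories
enumClassPosterior <- function(genotypes, pA, pB) {
  classes <- c("Pure_A", "Pure_B", "F1", "F2", "BC_A", "BC_B")
  lik <- sapply(classes, function(cl) {
    pr <- 1
    for (l in seq_along(genotypes))
      pr <- pr * classGenotypeLikelihood(genotypes[[l]], cl,
                                         pA[[l]], pB[[l]])
    pr
  })
  lik / sum(lik)
}

# brute-force minimum spanning tree weight over a component: tries all
# subsets of candidate edges of size n-1 (feasible for <= 6 nodes)
bruteMstWeight <- function(D) {
  n <- nrow(D)
  if (n < 2) return(0)
  edges <- which(upper.tri(D), arr.ind = TRUE)
  w <- D[edges]
  best <- Inf
  find <- function(i, par) { while (par[i] != i) i <- par[i]; i }
  for (sub in utils::combn(nrow(edges), n - 1, simplify = FALSE)) {
    parent <- seq_len(n)
    ok <- TRUE
    for (e in sub) {
      ri <- find(edges[e, 1], parent); rj <- find(edges[e, 2], parent)
      if (ri == rj) { ok <- FALSE; break }
      parent[ri] <- rj
    }
    if (ok) best <- min(best, sum(w[sub]))
  }
  best
}

# tiny deterministic alignment builder: mutate `steps` fresh positions
makeHapSeqs <- function(stepsFromRef, len = 40) {
  bases <- c("A", "C", "G", "T")
  ref <- rep("A", len)
  out <- list(ref = paste(ref, collapse = ""))
  pos <- 1
  for (nm in names(stepsFromRef)) {
    s <- ref
    k <- stepsFromRef[[nm]]
    if (k > 0) {
      s[pos:(pos + k - 1)] <- "C"
      pos <- pos + k
    }
    out[[nm]] <- paste(s, collapse = "")
  }
  out
}
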