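# Flowering-time statistics: among-individual synchrony (mean pairwise
# Pearson correlation of flowering curves), lineage-specific probability
# of hybrid formation under random mating, and stratified bootstrap
# confidence intervals.

#' Among-individual flowering synchrony (mean r)
#'
#' The mean of all pairwise Pearson correlation coefficients between
#' individual flowering curves (proportion of flowering stems per census).
#' Pairs in which either series has zero variance are excluded from the
#' mean and counted.
#'
#' @param s a [FloweringSchedule-class].
#' @param mode `within` (pairs sharing a lineage label, reported per
#'   lineage), `between` (only pairs from different lineages) or
#'   `overall` (all pairs).
#' @return list with `mode`, `meanR` (named per-lineage vector for
#'   `within`, otherwise a scalar), `nPairs` and `excludedPairs`
#'   (zero-variance pairs, same shape as `meanR`).
#' @export
floweringSynchrony <- function(s, mode = c("within", "between", "overall")) {
  mode <- match.arg(mode)
  stopifnot(methods::is(s, "FloweringSchedule"))
  v <- scheduleValues(s)
  if (ncol(v) < 3) stop("at least 3 censuses are required")
  lin <- as.character(lineageLabels(s))
  n <- nrow(v)
  # one pass: full pairwise correlation matrix; rows with zero variance
  # produce NA entries and are excluded pair-wise (and counted)
  C <- suppressWarnings(stats::cor(t(v)))
  up <- upper.tri(C)

  pairMask <- switch(mode,
    overall = matrix(TRUE, n, n),
    within = outer(lin, lin, "=="),
    between = outer(lin, lin, "!="))
  if (mode == "between" && length(unique(lin)) < 2)
    stop("between-lineage synchrony needs >= 2 lineages")

  summarise <- function(mask) {
    vals <- C[mask & up]
    usable <- sum(is.finite(vals))
    if (usable < 1) stop("no usable pairs (zero variance throughout)")
    c(meanR = mean(vals, na.rm = TRUE), nPairs = usable,
      excluded = sum(!is.finite(vals)))
  }
  if (mode == "within") {
    lins <- unique(lin)
    res <- vapply(lins, function(L)
      summarise(outer(lin == L, lin == L, "&")),
      c(meanR = 0, nPairs = 0, excluded = 0))
    colnames(res) <- lins
    list(mode = mode, meanR = res["meanR", ],
         nPairs = res["nPairs", ], excludedPairs = res["excluded", ])
  } else {
    res <- summarise(pairMask)
    list(mode = mode, meanR = unname(res["meanR"]),
         nPairs = unname(res["nPairs"]),
         excludedPairs = unname(res["excluded"]))
  }
}

#' Lineage-specific probability of hybrid formation
#'
#' Under random mating, the probability that a mating event of lineage
#' \eqn{i} at census \eqn{n} involves the other lineage \eqn{j} is the
#' frequency-weighted share of lineage \eqn{j} in the flowering pool,
#' \deqn{m_{ij}(n) = \frac{\bar x_j(n) N_j}{\bar x_i(n) N_i + \bar x_j(n) N_j},}
#' where \eqn{\bar x_i(n)} is the mean proportion of flowering stems over
#' individuals of lineage \eqn{i} and \eqn{N_i} the absolute number of
#' individuals of that lineage in the population (0 when the denominator
#' is 0).  The whole-season probability weights each census by lineage
#' \eqn{i}'s share of its own cumulative flowering:
#' \deqn{P_i = \sum_n \frac{\bar x_i(n)}{\sum_m \bar x_i(m)}\, m_{ij}(n).}
#'
#' @param s a [FloweringSchedule-class].
#' @param lineageI,lineageJ the two lineage labels to contrast.
#' @param Ni,Nj absolute numbers of individuals of each lineage assumed
#'   for the population.
#' @return list with `P` (named vector, one entry per lineage) and
#'   `perCensus` (data.frame of \eqn{\bar x} and \eqn{m} values).
#' @export
hybridFormationProbability <- function(s, lineageI, lineageJ, Ni, Nj) {
  stopifnot(methods::is(s, "FloweringSchedule"), Ni > 0, Nj > 0)
  lin <- as.character(lineageLabels(s))
  if (!lineageI %in% lin || !lineageJ %in% lin)
    stop("lineage label not present in schedule")
  v <- scheduleValues(s)
  xi <- colMeans(v[lin == lineageI, , drop = FALSE])
  xj <- colMeans(v[lin == lineageJ, , drop = FALSE])
  denom <- xi * Ni + xj * Nj
  mij <- ifelse(denom > 0, xj * Nj / denom, 0)
  mji <- ifelse(denom > 0, xi * Ni / denom, 0)
  PofI <- function(x, m) {
    tot <- sum(x)
    if (tot == 0) {
      warning("lineage never flowers; probability undefined")
      return(NaN)
    }
    sum(x / tot * m)
  }
  P <- c(PofI(xi, mij), PofI(xj, mji))
  names(P) <- c(lineageI, lineageJ)
  list(P = P,
       perCensus = data.frame(date = censusDates(s), xbar_i = xi,
                              xbar_j = xj, m_ij = mij, m_ji = mji,
                              row.names = NULL))
}

#' Stratified bootstrap confidence interval for a schedule statistic
#'
#' Resamples individuals with replacement within lineage strata, applies
#' `statistic` to each resampled schedule and returns a percentile
#' interval.  Resamples on which the statistic is undefined (error,
#' `NA`/`NaN`) are redrawn and counted.
#'
#' @param statistic function taking a [FloweringSchedule-class] and
#'   returning a numeric scalar or named vector.
#' @param s a [FloweringSchedule-class].
#' @param replicates number of bootstrap replicates (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#' @param maxRedraw cap on redraws of degenerate resamples.
#' @return list with `estimate`, `lower`, `upper`, `level`, `replicates`,
#'   `redraws` and `seed`.
#' @export
bootstrapCi <- function(statistic, s, replicates = 1000, level = 0.95,
                        seed = NULL, maxRedraw = 10 * replicates) {
  stopifnot(methods::is(s, "FloweringSchedule"), replicates >= 2)
  if (!is.null(seed)) set.seed(seed)
  est <- statistic(s)
  v <- scheduleValues(s)
  lin <- as.character(lineageLabels(s))
  strata <- split(seq_len(nrow(v)), lin)

  draws <- matrix(NA_real_, replicates, length(est))
  colnames(draws) <- names(est)
  redraws <- 0L
  r <- 1L
  while (r <= replicates) {
    idx <- unlist(lapply(strata, function(ix)
      ix[sample.int(length(ix), length(ix), replace = TRUE)]),
      use.names = FALSE)
    sb <- floweringSchedule(
      `rownames<-`(v[idx, , drop = FALSE],
                   make.unique(rownames(v)[idx])),
      censusDates(s), lin[idx])
    val <- tryCatch(suppressWarnings(statistic(sb)), error = function(e) NA)
    if (length(val) == length(est) && all(is.finite(val))) {
      draws[r, ] <- val
      r <- r + 1L
    } else {
      redraws <- redraws + 1L
      if (redraws > maxRedraw)
        stop("statistic undefined on too many bootstrap resamples")
    }
  }
  alpha <- (1 - level) / 2
  lower <- apply(draws, 2, stats::quantile, probs = alpha, names = FALSE)
  upper <- apply(draws, 2, stats::quantile, probs = 1 - alpha, names = FALSE)
  if (length(est) == 1) { lower <- unname(lower); upper <- unname(upper) }
  list(estimate = est, lower = lower, upper = upper, level = level,
       replicates = replicates, redraws = redraws, seed = seed)
}
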