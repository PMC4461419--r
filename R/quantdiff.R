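# Quantitative-trait analyses: one-way ANOVA with method-of-moments
# variance components and Tukey letters, correlation-matrix PCA, Fisher
# LDA with trait-posterior diagnostics, overdispersed-binomial GLMs, and
# PST divergence.

#' One-way ANOVA with method-of-moments variance components
#'
#' Standard one-way ANOVA plus the variance components needed for PST:
#' \eqn{\sigma^2_W = MS_W} and
#' \eqn{\sigma^2_B = (MS_B - MS_W)/n_0} with the unbalanced-design
#' coefficient \eqn{n_0 = (N - \sum_k n_k^2/N)/(K-1)}; a negative
#' between-group component is truncated at zero (the raw value is also
#' reported).
#'
#' @param values numeric response vector.
#' @param groups group labels, same length.
#' @return list with `F`, `p`, `df`, `MSB`, `MSW`, `n0`, `sigma2W`,
#'   `sigma2B` (truncated) and `sigma2B_raw`.
#' @export
anovaOneway <- function(values, groups) {
  groups <- factor(groups)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  if (nlevels(groups) < 2) stop("at least 2 groups are required")
  if (any(table(groups) < 2)) stop("at least 2 observations per group")
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  MSB <- tab["groups", "Mean Sq"]
  MSW <- tab["Residuals", "Mean Sq"]
  if (MSW <= (MSB + MSW) * 1e-12) {
    warning("zero within-group variance; F undefined")
    Fval <- NaN; p <- NaN
  } else {
    Fval <- tab["groups", "F value"]
    p <- tab["groups", "Pr(>F)"]
  }
  nk <- as.numeric(table(groups))
  N <- sum(nk); K <- length(nk)
  n0 <- (N - sum(nk^2) / N) / (K - 1)
  s2Braw <- (MSB - MSW) / n0
  list(F = Fval, p = p, df = c(between = K - 1, within = N - K),
       MSB = MSB, MSW = MSW, n0 = n0,
       sigma2W = MSW, sigma2B = max(0, s2Braw), sigma2B_raw = s2Braw,
       fit = fit)
}

#' Tukey HSD pairwise comparisons with compact letter display
#'
#' Studentized-range pairwise tests at level `alpha`; groups that share a
#' letter do not differ significantly.
#'
#' @inheritParams anovaOneway
#' @param alpha significance level for the letter display.
#' @return list with `comparisons` (the `TukeyHSD` table as data.frame)
#'   and `letters` (named character vector, groups ordered by decreasing
#'   mean).
#' @export
tukeyHsd <- function(values, groups, alpha = 0.05) {
  a <- anovaOneway(values, groups)
  th <- stats::TukeyHSD(a$fit, conf.level = 1 - alpha)$groups
  comp <- data.frame(comparison = rownames(th), th, row.names = NULL)
  groups <- droplevels(factor(groups[!is.na(values)]))
  means <- tapply(values[!is.na(values)], groups, mean)
  lv <- names(sort(means, decreasing = TRUE))
  sig <- comp$comparison[comp$`p.adj` < alpha]
  sigPairs <- strsplit(sig, "-", fixed = TRUE)
  letters <- .compactLetters(lv, sigPairs)
  list(comparisons = comp, letters = letters)
}

# insert-and-absorb compact letter display: `sigPairs` is a list of
# length-2 label vectors that must NOT share a letter
.compactLetters <- function(labels, sigPairs) {
  sets <- list(labels)
  for (pr in sigPairs) {
    newSets <- list()
    for (s in sets) {
      if (all(pr %in% s)) {
        newSets <- c(newSets, list(setdiff(s, pr[1])),
                     list(setdiff(s, pr[2])))
      } else newSets <- c(newSets, list(s))
    }
    # absorb subsets
    keep <- rep(TRUE, length(newSets))
    for (i in seq_along(newSets)) for (j in seq_along(newSets))
      if (i != j && keep[i] && keep[j] &&
          all(newSets[[i]] %in% newSets[[j]]) &&
          length(newSets[[i]]) < length(newSets[[j]])) keep[i] <- FALSE
    # drop duplicates
    sets <- unique(newSets[keep])
  }
  out <- stats::setNames(rep("", length(labels)), labels)
  for (k in seq_along(sets))
    out[sets[[k]]] <- paste0(out[sets[[k]]], letters[k])
  out
}

#' PST: phenotypic divergence from ANOVA variance components
#'
#' \deqn{P_{ST} = \frac{(c/h^2)\,\sigma^2_B}{(c/h^2)\,\sigma^2_B + 2\sigma^2_W}}
#' where \eqn{c} is the assumed proportion of the between-group variance
#' that is additive and \eqn{h^2} the narrow-sense heritability.  With
#' the conventional \eqn{c = 1}, \eqn{h^2 = 0.5} the statistic is
#' directly comparable to neutral \eqn{F_{ST}}.
#'
#' @param sigma2B,sigma2W between- and within-group variance components
#'   (e.g. from [anovaOneway()]).
#' @param c additive proportion of between-group variance (default 1).
#' @param h2 heritability (default 0.5); must be positive.
#' @return list with `pst`, `sigma2B`, `sigma2W`, `c`, `h2`.
#' @export
pst <- function(sigma2B, sigma2W, c = 1, h2 = 0.5) {
  if (h2 <= 0) stop("h2 must be positive")
  if (sigma2B < 0 || sigma2W < 0) stop("variance components must be >= 0")
  num <- (c / h2) * sigma2B
  val <- if (num == 0 && sigma2W == 0) NaN else num / (num + 2 * sigma2W)
  list(pst = val, sigma2B = sigma2B, sigma2W = sigma2W, c = c, h2 = h2)
}

#' PST of a trait column
#'
#' Convenience wrapper: one-way ANOVA variance components of `trait`
#' across `groups`, passed to [pst()].
#'
#' @param df trait data.frame (see [readTraitCsv()]).
#' @param trait trait column name.
#' @param groups grouping column name (default `lineage`).
#' @inheritParams pst
#' @return as [pst()], plus the `anova` component list.
#' @export
pstFromTrait <- function(df, trait, groups = "lineage", c = 1, h2 = 0.5) {
  a <- anovaOneway(df[[trait]], df[[groups]])
  out <- pst(a$sigma2B, a$sigma2W, c = c, h2 = h2)
  out$anova <- a[setdiff(names(a), "fit")]
  out
}

#' Correlation-matrix PCA of quantitative traits
#'
#' Traits are standardized to unit variance; constant traits are dropped
#' with a warning; complete cases only.
#'
#' @param df trait data.frame.
#' @param traits character vector of trait column names.
#' @return list with `scores`, `loadings`, `percentVariance` and
#'   `dropped` (constant traits).
#' @export
traitPca <- function(df, traits) {
  X <- as.matrix(df[, traits, drop = FALSE])
  cc <- stats::complete.cases(X)
  X <- X[cc, , drop = FALSE]
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped)) {
    warning("dropping constant trait(s): ", paste(dropped, collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  pr <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  pv <- 100 * pr$sdev^2 / sum(pr$sdev^2)
  list(scores = pr$x, loadings = pr$rotation, percentVariance = pv,
       dropped = dropped, completeCases = which(cc))
}

#' Linear discriminant analysis with trait-posterior diagnostics
#'
#' Fisher LDA on standardized traits with pooled covariance (via
#' `MASS::lda`); reports the resubstitution correct-classification rate
#' per group and, to identify diagnostic traits, the Pearson correlation
#' between each trait and the logit-transformed posterior of each group
#' (posteriors clipped away from 0/1 before the logit).
#'
#' @param df trait data.frame.
#' @param traits character vector of trait column names.
#' @param groups grouping column name (default `lineage`).
#' @return list with `posterior`, `predicted`, `correctRate` (per group
#'   and overall), `traitPosteriorCor` (traits x groups) and the fitted
#'   `lda` object.
#' @export
ldaClassify <- function(df, traits, groups = "lineage") {
  X <- as.matrix(df[, traits, drop = FALSE])
  grp <- factor(df[[groups]])
  cc <- stats::complete.cases(X) & !is.na(grp)
  X <- scale(X[cc, , drop = FALSE])
  grp <- droplevels(grp[cc])
  if (nlevels(grp) < 2) stop("at least 2 groups are required")
  fit <- tryCatch(MASS::lda(X, grouping = grp),
    error = function(e) {
      warning("singular pooled covariance; adding ridge jitter")
      MASS::lda(X + matrix(stats::rnorm(length(X), 0, 1e-6), nrow(X)),
                grouping = grp)
    })
  pred <- stats::predict(fit, X)
  perGroup <- vapply(levels(grp), function(g)
    mean(pred$class[grp == g] == g), 0)
  eps <- 1e-8
  lp <- stats::qlogis(pmin(pmax(pred$posterior, eps), 1 - eps))
  tpc <- stats::cor(X, lp)
  list(posterior = pred$posterior, predicted = pred$class,
       correctRate = c(perGroup, overall = mean(pred$class == grp)),
       traitPosteriorCor = tpc, lda = fit, groups = grp)
}

#' Overdispersed (quasibinomial) logistic regression on proportions
#'
#' Binomial-logit GLM fitted by iteratively reweighted least squares with
#' a quasibinomial variance function: the dispersion
#' \eqn{\phi = \chi^2_{Pearson}/df} scales all coefficient standard
#' errors.  Complete separation is flagged and finite estimates are
#' obtained by refitting with lightly weighted pseudo-observations that
#' shrink each group's logit toward zero.
#'
#' @param successes,totals integer vectors of successes (e.g. damaged
#'   capsules) and trials (total capsules).
#' @param groups group labels.
#' @return list with `coefficients` (estimate, SE, t, p), `dispersion`,
#'   `contrasts` (pairwise group differences on the logit scale),
#'   `separation` flag and the `glm` fit.
#' @export
quasibinomialGlm <- function(successes, totals, groups) {
  stopifnot(length(successes) == length(totals),
            length(groups) == length(totals), all(totals >= 1),
            all(successes >= 0), all(successes <= totals))
  grp <- factor(groups)
  dat <- data.frame(s = successes, f = totals - successes, grp = grp)
  fit <- stats::glm(cbind(s, f) ~ grp, family = stats::quasibinomial(),
                    data = dat)
  separation <- any(abs(stats::coef(fit)) > 15) ||
    any(fitted(fit) < 1e-10) || any(fitted(fit) > 1 - 1e-10)
  if (separation) {
    warning("complete separation detected; shrinking with pseudo-observations")
    aug <- rbind(dat, data.frame(s = 0.5, f = 0.5, grp = levels(grp)))
    w <- c(rep(1, nrow(dat)), rep(1e-3, nlevels(grp)))
    fit <- stats::glm(cbind(s, f) ~ grp, family = stats::quasibinomial(),
                      data = aug, weights = w)
  }
  sm <- summary(fit)
  phi <- sm$dispersion
  cf <- as.data.frame(sm$coefficients)
  names(cf) <- c("estimate", "se", "t", "p")

  # pairwise group contrasts on the logit scale
  lv <- levels(grp)
  V <- sm$cov.scaled
  beta <- stats::coef(fit)
  dfres <- fit$df.residual
  rows <- list()
  cfNames <- names(beta)
  colOf <- function(g) if (g == lv[1]) NULL else paste0("grp", g)
  for (i in seq_along(lv)[-length(lv)]) for (j in seq(i + 1, length(lv))) {
    L <- stats::setNames(numeric(length(beta)), cfNames)
    ci <- colOf(lv[i]); cj <- colOf(lv[j])
    if (!is.null(ci)) L[ci] <- -1
    if (!is.null(cj)) L[cj] <- L[cj] + 1
    estv <- sum(L * beta)
    se <- sqrt(drop(t(L) %*% V %*% L))
    tv <- estv / se
    rows[[length(rows) + 1]] <- data.frame(
      contrast = paste(lv[j], "-", lv[i]), estimate = estv, se = se,
      t = tv, p = 2 * stats::pt(-abs(tv), dfres))
  }
  list(coefficients = cf, dispersion = phi,
       contrasts = do.call(rbind, rows), separation = separation,
       glm = fit)
}
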