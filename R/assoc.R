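# Population statistics, the relatedness correction factor, the family
# statistics and their permutation p-values.

#' PhenotypeContrast: case/control contrast vector
#'
#' The score machinery behind every test compares affected and unaffected
#' individuals through the contrast \eqn{c = u - (n_c/n) 1} over phenotyped
#' individuals, the derivative-based contrast of the mean model
#' \eqn{E[z_i] = p + u_i r}.  The contrast sums to zero, takes value
#' \eqn{n_G/n} for cases and \eqn{-n_c/n} for controls, and is zero for
#' phenotype-missing individuals (they drop out of all statistics but still
#' anchor relatedness estimation).
#'
#' @param u Affection vector (1 = affected, 0 = unaffected, NA = missing),
#'   or a \linkS4class{PedigreeSet} / \linkS4class{PedGenotypes}.
#' @return A \code{PhenotypeContrast} object with slots \code{u},
#'   \code{contrast}, \code{n}, \code{nCase}, \code{nControl}.
#' @examples
#' ct <- phenotypeContrast(c(1, 1, 0, 0))
#' sum(ct@contrast)  # 0
#' @aliases PhenotypeContrast
#' @export
phenotypeContrast <- function(u) {
  if (is(u, "PedigreeSet") || is(u, "PedGenotypes")) u <- affection(u)
  u <- as.numeric(u)
  nCase <- sum(u == 1, na.rm = TRUE)
  nControl <- sum(u == 0, na.rm = TRUE)
  stopIf(nCase == 0, "no affected individuals: contrast undefined")
  stopIf(nControl == 0, "no unaffected individuals: contrast undefined")
  n <- nCase + nControl
  cvec <- ifelse(is.na(u), 0, u - nCase / n)
  new("PhenotypeContrast", u = u, contrast = cvec, n = n,
      nCase = nCase, nControl = nControl)
}

#' @export
setClass("PhenotypeContrast",
         representation(u = "numeric", contrast = "numeric", n = "numeric",
                        nCase = "numeric", nControl = "numeric"))

setValidity("PhenotypeContrast", function(object) {
  if (abs(sum(object@contrast)) > 1e-8) return("contrast must sum to zero")
  TRUE
})

#' AssocResult: one test statistic with its relatedness correction
#'
#' Slots: \code{test} (one of \code{"collapsing"}, \code{"wss"},
#' \code{"vt"}, \code{"single_marker"}), the population statistic
#' \code{statPop}, the correction factor \code{pCorr}, the family statistic
#' \code{statFam = statPop / pCorr}, the p-value and how it was obtained
#' (\code{"chi2_df1"} or \code{"permutation"} with \code{B} and
#' \code{seed}), a \code{degenerate} flag (constant indicator or zero
#' variance; such results carry p = 1), and an \code{extra} list (e.g. the
#' score \code{H} and its variance \code{Gamma} for the collapsing test, or
#' the maximizing MAF threshold for VT).
#'
#' @aliases AssocResult
#' @export
setClass("AssocResult",
         representation(test = "character", statPop = "numeric",
                        pCorr = "numeric", statFam = "numeric",
                        pValue = "numeric", pMethod = "character",
                        B = "integer", seed = "integer",
                        degenerate = "logical", extra = "list"))

setValidity("AssocResult", function(object) {
  if (length(object@pValue) == 1 &&
      (object@pValue < 0 || object@pValue > 1))
    return("pValue must lie in [0, 1]")
  if (!object@degenerate && length(object@statPop) == 1 &&
      is.finite(object@statPop) &&
      abs(object@statFam * object@pCorr - object@statPop) >
        1e-8 * max(1, abs(object@statPop)))
    return("statFam * pCorr must equal statPop")
  TRUE
})

setMethod("show", "AssocResult", function(object) {
  cat("AssocResult [", object@test, "]  T_pop = ",
      signif(object@statPop, 5), "  P_corr = ", signif(object@pCorr, 5),
      "  T_fam = ", signif(object@statFam, 5), "  p = ",
      format(object@pValue, digits = 4), " (", object@pMethod, ")",
      if (object@degenerate) "  [degenerate]" else "", "\n", sep = "")
})

newResult <- function(test, statPop, pCorr, pValue, pMethod,
                      B = NA_integer_, seed = NA_integer_,
                      degenerate = FALSE, extra = list()) {
  new("AssocResult", test = test, statPop = statPop, pCorr = pCorr,
      statFam = statPop / pCorr, pValue = pValue, pMethod = pMethod,
      B = as.integer(B), seed = as.integer(seed), degenerate = degenerate,
      extra = extra)
}

#' Relatedness correction factor
#'
#' \deqn{P_{corr} = \frac{n}{n_c n_G} c^T K c}
#' with \eqn{c} the case/control contrast and \eqn{K} the genetic
#' relationship matrix.  For unrelated, non-inbred individuals
#' (\eqn{K = I}) the quadratic form equals \eqn{n_c n_G / n} and
#' \eqn{P_{corr} = 1}, so the family statistics reduce to their
#' population-based counterparts.  Positive within-class relatedness pushes
#' \eqn{P_{corr}} above 1 (the uncorrected statistic is anticonservative);
#' balanced within-family contrasts push it below 1.
#'
#' @param contrast A \linkS4class{PhenotypeContrast} (or affection vector).
#' @param K A \linkS4class{RelatednessMatrix}, a plain matrix, or
#'   \code{NULL} for the identity.
#' @return The scalar correction factor.
#' @examples
#' correctionFactor(phenotypeContrast(c(1, 0)), diag(2))  # 1
#' @export
correctionFactor <- function(contrast, K = NULL) {
  if (!is(contrast, "PhenotypeContrast"))
    contrast <- phenotypeContrast(contrast)
  cvec <- contrast@contrast
  if (is.null(K)) {
    quad <- sum(cvec^2)
  } else {
    if (is(K, "RelatednessMatrix")) K <- relMatrix(K)
    stopIf(nrow(K) != length(cvec),
           "K dimension does not match the contrast")
    quad <- as.numeric(crossprod(cvec, K %*% cvec))
  }
  p <- contrast@n / (contrast@nCase * contrast@nControl) * quad
  stopIf(p <= 0,
         "correction factor is not positive: K is not positive ",
         "semidefinite on the contrast")
  p
}

#' Population-based collapsing test
#'
#' Score \eqn{H_C = c^T z = \frac{n_c n_G}{n} (\bar Z_A - \bar Z_G)} and
#' statistic
#' \deqn{T_C = \frac{n_c n_G}{n} \frac{(\bar Z_A - \bar Z_G)^2}{\sigma^2},}
#' where \eqn{\bar Z_A, \bar Z_G} are the carrier-indicator means in cases
#' and controls and \eqn{\sigma^2 = \hat p (1 - \hat p)} with the pooled
#' estimate \eqn{\hat p = \bar Z} (the null MLE; a GLS-weighted estimate
#' can be supplied through \code{pHat}).
#'
#' @param z A \linkS4class{CollapsedVector} or numeric 0/1 vector.
#' @param contrast A \linkS4class{PhenotypeContrast}.
#' @param pHat Optional override for the presence-probability estimate.
#' @return List with \code{H} (score), \code{stat} (\eqn{T_C}),
#'   \code{sigma2} and \code{degenerate}.
#' @export
collapsingTest <- function(z, contrast, pHat = NULL) {
  zv <- if (is(z, "CollapsedVector")) z@z else z
  stopIf(length(zv) != length(contrast@contrast),
         "z length does not match the contrast")
  if (is.null(pHat)) pHat <- mean(zv[!is.na(contrast@u)])
  sigma2 <- pHat * (1 - pHat)
  H <- sum(contrast@contrast * zv)
  if (sigma2 <= 0)
    return(list(H = H, stat = NA_real_, sigma2 = sigma2,
                degenerate = TRUE))
  w <- contrast@nCase * contrast@nControl / contrast@n
  list(H = H, stat = H^2 / (w * sigma2), sigma2 = sigma2,
       degenerate = FALSE)
}

#' Family-based collapsing test
#'
#' The relatedness-corrected collapsing statistic
#' \deqn{T_{CF} = \frac{H_C^2}{\Gamma} = \frac{T_C}{P_{corr}}, \qquad
#'   \Gamma = c^T K c \, \sigma^2,}
#' distributed as central chi-squared with 1 df under the null.  With
#' \eqn{K = I} it equals the population statistic exactly.
#'
#' @inheritParams collapsingTest
#' @param K Relationship matrix (see \code{\link{correctionFactor}});
#'   \code{NULL} for identity.
#' @return An \linkS4class{AssocResult}.  Degenerate input (constant
#'   indicator, \eqn{\Gamma = 0}) yields p = 1 and a degenerate flag.
#' @examples
#' ct <- phenotypeContrast(c(1, 1, 0, 0))
#' familyCollapsingTest(c(1, 0, 0, 0), ct, diag(4))
#' @export
familyCollapsingTest <- function(z, contrast, K = NULL, pHat = NULL) {
  pop <- collapsingTest(z, contrast, pHat = pHat)
  if (pop$degenerate)
    return(newResult("collapsing", NA_real_, 1, 1, "chi2_df1",
                     degenerate = TRUE, extra = list(H = pop$H)))
  pcorr <- correctionFactor(contrast, K)
  tfam <- pop$stat / pcorr
  gamma <- pop$sigma2 * pcorr * contrast@nCase * contrast@nControl /
    contrast@n
  newResult("collapsing", pop$stat, pcorr, chisq1P(tfam), "chi2_df1",
            extra = list(H = pop$H, Gamma = gamma))
}

#' Relatedness-corrected single-marker chi-squared test
#'
#' Applies the score/correction machinery to a single dosage vector:
#' \deqn{T = \frac{(c^T x / 2)^2}{c^T K c \; \hat p (1 - \hat p) / 2}}
#' with \eqn{\hat p} the allele frequency of the tested variant.  With
#' \eqn{K = I} this equals the classical allelic (2 x 2 allele table)
#' Pearson chi-squared.  Monomorphic variants are degenerate (p = 1).
#'
#' @param x Dosage vector for one variant.
#' @param contrast A \linkS4class{PhenotypeContrast}.
#' @param K Relationship matrix or \code{NULL} for identity.
#' @return An \linkS4class{AssocResult}.
#' @export
correctedSingleMarker <- function(x, contrast, K = NULL) {
  x <- ifelse(is.na(x), 0, x)
  keepMask <- !is.na(contrast@u)
  pHat <- sum(x[keepMask]) / (2 * sum(keepMask))
  if (pHat <= 0 || pHat >= 1)
    return(newResult("single_marker", NA_real_, 1, 1, "chi2_df1",
                     degenerate = TRUE))
  num <- (sum(contrast@contrast * x) / 2)^2
  w <- contrast@nCase * contrast@nControl / contrast@n
  tpop <- num / (w * pHat * (1 - pHat) / 2)
  pcorr <- correctionFactor(contrast, K)
  tfam <- tpop / pcorr
  newResult("single_marker", tpop, pcorr, chisq1P(tfam), "chi2_df1",
            extra = list(pHat = pHat))
}

#' Min-p empirical p-value across the variants of a region
#'
#' Computes the corrected single-marker chi-squared p-value for every
#' variant in the region, takes the minimum \eqn{P_{min}}, then permutes
#' the affection labels \code{B} times (recomputing every per-variant
#' statistic and the correction factor for each permuted label vector) and
#' reports the empirical p-value
#' \deqn{\hat p = \sum_{b} I(P_{min}^{(b)} \le P_{min}) / B.}
#'
#' @param x Dosage matrix or \linkS4class{PedGenotypes}.
#' @param contrast A \linkS4class{PhenotypeContrast}.
#' @param region Variant columns (default all).
#' @param K Relationship matrix or \code{NULL} for identity.
#' @param B Number of permutations (default 5000).
#' @param seed RNG seed for the permutations.
#' @return An \linkS4class{AssocResult} with \code{extra$pMin} and
#'   \code{extra$perVariant} (observed per-variant p-values).
#' @export
minpEmpirical <- function(x, contrast, region = NULL, K = NULL, B = 5000,
                          seed = NULL) {
  stopIf(B < 1, "B must be at least 1")
  X <- if (is(x, "PedGenotypes")) dosages(x) else x
  if (is.null(region)) region <- seq_len(ncol(X))
  X <- X[, region, drop = FALSE]
  X[is.na(X)] <- 0
  keepMask <- !is.na(contrast@u)
  pk <- colSums(X[keepMask, , drop = FALSE]) / (2 * sum(keepMask))
  poly <- pk > 0 & pk < 1
  stopIf(!any(poly), "no polymorphic variant to test in the region")
  X <- X[, poly, drop = FALSE]
  pk <- pk[poly]
  if (is(K, "RelatednessMatrix")) K <- relMatrix(K)

  w <- contrast@nCase * contrast@nControl / contrast@n
  halfVar <- pk * (1 - pk) / 2
  statsFor <- function(cvec, quad) {
    num <- (as.numeric(crossprod(X, cvec)) / 2)^2
    (num / halfVar) / quad
  }
  quadOf <- function(cvec) {
    if (is.null(K)) sum(cvec^2)
    else as.numeric(crossprod(cvec, K %*% cvec))
  }
  cobs <- contrast@contrast
  qobs <- quadOf(cobs)
  tObs <- statsFor(cobs, qobs)
  pObs <- chisq1P(tObs)
  pMin <- min(pObs)

  maybeSeed(seed)
  u <- contrast@u
  obsIdx <- which(!is.na(u))
  tMaxPerm <- numeric(B)
  for (b in seq_len(B)) {
    up <- u
    up[obsIdx] <- u[sample(obsIdx)]
    cp <- ifelse(is.na(up), 0, up - contrast@nCase / contrast@n)
    tMaxPerm[b] <- max(statsFor(cp, quadOf(cp)))
  }
  # P_min(b) <= P_min  <=>  max T(b) >= max T (same chi2_1 df throughout)
  emp <- sum(tMaxPerm >= max(tObs)) / B
  pcorr <- qobs / w  # n/(nc nG) * c'Kc
  newResult("single_marker", max(tObs) * pcorr, pcorr, pValue = emp,
            pMethod = "permutation", B = B,
            seed = if (is.null(seed)) NA_integer_ else seed,
            extra = list(pMin = pMin, perVariant = pObs))
}

#' Population weighted-sum (WSS) rank statistic
#'
#' Madsen-Browning rank sum: all individuals are ranked by their weighted
#' genetic score (midranks for ties), \eqn{x = \sum_{i \in cases}
#' rank(\gamma_i)} is standardized by its permutation-null mean
#' \eqn{n_c(n+1)/2} and variance \eqn{n_c n_G (n+1)/12}, and the squared
#' z-score is returned.
#'
#' @param score Numeric per-individual score (for example
#'   \code{wssScore(...)$score}).
#' @param contrast A \linkS4class{PhenotypeContrast}.
#' @return List with \code{stat} (\eqn{T_{WSS}}), \code{z}, and
#'   \code{degenerate}.
#' @export
wssTest <- function(score, contrast) {
  u <- contrast@u
  keep <- !is.na(u)
  sc <- score[keep]; uk <- u[keep]
  n <- length(sc)
  r <- rank(sc)  # midranks
  x <- sum(r[uk == 1])
  nc <- contrast@nCase; ng <- contrast@nControl
  mu <- nc * (n + 1) / 2
  v <- nc * ng * (n + 1) / 12
  z <- (x - mu) / sqrt(v)
  list(stat = z^2, z = z, degenerate = length(unique(sc)) == 1)
}

#' Population variable-threshold (VT) statistic
#'
#' For every candidate MAF threshold \eqn{t} the rare-variant carrier count
#' \eqn{C_i(t) = \sum_{k: maf_k \le t} x_{ik}} is scored against the
#' phenotype contrast, \eqn{z(t) = c^T C(t) / \sqrt{\widehat{Var}}} with
#' \eqn{\widehat{Var} = s^2(C(t)) \, c^T c}, and the statistic is the
#' maximum of \eqn{z(t)^2} over thresholds.  Its null distribution is not
#' chi-squared; use \code{\link{familyPermutationTest}} for p-values.
#'
#' @param x Dosage matrix or \linkS4class{PedGenotypes}.
#' @param contrast A \linkS4class{PhenotypeContrast}.
#' @param region Variant columns (default all).
#' @param upperBound Largest MAF considered (default 0.05).
#' @return List with \code{stat}, \code{threshold} (argmax), and the
#'   per-threshold z-scores.
#' @export
vtTest <- function(x, contrast, region = NULL, upperBound = 0.05,
                   maf = NULL) {
  X <- if (is(x, "PedGenotypes")) dosages(x) else x
  if (is.null(region)) region <- seq_len(ncol(X))
  thr <- vtThresholds(X, region, upperBound, maf = maf)
  stopIf(length(thr) == 0,
         "no candidate threshold: every MAF exceeds ", upperBound)
  CT <- vtCarrierCounts(X, region, thr, maf = maf)
  zsc <- vtZScores(CT, contrast)
  best <- which.max(zsc^2)
  list(stat = max(zsc^2), threshold = thr[best], z = zsc,
       thresholds = thr)
}

# Carrier-count matrix, one column per candidate threshold.
vtCarrierCounts <- function(X, region, thr, maf = NULL) {
  if (is.null(maf)) maf <- suppressWarnings(computeMaf(X, region))
  sub <- X[, region, drop = FALSE]
  sub[is.na(sub)] <- 0
  ct <- vapply(thr,
               function(t) rowSums(sub[, !is.na(maf) & maf <= t,
                                       drop = FALSE]),
               numeric(nrow(sub)))
  matrix(ct, nrow = nrow(sub))
}

vtZScores <- function(CT, contrast) {
  cvec <- contrast@contrast
  num <- as.numeric(crossprod(CT, cvec))
  v <- apply(CT, 2, var) * sum(cvec^2)
  z <- ifelse(v > 0, num / sqrt(v), 0)
  z
}

#' Family-based permutation test for the WSS and VT statistics
#'
#' The family statistic is \eqn{T_{fam} = T_{pop} / P_{corr}(u)}.  Because
#' both the Madsen-Browning weights and the correction factor depend on the
#' affection labels, each permutation redraws the labels, re-estimates the
#' weights from the permuted unaffected set (WSS), recomputes the population
#' statistic and the correction factor, and the p-value is
#' \eqn{(1 + \sum_b I(T_{fam}^{(b)} \ge T_{fam})) / (B + 1)}.
#' Permutations are unrestricted by default, matching a null in which
#' affection is exchangeable across the sample;
#' \code{within = "pedigree"} restricts label swaps to pedigrees for
#' sensitivity analyses, and \code{recomputePcorr = FALSE} freezes the
#' observed correction factor.
#'
#' @param test \code{"wss"} or \code{"vt"}.
#' @param x Dosage matrix or \linkS4class{PedGenotypes}.
#' @param contrast A \linkS4class{PhenotypeContrast}.
#' @param region Variant columns (default all).
#' @param K Relationship matrix or \code{NULL} for identity.
#' @param B Number of permutations (default 5000).
#' @param seed RNG seed.
#' @param mafThreshold Rare-variant cut-off for the WSS score (default 1:
#'   keep all supplied variants).
#' @param upperBound VT threshold upper bound (default 0.05).
#' @param maf Optional MAF override for rare filters and VT thresholds
#'   (as in \code{\link{collapseRegion}}).
#' @param within \code{"sample"} (default) or \code{"pedigree"}.
#' @param recomputePcorr Recompute \eqn{P_{corr}} per permutation
#'   (default \code{TRUE}).
#' @param ped Pedigree (needed for \code{within = "pedigree"} with matrix
#'   input).
#' @return An \linkS4class{AssocResult}.
#' @export
familyPermutationTest <- function(test = c("wss", "vt"), x, contrast,
                                  region = NULL, K = NULL, B = 5000,
                                  seed = NULL, mafThreshold = 1,
                                  upperBound = 0.05, maf = NULL,
                                  within = c("sample", "pedigree"),
                                  recomputePcorr = TRUE, ped = NULL) {
  test <- match.arg(test)
  within <- match.arg(within)
  stopIf(B < 1, "B must be at least 1")
  X <- if (is(x, "PedGenotypes")) dosages(x) else x
  if (is.null(ped) && is(x, "PedGenotypes")) ped <- pedigree(x)
  if (is.null(region)) region <- seq_len(ncol(X))
  if (is(K, "RelatednessMatrix")) K <- relMatrix(K)

  # label-independent precomputation: the dosage submatrix (WSS) and the
  # per-threshold carrier counts (VT) do not change across permutations
  if (test == "wss") {
    reg <- region
    if (mafThreshold < 1) {
      if (is.null(maf)) maf <- suppressWarnings(computeMaf(X, reg))
      reg <- reg[!is.na(maf) & maf <= mafThreshold]
      stopIf(length(reg) == 0, "no variant below the MAF threshold")
    }
    sub <- X[, reg, drop = FALSE]
    sub[is.na(sub)] <- 0
    nTot <- nrow(sub)
    popStat <- function(ct) {
      unaff <- which(!is.na(ct@u) & ct@u == 0)
      zeta <- (colSums(sub[unaff, , drop = FALSE]) + 1) /
        (2 * length(unaff) + 2)
      w <- sqrt(nTot * zeta * (1 - zeta))
      wssTest(as.numeric(sub %*% (1 / w)), ct)$stat
    }
  } else {
    thr <- vtThresholds(X, region, upperBound, maf = maf)
    stopIf(length(thr) == 0,
           "no candidate threshold: every MAF exceeds ", upperBound)
    CT <- vtCarrierCounts(X, region, thr, maf = maf)
    popStat <- function(ct) max(vtZScores(CT, ct)^2)
  }
  pcorrOf <- function(ct) {
    if (!recomputePcorr) return(pcorrObs)
    correctionFactor(ct, K)
  }
  pcorrObs <- correctionFactor(contrast, K)
  tObs <- popStat(contrast) / pcorrObs

  u <- contrast@u
  obsIdx <- which(!is.na(u))
  groups <- if (within == "pedigree") {
    stopIf(is.null(ped), "'ped' required for within-pedigree permutation")
    split(obsIdx, pedigree(ped)$pedigree[obsIdx])
  } else list(obsIdx)

  maybeSeed(seed)
  exceed <- 0L
  for (b in seq_len(B)) {
    up <- u
    for (g in groups) if (length(g) > 1) up[g] <- up[sample(g)]
    ct <- phenotypeContrast(up)
    tb <- popStat(ct) / pcorrOf(ct)
    if (tb >= tObs) exceed <- exceed + 1L
  }
  pval <- (1 + exceed) / (B + 1)
  newResult(test, tObs * pcorrObs, pcorrObs, pval, "permutation", B = B,
            seed = if (is.null(seed)) NA_integer_ else seed)
}
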