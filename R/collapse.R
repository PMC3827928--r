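# Region-level collapsing, Madsen-Browning weighting, variable thresholds
# and Mendelian-consistency checks.

#' CollapsedVector: per-individual rare-variant presence indicator
#'
#' Stores the carrier indicator \eqn{z_i \in \{0, 1\}} (1 when the
#' individual carries at least one minor allele at at least one collapsed
#' variant), the presence probability estimate \eqn{p = \bar z} and its
#' variance \eqn{\sigma^2 = p(1 - p)}, together with the MAF threshold and
#' variant indices that defined the collapse.
#'
#' @aliases CollapsedVector
#' @export
setClass("CollapsedVector",
         representation(z = "numeric", p = "numeric", sigma2 = "numeric",
                        threshold = "numeric", variants = "integer"))

setValidity("CollapsedVector", function(object) {
  if (!all(object@z %in% c(0, 1) | is.na(object@z)))
    return("z must be 0/1 or NA")
  if (object@p < 0 || object@p > 1) return("p must lie in [0, 1]")
  if (abs(object@sigma2 - object@p * (1 - object@p)) > 1e-12)
    return("sigma2 must equal p (1 - p)")
  TRUE
})

setMethod("show", "CollapsedVector", function(object) {
  cat("CollapsedVector: n =", length(object@z),
      " carriers =", sum(object@z),
      " p =", signif(object@p, 4),
      " (MAF <=", object@threshold, ",",
      length(object@variants), "variants)\n")
})

#' Minor allele frequencies
#'
#' \eqn{maf_k = \min(f_k, 1 - f_k)} where \eqn{f_k} is the counted-allele
#' frequency over non-missing genotypes.  Variants with all genotypes
#' missing get \code{NA} with a warning.
#'
#' @param x Dosage matrix (n x m) or \linkS4class{PedGenotypes}.
#' @param variants Optional integer vector of variant columns (default all).
#' @return Named numeric vector of MAFs.
#' @examples
#' computeMaf(matrix(c(0, 0, 1), 3, 1))  # 1/6
#' @export
computeMaf <- function(x, variants = NULL) {
  X <- if (is(x, "PedGenotypes")) dosages(x) else x
  if (!is.null(variants)) X <- X[, variants, drop = FALSE]
  nObs <- colSums(!is.na(X))
  f <- colSums(X, na.rm = TRUE) / (2 * nObs)
  if (any(nObs == 0)) {
    warning(sum(nObs == 0), " variant(s) with all genotypes missing; ",
            "MAF undefined")
    f[nObs == 0] <- NA_real_
  }
  pmin(f, 1 - f)
}

#' Collapse rare variants in a region into a carrier indicator
#'
#' Variants with MAF less than or equal to \code{mafThreshold} are retained
#' and the indicator \eqn{z_i = 1} iff individual \eqn{i} carries at least
#' one minor allele across them.  Missing dosages count as zero copies
#' (non-carrier) by default, which keeps the indicator defined for every
#' individual; \code{missingAction = "drop"} instead removes individuals
#' with any missing genotype in the region (their \code{z} is \code{NA}).
#'
#' @param x Dosage matrix or \linkS4class{PedGenotypes}.
#' @param region Integer vector of variant columns forming the region
#'   (default: all columns).
#' @param mafThreshold Inclusive MAF cut-off for "rare" (default 0.01).
#' @param missingAction \code{"zero"} (default) or \code{"drop"}.
#' @param maf Optional per-variant MAF vector (one entry per column of the
#'   region) used for the rare filter instead of frequencies computed from
#'   the full sample -- e.g. frequencies estimated in unaffected
#'   individuals, which avoids dropping causal variants whose sample
#'   frequency is inflated by ascertainment.
#' @return A \linkS4class{CollapsedVector}.
#' @examples
#' X <- matrix(c(0, 1, 0, 0, 0, 0), 3, 2)
#' collapseRegion(X, mafThreshold = 0.5)
#' @export
collapseRegion <- function(x, region = NULL, mafThreshold = 0.01,
                           missingAction = c("zero", "drop"), maf = NULL) {
  missingAction <- match.arg(missingAction)
  X <- if (is(x, "PedGenotypes")) dosages(x) else x
  if (is.null(region)) region <- seq_len(ncol(X))
  if (is.null(maf)) maf <- suppressWarnings(computeMaf(X, region))
  stopIf(length(maf) != length(region),
         "'maf' must have one entry per region variant")
  keep <- region[!is.na(maf) & maf <= mafThreshold]
  stopIf(length(keep) == 0,
         "nothing to collapse: no variant with MAF <= ", mafThreshold,
         " in the region")
  sub <- X[, keep, drop = FALSE]
  if (missingAction == "zero") {
    sub[is.na(sub)] <- 0
    z <- as.numeric(rowSums(sub >= 1) > 0)
  } else {
    z <- as.numeric(rowSums(sub >= 1) > 0)
    z[rowSums(is.na(sub)) > 0] <- NA_real_
  }
  p <- mean(z, na.rm = TRUE)
  new("CollapsedVector", z = z, p = p, sigma2 = p * (1 - p),
      threshold = mafThreshold, variants = as.integer(keep))
}

#' Madsen-Browning weighted genetic score
#'
#' Frequency-inverse weights estimated from unaffected individuals with a
#' pseudo-count: \eqn{\zeta_k = (m_k^U + 1) / (2 n_U + 2)} where
#' \eqn{m_k^U} is the minor-allele count among unaffected individuals, the
#' weight is \eqn{w_k = \sqrt{n \zeta_k (1 - \zeta_k)}}, and the
#' per-individual score is \eqn{\gamma_i = \sum_k x_{ik} / w_k} over the
#' retained variants (MAF below \code{mafThreshold}; set it to 1 to keep
#' all).  Because the weights depend only on the unaffected genotypes, the
#' resulting rank-sum test requires permutation p-values.
#'
#' @param x Dosage matrix or \linkS4class{PedGenotypes}.
#' @param u Affection vector (1/0/NA); defaults to the pedigree's.
#' @param region Variant columns (default all).
#' @param mafThreshold Inclusive MAF cut-off (default 1, keep everything,
#'   since rare-variant filtering is usually applied upstream).
#' @param maf Optional MAF override (as in \code{\link{collapseRegion}}).
#' @return A list with \code{score} (\eqn{\gamma_i}), \code{weights}
#'   (\eqn{w_k}) and \code{variants} (retained columns).
#' @export
wssScore <- function(x, u = NULL, region = NULL, mafThreshold = 1,
                     maf = NULL) {
  X <- if (is(x, "PedGenotypes")) dosages(x) else x
  if (is.null(u) && is(x, "PedGenotypes")) u <- affection(x)
  stopIf(is.null(u), "affection vector 'u' required for matrix input")
  if (is.null(region)) region <- seq_len(ncol(X))
  if (mafThreshold < 1) {
    if (is.null(maf)) maf <- suppressWarnings(computeMaf(X, region))
    region <- region[!is.na(maf) & maf <= mafThreshold]
    stopIf(length(region) == 0, "no variant below the MAF threshold")
  }
  sub <- X[, region, drop = FALSE]
  sub[is.na(sub)] <- 0
  unaff <- which(!is.na(u) & u == 0)
  stopIf(length(unaff) == 0,
         "weights undefined: no unaffected individuals")
  nU <- length(unaff)
  mU <- colSums(sub[unaff, , drop = FALSE])
  zeta <- (mU + 1) / (2 * nU + 2)
  w <- sqrt(nrow(sub) * zeta * (1 - zeta))
  list(score = as.numeric(sub %*% (1 / w)), weights = w,
       variants = as.integer(region))
}

#' Candidate thresholds for the variable-threshold test
#'
#' Sorted unique observed MAFs at or below \code{upperBound}; each value
#' defines one candidate collapsing set ("all variants at least this rare").
#'
#' @param x Dosage matrix or \linkS4class{PedGenotypes}.
#' @param region Variant columns (default all).
#' @param upperBound Largest MAF considered (default 0.05).
#' @param maf Optional MAF override (as in \code{\link{collapseRegion}}).
#' @return Sorted numeric vector (possibly empty).
#' @export
vtThresholds <- function(x, region = NULL, upperBound = 0.05, maf = NULL) {
  X <- if (is(x, "PedGenotypes")) dosages(x) else x
  if (is.null(region)) region <- seq_len(ncol(X))
  if (is.null(maf)) maf <- suppressWarnings(computeMaf(X, region))
  maf <- maf[!is.na(maf) & maf > 0 & maf <= upperBound]
  sort(unique(maf))
}

#' Mendelian-consistency check for genotyped trios
#'
#' Flags (individual, variant) pairs whose dosage is impossible given both
#' parents' dosages under Mendelian transmission (for example parents 0/0
#' with a carrier child).  Only trios with both parents genotyped at the
#' variant are checked.  Downstream, flagged genotypes are typically set to
#' missing; this function only detects.
#'
#' @param x A \linkS4class{PedGenotypes}, or a dosage matrix plus a
#'   \code{ped} \linkS4class{PedigreeSet}.
#' @param ped Pedigree when \code{x} is a matrix.
#' @return A \code{data.frame} with columns \code{individual},
#'   \code{variant}, \code{child}, \code{father}, \code{mother} (dosages).
#' @export
mendelCheck <- function(x, ped = NULL) {
  X <- if (is(x, "PedGenotypes")) dosages(x) else x
  if (is.null(ped) && is(x, "PedGenotypes")) ped <- pedigree(x)
  pd <- pedigree(ped)
  idx <- seq_len(nrow(pd))
  names(idx) <- pd$id
  out <- list()
  kids <- which(!is.na(pd$father) & !is.na(pd$mother))
  for (i in kids) {
    f <- idx[pd$father[i]]; m <- idx[pd$mother[i]]
    xc <- X[i, ]; xf <- X[f, ]; xm <- X[m, ]
    ok <- !is.na(xc) & !is.na(xf) & !is.na(xm)
    bad <- ok & !mendelCompatible(xc, xf, xm)
    if (any(bad)) {
      out[[length(out) + 1L]] <- data.frame(
        individual = pd$id[i], variant = colnames(X)[bad],
        child = xc[bad], father = xf[bad], mother = xm[bad],
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  if (length(out) == 0)
    return(data.frame(individual = character(0), variant = character(0),
                      child = numeric(0), father = numeric(0),
                      mother = numeric(0)))
  do.call(rbind, out)
}

# Vectorized trio compatibility: the child dosage must be expressible as one
# allele from each parent (parent dosage 0 -> {0}, 1 -> {0, 1}, 2 -> {1}).
mendelCompatible <- function(child, father, mother) {
  loF <- ifelse(father == 2, 1, 0); hiF <- ifelse(father == 0, 0, 1)
  loM <- ifelse(mother == 2, 1, 0); hiM <- ifelse(mother == 0, 0, 1)
  child >= loF + loM & child <= hiF + hiM
}
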