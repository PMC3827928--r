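# Genetic relationship matrices: genotype-based estimation, pedigree
# recursion, and the joint kinship/allele-frequency iteration.

# Per-variant mean imputation of missing dosages (kinship estimation only).
imputeMean <- function(X) {
  if (!anyNA(X)) return(X)
  mu <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  X[idx] <- mu[idx[, 2]]
  X
}

#' Estimate the genetic relationship matrix from genotypes
#'
#' Computes the genotype-based genetic relationship matrix \eqn{K} whose
#' off-diagonal entries are
#' \deqn{K_{ij} = \frac{1}{m}\sum_k \frac{(x_{ik}-2p_k)(x_{jk}-2p_k)}
#'   {2p_k(1-p_k)}}
#' and whose diagonal is
#' \deqn{K_{ii} = 1 + \frac{1}{m}\sum_k \frac{x_{ik}^2-(1+2p_k)x_{ik}+2p_k^2}
#'   {2p_k(1-p_k)},}
#' with \eqn{p_k} the reference (counted) allele frequency.  Off-diagonal
#' entries estimate twice the kinship coefficient and the diagonal estimates
#' one plus the inbreeding coefficient.  Rare variants make these estimates
#' unstable, so only variants with minor allele frequency at least
#' \code{mafBound} are used.  Missing dosages are mean-imputed per variant.
#'
#' @param x Numeric n x m dosage matrix (individuals by variants) or a
#'   \linkS4class{PedGenotypes}.
#' @param freq Optional per-variant allele frequencies for the counted
#'   allele; defaults to the observed pooled frequencies.  Frequencies of 0
#'   or 1 are an error.
#' @param mafBound Minimum minor allele frequency for a variant to enter the
#'   estimate (default 0.05).
#' @param ... Passed to the matrix method.
#' @return A \linkS4class{RelatednessMatrix} with method
#'   \code{"estimated"}.
#' @examples
#' X <- matrix(rbinom(200, 2, 0.3), 10, 20)
#' grmEstimate(X)
#' @export
setMethod("grmEstimate", "matrix", function(x, freq = NULL, mafBound = 0.05,
                                            ...) {
  X <- imputeMean(x)
  if (is.null(freq)) freq <- colMeans(X) / 2
  stopIf(length(freq) != ncol(X),
         "'freq' must have one entry per variant")
  keep <- pmin(freq, 1 - freq) >= mafBound
  stopIf(!any(keep), "no variants left after MAF >= ", mafBound,
         " filtering")
  bad <- keep & (freq <= 0 | freq >= 1)
  if (any(bad)) {
    nm <- colnames(X)[bad]
    if (is.null(nm)) nm <- which(bad)
    stop("allele frequency 0 or 1 for variant(s): ",
         paste(head(nm, 5), collapse = ", "), call. = FALSE)
  }
  X <- X[, keep, drop = FALSE]
  p <- freq[keep]
  m <- ncol(X)
  den <- 2 * p * (1 - p)
  W <- sweep(X, 2, 2 * p)
  W <- sweep(W, 2, sqrt(den), "/")
  K <- tcrossprod(W) / m
  # the diagonal uses its own estimator, not the squared centred dosage
  diagK <- 1 + colMeans((t(X)^2 - (1 + 2 * p) * t(X) + 2 * p^2) / den)
  diag(K) <- diagK
  dimnames(K) <- list(rownames(x), rownames(x))
  RelatednessMatrix(K, method = "estimated", freq = p)
})

#' @rdname grmEstimate
#' @export
setMethod("grmEstimate", "PedGenotypes", function(x, freq = NULL,
                                                  mafBound = 0.05, ...) {
  grmEstimate(dosages(x), freq = freq, mafBound = mafBound)
})

#' Pedigree-theoretical kinship matrix
#'
#' Standard recursive kinship: founders have \eqn{\phi_{ii} = 1/2} and are
#' mutually unrelated; for a non-founder \eqn{i} with parents \eqn{f,m},
#' \eqn{\phi_{ij} = (\phi_{fj} + \phi_{mj})/2} for \eqn{j} not a descendant,
#' and \eqn{\phi_{ii} = (1 + \phi_{fm})/2}.  The returned relationship
#' matrix has \eqn{K_{ij} = 2\phi_{ij}} off the diagonal and
#' \eqn{K_{ii} = 1 + h_i} with inbreeding \eqn{h_i = 2\phi_{ii} - 1}.
#' Individuals in different pedigrees have entry zero.
#'
#' @param x A \linkS4class{PedigreeSet}.
#' @param ... Unused.
#' @return A \linkS4class{RelatednessMatrix} with method
#'   \code{"theoretical"}.
#' @examples
#' ped <- PedigreeSet(data.frame(pedigree = "F", id = c("f", "m", "c"),
#'   father = c(NA, NA, "f"), mother = c(NA, NA, "m"), sex = c(1, 2, 1),
#'   affection = NA))
#' relMatrix(pedigreeKinship(ped))
#' @export
setMethod("pedigreeKinship", "PedigreeSet", function(x, ...) {
  ped <- pedigree(x)
  n <- nrow(ped)
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (fam in split(seq_len(n), ped$pedigree)) {
    sub <- ped[fam, , drop = FALSE]
    phi <- kinshipRecursion(sub)
    Kb <- 2 * phi
    diag(Kb) <- 2 * diag(phi)  # = 1 + h
    K[fam, fam] <- Kb
  }
  RelatednessMatrix(K, method = "theoretical")
})

# Kinship recursion for one pedigree; returns the phi matrix
# (phi_ii = (1 + h_i)/2).
kinshipRecursion <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  fa <- idx[ped$father]; mo <- idx[ped$mother]
  ord <- pedOrder(ped)
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in ord) {
    if (is.na(fa[i]) && is.na(mo[i])) {
      phi[i, i] <- 0.5
    } else {
      f <- fa[i]; m <- mo[i]
      phifm <- if (is.na(f) || is.na(m)) 0 else phi[f, m]
      phi[i, i] <- 0.5 * (1 + phifm)
      prev <- ord[seq_len(which(ord == i) - 1)]
      for (j in prev) {
        v <- 0
        if (!is.na(f)) v <- v + phi[f, j]
        if (!is.na(m)) v <- v + phi[m, j]
        phi[i, j] <- phi[j, i] <- v / 2
      }
    }
  }
  phi
}

#' Best linear unbiased estimate of an allele frequency under relatedness
#'
#' Generalized-least-squares estimate of the allele frequency from a dosage
#' vector whose covariance is proportional to the relationship matrix
#' \eqn{K}: \eqn{\hat p = (1^T K^{-1} 1)^{-1} (1^T K^{-1} x) / 2}.  With
#' \eqn{K = I} this reduces to half the sample mean.  Estimates are clipped
#' to \eqn{[1/(2n+2), 1 - 1/(2n+2)]} so that downstream denominators of the
#' form \eqn{2p(1-p)} stay positive even for monomorphic samples.
#'
#' @param x Dosage vector (missing values mean-imputed), or an n x m matrix
#'   to estimate all variants at once.
#' @param K A \linkS4class{RelatednessMatrix} or plain matrix.  Near-singular
#'   matrices are ridge-regularized by \code{ridge} times the identity.
#' @param ridge Ridge added when the condition number exceeds 1e10.
#' @return Estimated frequency (vector of length m for matrix input).
#' @examples
#' blueAlleleFreq(c(0, 1, 2), diag(3))
#' @export
blueAlleleFreq <- function(x, K, ridge = 1e-6) {
  if (is(K, "RelatednessMatrix")) K <- relMatrix(K)
  X <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  X <- imputeMean(X)
  n <- nrow(X)
  stopIf(nrow(K) != n, "dimension mismatch between x and K")
  kap <- tryCatch(kappa(K, exact = FALSE), error = function(e) Inf)
  if (!is.finite(kap) || kap > 1e10) K <- K + diag(ridge, n)
  sol <- tryCatch(solve(K, cbind(1, X)), error = function(e)
    stop("relationship matrix is singular even after regularization",
         call. = FALSE))
  denom <- sum(sol[, 1])
  stopIf(abs(denom) < .Machine$double.eps,
         "degenerate GLS weights in allele-frequency estimation")
  p <- as.numeric(colSums(sol[, -1, drop = FALSE])) / (2 * denom)
  clip(p, 1 / (2 * n + 2), 1 - 1 / (2 * n + 2))
}

#' Joint iterative estimation of kinship and allele frequencies
#'
#' When reference allele frequencies are unavailable they must be estimated
#' from the pedigree members themselves, but the naive pooled frequency
#' ignores relatedness while the relatedness estimate needs frequencies.
#' The iteration starts from the observed pooled frequencies (step 1),
#' estimates \eqn{K} from common variants, then alternates a
#' generalized-least-squares frequency update given \eqn{K} (all variants)
#' with a relationship-matrix update given the frequencies (common variants)
#' until the largest frequency change falls below \code{tol} or
#' \code{maxIter} is reached.
#'
#' @param x Dosage matrix (n x m) or \linkS4class{PedGenotypes}.
#' @param mafBound Common-variant MAF bound for the relationship update
#'   (default 0.05).
#' @param maxIter Iteration limit (default 20).
#' @param tol Convergence tolerance on
#'   \eqn{\max_k |\hat p_k^{(s+1)} - \hat p_k^{(s)}|}.  The default
#'   (\code{NULL}) adapts to the sampling-noise floor of the GLS update,
#'   a quarter of the typical frequency standard error
#'   \eqn{0.25\sqrt{\bar p(1-\bar p)/(2n)}}: frequency changes below that
#'   level are statistically meaningless, and insisting on a fixed small
#'   tolerance (say 1e-4) merely runs into the iteration cap.
#' @return A list with elements \code{K} (\linkS4class{RelatednessMatrix}),
#'   \code{freq} (frequency vector for every input variant),
#'   \code{iterations}, \code{converged}, \code{lastDelta} and
#'   \code{tol} (the tolerance actually applied).  Non-convergence warns
#'   and sets \code{converged = FALSE} rather than failing.
#' @export
iterateKinshipFreq <- function(x, mafBound = 0.05, maxIter = 20,
                               tol = NULL) {
  X <- if (is(x, "PedGenotypes")) dosages(x) else x
  X <- imputeMean(X)
  p <- colMeans(X) / 2
  n <- nrow(X)
  p <- clip(p, 1 / (2 * n + 2), 1 - 1 / (2 * n + 2))
  common <- pmin(p, 1 - p) >= mafBound
  stopIf(!any(common), "no common variants (MAF >= ", mafBound,
         ") for kinship estimation")
  if (is.null(tol))
    tol <- 0.25 * sqrt(mean(p * (1 - p)) / (2 * n))
  K <- grmEstimate(X[, common, drop = FALSE], freq = p[common],
                   mafBound = mafBound)
  iter <- 0L
  converged <- FALSE
  delta <- NA_real_
  while (iter < maxIter) {
    iter <- iter + 1L
    pNew <- blueAlleleFreq(X, K)
    delta <- max(abs(pNew - p))
    p <- pNew
    common <- pmin(p, 1 - p) >= mafBound
    K <- grmEstimate(X[, common, drop = FALSE], freq = p[common],
                     mafBound = mafBound)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("kinship/frequency iteration did not converge in ", maxIter,
            " iterations")
  list(K = K, freq = p, iterations = iter, converged = converged,
       lastDelta = delta, tol = tol)
}

#' Relatedness correction factor straight from marker genotypes
#'
#' Computes \eqn{P_{corr} = \frac{n}{n_c n_G} c^T K c} for the
#' genotype-estimated relationship matrix without materializing the n x n
#' matrix.  Because the contrast \eqn{c} sums to zero, the off-diagonal
#' (cross-product) part reduces to
#' \eqn{c^T W W^T c / m = \frac{1}{m}\sum_k (X^T c)_k^2 / (2p_k(1-p_k))},
#' and the diagonal correction is a single matrix-vector product.  This is
#' algebraically identical to \code{correctionFactor(contrast,
#' grmEstimate(X))} (see the package tests) at a fraction of the cost, which
#' matters inside replicate loops.
#'
#' @param X Marker dosage matrix (n x m), complete (no missing values).
#' @param contrast A \linkS4class{PhenotypeContrast}.
#' @param freq Optional counted-allele frequencies; default observed pooled.
#' @param keep Optional logical mask of columns to use (e.g. realized MAF at
#'   least 0.05); avoids copying a large matrix to subset it.
#' @return The scalar correction factor.
#' @export
grmCorrectionFactor <- function(X, contrast, freq = NULL, keep = NULL) {
  p <- if (is.null(freq)) colMeans(X) / 2 else freq
  cvec <- contrast@contrast
  stopIf(length(cvec) != nrow(X), "contrast length must equal nrow(X)")
  if (is.null(keep)) keep <- rep(TRUE, ncol(X))
  m <- sum(keep)
  stopIf(m == 0, "no marker left after filtering")
  pk <- p[keep]
  stopIf(any(pk <= 0 | pk >= 1), "allele frequency 0 or 1 among kept markers")
  den <- 2 * pk * (1 - pk)
  v <- as.numeric(crossprod(X, cvec))       # (X - 2p)'c == X'c since sum(c)=0
  quadFull <- sum(v[keep]^2 / den) / m      # c' (W W'/m) c over all i, j
  # swap the cross-product diagonal for the dedicated diagonal estimator:
  # Yang diag - product diag = 1 + (1/m) sum_k ((2p_k - 1) x_ik - 2 p_k^2) / den_k
  a <- numeric(ncol(X))
  a[keep] <- (2 * pk - 1) / den
  b <- -2 * pk^2 / den
  dAdj <- 1 + (as.numeric(X %*% a) + sum(b)) / m
  quad <- quadFull + sum(cvec^2 * dAdj)
  n <- contrast@n
  n / (contrast@nCase * contrast@nControl) * quad
}
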