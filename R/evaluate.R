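# Replicate experiments: empirical type I error and power of the
# family-based statistics under the study designs.

#' Empirical type I error of the family-based collapsing test
#'
#' Simulates \code{R} independent null datasets under a family design (the
#' test gene is unlinked to the phenotype), computes the corrected
#' collapsing statistic \eqn{T_{CF}} per replicate under one or more
#' relatedness scenarios, and tallies chi-squared(1) rejections at each
#' nominal level.  Scenarios: \code{"estimated"} estimates all pairwise
#' relationships from an unlinked common-marker panel simulated through the
#' same pedigrees; \code{"theoretical"} uses recursive pedigree kinship with
#' cross-pedigree entries zero (constant across replicates, computed once);
#' \code{"identity"} applies no correction (\eqn{P_{corr} = 1}), exposing
#' the inflation caused by ignored relatedness.  Replicates with a
#' degenerate collapsed indicator count as non-rejections.
#'
#' @param design Design name (see \code{\link{familyDesign}}) or object.
#' @param pool \linkS4class{FounderPool} for the test gene.
#' @param n Total phenotyped individuals per replicate (default 2100).
#' @param R Number of replicates (default 1000).
#' @param alpha Nominal levels (default 0.05, 0.01, 0.001).
#' @param scenarios Subset of \code{c("estimated", "theoretical",
#'   "identity")}.
#' @param nMarkers Markers in the kinship panel (default 1000).
#' @param mafRare Collapsing MAF threshold (default 0.01).
#' @param mafKinship Common-marker MAF bound for estimation (default 0.05).
#' @param seed Master seed; per-replicate seeds are derived by counter.
#' @return A \code{data.frame} with one row per (scenario, alpha):
#'   rejection counts, rates and exact binomial 95\% confidence bounds.
#'   The per-replicate p-value matrix is attached as
#'   \code{attr(, "pvalues")} (R x scenarios), for reuse (e.g. null
#'   calibration checks or uncorrected re-analyses of the same replicates).
#' @export
typeIExperiment <- function(design, pool, n = 2100, R = 1000,
                            alpha = c(0.05, 0.01, 0.001),
                            scenarios = c("estimated", "theoretical",
                                          "identity"),
                            nMarkers = 1000, mafRare = 0.01,
                            mafKinship = 0.05, seed = 1) {
  if (is.character(design)) design <- familyDesign(design)
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  needMarkers <- "estimated" %in% scenarios
  panel <- if (needMarkers)
    markerPanel(nMarkers, seed = childSeed(seed, 0L)) else NULL

  # design labels are fixed, so the contrast and the pedigree-theoretical
  # correction factor are constant across replicates
  set.seed(childSeed(seed, 1L))
  proto <- simulateDesignRaw(design, "null", n, pool, NULL, NULL)
  contrast <- phenotypeContrast(proto$pedDf$affection)
  pcorrTheo <- if ("theoretical" %in% scenarios) {
    correctionFactor(contrast, designKinship(design, n))
  } else NA_real_

  pv <- matrix(NA_real_, R, length(scenarios),
               dimnames = list(NULL, scenarios))
  for (r in seq_len(R)) {
    set.seed(childSeed(seed, 1L + r))
    raw <- simulateDesignRaw(design, "null", n, pool, NULL, panel,
                             pedDf = proto$pedDf)
    pop <- tryCatch({
      z <- collapseRegion(raw$gene, mafThreshold = mafRare)
      collapsingTest(z, contrast)
    }, error = function(e) list(stat = NA_real_, degenerate = TRUE))
    for (s in scenarios) {
      if (pop$degenerate) {
        pv[r, s] <- 1
        next
      }
      pc <- switch(s,
        estimated = {
          X <- raw$markers
          pk <- colMeans(X) / 2
          grmCorrectionFactor(X, contrast, freq = pk,
                              keep = pmin(pk, 1 - pk) >= mafKinship)
        },
        theoretical = pcorrTheo,
        identity = 1)
      pv[r, s] <- chisq1P(pop$stat / pc)
    }
  }

  out <- do.call(rbind, lapply(scenarios, function(s) {
    do.call(rbind, lapply(alpha, function(a) {
      x <- sum(pv[, s] <= a)
      ci <- binomCI(x, R)
      data.frame(design = design$name, scenario = s, alpha = a, R = R,
                 rejections = x, rate = x / R,
                 ciLower = ci[1], ciUpper = ci[2])
    }))
  }))
  rownames(out) <- NULL
  attr(out, "pvalues") <- pv
  out
}

#' Empirical power of the family statistics
#'
#' Simulates \code{R} ascertained datasets under the alternative (the test
#' gene carries the causal variants of the supplied penetrance model),
#' applies the requested family statistics and reports the rejection rate
#' at level \code{alpha}.  The collapsing test uses its chi-squared(1)
#' p-value; WSS and VT use \code{\link{familyPermutationTest}} with
#' \code{B} permutations; the single-marker test uses the min-p empirical
#' p-value (\code{\link{minpEmpirical}}).  Relatedness is corrected with
#' the pedigree-theoretical matrix of the design (constant across
#' replicates).
#'
#' @param design Design name or object.
#' @param pool \linkS4class{FounderPool} carrying the causal gene.
#' @param pen \linkS4class{PenetranceModel} for the pool.
#' @param n Individuals per replicate.
#' @param R Replicates.
#' @param B Permutations for WSS/VT/min-p (default 500).
#' @param alpha Rejection level (default 0.05).
#' @param stats Statistics to evaluate; subset of \code{c("collapsing",
#'   "wss", "vt", "single_marker")}.
#' @param mafRare Collapsing MAF threshold (default 0.01).
#' @param vtUpper VT threshold upper bound (default 0.05).
#' @param seed Master seed.
#' @details Rare/common status is decided by frequencies estimated in the
#'   unaffected individuals of each replicate: in an ascertained multiplex
#'   sample the causal variants are strongly enriched among cases, and a
#'   full-sample frequency filter would discard exactly the variants
#'   carrying the signal.
#' @return \code{data.frame} with one row per statistic: power and exact
#'   binomial confidence bounds; per-replicate p-values in
#'   \code{attr(, "pvalues")}.
#' @export
powerExperiment <- function(design, pool, pen, n = 900, R = 200, B = 500,
                            alpha = 0.05,
                            stats = c("collapsing", "wss", "vt",
                                      "single_marker"),
                            mafRare = 0.01, vtUpper = 0.05, seed = 1) {
  if (is.character(design)) design <- familyDesign(design)
  stats <- match.arg(stats, several.ok = TRUE)

  set.seed(childSeed(seed, 0L))
  proto <- simulateDesignRaw(design, "alternative", n, pool, pen, NULL)
  contrast <- phenotypeContrast(proto$pedDf$affection)
  K <- relMatrix(designKinship(design, n))

  pv <- matrix(NA_real_, R, length(stats),
               dimnames = list(NULL, stats))
  for (r in seq_len(R)) {
    rs <- childSeed(seed, r)
    set.seed(rs)
    raw <- simulateDesignRaw(design, "alternative", n, pool, pen, NULL,
                             pedDf = proto$pedDf)
    X <- raw$gene
    mafCtl <- suppressWarnings(
      computeMaf(X[contrast@u == 0, , drop = FALSE]))
    for (s in stats) {
      pv[r, s] <- tryCatch(switch(s,
        collapsing = {
          z <- collapseRegion(X, mafThreshold = mafRare, maf = mafCtl)
          familyCollapsingTest(z, contrast, K)@pValue
        },
        wss = familyPermutationTest("wss", X, contrast, K = K, B = B,
                                    seed = childSeed(rs, 1L),
                                    mafThreshold = mafRare,
                                    maf = mafCtl)@pValue,
        vt = familyPermutationTest("vt", X, contrast, K = K, B = B,
                                   seed = childSeed(rs, 2L),
                                   upperBound = vtUpper,
                                   maf = mafCtl)@pValue,
        single_marker = minpEmpirical(X, contrast, K = K, B = B,
                                      seed = childSeed(rs, 3L))@pValue),
        error = function(e) 1)
    }
  }
  out <- do.call(rbind, lapply(stats, function(s) {
    x <- sum(pv[, s] <= alpha)
    ci <- binomCI(x, R)
    data.frame(design = design$name, n = n, statistic = s, R = R, B = B,
               alpha = alpha, power = x / R,
               ciLower = ci[1], ciUpper = ci[2])
  }))
  rownames(out) <- NULL
  attr(out, "pvalues") <- pv
  out
}

#' Write an experiment table as TSV with a settings header
#'
#' Deterministic given its inputs: a commented header records the settings,
#' followed by the tab-separated table (empty tables produce a header-only
#' file).
#'
#' @param tab \code{data.frame} from \code{\link{typeIExperiment}} or
#'   \code{\link{powerExperiment}} (or any data.frame).
#' @param path Output path.
#' @param settings Named list echoed into the header.
#' @return \code{path}, invisibly.
#' @export
reportTable <- function(tab, path, settings = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(settings))
    writeLines(paste0("# ", nm, ": ", settings[[nm]]), con)
  writeLines(paste(names(tab), collapse = "\t"), con)
  if (nrow(tab) > 0)
    write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  invisible(path)
}
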