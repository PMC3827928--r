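# Pedigree genotype/phenotype simulation: Wright-Fisher founder pool,
# family design templates, gene dropping, penetrance models, ascertainment.

#' FounderPool: haplotype pool from a forward Wright-Fisher simulation
#'
#' Holds the final-generation haplotypes of a neutral forward-in-time
#' simulation of one gene region (rows = haplotypes, columns = segregating
#' sites, entries 0/1), their variant positions and realized allele
#' frequencies, and the generating parameters.  Founders of simulated
#' pedigrees draw haplotype pairs uniformly from this pool.
#'
#' @aliases FounderPool
#' @export
setClass("FounderPool",
         representation(haplotypes = "matrix", freq = "numeric",
                        pos = "numeric", params = "list"))

setValidity("FounderPool", function(object) {
  if (nrow(object@haplotypes) %% 2 != 0)
    return("haplotype count must be even")
  if (length(object@freq) != ncol(object@haplotypes))
    return("freq length must equal number of sites")
  if (any(object@freq <= 0 | object@freq >= 1))
    return("all stored sites must be segregating")
  TRUE
})

setMethod("show", "FounderPool", function(object) {
  cat("FounderPool:", nrow(object@haplotypes), "haplotypes,",
      ncol(object@haplotypes), "segregating sites\n")
  cat("  region length:", object@params$regionLength, "bp;",
      "rare (MAF <= 0.01):", sum(pmin(object@freq, 1 - object@freq)
                                 <= 0.01), "sites\n")
})

#' Build a founder haplotype pool by forward Wright-Fisher simulation
#'
#' Simulates a randomly mating population of haplotypes under neutral drift
#' with infinite-sites mutation (rate \code{mutationRate} per base pair per
#' generation over a region of \code{regionLength} bp) for
#' \code{generations} generations.  The population holds \code{n0} diploids
#' until late expansion: in the last generations the size is multiplied by
#' \code{growth} per generation until it reaches \code{nMax}.  The
#' final-generation haplotypes form the founder pool; their site-frequency
#' spectrum is strongly rare-skewed, as expected after mutation-drift
#' balance plus recent growth.  A run that ends with no segregating sites is
#' retried with a derived seed up to \code{maxRetry} times.
#'
#' @param n0 Initial diploid population size (default 1000).
#' @param nMax Final diploid size after growth (default 5000).
#' @param generations Number of generations (default 100).
#' @param growth Per-generation growth factor during the expansion phase
#'   (default 2.1).
#' @param regionLength Region length in bp (default 1e5).
#' @param mutationRate Per-bp per-generation mutation rate (default
#'   2.5e-8).
#' @param seed RNG seed.
#' @param maxRetry Retries when no polymorphism survives (default 10).
#' @return A \linkS4class{FounderPool}.
#' @examples
#' pool <- buildFounderPool(n0 = 50, nMax = 100, generations = 20,
#'                          regionLength = 2e5, seed = 1)
#' @export
buildFounderPool <- function(n0 = 1000, nMax = 5000, generations = 100,
                             growth = 2.1, regionLength = 1e5,
                             mutationRate = 2.5e-8, seed = NULL,
                             maxRetry = 10) {
  stopIf(growth <= 1, "growth factor must exceed 1")
  for (attempt in seq_len(maxRetry)) {
    maybeSeed(if (is.null(seed)) NULL else childSeed(seed, attempt - 1L))
    growGens <- ceiling(log(nMax / n0) / log(growth))
    sizes <- rep(n0, generations)
    if (growGens > 0 && generations > growGens) {
      tailN <- pmin(nMax, n0 * growth^seq_len(growGens))
      sizes[(generations - growGens + 1):generations] <- round(tailN)
    }
    M <- matrix(0L, 2 * n0, 0)
    pos <- numeric(0)
    muRegion <- mutationRate * regionLength
    for (g in seq_len(generations)) {
      H <- 2 * sizes[g]
      idx <- sample.int(nrow(M), H, replace = TRUE)
      M <- M[idx, , drop = FALSE]
      nMut <- rpois(1, H * muRegion)
      if (nMut > 0) {
        newCols <- matrix(0L, H, nMut)
        newCols[cbind(sample.int(H, nMut, replace = TRUE),
                      seq_len(nMut))] <- 1L
        M <- cbind(M, newCols)
        pos <- c(pos, runif(nMut, 1, regionLength))
      }
      if (ncol(M) > 0) {
        cs <- colSums(M)
        keep <- cs > 0L & cs < H
        M <- M[, keep, drop = FALSE]
        pos <- pos[keep]
      }
    }
    if (ncol(M) > 0) {
      ord <- order(pos)
      M <- M[, ord, drop = FALSE]
      pos <- pos[ord]
      colnames(M) <- paste0("s", seq_along(pos))
      return(new("FounderPool", haplotypes = M, freq = colMeans(M),
                 pos = pos,
                 params = list(n0 = n0, nMax = nMax,
                               generations = generations, growth = growth,
                               regionLength = regionLength,
                               mutationRate = mutationRate, seed = seed,
                               attempt = attempt)))
    }
  }
  stop("no segregating sites after ", maxRetry,
       " attempts; increase regionLength, mutationRate or population size",
       call. = FALSE)
}

#' Unlinked common-marker panel for kinship estimation
#'
#' Generates a pool of haplotypes at \code{nMarkers} unlinked biallelic
#' markers with allele frequencies drawn uniformly from \code{mafRange}
#' (mimicking a sparse genome-wide SNP selection).  Sites are in linkage
#' equilibrium; transmission through pedigrees treats each marker as an
#' independent locus.
#'
#' @param nMarkers Number of markers (default 1000).
#' @param nHaplotypes Pool size (default 10000).
#' @param mafRange Frequency range (default \code{c(0.05, 0.5)}).
#' @param seed RNG seed.
#' @return List with \code{haplotypes} (logical pool matrix) and
#'   \code{freq}.
#' @export
markerPanel <- function(nMarkers = 1000, nHaplotypes = 10000,
                        mafRange = c(0.05, 0.5), seed = NULL) {
  maybeSeed(seed)
  freq <- runif(nMarkers, mafRange[1], mafRange[2])
  h <- matrix(runif(nHaplotypes * nMarkers) <
                rep(freq, each = nHaplotypes),
              nHaplotypes, nMarkers)
  list(haplotypes = h, freq = freq)
}

# ---------------------------------------------------------------------------
# Family design templates.
#
# A template is a small pedigree in which parents precede children.  Columns:
# role (label), father/mother (row index or NA), sex, sampled (genotyped and
# phenotyped), affected (designated status for sampled members).  Ascertained
# multiplex units carry >= 2 affected members; unaffected individuals enter
# the sample as unrelated controls, which concentrates relatedness within the
# affected class -- the configuration in which failing to correct for
# relatedness inflates type I error.

designTemplates <- function() {
  if (!is.null(.templateCache$tmpl)) return(.templateCache$tmpl)
  .templateCache$tmpl <- list(
    singleton = data.frame(
      role = "I", father = NA, mother = NA, sex = 1,
      sampled = TRUE, affected = TRUE),
    sibpair = data.frame(
      role = c("F", "M", "S1", "S2"),
      father = c(NA, NA, 1, 1), mother = c(NA, NA, 2, 2),
      sex = c(1, 2, 1, 2),
      sampled = c(FALSE, FALSE, TRUE, TRUE),
      affected = c(FALSE, FALSE, TRUE, TRUE)),
    nuclear = data.frame(
      role = c("F", "M", "C1", "C2"),
      father = c(NA, NA, 1, 1), mother = c(NA, NA, 2, 2),
      sex = c(1, 2, 1, 2),
      sampled = c(TRUE, FALSE, TRUE, TRUE),
      affected = c(TRUE, FALSE, TRUE, TRUE)),
    threegen = data.frame(
      role = c("GF", "GM", "P", "SP", "C1", "C2"),
      father = c(NA, NA, 1, NA, 3, 3), mother = c(NA, NA, 2, NA, 4, 4),
      sex = c(1, 2, 1, 2, 1, 2),
      sampled = c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE),
      affected = c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE)))
  .templateCache$tmpl
}

.templateCache <- new.env(parent = emptyenv())

#' Family study designs
#'
#' Returns a design specification: which ascertained multiplex family unit
#' supplies the affected individuals (affected sib pairs; nuclear families
#' with an affected parent and two affected children; three-generation
#' families with affected members among grandparents, children and
#' grandchildren), the affected:unaffected ratio (unaffected individuals
#' are unrelated population controls), and, for the mixed designs, the
#' mixture of unit types.  \code{"mix1"} draws affected units 33/33/34
#' percent from sib-pair-2, nuclear-2 and three-generation-2 units;
#' \code{"mix2"} half-and-half from sib-pair-2 and nuclear-2;
#' \code{"mix_cc"} combines nuclear-family units with unrelated cases and
#' controls.
#'
#' @param name One of \code{"case_control"}, \code{"sibpair1"},
#'   \code{"sibpair2"}, \code{"nuclear1"}, \code{"nuclear2"},
#'   \code{"threegen1"}, \code{"threegen2"}, \code{"mix1"}, \code{"mix2"},
#'   \code{"mix_cc"}.
#' @return A list with elements \code{name}, \code{ratio} (affected :
#'   unaffected), and \code{units} (named fractions of affected individuals
#'   contributed by each template).
#' @export
familyDesign <- function(name = c("case_control", "sibpair1", "sibpair2",
                                  "nuclear1", "nuclear2", "threegen1",
                                  "threegen2", "mix1", "mix2", "mix_cc")) {
  name <- match.arg(name)
  spec <- switch(name,
    case_control = list(ratio = 1, units = c(singleton = 1)),
    sibpair1 = list(ratio = 1, units = c(sibpair = 1)),
    sibpair2 = list(ratio = 2, units = c(sibpair = 1)),
    nuclear1 = list(ratio = 1, units = c(nuclear = 1)),
    nuclear2 = list(ratio = 2, units = c(nuclear = 1)),
    threegen1 = list(ratio = 1, units = c(threegen = 1)),
    threegen2 = list(ratio = 2, units = c(threegen = 1)),
    mix1 = list(ratio = 2, units = c(sibpair = 0.33, nuclear = 0.33,
                                     threegen = 0.34)),
    mix2 = list(ratio = 2, units = c(sibpair = 0.5, nuclear = 0.5)),
    mix_cc = list(ratio = 1, units = c(nuclear = 0.5, singleton = 0.5)))
  c(list(name = name), spec)
}

# Unit bookkeeping: number of families of each template and number of
# unrelated controls needed to realize ~n individuals at the design ratio.
designCounts <- function(design, n) {
  tmpl <- designTemplates()
  r <- design$ratio
  nCase <- round(n * r / (r + 1))
  out <- list()
  for (nm in names(design$units)) {
    a <- sum(tmpl[[nm]]$sampled & tmpl[[nm]]$affected)
    nFam <- max(1L, round(design$units[[nm]] * nCase / a))
    out[[nm]] <- nFam
  }
  nCaseReal <- sum(vapply(names(out), function(nm)
    out[[nm]] * sum(tmpl[[nm]]$sampled & tmpl[[nm]]$affected), numeric(1)))
  list(units = out, nControls = round(nCaseReal / r),
       nCases = as.integer(nCaseReal))
}

# ---------------------------------------------------------------------------
# Gene dropping.

#' Gene-drop a founder pool through pedigree templates
#'
#' Founders draw two haplotypes uniformly (with replacement) from the pool;
#' each non-founder receives one randomly chosen haplotype from each parent.
#' There is no recombination within the gene, so whole haplotypes are
#' transmitted.  All \code{nFam} replicate families are dropped at once.
#'
#' @param template A design template (see \code{pedburden:::designTemplates}),
#'   or its name.
#' @param nFam Number of independent families.
#' @param pool A \linkS4class{FounderPool}.
#' @param seed RNG seed.
#' @return List with \code{dosage} (rows = sampled members of family 1,
#'   family 2, ... stacked member-major: all first members, then all second
#'   members), \code{memberRows} bookkeeping, and the haplotype index
#'   matrices \code{hap1}, \code{hap2} (members x families).
#' @export
geneDrop <- function(template, nFam, pool, seed = NULL) {
  maybeSeed(seed)
  if (is.character(template)) template <- designTemplates()[[template]]
  idx <- geneDropIndices(template, nFam, nrow(pool@haplotypes))
  P <- pool@haplotypes
  sampled <- which(template$sampled)
  dosage <- do.call(rbind, lapply(sampled, function(j)
    P[idx$h1[j, ], , drop = FALSE] + P[idx$h2[j, ], , drop = FALSE]))
  list(dosage = dosage,
       member = rep(sampled, each = nFam),
       family = rep(seq_len(nFam), times = length(sampled)),
       hap1 = idx$h1, hap2 = idx$h2)
}

# Haplotype index matrices (template members x families) under Mendelian
# whole-haplotype transmission.
geneDropIndices <- function(template, nFam, H) {
  nm <- nrow(template)
  h1 <- matrix(0L, nm, nFam)
  h2 <- matrix(0L, nm, nFam)
  for (j in seq_len(nm)) {
    fa <- template$father[j]; mo <- template$mother[j]
    if (is.na(fa) && is.na(mo)) {
      h1[j, ] <- sample.int(H, nFam, replace = TRUE)
      h2[j, ] <- sample.int(H, nFam, replace = TRUE)
    } else {
      pick <- runif(nFam) < 0.5
      h1[j, ] <- ifelse(pick, h1[fa, ], h2[fa, ])
      pick <- runif(nFam) < 0.5
      h2[j, ] <- ifelse(pick, h1[mo, ], h2[mo, ])
    }
  }
  list(h1 = h1, h2 = h2)
}

# Drop an unlinked marker panel through a template: founders take pool rows,
# children receive an independently chosen parental allele at every marker
# (markers are unlinked, so per-site transmission is independent).
# Returns the stacked dosage matrix for sampled members (member-major).
dropMarkers <- function(template, nFam, panel, seed = NULL) {
  maybeSeed(seed)
  if (is.character(template)) template <- designTemplates()[[template]]
  H <- nrow(panel$haplotypes)
  m <- ncol(panel$haplotypes)
  recombine <- function(a, b) {
    # one independent parental pick per (family, marker)
    swap <- which(runif(nFam * m) < 0.5)
    out <- a
    out[swap] <- b[swap]
    out
  }
  pat <- vector("list", nrow(template))
  mat <- vector("list", nrow(template))
  for (j in seq_len(nrow(template))) {
    fa <- template$father[j]; mo <- template$mother[j]
    if (is.na(fa) && is.na(mo)) {
      pat[[j]] <- panel$haplotypes[sample.int(H, nFam, TRUE), ,
                                   drop = FALSE]
      mat[[j]] <- panel$haplotypes[sample.int(H, nFam, TRUE), ,
                                   drop = FALSE]
    } else {
      pat[[j]] <- recombine(pat[[fa]], mat[[fa]])
      mat[[j]] <- recombine(pat[[mo]], mat[[mo]])
    }
  }
  sampled <- which(template$sampled)
  do.call(rbind, lapply(sampled, function(j) pat[[j]] + mat[[j]]))
}

# ---------------------------------------------------------------------------
# Penetrance models.

#' PenetranceModel: per-variant relative risks under a disease model
#'
#' Baseline penetrance \code{f0} applies to non-carriers; a causal variant
#' multiplies the penetrance by \eqn{\gamma_{1k}} (heterozygote) or
#' \eqn{\gamma_{2k}} (homozygote), independently across variants (no
#' epistasis).  Model identities: dominant \eqn{\gamma_2 = \gamma_1};
#' additive \eqn{\gamma_2 = 2\gamma_1 - 1}; multiplicative
#' \eqn{\gamma_2 = \gamma_1^2}; recessive \eqn{\gamma_1 = 1}.
#'
#' @aliases PenetranceModel
#' @export
setClass("PenetranceModel",
         representation(model = "character", f0 = "numeric",
                        causal = "integer", gamma1 = "numeric",
                        gamma2 = "numeric", direction = "numeric",
                        par = "numeric"))

setValidity("PenetranceModel", function(object) {
  k <- length(object@causal)
  if (length(object@gamma1) != k || length(object@gamma2) != k)
    return("gamma vectors must match the causal set")
  if (object@f0 <= 0 || object@f0 > 1)
    return("baseline penetrance must lie in (0, 1]")
  ok <- switch(object@model,
    dominant = all(abs(object@gamma2 - object@gamma1) < 1e-9),
    additive = all(abs(object@gamma2 - (2 * object@gamma1 - 1)) < 1e-9 |
                     object@direction < 0),
    multiplicative = all(abs(object@gamma2 - object@gamma1^2) < 1e-9),
    recessive = all(object@gamma1 == 1),
    TRUE)
  if (!isTRUE(ok)) return("relative risks violate the model identity")
  TRUE
})

setMethod("show", "PenetranceModel", function(object) {
  cat("PenetranceModel (", object@model, "): f0 =", object@f0, ",",
      length(object@causal), "causal variants",
      if (any(object@direction < 0))
        paste0("(", sum(object@direction < 0), " protective)") else "",
      "\n")
})

#' Calibrate relative risks from population attributable risk
#'
#' Selects a causal subset of the pool's rare variants (a fraction
#' \code{pcv} of them, uniformly at random) and assigns each causal variant
#' a heterozygote relative risk via its attributable risk:
#' \deqn{\gamma_{1k} = 1 + \frac{PAR_k}{f_k (1 - PAR_k)}}
#' with \eqn{f_k} the carrier frequency \eqn{1 - (1 - q_k)^2}.  Because
#' carrier frequency is nearly proportional to MAF for rare variants, the
#' relative risk is inversely related to MAF.  \code{parMode} sets whether
#' \code{par} is the attributable risk of each causal variant
#' (\code{"per_variant"}, default 0.006 each) or a total split equally
#' across the causal set.  Homozygote risks follow the model identity (for
#' the recessive model the heterozygote risk is 1 and the homozygote risk
#' is calibrated against the homozygote frequency \eqn{q_k^2}).  With
#' \code{bidirectional = TRUE}, half the causal set (rounded down) receives
#' the reciprocal, protective effect.
#'
#' @param pool A \linkS4class{FounderPool}.
#' @param model Disease model.
#' @param pcv Proportion of causal variants among rare variants (default
#'   0.2).
#' @param par Population attributable risk (default 0.006, per variant).
#' @param parMode \code{"per_variant"} or \code{"total"}.
#' @param bidirectional Make half the causal variants protective.
#' @param f0 Baseline penetrance (default 0.01).
#' @param rareThreshold MAF bound defining the candidate causal set
#'   (default 0.01).
#' @param rareFloor Lower MAF bound for causal candidates (default 0.001):
#'   variants represented by only a handful of pool haplotypes cannot be
#'   stably ascertained from a finite founder pool, and their
#'   frequency-inverse risks would be essentially unbounded.
#' @param seed RNG seed for the causal draw.
#' @return A \linkS4class{PenetranceModel}.
#' @examples
#' pool <- buildFounderPool(n0 = 100, nMax = 200, generations = 30,
#'                          regionLength = 3e5, seed = 2)
#' calibrateRelativeRisks(pool, "dominant", pcv = 0.2, seed = 3)
#' @export
calibrateRelativeRisks <- function(pool,
                                   model = c("dominant", "additive",
                                             "multiplicative", "recessive"),
                                   pcv = 0.2, par = 0.006,
                                   parMode = c("per_variant", "total"),
                                   bidirectional = FALSE, f0 = 0.01,
                                   rareThreshold = 0.01, rareFloor = 0.001,
                                   seed = NULL) {
  model <- match.arg(model)
  parMode <- match.arg(parMode)
  maybeSeed(seed)
  maf <- pmin(pool@freq, 1 - pool@freq)
  rare <- which(maf <= rareThreshold & maf >= rareFloor)
  nCausal <- if (pcv > 0) max(1L, round(pcv * length(rare))) else 0L
  if (nCausal == 0L)
    return(new("PenetranceModel", model = model, f0 = f0,
               causal = integer(0), gamma1 = numeric(0),
               gamma2 = numeric(0), direction = numeric(0),
               par = numeric(0)))
  stopIf(length(rare) == 0, "no rare variant available as causal")
  causal <- sort(sample(rare, min(nCausal, length(rare))))
  park <- if (parMode == "per_variant") rep(par, length(causal))
          else rep(par / length(causal), length(causal))
  stopIf(any(park >= 1), "per-variant attributable risk must be < 1")
  q <- pool@freq[causal]
  carrier <- 1 - (1 - q)^2
  if (model == "recessive") {
    hom <- pmax(q^2, 1e-12)
    g1 <- rep(1, length(causal))
    g2 <- 1 + park / (hom * (1 - park))
  } else {
    g1 <- 1 + park / (carrier * (1 - park))
    g2 <- switch(model,
                 dominant = g1,
                 additive = 2 * g1 - 1,
                 multiplicative = g1^2)
  }
  direction <- rep(1, length(causal))
  if (bidirectional && length(causal) >= 2) {
    prot <- seq_len(floor(length(causal) / 2))
    direction[prot] <- -1
    g1[prot] <- 1 / g1[prot]
    g2[prot] <- 1 / g2[prot]
  }
  new("PenetranceModel", model = model, f0 = f0, causal = causal,
      gamma1 = g1, gamma2 = g2, direction = direction, par = park)
}

#' Rescale the baseline penetrance to hit a target disease prevalence
#'
#' The power settings fix the baseline penetrance at 0.01; when instead a
#' target population prevalence is required, this rescales \code{f0} so
#' that the expected penetrance of a random population member (two
#' haplotypes drawn from the pool) equals \code{prevalence}.  The expected
#' genotype relative-risk factor is evaluated by Monte Carlo over the pool.
#'
#' @param pool A \linkS4class{FounderPool}.
#' @param pen A \linkS4class{PenetranceModel}.
#' @param prevalence Target prevalence (default 0.09).
#' @param nSim Monte-Carlo draws (default 20000).
#' @param seed RNG seed.
#' @return The penetrance model with adjusted \code{f0}.
#' @export
calibrateBaseline <- function(pool, pen, prevalence = 0.09, nSim = 20000,
                              seed = NULL) {
  maybeSeed(seed)
  H <- nrow(pool@haplotypes)
  Xc <- pool@haplotypes[sample.int(H, nSim, TRUE), pen@causal,
                        drop = FALSE] +
    pool@haplotypes[sample.int(H, nSim, TRUE), pen@causal, drop = FALSE]
  meanRR <- mean(exp(as.numeric(
    (Xc == 1) %*% log(pen@gamma1) + (Xc == 2) %*% log(pen@gamma2))))
  pen@f0 <- min(1, prevalence / meanRR)
  pen
}

#' Assign affection status from genotypes and a penetrance model
#'
#' Individual penetrance is \eqn{\min(1, f_0 \prod_k \gamma_k(x_{ik}))}
#' over the causal variants (\eqn{\gamma(0) = 1}); affection is drawn
#' Bernoulli with that probability.  Non-carriers have penetrance exactly
#' \eqn{f_0}.
#'
#' @param x Dosage matrix or \linkS4class{PedGenotypes} over the pool's
#'   variants.
#' @param pen A \linkS4class{PenetranceModel}.
#' @param seed RNG seed.
#' @return Integer affection vector (1 affected, 0 unaffected).
#' @export
assignPhenotype <- function(x, pen, seed = NULL) {
  maybeSeed(seed)
  pi <- penetranceOf(if (is(x, "PedGenotypes")) dosages(x) else x, pen)
  as.integer(runif(length(pi)) < pi)
}

# Penetrance vector from a full-width dosage matrix.
penetranceOf <- function(X, pen) {
  if (length(pen@causal) == 0) return(rep(pen@f0, nrow(X)))
  penetranceCausal(X[, pen@causal, drop = FALSE], pen)
}

# Penetrance vector when the matrix is already restricted to the causal
# columns (in causal-set order).
penetranceCausal <- function(Xc, pen) {
  if (length(pen@causal) == 0) return(rep(pen@f0, nrow(Xc)))
  Xc[is.na(Xc)] <- 0
  lp <- (Xc == 1) %*% log(pen@gamma1) + (Xc == 2) %*% log(pen@gamma2)
  pmin(1, pen@f0 * exp(as.numeric(lp)))
}

# ---------------------------------------------------------------------------
# Ascertainment and dataset assembly.

# Sampling-importance-resampling draw of nFam families whose designated
# members are all affected.  Candidate families are gene-dropped in bulk,
# weighted by the probability that their designated members are affected
# (product of member penetrances), and resampled proportionally.  Exact as
# the candidate batch grows; batchFactor controls the batch size.
sirAscertainUnit <- function(templateName, nFam, pool, pen,
                             batchFactor = 150) {
  template <- designTemplates()[[templateName]]
  M <- max(2000L, as.integer(batchFactor * nFam))
  idx <- geneDropIndices(template, M, nrow(pool@haplotypes))
  aff <- which(template$sampled & template$affected)
  Pc <- pool@haplotypes[, pen@causal, drop = FALSE]
  w <- rep(1, M)
  if (length(pen@causal) > 0) {
    for (j in aff) {
      Xj <- Pc[idx$h1[j, ], , drop = FALSE] + Pc[idx$h2[j, ], , drop = FALSE]
      w <- w * penetranceCausal(Xj, pen)
    }
  } else {
    w <- w * pen@f0^length(aff)
  }
  stopIf(sum(w) <= 0, "ascertainment impossible: all family weights zero")
  keep <- sample.int(M, nFam, replace = TRUE, prob = w)
  list(h1 = idx$h1[, keep, drop = FALSE],
       h2 = idx$h2[, keep, drop = FALSE])
}

# Unrelated unaffected controls: rejection-sample individuals from the pool
# until nCtl unaffected are found (acceptance is ~1 - f0 under rare-variant
# models, so one or two rounds suffice).
sampleControls <- function(nCtl, pool, pen) {
  H <- nrow(pool@haplotypes)
  h1 <- integer(0); h2 <- integer(0)
  while (length(h1) < nCtl) {
    M <- max(100L, ceiling((nCtl - length(h1)) * 1.2))
    c1 <- sample.int(H, M, TRUE); c2 <- sample.int(H, M, TRUE)
    X <- pool@haplotypes[c1, pen@causal, drop = FALSE] +
      pool@haplotypes[c2, pen@causal, drop = FALSE]
    pi <- penetranceCausal(X, pen)
    ok <- runif(M) >= pi
    h1 <- c(h1, c1[ok]); h2 <- c(h2, c2[ok])
  }
  list(h1 = h1[seq_len(nCtl)], h2 = h2[seq_len(nCtl)])
}

#' Simulate one study dataset under a family design
#'
#' Draws an ascertained sample under the given design: multiplex family
#' units whose designated members are affected, plus unrelated unaffected
#' controls at the design's affected:unaffected ratio.  Under the
#' \code{"null"} scenario the returned test gene is unlinked to the
#' phenotype, so genotypes are plain gene drops and the affection labels
#' are fixed by the design (for an unlinked gene this equals
#' penetrance-based ascertainment exactly).  Under \code{"alternative"},
#' family units are ascertained conditional on their members' affection
#' through the penetrance model by weighted resampling, and the causal gene
#' is returned as the test region.
#'
#' @param design A design name or the result of \code{\link{familyDesign}}.
#' @param scenario \code{"null"} or \code{"alternative"}.
#' @param n Target total number of phenotyped individuals.
#' @param pool \linkS4class{FounderPool} for the test gene.
#' @param pen \linkS4class{PenetranceModel} (required for
#'   \code{"alternative"}).
#' @param panel Optional marker panel from \code{\link{markerPanel}}; when
#'   supplied, an unlinked common-marker matrix for kinship estimation is
#'   simulated through the same pedigrees.
#' @param seed RNG seed; identical seeds give identical datasets.
#' @return A list: \code{ped} (\linkS4class{PedigreeSet}), \code{gene}
#'   (\linkS4class{PedGenotypes} for the test region), \code{markers}
#'   (dosage matrix or \code{NULL}), \code{design}.
#' @examples
#' pool <- buildFounderPool(n0 = 100, nMax = 200, generations = 30,
#'                          regionLength = 3e5, seed = 4)
#' d <- simulateDataset("sibpair1", "null", n = 60, pool = pool, seed = 5)
#' nCases(d$ped)
#' @export
simulateDataset <- function(design, scenario = c("null", "alternative"),
                            n, pool, pen = NULL, panel = NULL,
                            seed = NULL) {
  scenario <- match.arg(scenario)
  if (is.character(design)) design <- familyDesign(design)
  maybeSeed(seed)
  raw <- simulateDesignRaw(design, scenario, n, pool, pen, panel)
  ped <- PedigreeSet(raw$pedDf)
  vi <- data.frame(id = colnames(pool@haplotypes),
                   chrom = 1, pos = pool@pos,
                   region = "gene1", stringsAsFactors = FALSE)
  dn <- raw$gene
  rownames(dn) <- raw$pedDf$id
  colnames(dn) <- vi$id
  gene <- PedGenotypes(dn, ped, vi)
  list(ped = ped, gene = gene, markers = raw$markers, design = design)
}

# Internal engine shared with the evaluation harness; returns plain
# structures (no S4 assembly) for speed inside replicate loops.  The
# pedigree table is identical across replicates of a design and can be
# passed in precomputed via 'pedDf'.
simulateDesignRaw <- function(design, scenario, n, pool, pen, panel,
                              pedDf = NULL) {
  tmpl <- designTemplates()
  cnt <- designCounts(design, n)
  if (scenario == "alternative")
    stopIf(is.null(pen), "'pen' is required for the alternative scenario")

  pedRows <- list()
  geneRows <- list()
  markerRows <- list()
  for (nm in names(cnt$units)) {
    nFam <- cnt$units[[nm]]
    template <- tmpl[[nm]]
    if (scenario == "null") {
      idx <- geneDropIndices(template, nFam, nrow(pool@haplotypes))
    } else {
      idx <- sirAscertainUnit(nm, nFam, pool, pen)
    }
    sampled <- which(template$sampled)
    P <- pool@haplotypes
    gd <- do.call(rbind, lapply(sampled, function(j)
      P[idx$h1[j, ], , drop = FALSE] + P[idx$h2[j, ], , drop = FALSE]))
    geneRows[[nm]] <- gd
    if (!is.null(panel))
      markerRows[[nm]] <- dropMarkers(template, nFam, panel)
    if (is.null(pedDf))
      pedRows[[nm]] <- templatePedDf(template, nm, nFam)
  }
  nCtl <- cnt$nControls
  if (nCtl > 0) {
    if (scenario == "null") {
      H <- nrow(pool@haplotypes)
      c1 <- sample.int(H, nCtl, TRUE); c2 <- sample.int(H, nCtl, TRUE)
    } else {
      ctl <- sampleControls(nCtl, pool, pen)
      c1 <- ctl$h1; c2 <- ctl$h2
    }
    geneRows[["ctrl"]] <- pool@haplotypes[c1, , drop = FALSE] +
      pool@haplotypes[c2, , drop = FALSE]
    if (!is.null(panel)) {
      Hm <- nrow(panel$haplotypes)
      markerRows[["ctrl"]] <-
        panel$haplotypes[sample.int(Hm, nCtl, TRUE), , drop = FALSE] +
        panel$haplotypes[sample.int(Hm, nCtl, TRUE), , drop = FALSE]
    }
    if (is.null(pedDf))
      pedRows[["ctrl"]] <- data.frame(
        pedigree = paste0("ctrl", seq_len(nCtl)),
        id = paste0("ctrl", seq_len(nCtl)),
        father = NA_character_, mother = NA_character_,
        sex = NA_integer_, affection = 0L, stringsAsFactors = FALSE)
  }
  markers <- if (is.null(panel)) NULL
             else do.call(rbind, unname(markerRows))
  if (!is.null(markers)) storage.mode(markers) <- "double"
  list(pedDf = if (is.null(pedDf)) do.call(rbind, unname(pedRows))
               else pedDf,
       gene = do.call(rbind, unname(geneRows)),
       markers = markers)
}

#' Pedigree-theoretical relatedness matrix of a simulated design
#'
#' Builds the theoretical relationship matrix for the sampled individuals
#' of a design at size \code{n}: within each family unit, entries come from
#' the recursive kinship of the full unit template (including ungenotyped
#' connecting relatives such as the parents of a sampled sib pair);
#' individuals in different pedigrees -- and the unrelated controls -- have
#' entry zero off the diagonal.  Row order matches the datasets produced by
#' \code{\link{simulateDataset}} for the same design and \code{n}.
#'
#' @param design Design name or \code{\link{familyDesign}} object.
#' @param n Target total number of phenotyped individuals.
#' @return A \linkS4class{RelatednessMatrix} with method
#'   \code{"theoretical"}.
#' @examples
#' relMatrix(designKinship("sibpair1", 8))
#' @export
designKinship <- function(design, n) {
  if (is.character(design)) design <- familyDesign(design)
  tmpl <- designTemplates()
  cnt <- designCounts(design, n)
  sizes <- vapply(names(cnt$units), function(nm)
    cnt$units[[nm]] * sum(tmpl[[nm]]$sampled), numeric(1))
  total <- sum(sizes) + cnt$nControls
  K <- diag(1, total)
  ids <- character(0)
  off <- 0L
  for (nm in names(cnt$units)) {
    template <- tmpl[[nm]]
    nFam <- cnt$units[[nm]]
    pedT <- data.frame(
      pedigree = "t", id = template$role,
      father = ifelse(is.na(template$father), NA,
                      template$role[template$father]),
      mother = ifelse(is.na(template$mother), NA,
                      template$role[template$mother]),
      sex = template$sex, affection = NA, stringsAsFactors = FALSE)
    phi <- kinshipRecursion(pedT)
    B <- 2 * phi  # off-diagonal 2*phi; diagonal 2*phi_ii = 1 + h
    sampled <- which(template$sampled)
    B <- B[sampled, sampled, drop = FALSE]
    ns <- length(sampled)
    for (j1 in seq_len(ns)) {
      r1 <- off + (j1 - 1L) * nFam + seq_len(nFam)
      for (j2 in seq_len(ns)) {
        r2 <- off + (j2 - 1L) * nFam + seq_len(nFam)
        K[cbind(r1, r2)] <- B[j1, j2]
      }
    }
    ids <- c(ids, paste0(nm, rep(seq_len(nFam), times = ns), "_",
                         rep(template$role[sampled], each = nFam)))
    off <- off + ns * nFam
  }
  if (cnt$nControls > 0)
    ids <- c(ids, paste0("ctrl", seq_len(cnt$nControls)))
  dimnames(K) <- list(ids, ids)
  RelatednessMatrix(K, method = "theoretical")
}

# Pedigree data.frame for nFam stacked copies of a template (member-major
# order, matching geneDrop / dropMarkers row order).
templatePedDf <- function(template, nm, nFam) {
  sampled <- which(template$sampled)
  fam <- rep(seq_len(nFam), times = length(sampled))
  mem <- rep(sampled, each = nFam)
  pedid <- paste0(nm, fam)
  idOf <- function(j) paste0(nm, fam[seq_len(nFam)], "_", template$role[j])
  ids <- paste0(pedid, "_", template$role[mem])
  parentId <- function(p) {
    out <- rep(NA_character_, length(mem))
    has <- !is.na(template[[p]][mem]) & template$sampled[template[[p]][mem]]
    out[has] <- paste0(pedid[has], "_",
                       template$role[template[[p]][mem[has]]])
    out
  }
  data.frame(pedigree = pedid, id = ids,
             father = parentId("father"), mother = parentId("mother"),
             sex = template$sex[mem],
             affection = as.integer(template$affected[mem]),
             stringsAsFactors = FALSE)
}
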