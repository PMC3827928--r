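# Relationship-matrix estimation and pedigree kinship.

test_that("single-variant relationship entries match hand evaluation", {
  # het individual at p = 0.5: diagonal (1 - 2 + 0.5)/0.5 = -1 -> K_ii = 0
  K <- relMatrix(grmEstimate(matrix(c(1, 2, 0), 3, 1), freq = 0.5,
                             mafBound = 0))
  expect_equal(K[1, 1], 0)
  # x_i = 2, x_j = 0 at p = 0.5: (2-1)(0-1)/0.5 = -2
  expect_equal(K[2, 3], -2)
  # hom-ref and hom-alt diagonals: (4 - 4 + .5)/.5 = 1 -> K_ii = 2
  expect_equal(K[2, 2], 2)
})

test_that("degenerate allele frequencies are rejected by variant name", {
  X <- cbind(v1 = c(0, 1, 2), v2 = c(2, 2, 2))
  expect_error(grmEstimate(X, freq = c(0.5, 1), mafBound = 0), "v2")
  expect_error(grmEstimate(cbind(v1 = c(0, 0, 1)), mafBound = 0.3),
               "no variants left")
})

test_that("estimated relationship matrices are exactly symmetric", {
  X <- randomDosage(15, 80, seed = 3)
  K <- relMatrix(grmEstimate(X))
  expect_identical(K, t(K))
})

test_that("pedigree kinship reproduces textbook coefficients", {
  K <- relMatrix(pedigreeKinship(toyPedigree()))
  expect_equal(K["dad", "kid1"], 0.5)   # parent-offspring, 2*phi = 0.5
  expect_equal(K["kid1", "kid2"], 0.5)  # full sibs
  expect_equal(K["dad", "mum"], 0)      # founders unrelated
  expect_equal(K["dad", "solo1"], 0)    # cross-pedigree zero
  expect_equal(unname(diag(K)), rep(1, 6))  # non-inbred diagonal

  # offspring of a full-sib mating: h = 0.25, K_ii = 1.25
  inc <- PedigreeSet(data.frame(
    pedigree = "F", id = c("f", "m", "s1", "s2", "kid"),
    father = c(NA, NA, "f", "f", "s1"),
    mother = c(NA, NA, "m", "m", "s2"),
    sex = c(1, 2, 1, 2, 1), affection = NA))
  Ki <- pedigreeKinship(inc)
  expect_equal(unname(inbreeding(Ki)["kid"]), 0.25)
  expect_equal(relMatrix(Ki)["kid", "kid"], 1.25)
  expect_equal(unname(inbreeding(Ki)[c("f", "m")]), c(0, 0))
})

test_that("self-ancestry raises an error", {
  expect_error(PedigreeSet(data.frame(
    pedigree = "F", id = "a", father = "a", mother = NA,
    sex = 1, affection = NA)), "cycle")
})

test_that("pedigree kinship matches a brute-force gene-dropping IBD oracle", {
  # drop unique founder alleles through the three-generation template and
  # estimate kinship as the probability that randomly drawn alleles match
  tmpl <- pedburden:::designTemplates()$threegen
  set.seed(99)
  nDrop <- 1e5
  idx <- pedburden:::geneDropIndices(tmpl, nDrop, H = 1e7)
  pedT <- PedigreeSet(data.frame(
    pedigree = "t", id = tmpl$role,
    father = ifelse(is.na(tmpl$father), NA, tmpl$role[tmpl$father]),
    mother = ifelse(is.na(tmpl$mother), NA, tmpl$role[tmpl$mother]),
    sex = tmpl$sex, affection = NA))
  phi <- kinshipCoef(pedigreeKinship(pedT))
  for (pair in list(c(1, 3), c(1, 5), c(3, 5), c(5, 6), c(1, 4))) {
    i <- pair[1]; j <- pair[2]
    est <- (mean(idx$h1[i, ] == idx$h1[j, ]) +
            mean(idx$h1[i, ] == idx$h2[j, ]) +
            mean(idx$h2[i, ] == idx$h1[j, ]) +
            mean(idx$h2[i, ] == idx$h2[j, ])) / 4
    expect_equal(est, phi[tmpl$role[i], tmpl$role[j]], tolerance = 0.01)
  }
})

test_that("GLS allele-frequency estimates reduce to known cases", {
  expect_equal(blueAlleleFreq(c(0, 1, 2), diag(3)), 0.5)
  # sib pair with symmetric weights: half the mean
  expect_equal(blueAlleleFreq(c(2, 0), matrix(c(1, .5, .5, 1), 2)), 0.5)
  # all-zero vector clips at the lower bound, never exactly 0
  p <- blueAlleleFreq(rep(0, 4), diag(4))
  expect_equal(p, 1 / 10)
  expect_gt(p, 0)
})

test_that("marker-estimated relationships recover sib-pair kinship", {
  set.seed(5)
  panel <- markerPanel(nMarkers = 2000, nHaplotypes = 2000)
  X <- pedburden:::dropMarkers("sibpair", 40, panel)
  K <- relMatrix(grmEstimate(X, freq = panel$freq))
  sib <- vapply(seq_len(40), function(f) K[f, 40 + f], numeric(1))
  expect_equal(mean(sib), 0.5, tolerance = 0.02)
  unrelated <- K[seq_len(20), 21:40]
  expect_equal(mean(unrelated), 0, tolerance = 0.02)
})

test_that("relationship estimates are unbiased for unrelated samples", {
  set.seed(8)
  maf <- runif(5000, 0.05, 0.5)
  X <- randomDosage(30, 5000, maf = maf)
  K <- relMatrix(grmEstimate(X, freq = maf))
  expect_lt(abs(mean(K[upper.tri(K)])), 0.02)
  expect_lt(abs(mean(diag(K)) - 1), 0.02)
})

test_that("fast quadratic-form correction equals the materialized route", {
  set.seed(12)
  X <- randomDosage(40, 300, seed = 12)
  ct <- phenotypeContrast(rep(c(1, 0), 20))
  pk <- colMeans(X) / 2
  keep <- pmin(pk, 1 - pk) >= 0.05
  full <- correctionFactor(ct, grmEstimate(X, mafBound = 0.05))
  fast <- grmCorrectionFactor(X, ct, freq = pk, keep = keep)
  expect_equal(fast, full, tolerance = 1e-12)
})

test_that("kinship/frequency iteration is a fixed point for unrelated data", {
  set.seed(21)
  X <- randomDosage(60, 1000, maf = runif(1000, 0.1, 0.5))
  fit <- iterateKinshipFreq(X)
  expect_true(fit$converged)
  expect_lte(fit$iterations, 3)
  expect_equal(fit$freq, colMeans(X) / 2, tolerance = 0.02)
  # feeding the result back changes frequencies by less than the applied
  # tolerance plus the last recorded update (fixed-point consistency)
  p2 <- blueAlleleFreq(X, fit$K)
  expect_lt(max(abs(p2 - fit$freq)), fit$tol + fit$lastDelta)
  # a tolerance below the sampling-noise floor caps out with a warning
  expect_warning(fitStrict <- iterateKinshipFreq(X, tol = 1e-6,
                                                 maxIter = 3),
                 "did not converge")
  expect_false(fitStrict$converged)
})

test_that("iterated kinship recovers pedigree relationships from markers", {
  set.seed(31)
  panel <- markerPanel(nMarkers = 1000, nHaplotypes = 2000)
  nFam <- 25
  X <- pedburden:::dropMarkers("threegen", nFam, panel)
  fit <- iterateKinshipFreq(X)
  K <- relMatrix(fit$K)
  Kth <- relMatrix(designKinship(familyDesign("threegen1"),
                                 ceiling(nFam * 4 / 0.5)))
  Kth <- Kth[seq_len(nrow(K)), seq_len(nrow(K))]
  off <- upper.tri(K)
  expect_lt(sqrt(mean((K[off] - Kth[off])^2)), 0.05)
})
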