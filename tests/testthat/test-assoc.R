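# Association statistics: correction factor, collapsing, single marker,
# WSS, VT, permutation machinery.

test_that("correction factor matches hand-evaluated quadratic forms", {
  # identity relationships: always exactly 1, any case/control split
  for (u in list(c(1, 0), c(1, 1, 0), rep(c(1, 0, 0), 5))) {
    ct <- phenotypeContrast(u)
    expect_equal(correctionFactor(ct, diag(length(u))), 1)
    expect_equal(correctionFactor(ct, NULL), 1)
  }
  # full sibs, one affected: c = (.5, -.5), c'Kc = 0.25, P = 2 * 0.25
  ct <- phenotypeContrast(c(1, 0))
  K <- matrix(c(1, .5, .5, 1), 2)
  expect_equal(correctionFactor(ct, K), 0.5)
  # invariance under simultaneous relabeling
  set.seed(30)
  u <- rep(c(1, 0), 10)
  A <- crossprod(matrix(rnorm(400), 20))  # random PSD
  diag(A) <- diag(A) + 1
  perm <- sample(20)
  expect_equal(correctionFactor(phenotypeContrast(u[perm]),
                                A[perm, perm]),
               correctionFactor(phenotypeContrast(u), A))
  expect_error(correctionFactor(phenotypeContrast(c(1, 0)),
                                -diag(2)), "not positive")
})

test_that("collapsing statistic matches hand arithmetic", {
  ct <- phenotypeContrast(c(1, 1, 1, 1, 0, 0, 0, 0))
  # cases z = (1,1,0,0), controls all 0: T_C = 2 * 0.25 / 0.1875
  pop <- collapsingTest(c(1, 1, 0, 0, 0, 0, 0, 0), ct)
  expect_equal(pop$stat, 2 * 0.25 / 0.1875, tolerance = 1e-12)
  expect_equal(pop$H, 0.5 * 2)  # (nc nG / n)(ZA - ZG) = 2 * 0.5 ... = 1
  # equal means give zero
  expect_equal(collapsingTest(rep(c(1, 0), 4), ct)$stat, 0)
  # label swap leaves the squared statistic unchanged
  expect_equal(collapsingTest(c(1, 1, 0, 0, 0, 0, 0, 0),
                              phenotypeContrast(c(0, 0, 0, 0, 1, 1, 1, 1)))$stat,
               pop$stat)
  # constant indicator is degenerate
  expect_true(collapsingTest(rep(1, 8), ct)$degenerate)
  expect_equal(familyCollapsingTest(rep(1, 8), ct, diag(8))@pValue, 1)
})

test_that("family and population forms obey the factorization identity", {
  set.seed(31)
  for (i in 1:40) {
    n <- sample(10:40, 1)
    u <- sample(c(rep(1, ceiling(n / 3)), rep(0, n - ceiling(n / 3))))
    ct <- phenotypeContrast(u)
    z <- rbinom(n, 1, 0.3)
    if (var(z) == 0) next
    A <- crossprod(matrix(rnorm(n * n), n)) / n
    diag(A) <- diag(A) + 0.5
    res <- familyCollapsingTest(z, ct, A)
    expect_equal(res@statFam * res@pCorr, res@statPop, tolerance = 1e-10)
    # Eq H^2 / Gamma equals T_C / P_corr
    expect_equal(res@extra$H^2 / res@extra$Gamma, res@statFam,
                 tolerance = 1e-10)
    # identity relationships reproduce the population statistic exactly
    resI <- familyCollapsingTest(z, ct, diag(n))
    expect_equal(resI@statFam, resI@statPop)
  }
})

test_that("corrected single-marker test equals the allelic chi-squared at K = I", {
  # allele table cases (4,0) / controls (0,4): Pearson chi2 = 8 at n = 4
  ct <- phenotypeContrast(c(1, 1, 0, 0))
  res <- correctedSingleMarker(c(2, 2, 0, 0), ct, diag(4))
  expect_equal(res@statFam, 8, tolerance = 1e-12)
  # balanced dosages give zero
  expect_equal(correctedSingleMarker(c(1, 1, 1, 1), ct, NULL)@statPop, 0)
  # doubling K halves the statistic
  set.seed(32)
  x <- rbinom(12, 2, 0.3)
  u <- rep(c(1, 0), 6)
  r1 <- correctedSingleMarker(x, phenotypeContrast(u), diag(12))
  r2 <- correctedSingleMarker(x, phenotypeContrast(u), 2 * diag(12))
  expect_equal(r2@statFam, r1@statFam / 2, tolerance = 1e-12)
  # oracle: classical allelic chi-squared on random tables
  for (i in 1:20) {
    x <- rbinom(20, 2, runif(1, 0.2, 0.8))
    if (sum(x) %in% c(0, 40)) next
    u <- rep(c(1, 0), 10)
    tab <- rbind(cases = c(sum(x[u == 1]), 2 * 10 - sum(x[u == 1])),
                 controls = c(sum(x[u == 0]), 2 * 10 - sum(x[u == 0])))
    oracle <- suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
    got <- correctedSingleMarker(x, phenotypeContrast(u), NULL)@statFam
    expect_equal(unname(got), unname(oracle), tolerance = 1e-10)
  }
  expect_true(correctedSingleMarker(rep(0, 4), ct, NULL)@degenerate)
})

test_that("rank-sum WSS statistic matches hand arithmetic", {
  # cases gamma = (3,4), controls (1,2): x = 7, mean = 5, var = 5/3
  ct <- phenotypeContrast(c(1, 1, 0, 0))
  out <- wssTest(c(3, 4, 1, 2), ct)
  expect_equal(out$stat, (7 - 5)^2 / (5 / 3), tolerance = 1e-12)
  # all-equal scores: midranks give exactly zero
  expect_equal(wssTest(rep(2, 4), ct)$stat, 0)
  expect_true(wssTest(rep(2, 4), ct)$degenerate)
  # invariance under monotone transforms
  set.seed(33)
  g <- rnorm(30)
  u <- rep(c(1, 0), 15)
  expect_equal(wssTest(exp(g), phenotypeContrast(u))$stat,
               wssTest(g, phenotypeContrast(u))$stat)
})

test_that("variable-threshold statistic maximizes over candidate cuts", {
  set.seed(34)
  X <- randomDosage(40, 10, maf = runif(10, 0.01, 0.04))
  ct <- phenotypeContrast(rep(c(1, 0), 20))
  out <- vtTest(X, ct)
  expect_equal(out$stat, max(out$z^2))
  expect_gte(out$stat, max(out$z[1]^2))
  expect_true(out$threshold %in% out$thresholds)
  # a monomorphic variant changes nothing
  X2 <- cbind(X, 0)
  expect_equal(vtTest(X2, ct)$stat, out$stat)
  # single threshold: the maximum is that threshold's z^2
  X1 <- X[, 1, drop = FALSE]
  o1 <- vtTest(X1, ct)
  expect_length(o1$thresholds, 1)
  expect_equal(o1$stat, o1$z^2)
})

test_that("min-p empirical p-value matches an exhaustive permutation oracle", {
  set.seed(35)
  X <- cbind(c(2, 1, 1, 0, 0, 0),
             c(0, 1, 0, 1, 0, 0),
             c(1, 0, 1, 0, 1, 0))
  u <- c(1, 1, 1, 0, 0, 0)
  ct <- phenotypeContrast(u)
  maxT <- function(uu) {
    cc <- phenotypeContrast(uu)
    max(vapply(1:3, function(k)
      correctedSingleMarker(X[, k], cc, NULL)@statFam, numeric(1)))
  }
  obs <- maxT(u)
  combos <- combn(6, 3)
  exh <- apply(combos, 2, function(idx) {
    uu <- rep(0, 6); uu[idx] <- 1
    maxT(uu)
  })
  oracle <- mean(exh >= obs)  # exhaustive label-permutation distribution
  res <- minpEmpirical(X, ct, K = NULL, B = 4000, seed = 9)
  expect_equal(res@pValue, oracle, tolerance = 0.03)
  # the reported value is an exact permutation count divided by B
  expect_equal(res@pValue * 4000, round(res@pValue * 4000))
  expect_equal(res@pMethod, "permutation")
  expect_error(minpEmpirical(X, ct, B = 0), "at least 1")
})

test_that("permutation p-values are seed-stable in distribution", {
  set.seed(36)
  X <- randomDosage(40, 8, maf = runif(8, 0.02, 0.2))
  ct <- phenotypeContrast(rep(c(1, 0), 20))
  B <- 2000
  p1 <- familyPermutationTest("wss", X, ct, K = NULL, B = B, seed = 1)@pValue
  p2 <- familyPermutationTest("wss", X, ct, K = NULL, B = B, seed = 2)@pValue
  expect_lt(abs(p1 - p2),
            4 * sqrt(max(p1, 1 / B) * (1 - min(p1, 1 - 1 / B)) / B))
  # identical seeds are bit-identical
  expect_identical(
    familyPermutationTest("vt", X, ct, K = NULL, B = 200, seed = 5)@pValue,
    familyPermutationTest("vt", X, ct, K = NULL, B = 200, seed = 5)@pValue)
})

test_that("identity-relationship permutation tests match the uncorrected test", {
  set.seed(37)
  X <- randomDosage(30, 6, maf = runif(6, 0.03, 0.2))
  ct <- phenotypeContrast(rep(c(1, 0), 15))
  for (tst in c("wss", "vt")) {
    pI <- familyPermutationTest(tst, X, ct, K = diag(30), B = 300,
                                seed = 4)@pValue
    pN <- familyPermutationTest(tst, X, ct, K = NULL, B = 300,
                                seed = 4)@pValue
    expect_equal(pI, pN)
  }
})

test_that("permutation p-values are uniform under the null", {
  set.seed(38)
  ps <- vapply(1:150, function(i) {
    X <- randomDosage(24, 5, maf = runif(5, 0.05, 0.3))
    u <- sample(rep(c(1, 0), 12))
    familyPermutationTest("wss", X, phenotypeContrast(u), K = NULL,
                          B = 99, seed = i)@pValue
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("inflating case indicators weakly increases the family statistic", {
  u <- rep(c(1, 0), 20)
  ct <- phenotypeContrast(u)
  K <- relMatrix(designKinship("case_control", 40))
  # cases already carry more than controls; flipping case non-carriers to
  # carriers can only strengthen the signal
  z <- as.numeric(u == 1 & seq_along(u) <= 24) + 0
  z[u == 0][1:2] <- 1
  base <- familyCollapsingTest(z, ct, K)@statFam
  for (flip in which(u == 1 & z == 0)) {
    z2 <- z
    z2[flip] <- 1
    expect_gte(familyCollapsingTest(z2, ct, K)@statFam, base)
  }
})
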