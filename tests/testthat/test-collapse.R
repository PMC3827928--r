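# Collapsing, weights, thresholds, Mendel checks.

test_that("minor allele frequencies match explicit allele tallies", {
  expect_equal(unname(computeMaf(matrix(c(0, 0, 1), 3, 1))), 1 / 6)
  expect_equal(unname(computeMaf(matrix(c(2, 2, 2), 3, 1))), 0)
  set.seed(14)
  for (i in 1:25) {
    X <- randomDosage(8, 6)
    X[sample(length(X), 5)] <- NA
    maf <- suppressWarnings(computeMaf(X))
    oracle <- apply(X, 2, function(x) {
      x <- x[!is.na(x)]
      if (length(x) == 0) return(NA_real_)
      f <- sum(x) / (2 * length(x))
      min(f, 1 - f)
    })
    expect_equal(unname(maf), unname(oracle))
  }
  expect_warning(computeMaf(matrix(NA_real_, 3, 1)), "missing")
})

test_that("collapsing equals the OR of per-variant carrier indicators", {
  X <- matrix(c(0, 1, 0,
                0, 0, 0), 3, 2)
  cv <- collapseRegion(X, mafThreshold = 0.5)
  expect_equal(cv@z, c(0, 1, 0))
  expect_equal(cv@sigma2, cv@p * (1 - cv@p))
  set.seed(15)
  for (i in 1:20) {
    X <- randomDosage(20, 8, maf = runif(8, 0.01, 0.2))
    cv <- collapseRegion(X, mafThreshold = 1)
    oracle <- as.numeric(apply(X >= 1, 1, any))
    expect_equal(cv@z, oracle)
    expect_equal(cv@sigma2, cv@p * (1 - cv@p), tolerance = 1e-15)
  }
})

test_that("collapsing respects the MAF threshold and missing rules", {
  X <- cbind(rare = c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0),
             common = c(2, 2, 1, 1, 1, 1, 0, 0, 0, 0))
  cv <- collapseRegion(X, mafThreshold = 0.1)
  expect_equal(cv@variants, 1L)
  expect_equal(cv@z, c(1, rep(0, 9)))
  expect_error(collapseRegion(X, mafThreshold = 0.001),
               "nothing to collapse")
  Xm <- X; Xm[2, 1] <- NA
  expect_equal(collapseRegion(Xm, mafThreshold = 0.1)@z[2], 0)  # NA -> 0
  cvd <- collapseRegion(Xm, mafThreshold = 0.1, missingAction = "drop")
  expect_true(is.na(cvd@z[2]))
})

test_that("an externally supplied MAF vector overrides the sample filter", {
  X <- cbind(a = c(1, 1, 1, 0), b = c(0, 1, 0, 0))
  cv <- collapseRegion(X, mafThreshold = 0.2, maf = c(0.001, 0.5))
  expect_equal(cv@variants, 1L)
})

test_that("weighted scores follow the unaffected-frequency weighting", {
  # single variant, 2 unaffected with dosages 0,1; 2 affected with 2,0:
  # zeta = (1+1)/(2*2+2) = 1/3, w = sqrt(4 * (1/3)(2/3)) = 0.9428
  X <- matrix(c(2, 0, 0, 1), 4, 1)
  u <- c(1, 1, 0, 0)
  sc <- wssScore(X, u)
  expect_equal(sc$weights, sqrt(4 * (1 / 3) * (2 / 3)), tolerance = 1e-4)
  expect_equal(sc$score, as.numeric(X / sc$weights))
  # all-zero dosages give all-zero scores
  expect_equal(wssScore(matrix(0, 4, 3), u)$score, rep(0, 4))
  expect_error(wssScore(X, c(1, 1, 1, 1)), "no unaffected")
})

test_that("weights ignore affected genotypes and variant order", {
  set.seed(16)
  X <- randomDosage(30, 10)
  u <- rep(c(1, 0), 15)
  w1 <- wssScore(X, u)$weights
  Xp <- X
  Xp[u == 1, ] <- Xp[sample(which(u == 1)), ]  # permute affected rows
  expect_equal(wssScore(Xp, u)$weights, w1)
  perm <- sample(10)
  expect_equal(unname(wssScore(X[, perm], u)$score),
               unname(wssScore(X, u)$score))
})

test_that("variable-threshold candidates are the sorted unique rare MAFs", {
  X <- cbind(c(0, 1, 0, 0, 0, 0, 0, 0, 0, 0, rep(0, 40)),
             c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0, rep(0, 40)),
             c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0, rep(0, 40)))
  thr <- vtThresholds(X, upperBound = 0.05)
  expect_equal(thr, c(0.01, 0.03))
  expect_length(vtThresholds(X, upperBound = 0.001), 0)
  expect_lte(length(vtThresholds(randomDosage(30, 12, seed = 2))), 12)
})

test_that("Mendel checks match exhaustive transmission enumeration", {
  allowed <- function(f, m) {
    A <- function(g) switch(g + 1, 0, c(0, 1), 1)
    unique(outer(A(f), A(m), "+"))
  }
  grid <- expand.grid(f = 0:2, m = 0:2, c = 0:2)
  oracle <- mapply(function(f, m, c) c %in% allowed(f, m),
                   grid$f, grid$m, grid$c)
  got <- pedburden:::mendelCompatible(grid$c, grid$f, grid$m)
  expect_equal(unname(got), unname(oracle))
})

test_that("violations are reported per individual and variant", {
  ped <- toyPedigree()
  X <- matrix(0, 6, 2, dimnames = list(pedigree(ped)$id, c("v1", "v2")))
  X["kid1", "v1"] <- 1  # parents 0/0 -> impossible
  X["kid2", "v2"] <- 1
  X["dad", "v2"] <- 1   # het parent: both child dosages are fine
  g <- PedGenotypes(X, ped)
  v <- mendelCheck(g)
  expect_equal(nrow(v), 1)
  expect_equal(v$individual, "kid1")
  expect_equal(v$variant, "v1")
})
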