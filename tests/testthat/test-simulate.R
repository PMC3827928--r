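# Founder pool, designs, gene dropping, penetrance, ascertainment.

test_that("founder pools are seed-reproducible and rare-skewed", {
  p1 <- buildFounderPool(n0 = 100, nMax = 200, generations = 25,
                         regionLength = 2e5, seed = 7)
  p2 <- buildFounderPool(n0 = 100, nMax = 200, generations = 25,
                         regionLength = 2e5, seed = 7)
  expect_identical(p1@haplotypes, p2@haplotypes)
  expect_identical(p1@pos, p2@pos)
  pool <- smallPool()
  maf <- pmin(pool@freq, 1 - pool@freq)
  expect_gte(mean(maf <= 0.01), 0.5)  # most segregating sites are rare
})

test_that("zero mutation rate exhausts retries with an error", {
  expect_error(buildFounderPool(n0 = 30, nMax = 60, generations = 5,
                                mutationRate = 0, seed = 1, maxRetry = 2),
               "no segregating sites")
})

test_that("segregating-site counts grow with region length", {
  s <- vapply(c(5e4, 2e5, 8e5), function(L) {
    mean(vapply(1:3, function(i)
      ncol(buildFounderPool(n0 = 80, nMax = 160, generations = 25,
                            regionLength = L,
                            seed = 100 + i)@haplotypes), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(s) > 0))
})

test_that("gene dropping transmits haplotypes Mendelianly", {
  pool <- smallPool()
  # a pool of identical haplotypes makes every individual identical
  mono <- pool
  mono@haplotypes <- matrix(1L, 10, 3)
  mono@freq <- rep(0.5, 3)  # placate validity; contents are what matters
  mono@pos <- 1:3
  gd <- geneDrop("sibpair", 5, mono, seed = 1)
  expect_true(all(gd$dosage == 2))

  # sib IBD sharing 0/1/2 with probabilities 1/4, 1/2, 1/4
  set.seed(50)
  tmpl <- pedburden:::designTemplates()$sibpair
  idx <- pedburden:::geneDropIndices(tmpl, 2e4, H = 1e7)
  shared <- (idx$h1[3, ] == idx$h1[4, ]) + (idx$h2[3, ] == idx$h2[4, ])
  tab <- tabulate(shared + 1, 3)
  expect_gt(chisq.test(tab, p = c(.25, .5, .25))$p.value, 0.01)

  # dropped genotypes contain no Mendelian violations
  d <- simulateDataset("nuclear1", "null", n = 60, pool = pool, seed = 3)
  expect_equal(nrow(mendelCheck(d$gene)), 0)
})

test_that("relative risks follow the attributable-risk calibration", {
  pool <- smallPool()
  pen <- calibrateRelativeRisks(pool, "dominant", pcv = 0.3, seed = 2)
  q <- pool@freq[pen@causal]
  carrier <- 1 - (1 - q)^2
  expect_equal(pen@gamma1, 1 + 0.006 / (carrier * (1 - 0.006)),
               tolerance = 1e-12)
  expect_equal(pen@gamma2, pen@gamma1)
  # hand example: carrier frequency 0.01 gives gamma = 1.6036
  expect_equal(1 + 0.006 / (0.01 * (1 - 0.006)), 1.60362,
               tolerance = 1e-4)
  # rarer variants get larger risks
  ord <- order(carrier)
  expect_true(all(diff(pen@gamma1[ord]) <= 0))
  # model identities
  penA <- calibrateRelativeRisks(pool, "additive", pcv = 0.2, seed = 2)
  expect_equal(penA@gamma2, 2 * penA@gamma1 - 1)
  penM <- calibrateRelativeRisks(pool, "multiplicative", pcv = 0.2, seed = 2)
  expect_equal(penM@gamma2, penM@gamma1^2)
  penR <- calibrateRelativeRisks(pool, "recessive", pcv = 0.2, seed = 2)
  expect_true(all(penR@gamma1 == 1))
  # bidirectional: half the causal set becomes protective
  penB <- calibrateRelativeRisks(pool, "dominant", pcv = 0.3,
                                 bidirectional = TRUE, seed = 2)
  expect_equal(sum(penB@direction < 0), floor(length(penB@causal) / 2))
  expect_true(all(penB@gamma1[penB@direction < 0] < 1))
  expect_error(calibrateRelativeRisks(pool, "dominant", pcv = 0.2,
                                      par = 1.5), "< 1")
})

test_that("penetrance assignment honours the model", {
  pool <- smallPool()
  pen <- calibrateRelativeRisks(pool, "dominant", pcv = 0.2, seed = 4)
  X <- matrix(0, 5, ncol(pool@haplotypes))
  # non-carrier penetrance is exactly f0
  expect_equal(pedburden:::penetranceOf(X, pen), rep(0.01, 5))
  # one causal het multiplies by exactly gamma1
  X[1, pen@causal[1]] <- 1
  expect_equal(unname(pedburden:::penetranceOf(X, pen)[1]),
               unname(0.01 * pen@gamma1[1]))
  # neutral model: prevalence matches f0
  pen0 <- pen
  pen0@gamma1[] <- 1
  pen0@gamma2[] <- 1
  set.seed(6)
  Xr <- pool@haplotypes[sample(nrow(pool@haplotypes), 4000, TRUE), ] +
    pool@haplotypes[sample(nrow(pool@haplotypes), 4000, TRUE), ]
  aff <- assignPhenotype(Xr, pen0, seed = 8)
  expect_lt(abs(mean(aff) - 0.01), 0.005)
})

test_that("baseline calibration hits the target prevalence", {
  pool <- smallPool()
  pen <- calibrateRelativeRisks(pool, "dominant", pcv = 0.2, seed = 4)
  penP <- calibrateBaseline(pool, pen, prevalence = 0.09, seed = 9)
  set.seed(10)
  H <- nrow(pool@haplotypes)
  Xr <- pool@haplotypes[sample(H, 6000, TRUE), ] +
    pool@haplotypes[sample(H, 6000, TRUE), ]
  aff <- assignPhenotype(Xr, penP, seed = 11)
  expect_lt(abs(mean(aff) - 0.09), 0.015)
})

test_that("designs compose multiplex units and controls at the stated ratio", {
  for (nm in c("case_control", "sibpair1", "sibpair2", "nuclear2",
               "threegen1", "mix1", "mix2", "mix_cc")) {
    d <- familyDesign(nm)
    cnt <- pedburden:::designCounts(d, 900)
    expect_equal(cnt$nCases / cnt$nControls, d$ratio, tolerance = 0.06)
  }
  # every ascertained family unit carries at least two affected members
  tmpl <- pedburden:::designTemplates()
  for (nm in c("sibpair", "nuclear", "threegen"))
    expect_gte(sum(tmpl[[nm]]$sampled & tmpl[[nm]]$affected), 2)
})

test_that("null datasets match the design labels and are reproducible", {
  pool <- smallPool()
  d1 <- simulateDataset("sibpair2", "null", n = 90, pool = pool, seed = 21)
  d2 <- simulateDataset("sibpair2", "null", n = 90, pool = pool, seed = 21)
  expect_identical(dosages(d1$gene), dosages(d2$gene))
  ped <- pedigree(d1$ped)
  expect_equal(nCases(d1$ped) / nControls(d1$ped), 2, tolerance = 0.05)
  # affected sibs share a pedigree; controls are singletons
  fams <- table(ped$pedigree[ped$affection == 1])
  expect_true(all(fams == 2))
})

test_that("ascertained alternatives enrich cases for causal variants", {
  pool <- smallPool()
  pen <- calibrateRelativeRisks(pool, "dominant", pcv = 0.2, seed = 4)
  d <- simulateDataset("sibpair2", "alternative", n = 120, pool = pool,
                       pen = pen, seed = 22)
  X <- dosages(d$gene)
  u <- pedigree(d$ped)$affection
  caseCarrier <- mean(rowSums(X[u == 1, pen@causal, drop = FALSE]) > 0)
  ctlCarrier <- mean(rowSums(X[u == 0, pen@causal, drop = FALSE]) > 0)
  expect_gt(caseCarrier, ctlCarrier)
  # with no causal variants the alternative degenerates to the null
  pen0 <- calibrateRelativeRisks(pool, "dominant", pcv = 0, seed = 4)
  expect_length(pen0@causal, 0)
  d0 <- simulateDataset("sibpair2", "alternative", n = 120, pool = pool,
                        pen = pen0, seed = 23)
  expect_equal(nCases(d0$ped), 80)
})

test_that("null test-gene genotypes are independent of affection", {
  pool <- smallPool()
  set.seed(24)
  cors <- vapply(1:40, function(i) {
    d <- simulateDataset("case_control", "null", n = 80, pool = pool)
    z <- collapseRegion(d$gene, mafThreshold = 0.05)@z
    u <- pedigree(d$ped)$affection
    if (var(z) == 0) return(0)
    cor(z, u)
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.05)
})

test_that("design kinship blocks mirror the unit templates", {
  K <- relMatrix(designKinship("threegen1", 8))
  # one family of GF, P, C1, C2 (member-major with nFam = 1)
  expect_equal(K[1, 2], 0.5)   # grandparent-parent
  expect_equal(K[1, 3], 0.25)  # grandparent-grandchild
  expect_equal(K[2, 3], 0.5)   # parent-child
  expect_equal(K[3, 4], 0.5)   # sibs
  expect_equal(unname(diag(K)), rep(1, nrow(K)))
  expect_true(all(K[5:nrow(K), 1:4] == 0))
})
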