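# Shared fixtures, built in code.

.fixtureEnv <- new.env(parent = emptyenv())

# Small Wright-Fisher founder pool, built once per test run.
smallPool <- function() {
  if (is.null(.fixtureEnv$pool))
    .fixtureEnv$pool <- buildFounderPool(n0 = 200, nMax = 400,
                                         generations = 40,
                                         regionLength = 3e5, seed = 42)
  .fixtureEnv$pool
}

# Default-parameter pool for the acceptance-scale experiments.
deskPool <- function() {
  if (is.null(.fixtureEnv$deskPool))
    .fixtureEnv$deskPool <- buildFounderPool(seed = 11)
  .fixtureEnv$deskPool
}

# A nuclear-family pedigree (both parents genotyped) plus two singletons.
toyPedigree <- function() {
  PedigreeSet(data.frame(
    pedigree = c("F1", "F1", "F1", "F1", "U1", "U2"),
    id = c("dad", "mum", "kid1", "kid2", "solo1", "solo2"),
    father = c(NA, NA, "dad", "dad", NA, NA),
    mother = c(NA, NA, "mum", "mum", NA, NA),
    sex = c(1, 2, 1, 2, 1, 2),
    affection = c(0, 0, 1, 1, 1, 0),
    stringsAsFactors = FALSE))
}

# Write a tiny PED/MAP pair; returns the two paths.
writeToyPedMap <- function(dir = tempfile("pedmap")) {
  dir.create(dir)
  ped <- file.path(dir, "toy.ped")
  map <- file.path(dir, "toy.map")
  writeLines(c(
    "F1 I1 0 0 1 2 A A G T C C",
    "F1 I2 0 0 2 1 A T T T C G",
    "F2 I3 0 0 1 0 A A T T 0 0"), ped)
  writeLines(c("1 rs1 0 100", "1 rs2 0 200", "2 rs3 0 50"), map)
  list(ped = ped, map = map)
}

# Random dosage matrix with minor-allele coding.
randomDosage <- function(n, m, maf = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(maf)) maf <- runif(m, 0.02, 0.45)
  matrix(rbinom(n * m, 2, rep(maf, each = n)), n, m)
}
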