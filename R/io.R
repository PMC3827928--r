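# Reading and writing pedigree, genotype, region and result files.

#' Read PLINK-style PED/MAP files
#'
#' Parses a whitespace-delimited PED file (six leading columns: family id,
#' individual id, father, mother, sex, affection; then two allele columns per
#' variant) together with its MAP file (chrom, variant id, genetic distance,
#' position).  Dosages count the minor allele, with the minor allele
#' determined from the full sample at each variant; allele code \code{"0"}
#' marks a missing allele and yields a missing dosage.  Affection is recoded
#' from PLINK conventions: 2 = affected -> 1, 1 = unaffected -> 0, 0 or -9 ->
#' missing.
#'
#' @param pedPath,mapPath Paths to the PED and MAP files.
#' @return A \linkS4class{PedGenotypes} object.
#' @examples
#' ped <- tempfile(fileext = ".ped"); map <- tempfile(fileext = ".map")
#' writeLines(c("F1 I1 0 0 1 2 A A G T", "F1 I2 0 0 2 1 A T T T"), ped)
#' writeLines(c("1 rs1 0 100", "1 rs2 0 200"), map)
#' g <- readPedMap(ped, map)
#' dosages(g)
#' @export
readPedMap <- function(pedPath, mapPath) {
  stopIf(!file.exists(pedPath), "PED file not found: ", pedPath)
  stopIf(!file.exists(mapPath), "MAP file not found: ", mapPath)
  map <- read.table(mapPath, header = FALSE, stringsAsFactors = FALSE)
  stopIf(ncol(map) < 4, "MAP file must have >= 4 columns")
  names(map)[1:4] <- c("chrom", "id", "cm", "pos")
  m <- nrow(map)

  lines <- readLines(pedPath)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * m
  lens <- lengths(toks)
  if (any(lens != want)) {
    bad <- which(lens != want)[1]
    stop("malformed PED line ", bad, ": expected ", want, " fields, found ",
         lens[bad], call. = FALSE)
  }
  tok <- matrix(unlist(toks), nrow = length(toks), byrow = TRUE)
  ids <- tok[, 2]
  stopIf(anyDuplicated(ids) > 0, "duplicate individual id in PED: ",
         ids[duplicated(ids)][1])
  aff <- suppressWarnings(as.integer(tok[, 6]))
  aff <- ifelse(is.na(aff) | aff %in% c(0L, -9L), NA_integer_,
                ifelse(aff == 2L, 1L, ifelse(aff == 1L, 0L, NA_integer_)))
  ped <- PedigreeSet(data.frame(
    pedigree = tok[, 1], id = ids,
    father = ifelse(tok[, 3] == "0", NA, tok[, 3]),
    mother = ifelse(tok[, 4] == "0", NA, tok[, 4]),
    sex = ifelse(tok[, 5] %in% c("1", "2"), tok[, 5], NA),
    affection = aff, stringsAsFactors = FALSE))

  n <- length(ids)
  a1 <- tok[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- tok[, 6L + 2L * seq_len(m), drop = FALSE]
  dosage <- matrix(NA_real_, n, m, dimnames = list(ids, map$id))
  alleles <- character(2 * m)
  for (k in seq_len(m)) {
    obs <- c(a1[, k], a2[, k])
    obs <- obs[obs != "0"]
    lev <- sort(unique(obs))
    stopIf(length(lev) > 2, "variant ", map$id[k], " has >2 alleles")
    if (length(lev) == 0) lev <- c("?", "?")
    counts <- table(factor(obs, levels = lev))
    # minor allele = least frequent; deterministic tie-break on allele order
    minor <- lev[which.min(counts)]
    major <- if (length(lev) == 2) setdiff(lev, minor) else minor
    alleles[2 * k - 1] <- minor
    alleles[2 * k] <- major
    d <- (a1[, k] == minor) + (a2[, k] == minor)
    d[a1[, k] == "0" | a2[, k] == "0"] <- NA_real_
    dosage[, k] <- d
  }
  vi <- data.frame(id = map$id, chrom = map$chrom, pos = map$pos,
                   minor = alleles[2 * seq_len(m) - 1],
                   major = alleles[2 * seq_len(m)],
                   stringsAsFactors = FALSE)
  PedGenotypes(dosage, ped, vi)
}

#' Write a PedGenotypes object as PED/MAP
#'
#' Inverse of \code{\link{readPedMap}}: dosages are expanded back to allele
#' pairs (minor/major codes from the variant metadata, or \code{"A"}/
#' \code{"B"} when absent) and affection is recoded to PLINK 2/1/0.
#'
#' @param x A \linkS4class{PedGenotypes}.
#' @param pedPath,mapPath Output paths.
#' @return \code{pedPath}, invisibly.
#' @export
writePed <- function(x, pedPath, mapPath) {
  ped <- pedigree(pedigree(x))
  dos <- dosages(x)
  vi <- variantInfo(x)
  minor <- if (!is.null(vi$minor)) vi$minor else rep("A", nrow(vi))
  major <- if (!is.null(vi$major)) vi$major else rep("B", nrow(vi))
  n <- nrow(dos); m <- ncol(dos)
  allele <- matrix("0", n, 2 * m)
  for (k in seq_len(m)) {
    d <- dos[, k]
    allele[, 2 * k - 1] <- ifelse(is.na(d), "0",
                                  ifelse(d >= 1, minor[k], major[k]))
    allele[, 2 * k] <- ifelse(is.na(d), "0",
                              ifelse(d == 2, minor[k], major[k]))
  }
  aff <- ped$affection
  affOut <- ifelse(is.na(aff), "0", ifelse(aff == 1L, "2", "1"))
  lead <- cbind(ped$pedigree, ped$id,
                ifelse(is.na(ped$father), "0", ped$father),
                ifelse(is.na(ped$mother), "0", ped$mother),
                ifelse(is.na(ped$sex), "0", as.character(ped$sex)),
                affOut)
  writeLines(apply(cbind(lead, allele), 1, paste, collapse = " "), pedPath)
  chrom <- if (!is.null(vi$chrom)) vi$chrom else rep(1, m)
  pos <- if (!is.null(vi$pos)) vi$pos else seq_len(m)
  writeLines(paste(chrom, vi$id, 0, pos, sep = "\t"), mapPath)
  invisible(pedPath)
}

#' Read genotypes from VCF plus a PLINK FAM file
#'
#' Extracts GT fields from a VCF 4.x file (phased and unphased separators
#' parse identically; \code{"./."} yields a missing dosage, and the dosage
#' counts ALT alleles) and takes pedigree structure and affection status from
#' a six-column FAM file.  Sample ids must match between the two files;
#' individuals are returned in FAM order.
#'
#' @param vcfPath,famPath Paths to the VCF and FAM files.
#' @return A \linkS4class{PedGenotypes}.
#' @export
readVcfFam <- function(vcfPath, famPath) {
  stopIf(!file.exists(vcfPath), "VCF file not found: ", vcfPath)
  stopIf(!file.exists(famPath), "FAM file not found: ", famPath)
  vcf <- vcfR::read.vcfR(vcfPath, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  fam <- read.table(famPath, header = FALSE, stringsAsFactors = FALSE)
  stopIf(ncol(fam) < 6, "FAM file must have 6 columns")
  names(fam)[1:6] <- c("pedigree", "id", "father", "mother", "sex", "aff")
  vcfIds <- colnames(gt)
  missing <- setdiff(fam$id, vcfIds)
  extra <- setdiff(vcfIds, fam$id)
  stopIf(length(missing) > 0 || length(extra) > 0,
         "sample ids differ between VCF and FAM; missing in VCF: [",
         paste(missing, collapse = ","), "]; absent from FAM: [",
         paste(extra, collapse = ","), "]")
  gt <- gt[, fam$id, drop = FALSE]
  alt <- function(g) {
    al <- strsplit(g, "[/|]")
    vapply(al, function(a) {
      if (any(a == ".") || length(a) != 2) NA_real_
      else sum(a != "0")
    }, numeric(1))
  }
  dosage <- apply(gt, 2, alt)
  if (is.null(dim(dosage)))
    dosage <- matrix(dosage, nrow = 1, dimnames = list(NULL, fam$id))
  dosage <- t(dosage)
  vid <- rownames(gt)
  if (is.null(vid))
    vid <- paste0(vcf@fix[, "CHROM"], ":", vcf@fix[, "POS"])
  colnames(dosage) <- vid
  aff <- suppressWarnings(as.integer(fam$aff))
  aff <- ifelse(is.na(aff) | aff %in% c(0L, -9L), NA_integer_,
                ifelse(aff == 2L, 1L, ifelse(aff == 1L, 0L, NA_integer_)))
  ped <- PedigreeSet(data.frame(
    pedigree = fam$pedigree, id = fam$id,
    father = ifelse(fam$father == "0", NA, fam$father),
    mother = ifelse(fam$mother == "0", NA, fam$mother),
    sex = fam$sex, affection = aff, stringsAsFactors = FALSE))
  vi <- data.frame(id = vid,
                   chrom = as.character(vcf@fix[, "CHROM"]),
                   pos = as.numeric(vcf@fix[, "POS"]),
                   stringsAsFactors = FALSE)
  PedGenotypes(dosage, ped, vi)
}

#' Read a region-to-variant map
#'
#' Two-column tab-separated text: region name, variant id.  Regions are
#' inclusive variant lists.
#'
#' @param path File path.
#' @param x A \linkS4class{PedGenotypes} used to resolve variant ids to
#'   column indices; unknown ids raise an error.
#' @return Named list mapping each region to an integer vector of variant
#'   column indices.
#' @export
readRegions <- function(path, x) {
  tab <- read.table(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
  stopIf(ncol(tab) < 2, "region file must have 2 tab-separated columns")
  ids <- variantInfo(x)$id
  idx <- match(tab[[2]], ids)
  stopIf(anyNA(idx), "unknown variant id in region file: ",
         tab[[2]][is.na(idx)][1])
  out <- split(idx, tab[[1]])
  lapply(out, function(i) {
    stopIf(anyDuplicated(i) > 0, "duplicate variant index within a region")
    i
  })
}

#' Write association results as a tab-separated table
#'
#' One row per region with the four test statistics and their p-values in
#' scientific notation (columns: region, n_variants, then statistic and
#' p-value per test in a deterministic order).
#'
#' @param results Named list (by region) of lists of
#'   \linkS4class{AssocResult} objects.
#' @param path Output path.
#' @param nVariants Optional named integer vector of variant counts per
#'   region.
#' @return \code{path}, invisibly.
#' @export
writeResults <- function(results, path, nVariants = NULL) {
  tests <- c("single_marker", "collapsing", "vt", "wss")
  header <- c("region", "n_variants",
              unlist(lapply(tests, function(t) c(t, paste0(t, "_p")))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  for (rg in names(results)) {
    res <- results[[rg]]
    byName <- setNames(res, vapply(res, function(r) r@test, character(1)))
    nv <- if (!is.null(nVariants)) nVariants[[rg]] else NA
    fields <- c(rg, as.character(nv))
    for (t in tests) {
      r <- byName[[t]]
      if (is.null(r)) {
        fields <- c(fields, "NA", "NA")
      } else {
        fields <- c(fields, format(r@statFam, digits = 12),
                    format(r@pValue, scientific = TRUE, digits = 12))
      }
    }
    writeLines(paste(fields, collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname writeResults
#' @export
readResults <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
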