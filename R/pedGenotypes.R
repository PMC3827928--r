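#' PedGenotypes: allele-dosage matrix aligned to a pedigree
#'
#' Genotypes are stored as a \linkS4class{SummarizedExperiment} with one
#' assay \code{"dosage"} holding minor-allele counts (variants in rows,
#' individuals in columns; \code{NA} = missing), variant metadata in
#' \code{rowData} (id, chrom, pos, maf, region) and the matching
#' \linkS4class{PedigreeSet} in the \code{pedigree} slot.  Column order is
#' identical to the individual order of the pedigree, so statistics indexed
#' by individual line up by construction.
#'
#' \code{dosages()} returns the transposed n x m individuals-by-variants
#' matrix used throughout the statistical layer.
#'
#' @param dosage Numeric n x m matrix, individuals in rows, variants in
#'   columns; values 0/1/2/NA count copies of the minor allele.
#' @param ped A \linkS4class{PedigreeSet} whose individual order matches the
#'   rows of \code{dosage}.
#' @param variants Optional \code{data.frame} of per-variant metadata with at
#'   least an \code{id} column; a \code{region} column assigns variants to
#'   genes/regions.
#' @param x A \code{PedGenotypes} object.
#' @param ... Unused.
#'
#' @return \code{PedGenotypes()} returns a validated object. \code{dosages()}
#'   returns the n x m dosage matrix, \code{variantInfo()} the variant
#'   metadata, \code{regions()} a named list mapping region labels to variant
#'   column indices.
#'
#' @examples
#' ped <- PedigreeSet(data.frame(pedigree = c("F1", "F2"), id = c("a", "b"),
#'   father = NA, mother = NA, sex = 1, affection = c(1, 0)))
#' g <- PedGenotypes(matrix(c(0, 1, 2, 0), 2, 2,
#'                          dimnames = list(c("a", "b"), c("v1", "v2"))), ped)
#' dosages(g)
#' @aliases dosages variantInfo regions
#' @export
PedGenotypes <- function(dosage, ped, variants = NULL) {
  stopIf(!is.matrix(dosage), "'dosage' must be a matrix")
  stopIf(nrow(dosage) != nrow(pedigree(ped)),
         "dosage rows (", nrow(dosage), ") != pedigree individuals (",
         nrow(pedigree(ped)), ")")
  if (is.null(rownames(dosage))) rownames(dosage) <- pedigree(ped)$id
  stopIf(!identical(rownames(dosage), pedigree(ped)$id),
         "dosage row order must match pedigree individual order")
  if (is.null(colnames(dosage)))
    colnames(dosage) <- paste0("v", seq_len(ncol(dosage)))
  if (is.null(variants))
    variants <- data.frame(id = colnames(dosage))
  stopIf(nrow(variants) != ncol(dosage),
         "variant metadata rows must match dosage columns")
  se <- SummarizedExperiment(
    assays = list(dosage = t(dosage)),
    rowData = S4Vectors::DataFrame(variants))
  new("PedGenotypes", se, pedigree = ped)
}

#' @export
setClass("PedGenotypes",
         contains = "SummarizedExperiment",
         representation(pedigree = "PedigreeSet"))

setValidity("PedGenotypes", function(object) {
  if (!"dosage" %in% assayNames(object))
    return("assay 'dosage' is required")
  if (!identical(colnames(object), pedigree(object@pedigree)$id))
    return("column order must equal pedigree individual order")
  TRUE
})

#' @rdname PedGenotypes
#' @export
setMethod("dosages", "PedGenotypes", function(x, ...) t(assay(x, "dosage")))

#' @rdname PedGenotypes
#' @export
setMethod("pedigree", "PedGenotypes", function(x, ...) x@pedigree)

#' @rdname PedGenotypes
#' @export
setMethod("affection", "PedGenotypes", function(x, ...) affection(x@pedigree))

#' @rdname PedGenotypes
#' @export
setMethod("variantInfo", "PedGenotypes", function(x, ...) {
  as.data.frame(rowData(x))
})

#' @rdname PedGenotypes
#' @export
setMethod("regions", "PedGenotypes", function(x, ...) {
  vi <- variantInfo(x)
  if (is.null(vi$region)) return(setNames(list(seq_len(nrow(vi))), "all"))
  split(seq_len(nrow(vi)), vi$region)
})

setMethod("show", "PedGenotypes", function(object) {
  cat("PedGenotypes:", ncol(object), "individuals x", nrow(object),
      "variants\n")
  show(object@pedigree)
})
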