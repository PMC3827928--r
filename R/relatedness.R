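#' RelatednessMatrix: genetic relationship matrix with kinship accessors
#'
#' Holds the n x n symmetric genetic relationship matrix \eqn{K}.  Its
#' off-diagonal entries equal twice the kinship coefficient,
#' \eqn{K_{ij} = 2\phi_{ij}}, and its diagonal equals one plus the
#' inbreeding coefficient, \eqn{K_{ii} = 1 + h_i}.  This is the matrix that
#' enters every covariance and correction-factor computation; kinship
#' \eqn{\phi} and inbreeding \eqn{h} are reported as derived descriptive
#' quantities (\code{kinshipCoef()}, \code{inbreeding()}).
#'
#' @param K Symmetric numeric matrix.
#' @param method How the matrix was obtained: \code{"estimated"} (from
#'   genotypes), \code{"theoretical"} (pedigree recursion),
#'   \code{"identity"}, or \code{"imported"}.
#' @param freq Optional per-variant allele-frequency vector used during
#'   estimation.
#' @param x A \code{RelatednessMatrix}.
#' @param ... Unused.
#'
#' @return \code{RelatednessMatrix()} returns a validated object.
#'   \code{relMatrix()} returns \eqn{K}; \code{kinshipCoef()} the kinship
#'   matrix \eqn{K/2}; \code{inbreeding()} the vector \eqn{diag(K) - 1};
#'   \code{alleleFreq()} the stored frequency vector (or \code{NULL}).
#'
#' @examples
#' K <- RelatednessMatrix(matrix(c(1, .5, .5, 1), 2), method = "theoretical")
#' inbreeding(K)
#' @aliases relMatrix kinshipCoef inbreeding alleleFreq
#' @export
RelatednessMatrix <- function(K, method = c("estimated", "theoretical",
                                            "identity", "imported"),
                              freq = NULL) {
  method <- match.arg(method)
  K <- (K + t(K)) / 2  # enforce exact symmetry
  new("RelatednessMatrix", K = K, method = method,
      freq = if (is.null(freq)) numeric(0) else freq)
}

#' @export
setClass("RelatednessMatrix",
         representation(K = "matrix", method = "character",
                        freq = "numeric"))

setValidity("RelatednessMatrix", function(object) {
  K <- object@K
  if (nrow(K) != ncol(K)) return("K must be square")
  if (!isSymmetric(unname(K), tol = 1e-8)) return("K must be symmetric")
  if (any(diag(K) < 0)) return("diagonal of K must be non-negative")
  TRUE
})

#' @rdname RelatednessMatrix
#' @export
setMethod("relMatrix", "RelatednessMatrix", function(x, ...) x@K)

#' @rdname RelatednessMatrix
#' @export
setMethod("kinshipCoef", "RelatednessMatrix", function(x, ...) x@K / 2)

#' @rdname RelatednessMatrix
#' @export
setMethod("inbreeding", "RelatednessMatrix", function(x, ...) {
  setNames(diag(x@K) - 1, rownames(x@K))
})

#' @rdname RelatednessMatrix
#' @export
setMethod("alleleFreq", "RelatednessMatrix", function(x, ...) {
  if (length(x@freq) == 0) NULL else x@freq
})

setMethod("show", "RelatednessMatrix", function(object) {
  K <- object@K
  off <- K[upper.tri(K)]
  cat("RelatednessMatrix (", object@method, "): ", nrow(K), " x ", ncol(K),
      "\n  mean off-diagonal: ", signif(mean(off), 4),
      "  mean diagonal: ", signif(mean(diag(K)), 4), "\n", sep = "")
})

#' Export / import a relatedness matrix as TSV
#'
#' The text format is a header line of individual ids followed by the n x n
#' numeric matrix, so expensive genotype-based estimates can be reused
#' across runs.
#'
#' @param x A \linkS4class{RelatednessMatrix}.
#' @param path File path.
#' @return \code{readKinship} returns a \linkS4class{RelatednessMatrix} with
#'   method \code{"imported"}; \code{writeKinship} returns \code{path}
#'   invisibly.
#' @export
writeKinship <- function(x, path) {
  K <- relMatrix(x)
  ids <- rownames(K)
  if (is.null(ids)) ids <- paste0("id", seq_len(nrow(K)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(ids, collapse = "\t"), con)
  write.table(format(K, digits = 12, trim = TRUE), con, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeKinship
#' @export
readKinship <- function(path) {
  ids <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  K <- as.matrix(read.table(path, skip = 1, sep = "\t"))
  dimnames(K) <- list(ids, ids)
  RelatednessMatrix(K, method = "imported")
}
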