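#' PedigreeSet: individuals, parent links and affection status
#'
#' An S4 container for pedigree structure.  Each row of the backing table
#' describes one individual: its pedigree label, individual id, father and
#' mother ids (\code{NA} for founders), sex (1 = male, 2 = female, \code{NA}
#' unknown) and affection status (1 = affected, 0 = unaffected, \code{NA}
#' missing, PLINK-style input codes 2/1/0 are recoded on read).
#'
#' Validity enforces that ids are unique, that every non-missing parent id
#' refers to an individual in the same pedigree, and that the parent graph is
#' acyclic (no individual is its own ancestor).
#'
#' @param ped A \code{data.frame} with columns \code{pedigree}, \code{id},
#'   \code{father}, \code{mother}, \code{sex}, \code{affection}.
#' @param x A \code{PedigreeSet}.
#' @param ... Unused.
#'
#' @return \code{PedigreeSet()} returns a validated object.
#'   \code{pedigree()} returns the backing \code{data.frame}; \code{affection()}
#'   the affection vector named by individual id; \code{nCases()} and
#'   \code{nControls()} the phenotyped case/control counts.
#'
#' @examples
#' trio <- PedigreeSet(data.frame(
#'   pedigree = "F1", id = c("dad", "mum", "kid"),
#'   father = c(NA, NA, "dad"), mother = c(NA, NA, "mum"),
#'   sex = c(1, 2, 1), affection = c(0, 0, 1)))
#' nCases(trio)
#' @aliases pedigree affection nCases nControls
#' @export
PedigreeSet <- function(ped) {
  stopIf(!is.data.frame(ped), "'ped' must be a data.frame")
  need <- c("pedigree", "id", "father", "mother", "sex", "affection")
  miss <- setdiff(need, names(ped))
  stopIf(length(miss) > 0, "missing pedigree columns: ",
         paste(miss, collapse = ", "))
  ped <- ped[, need]
  for (col in c("pedigree", "id", "father", "mother"))
    ped[[col]] <- as.character(ped[[col]])
  ped$sex <- suppressWarnings(as.integer(ped$sex))
  ped$affection <- suppressWarnings(as.integer(ped$affection))
  rownames(ped) <- NULL
  new("PedigreeSet", ped = ped)
}

#' @export
setClass("PedigreeSet", representation(ped = "data.frame"))

setValidity("PedigreeSet", function(object) {
  ped <- object@ped
  if (anyDuplicated(ped$id))
    return(paste("duplicate individual id:",
                 ped$id[duplicated(ped$id)][1]))
  if (any(!is.na(ped$affection) & !(ped$affection %in% c(0L, 1L))))
    return("affection must be 0, 1 or NA")
  idx <- seq_len(nrow(ped))
  names(idx) <- ped$id
  for (col in c("father", "mother")) {
    par <- ped[[col]]
    known <- !is.na(par)
    bad <- known & is.na(idx[par])
    if (any(bad))
      return(paste0(col, " id not in pedigree set: ", par[bad][1]))
    same <- ped$pedigree[idx[par[known]]] == ped$pedigree[known]
    if (any(!same))
      return(paste0(col, " in a different pedigree for individual ",
                    ped$id[known][!same][1]))
  }
  # acyclicity: repeatedly peel individuals whose parents are all peeled
  fa <- idx[ped$father]; mo <- idx[ped$mother]
  done <- rep(FALSE, nrow(ped))
  repeat {
    ready <- !done & (is.na(fa) | done[fa]) & (is.na(mo) | done[mo])
    if (!any(ready)) break
    done[ready] <- TRUE
  }
  if (!all(done))
    return(paste("pedigree parent graph has a cycle involving individual",
                 ped$id[!done][1]))
  TRUE
})

#' @rdname PedigreeSet
#' @export
setMethod("pedigree", "PedigreeSet", function(x, ...) x@ped)

#' @rdname PedigreeSet
#' @export
setMethod("affection", "PedigreeSet", function(x, ...) {
  setNames(x@ped$affection, x@ped$id)
})

#' @rdname PedigreeSet
#' @export
setMethod("nCases", "PedigreeSet", function(x, ...) {
  sum(x@ped$affection == 1L, na.rm = TRUE)
})

#' @rdname PedigreeSet
#' @export
setMethod("nControls", "PedigreeSet", function(x, ...) {
  sum(x@ped$affection == 0L, na.rm = TRUE)
})

setMethod("show", "PedigreeSet", function(object) {
  ped <- object@ped
  cat("PedigreeSet:", nrow(ped), "individuals in",
      length(unique(ped$pedigree)), "pedigrees\n")
  cat("  affected:", nCases(object), " unaffected:", nControls(object),
      " missing:", sum(is.na(ped$affection)), "\n")
})

# Order individuals so that parents precede offspring (topological sort).
# Returns an integer permutation of row indices.
pedOrder <- function(ped) {
  idx <- seq_len(nrow(ped))
  names(idx) <- ped$id
  fa <- idx[ped$father]; mo <- idx[ped$mother]
  done <- rep(FALSE, nrow(ped))
  ord <- integer(0)
  repeat {
    ready <- !done & (is.na(fa) | done[fa]) & (is.na(mo) | done[mo])
    if (!any(ready)) break
    ord <- c(ord, which(ready))
    done[ready] <- TRUE
  }
  stopIf(!all(done), "pedigree parent graph has a cycle")
  ord
}
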