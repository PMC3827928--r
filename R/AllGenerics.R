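#' @rdname PedigreeSet-class
#' @export
setGeneric("pedigree", function(x, ...) standardGeneric("pedigree"))

#' @rdname PedigreeSet-class
#' @export
setGeneric("affection", function(x, ...) standardGeneric("affection"))

#' @rdname PedigreeSet-class
#' @export
setGeneric("nCases", function(x, ...) standardGeneric("nCases"))

#' @rdname PedigreeSet-class
#' @export
setGeneric("nControls", function(x, ...) standardGeneric("nControls"))

#' @rdname PedGenotypes-class
#' @export
setGeneric("dosages", function(x, ...) standardGeneric("dosages"))

#' @rdname PedGenotypes-class
#' @export
setGeneric("variantInfo", function(x, ...) standardGeneric("variantInfo"))

#' @rdname PedGenotypes-class
#' @export
setGeneric("regions", function(x, ...) standardGeneric("regions"))

#' @rdname RelatednessMatrix-class
#' @export
setGeneric("relMatrix", function(x, ...) standardGeneric("relMatrix"))

#' @rdname RelatednessMatrix-class
#' @export
setGeneric("kinshipCoef", function(x, ...) standardGeneric("kinshipCoef"))

#' @rdname RelatednessMatrix-class
#' @export
setGeneric("inbreeding", function(x, ...) standardGeneric("inbreeding"))

#' @rdname RelatednessMatrix-class
#' @export
setGeneric("alleleFreq", function(x, ...) standardGeneric("alleleFreq"))

#' @rdname grmEstimate
#' @export
setGeneric("grmEstimate", function(x, ...) standardGeneric("grmEstimate"))

#' @rdname pedigreeKinship
#' @export
setGeneric("pedigreeKinship", function(x, ...) standardGeneric("pedigreeKinship"))
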