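#' Accessors for AssemblyDesign and VerificationReport objects
#'
#' @param x an [AssemblyDesign-class] or [VerificationReport-class] object.
#' @param ... passed to methods.
#' @return `oligomers()`, `overlaps()`, `designScores()` and
#'   `conflictPairs()` return `DataFrame`s; `clusters()` an integer vector;
#'   `designParams()` a [DesignParams-class]; `referenceSeq()` and
#'   `reconstructedSeq()` a [Biostrings::DNAString];
#'   `matchesReference()` and `uniqueJunctions()` a logical scalar.
#' @name design-accessors
NULL

#' @rdname design-accessors
#' @export
setGeneric("oligomers", function(x, ...) standardGeneric("oligomers"))

#' @rdname design-accessors
#' @export
setGeneric("overlaps", function(x, ...) standardGeneric("overlaps"))

#' @rdname design-accessors
#' @export
setGeneric("designScores", function(x, ...) standardGeneric("designScores"))

#' @rdname design-accessors
#' @export
setGeneric("clusters", function(x, ...) standardGeneric("clusters"))

#' @rdname design-accessors
#' @export
setGeneric("conflictPairs", function(x, ...) standardGeneric("conflictPairs"))

#' @rdname design-accessors
#' @export
setGeneric("designParams", function(x, ...) standardGeneric("designParams"))

#' @rdname design-accessors
#' @export
setGeneric("referenceSeq", function(x, ...) standardGeneric("referenceSeq"))

#' @rdname design-accessors
#' @export
setGeneric("reconstructedSeq",
           function(x, ...) standardGeneric("reconstructedSeq"))

#' @rdname design-accessors
#' @export
setGeneric("matchesReference",
           function(x, ...) standardGeneric("matchesReference"))

#' @rdname design-accessors
#' @export
setGeneric("uniqueJunctions",
           function(x, ...) standardGeneric("uniqueJunctions"))

#' @rdname reconstruct
#' @export
setGeneric("reconstruct", function(design, ...) standardGeneric("reconstruct"))

#' @rdname crosscheck
#' @export
setGeneric("crosscheck", function(design, ...) standardGeneric("crosscheck"))

#' @rdname reoptimize
#' @export
setGeneric("reoptimize",
           function(design, index, overrides = list(), ...)
             standardGeneric("reoptimize"))

#' @rdname design-accessors
#' @export
setMethod("oligomers", "AssemblyDesign", function(x, ...) x@oligos)

#' @rdname design-accessors
#' @export
setMethod("overlaps", "AssemblyDesign", function(x, ...) x@overlaps)

#' @rdname design-accessors
#' @export
setMethod("designScores", "AssemblyDesign", function(x, ...) x@scores)

#' @rdname design-accessors
#' @export
setMethod("clusters", "AssemblyDesign", function(x, ...) x@clusters)

#' @rdname design-accessors
#' @export
setMethod("conflictPairs", "AssemblyDesign", function(x, ...) x@conflicts)

#' @rdname design-accessors
#' @export
setMethod("designParams", "AssemblyDesign", function(x, ...) x@params)

#' @rdname design-accessors
#' @export
setMethod("referenceSeq", "AssemblyDesign",
          function(x, ...) Biostrings::DNAString(x@reference))

#' @rdname design-accessors
#' @export
setMethod("conflictPairs", "VerificationReport", function(x, ...) x@conflicts)

#' @rdname design-accessors
#' @export
setMethod("reconstructedSeq", "VerificationReport",
          function(x, ...) Biostrings::DNAString(x@reconstructed))

#' @rdname design-accessors
#' @export
setMethod("matchesReference", "VerificationReport",
          function(x, ...) x@matchesReference)

#' @rdname design-accessors
#' @export
setMethod("uniqueJunctions", "VerificationReport",
          function(x, ...) x@uniqueJunctions)
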