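#' Accessors for SpliceScape classes
#'
#' @param x an object of the documented class.
#' @return \code{strainName}: the strain label of a [StrainJunctions].
#'   \code{junctions}: the junction \code{GRanges}. \code{sourcePath}: the
#'   file of origin. \code{annotatedJunctions} / \code{geneRanges} /
#'   \code{annotationSource}: the components of a [JunctionAnnotationDB].
#'   \code{coverageMatrix}: the junction-by-strain unique-read matrix of a
#'   [JunctionLandscape]. \code{sharedCounts} / \code{sharingThreshold}: the
#'   matrix and threshold of a [SharingMatrix]. \code{newickString}: the
#'   Newick serialisation of a [SplicingPhylogeny].
#'
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("strainName", function(x) standardGeneric("strainName"))

#' @rdname accessors
#' @export
setGeneric("junctions", function(x) standardGeneric("junctions"))

#' @rdname accessors
#' @export
setGeneric("sourcePath", function(x) standardGeneric("sourcePath"))

#' @rdname accessors
#' @export
setGeneric("annotatedJunctions",
           function(x) standardGeneric("annotatedJunctions"))

#' @rdname accessors
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @rdname accessors
#' @export
setGeneric("annotationSource",
           function(x) standardGeneric("annotationSource"))

#' @rdname accessors
#' @export
setGeneric("coverageMatrix", function(x) standardGeneric("coverageMatrix"))

#' @rdname accessors
#' @export
setGeneric("sharedCounts", function(x) standardGeneric("sharedCounts"))

#' @rdname accessors
#' @export
setGeneric("sharingThreshold",
           function(x) standardGeneric("sharingThreshold"))

#' @rdname accessors
#' @export
setGeneric("newickString", function(x) standardGeneric("newickString"))

#' @rdname accessors
setMethod("strainName", "StrainJunctions", function(x) x@strain)

#' @rdname accessors
setMethod("junctions", "StrainJunctions", function(x) x@junctions)

#' @rdname accessors
setMethod("sourcePath", "StrainJunctions", function(x) x@sourcePath)

#' @rdname accessors
setMethod("annotatedJunctions", "JunctionAnnotationDB",
          function(x) x@junctions)

#' @rdname accessors
setMethod("geneRanges", "JunctionAnnotationDB", function(x) x@genes)

#' @rdname accessors
setMethod("annotationSource", "JunctionAnnotationDB", function(x) x@source)

#' @rdname accessors
setMethod("coverageMatrix", "JunctionLandscape", function(x)
    SummarizedExperiment::assay(x, "uniqueReads"))

#' @rdname accessors
setMethod("sharedCounts", "SharingMatrix", function(x) x@shared)

#' @rdname accessors
setMethod("sharingThreshold", "SharingMatrix", function(x) x@threshold)

#' @rdname accessors
setMethod("newickString", "SplicingPhylogeny", function(x) x@newick)

setMethod("show", "StrainJunctions", function(object) {
    cat("StrainJunctions for strain '", object@strain, "': ",
        length(object@junctions), " junctions",
        if (nzchar(object@sourcePath))
            paste0(" [", object@sourcePath, "]") else "",
        "\n", sep = "")
    tab <- table(mcols(object@junctions)$motif)
    cat("  motif classes:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "JunctionAnnotationDB", function(object) {
    cat("JunctionAnnotationDB (", object@source, "): ",
        length(object@junctions), " annotated junctions, ",
        length(object@genes), " genes\n", sep = "")
})

setMethod("show", "JunctionLandscape", function(object) {
    cat("JunctionLandscape: ", nrow(object), " junction keys x ",
        ncol(object), " strains (",
        paste(colnames(object), collapse = ", "), ")\n", sep = "")
})

setMethod("show", "SharingMatrix", function(object) {
    cat("SharingMatrix at coverage >= ", object@threshold, ":\n", sep = "")
    print(object@shared)
})

setMethod("show", "SSSConfig", function(object) {
    cat("SSSConfig: minCoverage=", object@minCoverage,
        ", canonicalSet={", paste(object@canonicalSet, collapse = ","),
        "}, requireAbsentReads=", object@requireAbsentReads, "\n", sep = "")
})

setMethod("show", "SplicingPhylogeny", function(object) {
    cat("SplicingPhylogeny (", object@linkage, " linkage):\n  ",
        object@newick, "\n", sep = "")
})
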