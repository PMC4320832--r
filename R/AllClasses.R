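#' @import methods
#' @import BiocGenerics
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

## Motif vocabulary used throughout: the three canonical splice-site classes
## plus the catch-all, and "unknown" for junctions not yet classified.
MOTIF_LEVELS <- c("GT/AG", "GC/AG", "AT/AC", "non-canonical", "unknown")
CANONICAL_MOTIFS <- c("GT/AG", "GC/AG", "AT/AC")
STRAND_LEVELS <- c("plus", "minus", "undefined", "conflict")

#' StrainJunctions: all splice junctions observed in one strain
#'
#' A thin S4 container pairing a strain label with a \link[GenomicRanges]{GRanges}
#' of intron intervals (1-based closed coordinates of the first and last
#' intronic base, the native convention of aligner splice-junction tables).
#' Metadata columns carried per junction: \code{motif} (factor: GT/AG, GC/AG,
#' AT/AC, non-canonical, unknown), \code{annotatedFlag} (logical, as carried
#' by the input table), \code{uniqueReads}, \code{multiReads},
#' \code{maxOverhang} (non-negative integers).
#'
#' @slot strain single strain label.
#' @slot junctions \code{GRanges} of intron intervals with the metadata
#'   columns listed above. Strand \code{*} means undefined.
#' @slot sourcePath provenance: the file the set was read from ("" if
#'   constructed in memory).
#'
#' @seealso [readSJ()] to construct from a splice-junction table.
#' @exportClass StrainJunctions
setClass("StrainJunctions",
    representation(strain = "character", junctions = "GRanges",
                   sourcePath = "character"))

setValidity("StrainJunctions", function(object) {
    msg <- character()
    if (length(object@strain) != 1L || !nzchar(object@strain))
        msg <- c(msg, "'strain' must be a single non-empty label")
    gr <- object@junctions
    need <- c("motif", "annotatedFlag", "uniqueReads", "multiReads",
              "maxOverhang")
    miss <- setdiff(need, names(mcols(gr)))
    if (length(miss))
        msg <- c(msg, paste0("missing junction columns: ",
                             paste(miss, collapse = ", ")))
    if (!length(miss)) {
        if (any(mcols(gr)$uniqueReads < 0L))
            msg <- c(msg, "uniqueReads must be non-negative")
        if (anyDuplicated(junctionKeys(gr)))
            msg <- c(msg, "duplicate junction keys within one strain")
    }
    if (length(msg)) msg else TRUE
})

#' JunctionAnnotationDB: annotated introns and gene intervals from a GTF
#'
#' Built by [buildAnnotationDB()]. Holds every intron implied by a pair of
#' consecutive exons of an annotated transcript (deduplicated across
#' transcripts, with the annotated strand retained) plus one interval per
#' gene (the min/max span over that gene's exons).
#'
#' @slot junctions \code{GRanges} of annotated introns (1-based closed).
#' @slot genes \code{GRanges} of gene spans with a \code{gene_id} column.
#' @slot source annotation version label (by default the GTF file name).
#'
#' @exportClass JunctionAnnotationDB
setClass("JunctionAnnotationDB",
    representation(junctions = "GRanges", genes = "GRanges",
                   source = "character"))

setValidity("JunctionAnnotationDB", function(object) {
    msg <- character()
    if (!"gene_id" %in% names(mcols(object@genes)))
        msg <- c(msg, "genes must carry a 'gene_id' column")
    if (length(msg)) msg else TRUE
})

#' JunctionLandscape: the merged junction-by-strain coverage landscape
#'
#' A \link[SummarizedExperiment]{RangedSummarizedExperiment} with one row per
#' distinct junction key (chromosome, intron start, intron end; strand is
#' deliberately not part of the key, see [mergeStrains()]), one column per
#' strain, and a single \code{uniqueReads} assay in which 0 means the
#' junction was not observed in that strain. Row metadata carries
#' \code{reconciledStrand} (plus/minus/undefined/conflict) and
#' \code{tableMotif}, the motif class reported by the input tables.
#'
#' @exportClass JunctionLandscape
setClass("JunctionLandscape", contains = "RangedSummarizedExperiment")

setValidity("JunctionLandscape", function(object) {
    msg <- character()
    if (!"uniqueReads" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'uniqueReads' is required")
    rr <- SummarizedExperiment::rowRanges(object)
    if (!"reconciledStrand" %in% names(mcols(rr)))
        msg <- c(msg, "rowRanges must carry 'reconciledStrand'")
    if (ncol(object) < 2L)
        msg <- c(msg, "a landscape needs at least 2 strains")
    if (length(msg)) msg else TRUE
})

#' SharingMatrix: pairwise shared-junction counts between strains
#'
#' Cell (i, j) counts junctions with coverage at or above the threshold in
#' both strain i and strain j; the diagonal holds per-strain totals at that
#' threshold. Symmetric by construction.
#'
#' @slot shared symmetric integer matrix with strain dimnames.
#' @slot threshold the per-strain coverage threshold used.
#'
#' @exportClass SharingMatrix
setClass("SharingMatrix",
    representation(shared = "matrix", threshold = "integer"))

setValidity("SharingMatrix", function(object) {
    m <- object@shared
    msg <- character()
    if (nrow(m) != ncol(m) || !isTRUE(all.equal(m, t(m))))
        msg <- c(msg, "'shared' must be a symmetric matrix")
    if (is.null(rownames(m)))
        msg <- c(msg, "'shared' must have strain dimnames")
    d <- diag(m)
    if (any(m > pmin(matrix(d, nrow(m), ncol(m)),
                     matrix(d, nrow(m), ncol(m), byrow = TRUE))))
        msg <- c(msg, "shared(i,j) cannot exceed min(shared(i,i), shared(j,j))")
    if (length(object@threshold) != 1L || object@threshold < 1L)
        msg <- c(msg, "'threshold' must be a single integer >= 1")
    if (length(msg)) msg else TRUE
})

#' SSSConfig: thresholds for high-confidence strain-specific splicing
#'
#' The three criteria for a high-confidence strain-specific splicing (SSS)
#' event are: detected in exactly one strain, read coverage at or above
#' \code{minCoverage}, and a splice-site motif in \code{canonicalSet}.
#' "Detected in only one strain" means every other strain has at most
#' \code{requireAbsentReads} uniquely mapped reads (0 by default: strict
#' absence).
#'
#' @slot minCoverage coverage floor for the focal strain (default 10).
#' @slot canonicalSet motif classes accepted as canonical
#'   (default GT/AG, GC/AG, AT/AC).
#' @slot requireAbsentReads maximum coverage tolerated in non-focal strains
#'   (default 0).
#'
#' @export SSSConfig
#' @exportClass SSSConfig
SSSConfig <- setClass("SSSConfig",
    representation(minCoverage = "integer", canonicalSet = "character",
                   requireAbsentReads = "integer"),
    prototype(minCoverage = 10L,
              canonicalSet = CANONICAL_MOTIFS,
              requireAbsentReads = 0L))

setValidity("SSSConfig", function(object) {
    msg <- character()
    if (length(object@minCoverage) != 1L || object@minCoverage < 1L)
        msg <- c(msg, "minCoverage must be a single integer >= 1")
    if (!all(object@canonicalSet %in% CANONICAL_MOTIFS))
        msg <- c(msg, "canonicalSet must be a subset of GT/AG, GC/AG, AT/AC")
    if (length(object@requireAbsentReads) != 1L ||
        object@requireAbsentReads < 0L)
        msg <- c(msg, "requireAbsentReads must be a single integer >= 0")
    if (length(msg) == 0 &&
        object@requireAbsentReads >= object@minCoverage)
        msg <- c(msg, "requireAbsentReads must be below minCoverage")
    if (length(msg)) msg else TRUE
})

#' SplicingPhylogeny: strain dendrogram from shared-junction counts
#'
#' @slot hclust the \code{\link[stats]{hclust}} object (merge heights).
#' @slot phylo the \code{\link[ape]{as.phylo}} conversion of it.
#' @slot newick single Newick string with branch lengths.
#' @slot linkage agglomeration method used.
#'
#' @exportClass SplicingPhylogeny
setClass("SplicingPhylogeny",
    representation(hclust = "ANY", phylo = "ANY", newick = "character",
                   linkage = "character"))
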