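## The three-step protocol for high-confidence strain-specific splicing:
## (1) junctions detected in exactly one strain, (2) a read-coverage floor
## (default 10, chosen relative to the pooled coverage median, see
## coverageMedian), (3) a canonical splice-site motif.

#' Step 1: potential strain-specific splicing events
#'
#' Emits one potential call per junction whose coverage is at least
#' \code{focalMin} in exactly one strain while every other strain has at
#' most \code{requireAbsentReads} reads (0 by default — strict absence).
#'
#' @param x a [JunctionLandscape].
#' @param focalMin coverage floor in the focal strain (default 1: all
#'   singleton junctions).
#' @param requireAbsentReads maximum coverage tolerated elsewhere.
#' @return a \code{GRanges} of calls with metadata columns \code{strain},
#'   \code{coverage}, \code{tableMotif} and \code{tier} ("potential").
#' @export
findPotentialSSS <- function(x, focalMin = 1L, requireAbsentReads = 0L) {
    stopifnot(is(x, "JunctionLandscape"))
    focalMin <- as.integer(focalMin)
    requireAbsentReads <- as.integer(requireAbsentReads)
    if (focalMin <= requireAbsentReads)
        stop("focalMin must exceed requireAbsentReads")
    cov <- coverageMatrix(x)
    nPresent <- rowSums(cov > requireAbsentReads)
    rowMax <- do.call(pmax, lapply(seq_len(ncol(cov)),
                                   function(j) cov[, j]))
    hit <- which(nPresent == 1L & rowMax >= focalMin)
    rr <- SummarizedExperiment::rowRanges(x)[hit]
    focal <- max.col(cov[hit, , drop = FALSE], ties.method = "first")
    out <- GRanges(seqnames(rr), IRanges(start(rr), end(rr)),
                   strand = strand(rr))
    mcols(out) <- DataFrame(
        strain = colnames(cov)[focal],
        coverage = rowMax[hit],
        tableMotif = mcols(rr)$tableMotif,
        tier = rep("potential", length(hit)))
    out
}

#' Steps 2-3: filter potential calls to high confidence
#'
#' Keeps potential calls with coverage at or above the configured floor and
#' a splice-site motif in the configured canonical set, then attaches the
#' annotation status ([isAnnotated()]) and overlapping gene
#' ([overlapsGene()]). By default the motif used for filtering is
#' re-derived from the genome sequence ([classifyMotif()]), which makes the
#' filter independent of the aligner's motif codes; set
#' \code{useTableMotif = TRUE} to trust the input table's codes instead.
#'
#' @param potentials calls from [findPotentialSSS()].
#' @param config an [SSSConfig].
#' @param genome genome FASTA (path or \code{DNAStringSet}); required
#'   unless \code{useTableMotif = TRUE}.
#' @param db a [JunctionAnnotationDB].
#' @param useTableMotif trust the table motif instead of re-deriving it.
#' @return a \code{GRanges} of high-confidence calls with metadata columns
#'   \code{strain}, \code{coverage}, \code{motif}, \code{resolvedStrand},
#'   \code{annotated}, \code{gene} and \code{tier} ("high_confidence").
#' @export
callHighConfidence <- function(potentials, config = SSSConfig(),
                               genome = NULL, db = NULL,
                               useTableMotif = FALSE) {
    stopifnot(is(config, "SSSConfig"))
    if (is.null(db))
        stop("configuration error: an annotation database is required")
    if (!useTableMotif && is.null(genome))
        stop("configuration error: a genome is required to re-derive ",
             "splice-site motifs (or set useTableMotif = TRUE)")
    if (useTableMotif) {
        motif <- as.character(mcols(potentials)$tableMotif)
        resolvedStrand <- ifelse(
            as.character(strand(potentials)) == "+", "plus",
            ifelse(as.character(strand(potentials)) == "-", "minus",
                   "undefined"))
    } else {
        mc <- classifyMotif(potentials, genome)
        motif <- as.character(mc$motif)
        resolvedStrand <- as.character(mc$resolvedStrand)
    }
    keep <- mcols(potentials)$coverage >= config@minCoverage &
        motif %in% config@canonicalSet
    out <- potentials[keep]
    ## gene overlap is strand-aware where strand is known: use the motif-
    ## resolved strand for the retained (canonical) calls
    strand(out) <- c(plus = "+", minus = "-",
                     undefined = "*")[resolvedStrand[keep]]
    mcols(out) <- DataFrame(
        strain = mcols(out)$strain,
        coverage = mcols(out)$coverage,
        motif = factor(motif[keep], levels = MOTIF_LEVELS),
        resolvedStrand = factor(resolvedStrand[keep],
                                levels = STRAND_LEVELS),
        annotated = isAnnotated(out, db),
        gene = overlapsGene(out, db),
        tier = rep("high_confidence", sum(keep)))
    out
}

#' Per-strain summary of strain-specific splicing calls
#'
#' Counts per strain: total calls, annotated calls, calls per canonical
#' motif class, and calls overlapping an annotated gene.
#'
#' @param calls high-confidence calls from [callHighConfidence()].
#' @param strains strain labels to tabulate (defaults to those present in
#'   the calls, sorted); strains with zero calls get all-zero rows.
#' @return data.frame with columns \code{strain}, \code{total},
#'   \code{annotated}, \code{GT/AG}, \code{GC/AG}, \code{AT/AC},
#'   \code{overlap_gene}.
#' @seealso [sssOverallStats()] for panel-wide totals and percentages.
#' @export
sssSummary <- function(calls, strains = NULL) {
    cs <- as.character(mcols(calls)$strain)
    if (is.null(strains)) strains <- sort(unique(cs))
    mot <- as.character(mcols(calls)$motif)
    ann <- mcols(calls)$annotated
    gene <- mcols(calls)$gene
    one <- function(s) {
        i <- cs == s
        c(total = sum(i), annotated = sum(ann[i]),
          `GT/AG` = sum(i & mot == "GT/AG"),
          `GC/AG` = sum(i & mot == "GC/AG"),
          `AT/AC` = sum(i & mot == "AT/AC"),
          overlap_gene = sum(i & !is.na(gene)))
    }
    m <- t(vapply(strains, one, numeric(6L)))
    df <- data.frame(strain = strains, m, check.names = FALSE,
                     row.names = NULL)
    names(df) <- c("strain", "total", "annotated", "GT/AG", "GC/AG",
                   "AT/AC", "overlap_gene")
    df
}

#' Panel-wide statistics from a per-strain summary table
#'
#' Computes the grand total, the percentage of calls not previously
#' annotated (overall, and split by a designated reference strain when
#' given — the strain whose genome the reads were aligned to), and the
#' percentage of calls overlapping an annotated gene. Accepts any table in
#' the shape produced by [sssSummary()], so published per-strain counts can
#' be fed through it directly.
#'
#' @param tbl data.frame with columns \code{strain}, \code{total},
#'   \code{annotated} and \code{overlap_gene}.
#' @param referenceStrain optional label of the reference strain.
#' @return named list: \code{grandTotal}, \code{unannotatedPct},
#'   \code{geneOverlapPct}, and when a reference strain is named,
#'   \code{refUnannotatedPct} and \code{nonRefUnannotatedPct}. Percentages
#'   are on the 0-100 scale, unrounded.
#' @export
sssOverallStats <- function(tbl, referenceStrain = NULL) {
    need <- c("strain", "total", "annotated", "overlap_gene")
    miss <- setdiff(need, names(tbl))
    if (length(miss))
        stop("summary table lacks column(s): ",
             paste(miss, collapse = ", "))
    gt <- sum(tbl$total)
    out <- list(
        grandTotal = gt,
        unannotatedPct = 100 * (gt - sum(tbl$annotated)) / gt,
        geneOverlapPct = 100 * sum(tbl$overlap_gene) / gt)
    if (!is.null(referenceStrain)) {
        if (!referenceStrain %in% tbl$strain)
            stop("reference strain not in table: ", referenceStrain)
        ref <- tbl$strain == referenceStrain
        out$refUnannotatedPct <-
            100 * (sum(tbl$total[ref]) - sum(tbl$annotated[ref])) /
            sum(tbl$total[ref])
        out$nonRefUnannotatedPct <-
            100 * (sum(tbl$total[!ref]) - sum(tbl$annotated[!ref])) /
            sum(tbl$total[!ref])
    }
    out
}

.regionsAsGRanges <- function(regions) {
    if (is(regions, "GRanges")) {
        if (is.null(regions$label))
            mcols(regions)$label <- paste0("region_",
                                           seq_along(regions))
        return(regions)
    }
    if (is.character(regions) && length(regions) == 1L) {
        df <- utils::read.delim(regions, header = FALSE,
                                col.names = c("chrom", "start", "end",
                                              "label")[1:4],
                                colClasses = c("character", "integer",
                                               "integer", "character"))
        if (grepl("\\.bed$", regions, ignore.case = TRUE)) {
            ## BED is 0-based half-open
            df$start <- df$start + 1L
        }
        regions <- df
    }
    if (!is.data.frame(regions) ||
        !all(c("chrom", "start", "end") %in% names(regions)))
        stop("malformed regions: need chrom/start/end (+ optional label)")
    if (any(is.na(regions$start)) || any(is.na(regions$end)) ||
        any(regions$start > regions$end))
        stop("malformed regions: start must be <= end and numeric")
    lab <- if ("label" %in% names(regions)) regions$label else
        paste0("region_", seq_len(nrow(regions)))
    gr <- GRanges(regions$chrom, IRanges(regions$start, regions$end))
    mcols(gr)$label <- lab
    gr
}

#' Intersect calls with genomic regions
#'
#' Keeps calls whose intron interval intersects any supplied region
#' (1-based closed; BED input is converted), annotating each retained call
#' with the label(s) of the region(s) hit.
#'
#' @param calls a \code{GRanges} of calls.
#' @param regions a \code{GRanges} with an optional \code{label} column, a
#'   data.frame with chrom/start/end/label, or a path to a BED or TSV file.
#' @return the intersecting calls, with a \code{region} metadata column.
#' @export
intersectRegions <- function(calls, regions) {
    gr <- .regionsAsGRanges(regions)
    hits <- findOverlaps(calls, gr, ignore.strand = TRUE)
    q <- S4Vectors::queryHits(hits)
    lab <- vapply(split(mcols(gr)$label[S4Vectors::subjectHits(hits)], q),
                  function(v) paste(unique(v), collapse = ","), "")
    keep <- sort(unique(q))
    out <- calls[keep]
    mcols(out)$region <- as.character(lab[as.character(keep)])
    out
}

#' Write strain-specific splicing calls
#'
#' TSV with one row per call and all fields; optionally a BED6 companion
#' (0-based half-open, name = strain, score = min(coverage, 1000)).
#'
#' @param calls a \code{GRanges} of calls.
#' @param path TSV output file.
#' @param bedPath optional BED6 output file.
#' @return the TSV path, invisibly.
#' @export
writeSSSCalls <- function(calls, path, bedPath = NULL) {
    df <- data.frame(
        chrom = as.character(seqnames(calls)),
        intron_start = start(calls), intron_end = end(calls),
        strand = as.character(strand(calls)),
        as.data.frame(mcols(calls)), check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(bedPath)) {
        st <- as.character(strand(calls)); st[st == "*"] <- "."
        writeLines(paste(as.character(seqnames(calls)),
                         start(calls) - 1L, end(calls),
                         as.character(mcols(calls)$strain),
                         pmin(mcols(calls)$coverage, 1000L), st,
                         sep = "\t"), bedPath)
    }
    invisible(path)
}
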