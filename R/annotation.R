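## Annotated-junction database from a GTF and splice-site motif
## classification against a genome FASTA.

#' Build the annotated-junction database and gene index from a GTF
#'
#' For every transcript with k >= 2 exons, the k-1 introns between
#' consecutive exons are emitted as annotated junction keys:
#' intron start = upstream exon end + 1, intron end = downstream exon
#' start - 1 (1-based closed). Keys duplicated across transcripts are
#' stored once, keeping the annotated strand. Gene intervals are the
#' min/max span over each gene's exons. Transcripts whose exons overlap
#' (or abut with no intron between them) are skipped with a warning.
#'
#' @param gtfPath an Ensembl-dialect GTF (or GFF3; any format
#'   \code{\link[rtracklayer]{import}} recognises) with exon features
#'   carrying \code{transcript_id} and \code{gene_id}.
#' @return a [JunctionAnnotationDB].
#' @export
buildAnnotationDB <- function(gtfPath) {
    gr <- rtracklayer::import(gtfPath)
    ex <- gr[!is.na(gr$type) & gr$type == "exon"]
    if (length(ex) == 0L)
        stop("empty annotation database: no exon features in ", gtfPath)
    if (is.null(ex$transcript_id) || is.null(ex$gene_id))
        stop("exon features must carry transcript_id and gene_id")

    o <- order(ex$transcript_id, as.integer(start(ex)))
    ex <- ex[o]
    tx <- ex$transcript_id
    n <- length(ex)
    sameTx <- tx[-1L] == tx[-n]
    istart <- end(ex)[-n] + 1L
    iend <- start(ex)[-1L] - 1L
    ## an intron of non-positive length means overlapping (or bookended)
    ## exons within the transcript -> skip the whole transcript
    degenerate <- sameTx & istart > iend
    if (any(degenerate)) {
        badTx <- unique(tx[-1L][degenerate])
        warning("skipping ", length(badTx),
                " transcript(s) with overlapping exons: ",
                paste(utils::head(badTx, 5L), collapse = ", "),
                if (length(badTx) > 5L) ", ..." else "")
        keep <- sameTx & !(tx[-1L] %in% badTx)
    } else keep <- sameTx

    jxn <- GRanges(as.character(seqnames(ex))[-n][keep],
                   IRanges(istart[keep], iend[keep]),
                   strand = as.character(strand(ex))[-n][keep])
    jxn <- jxn[!duplicated(junctionKeys(jxn))]
    jxn <- GenomicRanges::sort(jxn, ignore.strand = TRUE)

    gspl <- split(ex, ex$gene_id)
    genes <- unlist(range(gspl, ignore.strand = FALSE))
    mcols(genes)$gene_id <- names(genes)
    names(genes) <- NULL
    genes <- GenomicRanges::sort(genes, ignore.strand = TRUE)

    new("JunctionAnnotationDB", junctions = jxn, genes = genes,
        source = basename(gtfPath))
}

.revcomp2 <- function(x) {
    chartr("ACGTN", "TGCAN",
           vapply(strsplit(x, ""), function(s)
               paste(rev(s), collapse = ""), ""))
}

.CANONICAL_PAIRS <- data.frame(
    donor = c("GT", "GC", "AT"),
    acceptor = c("AG", "AG", "AC"),
    motif = CANONICAL_MOTIFS)

.asGenome <- function(genome) {
    if (is.character(genome) && length(genome) == 1L)
        genome <- Biostrings::readDNAStringSet(genome)
    if (!is(genome, "DNAStringSet"))
        stop("genome must be a DNAStringSet or a FASTA path")
    names(genome) <- sub("\\s.*$", "", names(genome))
    genome
}

#' Classify splice-site motifs from the genome sequence
#'
#' Looks up the first two and last two intronic bases on the plus strand of
#' the reference. If the (donor, acceptor) dinucleotide pair is GT..AG,
#' GC..AG or AT..AC the junction is that motif on the plus strand; if the
#' reverse-complemented pair read in the opposite orientation matches, it
#' is that motif on the minus strand; anything else (including any N) is
#' non-canonical, and the junction's own strand is carried through
#' unchanged.
#'
#' @param x a \code{GRanges} of intron intervals or a [StrainJunctions].
#' @param genome a \code{DNAStringSet}, or the path to a FASTA file.
#' @return a \code{DataFrame} with columns \code{motif},
#'   \code{resolvedStrand} (plus/minus/undefined), \code{donor} and
#'   \code{acceptor} (the plus-strand dinucleotides), one row per junction.
#' @export
classifyMotif <- function(x, genome) {
    gr <- if (is(x, "StrainJunctions")) x@junctions else x
    genome <- .asGenome(genome)
    if (length(gr) && any(width(gr) < 4L))
        stop("degenerate junction: intron length below 4 bases")
    chrom <- as.character(seqnames(gr))
    miss <- setdiff(unique(chrom), names(genome))
    if (length(miss))
        stop("chromosome(s) absent from genome: ",
             paste(miss, collapse = ", "))
    donor <- character(length(gr)); acceptor <- character(length(gr))
    for (ch in unique(chrom)) {
        idx <- which(chrom == ch)
        seqLen <- length(genome[[ch]])
        if (any(start(gr)[idx] < 1L | end(gr)[idx] > seqLen))
            stop("junction coordinates outside chromosome ", ch)
        donor[idx] <- toupper(as.character(Biostrings::extractAt(
            genome[[ch]], IRanges(start(gr)[idx], start(gr)[idx] + 1L))))
        acceptor[idx] <- toupper(as.character(Biostrings::extractAt(
            genome[[ch]], IRanges(end(gr)[idx] - 1L, end(gr)[idx]))))
    }
    fwd <- match(paste(donor, acceptor),
                 paste(.CANONICAL_PAIRS$donor, .CANONICAL_PAIRS$acceptor))
    rev <- match(paste(.revcomp2(acceptor), .revcomp2(donor)),
                 paste(.CANONICAL_PAIRS$donor, .CANONICAL_PAIRS$acceptor))
    motif <- rep("non-canonical", length(gr))
    resolvedStrand <- ifelse(as.character(strand(gr)) == "+", "plus",
                      ifelse(as.character(strand(gr)) == "-", "minus",
                             "undefined"))
    hitF <- !is.na(fwd)
    motif[hitF] <- .CANONICAL_PAIRS$motif[fwd[hitF]]
    resolvedStrand[hitF] <- "plus"
    hitR <- !hitF & !is.na(rev)
    motif[hitR] <- .CANONICAL_PAIRS$motif[rev[hitR]]
    resolvedStrand[hitR] <- "minus"
    DataFrame(motif = factor(motif, levels = MOTIF_LEVELS),
              resolvedStrand = factor(resolvedStrand,
                                      levels = STRAND_LEVELS),
              donor = donor, acceptor = acceptor)
}

#' Is a junction annotated?
#'
#' Exact coordinate match of (chromosome, intron start, intron end) against
#' the annotated-junction database. Strand is deliberately not required to
#' match: junction keys are strandless, and a motif-inferred strand
#' disagreement should not demote a coordinate-exact annotated junction.
#'
#' @param x a \code{GRanges}, [StrainJunctions] or character vector of
#'   junction keys as produced by [junctionKeys()].
#' @param db a [JunctionAnnotationDB].
#' @return logical vector, one element per junction.
#' @export
isAnnotated <- function(x, db) {
    stopifnot(is(db, "JunctionAnnotationDB"))
    keys <- if (is.character(x)) x else junctionKeys(x)
    keys %in% junctionKeys(db@junctions)
}

#' Which annotated gene does a junction fall in?
#'
#' Intersects the intron interval with the gene spans of the database
#' (at least 1 bp of overlap). Strand agreement is required only when the
#' junction's strand is defined. Ties are broken by the longest overlap,
#' then by lexicographic gene id, making the result independent of the
#' gene-list input order.
#'
#' @param x a \code{GRanges} of intron intervals or a [StrainJunctions].
#' @param db a [JunctionAnnotationDB].
#' @return character vector of gene ids (NA where no gene overlaps).
#' @export
overlapsGene <- function(x, db) {
    stopifnot(is(db, "JunctionAnnotationDB"))
    gr <- if (is(x, "StrainJunctions")) x@junctions else x
    genes <- db@genes
    hits <- findOverlaps(gr, genes, ignore.strand = TRUE)
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    jStrand <- as.character(strand(gr))[q]
    gStrand <- as.character(strand(genes))[s]
    ok <- jStrand == "*" | gStrand == "*" | jStrand == gStrand
    q <- q[ok]; s <- s[ok]
    out <- rep(NA_character_, length(gr))
    if (length(q)) {
        ovw <- pmin(end(gr)[q], end(genes)[s]) -
               pmax(start(gr)[q], start(genes)[s]) + 1L
        gid <- mcols(genes)$gene_id[s]
        o <- order(q, -ovw, gid)
        q <- q[o]; gid <- gid[o]
        first <- !duplicated(q)
        out[q[first]] <- gid[first]
    }
    out
}

#' Persist / inspect an annotation database
#'
#' Writes the annotated junction keys as a sorted TSV and the gene index
#' as BED6 for external inspection.
#'
#' @param db a [JunctionAnnotationDB].
#' @param junctionsPath TSV output for the junction keys.
#' @param genesPath BED6 output for gene intervals (optional).
#' @return invisibly, the junction path.
#' @export
writeAnnotationDB <- function(db, junctionsPath, genesPath = NULL) {
    jx <- db@junctions
    df <- data.frame(chrom = as.character(seqnames(jx)),
                     intron_start = start(jx), intron_end = end(jx),
                     strand = as.character(strand(jx)))
    utils::write.table(df, junctionsPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(genesPath)) {
        g <- db@genes
        st <- as.character(strand(g)); st[st == "*"] <- "."
        writeLines(paste(as.character(seqnames(g)), start(g) - 1L, end(g),
                         mcols(g)$gene_id, 0L, st, sep = "\t"), genesPath)
    }
    invisible(junctionsPath)
}
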