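## Reading, keying and writing the aligner splice-junction tabular dialect.
## Columns: chrom, intron start, intron end (1-based, first/last intronic
## base), strand code (0 undefined / 1 plus / 2 minus), motif code (0
## non-canonical, 1/2 GT/AG, 3/4 GC/AG, 5/6 AT/AC; even codes are the
## minus-strand observations), annotated flag, unique reads, multi reads,
## max overhang.

#' Junction keys
#'
#' The identity of a junction across strains is its chromosome plus the
#' 1-based coordinates of the first and last intronic base. Strand is not
#' part of the key: an intron seen with undefined strand in one strain must
#' unify with the same intron strand-called in another; strands are
#' reconciled when strains are merged.
#'
#' @param x a \code{GRanges} of intron intervals or a [StrainJunctions].
#' @return character vector of keys, "chrom:start-end".
#' @export
junctionKeys <- function(x) {
    if (is(x, "StrainJunctions")) x <- x@junctions
    if (length(x) == 0L) return(character())
    paste0(as.character(seqnames(x)), ":", start(x), "-", end(x))
}

.decodeStrand <- c("*", "+", "-")           # codes 0,1,2
.decodeMotif <- c("non-canonical", "GT/AG", "GT/AG", "GC/AG", "GC/AG",
                  "AT/AC", "AT/AC")         # codes 0..6

#' Read a splice-junction table for one strain
#'
#' Parses the whitespace-separated junction dialect written by spliced
#' aligners (plain or gzip-compressed). Every row is kept: no filtering by
#' motif, annotation status or coverage happens at ingest, mirroring a
#' permissive junction-detection policy in which both annotated and
#' unannotated junctions are reported.
#'
#' Dialect decoding: strand code 0/1/2 becomes undefined/plus/minus; motif
#' codes 1/2, 3/4 and 5/6 collapse to the biological classes GT/AG, GC/AG
#' and AT/AC (the even codes being the minus-strand observation of the same
#' motif), and code 0 is non-canonical. When the strand code is 0 but the
#' motif code is canonical, the strand implied by the code's parity is
#' recorded (odd = plus, even = minus).
#'
#' @param path file to read (".gz" suffix is decompressed transparently).
#' @param strain strain label to attach.
#' @return a [StrainJunctions].
#'
#' @examples
#' tf <- tempfile()
#' writeLines("chr1\t100\t200\t1\t1\t0\t12\t3\t40", tf)
#' readSJ(tf, "B6")
#' @export
readSJ <- function(path, strain) {
    if (!file.exists(path))
        stop("splice-junction table not found: ", path)
    con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
    on.exit(close(con))
    lines <- readLines(con)
    lineNo <- which(nzchar(trimws(lines)))
    if (length(lineNo) == 0L) {
        gr <- GRanges()
        mcols(gr) <- DataFrame(
            motif = factor(character(), levels = MOTIF_LEVELS),
            annotatedFlag = logical(), uniqueReads = integer(),
            multiReads = integer(), maxOverhang = integer())
        return(new("StrainJunctions", strain = strain, junctions = gr,
                   sourcePath = path))
    }
    fields <- strsplit(trimws(lines[lineNo]), "[ \t]+")
    nf <- lengths(fields)
    if (any(nf < 9L))
        stop("malformed row (fewer than 9 fields) at line ",
             paste(lineNo[nf < 9L], collapse = ", "), " of ", path)
    m <- matrix(unlist(lapply(fields, `[`, 1:9)), ncol = 9L, byrow = TRUE)
    num <- suppressWarnings(apply(m[, 2:9, drop = FALSE], 2L, as.numeric))
    num <- matrix(num, ncol = 8L)
    badNum <- which(rowSums(is.na(num)) > 0L | rowSums(num %% 1 != 0) > 0L)
    if (length(badNum))
        stop("malformed row (non-integer field) at line ",
             paste(lineNo[badNum], collapse = ", "), " of ", path)
    chrom <- m[, 1L]
    istart <- as.integer(num[, 1L]); iend <- as.integer(num[, 2L])
    strandCode <- as.integer(num[, 3L]); motifCode <- as.integer(num[, 4L])
    annot <- as.integer(num[, 5L])
    uniq <- as.integer(num[, 6L]); multi <- as.integer(num[, 7L])
    over <- as.integer(num[, 8L])

    bad <- which(!(strandCode %in% 0:2))
    if (length(bad))
        stop("out-of-range strand code at line ",
             paste(lineNo[bad], collapse = ", "), " of ", path)
    bad <- which(!(motifCode %in% 0:6))
    if (length(bad))
        stop("out-of-range motif code at line ",
             paste(lineNo[bad], collapse = ", "), " of ", path)
    bad <- which(istart > iend)
    if (length(bad))
        stop("integrity error: intron start exceeds intron end at line ",
             paste(lineNo[bad], collapse = ", "), " of ", path)
    bad <- which(uniq < 0L | multi < 0L | over < 0L)
    if (length(bad))
        stop("integrity error: negative count at line ",
             paste(lineNo[bad], collapse = ", "), " of ", path)

    keys <- paste0(chrom, ":", istart, "-", iend)
    if (anyDuplicated(keys)) {
        dupKeys <- unique(keys[duplicated(keys)])
        stop("integrity error: duplicate junction keys in ", path,
             " at lines ",
             paste(lineNo[keys %in% dupKeys], collapse = ", "))
    }

    strand <- .decodeStrand[strandCode + 1L]
    ## strand implied by a canonical motif code when the strand field is 0
    implied <- strandCode == 0L & motifCode > 0L
    strand[implied] <- c("-", "+")[motifCode[implied] %% 2L + 1L]

    gr <- GRanges(chrom, IRanges(istart, iend), strand = strand)
    mcols(gr) <- DataFrame(
        motif = factor(.decodeMotif[motifCode + 1L], levels = MOTIF_LEVELS),
        annotatedFlag = annot != 0L,
        uniqueReads = uniq, multiReads = multi, maxOverhang = over)
    new("StrainJunctions", strain = strain, junctions = gr,
        sourcePath = path)
}

#' Write junctions as BED6
#'
#' Exports the intron intervals in 0-based half-open BED convention
#' (bedStart = intron start - 1, bedEnd = intron end), name = motif class,
#' score = min(unique reads, 1000), strand "." when undefined.
#'
#' @param x a [StrainJunctions].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeJunctionBED <- function(x, path) {
    stopifnot(is(x, "StrainJunctions"))
    gr <- x@junctions
    st <- as.character(strand(gr))
    st[st == "*"] <- "."
    lines <- if (length(gr) == 0L) character() else
        paste(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
              as.character(mcols(gr)$motif),
              pmin(mcols(gr)$uniqueReads, 1000L), st, sep = "\t")
    ok <- tryCatch({ writeLines(lines, path); TRUE },
                   error = function(e) e)
    if (!isTRUE(ok)) stop("cannot write BED to ", path, ": ",
                          conditionMessage(ok))
    invisible(path)
}

#' Dump / reload all junction fields as TSV
#'
#' A lossless interchange dump: one row per junction, a header line, all
#' fields of the in-memory representation. \code{readJunctionTSV} restores
#' the [StrainJunctions] exactly (round trip preserves every field).
#'
#' @param x a [StrainJunctions].
#' @param path file to write or read.
#' @param strain strain label for the reloaded object (defaults to the one
#'   stored in the file).
#' @return \code{writeJunctionTSV}: the path, invisibly;
#'   \code{readJunctionTSV}: a [StrainJunctions].
#' @export
writeJunctionTSV <- function(x, path) {
    stopifnot(is(x, "StrainJunctions"))
    gr <- x@junctions
    df <- data.frame(
        strain = rep(x@strain, length(gr)),
        chrom = as.character(seqnames(gr)),
        intron_start = start(gr), intron_end = end(gr),
        strand = as.character(strand(gr)),
        motif = as.character(mcols(gr)$motif),
        annotated_flag = as.integer(mcols(gr)$annotatedFlag),
        unique_reads = mcols(gr)$uniqueReads,
        multi_reads = mcols(gr)$multiReads,
        max_overhang = mcols(gr)$maxOverhang,
        check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeJunctionTSV
#' @export
readJunctionTSV <- function(path, strain = NULL) {
    df <- utils::read.delim(path, colClasses = c(
        strain = "character", chrom = "character"))
    if (is.null(strain))
        strain <- if (nrow(df)) df$strain[1L] else "unknown"
    gr <- GRanges(df$chrom, IRanges(df$intron_start, df$intron_end),
                  strand = df$strand)
    mcols(gr) <- DataFrame(
        motif = factor(df$motif, levels = MOTIF_LEVELS),
        annotatedFlag = df$annotated_flag != 0L,
        uniqueReads = as.integer(df$unique_reads),
        multiReads = as.integer(df$multi_reads),
        maxOverhang = as.integer(df$max_overhang))
    new("StrainJunctions", strain = strain, junctions = gr,
        sourcePath = path)
}

#' Pooled coverage median across strains
#'
#' The median of unique-read coverage pooled over every junction record of
#' every strain (a junction shared by k strains contributes k values).
#' Reported to help choose the coverage floor for strain-specific calls;
#' an even-count median is the mean of the two central values.
#'
#' @param sets list of [StrainJunctions].
#' @return a single number.
#' @export
coverageMedian <- function(sets) {
    if (is(sets, "StrainJunctions")) sets <- list(sets)
    pooled <- unlist(lapply(sets, function(s)
        mcols(s@junctions)$uniqueReads), use.names = FALSE)
    if (length(pooled) == 0L)
        stop("coverage median undefined: no junctions in any strain")
    stats::median(pooled)
}
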