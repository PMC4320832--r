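suppressPackageStartupMessages({
    library(GenomicRanges)
    library(Biostrings)
    library(SummarizedExperiment)
})

## --- tiny fixture builders -------------------------------------------------

## one splice-junction table row in the aligner dialect
sjLine <- function(chrom, s, e, strandCode = 1L, motifCode = 1L,
                   ann = 0L, uniq = 1L, multi = 0L, over = 20L) {
    paste(chrom, s, e, strandCode, motifCode, ann, uniq, multi, over,
          sep = "\t")
}

writeSJFile <- function(lines, path = tempfile(fileext = ".tab")) {
    writeLines(lines, path)
    path
}

## a StrainJunctions with given coverages at regularly spaced introns
strainSet <- function(label, cov, chrom = "chr1", start0 = 1000L,
                      gap = 1000L, strandCode = 1L, motifCode = 1L) {
    n <- length(cov)
    s <- start0 + gap * (seq_len(n) - 1L)
    readSJ(writeSJFile(vapply(seq_len(n), function(i)
        sjLine(chrom, s[i], s[i] + 100L, strandCode, motifCode,
               uniq = cov[i]), "")), label)
}

## GTF exon line (Ensembl dialect)
gtfExon <- function(chrom, s, e, strand, gene, tx) {
    paste(chrom, "test", "exon", s, e, ".", strand, ".",
          sprintf('gene_id "%s"; transcript_id "%s";', gene, tx),
          sep = "\t")
}

writeGTF <- function(lines, path = tempfile(fileext = ".gtf")) {
    writeLines(lines, path)
    path
}

## --- cached expensive fixtures ---------------------------------------------

.fixtures <- new.env(parent = emptyenv())

## the default synthetic landscape (study-condition defaults, seed 42)
defaultLandscape <- function() {
    if (is.null(.fixtures$land)) {
        spec <- landscapeSpec()
        genome <- generateGenome(seed = spec@seed)
        .fixtures$land <- generateLandscape(spec, genome)
    }
    .fixtures$land
}

defaultMerged <- function() {
    if (is.null(.fixtures$merged))
        .fixtures$merged <- mergeStrains(defaultLandscape()$sets)
    .fixtures$merged
}

defaultDB <- function() {
    if (is.null(.fixtures$db)) {
        p <- tempfile(fileext = ".gtf")
        writeLines(defaultLandscape()$gtf, p)
        .fixtures$db <- buildAnnotationDB(p)
    }
    .fixtures$db
}

## a small, fast landscape for structural tests
smallLandscape <- function(seed = 5L, ...) {
    spec <- landscapeSpec(nCoreJunctions = 200L,
                          nPartialJunctions = 400L,
                          nPrivatePerStrain = 50L, noiseRate = 30,
                          seed = seed, ...)
    genome <- generateGenome(nChroms = 2L, chromLength = 300000L,
                             seed = seed)
    generateLandscape(spec, genome)
}

truthKeys <- function(truth) {
    paste0(truth$chrom, ":", truth$intron_start, "-", truth$intron_end)
}

## --- independent brute-force oracles ---------------------------------------
## These deliberately avoid the package's vectorised code paths.

## pooled median by explicit sort
oracleMedian <- function(values) {
    v <- sort(unname(values))
    n <- length(v)
    if (n %% 2L == 1L) v[(n + 1L) / 2L] else (v[n / 2L] + v[n / 2L + 1L]) / 2
}

## pairwise shared counts by nested loops over strain pairs
oracleSharing <- function(cov, t) {
    ns <- ncol(cov)
    m <- matrix(0L, ns, ns, dimnames = list(colnames(cov), colnames(cov)))
    for (i in seq_len(ns)) for (j in seq_len(ns)) {
        cnt <- 0L
        for (r in seq_len(nrow(cov)))
            if (cov[r, i] >= t && cov[r, j] >= t) cnt <- cnt + 1L
        m[i, j] <- cnt
    }
    m
}

## region intersection by nested loops (1-based closed intervals)
oracleIntersect <- function(callsDf, regionsDf) {
    hit <- logical(nrow(callsDf))
    for (i in seq_len(nrow(callsDf))) for (j in seq_len(nrow(regionsDf))) {
        if (callsDf$chrom[i] == regionsDf$chrom[j] &&
            callsDf$start[i] <= regionsDf$end[j] &&
            callsDf$end[i] >= regionsDf$start[j]) hit[i] <- TRUE
    }
    which(hit)
}

## annotated junction keys by a plain exon-pair walk over a GTF data.frame
oracleJunctionWalk <- function(exons) {
    keys <- character()
    for (tx in unique(exons$tx)) {
        e <- exons[exons$tx == tx, ]
        e <- e[order(e$start), ]
        if (nrow(e) < 2L) next
        for (i in seq_len(nrow(e) - 1L))
            keys <- c(keys, paste0(e$chrom[i], ":", e$end[i] + 1L, "-",
                                   e$start[i + 1L] - 1L))
    }
    sort(unique(keys))
}

## per-junction motif by slicing a re-parsed FASTA (second, independent
## reader: plain readLines reassembly)
oracleMotif <- function(fastaPath, chrom, s, e, strandIn) {
    lines <- readLines(fastaPath)
    heads <- grep("^>", lines)
    seqs <- list()
    for (i in seq_along(heads)) {
        nm <- sub("^>(\\S+).*", "\\1", lines[heads[i]])
        to <- if (i < length(heads)) heads[i + 1L] - 1L else length(lines)
        seqs[[nm]] <- paste(lines[(heads[i] + 1L):to], collapse = "")
    }
    rc <- function(x) chartr("ACGT", "TGCA",
                             paste(rev(strsplit(x, "")[[1]]),
                                   collapse = ""))
    canon <- c("GT AG" = "GT/AG", "GC AG" = "GC/AG", "AT AC" = "AT/AC")
    out <- character(length(s))
    for (i in seq_along(s)) {
        sq <- seqs[[chrom[i]]]
        L <- toupper(substr(sq, s[i], s[i] + 1L))
        R <- toupper(substr(sq, e[i] - 1L, e[i]))
        if (!is.na(canon[paste(L, R)])) out[i] <- canon[paste(L, R)]
        else if (!is.na(canon[paste(rc(R), rc(L))]))
            out[i] <- canon[paste(rc(R), rc(L))]
        else out[i] <- "non-canonical"
    }
    out
}
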