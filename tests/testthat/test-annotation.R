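test_that("consecutive exon pairs become annotated junction keys", {
    p <- writeGTF(c(
        gtfExon("chr1", 101, 200, "+", "G1", "T1"),
        gtfExon("chr1", 301, 400, "+", "G1", "T1"),
        gtfExon("chr1", 501, 600, "+", "G1", "T1"),
        gtfExon("chr2", 50, 80, "-", "G2", "T2")))   # single exon
    db <- buildAnnotationDB(p)
    expect_equal(junctionKeys(annotatedJunctions(db)),
                 c("chr1:201-300", "chr1:401-500"))
    ## gene span = min/max over exons
    g <- geneRanges(db)
    expect_equal(start(g[mcols(g)$gene_id == "G1"]), 101L)
    expect_equal(end(g[mcols(g)$gene_id == "G1"]), 600L)
})

test_that("overlapping-exon transcripts are skipped with a warning", {
    p <- writeGTF(c(
        gtfExon("chr1", 100, 250, "+", "G1", "T1"),
        gtfExon("chr1", 200, 300, "+", "G1", "T1"),   # overlaps previous
        gtfExon("chr1", 1000, 1100, "+", "G2", "T2"),
        gtfExon("chr1", 1301, 1400, "+", "G2", "T2")))
    expect_warning(db <- buildAnnotationDB(p), "overlapping exons")
    expect_equal(junctionKeys(annotatedJunctions(db)), "chr1:1101-1300")
})

test_that("a GTF without exon features is an empty-database error", {
    p <- writeGTF(paste("chr1", "t", "CDS", 1, 10, ".", "+", "0",
                        'gene_id "G"; transcript_id "T";', sep = "\t"))
    expect_error(buildAnnotationDB(p), "no exon features")
})

test_that("junction-key derivation matches an independent exon-pair walk", {
    ## random synthetic GTF: 20 genes x 3 transcripts (seed 7)
    set.seed(7)
    exons <- do.call(rbind, lapply(seq_len(20), function(g) {
        chrom <- sample(c("chr1", "chr2"), 1)
        strand <- sample(c("+", "-"), 1)
        base <- g * 100000L
        do.call(rbind, lapply(seq_len(3), function(t) {
            nEx <- sample(2:5, 1)
            starts <- base + sort(sample(seq(0L, 20000L, by = 400L), nEx))
            data.frame(chrom = chrom, start = starts,
                       end = starts + 200L, strand = strand,
                       gene = paste0("G", g),
                       tx = paste0("G", g, ".T", t))
        }))
    }))
    p <- writeGTF(vapply(seq_len(nrow(exons)), function(i)
        gtfExon(exons$chrom[i], exons$start[i], exons$end[i],
                exons$strand[i], exons$gene[i], exons$tx[i]), ""))
    db <- buildAnnotationDB(p)
    expect_setequal(junctionKeys(annotatedJunctions(db)),
                    oracleJunctionWalk(exons))
})

test_that("splice-site motifs are read off the genome on both strands", {
    ##            1234567890123456789012345678901234
    g <- DNAStringSet(c(chr1 = "AAAAGTCCCCCCAGAAAACTCCCCCCACAAAAAA"))
    ## plus-strand GT..AG intron at 5-14; CT..AC (minus GT/AG) at 19-28
    plus <- GRanges("chr1", IRanges(5, 14))
    minus <- GRanges("chr1", IRanges(19, 28))
    mcPlus <- classifyMotif(plus, g)
    expect_equal(as.character(mcPlus$motif), "GT/AG")
    expect_equal(as.character(mcPlus$resolvedStrand), "plus")
    mcMinus <- classifyMotif(minus, g)
    expect_equal(as.character(mcMinus$motif), "GT/AG")
    expect_equal(as.character(mcMinus$resolvedStrand), "minus")
    ## anything else is non-canonical and keeps the input strand
    nc <- GRanges("chr1", IRanges(1, 34), strand = "-")
    mcNC <- classifyMotif(nc, g)
    expect_equal(as.character(mcNC$motif), "non-canonical")
    expect_equal(as.character(mcNC$resolvedStrand), "minus")
    ## N in a dinucleotide is never canonical
    gn <- DNAStringSet(c(chr1 = "AAAANTCCCCCCAGAA"))
    expect_equal(as.character(classifyMotif(GRanges("chr1", IRanges(5, 14)),
                                            gn)$motif), "non-canonical")
    ## errors: degenerate intron, unknown chromosome, out of bounds
    expect_error(classifyMotif(GRanges("chr1", IRanges(5, 7)), g),
                 "degenerate")
    expect_error(classifyMotif(GRanges("chrX", IRanges(5, 14)), g),
                 "absent")
    expect_error(classifyMotif(GRanges("chr1", IRanges(30, 40)), g),
                 "outside")
})

test_that("motif classification matches an independent FASTA slicing oracle", {
    land <- smallLandscape(seed = 9L)
    fa <- tempfile(fileext = ".fa")
    writeXStringSet(land$genome, fa)
    tr <- land$truth
    n <- min(1000L, nrow(tr))
    idx <- seq_len(n)
    gr <- GRanges(tr$chrom[idx], IRanges(tr$intron_start[idx],
                                         tr$intron_end[idx]))
    mc <- classifyMotif(gr, land$genome)
    expect_equal(as.character(mc$motif),
                 oracleMotif(fa, tr$chrom[idx], tr$intron_start[idx],
                             tr$intron_end[idx]))
})

test_that("motif calls are strand-consistent under genome reversal", {
    land <- smallLandscape(seed = 13L)
    tr <- land$truth[1:200, ]
    gr <- GRanges(tr$chrom, IRanges(tr$intron_start, tr$intron_end))
    mc <- classifyMotif(gr, land$genome)
    rcGenome <- reverseComplement(land$genome)
    names(rcGenome) <- names(land$genome)
    chromLen <- setNames(width(land$genome), names(land$genome))
    L <- chromLen[tr$chrom]
    grRC <- GRanges(tr$chrom, IRanges(L - tr$intron_end + 1L,
                                      L - tr$intron_start + 1L))
    mcRC <- classifyMotif(grRC, rcGenome)
    expect_equal(as.character(mcRC$motif), as.character(mc$motif))
    canon <- mc$motif %in% c("GT/AG", "GC/AG", "AT/AC")
    flip <- c(plus = "minus", minus = "plus")
    expect_equal(as.character(mcRC$resolvedStrand)[canon],
                 unname(flip[as.character(mc$resolvedStrand)[canon]]))
})

test_that("annotation lookup is an exact, strand-blind coordinate match", {
    p <- writeGTF(c(gtfExon("chr1", 101, 200, "+", "G1", "T1"),
                    gtfExon("chr1", 301, 400, "+", "G1", "T1")))
    db <- buildAnnotationDB(p)
    expect_true(isAnnotated(GRanges("chr1", IRanges(201, 300)), db))
    ## strand disagreement does not demote a coordinate-exact match
    expect_true(isAnnotated(GRanges("chr1", IRanges(201, 300),
                                    strand = "-"), db))
    ## off by one in either coordinate is a miss
    expect_false(isAnnotated(GRanges("chr1", IRanges(202, 300)), db))
    expect_false(isAnnotated(GRanges("chr1", IRanges(201, 301)), db))
})

test_that("half the true junctions are annotated in the synthetic world", {
    land <- defaultLandscape()
    tr <- land$truth[land$truth$origin != "noise", ]
    frac <- mean(isAnnotated(truthKeys(tr), defaultDB()))
    expect_lt(abs(frac - 0.5), 0.02)
    ## annotated implies canonical by generator construction
    ann <- tr[tr$annotated, ]
    expect_true(all(ann$motif %in% c("GT/AG", "GC/AG", "AT/AC")))
    mc <- classifyMotif(GRanges(ann$chrom[1:500],
                                IRanges(ann$intron_start[1:500],
                                        ann$intron_end[1:500])),
                        land$genome)
    expect_true(all(mc$motif %in% c("GT/AG", "GC/AG", "AT/AC")))
})

test_that("gene overlap respects strand only when the strand is known", {
    p <- writeGTF(c(gtfExon("chr1", 1000, 1100, "+", "GP", "TP1"),
                    gtfExon("chr1", 1901, 2000, "+", "GP", "TP1"),
                    gtfExon("chr2", 1000, 1100, "-", "GM", "TM1"),
                    gtfExon("chr2", 1901, 2000, "-", "GM", "TM1")))
    db <- buildAnnotationDB(p)
    inPlus <- GRanges("chr1", IRanges(1200, 1400), strand = "+")
    expect_equal(overlapsGene(inPlus, db), "GP")
    strand(inPlus) <- "-"
    expect_true(is.na(overlapsGene(inPlus, db)))
    ## undefined strand waives the strand test
    undef <- GRanges("chr2", IRanges(1200, 1400), strand = "*")
    expect_equal(overlapsGene(undef, db), "GM")
    ## no overlap at all
    expect_true(is.na(overlapsGene(GRanges("chr1", IRanges(5000, 5100)),
                                   db)))
})

test_that("gene-overlap ties break by longest overlap then gene id", {
    lines <- c(gtfExon("chr1", 1000, 1040, "+", "GSHORT", "T1"),
               gtfExon("chr1", 2960, 3000, "+", "GSHORT", "T1"),
               gtfExon("chr1", 500, 600, "+", "GLONG", "T2"),
               gtfExon("chr1", 4900, 5000, "+", "GLONG", "T2"),
               gtfExon("chr1", 1000, 1100, "+", "AAA", "T3"),
               gtfExon("chr1", 2900, 3000, "+", "AAA", "T3"))
    db1 <- buildAnnotationDB(writeGTF(lines))
    db2 <- buildAnnotationDB(writeGTF(rev(lines)))
    ## fully inside GSHORT [1000,3000], AAA [1000,3000] and GLONG [500,5000]:
    ## overlap width ties between GSHORT and AAA -> lexicographic AAA
    j <- GRanges("chr1", IRanges(1200, 2800), strand = "+")
    expect_equal(overlapsGene(j, db1), "AAA")
    expect_equal(overlapsGene(j, db2), "AAA")
    ## a junction wider than the tied genes overlaps GLONG the most
    j2 <- GRanges("chr1", IRanges(600, 4000), strand = "+")
    expect_equal(overlapsGene(j2, db1), "GLONG")
    expect_equal(overlapsGene(j2, db2), "GLONG")
})
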