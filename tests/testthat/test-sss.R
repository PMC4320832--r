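## helper: a 3-strain landscape from explicit coverage vectors over
## shared junction positions
covLandscape <- function(covMat) {
    sets <- lapply(colnames(covMat), function(s) {
        keep <- which(covMat[, s] > 0L)
        readSJ(writeSJFile(vapply(keep, function(i)
            sjLine("chr1", 1000L * i, 1000L * i + 100L,
                   uniq = covMat[i, s]), "")), s)
    })
    mergeStrains(sets)
}

test_that("potential calls require presence in exactly one strain", {
    cov <- matrix(c(12L, 0L, 0L,
                    12L, 1L, 0L,
                    9L,  0L, 0L,
                    0L,  0L, 30L), 4L, byrow = TRUE,
                  dimnames = list(NULL, c("A", "B", "C")))
    land <- covLandscape(cov)
    pot10 <- findPotentialSSS(land, focalMin = 10L)
    expect_equal(length(pot10), 2L)
    expect_setequal(as.character(mcols(pot10)$strain), c("A", "C"))
    expect_true(all(mcols(pot10)$tier == "potential"))
    ## (12,1,0) is excluded under strict absence but allowed at 1 tolerated
    ## read elsewhere
    pot10lenient <- findPotentialSSS(land, focalMin = 10L,
                                     requireAbsentReads = 1L)
    expect_equal(length(pot10lenient), 3L)
    ## focal floor of 1 admits the coverage-9 singleton too
    expect_equal(length(findPotentialSSS(land, focalMin = 1L)), 3L)
    expect_error(findPotentialSSS(land, focalMin = 1L,
                                  requireAbsentReads = 2L),
                 "must exceed")
})

test_that("high-confidence filtering applies the coverage and motif criteria", {
    ## genome: junction 1 GT..AG, junction 2 non-canonical, junction 3 GT..AG
    seqs <- paste0(strrep("A", 999), "GT", strrep("C", 97), "AG",
                   strrep("A", 899), "CC", strrep("C", 97), "GG",
                   strrep("A", 899), "GT", strrep("C", 97), "AG",
                   strrep("A", 500))
    genome <- DNAStringSet(setNames(seqs, "chr1"))
    gtfP <- writeGTF(gtfExon("chr1", 1, 100, "+", "G1", "T1"))
    db <- suppressWarnings(buildAnnotationDB(gtfP))
    cov <- matrix(c(12L, 0L, 0L,
                    12L, 0L, 0L,
                    9L,  0L, 0L), 3L, byrow = TRUE,
                  dimnames = list(NULL, c("A", "B", "C")))
    land <- covLandscape(cov)   # junctions at 1000-1100, 2000-2100, 3000-3100
    pot <- findPotentialSSS(land, focalMin = 1L)
    expect_equal(length(pot), 3L)
    hc <- callHighConfidence(pot, SSSConfig(), genome = genome, db = db)
    ## kept: coverage 12 + GT/AG; dropped: non-canonical at 12, GT/AG at 9
    expect_equal(length(hc), 1L)
    expect_equal(start(hc), 1000L)
    expect_equal(as.character(mcols(hc)$motif), "GT/AG")
    expect_true(all(mcols(hc)$tier == "high_confidence"))
    ## missing database or genome is a configuration error
    expect_error(callHighConfidence(pot, SSSConfig(), genome = genome),
                 "configuration")
    expect_error(callHighConfidence(pot, SSSConfig(), db = db),
                 "configuration")
    ## trusting the table motif instead of the genome
    hcTab <- callHighConfidence(pot, SSSConfig(), db = db,
                                useTableMotif = TRUE)
    expect_equal(length(hcTab), 2L)  # table codes said GT/AG for all three
})

test_that("the filter chain is monotone in its thresholds", {
    land <- defaultMerged()
    genome <- defaultLandscape()$genome
    db <- defaultDB()
    pot <- findPotentialSSS(land, focalMin = 1L)
    hc <- callHighConfidence(pot, SSSConfig(), genome = genome, db = db)
    ## high-confidence calls are a subset of the potential calls
    expect_true(all(junctionKeys(hc) %in% junctionKeys(pot)))
    ## counts fall as the coverage floor rises
    nAt <- vapply(c(3L, 10L, 20L), function(m)
        length(callHighConfidence(pot, SSSConfig(minCoverage = m),
                                  genome = genome, db = db)), 0L)
    expect_true(all(diff(nAt) < 0))
    ## counts fall as the canonical set shrinks
    nGT <- length(callHighConfidence(
        pot, SSSConfig(canonicalSet = "GT/AG"), genome = genome,
        db = db))
    expect_lt(nGT, length(hc))
})

test_that("raising the floor from 3 to 10 removes noise-origin calls", {
    land <- defaultLandscape()
    merged <- defaultMerged()
    pot <- findPotentialSSS(merged, focalMin = 1L)
    noiseKeys <- truthKeys(land$truth[land$truth$origin == "noise", ])
    nNoise <- vapply(c(3L, 10L), function(m) {
        hc <- callHighConfidence(pot, SSSConfig(minCoverage = m),
                                 genome = land$genome, db = defaultDB())
        sum(junctionKeys(hc) %in% noiseKeys)
    }, 0L)
    expect_gt(nNoise[1], nNoise[2])
})

test_that("per-strain summaries count motifs, annotation and gene overlap", {
    ## zero calls: an all-zero table
    empty <- GRanges()
    mcols(empty) <- DataFrame(strain = character(), coverage = integer(),
                              motif = factor(character(),
                                             levels = "GT/AG"),
                              annotated = logical(),
                              gene = character(), tier = character())
    tab0 <- sssSummary(empty, strains = c("A", "B"))
    expect_equal(tab0$total, c(0, 0))
    expect_equal(tab0$annotated, c(0, 0))
    ## a hand-built set of calls
    calls <- GRanges("chr1", IRanges(c(100, 300, 500), c(200, 400, 600)))
    mcols(calls) <- DataFrame(
        strain = c("A", "A", "B"), coverage = c(12L, 15L, 20L),
        motif = factor(c("GT/AG", "GC/AG", "GT/AG"),
                       levels = c("GT/AG", "GC/AG", "AT/AC",
                                  "non-canonical", "unknown")),
        annotated = c(TRUE, FALSE, FALSE),
        gene = c("G1", NA, "G2"), tier = "high_confidence")
    tab <- sssSummary(calls)
    expect_equal(tab$strain, c("A", "B"))
    expect_equal(tab$total, c(2, 1))
    expect_equal(tab$`GT/AG`, c(1, 1))
    expect_equal(tab$`GC/AG`, c(1, 0))
    expect_equal(tab$annotated, c(1, 0))
    expect_equal(tab$overlap_gene, c(1, 1))
    st <- sssOverallStats(tab, referenceStrain = "A")
    expect_equal(st$grandTotal, 3)
    expect_equal(st$unannotatedPct, 100 * 2 / 3)
    expect_equal(st$refUnannotatedPct, 50)
    expect_equal(st$nonRefUnannotatedPct, 100)
    expect_error(sssOverallStats(tab, referenceStrain = "Z"),
                 "not in table")
})

test_that("region intersection keeps calls inside 1-based closed intervals", {
    calls <- GRanges("chr2", IRanges(c(80000000, 200000000),
                                     width = 1000))
    mcols(calls)$strain <- c("WSB", "WSB")
    regions <- data.frame(chrom = "chr2", start = 73250000,
                          end = 124850000, label = "WSB_over")
    hit <- intersectRegions(calls, regions)
    expect_equal(length(hit), 1L)
    expect_equal(start(hit), 80000000L)
    expect_equal(mcols(hit)$region, "WSB_over")
    ## a call outside the region on the same chromosome is dropped
    callsX <- GRanges("chrX", IRanges(20000000, 20001000))
    expect_equal(length(intersectRegions(
        callsX, data.frame(chrom = "chrX", start = 35000000,
                           end = 135000000))), 0L)
    expect_error(intersectRegions(calls,
                                  data.frame(chrom = "chr2",
                                             start = 10, end = 5)),
                 "malformed")
})

test_that("region intersection matches the nested-loop oracle", {
    set.seed(11)
    n <- 300L
    callsDf <- data.frame(
        chrom = sample(c("chr1", "chr2"), n, TRUE),
        start = sample.int(100000L, n))
    callsDf$end <- callsDf$start + sample.int(500L, n)
    regionsDf <- data.frame(
        chrom = sample(c("chr1", "chr2"), 20L, TRUE),
        start = sample.int(100000L, 20L))
    regionsDf$end <- regionsDf$start + sample.int(5000L, 20L)
    regionsDf$label <- paste0("R", seq_len(20L))
    calls <- GRanges(callsDf$chrom, IRanges(callsDf$start, callsDf$end))
    mcols(calls)$strain <- "A"
    hit <- intersectRegions(calls, regionsDf)
    expected <- oracleIntersect(callsDf, regionsDf)
    got <- match(junctionKeys(hit),
                 paste0(callsDf$chrom, ":", callsDf$start, "-",
                        callsDf$end))
    expect_setequal(got, expected)
})

test_that("call tables round-trip through the TSV writer", {
    calls <- GRanges("chr1", IRanges(c(100, 300), c(200, 400)),
                     strand = c("+", "-"))
    mcols(calls) <- DataFrame(
        strain = c("A", "B"), coverage = c(12L, 15L),
        motif = factor(c("GT/AG", "AT/AC"),
                       levels = c("GT/AG", "GC/AG", "AT/AC",
                                  "non-canonical", "unknown")),
        annotated = c(TRUE, FALSE), gene = c("G1", NA),
        tier = "high_confidence")
    p <- tempfile(fileext = ".tsv"); pb <- tempfile(fileext = ".bed")
    writeSSSCalls(calls, p, pb)
    df <- read.delim(p)
    expect_equal(nrow(df), 2L)
    expect_equal(df$intron_start, c(100L, 300L))
    bed <- strsplit(readLines(pb), "\t")
    expect_equal(bed[[1]][2], "99")
    expect_equal(bed[[2]][6], "-")
})
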