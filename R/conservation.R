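## Cross-strain merge, conservation statistics and the splicing phylogeny.

#' Merge per-strain junction sets into one landscape
#'
#' Takes the union over junction keys of all strains and assembles a
#' junction-by-strain unique-read matrix (0 = junction not observed in that
#' strain). Because unannotated junctions carry a motif-inferred strand that
#' can be undefined in one strain and called in another, keys are
#' strandless; the strand is reconciled here: the unique non-undefined
#' strand observed across strains, \code{undefined} if none, and
#' \code{conflict} if both orientations were reported (conflicting
#' junctions are kept and flagged, not dropped).
#'
#' @param sets list of [StrainJunctions] (at least two, distinct labels).
#' @return a [JunctionLandscape].
#' @export
mergeStrains <- function(sets) {
    if (is(sets, "StrainJunctions")) sets <- list(sets)
    if (length(sets) < 2L)
        stop("need at least 2 strain junction sets to merge")
    labels <- vapply(sets, strainName, "")
    if (anyDuplicated(labels))
        stop("duplicate strain labels: ",
             paste(unique(labels[duplicated(labels)]), collapse = ", "))

    keyList <- lapply(sets, junctionKeys)
    allKeys <- unique(unlist(keyList, use.names = FALSE))
    ## canonical row order: chromosome, start, end
    parts <- regmatches(allKeys,
                        regexec("^(.*):(\\d+)-(\\d+)$", allKeys))
    chrom <- vapply(parts, `[`, "", 2L)
    istart <- as.integer(vapply(parts, `[`, "", 3L))
    iend <- as.integer(vapply(parts, `[`, "", 4L))
    o <- order(chrom, istart, iend)
    allKeys <- allKeys[o]; chrom <- chrom[o]
    istart <- istart[o]; iend <- iend[o]

    n <- length(allKeys)
    cov <- matrix(0L, n, length(sets),
                  dimnames = list(NULL, labels))
    hasPlus <- hasMinus <- logical(n)
    tableMotif <- rep(NA_character_, n)
    for (j in seq_along(sets)) {
        idx <- match(keyList[[j]], allKeys)
        gr <- junctions(sets[[j]])
        cov[idx, j] <- mcols(gr)$uniqueReads
        st <- as.character(strand(gr))
        hasPlus[idx[st == "+"]] <- TRUE
        hasMinus[idx[st == "-"]] <- TRUE
        mot <- as.character(mcols(gr)$motif)
        fill <- is.na(tableMotif[idx]) & mot != "unknown"
        tableMotif[idx[fill]] <- mot[fill]
    }
    reconciled <- ifelse(hasPlus & hasMinus, "conflict",
                  ifelse(hasPlus, "plus",
                  ifelse(hasMinus, "minus", "undefined")))
    grStrand <- c(plus = "+", minus = "-", undefined = "*",
                  conflict = "*")[reconciled]
    rr <- GRanges(chrom, IRanges(istart, iend), strand = grStrand)
    mcols(rr) <- DataFrame(
        reconciledStrand = factor(reconciled, levels = STRAND_LEVELS),
        tableMotif = factor(ifelse(is.na(tableMotif), "unknown",
                                   tableMotif), levels = MOTIF_LEVELS))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(uniqueReads = cov), rowRanges = rr,
        colData = DataFrame(strain = labels,
                            sourcePath = vapply(sets, sourcePath, ""),
                            row.names = labels))
    new("JunctionLandscape", se)
}

#' Conservation of the splicing landscape at coverage thresholds
#'
#' For each threshold t the junction universe is every key with coverage
#' >= t in at least one strain; the table reports the fraction of that
#' universe conserved in at least two strains and in all strains. Two
#' readings of "conserved at t" are supported: \code{"per-strain"}
#' (default) counts a strain only when its own coverage is >= t — the
#' symmetric reading; \code{"focal"} only requires the junction to reach t
#' somewhere and counts presence elsewhere at >= 1 read.
#'
#' @param x a [JunctionLandscape].
#' @param thresholds increasing positive integers (default 1, 3, 10).
#' @param mode thresholding mode, see above.
#' @return data.frame with columns \code{threshold}, \code{n_universe},
#'   \code{frac_ge2_strains}, \code{frac_all_strains} (NA fractions when
#'   the universe is empty).
#' @export
conservationSummary <- function(x, thresholds = c(1L, 3L, 10L),
                                mode = c("per-strain", "focal")) {
    stopifnot(is(x, "JunctionLandscape"))
    mode <- match.arg(mode)
    thresholds <- as.integer(thresholds)
    if (any(thresholds < 1L) || is.unsorted(thresholds))
        stop("thresholds must be >= 1 and sorted increasing")
    cov <- coverageMatrix(x)
    ns <- ncol(cov)
    rows <- lapply(thresholds, function(t) {
        atT <- cov >= t
        uni <- rowSums(atT) >= 1L
        nU <- sum(uni)
        if (nU == 0L)
            return(data.frame(threshold = t, n_universe = 0L,
                              frac_ge2_strains = NA_real_,
                              frac_all_strains = NA_real_))
        pres <- if (mode == "per-strain") atT else cov >= 1L
        k <- rowSums(pres[uni, , drop = FALSE])
        data.frame(threshold = t, n_universe = nU,
                   frac_ge2_strains = mean(k >= 2L),
                   frac_all_strains = mean(k == ns))
    })
    do.call(rbind, rows)
}

#' Pairwise shared-junction counts
#'
#' Cell (i, j) is the number of junctions with coverage >= t in both
#' strain i and strain j; the diagonal holds per-strain totals at t.
#' Computed in one pass as the cross-product of the presence matrix.
#'
#' @param x a [JunctionLandscape].
#' @param t per-strain coverage threshold (default 1: all observed
#'   junctions).
#' @return a [SharingMatrix].
#' @export
sharingMatrix <- function(x, t = 1L) {
    stopifnot(is(x, "JunctionLandscape"))
    t <- as.integer(t)
    if (length(t) != 1L || t < 1L) stop("t must be a single integer >= 1")
    pres <- (coverageMatrix(x) >= t) * 1L
    shared <- crossprod(pres)
    storage.mode(shared) <- "integer"
    new("SharingMatrix", shared = shared, threshold = t)
}

#' Splicing phylogeny of the strains
#'
#' Each strain is represented by its row of pairwise shared-junction
#' counts; strains are clustered agglomeratively on the Euclidean distance
#' between those rows. Rows are ordered by strain label before clustering
#' so the result is invariant to input order (label-ordered tie-breaking).
#' Branch lengths follow the usual ultrametric convention (leaf depth =
#' merge height / 2).
#'
#' @param x a [SharingMatrix] (symmetric, at least 2 strains).
#' @param linkage agglomeration method: average (default), complete or
#'   single.
#' @return a [SplicingPhylogeny]; see [newickString()].
#' @export
splicingPhylogeny <- function(x, linkage = c("average", "complete",
                                             "single")) {
    linkage <- match.arg(linkage)
    m <- if (is(x, "SharingMatrix")) sharedCounts(x) else x
    if (!is.matrix(m) || nrow(m) < 2L || nrow(m) != ncol(m) ||
        !isTRUE(all.equal(m, t(m))))
        stop("input must be a symmetric strain-by-strain matrix (n >= 2)")
    o <- order(rownames(m))
    m <- m[o, o, drop = FALSE]
    hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                        method = linkage)
    phy <- ape::as.phylo(hc)
    new("SplicingPhylogeny", hclust = hc, phylo = phy,
        newick = ape::write.tree(phy), linkage = linkage)
}

#' Write outputs of the conservation module
#'
#' @param x a [SharingMatrix] or [SplicingPhylogeny].
#' @param path output file (TSV for the matrix, Newick for the tree).
#' @return the path, invisibly.
#' @export
writeSharingMatrix <- function(x, path) {
    stopifnot(is(x, "SharingMatrix"))
    m <- sharedCounts(x)
    df <- data.frame(strain = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeSharingMatrix
#' @export
writeNewick <- function(x, path) {
    stopifnot(is(x, "SplicingPhylogeny"))
    writeLines(x@newick, path)
    invisible(path)
}
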