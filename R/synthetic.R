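## Synthetic multi-strain junction landscapes with ground truth.
##
## The generator emulates the landscape shape seen in striatum RNA-seq of
## an 8-strain inbred panel: a conserved core present in every strain, a
## partially shared tier, per-strain private junctions, and low-coverage
## noise junctions (the stand-in for sequencing errors and alignment
## artifacts) enriched for non-canonical motifs. Junction coverage is
## negative binomial around a shared per-junction expression level, so
## highly expressed junctions are the ones conserved at high thresholds.

.DEFAULT_STRAINS <- c("129", "AJ", "B6", "CAST", "NOD", "NZO", "PWK",
                      "WSB")
.BLOCK <- 400L   # one junction per genome block; guarantees that planted
                 # splice dinucleotides and annotated exon flanks never
                 # collide between junctions

#' LandscapeSpec: parameters of the synthetic junction landscape
#'
#' Constructed with [landscapeSpec()]; see that help page for the meaning
#' and defaults of every slot.
#'
#' @exportClass LandscapeSpec
setClass("LandscapeSpec", representation(
    nStrains = "integer", strains = "character",
    nCoreJunctions = "integer", nPartialJunctions = "integer",
    partialSizeProb = "numeric", nPrivatePerStrain = "integer",
    privateMinCoverage = "integer", noiseRate = "numeric",
    noiseNoncanonicalFraction = "numeric", noiseCoverageP = "numeric",
    annotatedFraction = "numeric", coverageMean = "numeric",
    coverageDispersion = "numeric",
    coreExpressionLogMean = "numeric", coreExpressionLogSd = "numeric",
    coreDispersion = "numeric",
    partialExpressionLogMean = "numeric",
    partialExpressionLogSd = "numeric",
    motifProb = "numeric", intronLengthRange = "integer",
    seed = "integer"))

setValidity("LandscapeSpec", function(object) {
    msg <- character()
    if (object@nStrains < 2L) msg <- c(msg, "need at least 2 strains")
    if (length(object@strains) != object@nStrains)
        msg <- c(msg, "strains must have length nStrains")
    fr <- c(object@noiseNoncanonicalFraction, object@annotatedFraction)
    if (any(fr < 0) || any(fr > 1))
        msg <- c(msg, "fractions must be in [0, 1]")
    if (any(c(object@nCoreJunctions, object@nPartialJunctions,
              object@nPrivatePerStrain, object@noiseRate) < 0))
        msg <- c(msg, "all counts must be >= 0")
    if (!setequal(names(object@motifProb),
                  c(CANONICAL_MOTIFS, "non-canonical")))
        msg <- c(msg, "motifProb must name the four motif classes")
    if (length(msg)) msg else TRUE
})

#' Specify a synthetic junction landscape
#'
#' Defaults describe the study conditions the generator emulates: 8
#' strains; 3400 core junctions shared by all strains and 7750 partially
#' shared ones, so that 65\% of distinct junctions are seen in at least 2
#' strains and ~20\% in all strains; 500 private junctions per strain at
#' coverage >= 10 (the scale of strain-specific junctions surviving a
#' 10-read floor in deep striatum libraries); ~250 low-coverage noise
#' junctions per strain, half of them non-canonical; half of all true
#' junctions annotated in the companion GTF. Coverage is negative binomial
#' (dispersion \code{coverageDispersion}) around a log-normal per-junction
#' expression level whose scale differs between the core (highly expressed,
#' tight) and partial tiers; under the defaults the pooled coverage median
#' is ~7.5 and the all-strain conservation fraction increases with the
#' coverage threshold.
#'
#' @param nStrains number of strains (default 8).
#' @param strains strain labels (defaults to the classical + wild-derived
#'   founder labels of the Collaborative Cross panel).
#' @param nCoreJunctions junctions present in every strain.
#' @param nPartialJunctions junctions present in 2..(nStrains-1) strains.
#' @param partialSizeProb sampling weights over those subset sizes.
#' @param nPrivatePerStrain true strain-private junctions, scalar or one
#'   value per strain (raise individual strains to emulate wild-derived
#'   divergence).
#' @param privateMinCoverage coverage floor added to private junctions.
#' @param noiseRate expected spurious junctions per strain (Poisson).
#' @param noiseNoncanonicalFraction fraction of noise junctions planted
#'   with a non-canonical motif.
#' @param noiseCoverageP geometric success parameter for noise coverage
#'   (coverage = 1 + geometric; 0.55 keeps 1-3 reads dominant).
#' @param annotatedFraction fraction of true junctions emitted as two-exon
#'   transcripts in the GTF (drawn from the canonical-motif junctions, so
#'   annotated implies canonical in the synthetic world).
#' @param coverageMean,coverageDispersion negative-binomial mean scale and
#'   size for the partial/private tiers.
#' @param coreExpressionLogMean,coreExpressionLogSd,coreDispersion
#'   log-normal expression multiplier and NB size of the core tier.
#' @param partialExpressionLogMean,partialExpressionLogSd log-normal
#'   expression multiplier of the partial tier.
#' @param motifProb motif-class probabilities for true junctions.
#' @param intronLengthRange min/max intron length (bases).
#' @param seed RNG seed; identical spec + genome gives byte-identical
#'   outputs.
#' @return a [LandscapeSpec].
#' @export
landscapeSpec <- function(nStrains = 8L,
                          strains = NULL,
                          nCoreJunctions = 3400L,
                          nPartialJunctions = 7750L,
                          partialSizeProb = NULL,
                          nPrivatePerStrain = 500L,
                          privateMinCoverage = 10L,
                          noiseRate = 250,
                          noiseNoncanonicalFraction = 0.5,
                          noiseCoverageP = 0.55,
                          annotatedFraction = 0.5,
                          coverageMean = 9,
                          coverageDispersion = 2,
                          coreExpressionLogMean = log(3),
                          coreExpressionLogSd = 0.4,
                          coreDispersion = 12,
                          partialExpressionLogMean = log(0.19),
                          partialExpressionLogSd = 0.7,
                          motifProb = c("GT/AG" = 0.95, "GC/AG" = 0.035,
                                        "AT/AC" = 0.005,
                                        "non-canonical" = 0.01),
                          intronLengthRange = c(60L, 250L),
                          seed = 42L) {
    nStrains <- as.integer(nStrains)
    if (is.null(strains))
        strains <- if (nStrains == 8L) .DEFAULT_STRAINS else
            paste0("S", seq_len(nStrains))
    if (is.null(partialSizeProb))
        partialSizeProb <- if (nStrains == 8L)
            c(0.25, 0.20, 0.17, 0.14, 0.13, 0.11) else
            rep(1 / (nStrains - 2L), nStrains - 2L)
    nPriv <- as.integer(rep_len(nPrivatePerStrain, nStrains))
    new("LandscapeSpec", nStrains = nStrains, strains = strains,
        nCoreJunctions = as.integer(nCoreJunctions),
        nPartialJunctions = as.integer(nPartialJunctions),
        partialSizeProb = partialSizeProb / sum(partialSizeProb),
        nPrivatePerStrain = nPriv,
        privateMinCoverage = as.integer(privateMinCoverage),
        noiseRate = noiseRate,
        noiseNoncanonicalFraction = noiseNoncanonicalFraction,
        noiseCoverageP = noiseCoverageP,
        annotatedFraction = annotatedFraction,
        coverageMean = coverageMean,
        coverageDispersion = coverageDispersion,
        coreExpressionLogMean = coreExpressionLogMean,
        coreExpressionLogSd = coreExpressionLogSd,
        coreDispersion = coreDispersion,
        partialExpressionLogMean = partialExpressionLogMean,
        partialExpressionLogSd = partialExpressionLogSd,
        motifProb = motifProb,
        intronLengthRange = as.integer(intronLengthRange),
        seed = as.integer(seed))
}

#' Generate a uniform random genome
#'
#' @param nChroms number of chromosomes (named chr1, chr2, ...).
#' @param chromLength length of each chromosome (>= 10 kb).
#' @param seed RNG seed (deterministic output).
#' @return a \code{DNAStringSet}.
#' @export
generateGenome <- function(nChroms = 6L, chromLength = 1250000L,
                           seed = 42L) {
    if (chromLength < 10000L)
        stop("chromLength must be at least 10 kb")
    set.seed(seed)
    seqs <- vapply(seq_len(nChroms), function(i)
        paste(sample(c("A", "C", "G", "T"), chromLength, replace = TRUE),
              collapse = ""), "")
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- paste0("chr", seq_len(nChroms))
    out
}

## plus-strand (donor, acceptor) dinucleotides for a motif planted on a
## given strand; non-canonical pairs are chosen so neither orientation
## reads as canonical
.plantDinucs <- function(motif, strand) {
    fwd <- rbind("GT/AG" = c("GT", "AG"), "GC/AG" = c("GC", "AG"),
                 "AT/AC" = c("AT", "AC"))
    n <- length(motif)
    donor <- acceptor <- character(n)
    canon <- motif %in% CANONICAL_MOTIFS
    plus <- strand == "+"
    donor[canon & plus] <- fwd[motif[canon & plus], 1L]
    acceptor[canon & plus] <- fwd[motif[canon & plus], 2L]
    donor[canon & !plus] <- .revcomp2(fwd[motif[canon & !plus], 2L])
    acceptor[canon & !plus] <- .revcomp2(fwd[motif[canon & !plus], 1L])
    nc <- which(!canon)
    if (length(nc)) {
        safe <- rbind(c("CC", "GG"), c("AA", "TT"), c("GG", "CC"),
                      c("TT", "AA"))
        pick <- sample.int(nrow(safe), length(nc), replace = TRUE)
        donor[nc] <- safe[pick, 1L]
        acceptor[nc] <- safe[pick, 2L]
    }
    list(donor = donor, acceptor = acceptor)
}

#' Generate a multi-strain junction landscape with ground truth
#'
#' Places every junction in its own genome block so splice dinucleotides
#' and annotated exon flanks never collide, overwrites the genome copy with
#' each junction's planted motif, assigns strain membership and negative-
#' binomial coverage per tier, writes the annotated half of the true
#' junctions as two-exon transcripts of a synthetic GTF, and renders
#' per-strain splice-junction tables in the standard aligner dialect.
#'
#' @param spec a [LandscapeSpec].
#' @param genome a \code{DNAStringSet} from [generateGenome()] (large
#'   enough to hold all junctions; error otherwise).
#' @param dir optional output directory; when given, writes
#'   \code{<strain>.SJ.out.tab} per strain, \code{genome.fa} (the modified
#'   copy), \code{annotation.gtf}, \code{truth.tsv} and
#'   \code{landscape_spec.txt}, all byte-deterministic under the spec seed.
#' @return list with elements \code{sets} (list of [StrainJunctions]),
#'   \code{genome} (modified \code{DNAStringSet}), \code{gtf} (character
#'   lines), \code{truth} (data.frame: chrom, intron_start, intron_end,
#'   strand, origin, owners, motif, annotated, gene_id), \code{spec}, and
#'   \code{paths} (named character, when \code{dir} was given).
#' @export
generateLandscape <- function(spec, genome, dir = NULL) {
    stopifnot(is(spec, "LandscapeSpec"))
    genome <- .asGenome(genome)
    set.seed(spec@seed)
    ns <- spec@nStrains
    strains <- spec@strains
    nCore <- spec@nCoreJunctions
    nPartial <- spec@nPartialJunctions
    nPriv <- spec@nPrivatePerStrain
    nNoise <- stats::rpois(ns, spec@noiseRate)
    n <- nCore + nPartial + sum(nPriv) + sum(nNoise)

    ## --- placement: one block per junction ---
    nbPerChrom <- as.integer(Biostrings::width(genome) %/% .BLOCK)
    totalBlocks <- sum(nbPerChrom)
    if (n > totalBlocks)
        stop("placement exhausted: ", n, " junctions need more than ",
             totalBlocks, " genome blocks; supply a larger genome")
    blockId <- sample.int(totalBlocks, n)
    chromIdx <- findInterval(blockId - 1L, cumsum(c(0L, nbPerChrom)),
                             rightmost.closed = FALSE)
    chrom <- names(genome)[chromIdx]
    blockStart <- (blockId - c(0L, cumsum(nbPerChrom))[chromIdx] - 1L) *
        .BLOCK
    L <- sample(seq(spec@intronLengthRange[1L],
                    spec@intronLengthRange[2L]), n, replace = TRUE)
    istart <- blockStart + 101L
    iend <- istart + L - 1L
    strand <- sample(c("+", "-"), n, replace = TRUE)

    ## --- origin tiers ---
    origin <- rep(c("core", "partial"), c(nCore, nPartial))
    origin <- c(origin, rep("private", sum(nPriv)),
                rep("noise", sum(nNoise)))
    privOwner <- rep(seq_len(ns), nPriv)
    noiseOwner <- rep(seq_len(ns), nNoise)

    ## --- motifs ---
    nTrue <- nCore + nPartial + sum(nPriv)
    motif <- character(n)
    motif[seq_len(nTrue)] <- sample(names(spec@motifProb), nTrue,
                                    replace = TRUE,
                                    prob = spec@motifProb)
    nzN <- sum(nNoise)
    if (nzN)
        motif[nTrue + seq_len(nzN)] <-
            ifelse(stats::runif(nzN) < spec@noiseNoncanonicalFraction,
                   "non-canonical", "GT/AG")
    ## non-canonical junctions carry no strand call in the tables
    strandObs <- ifelse(motif == "non-canonical", "*", strand)

    ## --- plant splice dinucleotides into a genome copy ---
    dn <- .plantDinucs(motif, strand)
    for (ch in unique(chrom)) {
        i <- which(chrom == ch)
        at <- c(rbind(istart[i], istart[i] + 1L,
                      iend[i] - 1L, iend[i]))
        letters <- c(rbind(substr(dn$donor[i], 1L, 1L),
                           substr(dn$donor[i], 2L, 2L),
                           substr(dn$acceptor[i], 1L, 1L),
                           substr(dn$acceptor[i], 2L, 2L)))
        genome[[ch]] <- Biostrings::replaceLetterAt(
            genome[[ch]], at, paste(letters, collapse = ""))
    }

    ## --- membership matrix ---
    member <- matrix(FALSE, n, ns, dimnames = list(NULL, strains))
    member[seq_len(nCore), ] <- TRUE
    kSizes <- 2L:(ns - 1L)
    partIdx <- nCore + seq_len(nPartial)
    k <- kSizes[sample.int(length(kSizes), nPartial, replace = TRUE,
                           prob = spec@partialSizeProb)]
    for (i in seq_len(nPartial))
        member[partIdx[i], sample.int(ns, k[i])] <- TRUE
    privIdx <- nCore + nPartial + seq_len(sum(nPriv))
    member[cbind(privIdx, privOwner)] <- TRUE
    noiseIdx <- nTrue + seq_len(nzN)
    if (nzN) member[cbind(noiseIdx, noiseOwner)] <- TRUE

    ## --- coverage ---
    cov <- matrix(0L, n, ns, dimnames = list(NULL, strains))
    lamCore <- spec@coverageMean *
        stats::rlnorm(nCore, spec@coreExpressionLogMean,
                      spec@coreExpressionLogSd)
    cov[seq_len(nCore), ] <- pmax(
        stats::rnbinom(nCore * ns, size = spec@coreDispersion,
                       mu = rep(lamCore, ns)), 1L)
    lamPart <- spec@coverageMean *
        stats::rlnorm(nPartial, spec@partialExpressionLogMean,
                      spec@partialExpressionLogSd)
    for (i in seq_len(nPartial)) {
        s <- which(member[partIdx[i], ])
        cov[partIdx[i], s] <- pmax(
            stats::rnbinom(length(s), size = spec@coverageDispersion,
                           mu = lamPart[i]), 1L)
    }
    if (sum(nPriv))
        cov[cbind(privIdx, privOwner)] <- spec@privateMinCoverage +
            stats::rnbinom(sum(nPriv), size = spec@coverageDispersion,
                           mu = spec@coverageMean)
    if (nzN)
        cov[cbind(noiseIdx, noiseOwner)] <- 1L +
            stats::rgeom(nzN, spec@noiseCoverageP)
    storage.mode(cov) <- "integer"

    ## --- annotation: two-exon transcripts for half the true junctions ---
    canonTrue <- which(origin != "noise" & motif != "non-canonical")
    nAnn <- round(spec@annotatedFraction * nTrue)
    if (nAnn > length(canonTrue))
        stop("annotatedFraction too high for the canonical junction count")
    annIdx <- sort(canonTrue[sample.int(length(canonTrue), nAnn)])
    annotated <- logical(n); annotated[annIdx] <- TRUE
    geneId <- rep(NA_character_, n)
    geneId[annIdx] <- sprintf("SYNG%05d", seq_len(nAnn))
    txId <- sprintf("SYNT%05d", seq_len(nAnn))
    attr1 <- sprintf(
        'gene_id "%s"; transcript_id "%s"; exon_number "1";',
        geneId[annIdx], txId)
    attr2 <- sub('"1"', '"2"', attr1, fixed = TRUE)
    gtf <- c(
        paste(chrom[annIdx], "synthetic", "exon", istart[annIdx] - 50L,
              istart[annIdx] - 1L, ".", strand[annIdx], ".", attr1,
              sep = "\t"),
        paste(chrom[annIdx], "synthetic", "exon", iend[annIdx] + 1L,
              iend[annIdx] + 50L, ".", strand[annIdx], ".", attr2,
              sep = "\t"))
    gtf <- gtf[order(rep(annIdx, 2L), rep(1:2, each = nAnn))]

    ## --- per-strain junction tables ---
    .motifCode <- function(m, st) {
        base <- c("GT/AG" = 1L, "GC/AG" = 3L, "AT/AC" = 5L)
        ifelse(m == "non-canonical", 0L,
               base[m] + as.integer(st == "-"))
    }
    sets <- vector("list", ns); names(sets) <- strains
    tabLines <- vector("list", ns)
    for (j in seq_len(ns)) {
        rows <- which(member[, j])
        rows <- rows[order(chrom[rows], istart[rows], iend[rows])]
        cnt <- length(rows)
        strandCode <- ifelse(strandObs[rows] == "*", 0L,
                             ifelse(strandObs[rows] == "+", 1L, 2L))
        multi <- stats::rpois(cnt, 0.5)
        over <- sample(20:50, cnt, replace = TRUE)
        tabLines[[j]] <- paste(chrom[rows], istart[rows], iend[rows],
                               strandCode,
                               .motifCode(motif[rows], strand[rows]),
                               as.integer(annotated[rows]),
                               cov[rows, j], multi, over, sep = "\t")
        gr <- GRanges(chrom[rows], IRanges(istart[rows], iend[rows]),
                      strand = strandObs[rows])
        mcols(gr) <- DataFrame(
            motif = factor(motif[rows], levels = MOTIF_LEVELS),
            annotatedFlag = annotated[rows],
            uniqueReads = cov[rows, j],
            multiReads = as.integer(multi),
            maxOverhang = as.integer(over))
        sets[[j]] <- new("StrainJunctions", strain = strains[j],
                         junctions = gr, sourcePath = "")
    }

    truth <- data.frame(
        chrom = chrom, intron_start = istart, intron_end = iend,
        strand = strand, origin = origin,
        owners = vapply(seq_len(n), function(i)
            paste(strains[member[i, ]], collapse = ","), ""),
        motif = motif, annotated = annotated, gene_id = geneId,
        stringsAsFactors = FALSE)

    paths <- NULL
    if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        sjPaths <- file.path(dir, paste0(strains, ".SJ.out.tab"))
        for (j in seq_len(ns)) writeLines(tabLines[[j]], sjPaths[j])
        genomePath <- file.path(dir, "genome.fa")
        Biostrings::writeXStringSet(genome, genomePath, width = 80L)
        gtfPath <- file.path(dir, "annotation.gtf")
        writeLines(gtf, gtfPath)
        truthPath <- file.path(dir, "truth.tsv")
        utils::write.table(truth, truthPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        specPath <- file.path(dir, "landscape_spec.txt")
        sl <- slotNames(spec)
        writeLines(paste0(sl, ": ", vapply(sl, function(s)
            paste(format(slot(spec, s)), collapse = " "), "")), specPath)
        paths <- c(stats::setNames(sjPaths, strains),
                   genome = genomePath, gtf = gtfPath,
                   truth = truthPath, spec = specPath)
        for (j in seq_len(ns)) sets[[j]]@sourcePath <- sjPaths[j]
    }

    list(sets = sets, genome = genome, gtf = gtf, truth = truth,
         spec = spec, paths = paths)
}
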