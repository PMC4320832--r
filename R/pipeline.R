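## End-to-end pipeline driver and publication-style summary tables.

.pct <- function(x) sprintf("%.2f", round(100 * x, 2))  # half-even, 2 dp

.provenance <- function(params) {
    ver <- as.character(utils::packageVersion("SpliceScape"))
    tf <- tempfile()
    writeLines(paste0(names(params), "=",
                      vapply(params, function(p)
                          paste(format(p), collapse = ","), "")), tf)
    h <- unname(tools::md5sum(tf))
    unlink(tf)
    c(paste0("# SpliceScape ", ver),
      paste0("# config-md5: ", h),
      paste0("# ", names(params), ": ",
             vapply(params, function(p)
                 paste(format(p), collapse = ","), "")))
}

.writeTSV <- function(df, path, header) {
    con <- file(path, "wt")
    on.exit(close(con))
    writeLines(header, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Per-strain junction summary (motif, annotation and gene-overlap rates)
#'
#' For each strain: the number of mapped junctions, the percentage
#' previously annotated, the percentage in each splice-site motif class
#' (re-derived from the genome), and the percentage overlapping an
#' annotated gene (same strand required when the strand is known).
#'
#' @param sets list of [StrainJunctions].
#' @param genome genome FASTA (path or \code{DNAStringSet}).
#' @param db a [JunctionAnnotationDB].
#' @return data.frame, one row per strain; percentage columns are numeric
#'   on the 0-100 scale.
#' @export
perStrainSummary <- function(sets, genome, db) {
    genome <- .asGenome(genome)
    rows <- lapply(sets, function(s) {
        gr <- junctions(s)
        ngr <- length(gr)
        mc <- classifyMotif(gr, genome)
        gene <- overlapsGene(.withResolvedStrand(gr, mc), db)
        data.frame(
            strain = strainName(s),
            mapped_junctions = ngr,
            annotated_pct = 100 * mean(isAnnotated(gr, db)),
            `GT/AG_pct` = 100 * mean(mc$motif == "GT/AG"),
            `GC/AG_pct` = 100 * mean(mc$motif == "GC/AG"),
            `AT/AC_pct` = 100 * mean(mc$motif == "AT/AC"),
            noncanonical_pct = 100 * mean(mc$motif == "non-canonical"),
            overlap_gene_pct = 100 * mean(!is.na(gene)),
            check.names = FALSE)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

## junction GRanges with strand replaced by the motif-resolved strand
.withResolvedStrand <- function(gr, mc) {
    out <- gr
    strand(out) <- c(plus = "+", minus = "-",
                     undefined = "*")[as.character(mc$resolvedStrand)]
    out
}

#' Read a pipeline run configuration
#'
#' A YAML file with fields: \code{sj_tables} (mapping strain label to
#' file), \code{genome}, \code{gtf}, \code{out_dir}, and optionally
#' \code{min_coverage} (default 10), \code{thresholds} (default 1,3,10),
#' \code{linkage} (default average), \code{phylo_threshold} (default 1).
#'
#' @param path YAML config file.
#' @return a named list of validated fields.
#' @export
readRunConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    need <- c("sj_tables", "genome", "gtf", "out_dir")
    miss <- setdiff(need, names(cfg))
    if (length(miss))
        stop("run config lacks field(s): ", paste(miss, collapse = ", "))
    ins <- c(unlist(cfg$sj_tables), cfg$genome, cfg$gtf)
    absent <- ins[!file.exists(ins)]
    if (length(absent))
        stop("input path(s) do not exist: ",
             paste(absent, collapse = ", "))
    cfg$min_coverage <- cfg$min_coverage %||% 10L
    cfg$thresholds <- cfg$thresholds %||% c(1L, 3L, 10L)
    cfg$linkage <- cfg$linkage %||% "average"
    cfg$phylo_threshold <- cfg$phylo_threshold %||% 1L
    cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full junction-landscape pipeline and write summary tables
#'
#' Reads per-strain splice-junction tables, merges them, and writes five
#' summary files into \code{outDir}, each with a provenance header
#' (package version, config hash, parameters): \code{strain_summary.tsv}
#' (per-strain junction counts and motif/annotation/gene-overlap
#' percentages), \code{conservation.tsv} (conserved fractions per coverage
#' threshold), \code{sharing_matrix.tsv}, \code{splicing_phylogeny.nwk},
#' and \code{sss_summary.tsv} (per-strain high-confidence strain-specific
#' splicing counts), plus \code{sss_calls.tsv} with the individual calls.
#' Outputs are deterministic: re-running with the same inputs produces
#' byte-identical files.
#'
#' @param sjPaths named character vector (strain label -> table path).
#' @param genomePath genome FASTA.
#' @param gtfPath annotation GTF.
#' @param outDir output directory (created if needed).
#' @param config an [SSSConfig] for the strain-specific calls.
#' @param thresholds conservation coverage thresholds.
#' @param linkage clustering linkage for the phylogeny.
#' @param phyloThreshold sharing-matrix threshold for the phylogeny
#'   (default 1: all identified junctions included).
#' @return invisibly, a named list of the output paths.
#' @export
runPipeline <- function(sjPaths, genomePath, gtfPath, outDir,
                        config = SSSConfig(),
                        thresholds = c(1L, 3L, 10L),
                        linkage = "average", phyloThreshold = 1L) {
    if (is.null(names(sjPaths)) || any(!nzchar(names(sjPaths))))
        stop("sjPaths must be named by strain label")
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    params <- list(
        strains = names(sjPaths), sj_tables = unname(sjPaths),
        genome = genomePath, gtf = gtfPath,
        min_coverage = config@minCoverage,
        canonical_set = config@canonicalSet,
        require_absent_reads = config@requireAbsentReads,
        thresholds = thresholds, linkage = linkage,
        phylo_threshold = phyloThreshold)
    prov <- .provenance(params)

    sets <- lapply(names(sjPaths), function(s) readSJ(sjPaths[[s]], s))
    genome <- .asGenome(genomePath)
    db <- buildAnnotationDB(gtfPath)
    land <- mergeStrains(sets)

    out <- c(strain_summary = file.path(outDir, "strain_summary.tsv"),
             conservation = file.path(outDir, "conservation.tsv"),
             sharing_matrix = file.path(outDir, "sharing_matrix.tsv"),
             phylogeny = file.path(outDir, "splicing_phylogeny.nwk"),
             sss_summary = file.path(outDir, "sss_summary.tsv"),
             sss_calls = file.path(outDir, "sss_calls.tsv"))

    ss <- perStrainSummary(sets, genome, db)
    pctCols <- grep("_pct$", names(ss))
    ss[pctCols] <- lapply(ss[pctCols], function(x) .pct(x / 100))
    .writeTSV(ss, out[["strain_summary"]], prov)

    cons <- conservationSummary(land, thresholds)
    cons$frac_ge2_strains <- ifelse(is.na(cons$frac_ge2_strains), "NA",
                                    .pct(cons$frac_ge2_strains))
    cons$frac_all_strains <- ifelse(is.na(cons$frac_all_strains), "NA",
                                    .pct(cons$frac_all_strains))
    names(cons)[3:4] <- c("pct_ge2_strains", "pct_all_strains")
    .writeTSV(cons, out[["conservation"]], prov)

    sm <- sharingMatrix(land, phyloThreshold)
    m <- sharedCounts(sm)
    .writeTSV(data.frame(strain = rownames(m), m, check.names = FALSE),
              out[["sharing_matrix"]], prov)
    phy <- splicingPhylogeny(sm, linkage)
    writeLines(newickString(phy), out[["phylogeny"]])

    pot <- findPotentialSSS(land, focalMin = 1L,
                            requireAbsentReads = config@requireAbsentReads)
    hc <- callHighConfidence(pot, config, genome = genome, db = db)
    writeSSSCalls(hc, out[["sss_calls"]])
    tab <- sssSummary(hc, strains = names(sjPaths))
    stats <- sssOverallStats(tab)
    footer <- c(paste0("# grand_total: ", stats$grandTotal),
                paste0("# unannotated_pct: ",
                       .pct(stats$unannotatedPct / 100)),
                paste0("# gene_overlap_pct: ",
                       .pct(stats$geneOverlapPct / 100)))
    .writeTSV(tab, out[["sss_summary"]], c(prov, footer))

    invisible(as.list(out))
}

#' Simulate a synthetic dataset directory
#'
#' Thin wrapper over [generateGenome()] + [generateLandscape()]: writes
#' per-strain junction tables, the motif-planted genome FASTA, the
#' synthetic GTF, the ground-truth table and a spec echo into \code{dir}.
#'
#' @param dir output directory.
#' @param spec a [LandscapeSpec] (default [landscapeSpec()]).
#' @param nChroms,chromLength genome geometry passed to
#'   [generateGenome()] (seeded from the spec seed).
#' @return the [generateLandscape()] result list (with \code{paths}).
#' @export
simulateLandscape <- function(dir, spec = landscapeSpec(),
                              nChroms = 6L, chromLength = 1250000L) {
    genome <- generateGenome(nChroms, chromLength, seed = spec@seed)
    generateLandscape(spec, genome, dir = dir)
}
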