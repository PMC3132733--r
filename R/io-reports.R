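#' Write the pipeline's report files
#'
#' Emits (a) a per-SNP association TSV (snp, chr, position, role, p,
#' minor allele, MAF, OR and its 95% CI — OR and CI to 4 significant
#' digits), (b) a per-gene TSV (gene, best SNP, p_min, r, set-membership
#' and leading-edge flags), (c) a per-set TSV (set, N_S, ES, NES, nominal
#' p, K, seed; a permutation p of 0 is written as e.g. `<0.001` at
#' K = 1000), and (d) a plain-text run log echoing the configuration and
#' QC tallies.
#'
#' @param outDir output directory (created if needed).
#' @param scan per-SNP `DataFrame` from [associationScan()].
#' @param enrichment per-set `DataFrame` from [runPathwayAnalysis()]
#'   (carries the per-set results and the observed ranking in its
#'   metadata), or `NULL`.
#' @param qcReport a [QcReport], or `NULL`.
#' @param snpInfo optional `DataFrame`/data.frame with rownames = SNP id
#'   and any of `chr`, `pos`, `role` to decorate the per-SNP table.
#' @param config optional named list echoed into the run log.
#' @return Invisibly, a named vector of the written paths.
#' @export
writeReports <- function(outDir, scan, enrichment = NULL, qcReport = NULL,
                         snpInfo = NULL, config = list()) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(outDir)) stop("cannot create directory: ", outDir)
    paths <- c(snp = file.path(outDir, "snp_association.tsv"),
               gene = file.path(outDir, "gene_statistics.tsv"),
               set = file.path(outDir, "set_enrichment.tsv"),
               log = file.path(outDir, "run_log.txt"))

    # (a) per-SNP table
    lookup <- function(col) {
        if (!is.null(snpInfo) && col %in% colnames(snpInfo))
            as.vector(snpInfo[match(scan$snp, rownames(snpInfo)), col])
        else rep(NA, nrow(scan))
    }
    snpTab <- data.frame(
        snp = scan$snp,
        chr = lookup("chr"),
        position = lookup("pos"),
        role = lookup("role"),
        p = signif(scan$p, 4L),
        minor_allele = lookup("alleleMinor"),
        maf = signif(scan$maf, 3L),
        OR = signif(scan$oddsRatio, 4L),
        ci_low = signif(scan$ciLow, 4L),
        ci_high = signif(scan$ciHigh, 4L),
        flagged = scan$flagged,
        flag_reason = scan$flagReason)
    utils::write.table(snpTab, paths["snp"], sep = "\t", quote = FALSE,
                       row.names = FALSE)

    written <- paths[c("snp", "log")]

    # (b) per-gene table
    if (!is.null(enrichment)) {
        md <- S4Vectors::metadata(enrichment)
        ranked <- md$ranked
        results <- md$results
        gs <- as.data.frame(geneRanking(ranked))
        # a gene counts as in-set / leading-edge when any tested set says so
        allMembers <- unique(unlist(md$geneSets))
        allLeading <- unique(unlist(lapply(results, function(r)
            r@leadingEdge)))
        geneTab <- data.frame(
            gene = gs$geneId, best_snp = gs$bestSnp,
            p_min = signif(gs$pMin, 4L), r = signif(gs$r, 4L),
            rank = seq_len(nrow(gs)),
            in_set = gs$geneId %in% allMembers,
            leading_edge = gs$geneId %in% allLeading)
        utils::write.table(geneTab, paths["gene"], sep = "\t",
                           quote = FALSE, row.names = FALSE)

        # (c) per-set table
        setTab <- data.frame(
            set = enrichment$set, n_s = enrichment$nS,
            es = signif(enrichment$es, 4L),
            nes = signif(enrichment$nes, 4L),
            nominal_p = vapply(seq_len(nrow(enrichment)), function(i)
                formatPermP(enrichment$nominalP[i], enrichment$k[i]),
                character(1)),
            k = enrichment$k, seed = enrichment$seed,
            leading_edge = vapply(results, function(r)
                paste(r@leadingEdge, collapse = ","), character(1)))
        utils::write.table(setTab, paths["set"], sep = "\t",
                           quote = FALSE, row.names = FALSE)
        written <- c(written, paths[c("gene", "set")])
    }

    # (d) run log
    logLines <- c(
        paste("pathwayGWAS run log -", format(Sys.time())),
        "",
        "configuration:",
        if (length(config))
            paste0("  ", names(config), " = ",
                   vapply(config, function(x)
                       paste(format(x), collapse = ","), character(1)))
        else "  (none given)",
        "")
    if (!is.null(qcReport))
        logLines <- c(logLines,
            "quality control:",
            sprintf("  SNPs in: %d", qcReport@nInput),
            sprintf("  fail call rate: %d", qcReport@nFailCallRate),
            sprintf("  fail HWE: %d", qcReport@nFailHwe),
            sprintf("  fail MAF: %d", qcReport@nFailMaf),
            sprintf("  retained: %d", qcReport@nPass))
    writeLines(logLines, paths["log"])
    invisible(written)
}
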