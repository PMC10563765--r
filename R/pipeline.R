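#' Run the full synthetic study end-to-end
#'
#' Orchestrates every stage on generated data: genome and fragment
#' simulation, QC gating, RNA normalization (expression filter, TMM,
#' residual-PCA covariates), RNA differential expression under the
#' contrast families, ATAC window filtering, loess offsets, residual-PCA
#' correction, window-level differential accessibility with region
#' merging and Simes combination, peak classification, motif deviation
#' z-scores and enrichment, and peak-gene linkage with regulation scores.
#' Later stages depend on earlier ones; a failing stage halts its
#' dependents with a clear message.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @param outdir Optional directory; when given, the main tables are
#'   written as TSV with a provenance header (package version, seed,
#'   config hash).
#' @param n_qc_good,n_qc_bad Number of good/bad fragment libraries to
#'   simulate for the QC stage.
#' @param quiet Suppress progress messages.
#' @return A run-report list: \code{qc} (per-library report), \code{rna}
#'   (tests per family, covariate count), \code{atac} (region results,
#'   covariate count), \code{classes} (peak-class table), \code{motifs}
#'   (deviations, enrichment), \code{linkage} (links, dorc, regulation
#'   scores), \code{truth}, \code{sim}, and \code{timings}.
#' @export
runPipeline <- function(config, outdir = NULL, n_qc_good = 3L,
                        n_qc_bad = 1L, quiet = FALSE) {
    validateSimulationConfig(config)
    say <- function(...) if (!quiet) message(...)
    tic <- function() proc.time()[["elapsed"]]
    timings <- c()
    t0 <- tic()

    say("simulate: genome, fragments, counts, motifs")
    genome <- simulateGenome(config)
    sim <- simulateCounts(genome, config)
    genome <- sim$genome
    mot <- simulateMotifs(genome, config, sim$truth)
    truth <- mot$truth
    frag <- list()
    for (i in seq_len(n_qc_good))
        frag[[paste0("good_", i)]] <-
            simulateFragments(genome, config, "good",
                              seed = config$seed + 100L + i)
    for (i in seq_len(n_qc_bad))
        frag[[paste0("bad_", i)]] <-
            simulateFragments(genome, config, "bad",
                              seed = config$seed + 200L + i)
    timings["simulate"] <- tic() - t0

    say("qc: insert-size, TSS enrichment, FRiP, gate")
    t0 <- tic()
    rna_counts <- assay(sim$rna, "counts")
    f0 <- tmmFactors(rna_counts)
    cpm0 <- sweep(rna_counts, 2, colSums(rna_counts) * f0, "/") * 1e6
    expressed <- rownames(rna_counts)[rowMeans(cpm0) > 10]
    npk <- c(rep(config$n_peaks_called_good, n_qc_good),
             rep(config$n_peaks_called_bad, n_qc_bad))
    qc <- atacQC(frag, genome, expressed, npk)
    timings["qc"] <- tic() - t0

    say("rna: filter, TMM, residual-PCA covariates, contrasts")
    t0 <- tic()
    rna_f <- filterExpressed(rna_counts)
    fac <- tmmFactors(rna_f)
    lg <- cpmLog(rna_f, fac)
    grp <- factor(paste0("stage", colData(sim$rna)$stage, ".",
                         colData(sim$rna)$somite))
    cov_rna <- residualPcaCovariates(lg, grp, seed = config$seed + 11L)
    fit_rna <- fitNbGlm(rna_f, grp, covariates = cov_rna$covariates)
    fams <- buildContrasts(config$stages, config$somites)
    res_rna <- testContrasts(fit_rna, fams)
    de_genes <- unique(unlist(lapply(res_rna, function(r)
        r$feature[r$call])))
    timings["rna"] <- tic() - t0

    say("atac: window filter, loess offsets, covariates, DA regions")
    t0 <- tic()
    atac_f <- filterWindows(sim$atac, peakSet(genome), min_mean = 4)
    if (nrow(atac_f) < 100L)
        stop("atac stage failed: too few windows after filtering; ",
             "dependent stages halted")
    wc <- assay(atac_f, "counts")
    off <- loessOffsets(wc)
    lw <- offsetCorrectedLog(wc, off)
    cov_atac <- residualPcaCovariates(lw, grp, seed = config$seed + 12L)
    fit_atac <- fitNbGlm(wc, grp, covariates = cov_atac$covariates,
                         offsets = off)
    res_atac <- testContrasts(fit_atac, fams)
    wgr <- SummarizedExperiment::rowRanges(atac_f)
    merged <- mergeWindows(wgr)
    regions <- lapply(res_atac, combineRegions, merged = merged)
    timings["atac"] <- tic() - t0

    say("classify + motifs")
    t0 <- tic()
    classes <- classifyPeaks(peakSet(genome), genome)
    pk_counts <- assay(sim$atacPeaks, "counts")
    bg <- matchBackground(peakSet(genome), n_iter = 50L,
                          bins = max(2L, min(10L,
                              floor(sqrt(length(peakSet(genome)) / 30)))),
                          seed = config$seed + 21L)
    devs <- deviationZScores(pk_counts, mot$motifs, bg)
    da_pk <- unique(unlist(lapply(names(regions), function(nm) {
        reg <- regions[[nm]]
        hit <- reg$region[reg$call]
        if (length(hit) == 0L) return(character())
        ov <- findOverlaps(merged$regions[hit], peakSet(genome))
        names(peakSet(genome))[subjectHits(ov)]
    })))
    enr <- NULL
    if (length(da_pk) >= 10L) {
        fg <- match(da_pk, names(peakSet(genome)))
        enr <- motifEnrichment(fg,
                               setdiff(seq_along(peakSet(genome)), fg),
                               mot$motifs,
                               widths = width(peakSet(genome)),
                               seed = config$seed + 22L)
    }
    timings["motifs"] <- tic() - t0

    say("linkage: peak-gene links, DORC scores, regulation scores")
    t0 <- tic()
    expr_c <- removeCovariateEffects(lg, cov_rna$covariates)
    accp <- cpmLog(pk_counts, tmmFactors(pk_counts))
    accp_c <- removeCovariateEffects(accp, cov_atac$covariates)
    link_genes <- union(de_genes, truth$dorc_genes)
    link_genes <- intersect(link_genes, rownames(expr_c))
    links <- linkPeaksToGenes(expr_c, accp_c, peakSet(genome), genome,
                              genes = link_genes,
                              seed = config$seed + 31L)
    dorc <- dorcScores(links, accp_c)
    regs <- NULL
    if (!is.null(truth$tfs) && any(dorc$flagged)) {
        tf_in <- intersect(truth$tfs$tf_gene, rownames(expr_c))
        if (length(tf_in) > 0L) {
            tfm <- stats::setNames(truth$tfs$motif, truth$tfs$tf_gene)
            regs <- regulationScores(dorc, expr_c[tf_in, , drop = FALSE],
                                     mot$motifs, tfm[tf_in], links,
                                     peakSet(genome),
                                     seed = config$seed + 32L)
        }
    }
    timings["linkage"] <- tic() - t0

    report <- list(qc = qc, genome = genome, sim = sim, motifs = list(
                       matrix = mot$motifs, deviations = devs,
                       enrichment = enr),
                   rna = list(tests = res_rna,
                              n_covariates = cov_rna$n_selected,
                              de_genes = de_genes, logcpm = lg,
                              corrected = expr_c, factors = fac),
                   atac = list(tests = res_atac, regions = regions,
                               merged = merged,
                               n_covariates = cov_atac$n_selected,
                               offsets = off, corrected = lw,
                               peak_acc = accp_c),
                   classes = table(classes),
                   linkage = list(links = links, dorc = dorc,
                                  regulation = regs),
                   truth = truth, timings = timings,
                   seed = config$seed)
    if (!is.null(outdir)) writeRunReport(report, outdir, config)
    report
}

#' Null check between matched groups
#'
#' Runs the differential stage between two groups expected to be
#' molecularly identical (the left/right somite design check) and reports
#' the number of FDR-significant features.
#'
#' @param counts Feature x sample count matrix.
#' @param labels Two-level factor splitting the samples.
#' @param fdr FDR level.
#' @return List: \code{n_significant}, \code{fraction}, \code{table}.
#' @export
nullGroupCheck <- function(counts, labels, fdr = 0.05) {
    labels <- factor(labels)
    if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
    if (any(table(labels) < 2L))
        stop("single sample per group: no replication")
    if (diff(table(labels)) != 0)
        warning("unbalanced pairing between the groups")
    fit <- fitNbGlm(counts, labels)
    W <- matrix(c(1, -1), 2, 1,
                dimnames = list(levels(labels), "null"))
    res <- testContrasts(fit, list(null = list(name = "null",
                                               weights = W,
                                               joint = FALSE)),
                         fdr = fdr)[[1]]
    list(n_significant = sum(res$FDR < fdr),
         fraction = mean(res$FDR < fdr), table = res)
}

#' Stage-ordering sanity check on a marker panel
#'
#' PCA of the panel's expression; reports the Spearman rank correlation
#' between the first principal component and the stage labels. A
#' stage-graded panel (monotone activation, Hox-like) should give
#' |rho| > 0.9.
#'
#' @param panel_expr Log-expression matrix (panel genes x samples).
#' @param stages Numeric stage label per sample.
#' @return List: \code{rho} (signed), \code{pc1} (scores).
#' @export
orderingCheck <- function(panel_expr, stages) {
    if (nrow(panel_expr) < 2L) stop("panel too small")
    if (all(apply(panel_expr, 1, stats::sd) == 0))
        stop("constant panel: PCA undefined")
    pc <- stats::prcomp(t(panel_expr), center = TRUE)
    s <- pc$x[, 1]
    rho <- suppressWarnings(stats::cor(s, as.numeric(stages),
                                       method = "spearman"))
    list(rho = rho, pc1 = s)
}
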