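test_that("contrast families carry the printed averaging weights", {
    stages <- c(8, 18, 21, 25, 27, 35)
    somites <- c("SI", "SII", "SIII")
    fam <- buildContrasts(stages, somites)
    w13 <- fam[["somite_SI.vs.SIII"]]$weights[, 1]
    expect_equal(unname(w13[paste0("stage", stages, ".SI")]),
                 rep(1 / 6, 6))
    expect_equal(unname(w13[paste0("stage", stages, ".SIII")]),
                 rep(-1 / 6, 6))
    expect_equal(sum(w13), 0)
    sv <- fam[["stage.average"]]$weights[, "stage_8.vs.35"]
    expect_equal(unname(sv[paste0("stage8.", somites)]), rep(1 / 3, 3))
    expect_equal(unname(sv[paste0("stage35.", somites)]), rep(-1 / 3, 3))
    # every emitted contrast sums to zero
    allw <- do.call(cbind, lapply(fam, function(f) f$weights))
    expect_true(all(abs(colSums(allw)) < 1e-12))
    # family structure: 3 somite averages + 6 per-stage joints +
    # 1 stage average + 3 per-somite joints
    expect_equal(length(fam), 13L)
    expect_equal(ncol(fam[["somite.stage_8"]]$weights), 3L)
    expect_equal(ncol(fam[["stage.average"]]$weights), 15L)
    expect_error(buildContrasts(numeric(), somites), "at least one")
})

test_that("Simes combination matches the formula and its bounds", {
    expect_equal(simesP(c(0.01, 0.03, 0.04)), 0.03)
    expect_equal(simesP(0.2), 0.2)
    expect_equal(simesP(rep(1, 5)), 1)
    # brute-force oracle over random vectors
    withr::with_seed(11, {
        for (i in 1:50) {
            p <- runif(sample(1:8, 1))
            ps <- sort(p)
            brute <- min(vapply(seq_along(ps), function(i)
                length(ps) * ps[i] / i, numeric(1)))
            expect_equal(simesP(p), brute, tolerance = 1e-12)
            expect_gte(simesP(p), min(p))
            expect_lte(simesP(p), min(1, length(p) * min(p)))
        }
    })
})

test_that("a joint family of one contrast equals the single test", {
    cfg <- nullCohortConfig(seed = 41, n_genes = 300)
    sim <- simulateCounts(simulateGenome(cfg), cfg)
    cn <- filterExpressed(SummarizedExperiment::assay(sim$rna))
    grp <- groupsOf(sim$rna)
    fit <- fitNbGlm(cn, grp)
    W <- matrix(0, nlevels(grp), 1,
                dimnames = list(levels(grp), "c1"))
    W[1, 1] <- 1; W[2, 1] <- -1
    single <- list(f = list(name = "f", weights = W, joint = FALSE))
    joint <- list(f = list(name = "f", weights = W, joint = TRUE))
    r1 <- testContrasts(fit, single)[[1]]
    r2 <- testContrasts(fit, joint)[[1]]
    expect_equal(r1$PValue, r2$PValue, tolerance = 1e-8)
    expect_equal(r1$logFC, r2$logFC, tolerance = 1e-8)
})

test_that("null cohorts give calibrated p-values and no-call FC gates", {
    cfg <- nullCohortConfig(seed = 42, n_genes = 2500)
    sim <- simulateCounts(simulateGenome(cfg), cfg)
    cn <- filterExpressed(SummarizedExperiment::assay(sim$rna))
    fit <- fitNbGlm(cn, groupsOf(sim$rna))
    fam <- buildContrasts(cfg$stages, cfg$somites)
    res <- testContrasts(fit, fam)
    p <- res[["somite_SI.vs.SIII"]]$PValue
    expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
    expect_gt(mean(p < 0.05), 0.03)
    expect_lt(mean(p < 0.05), 0.07)
    expect_equal(sum(res[["somite_SI.vs.SIII"]]$call), 0L)
})

test_that("planted effects are recovered; small folds fail the gate", {
    cfg <- simulationConfig(seed = 43, stages = c(8, 18),
        somites = c("SI", "SII", "SIII"), replicates = 4,
        batch_sd = 0, trend_amplitude = 0, de_fraction = 0.2,
        de_lfc = 1, n_genes = 1200,
        chrom_lengths = c(chr1 = 3e7, chr2 = 3e7),
        n_dorc_genes = 0, n_tfs = 0)
    sim <- simulateCounts(simulateGenome(cfg), cfg)
    cn <- filterExpressed(SummarizedExperiment::assay(sim$rna))
    fit <- fitNbGlm(cn, groupsOf(sim$rna))
    fam <- buildContrasts(cfg$stages, cfg$somites)
    res <- testContrasts(fit, fam)[["somite_SI.vs.SIII"]]
    tr <- sim$truth$de_genes
    som <- tr[tr$axis == "somite" & tr$gene %in% res$feature, ]
    est <- res$logFC[match(som$gene, res$feature)]
    # SIII - SI gradient: estimated contrast is SI - SIII
    expect_lt(abs(mean(-est - som$lfc)), 0.1)
    expect_gt(mean(res$call[match(som$gene, res$feature)]), 0.8)
    # a planted |FC| = 1.3 never passes the 1.5-fold gate
    small <- res$FDR < 1e-4 & abs(res$logFC) < log2(1.4)
    expect_true(all(!res$call[small]))
    # calls are invariant under sample reordering
    perm <- withr::with_seed(1, sample(ncol(cn)))
    fitp <- fitNbGlm(cn[, perm], groupsOf(sim$rna)[perm])
    resp <- testContrasts(fitp, fam)[["somite_SI.vs.SIII"]]
    expect_equal(resp$call, res$call)
})

test_that("region combination picks the min-p member and drops empties", {
    wr <- data.frame(PValue = c(0.01, 0.03, 0.04, 0.2, 1),
                     logFC = c(2, -3, 1, 0.5, 0.1))
    win <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(1, 51, 101, 5001, 9001), width = 150))
    merged <- mergeWindows(win)
    out <- combineRegions(wr, merged)
    expect_equal(nrow(out), 3L)
    expect_equal(out$PValue[1], 0.03)   # Simes of {.01,.03,.04}
    expect_equal(out$logFC[1], 2)       # member with smallest p
    expect_equal(out$PValue[2], 0.2)    # single-member identity
    expect_equal(out$PValue[3], 1)
    # a region with no tested members is dropped with a warning
    merged2 <- merged
    merged2$map <- merged$map[merged$map$region != 2, ]
    expect_warning(out2 <- combineRegions(wr, merged2), "dropped")
    expect_equal(nrow(out2), 2L)
})
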