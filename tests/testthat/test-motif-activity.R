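test_that("deviations match a brute-force oracle on a tiny instance", {
    withr::with_seed(8, {
        X <- matrix(rpois(30, 40), 10, 3)
        M <- matrix(rbinom(20, 1, 0.4), 10, 2)
        bg <- matrix(sample.int(10, 10 * 4, replace = TRUE), 10, 4)
    })
    M[, 1][1] <- 1L   # ensure both motifs have members
    M[, 2][2] <- 1L
    dv <- deviationZScores(X, M, bg)
    # independent hand computation, scalar loops throughout
    for (m in 1:2) {
        S <- which(M[, m] == 1)
        for (j in 1:3) {
            o <- sum(X[S, j])
            e <- sum(rowSums(X)[S]) / sum(X) * sum(X[, j])
            raw <- (o - e) / e
            expect_equal(dv$raw[m, j], raw, tolerance = 1e-10)
            devs <- numeric(4)
            for (b in 1:4) {
                Sb <- bg[S, b]
                ob <- sum(X[Sb, j])
                eb <- sum(rowSums(X)[Sb]) / sum(X) * sum(X[, j])
                devs[b] <- (ob - eb) / eb
            }
            expect_equal(dv$corrected[m, j], raw - mean(devs),
                         tolerance = 1e-10)
            expect_equal(dv$z[m, j], (raw - mean(devs)) / sd(devs),
                         tolerance = 1e-10)
        }
    }
})

test_that("saturated motifs and empty motifs degenerate correctly", {
    withr::with_seed(9, X <- matrix(rpois(40, 30), 10, 4))
    M <- cbind(all = rep(1L, 10), none = rep(0L, 10))
    bg <- matrix(rep(1:10, 3), 10, 3)
    expect_warning(dv <- deviationZScores(X, M, bg), "no member peaks")
    expect_true(all(abs(dv$raw["all", ]) < 1e-12))
    expect_true(all(is.na(dv$raw["none", ])))
    # z undefined (sd 0 under identity backgrounds) is missing, not 0
    expect_true(all(is.na(dv$z["all", ])))
})

test_that("deviations cancel per-sample depth factors", {
    withr::with_seed(10, {
        X <- matrix(rnbinom(200 * 6, mu = 50, size = 10), 200, 6)
        M <- matrix(rbinom(200 * 5, 1, 0.2), 200, 5)
        bg <- matrix(sample.int(200, 200 * 10, replace = TRUE), 200, 10)
    })
    d1 <- deviationZScores(X, M, bg)
    X2 <- X; X2[, 3] <- X2[, 3] * 7L
    d2 <- deviationZScores(X2, M, bg)
    # the expected-fraction model absorbs the 7x depth shift: deviations
    # are unchanged up to the small reweighting of the peak fractions
    expect_lt(max(abs(d1$raw - d2$raw)), 0.05)
    expect_lt(max(abs(d1$corrected - d2$corrected)), 0.05)
})

test_that("background matching respects bins and degenerate cases", {
    df <- data.frame(gc = c(rep(0.2, 30), rep(0.8, 30)),
                     meanAcc = c(rep(1, 30), rep(9, 30)))
    bg <- matchBackground(df, n_iter = 20, bins = 2, seed = 3)
    # two well-separated clusters: no cross-cluster assignments
    expect_true(all(bg[1:30, ] <= 30))
    expect_true(all(bg[31:60, ] >= 31))
    # a bin of size one: the peak is its own background
    df1 <- data.frame(gc = c(0.1, 0.9), meanAcc = c(1, 9))
    bg1 <- matchBackground(df1, n_iter = 5, bins = 2, seed = 1)
    expect_true(all(bg1[1, ] == 1))
    expect_true(all(bg1[2, ] == 2))
    # uniform attributes: draws roughly uniform over all peaks
    dfu <- data.frame(gc = runif(50, .49, .51),
                      meanAcc = runif(50, 4.9, 5.1))
    bgu <- matchBackground(dfu, n_iter = 400, bins = 1, seed = 2)
    tab <- tabulate(as.vector(bgu), 50)
    expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("permuted-motif null z-scores are calibrated", {
    cfg <- simulationConfig(seed = 31, stages = 8,
        somites = c("SI", "SII", "SIII"), replicates = 8, batch_sd = 0,
        trend_amplitude = 0, de_fraction = 0, da_fraction = 0,
        n_genes = 500, chrom_lengths = c(chr1 = 4e7, chr2 = 4e7),
        n_dorc_genes = 0, n_tfs = 0)
    sim <- simulateCounts(simulateGenome(cfg), cfg)
    pk <- peakSet(sim$genome)
    X <- SummarizedExperiment::assay(sim$atacPeaks)
    withr::with_seed(7,
        M <- matrix(rbinom(length(pk) * 40, 1, 0.15), length(pk), 40))
    rownames(M) <- names(pk); colnames(M) <- sprintf("m%02d", 1:40)
    bg <- matchBackground(pk, n_iter = 50, bins = 5, seed = 7)
    z <- deviationZScores(X, M, bg)$z
    z <- z[!is.na(z)]
    expect_lt(abs(mean(z)), 0.1)
    expect_gt(sd(z), 0.8)
    expect_lt(sd(z), 1.2)
})

test_that("a group-shifted motif raises group z-scores", {
    hits <- vapply(1:6, function(s) {
        withr::with_seed(s, {
            X <- matrix(rnbinom(400 * 12, mu = 60, size = 8), 400, 12)
            M <- matrix(rbinom(400 * 10, 1, 0.15), 400, 10)
            up <- which(M[, 1] == 1)
            X[up, 7:12] <- X[up, 7:12] +
                matrix(rpois(length(up) * 6, 30), length(up))
            bg <- matrix(sample.int(400, 400 * 30, replace = TRUE),
                         400, 30)
        })
        z <- deviationZScores(X, M, bg)$z
        mean(z[1, 7:12]) > mean(z[1, 1:6])
    }, logical(1))
    expect_gte(sum(hits), 6L)
})

test_that("Fisher enrichment detects a 22% vs 12% motif contrast", {
    withr::with_seed(12, {
        M <- cbind(msgn1_like = c(rbinom(2000, 1, 0.22),
                                  rbinom(2000, 1, 0.12)),
                   flat = rbinom(4000, 1, 0.2))
    })
    rownames(M) <- paste0("p", 1:4000)
    enr <- motifEnrichment(1:2000, 2001:4000, M)
    expect_lt(enr$FDR[enr$motif == "msgn1_like"], 0.05)
    expect_gt(enr$PValue[enr$motif == "flat"], 0.05)
    expect_lt(abs(enr$odds_ratio[enr$motif == "flat"] - 1), 0.35)
    expect_error(motifEnrichment(1:5, 6:100, M), "smaller than 10")
    expect_error(motifEnrichment(1:20, 10:100, M), "disjoint")
})

test_that("identical membership patterns give odds ratios of one", {
    withr::with_seed(13, base <- rbinom(300, 1, 0.3))
    M <- cbind(m1 = c(base, base))
    rownames(M) <- paste0("p", 1:600)
    enr <- motifEnrichment(1:300, 301:600, M)
    expect_equal(enr$odds_ratio, 1, tolerance = 1e-12)
})

test_that("length matching equalises the background width profile", {
    withr::with_seed(14, {
        wfg <- runif(200, 200, 400)
        wbg <- runif(3000, 200, 2000)
        M <- cbind(m = rbinom(3200, 1, 0.2))
    })
    rownames(M) <- paste0("p", 1:3200)
    widths <- c(wfg, wbg)
    enr <- motifEnrichment(1:200, 201:3200, M, widths = widths,
                           seed = 4)
    expect_true(is.finite(enr$PValue))
})

test_that("overlap pruning keeps the most abundant window per run", {
    win <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(1, 51, 101, 1001), width = 150))
    cnt <- matrix(c(5, 50, 7, 3), 4, 2)
    ws <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = cnt), rowRanges = win)
    out <- dropOverlappingWindows(ws)
    expect_equal(nrow(out), 2L)
    expect_equal(GenomicRanges::start(
        SummarizedExperiment::rowRanges(out)), c(51, 1001))
})
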