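# One moderate linked cohort shared across the linkage tests.
linkedCohort <- local({
    cache <- NULL
    function() {
        if (!is.null(cache)) return(cache)
        cfg <- simulationConfig(seed = 21, stages = 8,
            somites = c("SI", "SII", "SIII"), replicates = 8,
            batch_sd = 0, trend_amplitude = 0.3, n_genes = 600,
            chrom_lengths = c(chr1 = 5e7, chr2 = 5e7),
            n_dorc_genes = 6, n_tfs = 4, de_fraction = 0.05)
        sim <- simulateCounts(simulateGenome(cfg), cfg)
        mot <- simulateMotifs(sim$genome, cfg, sim$truth)
        pk <- peakSet(sim$genome)
        expr <- cpmLog(filterExpressed(
            SummarizedExperiment::assay(sim$rna)))
        acc <- cpmLog(SummarizedExperiment::assay(sim$atacPeaks))
        rownames(acc) <- names(pk)
        links <- linkPeaksToGenes(expr, acc, pk, sim$genome,
            genes = mot$truth$dorc_genes, seed = 5)
        cache <<- list(cfg = cfg, sim = sim, mot = mot, pk = pk,
                       expr = expr, acc = acc, links = links,
                       truth = mot$truth)
        cache
    }
})

test_that("planted links are recovered at the p<0.05 & rho>0.3 gate", {
    co <- linkedCohort()
    links <- co$links
    key <- paste(links$gene, links$peak)
    tkey <- paste(co$truth$links$gene, co$truth$links$peak)
    expect_gte(mean(key[links$kept] %in% tkey), 0.9)   # precision
    expect_gte(mean(tkey %in% key[links$kept]), 0.9)   # sensitivity
    expect_true(all(links$kept == (!is.na(links$PValue) &
        links$PValue < 0.05 & links$rho > 0.3)))
    expect_true(all(links$distance <= 1e5))
})

test_that("thin background bins null the p-value (<50 distinct guard)", {
    co <- linkedCohort()
    # force tiny bins: with 10x10 equal-frequency bins on ~750 peaks each
    # bin holds ~7 peaks, far below 50 distinct
    links <- linkPeaksToGenes(co$expr, co$acc, co$pk, co$sim$genome,
        genes = co$truth$dorc_genes, bins = 10, seed = 5)
    expect_true(all(is.na(links$PValue)))
    expect_true(all(!links$kept))
})

test_that("linkage input contracts are enforced", {
    co <- linkedCohort()
    acc2 <- co$acc
    colnames(acc2)[1] <- "other"
    expect_error(linkPeaksToGenes(co$expr, acc2, co$pk, co$sim$genome),
                 "paired one-to-one")
    expect_error(linkPeaksToGenes(co$expr[, 1:5], co$acc[, 1:5], co$pk,
                                  co$sim$genome), "fewer than 8")
    # a gene with no peak within 100 kb yields zero rows, no error
    far <- names(geneBodies(co$sim$genome))[1]
    tssp <- GenomicRanges::start(tssSites(co$sim$genome)[far])
    chr <- as.character(GenomicRanges::seqnames(
        tssSites(co$sim$genome)[far]))
    mid <- (GenomicRanges::start(co$pk) + GenomicRanges::end(co$pk)) / 2
    near <- sum(as.character(GenomicRanges::seqnames(co$pk)) == chr &
                abs(mid - tssp) <= 1e5)
    if (near == 0) {
        out <- linkPeaksToGenes(co$expr, co$acc, co$pk, co$sim$genome,
                                genes = far, seed = 1)
        expect_equal(nrow(out), 0L)
    } else succeed()
})

test_that("DORC scores aggregate kept peaks with the strict >5 flag", {
    co <- linkedCohort()
    dorc <- dorcScores(co$links, co$acc)
    expect_true(all(dorc$flagged == (dorc$n_linked > 5L)))
    g <- names(dorc$n_linked)[1]
    pk <- co$links$peak[co$links$kept & co$links$gene == g]
    expect_equal(dorc$scores[g, ],
                 colSums(co$acc[pk, , drop = FALSE]))
    # additivity: dropping one peak removes exactly its contribution
    links2 <- co$links
    drop <- which(links2$kept & links2$gene == g)[1]
    links2$kept[drop] <- FALSE
    dorc2 <- dorcScores(links2, co$acc)
    expect_equal(dorc$scores[g, ] - dorc2$scores[g, ],
                 co$acc[links2$peak[drop], ])
    # boundary: exactly 5 and 6 kept peaks
    l5 <- co$links[co$links$kept & co$links$gene == g, ][1:5, ]
    l6 <- co$links[co$links$kept & co$links$gene == g, ][1:6, ]
    expect_false(dorcScores(l5, co$acc)$flagged[[g]])
    expect_true(dorcScores(l6, co$acc)$flagged[[g]])
})

test_that("regulation scores recover planted signs and antisymmetry", {
    co <- linkedCohort()
    truth <- co$truth
    dorc <- dorcScores(co$links, co$acc)
    tfe <- co$expr[truth$tfs$tf_gene, , drop = FALSE]
    tfm <- stats::setNames(truth$tfs$motif, truth$tfs$tf_gene)
    regs <- regulationScores(dorc, tfe, co$mot$motifs, tfm, co$links,
                             co$pk, seed = 6)
    tl <- rep_len(seq_len(nrow(truth$tfs)), length(truth$dorc_genes))
    planted <- paste(truth$tfs$tf_gene[tl], truth$dorc_genes)
    rk <- paste(regs$tf, regs$gene)
    pl <- regs[rk %in% planted, ]
    want <- truth$tfs$sign[match(pl$tf, truth$tfs$tf_gene)]
    expect_gte(mean(sign(pl$score) == want), 0.9)
    expect_gte(mean(pl$flag), 0.8)
    expect_true(all(regs$flag == (abs(regs$score) > 1.25)))
    # negating a TF's expression flips its score signs only
    regsN <- regulationScores(dorc, -tfe, co$mot$motifs, tfm, co$links,
                              co$pk, seed = 6)
    expect_equal(regsN$score, -regs$score, tolerance = 1e-10)
    # a TF without a motif is skipped with a message
    expect_message(regulationScores(dorc, tfe, co$mot$motifs,
                                    tfm[-1], co$links, co$pk, seed = 6),
                   "without motif")
})
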