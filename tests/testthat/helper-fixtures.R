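# Shared fixtures, all built in code.

# A tiny hand-made genome: one 1 Mb chromosome, two genes on opposite
# strands, three exons each, a few disjoint peaks, one blacklist interval.
tinyGenome <- function() {
    genes <- GenomicRanges::GRanges(
        "chr1",
        IRanges::IRanges(c(100000, 300000), c(110000, 312000)),
        strand = c("+", "-"))
    names(genes) <- c("gA", "gB")
    exons <- GenomicRanges::GRanges(
        "chr1",
        IRanges::IRanges(c(100000, 104000, 109800,
                           300000, 306000, 311800),
                         c(100200, 104150, 110000,
                           300200, 306150, 312000)),
        strand = rep(c("+", "-"), each = 3),
        gene_id = rep(c("gA", "gB"), each = 3))
    peaks <- GenomicRanges::GRanges(
        "chr1",
        IRanges::IRanges(c(99900, 104050, 130000, 360000, 900000),
                         width = 400))
    names(peaks) <- paste0("p", 1:5)
    bl <- GenomicRanges::GRanges("chr1", IRanges::IRanges(500000, 520000))
    GenomeModel(c(chr1 = 1e6), genes = genes, exons = exons,
                blacklist = bl, peaks = peaks)
}

# Fragments at given 1-based starts/widths on the tiny genome.
tinyFragments <- function(starts, widths, seqlen = c(chr1 = 1e6)) {
    gr <- GenomicRanges::GRanges(rep("chr1", length(starts)),
        IRanges::IRanges(starts, width = widths))
    GenomeInfoDb::seqlevels(gr) <- names(seqlen)
    GenomeInfoDb::seqlengths(gr) <- seqlen
    gr
}

# A small null cohort straight from the generator (no planted effects).
nullCohortConfig <- function(seed, n_genes = 1500, replicates = 4,
                             stages = c(8, 18)) {
    simulationConfig(seed = seed, stages = stages,
        somites = c("SI", "SII", "SIII"), replicates = replicates,
        batch_sd = 0, de_fraction = 0, da_fraction = 0,
        trend_amplitude = 0, n_genes = n_genes,
        chrom_lengths = c(chr1 = 4e7, chr2 = 4e7),
        n_dorc_genes = 0, n_tfs = 0)
}

groupsOf <- function(se) {
    cd <- SummarizedExperiment::colData(se)
    factor(paste0("stage", cd$stage, ".", cd$somite))
}
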