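#' Simulation configuration for the synthetic somite study
#'
#' Bundles every knob of the synthetic-data generator: genome geometry,
#' stage-by-somite design, negative-binomial count parameters, planted
#' differential effects, batch structure, abundance-dependent (trended)
#' efficiency bias, fragment-length mixture, TSS-insertion enrichment,
#' motif prevalence and planted peak-gene / TF-gene regulatory structure.
#' Defaults emulate the study conditions: six developmental stages (8, 18,
#' 21, 25, 27 and 35 somite pairs), the three most recent somites (I-III),
#' matched RNA/ATAC sample pairs, and collection batches partially
#' confounded with stage (early and late stages collected on disjoint
#' dates).
#'
#' @param seed Integer seed; together with the config it fully determines
#'   all generator output.
#' @param chrom_lengths Named vector of chromosome lengths (bp). Genes are
#'   laid out in the first 60\% of each chromosome; the remainder is a gene
#'   desert that guarantees intergenic peaks (> 100 kb from any gene).
#' @param n_genes Total gene count.
#' @param stages Numeric vector of developmental stages (somite counts).
#' @param somites Character vector of somite ages, youngest first.
#' @param replicates Embryos (sample pairs) per stage-by-somite group.
#' @param lib_size_range_rna,lib_size_range_atac Uniform sampling range of
#'   library sizes (fragments).
#' @param dispersion_rna,dispersion_atac NB dispersion (1/size); must be > 0.
#' @param de_fraction,de_lfc Fraction of genes with a planted expression
#'   effect and its log2 magnitude (applied as a centered gradient along the
#'   somite or stage axis; the extreme-group contrast equals \code{de_lfc}).
#' @param da_fraction,da_lfc Same for planted accessibility effects on peaks
#'   (all windows of a planted peak share the effect).
#' @param batch_sd Standard deviation of the per-gene log2 batch factor;
#'   0 disables batch effects.
#' @param n_batches Number of collection batches.
#' @param batch_scheme How batches relate to the design:
#'   \code{"stage_split"} (default, the study condition) gives early and
#'   late stages disjoint batch sets; \code{"round_robin"} cycles batches
#'   across samples (orthogonal to the design); \code{"imbalanced"}
#'   assigns batches with somite-age-dependent frequencies (partial
#'   confounding with the somite contrast).
#' @param trend_amplitude Amplitude of the smooth abundance-dependent
#'   efficiency bias in ATAC counts (log2 scale at the abundance extremes);
#'   0 disables the trend.
#' @param fragment_modes,fragment_sds Means/SDs (bp) of the truncated-normal
#'   fragment-length mixture components: sub-nucleosomal, mono-, di-, tri-
#'   and tetra-nucleosome.
#' @param fragment_weights_good,fragment_weights_bad Mixture weights for
#'   good-quality and bad-quality libraries ("bad" is sub-nucleosomal only).
#' @param frac_tss,frac_peak Fraction of good-library fragments centered
#'   near a TSS or inside a peak (the rest are uniform background); bad
#'   libraries are fully uniform.
#' @param tss_sd SD (bp) of fragment-center placement around the TSS.
#' @param n_fragments Fragments per simulated library.
#' @param n_peaks_called_good,n_peaks_called_bad Peak counts reported for
#'   simulated libraries (per-sample peak calling is outside the generator).
#' @param n_motifs Number of motifs in the peak-by-motif matrix.
#' @param motif_prevalence Background probability that a peak carries a
#'   given motif.
#' @param n_dorc_genes Genes with a planted regulatory domain.
#' @param links_per_gene Planted linked peaks per such gene (placed within
#'   \code{link_max_dist} of its TSS).
#' @param link_rho Target correlation between a linked peak's accessibility
#'   and its gene's expression across samples.
#' @param link_max_dist Maximum planted link distance (bp); capped at
#'   100,000, the linkage search window.
#' @param n_tfs Planted regulator TFs (alternating activator/repressor
#'   sign); planted target genes are split evenly among them.
#'
#' @return A validated list of class \code{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(seed = 1, n_genes = 50,
#'     chrom_lengths = c(chr1 = 4e6))
#' cfg$n_genes
#' @export
simulationConfig <- function(seed = 1L,
    chrom_lengths = c(chr1 = 10e6, chr2 = 10e6),
    n_genes = 200L,
    stages = c(8L, 18L, 21L, 25L, 27L, 35L),
    somites = c("SI", "SII", "SIII"),
    replicates = 2L,
    lib_size_range_rna = c(4e5, 12e5),
    lib_size_range_atac = c(3e5, 9e5),
    dispersion_rna = 0.05,
    dispersion_atac = 0.08,
    de_fraction = 0.1, de_lfc = 1,
    da_fraction = 0.1, da_lfc = 1.2,
    batch_sd = 0.4, n_batches = 4L,
    batch_scheme = c("stage_split", "round_robin", "imbalanced"),
    trend_amplitude = 0.3,
    fragment_modes = c(75, 200, 400, 600, 800),
    fragment_sds = c(25, 35, 45, 50, 55),
    fragment_weights_good = c(0.32, 0.30, 0.18, 0.12, 0.08),
    fragment_weights_bad = c(1, 0, 0, 0, 0),
    frac_tss = 0.15, frac_peak = 0.35, tss_sd = 50,
    n_fragments = 20000L,
    n_peaks_called_good = 20000L, n_peaks_called_bad = 8000L,
    n_motifs = 30L, motif_prevalence = 0.12,
    n_dorc_genes = 6L, links_per_gene = 8L,
    link_rho = 0.9, link_max_dist = 9e4,
    n_tfs = 4L) {
    cfg <- list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
        n_genes = as.integer(n_genes), stages = stages, somites = somites,
        replicates = as.integer(replicates),
        lib_size_range_rna = lib_size_range_rna,
        lib_size_range_atac = lib_size_range_atac,
        dispersion_rna = dispersion_rna, dispersion_atac = dispersion_atac,
        de_fraction = de_fraction, de_lfc = de_lfc,
        da_fraction = da_fraction, da_lfc = da_lfc,
        batch_sd = batch_sd, n_batches = as.integer(n_batches),
        batch_scheme = match.arg(batch_scheme),
        trend_amplitude = trend_amplitude,
        fragment_modes = fragment_modes, fragment_sds = fragment_sds,
        fragment_weights_good = fragment_weights_good,
        fragment_weights_bad = fragment_weights_bad,
        frac_tss = frac_tss, frac_peak = frac_peak, tss_sd = tss_sd,
        n_fragments = as.integer(n_fragments),
        n_peaks_called_good = as.integer(n_peaks_called_good),
        n_peaks_called_bad = as.integer(n_peaks_called_bad),
        n_motifs = as.integer(n_motifs),
        motif_prevalence = motif_prevalence,
        n_dorc_genes = as.integer(n_dorc_genes),
        links_per_gene = as.integer(links_per_gene),
        link_rho = link_rho, link_max_dist = link_max_dist,
        n_tfs = as.integer(n_tfs))
    class(cfg) <- "SimulationConfig"
    validateSimulationConfig(cfg)
    cfg
}

#' Validate a SimulationConfig
#'
#' Checks that probabilities lie in [0,1], dispersions are positive, mixture
#' weights are proper, and planted link distances respect the 100 kb
#' linkage window.
#'
#' @param cfg A \code{SimulationConfig}.
#' @return Invisibly \code{TRUE}; otherwise an error.
#' @export
validateSimulationConfig <- function(cfg) {
    stopifnot(inherits(cfg, "SimulationConfig"))
    if (is.null(names(cfg$chrom_lengths)) || any(cfg$chrom_lengths <= 0))
        stop("chrom_lengths must be a named vector of positive lengths")
    if (cfg$dispersion_rna <= 0 || cfg$dispersion_atac <= 0)
        stop("NB dispersion must be > 0")
    probs <- c(cfg$de_fraction, cfg$da_fraction, cfg$frac_tss,
               cfg$frac_peak, cfg$motif_prevalence,
               cfg$fragment_weights_good, cfg$fragment_weights_bad)
    if (any(probs < 0 | probs > 1))
        stop("all probabilities/weights must lie in [0, 1]")
    for (w in list(cfg$fragment_weights_good, cfg$fragment_weights_bad))
        if (abs(sum(w) - 1) > 1e-8)
            stop("fragment-length mixture weights must sum to 1")
    if (cfg$link_max_dist > 1e5)
        stop("planted link distance exceeds the 100 kb linkage window")
    if (abs(cfg$link_rho) > 1) stop("link_rho must lie in [-1, 1]")
    if (cfg$replicates < 1) stop("need at least one replicate per group")
    invisible(TRUE)
}

# Evaluate expr under a fixed seed without disturbing the caller's RNG.
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}
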