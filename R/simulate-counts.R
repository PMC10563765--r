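#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#'   rowRanges rowData
#' @importFrom stats rnorm runif rbeta rbinom rnbinom approx cor fisher.test
#'   loess lm.fit median p.adjust pnorm prcomp quantile sd cor.test
NULL

# Centered gradient along an axis: extreme groups differ by exactly lfc.
.gradientEffect <- function(idx, n_levels, lfc) {
    if (n_levels == 1L) return(rep(0, length(idx)))
    lfc * ((idx - 1) / (n_levels - 1) - 0.5)
}

# log2-scale latent loading that yields approximately `rho` correlation
# against NB noise at mean `mu` and dispersion `disp`.
.latentLoading <- function(rho, mu, disp) {
    s <- sqrt(1 / mu + disp) / log(2)
    s * rho / sqrt(max(1 - rho^2, 1e-6))
}

#' Simulate matched RNA and ATAC count matrices with a planted truth set
#'
#' Generates negative-binomial counts for genes (RNA) and for 150 bp
#' windows tiling the peak set (ATAC) under the stage-by-somite design of
#' the study. Planted structure comprises: differential features with a
#' centered log2 gradient along either the somite-age or the stage axis;
#' multiplicative per-gene log-normal batch factors with early- and
#' late-stage batches disjoint (the partially confounded design); a smooth
#' abundance-dependent efficiency bias in the ATAC counts; shared latent
#' factors that make planted peak-gene pairs co-vary at a target
#' correlation; and planted regulator TFs whose expression tracks (sign +1)
#' or opposes (sign -1) the accessibility of their targets' linked peaks.
#'
#' @param genome A \code{\link{GenomeModel}} from
#'   \code{\link{simulateGenome}} (its \code{link_gene} peak annotation
#'   defines the planted regulatory targets).
#' @param config A \code{\link{simulationConfig}}.
#' @param seed Seed; defaults to \code{config$seed}.
#' @return A list with elements \code{rna} (gene-level
#'   \code{RangedSummarizedExperiment}), \code{atac} (window-level, with a
#'   \code{peak} rowData column), \code{atacPeaks} (window counts summed per
#'   peak), \code{genome} (input genome with the \code{meanAcc} peak
#'   attribute filled in) and \code{truth} (planted effects: \code{de_genes},
#'   \code{da_peaks}, \code{da_windows}, \code{batch}, \code{links},
#'   \code{tfs}, \code{latents}).
#' @examples
#' cfg <- simulationConfig(seed = 1, n_genes = 60, n_dorc_genes = 2,
#'     chrom_lengths = c(chr1 = 8e6), replicates = 1)
#' sim <- simulateCounts(simulateGenome(cfg), cfg)
#' dim(SummarizedExperiment::assay(sim$rna))
#' @export
simulateCounts <- function(genome, config, seed = config$seed) {
    validateSimulationConfig(config)
    stopifnot(is(genome, "GenomeModel"))
    withSeed(seed, .simulateCounts(genome, config))
}

.simulateCounts <- function(genome, config) {
    stages <- config$stages
    somites <- config$somites
    reps <- config$replicates
    grid <- expand.grid(somite = somites, stage = stages,
                        rep = seq_len(reps), stringsAsFactors = FALSE)
    n <- nrow(grid)
    sample_ids <- sprintf("s%03d", seq_len(n))
    stage_idx <- match(grid$stage, stages)
    somite_idx <- match(grid$somite, somites)

    scheme <- if (is.null(config$batch_scheme)) "stage_split"
              else config$batch_scheme
    if (config$batch_sd <= 0 || config$n_batches < 2L) {
        batch <- rep(1L, n)
    } else if (scheme == "stage_split" && length(stages) >= 2L) {
        # the study condition: early and late stages on disjoint dates
        n_early_b <- max(1L, floor(config$n_batches / 2))
        early <- stage_idx <= ceiling(length(stages) / 2)
        batch <- integer(n)
        batch[early] <- (seq_len(sum(early)) - 1L) %% n_early_b + 1L
        batch[!early] <- (seq_len(sum(!early)) - 1L) %%
            (config$n_batches - n_early_b) + n_early_b + 1L
    } else if (scheme == "imbalanced") {
        # partial confounding: batch frequencies drift with somite age,
        # e.g. 3/4 of SI but only 1/4 of SIII on the first date
        batch <- integer(n)
        for (a in seq_along(somites)) {
            i <- which(somite_idx == a)
            frac1 <- 0.75 - 0.5 * (a - 1) / max(length(somites) - 1, 1)
            k1 <- round(frac1 * length(i))
            batch[i] <- rep(c(1L, 2L), c(k1, length(i) - k1))
        }
        if (config$n_batches > 2L) batch <- batch  # two dates suffice
    } else {
        # round robin: collection dates cut across groups
        batch <- (seq_len(n) - 1L) %% config$n_batches + 1L
    }

    genes <- geneBodies(genome)
    peaks <- peakSet(genome)
    gene_ids <- names(genes)
    G <- length(genes)

    dorc_genes <- unique(peaks$link_gene[!is.na(peaks$link_gene)])
    dorc_genes <- dorc_genes[dorc_genes %in% gene_ids]

    # TF genes: outside the planted-target set; each TF gets an even share
    # of the targets and one latent factor shared with their linked peaks
    avail <- setdiff(gene_ids, dorc_genes)
    n_tfs <- min(config$n_tfs, length(avail))
    tf_genes <- if (n_tfs > 0L)
        avail[round(seq(2, length(avail) - 1,
                        length.out = n_tfs))] else character()
    tf_sign <- rep_len(c(1, -1), n_tfs)
    tf_of_gene <- if (n_tfs > 0L && length(dorc_genes) > 0L)
        rep_len(seq_len(n_tfs), length(dorc_genes)) else integer()
    n_latent <- max(n_tfs, as.integer(length(dorc_genes) > 0))
    latents <- if (n_latent > 0L)
        matrix(rnorm(n_latent * n), n_latent, n,
               dimnames = list(NULL, sample_ids)) else
        matrix(0, 0, n)
    latent_of_gene <- if (length(dorc_genes) > 0L) {
        if (n_tfs > 0L) tf_of_gene else rep(1L, length(dorc_genes))
    } else integer()

    # planted DE genes, excluding regulator/target machinery
    de_pool <- setdiff(gene_ids, c(dorc_genes, tf_genes))
    n_de <- round(config$de_fraction * G)
    de_genes <- if (n_de > 0L) sample(de_pool, min(n_de, length(de_pool)))
                else character()
    de_axis <- rep_len(c("somite", "stage"), length(de_genes))
    de_sign <- rep_len(c(1, 1, -1, -1), length(de_genes))
    de_lfc <- de_sign * config$de_lfc

    # RNA generative means
    q <- exp(rnorm(G, log(5), 1.3))
    names(q) <- gene_ids
    mu_link <- 400
    q[dorc_genes] <- mu_link * q[dorc_genes] / q[dorc_genes] *
        exp(rnorm(length(dorc_genes), 0, 0.1))
    q[tf_genes] <- mu_link * exp(rnorm(length(tf_genes), 0, 0.1))
    eta <- matrix(0, G, n, dimnames = list(gene_ids, sample_ids))
    for (k in seq_along(de_genes)) {
        idx <- if (de_axis[k] == "somite") somite_idx else stage_idx
        nl <- if (de_axis[k] == "somite") length(somites)
              else length(stages)
        eta[de_genes[k], ] <- .gradientEffect(idx, nl, de_lfc[k])
    }
    rho <- config$link_rho
    a_gene <- .latentLoading(rho, mu_link, config$dispersion_rna)
    for (k in seq_along(dorc_genes))
        eta[dorc_genes[k], ] <- eta[dorc_genes[k], ] +
            a_gene * latents[latent_of_gene[k], ]
    for (t in seq_len(n_tfs))
        eta[tf_genes[t], ] <- eta[tf_genes[t], ] +
            tf_sign[t] * a_gene * latents[t, ]
    if (config$batch_sd > 0) {
        delta <- matrix(rnorm(G * max(batch), 0, config$batch_sd),
                        G, max(batch))
        eta <- eta + delta[, batch]
    }
    lib_rna <- round(runif(n, config$lib_size_range_rna[1],
                           config$lib_size_range_rna[2]))
    mu <- q * 2^eta
    mu <- sweep(mu, 2, colSums(mu), "/")
    mu <- sweep(mu, 2, lib_rna, "*")
    rna_counts <- matrix(rnbinom(G * n, mu = mu,
                                 size = 1 / config$dispersion_rna), G, n,
                         dimnames = list(gene_ids, sample_ids))

    # ATAC windows tiling each peak (150 bp, step 50)
    win_per_peak <- pmax((width(peaks) - 150L) %/% 50L + 1L, 1L)
    peak_of_win <- rep(seq_along(peaks), win_per_peak)
    off <- unlist(lapply(win_per_peak, function(k) seq_len(k) - 1L)) * 50L
    wstart <- start(peaks)[peak_of_win] + off
    windows <- GRanges(seqnames(peaks)[peak_of_win],
                       IRanges(wstart, wstart + 149L))
    windows$peak <- names(peaks)[peak_of_win]
    names(windows) <- sprintf("win_%06d", seq_along(windows))
    W <- length(windows)

    b_pk <- exp(rnorm(length(peaks), log(3), 0.9))
    b_pk[!is.na(peaks$link_gene)] <- mu_link / 50 *
        exp(rnorm(sum(!is.na(peaks$link_gene)), 0, 0.1))
    # tent-shaped within-peak profile
    prof <- unlist(lapply(win_per_peak, function(k) {
        x <- seq_len(k); 0.6 + 0.8 * (1 - abs(2 * (x - 1) / max(k - 1, 1) - 1))
    }))
    qw <- b_pk[peak_of_win] * prof

    da_pool <- which(is.na(peaks$link_gene))
    n_da <- round(config$da_fraction * length(peaks))
    da_pk <- if (n_da > 0L) sort(sample(da_pool, min(n_da,
                                                     length(da_pool))))
             else integer()
    da_axis <- rep_len(c("somite", "stage"), length(da_pk))
    da_sign <- rep_len(c(1, 1, -1, -1), length(da_pk))
    da_lfc <- da_sign * config$da_lfc

    etaw <- matrix(0, W, n, dimnames = list(names(windows), sample_ids))
    for (k in seq_along(da_pk)) {
        idx <- if (da_axis[k] == "somite") somite_idx else stage_idx
        nl <- if (da_axis[k] == "somite") length(somites)
              else length(stages)
        etaw[peak_of_win == da_pk[k], ] <-
            rep(1, sum(peak_of_win == da_pk[k])) %o%
            .gradientEffect(idx, nl, da_lfc[k])
    }
    link_rows <- which(!is.na(peaks$link_gene))
    a_pk <- .latentLoading(rho, mu_link / 4, config$dispersion_atac)
    for (k in link_rows) {
        lat <- latent_of_gene[match(peaks$link_gene[k], dorc_genes)]
        etaw[peak_of_win == k, ] <- etaw[peak_of_win == k, ] +
            rep(1, sum(peak_of_win == k)) %o% (a_pk * latents[lat, ])
    }
    if (config$batch_sd > 0) {
        deltaw <- matrix(rnorm(W * max(batch), 0, config$batch_sd),
                         W, max(batch))
        etaw <- etaw + deltaw[, batch]
    }
    if (config$trend_amplitude > 0) {
        amp <- config$trend_amplitude *
            (2 * (seq_len(n) - 1) / max(n - 1, 1) - 1)
        z <- as.numeric(scale(log(qw)))
        etaw <- etaw + tanh(z) %o% amp
    }
    lib_atac <- round(runif(n, config$lib_size_range_atac[1],
                            config$lib_size_range_atac[2]))
    muw <- qw * 2^etaw
    muw <- sweep(muw, 2, colSums(muw), "/")
    muw <- sweep(muw, 2, lib_atac, "*")
    atac_counts <- matrix(rnbinom(W * n, mu = muw,
                                  size = 1 / config$dispersion_atac), W, n,
                          dimnames = list(names(windows), sample_ids))

    cd <- DataFrame(sample = sample_ids, stage = factor(grid$stage,
                        levels = stages),
                    somite = factor(grid$somite, levels = somites),
                    batch = factor(batch), pair = sample_ids,
                    row.names = sample_ids)
    rna <- SummarizedExperiment(assays = list(counts = rna_counts),
                                rowRanges = genes, colData = cd)
    atac <- SummarizedExperiment(assays = list(counts = atac_counts),
                                 rowRanges = windows, colData = cd)
    pk_counts <- rowsum(atac_counts, windows$peak)
    pk_counts <- pk_counts[names(peaks), , drop = FALSE]
    atac_pk <- SummarizedExperiment(assays = list(counts = pk_counts),
                                    rowRanges = peaks, colData = cd)
    cpmpk <- sweep(pk_counts, 2, colSums(pk_counts), "/") * 1e6
    pk2 <- peaks
    pk2$meanAcc <- rowMeans(log2(cpmpk + 1))
    peakSet(genome) <- pk2
    SummarizedExperiment::rowRanges(atac_pk) <- pk2

    truth <- list(
        de_genes = data.frame(gene = de_genes, axis = de_axis,
                              lfc = de_lfc, stringsAsFactors = FALSE),
        da_peaks = data.frame(peak = names(peaks)[da_pk], axis = da_axis,
                              lfc = da_lfc, stringsAsFactors = FALSE),
        da_windows = names(windows)[peak_of_win %in% da_pk],
        batch = batch,
        links = data.frame(
            gene = peaks$link_gene[link_rows],
            peak = names(peaks)[link_rows],
            latent = latent_of_gene[match(peaks$link_gene[link_rows],
                                          dorc_genes)],
            stringsAsFactors = FALSE),
        tfs = if (n_tfs > 0L) data.frame(
            tf_gene = tf_genes, sign = tf_sign,
            latent = seq_len(n_tfs), motif = NA_character_,
            stringsAsFactors = FALSE) else NULL,
        dorc_genes = dorc_genes,
        latents = latents)
    list(rna = rna, atac = atac, atacPeaks = atac_pk, genome = genome,
         truth = truth)
}

#' Simulate a peak-by-motif match matrix with planted TF enrichment
#'
#' Each motif is present in a peak with the background prevalence; the
#' motif assigned to each planted regulator TF is additionally set in every
#' linked peak of that TF's target genes, so TF motifs are enriched in the
#' planted regulatory domains.
#'
#' @param genome A \code{\link{GenomeModel}} (defines the peak universe).
#' @param config A \code{\link{simulationConfig}}.
#' @param truth Truth list from \code{\link{simulateCounts}}; its
#'   \code{tfs$motif} column is filled in.
#' @param seed Seed; defaults to \code{config$seed + 1}.
#' @return A list with \code{motifs} (binary peaks-by-motifs matrix) and
#'   the updated \code{truth}.
#' @export
simulateMotifs <- function(genome, config, truth,
                           seed = config$seed + 1L) {
    validateSimulationConfig(config)
    peaks <- peakSet(genome)
    if (length(peaks) == 0L) stop("genome has no peaks")
    withSeed(seed, {
        M <- matrix(rbinom(length(peaks) * config$n_motifs, 1,
                           config$motif_prevalence),
                    length(peaks), config$n_motifs,
                    dimnames = list(names(peaks),
                                    sprintf("motif_%02d",
                                            seq_len(config$n_motifs))))
        if (!is.null(truth$tfs) && nrow(truth$tfs) > 0L) {
            truth$tfs$motif <- colnames(M)[seq_len(nrow(truth$tfs))]
            for (t in seq_len(nrow(truth$tfs))) {
                targets <- truth$dorc_genes[
                    rep_len(seq_len(nrow(truth$tfs)),
                            length(truth$dorc_genes)) == t]
                pks <- truth$links$peak[truth$links$gene %in% targets]
                M[pks, truth$tfs$motif[t]] <- 1L
            }
        }
        list(motifs = M, truth = truth)
    })
}
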