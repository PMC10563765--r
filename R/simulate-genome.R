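#' Simulate a genome model with structured gene and peak placement
#'
#' Lays genes along the first 60\% of each chromosome at regular spacing
#' (with jitter) and places peaks so that every genomic-context class is
#' represented: a promoter-band peak (within 200 bp of a TSS), an exonic
#' peak and a proximal peak are cycled across genes; distal (25-100 kb) and
#' intergenic (> 100 kb) peaks are placed in the gene desert occupying the
#' remainder of each chromosome. Genes selected as planted regulatory
#' targets additionally receive \code{links_per_gene} peaks within
#' \code{link_max_dist} of their TSS (recorded in the peaks'
#' \code{link_gene} column). Peaks carry a GC-fraction attribute drawn from
#' Beta(5, 5); overlapping placements are resolved by keeping planted link
#' peaks preferentially, so the final peak set is disjoint.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @param seed Seed; defaults to \code{config$seed}.
#' @return A \code{\link{GenomeModel}}.
#' @examples
#' gm <- simulateGenome(simulationConfig(seed = 1))
#' table(is.na(peakSet(gm)$link_gene))
#' @export
simulateGenome <- function(config, seed = config$seed) {
    validateSimulationConfig(config)
    withSeed(seed, .simulateGenome(config))
}

.simulateGenome <- function(config) {
    sl <- config$chrom_lengths
    nchr <- length(sl)
    n_per <- diff(round(seq(0, config$n_genes, length.out = nchr + 1)))
    gene_gr <- GRanges()
    peak_list <- list()
    bl_list <- list()
    gidx <- 0L
    for (ci in seq_len(nchr)) {
        L <- sl[ci]; chrom <- names(sl)[ci]; n_c <- n_per[ci]
        if (n_c == 0L) next
        zone <- floor(0.6 * L)
        spacing <- zone / (n_c + 1)
        if (spacing < 3000)
            stop("chromosome ", chrom, " too short for requested gene count")
        tss <- round(spacing * seq_len(n_c) +
                     runif(n_c, -0.08, 0.08) * spacing)
        strand <- sample(c("+", "-"), n_c, replace = TRUE)
        gw <- pmin(round(0.35 * spacing),
                   round(runif(n_c, 4000, 15000)))
        gw <- pmax(gw, 1500L)
        gstart <- ifelse(strand == "+", tss, tss - gw + 1L)
        gend <- ifelse(strand == "+", tss + gw - 1L, tss)
        gstart <- pmax(gstart, 1L); gend <- pmin(gend, L)
        g <- GRanges(chrom, IRanges(gstart, gend), strand = strand)
        names(g) <- sprintf("gene_%04d", gidx + seq_len(n_c))
        gene_gr <- suppressWarnings(c(gene_gr, g))

        # class-band peaks, cycling promoter -> exonic -> proximal
        cls <- (gidx + seq_len(n_c) - 1L) %% 3L
        cen <- integer(n_c); half <- integer(n_c)
        i0 <- cls == 0L          # promoter band
        cen[i0] <- tss[i0] + sample(-100:100, sum(i0), replace = TRUE)
        half[i0] <- 150L
        i1 <- cls == 1L          # over the 3' exon
        cen[i1] <- ifelse(strand[i1] == "+", gend[i1] - 300L,
                          gstart[i1] + 300L)
        half[i1] <- 200L
        i2 <- cls == 2L          # proximal to the gene body
        gap <- round(runif(sum(i2), min(2000, 0.3 * spacing),
                           min(20000, 0.4 * spacing)))
        cen[i2] <- gend[i2] + gap
        half[i2] <- 200L
        pk_start <- cen - half
        pk_end <- cen + half - 1L
        # desert peaks: distal and intergenic relative to the last gene
        last_end <- max(gend)
        n_dist <- max(2L, round(n_c / 10))
        dist_cen <- last_end + round(runif(n_dist, 30000, 90000))
        n_int <- max(2L, round(n_c / 10))
        int_lo <- last_end + 150000
        int_hi <- L - 100000
        if (int_hi > int_lo) {
            int_cen <- round(runif(n_int, int_lo, int_hi))
        } else int_cen <- integer()
        pk_start <- c(pk_start, dist_cen - 250L, int_cen - 250L)
        pk_end <- c(pk_end, dist_cen + 249L, int_cen + 249L)
        pk_start <- pmax(pk_start, 1L); pk_end <- pmin(pk_end, L)
        pk <- GRanges(chrom, IRanges(pk_start, pk_end))
        pk$link_gene <- NA_character_
        pk$priority <- 2L
        peak_list[[chrom]] <- pk
        # blacklist: one desert interval per chromosome
        bl_list[[chrom]] <- GRanges(chrom, IRanges(max(1, L - 60000),
                                                   L - 30001))
        gidx <- gidx + n_c
    }

    # planted regulatory-target genes get extra peaks within link_max_dist
    n_dorc <- min(config$n_dorc_genes, length(gene_gr))
    link_pk <- GRanges()
    if (n_dorc > 0L && config$links_per_gene > 0L) {
        pick <- round(seq(1, length(gene_gr), length.out = n_dorc))
        dorc_ids <- names(gene_gr)[pick]
        tssg <- ifelse(as.character(strand(gene_gr[pick])) == "-",
                       end(gene_gr[pick]), start(gene_gr[pick]))
        dists <- round(seq(12000, config$link_max_dist,
                           length.out = config$links_per_gene))
        for (k in seq_len(n_dorc)) {
            side <- rep_len(c(1, -1), config$links_per_gene)
            cen <- tssg[k] + side * dists
            chrom <- as.character(seqnames(gene_gr[pick[k]]))
            cen <- pmin(pmax(cen, 300), sl[chrom] - 300)
            lp <- GRanges(chrom, IRanges(cen - 200L, cen + 199L))
            lp$link_gene <- dorc_ids[k]
            lp$priority <- 1L
            link_pk <- suppressWarnings(c(link_pk, lp))
        }
    }

    peaks <- suppressWarnings(c(do.call(c, unname(peak_list)), link_pk))
    # resolve overlaps: keep link peaks preferentially, then leftmost
    o <- order(as.factor(seqnames(peaks)), peaks$priority, start(peaks))
    peaks <- peaks[o]
    keep <- rep(TRUE, length(peaks))
    hits <- GenomicRanges::findOverlaps(peaks, peaks)
    hits <- hits[S4Vectors::queryHits(hits) < S4Vectors::subjectHits(hits)]
    if (length(hits) > 0L)
        keep[unique(S4Vectors::subjectHits(hits))] <- FALSE
    peaks <- peaks[keep]
    peaks$priority <- NULL
    peaks <- GenomicRanges::sort(peaks)
    names(peaks) <- sprintf("peak_%05d", seq_along(peaks))
    peaks$gc <- rbeta(length(peaks), 5, 5)

    # exons: 5', middle and 3' exon per gene, within the body
    gs <- start(gene_gr); ge <- end(gene_gr); gwd <- width(gene_gr)
    mids <- gs + round(gwd * 0.45)
    exons <- GRanges(rep(as.character(seqnames(gene_gr)), 3L),
                     IRanges(c(gs, mids, ge - 249L),
                             c(gs + 199L, mids + 149L, ge)),
                     strand = rep(as.character(strand(gene_gr)), 3L),
                     gene_id = rep(names(gene_gr), 3L))
    exons <- GenomicRanges::sort(exons)

    GenomeModel(sl, genes = gene_gr, exons = exons,
                blacklist = suppressWarnings(do.call(c, unname(bl_list))), peaks = peaks)
}

#' Simulate an ATAC fragment library
#'
#' Draws fragments whose lengths follow a truncated-normal mixture with
#' sub-nucleosomal, mono-, di-, tri- and tetra-nucleosome modes, and whose
#' genomic placement reflects library quality: good libraries concentrate
#' fragment centers inside peaks and around TSSs on top of a uniform
#' background, while bad libraries are uniform with sub-nucleosomal lengths
#' only (tagmentation of naked/over-digested chromatin).
#'
#' @param genome A \code{\link{GenomeModel}} with peaks and genes.
#' @param config A \code{\link{simulationConfig}}.
#' @param quality \code{"good"} or \code{"bad"}.
#' @param seed Seed; defaults to \code{config$seed}.
#' @param n_fragments Number of fragments; defaults to
#'   \code{config$n_fragments}.
#' @return A \code{GRanges} of fragments (width = fragment length).
#' @examples
#' cfg <- simulationConfig(seed = 1, n_fragments = 500)
#' fr <- simulateFragments(simulateGenome(cfg), cfg, "good")
#' summary(width(fr))
#' @export
simulateFragments <- function(genome, config,
                              quality = c("good", "bad"),
                              seed = config$seed,
                              n_fragments = config$n_fragments) {
    quality <- match.arg(quality)
    validateSimulationConfig(config)
    stopifnot(is(genome, "GenomeModel"))
    if (length(peakSet(genome)) == 0L || length(geneBodies(genome)) == 0L)
        stop("genome must contain peaks and genes")
    withSeed(seed, .simulateFragments(genome, config, quality, n_fragments))
}

.simulateFragments <- function(genome, config, quality, n) {
    sl <- chromLengths(genome)
    if (n == 0L) {
        return(GRanges(seqinfo = GenomeInfoDb::Seqinfo(names(sl),
                                                       as.integer(sl))))
    }
    w <- if (quality == "good") config$fragment_weights_good
         else config$fragment_weights_bad
    comp <- sample.int(length(w), n, replace = TRUE, prob = w)
    len <- round(rnorm(n, config$fragment_modes[comp],
                       config$fragment_sds[comp]))
    len <- pmin(pmax(len, 25L), 1200L)

    ftss <- if (quality == "good") config$frac_tss else 0
    fpk <- if (quality == "good") config$frac_peak else 0
    u <- runif(n)
    kind <- ifelse(u < ftss, "tss", ifelse(u < ftss + fpk, "peak", "bg"))

    tss <- tssSites(genome)
    pk <- peakSet(genome)
    chrom <- character(n); cen <- numeric(n)
    i <- kind == "tss"
    if (any(i)) {
        j <- sample.int(length(tss), sum(i), replace = TRUE)
        chrom[i] <- as.character(seqnames(tss))[j]
        cen[i] <- start(tss)[j] + round(rnorm(sum(i), 0, config$tss_sd))
    }
    i <- kind == "peak"
    if (any(i)) {
        j <- sample.int(length(pk), sum(i), replace = TRUE,
                        prob = width(pk))
        chrom[i] <- as.character(seqnames(pk))[j]
        cen[i] <- round(start(pk)[j] + runif(sum(i)) * (width(pk)[j] - 1))
    }
    i <- kind == "bg"
    if (any(i)) {
        j <- sample.int(length(sl), sum(i), replace = TRUE,
                        prob = as.numeric(sl))
        chrom[i] <- names(sl)[j]
        cen[i] <- round(runif(sum(i)) * (as.numeric(sl)[j] - 1)) + 1
    }
    s <- cen - floor(len / 2)
    e <- s + len - 1
    lim <- as.numeric(sl[chrom])
    s <- pmax(s, 1); e <- pmin(e, lim)
    gr <- GRanges(chrom, IRanges(s, e),
                  seqinfo = GenomeInfoDb::Seqinfo(names(sl),
                                                  as.integer(sl)))
    GenomicRanges::sort(gr)
}
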