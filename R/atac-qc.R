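#' Insert-size distribution score (0-4)
#'
#' Scores an ATAC library by the number of nucleosomal modes in its
#' fragment-length histogram: 0 means only short (sub-nucleosomal)
#' fragments were recovered, 1 indicates mononucleosomes, 2 monomers plus
#' dimers, up to a maximum of 4 (tetramers or larger). Modes are detected
#' automatically on a Gaussian-smoothed log-count histogram, restricted to
#' the bands (120, 280], (280, 470], (470, 660] and (660, 900] bp; a band
#' counts as a mode when its smoothed maximum exceeds the preceding local
#' minimum by the prominence factor and the band holds a non-trivial
#' number of fragments.
#'
#' @param fragments \code{GRanges} of fragments (widths are lengths), or an
#'   integer vector of fragment lengths.
#' @param prominence Required ratio of mode height to the preceding local
#'   minimum of the smoothed log-histogram.
#' @param sigma SD (bp) of the Gaussian smoothing kernel.
#' @param min_band_count Minimum fragments within a band for it to be
#'   eligible as a mode.
#' @return Integer score in 0..4.
#' @export
insertSizeScore <- function(fragments, prominence = 1.15, sigma = 10,
                            min_band_count = 10L) {
    len <- if (is(fragments, "GRanges")) width(fragments)
           else as.integer(fragments)
    if (length(len) == 0L) stop("no fragments: cannot score insert sizes")
    bands <- list(c(120L, 280L), c(280L, 470L), c(470L, 660L),
                  c(660L, 900L))
    maxlen <- 1000L
    h <- tabulate(pmin(pmax(len, 1L), maxlen), maxlen)
    lh <- log1p(h)
    half <- ceiling(3 * sigma)
    kern <- stats::dnorm(seq(-half, half), sd = sigma)
    kern <- kern / sum(kern)
    padded <- c(rep(0, half), lh, rep(0, half))
    sm <- as.numeric(stats::filter(padded, kern, sides = 2))
    sm <- sm[half + seq_len(maxlen)]
    score <- 0L
    prev <- 100L  # end of the sub-nucleosomal region
    for (b in bands) {
        idx <- (b[1] + 1L):b[2]
        mode_pos <- idx[which.max(sm[idx])]
        mode_h <- sm[mode_pos]
        valley <- min(sm[prev:mode_pos])
        n_band <- sum(h[idx])
        if (n_band >= min_band_count && mode_h > 0 &&
            mode_h >= prominence * max(valley, .Machine$double.eps))
            score <- score + 1L
        prev <- mode_pos
    }
    score
}

#' TSS enrichment profile and score
#'
#' Computes per-bp Tn5 insertion counts (from \code{\link{shiftInsertions}})
#' over 2 kb intervals centered at the most 5' TSS of expressed genes,
#' strand-oriented, averaged across genes. The mean of the first and last
#' 100 bp estimates the background insertion rate; the enrichment curve is
#' the per-bp mean divided by that background, and the score is the maximum
#' of the smoothed curve (the ENCODE convention).
#'
#' @param fragments \code{GRanges} of fragments.
#' @param genome A \code{\link{GenomeModel}}.
#' @param expressed_genes Character vector of gene ids with moderate-high
#'   expression (mean normalized CPM > 10 from the RNA data); at least 10.
#' @param flank Half-width of the TSS interval (bp).
#' @param smooth Width (bp) of the running-mean smoother applied before
#'   taking the maximum.
#' @return List with \code{profile} (per-bp enrichment curve, 5' to 3') and
#'   \code{score}.
#' @export
tssEnrichment <- function(fragments, genome, expressed_genes,
                          flank = 1000L, smooth = 101L) {
    stopifnot(is(genome, "GenomeModel"))
    expressed_genes <- intersect(expressed_genes,
                                 names(geneBodies(genome)))
    if (length(expressed_genes) < 10L)
        stop("fewer than 10 expressed genes: background estimate unstable")
    tss <- tssSites(genome)[expressed_genes]
    win <- GRanges(seqnames(tss),
                   IRanges(pmax(start(tss) - flank, 1L),
                           start(tss) + flank - 1L),
                   strand = strand(tss))
    ins <- shiftInsertions(fragments)
    nb <- 2L * flank
    if (length(ins) == 0L) {
        warning("no insertions: TSS enrichment set to 0")
        return(list(profile = rep(0, nb), score = 0))
    }
    hits <- findOverlaps(ins, win, ignore.strand = TRUE)
    if (length(hits) == 0L) {
        warning("no insertions within any TSS window: score 0")
        return(list(profile = rep(0, nb), score = 0))
    }
    rel <- start(ins)[queryHits(hits)] - start(win)[subjectHits(hits)] + 1L
    neg <- as.character(strand(win))[subjectHits(hits)] == "-"
    rel[neg] <- nb + 1L - rel[neg]
    rel <- rel[rel >= 1L & rel <= nb]
    profile <- tabulate(rel, nb) / length(expressed_genes)
    bg <- mean(profile[c(seq_len(100L), (nb - 99L):nb)])
    if (bg == 0) bg <- 0.5 / (100 * length(expressed_genes))
    curve <- profile / bg
    k <- rep(1 / smooth, smooth)
    smoothed <- as.numeric(stats::filter(curve, k, sides = 2))
    list(profile = curve, score = max(smoothed, na.rm = TRUE))
}

#' Fraction of fragments in peaks (FRiP)
#'
#' @param fragments \code{GRanges} of fragments.
#' @param peaks \code{GRanges} of called peaks.
#' @return Fraction of fragments overlapping at least one peak.
#' @export
fripScore <- function(fragments, peaks) {
    if (length(fragments) == 0L) stop("no fragments: cannot compute FRiP")
    if (length(peaks) == 0L) {
        warning("empty peak set: FRiP is 0")
        return(0)
    }
    mean(overlapsAny(fragments, peaks, ignore.strand = TRUE))
}

#' Quality-control gate for an ATAC library
#'
#' Applies the four criteria (insert-size score >= 2, FRiP >= 3\%,
#' >= 15,000 called peaks, TSS enrichment >= 5); a library passes when at
#' least three of the four hold.
#'
#' @param insert_size_score Integer 0-4.
#' @param frip Fraction in [0, 1].
#' @param n_peaks Number of peaks called for the library.
#' @param tss_score TSS enrichment score.
#' @param thresholds Named list overriding the default cutoffs
#'   (\code{score}, \code{frip}, \code{n_peaks}, \code{tss}).
#' @return List with per-criterion logicals and \code{pass}.
#' @examples
#' qcGate(3, 0.04, 20000, 6)$pass   # TRUE, 4 of 4
#' qcGate(1, 0.04, 20000, 6)$pass   # TRUE, 3 of 4
#' @export
qcGate <- function(insert_size_score, frip, n_peaks, tss_score,
                   thresholds = list(score = 2L, frip = 0.03,
                                     n_peaks = 15000L, tss = 5)) {
    vals <- list(insert_size_score, frip, n_peaks, tss_score)
    if (any(vapply(vals, function(v) length(v) != 1L || is.na(v),
                   logical(1))))
        stop("all four QC measures must be present")
    crit <- c(score = insert_size_score >= thresholds$score,
              frip = frip >= thresholds$frip,
              n_peaks = n_peaks >= thresholds$n_peaks,
              tss = tss_score >= thresholds$tss)
    list(criteria = crit, n_met = sum(crit), pass = sum(crit) >= 3L)
}

#' Per-sample QC report
#'
#' Runs all three QC measures and the pass gate over a set of fragment
#' libraries.
#'
#' @param fragments Named list of \code{GRanges}, one per sample.
#' @param genome A \code{\link{GenomeModel}} (peaks used for FRiP).
#' @param expressed_genes Gene ids used for TSS enrichment.
#' @param n_peaks Named or positional vector of per-sample peak counts
#'   (per-sample peak calling happens upstream).
#' @param ... Passed to \code{\link{qcGate}}.
#' @return data.frame with one row per sample: the three scores,
#'   \code{n_peaks}, per-criterion logicals and \code{pass}.
#' @export
atacQC <- function(fragments, genome, expressed_genes, n_peaks, ...) {
    stopifnot(length(fragments) == length(n_peaks))
    pk <- peakSet(genome)
    rows <- lapply(seq_along(fragments), function(i) {
        fr <- fragments[[i]]
        if (length(fr) == 0L) {
            return(data.frame(insert_size_score = 0L, tss_enrichment = 0,
                              frip = 0, n_peaks = n_peaks[i],
                              crit_score = FALSE, crit_frip = FALSE,
                              crit_npeaks = n_peaks[i] >= 15000,
                              crit_tss = FALSE, pass = FALSE))
        }
        iss <- insertSizeScore(fr)
        tss <- tssEnrichment(fr, genome, expressed_genes)$score
        fp <- fripScore(fr, pk)
        g <- qcGate(iss, fp, n_peaks[i], tss, ...)
        data.frame(insert_size_score = iss, tss_enrichment = tss,
                   frip = fp, n_peaks = n_peaks[i],
                   crit_score = unname(g$criteria["score"]),
                   crit_frip = unname(g$criteria["frip"]),
                   crit_npeaks = unname(g$criteria["n_peaks"]),
                   crit_tss = unname(g$criteria["tss"]),
                   pass = g$pass)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- names(fragments)
    out
}
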