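#' Drop overlapping windows, keeping the most abundant per overlap run
#'
#' Deviation scoring assumes features are non-overlapping; within each run
#' of mutually overlapping windows the window with the highest total count
#' is retained.
#'
#' @param ws \code{RangedSummarizedExperiment} of window counts.
#' @return The reduced \code{RangedSummarizedExperiment}.
#' @export
dropOverlappingWindows <- function(ws) {
    gr <- SummarizedExperiment::rowRanges(ws)
    if (length(gr) <= 1L) return(ws)
    runs <- reduce(gr, ignore.strand = TRUE)
    h <- findOverlaps(gr, runs, ignore.strand = TRUE)
    tot <- rowSums(assay(ws, "counts"))
    keep <- vapply(split(queryHits(h), subjectHits(h)), function(w)
        w[which.max(tot[w])], integer(1))
    ws[sort(unname(keep)), ]
}

#' Sample GC/accessibility-matched background peaks
#'
#' Bins peaks on a 2-D equal-frequency grid of (GC fraction, mean
#' accessibility) and, for each peak and iteration, samples a background
#' peak with replacement from the same bin. Degenerate bins of size one
#' return the peak itself.
#'
#' @param peaks \code{GRanges} with \code{gc} and \code{meanAcc} metadata,
#'   or a data.frame with those columns.
#' @param n_iter Background iterations (draws per peak).
#' @param bins Bins per attribute dimension.
#' @param seed Seed for the sampling.
#' @return Integer matrix (peaks x n_iter) of background peak indices.
#' @export
matchBackground <- function(peaks, n_iter = 50L, bins = 10L, seed = 1L) {
    gc <- if (is(peaks, "GRanges")) peaks$gc else peaks$gc
    acc <- if (is(peaks, "GRanges")) peaks$meanAcc else peaks$meanAcc
    if (is.null(gc) || is.null(acc) || anyNA(gc) || anyNA(acc))
        stop("peaks must carry complete gc and meanAcc attributes")
    P <- length(gc)
    cut_ef <- function(x) {
        br <- unique(stats::quantile(x, seq(0, 1, length.out = bins + 1)))
        if (length(br) < 2L) return(rep(1L, length(x)))
        findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
    }
    bin <- paste(cut_ef(gc), cut_ef(acc))
    members <- split(seq_len(P), bin)
    withSeed(seed, {
        out <- matrix(0L, P, n_iter)
        for (m in members) {
            out[m, ] <- matrix(m[sample.int(length(m),
                                            length(m) * n_iter,
                                            replace = TRUE)],
                               length(m), n_iter)
        }
        out
    })
}

#' Motif accessibility deviations and z-scores
#'
#' For motif m and sample j, the observed count is
#' \code{o = sum_p M[p,m] X[p,j]} and the expected count under the
#' depth-only model is \code{e = (sum_p M[p,m] X[p,.] / X[.,.]) * X[.,j]};
#' the raw deviation is \code{(o - e)/e}. The same deviation is computed
#' on each matched background peak set; the bias-corrected deviation is
#' the raw deviation minus the background mean, and the z-score divides by
#' the background SD. Z-scores with zero background SD are reported as
#' missing, never as 0.
#'
#' @param counts Peak x sample count matrix.
#' @param motifs Binary peak x motif matrix.
#' @param backgrounds Peak x iteration index matrix from
#'   \code{\link{matchBackground}}.
#' @return List with matrices \code{raw}, \code{corrected}, \code{z}
#'   (motif x sample) and \code{n_iter}.
#' @export
deviationZScores <- function(counts, motifs, backgrounds) {
    stopifnot(nrow(counts) == nrow(motifs),
              nrow(counts) == nrow(backgrounds))
    M <- as.matrix(motifs)
    storage.mode(M) <- "double"
    X <- as.matrix(counts)
    frac <- rowSums(X) / sum(X)
    csum <- colSums(X)
    o <- crossprod(M, X)
    e <- (crossprod(M, frac)) %*% rbind(csum)
    empty <- colSums(M) == 0
    if (any(empty))
        warning(sum(empty), " motif(s) with no member peaks: scores missing")
    raw <- (o - e) / e
    raw[empty, ] <- NA_real_
    n_iter <- ncol(backgrounds)
    bg_sum <- matrix(0, nrow(raw), ncol(raw))
    bg_sq <- matrix(0, nrow(raw), ncol(raw))
    for (b in seq_len(n_iter)) {
        idx <- backgrounds[, b]
        ob <- crossprod(M, X[idx, , drop = FALSE])
        eb <- (crossprod(M, frac[idx])) %*% rbind(csum)
        dev <- (ob - eb) / eb
        bg_sum <- bg_sum + dev
        bg_sq <- bg_sq + dev^2
    }
    bg_mean <- bg_sum / n_iter
    bg_var <- pmax(bg_sq / n_iter - bg_mean^2, 0) * n_iter / (n_iter - 1)
    bg_sd <- sqrt(bg_var)
    corrected <- raw - bg_mean
    z <- corrected / bg_sd
    z[bg_sd == 0] <- NA_real_
    dimnames(raw) <- dimnames(corrected) <- dimnames(z) <-
        list(colnames(motifs), colnames(counts))
    list(raw = raw, corrected = corrected, z = z, n_iter = n_iter)
}

#' Motif enrichment in a peak set against a length-matched background
#'
#' Subsamples the candidate background to match the foreground peak-length
#' distribution (decile binning, proportional sampling without
#' replacement), then tests each motif's membership with Fisher's exact
#' test (one-sided, enrichment) and BH-corrects across motifs.
#'
#' @param foreground Indices (or names) of foreground peaks.
#' @param background Indices (or names) of candidate background peaks;
#'   must be disjoint from the foreground.
#' @param motifs Binary peak x motif matrix (full peak universe).
#' @param widths Peak widths (bp) for the full universe; used for length
#'   matching. If \code{NULL}, no length matching is done.
#' @param seed Seed for the subsampling.
#' @return data.frame per motif: \code{motif}, \code{odds_ratio} (sample
#'   odds ratio), \code{freq_fg}, \code{freq_bg}, \code{PValue},
#'   \code{FDR}.
#' @export
motifEnrichment <- function(foreground, background, motifs,
                            widths = NULL, seed = 1L) {
    if (is.character(foreground))
        foreground <- match(foreground, rownames(motifs))
    if (is.character(background))
        background <- match(background, rownames(motifs))
    if (length(foreground) < 10L)
        stop("foreground smaller than 10 peaks")
    if (length(intersect(foreground, background)) > 0L)
        stop("foreground and background must be disjoint")
    bg <- background
    if (!is.null(widths) && length(background) > length(foreground)) {
        br <- unique(stats::quantile(widths[foreground],
                                     seq(0, 1, 0.1)))
        fg_bin <- findInterval(widths[foreground], br,
                               rightmost.closed = TRUE, all.inside = TRUE)
        bg_bin <- findInterval(widths[background], br,
                               rightmost.closed = TRUE, all.inside = TRUE)
        fg_n <- tabulate(fg_bin, length(br))
        bg_by <- split(background, bg_bin)
        scale <- min(vapply(seq_along(fg_n), function(d) {
            if (fg_n[d] == 0) Inf
            else length(bg_by[[as.character(d)]]) / fg_n[d]
        }, numeric(1)))
        scale <- min(scale, length(background) / length(foreground))
        bg <- withSeed(seed, unlist(lapply(seq_along(fg_n), function(d) {
            avail <- bg_by[[as.character(d)]]
            take <- min(length(avail), floor(scale * fg_n[d]))
            if (take > 0) sample(avail, take) else integer()
        })))
    }
    a_fg <- colSums(motifs[foreground, , drop = FALSE] > 0)
    a_bg <- colSums(motifs[bg, , drop = FALSE] > 0)
    n_fg <- length(foreground); n_bg <- length(bg)
    p <- vapply(seq_len(ncol(motifs)), function(m) {
        stats::fisher.test(matrix(c(a_fg[m], n_fg - a_fg[m],
                                    a_bg[m], n_bg - a_bg[m]), 2),
                           alternative = "greater")$p.value
    }, numeric(1))
    or <- (a_fg / pmax(n_fg - a_fg, 0.5)) /
          pmax(a_bg / pmax(n_bg - a_bg, 0.5), .Machine$double.eps)
    or[a_bg == 0 & a_fg == 0] <- 1
    data.frame(motif = colnames(motifs), odds_ratio = or,
               freq_fg = a_fg / n_fg, freq_bg = a_bg / n_bg,
               PValue = p, FDR = stats::p.adjust(p, "BH"),
               row.names = NULL, stringsAsFactors = FALSE)
}
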