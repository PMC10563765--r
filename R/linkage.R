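#' Link peaks to genes by correlation against matched-background nulls
#'
#' For each gene and every peak whose midpoint lies within \code{window}
#' bp of the gene's TSS, computes the Spearman correlation of expression
#' and accessibility across paired samples and compares it with the
#' correlations of the same gene against \code{n_bg} background peaks
#' matched for GC content and mean accessibility (sampled with
#' replacement). The p-value is a one-sided z-test of the observed
#' correlation against the background mean/SD. When the background set for
#' a peak contains fewer than \code{min_distinct} different peaks, the
#' null is non-informative and the p-value is set to missing, excluding
#' the pair. A pair is kept when p < 0.05 and correlation > 0.3.
#'
#' @param expr Normalized, corrected log-expression matrix (genes x
#'   samples).
#' @param acc Normalized, corrected peak accessibility matrix (peaks x
#'   samples); columns must pair one-to-one with \code{expr} columns.
#' @param peaks \code{GRanges} of the peaks (rows of \code{acc}), with
#'   \code{gc} and \code{meanAcc} metadata.
#' @param genome A \code{\link{GenomeModel}} providing gene TSSs.
#' @param genes Genes to link (e.g. the differentially expressed set);
#'   default all rows of \code{expr}.
#' @param window Maximum midpoint-to-TSS distance (bp).
#' @param n_bg Background draws per peak.
#' @param bins Bins per attribute dimension for background matching;
#'   \code{"auto"} picks \code{floor(sqrt(n_peaks / 100))} clamped to
#'   [2, 10], so bins hold roughly 100 peaks.
#' @param min_distinct Minimum number of different background peaks for an
#'   informative null.
#' @param p_cut,rho_cut Keep thresholds.
#' @param seed Seed for the background sampling.
#' @return data.frame (linkage table): \code{gene}, \code{peak},
#'   \code{distance}, \code{rho}, \code{bg_mean}, \code{bg_sd},
#'   \code{n_distinct}, \code{PValue}, \code{kept}.
#' @export
linkPeaksToGenes <- function(expr, acc, peaks, genome,
                             genes = rownames(expr), window = 1e5,
                             n_bg = 100L, bins = "auto",
                             min_distinct = 50L, p_cut = 0.05,
                             rho_cut = 0.3, seed = 1L) {
    if (!identical(colnames(expr), colnames(acc)))
        stop("RNA and ATAC samples must be paired one-to-one ",
             "(identical column names)")
    n <- ncol(expr)
    if (n < 8L) stop("fewer than 8 paired samples: correlation unstable")
    stopifnot(length(peaks) == nrow(acc))
    if (identical(bins, "auto"))
        bins <- max(2L, min(10L, floor(sqrt(length(peaks) / 100))))
    bg <- matchBackground(peaks, n_iter = n_bg, bins = bins, seed = seed)
    n_distinct <- apply(bg, 1, function(r) length(unique(r)))

    # standardized ranks: Spearman correlations become cross-products
    zr <- function(m) {
        r <- t(apply(m, 1, rank))
        r <- r - rowMeans(r)
        s <- sqrt(rowSums(r^2))
        r / ifelse(s == 0, 1, s)
    }
    Za <- zr(acc)
    tss <- tssSites(genome)
    genes <- intersect(genes, names(tss))
    genes <- intersect(genes, rownames(expr))
    mid <- (start(peaks) + end(peaks)) %/% 2L
    pk_chr <- as.character(seqnames(peaks))
    pk_names <- if (!is.null(names(peaks))) names(peaks)
                else as.character(seq_along(peaks))
    out <- vector("list", length(genes))
    for (gi in seq_along(genes)) {
        g <- genes[gi]
        gchr <- as.character(seqnames(tss[g]))
        gpos <- start(tss[g])
        cand <- which(pk_chr == gchr & abs(mid - gpos) <= window)
        if (length(cand) == 0L) next
        rg <- rank(expr[g, ])
        zg <- (rg - mean(rg))
        zg <- zg / sqrt(sum(zg^2))
        C <- as.numeric(Za %*% zg)      # correlation with every peak
        obs <- C[cand]
        bg_mean <- rowMeans(matrix(C[bg[cand, , drop = FALSE]],
                                   length(cand), n_bg))
        bg_sd <- apply(matrix(C[bg[cand, , drop = FALSE]],
                              length(cand), n_bg), 1, stats::sd)
        z <- (obs - bg_mean) / bg_sd
        p <- stats::pnorm(z, lower.tail = FALSE)
        p[bg_sd == 0] <- NA_real_
        p[n_distinct[cand] < min_distinct] <- NA_real_
        out[[gi]] <- data.frame(gene = g, peak = pk_names[cand],
                                distance = abs(mid[cand] - gpos),
                                rho = obs, bg_mean = bg_mean,
                                bg_sd = bg_sd,
                                n_distinct = n_distinct[cand],
                                PValue = p, stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    if (is.null(res))
        res <- data.frame(gene = character(), peak = character(),
                          distance = numeric(), rho = numeric(),
                          bg_mean = numeric(), bg_sd = numeric(),
                          n_distinct = integer(), PValue = numeric(),
                          stringsAsFactors = FALSE)
    res$kept <- !is.na(res$PValue) & res$PValue < p_cut &
        res$rho > rho_cut
    rownames(res) <- NULL
    res
}

#' Aggregate linked-peak accessibility per gene (DORC scores)
#'
#' Sums normalized accessibility over each gene's kept peaks, per sample.
#' Genes with more than 5 linked peaks are flagged as highly regulated
#' (domains of regulatory chromatin).
#'
#' @param links Linkage table from \code{\link{linkPeaksToGenes}}.
#' @param acc Normalized accessibility matrix (peaks x samples) with peak
#'   names as row names.
#' @param min_peaks Strict lower bound for the highly-regulated flag.
#' @return List with \code{scores} (gene x sample matrix),
#'   \code{n_linked} (named vector) and \code{flagged} (named logical:
#'   \code{n_linked > min_peaks}).
#' @export
dorcScores <- function(links, acc, min_peaks = 5L) {
    kept <- links[links$kept, , drop = FALSE]
    genes <- unique(kept$gene)
    scores <- matrix(0, length(genes), ncol(acc),
                     dimnames = list(genes, colnames(acc)))
    for (g in genes) {
        pk <- kept$peak[kept$gene == g]
        scores[g, ] <- colSums(acc[pk, , drop = FALSE])
    }
    n_linked <- vapply(genes, function(g) sum(kept$gene == g),
                       integer(1))
    list(scores = scores, n_linked = n_linked,
         flagged = n_linked > min_peaks)
}

#' Signed TF-gene regulation scores
#'
#' For each (TF, highly-regulated gene) pair: the enrichment of the TF's
#' motif in the gene's kept peaks is tested against GC/accessibility-
#' matched background peaks (Fisher, one-sided), and the TF's expression
#' is rank-correlated with the gene's DORC score across paired samples.
#' The score is \code{sign(rho) * sqrt(-log10(p_enrich) * -log10(p_corr))}
#' capped at \code{cap}: monotone in both significances and signed by the
#' direction of the TF-accessibility relationship (negative for
#' repressors). Pairs with |score| > 1.25 are flagged putative
#' interactions.
#'
#' @param dorc Result of \code{\link{dorcScores}}.
#' @param tf_expr Matrix of TF expression (TFs x samples; columns paired
#'   with the DORC score columns).
#' @param motifs Binary peak x motif matrix.
#' @param tf_motifs Named character vector mapping TF (row of
#'   \code{tf_expr}) to its motif column; TFs without a motif are skipped
#'   with a message.
#' @param links Linkage table (to recover each gene's kept peaks).
#' @param peaks \code{GRanges} of the full peak universe with \code{gc}
#'   and \code{meanAcc} (for background matching).
#' @param n_bg Background iterations for the enrichment null.
#' @param bins Attribute bins for matching (\code{"auto"} as in
#'   \code{\link{linkPeaksToGenes}}).
#' @param cap Cap on |score|.
#' @param flag_cut Putative-interaction threshold on |score|.
#' @param seed Seed for background sampling.
#' @return data.frame: \code{tf}, \code{gene}, \code{p_enrich},
#'   \code{rho}, \code{p_corr}, \code{score}, \code{flag}.
#' @export
regulationScores <- function(dorc, tf_expr, motifs, tf_motifs, links,
                             peaks, n_bg = 25L, bins = "auto", cap = 10,
                             flag_cut = 1.25, seed = 1L) {
    genes <- names(dorc$flagged)[dorc$flagged]
    if (identical(bins, "auto"))
        bins <- max(2L, min(10L, floor(sqrt(length(peaks) / 100))))
    bg <- matchBackground(peaks, n_iter = n_bg, bins = bins, seed = seed)
    pk_names <- if (!is.null(names(peaks))) names(peaks)
                else rownames(motifs)
    kept <- links[links$kept, , drop = FALSE]
    tfs <- rownames(tf_expr)
    no_motif <- setdiff(tfs, names(tf_motifs))
    if (length(no_motif) > 0L)
        message("TF(s) without motif skipped: ",
                paste(no_motif, collapse = ", "))
    tfs <- intersect(tfs, names(tf_motifs))
    out <- list()
    for (g in genes) {
        gpk <- kept$peak[kept$gene == g]
        gidx <- match(gpk, pk_names)
        bg_idx <- unique(as.vector(bg[gidx, , drop = FALSE]))
        bg_idx <- setdiff(bg_idx, gidx)
        for (tf in tfs) {
            m <- tf_motifs[[tf]]
            a <- sum(motifs[gidx, m] > 0)
            b <- length(gidx) - a
            cc <- sum(motifs[bg_idx, m] > 0)
            d <- length(bg_idx) - cc
            p_enr <- if (length(bg_idx) == 0L) 1 else
                stats::fisher.test(matrix(c(a, b, cc, d), 2),
                                   alternative = "greater")$p.value
            ct <- suppressWarnings(
                stats::cor.test(tf_expr[tf, ], dorc$scores[g, ],
                                method = "spearman"))
            rho <- unname(ct$estimate)
            p_corr <- ct$p.value
            s <- sign(rho) * sqrt(min(-log10(max(p_enr, 1e-300)), cap) *
                                  min(-log10(max(p_corr, 1e-300)), cap))
            s <- sign(s) * min(abs(s), cap)
            out[[length(out) + 1L]] <- data.frame(
                tf = tf, gene = g, p_enrich = p_enr, rho = rho,
                p_corr = p_corr, score = s,
                flag = abs(s) > flag_cut, stringsAsFactors = FALSE)
        }
    }
    res <- do.call(rbind, out)
    if (is.null(res))
        res <- data.frame(tf = character(), gene = character(),
                          p_enrich = numeric(), rho = numeric(),
                          p_corr = numeric(), score = numeric(),
                          flag = logical(), stringsAsFactors = FALSE)
    rownames(res) <- NULL
    res
}
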