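#' @importFrom GenomicRanges findOverlaps countOverlaps reduce
#'   distanceToNearest
#' @importFrom IRanges overlapsAny
#' @importFrom S4Vectors queryHits subjectHits isSorted
NULL

#' Tn5 insertion sites from fragment intervals
#'
#' Converts each sequenced fragment into its two transposase insertion
#' points by shifting the fragment ends inward: +5 bp from the 5' end and
#' -4 bp from the 3' end, applied in the 0-based half-open convention (a
#' fragment [100, 300) yields insertions at 105 and 296). Fragments
#' shorter than 9 bp still emit both insertions but are flagged in the
#' \code{short} metadata column; insertions falling outside chromosome
#' bounds are clipped with a warning.
#'
#' @param fragments \code{GRanges} of fragments with seqlengths set.
#' @return \code{GRanges} of width-1 insertion positions, two per fragment,
#'   with logical metadata column \code{short}.
#' @examples
#' fr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 300))
#' GenomeInfoDb::seqlengths(fr) <- c(chr1 = 1000)
#' start(shiftInsertions(fr))   # 106, 297 (1-based; 105, 296 in 0-based)
#' @export
shiftInsertions <- function(fragments) {
    if (length(fragments) == 0L) {
        out <- GRanges(seqinfo = GenomeInfoDb::seqinfo(fragments))
        out$short <- logical(0)
        return(out)
    }
    short <- width(fragments) < 9L
    # 0-based [s0, e0): insertions s0+5 and e0-4 -> 1-based start+5, end-3
    p1 <- start(fragments) + 5L
    p2 <- end(fragments) - 3L
    chrom <- rep(as.character(seqnames(fragments)), 2L)
    pos <- c(p1, p2)
    sl <- GenomeInfoDb::seqlengths(fragments)
    lim <- sl[chrom]
    clipped <- pos < 1L | (!is.na(lim) & pos > lim)
    if (any(clipped)) {
        warning(sum(clipped),
                " insertion position(s) clipped to chromosome bounds")
        pos <- pmax(pos, 1L)
        pos <- ifelse(is.na(lim), pos, pmin(pos, lim))
    }
    out <- GRanges(chrom, IRanges(pos, pos),
                   seqinfo = GenomeInfoDb::seqinfo(fragments))
    out$short <- rep(short, 2L)
    out
}

#' Count fragments in sliding genomic windows
#'
#' Tiles every chromosome with fixed-width windows advancing by
#' \code{step}, counts the fragments of each sample overlapping each window
#' (a fragment contributes to every window it overlaps), excludes entirely
#' any fragment overlapping a blacklisted region, and drops windows whose
#' count summed across samples falls below \code{min_total}.
#'
#' @param fragments Named list of \code{GRanges}, one per sample.
#' @param genome A \code{\link{GenomeModel}} (chromosome lengths and
#'   blacklist).
#' @param width Window width in bp.
#' @param step Window step in bp; must not exceed \code{width}.
#' @param min_total Minimum summed count across samples for a window to be
#'   retained.
#' @return A \code{RangedSummarizedExperiment} of retained windows with a
#'   \code{counts} assay (windows x samples).
#' @export
countWindows <- function(fragments, genome, width = 150L, step = 50L,
                         min_total = 75L) {
    stopifnot(is(genome, "GenomeModel"), is.list(fragments))
    if (width < step) stop("window width must be >= step")
    sl <- chromLengths(genome)
    if (length(sl) == 0L) stop("genome has no chromosomes")
    bl <- blacklistRegions(genome)
    fragments <- lapply(fragments, function(fr) {
        if (length(bl) > 0L && length(fr) > 0L)
            fr[!overlapsAny(fr, bl, ignore.strand = TRUE)]
        else fr
    })
    starts <- lapply(names(sl), function(chrom) {
        L <- sl[[chrom]]
        if (L < width) return(integer())
        seq.int(1L, L - width + 1L, by = step)
    })
    windows <- GRanges(rep(names(sl), lengths(starts)),
                       IRanges(unlist(starts),
                               unlist(starts) + width - 1L),
                       seqinfo = GenomeInfoDb::Seqinfo(names(sl),
                                                       as.integer(sl)))
    # two-pass: cheap total count over all samples, then per-sample counts
    # restricted to windows that can survive the total filter
    allfr <- suppressWarnings(do.call(c, unname(fragments)))
    tot <- countOverlaps(windows, allfr, ignore.strand = TRUE)
    keep <- tot >= min_total
    windows <- windows[keep]
    if (length(windows) == 0L) {
        counts <- matrix(integer(0), 0L, length(fragments),
                         dimnames = list(NULL, names(fragments)))
    } else {
        counts <- vapply(fragments, function(fr)
            countOverlaps(windows, fr, ignore.strand = TRUE),
            integer(length(windows)))
        counts <- matrix(as.integer(counts), nrow = length(windows),
                         ncol = length(fragments),
                         dimnames = list(NULL, names(fragments)))
    }
    names(windows) <- sprintf("win_%06d", seq_along(windows))
    rownames(counts) <- names(windows)
    SummarizedExperiment(assays = list(counts = counts),
                         rowRanges = windows)
}

#' Filter windows to the common peak set and a minimum mean count
#'
#' Retains windows that overlap at least one peak of the unified peak set
#' and whose mean count across samples is at least \code{min_mean}.
#'
#' @param ws Window \code{RangedSummarizedExperiment} from
#'   \code{\link{countWindows}} (or the generator).
#' @param peaks \code{GRanges} of the unified peak set.
#' @param min_mean Minimum mean fragment count across samples.
#' @return The filtered \code{RangedSummarizedExperiment}.
#' @export
filterWindows <- function(ws, peaks, min_mean = 4) {
    stopifnot(is(ws, "SummarizedExperiment"))
    if (length(peaks) == 0L) {
        warning("empty peak set: no windows retained")
        return(ws[integer(0), ])
    }
    inpk <- overlapsAny(SummarizedExperiment::rowRanges(ws), peaks,
                        ignore.strand = TRUE)
    keep <- inpk & rowMeans(assay(ws, "counts")) >= min_mean
    ws[keep, ]
}

#' Merge tested windows into regions and split oversized spans
#'
#' Transitively merges windows separated by at most \code{gap} bp. Merged
#' spans wider than \code{max_width} are broken into
#' \code{k = ceiling(span / max_width)} overlapping sub-regions of
#' near-equal width (at most \code{max_width}, within about 100 bp of
#' span/k), with start positions distributed evenly and ties broken toward
#' the 5' end. Windows are assigned to every sub-region they overlap.
#'
#' @param windows \code{GRanges} of tested windows, coordinate-sorted.
#' @param gap Maximum inter-window gap (bp) for merging.
#' @param max_width Maximum region width (bp) after splitting.
#' @return A list with \code{regions} (\code{GRanges}) and \code{map}
#'   (data.frame with columns \code{window}, \code{region}: window index to
#'   region index, one row per overlap).
#' @export
mergeWindows <- function(windows, gap = 150L, max_width = 1500L) {
    stopifnot(is(windows, "GRanges"))
    if (length(windows) == 0L)
        return(list(regions = GRanges(),
                    map = data.frame(window = integer(),
                                     region = integer())))
    if (!isSorted(windows)) stop("windows must be coordinate-sorted")
    spans <- reduce(windows, min.gapwidth = gap + 1L,
                    ignore.strand = TRUE)
    reg_chr <- character(); reg_s <- integer(); reg_e <- integer()
    for (i in seq_along(spans)) {
        s <- start(spans)[i]; e <- end(spans)[i]
        span <- e - s + 1L
        if (span <= max_width) {
            reg_chr <- c(reg_chr, as.character(seqnames(spans))[i])
            reg_s <- c(reg_s, s); reg_e <- c(reg_e, e)
        } else {
            k <- ceiling(span / max_width)
            subw <- min(max_width, ceiling(span / k) + 100L)
            st <- floor(seq(s, e - subw + 1L, length.out = k))
            reg_chr <- c(reg_chr,
                         rep(as.character(seqnames(spans))[i], k))
            reg_s <- c(reg_s, st); reg_e <- c(reg_e, st + subw - 1L)
        }
    }
    regions <- GRanges(reg_chr, IRanges(reg_s, reg_e))
    hits <- findOverlaps(windows, regions, ignore.strand = TRUE)
    list(regions = regions,
         map = data.frame(window = queryHits(hits),
                          region = subjectHits(hits)))
}

#' Classify peaks by genomic context
#'
#' Assigns each peak exactly one class with precedence promoter > exonic >
#' proximal > distal > intergenic: \emph{promoter} if the peak lies within
#' 200 bp of any annotated TSS (edge-to-point), \emph{exonic} if it
#' overlaps an exon, \emph{proximal} if within 25 kb of a gene body
#' (edge-to-edge, strand-independent), \emph{distal} if within 100 kb, and
#' \emph{intergenic} otherwise.
#'
#' @param peaks \code{GRanges} of peaks.
#' @param genome A \code{\link{GenomeModel}} providing TSS, exons and gene
#'   bodies.
#' @return Factor of classes, one per peak, levels
#'   \code{c("promoter", "exonic", "proximal", "distal", "intergenic")}.
#' @export
classifyPeaks <- function(peaks, genome) {
    stopifnot(is(genome, "GenomeModel"))
    known <- names(chromLengths(genome))
    bad <- !(as.character(seqnames(peaks)) %in% known)
    if (any(bad)) {
        nm <- if (!is.null(names(peaks))) names(peaks)[bad][1]
              else which(bad)[1]
        stop("peak ", nm, " lies on an unknown chromosome")
    }
    lv <- c("promoter", "exonic", "proximal", "distal", "intergenic")
    cls <- rep("intergenic", length(peaks))
    distTo <- function(subject) {
        d <- rep(NA_real_, length(peaks))
        if (length(subject) == 0L) return(d)
        h <- distanceToNearest(peaks, subject, ignore.strand = TRUE)
        d[queryHits(h)] <- S4Vectors::mcols(h)$distance
        d
    }
    d_gene <- distTo(geneBodies(genome))
    cls[!is.na(d_gene) & d_gene <= 1e5] <- "distal"
    cls[!is.na(d_gene) & d_gene <= 25000] <- "proximal"
    if (length(geneExons(genome)) > 0L)
        cls[overlapsAny(peaks, geneExons(genome),
                        ignore.strand = TRUE)] <- "exonic"
    d_tss <- distTo(tssSites(genome))
    cls[!is.na(d_tss) & d_tss <= 200] <- "promoter"
    factor(cls, levels = lv)
}
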