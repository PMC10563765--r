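#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb Seqinfo seqlengths seqlevels seqnames
#' @importFrom S4Vectors mcols mcols<- DataFrame
NULL

#' GenomeModel: gene models, peaks and blacklist on a common genome
#'
#' Container for all interval annotation the pipeline needs: chromosome
#' lengths, gene bodies (with strand, from which the most 5' TSS is derived),
#' exons, a unified peak set and a blacklist of artifact-prone regions.
#' All ranges are stored 1-based closed (the native \code{GRanges}
#' convention); BED input/output converts to/from 0-based half-open.
#'
#' @slot seqinfo A \code{Seqinfo} with chromosome lengths.
#' @slot genes \code{GRanges} of gene bodies; names are gene identifiers.
#' @slot exons \code{GRanges} of exons with a \code{gene_id} metadata column.
#' @slot peaks \code{GRanges} of non-overlapping peaks; may carry \code{gc}
#'   (GC fraction) and \code{meanAcc} (mean accessibility) metadata used for
#'   matched-background sampling.
#' @slot blacklist \code{GRanges} of regions excluded from fragment counting.
#'
#' @export
setClass("GenomeModel",
    slots = c(
        seqinfo = "Seqinfo",
        genes = "GRanges",
        exons = "GRanges",
        peaks = "GRanges",
        blacklist = "GRanges"
    )
)

.validGenomeModel <- function(object) {
    msg <- character()
    sl <- GenomeInfoDb::seqlengths(object@seqinfo)
    chk <- function(gr, label) {
        if (length(gr) == 0L) return(character())
        m <- character()
        bad <- !(as.character(GenomicRanges::seqnames(gr)) %in% names(sl))
        if (any(bad)) {
            m <- c(m, sprintf("%s on unknown chromosome(s): %s", label,
                paste(unique(as.character(GenomicRanges::seqnames(gr))[bad]),
                      collapse = ", ")))
        } else {
            lim <- sl[as.character(GenomicRanges::seqnames(gr))]
            if (any(GenomicRanges::start(gr) < 1L) ||
                any(GenomicRanges::end(gr) > lim))
                m <- c(m, sprintf("%s extend beyond chromosome bounds", label))
        }
        m
    }
    msg <- c(msg, chk(object@genes, "genes"), chk(object@exons, "exons"),
             chk(object@peaks, "peaks"), chk(object@blacklist, "blacklist"))
    if (length(object@genes) > 0L && is.null(names(object@genes)))
        msg <- c(msg, "genes must be named by gene identifier")
    if (length(object@exons) > 0L) {
        if (is.null(object@exons$gene_id))
            msg <- c(msg, "exons must carry a gene_id metadata column")
        else if (!all(object@exons$gene_id %in% names(object@genes)))
            msg <- c(msg, "exon gene_id values must match gene names")
    }
    if (length(object@peaks) > 1L &&
        !GenomicRanges::isDisjoint(object@peaks))
        msg <- c(msg, "peaks must be non-overlapping")
    if (length(msg)) msg else TRUE
}
setValidity("GenomeModel", .validGenomeModel)

#' Construct a GenomeModel
#'
#' @param seqlengths Named integer vector of chromosome lengths (bp).
#' @param genes \code{GRanges} of gene bodies, named by gene id.
#' @param exons \code{GRanges} of exons with a \code{gene_id} column.
#' @param peaks \code{GRanges} of non-overlapping peaks.
#' @param blacklist \code{GRanges} of excluded regions.
#' @return A validated \code{GenomeModel}.
#' @examples
#' gm <- GenomeModel(c(chr1 = 1e6),
#'     genes = GenomicRanges::GRanges("chr1",
#'         IRanges::IRanges(1e4, 2e4), strand = "+",
#'         names = "g1"))
#' chromLengths(gm)
#' @export
GenomeModel <- function(seqlengths, genes = GRanges(), exons = GRanges(),
                        blacklist = GRanges(), peaks = GRanges()) {
    si <- Seqinfo(names(seqlengths), seqlengths = as.integer(seqlengths))
    fix <- function(gr) {
        GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(si)
        GenomeInfoDb::seqinfo(gr) <- si
        gr
    }
    new("GenomeModel", seqinfo = si, genes = fix(genes), exons = fix(exons),
        peaks = fix(GenomicRanges::sort(peaks)), blacklist = fix(blacklist))
}

#' @rdname GenomeModel-accessors
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))
#' @rdname GenomeModel-accessors
#' @export
setGeneric("geneBodies", function(x) standardGeneric("geneBodies"))
#' @rdname GenomeModel-accessors
#' @export
setGeneric("geneExons", function(x) standardGeneric("geneExons"))
#' @rdname GenomeModel-accessors
#' @export
setGeneric("peakSet", function(x) standardGeneric("peakSet"))
#' @rdname GenomeModel-accessors
#' @export
setGeneric("peakSet<-", function(x, value) standardGeneric("peakSet<-"))
#' @rdname GenomeModel-accessors
#' @export
setGeneric("blacklistRegions", function(x) standardGeneric("blacklistRegions"))
#' @rdname GenomeModel-accessors
#' @export
setGeneric("tssSites", function(x) standardGeneric("tssSites"))

#' Accessors for GenomeModel
#'
#' \code{chromLengths} returns the named chromosome-length vector;
#' \code{geneBodies}, \code{geneExons}, \code{peakSet} and
#' \code{blacklistRegions} return the corresponding \code{GRanges};
#' \code{tssSites} returns width-1 ranges at each gene's most 5' coordinate
#' (start on \code{+} genes, end on \code{-} genes).
#'
#' @param x A \code{GenomeModel}.
#' @param value Replacement \code{GRanges} of non-overlapping peaks.
#' @return See description.
#' @name GenomeModel-accessors
NULL

#' @rdname GenomeModel-accessors
setMethod("chromLengths", "GenomeModel",
    function(x) GenomeInfoDb::seqlengths(x@seqinfo))
#' @rdname GenomeModel-accessors
setMethod("geneBodies", "GenomeModel", function(x) x@genes)
#' @rdname GenomeModel-accessors
setMethod("geneExons", "GenomeModel", function(x) x@exons)
#' @rdname GenomeModel-accessors
setMethod("peakSet", "GenomeModel", function(x) x@peaks)
#' @rdname GenomeModel-accessors
setMethod("peakSet<-", "GenomeModel", function(x, value) {
    GenomeInfoDb::seqlevels(value) <- GenomeInfoDb::seqlevels(x@seqinfo)
    GenomeInfoDb::seqinfo(value) <- x@seqinfo
    x@peaks <- GenomicRanges::sort(value)
    validObject(x)
    x
})
#' @rdname GenomeModel-accessors
setMethod("blacklistRegions", "GenomeModel", function(x) x@blacklist)
#' @rdname GenomeModel-accessors
setMethod("tssSites", "GenomeModel", function(x) {
    g <- x@genes
    if (length(g) == 0L) return(GRanges(seqinfo = x@seqinfo))
    pos <- ifelse(as.character(GenomicRanges::strand(g)) == "-",
                  GenomicRanges::end(g), GenomicRanges::start(g))
    out <- GRanges(GenomicRanges::seqnames(g), IRanges(pos, pos),
                   strand = GenomicRanges::strand(g))
    names(out) <- names(g)
    GenomeInfoDb::seqinfo(out) <- x@seqinfo
    out
})

setMethod("show", "GenomeModel", function(object) {
    sl <- GenomeInfoDb::seqlengths(object@seqinfo)
    cat("GenomeModel with", length(sl), "chromosome(s) (",
        format(sum(as.numeric(sl)), big.mark = ","), "bp )\n")
    cat("  genes:    ", length(object@genes), "\n")
    cat("  exons:    ", length(object@exons), "\n")
    cat("  peaks:    ", length(object@peaks), "\n")
    cat("  blacklist:", length(object@blacklist), "\n")
})
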