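#' @importFrom rtracklayer import export
#' @importFrom utils write.table read.delim packageVersion combn
NULL

# short deterministic hash of a config for provenance headers
.configHash <- function(config) {
    txt <- paste(deparse(config), collapse = "")
    raw <- utf8ToInt(txt)
    h <- 5381
    for (v in raw) h <- (h * 33 + v) %% 2147483647
    sprintf("%08x", as.integer(h))
}

.provHeader <- function(seed, config) {
    sprintf("# somiteMap %s | seed %s | config %s",
            as.character(utils::packageVersion("somiteMap")),
            as.character(seed),
            if (is.null(config)) "NA" else .configHash(config))
}

#' Write a table with a provenance header
#'
#' @param df data.frame.
#' @param file Output path.
#' @param seed Seed recorded in the header.
#' @param config Optional config whose hash is recorded.
#' @export
writeTableWithProvenance <- function(df, file, seed, config = NULL) {
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(.provHeader(seed, config), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' Write fragments as 3-column BED (0-based half-open)
#'
#' @param fragments \code{GRanges}.
#' @param file Output path.
#' @export
writeFragmentsBed <- function(fragments, file) {
    df <- data.frame(chrom = as.character(seqnames(fragments)),
                     start = start(fragments) - 1L,
                     end = end(fragments))
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(file)
}

#' Read fragments from BED
#'
#' @param file BED path.
#' @param seqlengths Optional named chromosome lengths.
#' @return \code{GRanges} of fragments.
#' @export
readFragmentsBed <- function(file, seqlengths = NULL) {
    gr <- rtracklayer::import(file, format = "BED")
    if (!is.null(seqlengths)) {
        GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
        GenomeInfoDb::seqlengths(gr) <- as.integer(seqlengths)
    }
    gr
}

#' Write a gene-model TSV (0-based half-open coordinates)
#'
#' Columns: gene, chrom, start, end, strand, tss.
#'
#' @param genome A \code{\link{GenomeModel}}.
#' @param file Output path.
#' @export
writeGeneModelTsv <- function(genome, file) {
    g <- geneBodies(genome)
    tss <- tssSites(genome)
    df <- data.frame(gene = names(g),
                     chrom = as.character(seqnames(g)),
                     start = start(g) - 1L, end = end(g),
                     strand = as.character(strand(g)),
                     tss = start(tss) - 1L)
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' Read a gene-model TSV written by \code{\link{writeGeneModelTsv}}
#'
#' @param file TSV path.
#' @param seqlengths Named chromosome lengths.
#' @return A \code{\link{GenomeModel}} (genes only).
#' @export
readGeneModelTsv <- function(file, seqlengths) {
    df <- utils::read.delim(file, comment.char = "#")
    g <- GRanges(df$chrom, IRanges(df$start + 1L, df$end),
                 strand = df$strand)
    names(g) <- df$gene
    GenomeModel(seqlengths, genes = g)
}

#' Export genome annotation and count tables of a run report
#'
#' Writes peaks and blacklist as BED, the gene model as TSV, and the main
#' result tables (QC report, per-family differential results, region
#' calls, linkage table, regulation scores) as TSV with provenance
#' headers.
#'
#' @param report Run report from \code{\link{runPipeline}}.
#' @param outdir Output directory (created if needed).
#' @param config The \code{\link{simulationConfig}} used.
#' @export
writeRunReport <- function(report, outdir, config) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    genome <- report$genome
    rtracklayer::export(peakSet(genome),
                        file.path(outdir, "peaks.bed"), format = "BED")
    if (length(blacklistRegions(genome)) > 0L)
        rtracklayer::export(blacklistRegions(genome),
                            file.path(outdir, "blacklist.bed"),
                            format = "BED")
    writeGeneModelTsv(genome, file.path(outdir, "gene_model.tsv"))
    seed <- report$seed
    writeTableWithProvenance(cbind(sample = rownames(report$qc),
                                   report$qc),
                             file.path(outdir, "qc_report.tsv"),
                             seed, config)
    for (nm in names(report$rna$tests))
        writeTableWithProvenance(report$rna$tests[[nm]],
            file.path(outdir, paste0("rna_", nm, ".tsv")), seed, config)
    for (nm in names(report$atac$regions))
        writeTableWithProvenance(report$atac$regions[[nm]],
            file.path(outdir, paste0("atac_regions_", nm, ".tsv")),
            seed, config)
    writeTableWithProvenance(report$linkage$links,
        file.path(outdir, "linkage.tsv"), seed, config)
    if (!is.null(report$linkage$regulation))
        writeTableWithProvenance(report$linkage$regulation,
            file.path(outdir, "regulation_scores.tsv"), seed, config)
    invisible(outdir)
}
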