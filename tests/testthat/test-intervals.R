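test_that("Tn5 shift emits +5/-4 insertions in half-open convention", {
    # 0-based [100, 300) is 1-based [101, 300]; insertions 105 and 296
    # (0-based) are 1-based 106 and 297
    fr <- tinyFragments(101, 200)
    ins <- shiftInsertions(fr)
    expect_equal(sort(GenomicRanges::start(ins)), c(106, 297))
    expect_false(any(ins$short))
})

test_that("Tn5 shift clips at bounds and flags short fragments", {
    fr <- tinyFragments(c(1, 999997), c(3, 3))
    expect_warning(ins <- shiftInsertions(fr), "clipped")
    expect_true(all(GenomicRanges::start(ins) >= 1))
    expect_true(all(ins$short))
    empty <- shiftInsertions(tinyFragments(integer(), integer()))
    expect_equal(length(empty), 0L)
})

test_that("window counting matches brute-force overlap enumeration", {
    gm <- GenomeModel(c(chr1 = 10000))
    set.seed(42)
    frs <- lapply(1:3, function(i) {
        s <- sample(1:9500, 60, replace = TRUE)
        tinyFragments(s, sample(80:400, 60, replace = TRUE),
                      c(chr1 = 10000))
    })
    names(frs) <- paste0("s", 1:3)
    ws <- countWindows(frs, gm, width = 150, step = 50, min_total = 0)
    win <- SummarizedExperiment::rowRanges(ws)
    cnt <- SummarizedExperiment::assay(ws, "counts")
    # independent O(F x W) oracle
    for (j in 1:3) {
        fs <- GenomicRanges::start(frs[[j]])
        fe <- GenomicRanges::end(frs[[j]])
        brute <- vapply(seq_along(win), function(w) {
            sum(fs <= GenomicRanges::end(win)[w] &
                fe >= GenomicRanges::start(win)[w])
        }, numeric(1))
        expect_equal(unname(cnt[, j]), brute)
    }
    # a single fragment [100, 300) overlaps windows starting 0..250 by 50
    one <- countWindows(list(a = tinyFragments(101, 200,
                                               c(chr1 = 10000))),
                        gm, min_total = 0)
    hit <- SummarizedExperiment::assay(one)[, 1] > 0
    st0 <- GenomicRanges::start(
        SummarizedExperiment::rowRanges(one))[hit] - 1L
    expect_equal(st0, seq(0L, 250L, by = 50L))
})

test_that("blacklisted fragments and low-total windows are excluded", {
    gm <- tinyGenome()  # blacklist [500000, 520000]
    fr <- tinyFragments(c(505000, 1000), c(200, 200))
    ws <- countWindows(list(a = fr), gm, min_total = 0)
    win <- SummarizedExperiment::rowRanges(ws)
    cnt <- SummarizedExperiment::assay(ws)[, 1]
    inbl <- IRanges::overlapsAny(win, blacklistRegions(gm))
    expect_true(all(cnt[inbl] == 0))
    # min_total filter empties the result
    ws2 <- countWindows(list(a = fr), gm, min_total = 75)
    expect_equal(nrow(ws2), 0L)
})

test_that("window filtering needs peak overlap and mean count >= 4", {
    gm <- tinyGenome()
    win <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(99950, 99950, 700000), width = 150))
    cnt <- rbind(c(4L, 4L, 4L), c(3L, 3L, 3L), c(100L, 100L, 100L))
    ws <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = cnt), rowRanges = win)
    kept <- filterWindows(ws, peakSet(gm))
    expect_equal(nrow(kept), 1L)           # row 1 only
    expect_equal(unname(SummarizedExperiment::assay(kept)[1, ]),
                 c(4L, 4L, 4L))
    expect_warning(out <- filterWindows(ws, GenomicRanges::GRanges()),
                   "empty peak")
    expect_equal(nrow(out), 0L)
})

test_that("window merging follows the gap rule and splits long spans", {
    w1 <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(1, 251), c(150, 400)))    # gap 100 -> merge
    m1 <- mergeWindows(w1)
    expect_equal(length(m1$regions), 1L)
    expect_equal(GenomicRanges::start(m1$regions), 1)
    expect_equal(GenomicRanges::end(m1$regions), 400)
    w2 <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(1, 401), c(150, 550)))    # gap 250 -> two
    expect_equal(length(mergeWindows(w2)$regions), 2L)
    # 3000 bp span -> 2 sub-regions of ~1500 bp, each within +/-100 bp
    w3 <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(seq(1, 2851, by = 50), width = 150))
    m3 <- mergeWindows(w3)
    expect_equal(length(m3$regions), 2L)
    expect_true(all(abs(GenomicRanges::width(m3$regions) - 1500) <= 100))
    expect_true(all(GenomicRanges::width(m3$regions) <= 1500))
    # every window assigned to each sub-region it overlaps
    expect_true(all(table(m3$map$region) > 0))
    expect_error(mergeWindows(rev(w2)), "sorted")
})

test_that("merging is idempotent and spans are preserved", {
    set.seed(7)
    st <- sort(sample(seq(1, 50000, by = 50), 120))
    w <- GenomicRanges::GRanges("chr1", IRanges::IRanges(st, width = 150))
    m <- mergeWindows(w)
    cov_w <- GenomicRanges::reduce(w)
    cov_r <- GenomicRanges::reduce(m$regions)
    spans <- GenomicRanges::reduce(w, min.gapwidth = 151L)
    # regions cover every window and never reach outside the merged spans
    expect_equal(sum(GenomicRanges::width(
        GenomicRanges::setdiff(cov_w, cov_r))), 0)
    expect_equal(sum(GenomicRanges::width(
        GenomicRanges::setdiff(cov_r, spans))), 0)
    # merging unsplit regions again changes nothing
    short <- m$regions[GenomicRanges::width(m$regions) <= 1500]
    m2 <- mergeWindows(GenomicRanges::sort(short))
    expect_true(length(m2$regions) <= length(short))
})

test_that("peak classification applies the precedence bands", {
    gm <- tinyGenome()
    # p1 straddles gA TSS (promoter even though exonic), p2 over an exon,
    # p3 ~20 kb from gA (proximal), p4 ~48 kb from gB (distal),
    # p5 > 100 kb from both (intergenic)
    cls <- classifyPeaks(peakSet(gm), gm)
    expect_equal(as.character(cls),
                 c("promoter", "exonic", "proximal", "distal",
                   "intergenic"))
    # exactly one class per peak; the table partitions the peak set
    expect_equal(sum(table(cls)), length(peakSet(gm)))
    expect_error(classifyPeaks(
        GenomicRanges::GRanges("chrZ", IRanges::IRanges(1, 10)), gm),
        "unknown chromosome")
})

test_that("proximal/distal bands are strand-independent", {
    gm <- tinyGenome()
    pk <- peakSet(gm)
    gmFlip <- GenomeModel(chromLengths(gm),
        genes = {
            g <- geneBodies(gm)
            GenomicRanges::strand(g) <-
                ifelse(as.character(GenomicRanges::strand(g)) == "+",
                       "-", "+")
            g
        },
        exons = geneExons(gm), blacklist = blacklistRegions(gm),
        peaks = pk)
    c1 <- classifyPeaks(pk, gm)
    c2 <- classifyPeaks(pk, gmFlip)
    # gene-body distance bands unchanged by flipping strands
    expect_equal(as.character(c1)[3:5], as.character(c2)[3:5])
})
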