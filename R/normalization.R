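#' @importFrom edgeR DGEList calcNormFactors estimateDisp glmQLFit
#'   glmQLFTest topTags cpm
NULL

#' Filter to expressed features
#'
#' Keeps features with at least 10 counts in three or more samples.
#'
#' @param counts Integer matrix (features x samples) or a
#'   \code{SummarizedExperiment} with a \code{counts} assay.
#' @param min_count,min_samples Rule parameters.
#' @return Object of the same type, restricted to retained features.
#' @export
filterExpressed <- function(counts, min_count = 10L, min_samples = 3L) {
    m <- if (is(counts, "SummarizedExperiment")) assay(counts, "counts")
         else counts
    if (ncol(m) < 3L) stop("need at least 3 samples to filter expression")
    keep <- rowSums(m >= min_count) >= min_samples
    counts[keep, , drop = FALSE]
}

#' Trimmed-mean-of-M-values size factors
#'
#' Composition-robust library size factors: the reference sample is the one
#' whose upper quartile is closest to the mean upper quartile; per sample,
#' M (log-ratio) and A (log-abundance) values over features positive in
#' both are doubly trimmed (30\% on M, 5\% on A) and combined by a
#' precision-weighted mean; factors are rescaled to geometric mean 1.
#' Computed with the edgeR implementation of the method.
#'
#' @param counts Integer matrix (features x samples).
#' @param trim_M,trim_A Trim fractions for M and A values.
#' @return Numeric vector of size factors (geometric mean 1), one per
#'   sample.
#' @export
tmmFactors <- function(counts, trim_M = 0.30, trim_A = 0.05) {
    if (ncol(counts) < 2L) stop("need at least 2 samples")
    if (any(colSums(counts) == 0)) stop("zero-count library")
    f <- edgeR::calcNormFactors(counts, method = "TMM",
                                logratioTrim = trim_M, sumTrim = trim_A)
    f / exp(mean(log(f)))
}

#' Normalized log2 counts-per-million
#'
#' \code{log2(CPM + pseudo)} against TMM-effective library sizes.
#'
#' @param counts Integer matrix.
#' @param factors Size factors from \code{\link{tmmFactors}}.
#' @param pseudo Pseudo-count added on the CPM scale.
#' @return Matrix of normalized log2 expression values.
#' @export
cpmLog <- function(counts, factors = tmmFactors(counts), pseudo = 0.5) {
    eff <- colSums(counts) * factors
    log2(sweep(counts, 2, eff, "/") * 1e6 + pseudo)
}

#' Abundance-dependent loess offsets for window counts
#'
#' For each sample, fits a loess curve (span 0.4, degree 1, evaluated on a
#' 200-point abundance grid and interpolated) of the sample's log2-count
#' deviation from the cross-sample average log2 abundance, against that
#' average abundance. The fitted values capture both the sample's depth and
#' its abundance-dependent efficiency bias; offsets are centered across
#' samples within each window so they encode no global per-window shift.
#'
#' @param ws Window counts: matrix or \code{SummarizedExperiment} with a
#'   \code{counts} assay; at least 100 windows.
#' @param span,degree Loess parameters.
#' @param grid_n Number of abundance grid points.
#' @return Matrix of log2-scale offsets (windows x samples), row-centered.
#'   Subtracting them from \code{log2(count + 0.5)} yields trend-corrected
#'   values (see \code{\link{offsetCorrectedLog}}).
#' @export
loessOffsets <- function(ws, span = 0.4, degree = 1, grid_n = 200L) {
    m <- if (is(ws, "SummarizedExperiment")) assay(ws, "counts") else ws
    if (nrow(m) < 100L)
        stop("fewer than 100 windows: loess curve unstable")
    l <- log2(m + 0.5)
    A <- rowMeans(l)
    grid <- seq(min(A), max(A), length.out = grid_n)
    off <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
    for (j in seq_len(ncol(m))) {
        dev <- l[, j] - A
        fit <- stats::loess(dev ~ A, span = span, degree = degree,
                            control = stats::loess.control(
                                surface = "interpolate"))
        fg <- stats::predict(fit, newdata = data.frame(A = grid))
        off[, j] <- stats::approx(grid, fg, xout = A, rule = 2)$y
    }
    off - rowMeans(off)
}

#' Offset-corrected log2 counts
#'
#' @param counts Window count matrix.
#' @param offsets Offsets from \code{\link{loessOffsets}} (log2 scale).
#' @param pseudo Pseudo-count.
#' @return \code{log2(counts + pseudo) - offsets}.
#' @export
offsetCorrectedLog <- function(counts, offsets, pseudo = 0.5) {
    log2(counts + pseudo) - offsets
}

#' Covariates of unwanted variation via residual PCA
#'
#' Fits per-feature least-squares group means for the stage-by-somite
#' design, performs PCA on the residual matrix, and selects the number of
#' components by permutation (parallel analysis): each feature's residuals
#' are permuted independently across samples, the spectrum is recomputed
#' \code{n_perm} times, and the retained components are the leading run
#' whose variance exceeds the permutation distribution at level
#' \code{alpha}. The covariates are the corresponding residual PC scores,
#' scaled to unit norm; by construction they are orthogonal to the design
#' column space.
#'
#' @param logmat Normalized log-scale matrix (features x samples).
#' @param groups Factor of group membership (one stage-by-somite group per
#'   sample), or a design matrix.
#' @param n_perm Number of permutations.
#' @param alpha Significance level for component retention.
#' @param seed Seed for the permutations.
#' @return List with \code{n_selected}, \code{covariates} (samples x
#'   n_selected, orthonormal; 0 columns when none selected),
#'   \code{var_share} (observed spectrum) and \code{perm_threshold}
#'   (per-component permutation quantile).
#' @export
residualPcaCovariates <- function(logmat, groups, n_perm = 100L,
                                  alpha = 0.05, seed = 1L) {
    X <- if (is.matrix(groups)) groups
         else stats::model.matrix(~0 + g,
                                  data = data.frame(g = factor(groups)))
    n <- ncol(logmat)
    if (n <= qr(X)$rank)
        stop("no residual degrees of freedom: samples <= groups")
    fit <- stats::lm.fit(X, t(logmat))
    R <- t(stats::residuals(fit))       # features x samples
    pc <- stats::prcomp(t(R), center = TRUE)
    v_obs <- pc$sdev^2
    v_obs <- v_obs / sum(v_obs)
    G <- nrow(R)
    perm_v <- withSeed(seed, {
        vapply(seq_len(n_perm), function(b) {
            key <- matrix(stats::runif(G * n), G, n)
            o <- order(row(key), key)
            Rp <- matrix(R[o], G, n, byrow = TRUE)
            # project out the design so the permuted spectrum lives in
            # the same residual subspace as the observed one
            Rp <- t(stats::residuals(stats::lm.fit(X, t(Rp))))
            d <- svd(scale(t(Rp), center = TRUE, scale = FALSE),
                     nu = 0, nv = 0)$d^2
            d <- d / sum(d)
            length(d) <- length(v_obs)
            d[is.na(d)] <- 0
            d
        }, numeric(length(v_obs)))
    })
    pvals <- (rowSums(perm_v >= v_obs) + 1) / (n_perm + 1)
    n_sel <- 0L
    for (i in seq_along(pvals)) {
        if (pvals[i] < alpha) n_sel <- i else break
    }
    max_k <- n - qr(X)$rank
    n_sel <- min(n_sel, max_k)
    cov <- pc$x[, seq_len(n_sel), drop = FALSE]
    if (n_sel > 0L)
        cov <- sweep(cov, 2, sqrt(colSums(cov^2)), "/")
    list(n_selected = n_sel, covariates = cov, var_share = v_obs,
         perm_threshold = apply(perm_v, 1, stats::quantile,
                                probs = 1 - alpha),
         pvals = pvals)
}

#' Remove covariate-captured variation from a log matrix
#'
#' Projects out the span of the (orthonormal) unwanted-variation
#' covariates from each feature's values, leaving the design signal (to
#' which the covariates are orthogonal) untouched.
#'
#' @param logmat Features x samples matrix.
#' @param covariates Samples x k orthonormal matrix from
#'   \code{\link{residualPcaCovariates}}.
#' @return Corrected matrix of the same shape.
#' @export
removeCovariateEffects <- function(logmat, covariates) {
    if (is.null(covariates) || ncol(covariates) == 0L) return(logmat)
    logmat - (logmat %*% covariates) %*% t(covariates)
}
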