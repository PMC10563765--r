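#' Build the stage-by-somite contrast families
#'
#' Emits the four contrast families over the group means
#' \code{stage<k>.<somite>}: (1) each somite-age pair averaged over all
#' stages (weights +/- 1/(number of stages)); (2) all somite-age pairs
#' within each stage, grouped into one joint test per stage (the p-value
#' asks whether the feature differs between at least one pair of somite
#' ages at that stage); (3) each stage pair averaged over somite ages
#' (weights +/- 1/(number of somite ages)), all pairs grouped into one
#' joint test; (4) all stage pairs within each somite age, grouped per
#' somite age.
#'
#' @param stages Vector of stages (e.g. \code{c(8,18,21,25,27,35)}).
#' @param somites Character vector of somite ages, e.g.
#'   \code{c("SI","SII","SIII")}.
#' @return Named list of contrast families; each is a list with
#'   \code{name}, \code{weights} (groups x contrasts matrix, columns sum
#'   to 0) and \code{joint} (logical: tested as one multi-df test).
#' @examples
#' fam <- buildContrasts(c(8, 18), c("SI", "SII", "SIII"))
#' fam[[1]]$weights
#' @export
buildContrasts <- function(stages, somites) {
    if (length(stages) < 1L || length(somites) < 2L)
        stop("need at least one stage and two somite ages")
    groups <- as.vector(outer(somites, stages,
                              function(s, k) paste0("stage", k, ".", s)))
    ns <- length(stages); na <- length(somites)
    col <- function(pairs) {
        L <- matrix(0, length(groups), length(pairs),
                    dimnames = list(groups, names(pairs)))
        for (j in seq_along(pairs)) {
            w <- pairs[[j]]
            L[names(w), j] <- w
        }
        L
    }
    fam <- list()
    # family 1: somite pairs averaged across stages (single-df each)
    for (p in utils::combn(seq_len(na), 2, simplify = FALSE)) {
        i <- somites[p[1]]; j <- somites[p[2]]
        w <- c(stats::setNames(rep(1 / ns, ns),
                               paste0("stage", stages, ".", i)),
               stats::setNames(rep(-1 / ns, ns),
                               paste0("stage", stages, ".", j)))
        nm <- paste0("somite_", i, ".vs.", j)
        fam[[nm]] <- list(name = nm,
                          weights = col(stats::setNames(list(w), nm)),
                          joint = FALSE)
    }
    # family 2: per-stage somite pairs, one joint test per stage
    for (k in stages) {
        pairs <- lapply(utils::combn(seq_len(na), 2, simplify = FALSE),
            function(p) {
                stats::setNames(c(1, -1),
                    paste0("stage", k, ".", somites[p]))
            })
        names(pairs) <- vapply(utils::combn(seq_len(na), 2,
                                            simplify = FALSE),
            function(p) paste0("somite_", somites[p[1]], ".vs.",
                               somites[p[2]], ".stage_", k), character(1))
        nm <- paste0("somite.stage_", k)
        fam[[nm]] <- list(name = nm, weights = col(pairs), joint = TRUE)
    }
    # family 3: stage pairs averaged across somite ages, one joint test
    if (ns >= 2L) {
        sp <- utils::combn(seq_len(ns), 2, simplify = FALSE)
        pairs <- lapply(sp, function(p) {
            c(stats::setNames(rep(1 / na, na),
                  paste0("stage", stages[p[1]], ".", somites)),
              stats::setNames(rep(-1 / na, na),
                  paste0("stage", stages[p[2]], ".", somites)))
        })
        names(pairs) <- vapply(sp, function(p)
            paste0("stage_", stages[p[1]], ".vs.", stages[p[2]]),
            character(1))
        fam[["stage.average"]] <- list(name = "stage.average",
                                       weights = col(pairs), joint = TRUE)
        # family 4: per-somite-age stage pairs
        for (i in somites) {
            pairs <- lapply(sp, function(p) {
                stats::setNames(c(1, -1),
                    paste0("stage", stages[p], ".", i))
            })
            names(pairs) <- vapply(sp, function(p)
                paste0("stage_", stages[p[1]], ".vs.", stages[p[2]],
                       ".somite_", i), character(1))
            nm <- paste0("stage.somite_", i)
            fam[[nm]] <- list(name = nm, weights = col(pairs),
                              joint = TRUE)
        }
    }
    fam
}

#' Fit per-feature negative-binomial GLMs
#'
#' Fits the group-mean design (one coefficient per stage-by-somite group)
#' plus optional unwanted-variation covariates, with per-feature NB
#' dispersion estimated and shrunk toward the mean-dispersion trend
#' (empirical Bayes, robustified) and quasi-likelihood variance modeling
#' (the edgeR glmQLFit machinery).
#'
#' @param counts Integer matrix (features x samples), filtered.
#' @param groups Factor of group membership; levels become design columns.
#' @param covariates Optional samples x k matrix (orthogonal to the
#'   design).
#' @param offsets Optional features x samples matrix of log2-scale offsets
#'   (from \code{\link{loessOffsets}}); when absent, TMM size factors are
#'   used.
#' @return An object of class \code{NbGlmFit} wrapping the fitted model.
#' @export
fitNbGlm <- function(counts, groups, covariates = NULL, offsets = NULL) {
    groups <- factor(groups)
    design <- stats::model.matrix(~0 + groups)
    colnames(design) <- levels(groups)
    if (!is.null(covariates) && ncol(covariates) > 0L) {
        colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
        design <- cbind(design, covariates)
    }
    y <- edgeR::DGEList(counts = counts)
    if (is.null(offsets)) {
        y <- edgeR::calcNormFactors(y)
    } else {
        y <- edgeR::scaleOffset(y, log(2) * offsets +
                                    log(mean(colSums(counts))))
    }
    y <- edgeR::estimateDisp(y, design, robust = TRUE)
    fit <- edgeR::glmQLFit(y, design, robust = TRUE)
    structure(list(fit = fit, design = design,
                   group_levels = levels(groups)),
              class = "NbGlmFit")
}

#' Test contrast families on a fitted model
#'
#' Single-contrast families yield one-df quasi-likelihood F-tests; grouped
#' families yield one joint multi-df test per family (the p-value asks
#' whether the feature differs for at least one member contrast).
#' Benjamini-Hochberg correction is applied across features within each
#' family; a feature is called significant when FDR < \code{fdr} and its
#' absolute fold-change exceeds \code{fc} (for joint families, the largest
#' absolute member fold-change is used for the gate and reported).
#'
#' @param fitobj \code{NbGlmFit} from \code{\link{fitNbGlm}}.
#' @param contrasts Contrast families from \code{\link{buildContrasts}}.
#' @param fdr FDR level.
#' @param fc Fold-change threshold (natural scale).
#' @return Named list of data.frames (one per family) with columns
#'   \code{feature}, \code{logFC} (log2; signed single-contrast value, or
#'   the member value of largest magnitude for joint families),
#'   \code{PValue}, \code{FDR}, \code{call}.
#' @export
testContrasts <- function(fitobj, contrasts, fdr = 0.05, fc = 1.5) {
    stopifnot(inherits(fitobj, "NbGlmFit"))
    design_cols <- colnames(fitobj$design)
    lapply(contrasts, function(fm) {
        W <- fm$weights
        missing <- setdiff(rownames(W), design_cols)
        if (length(missing) > 0L)
            stop("contrast group(s) absent from design: ",
                 paste(missing, collapse = ", "))
        L <- matrix(0, length(design_cols), ncol(W),
                    dimnames = list(design_cols, colnames(W)))
        L[rownames(W), ] <- W
        res <- edgeR::glmQLFTest(fitobj$fit, contrast = L)
        tab <- res$table
        if (ncol(W) == 1L) {
            lfc <- tab$logFC
        } else {
            lfcm <- as.matrix(tab[, grep("^logFC", colnames(tab)),
                                  drop = FALSE])
            pickmax <- max.col(abs(lfcm), ties.method = "first")
            lfc <- lfcm[cbind(seq_len(nrow(lfcm)), pickmax)]
        }
        p <- tab$PValue
        adj <- stats::p.adjust(p, method = "BH")
        data.frame(feature = rownames(tab), logFC = lfc, PValue = p,
                   FDR = adj,
                   call = adj < fdr & abs(lfc) > log2(fc),
                   row.names = NULL, stringsAsFactors = FALSE)
    })
}

#' Simes combined p-value
#'
#' \code{min_i (n * p_(i) / i)} over the sorted member p-values; equals the
#' single p-value when n = 1. Ties in the sort are broken by original
#' order (deterministic).
#'
#' @param p Numeric vector of member p-values.
#' @return The combined p-value.
#' @examples
#' simesP(c(0.01, 0.03, 0.04))   # 0.03
#' @export
simesP <- function(p) {
    p <- p[!is.na(p)]
    n <- length(p)
    if (n == 0L) return(NA_real_)
    ps <- p[order(p)]            # stable: ties keep original order
    min(n * ps / seq_len(n))
}

#' Combine window-level tests into region-level results
#'
#' Each region's p-value is the Simes combination of its member windows'
#' p-values; the region fold-change is that of the member window with the
#' smallest p-value (ties broken by original window order). Multiple
#' testing is corrected at the region level (BH), and regions are called
#' at FDR < \code{fdr} with |fold-change| > \code{fc}.
#'
#' @param window_result data.frame with per-window \code{PValue} and
#'   \code{logFC} (rows in window order).
#' @param merged Result of \code{\link{mergeWindows}} on the same windows.
#' @param fdr,fc Significance thresholds.
#' @return data.frame with one row per region: \code{region} (index into
#'   \code{merged$regions}), \code{n_windows}, \code{PValue}, \code{FDR},
#'   \code{logFC}, \code{call}.
#' @export
combineRegions <- function(window_result, merged, fdr = 0.05, fc = 1.5) {
    map <- merged$map
    nreg <- length(merged$regions)
    empty <- setdiff(seq_len(nreg), unique(map$region))
    if (length(empty) > 0L)
        warning(length(empty), " region(s) without tested windows dropped")
    keep <- sort(unique(map$region))
    rows <- lapply(keep, function(r) {
        w <- map$window[map$region == r]
        p <- window_result$PValue[w]
        best <- w[which.min(p)]      # which.min is first-of-ties
        data.frame(region = r, n_windows = length(w),
                   PValue = simesP(p),
                   logFC = window_result$logFC[best])
    })
    out <- do.call(rbind, rows)
    out$FDR <- stats::p.adjust(out$PValue, method = "BH")
    out$call <- out$FDR < fdr & abs(out$logFC) > log2(fc)
    out[, c("region", "n_windows", "PValue", "FDR", "logFC", "call")]
}
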