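#' Two-group differential expression on a complete log2 matrix
#'
#' Per feature: equal-variance two-tailed Student's t-test (Welch by
#' `varEqual = FALSE`), Benjamini-Hochberg correction over all features,
#' and the conjunction call rule: significant when BH-adjusted p < `alpha`
#' and |log2 fold change| > `fcThreshold` (default 0.585 = log2(1.5)).
#' The fold change is mean(first group) - mean(second group), first group
#' = first `group_label` appearing in the design.
#'
#' @param m a complete [ProteoSet-class] (post-imputation) on log2 scale.
#' @param design data.frame `sample_id`, `group_label` (exactly 2 labels,
#'   each with >= 2 samples).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param fcThreshold |log2 FC| cutoff (default 0.585).
#' @param varEqual pooled-variance Student's t (default) or Welch.
#' @return data.frame `feature_id`, `log2fc`, `p_value`, `bh_adjusted_p`,
#'   `significant`, `direction` (`up`/`down`/`ns`).  Features with zero
#'   variance in both groups and equal means get p = 1 by convention.
#' @export
differentialExpression <- function(m, design, alpha = 0.05,
                                   fcThreshold = 0.585, varEqual = TRUE) {
    v <- .values(.asProteoSet(m))
    if (anyNA(v)) stop("matrix must be complete (impute first)")
    labs <- unique(design$group_label)
    if (length(labs) != 2L) stop("exactly 2 group labels required")
    g1 <- design$sample_id[design$group_label == labs[1L]]
    g2 <- design$sample_id[design$group_label == labs[2L]]
    if (length(g1) < 2L || length(g2) < 2L)
        stop("each group needs >= 2 samples")
    i1 <- match(g1, colnames(v)); i2 <- match(g2, colnames(v))
    if (anyNA(c(i1, i2))) stop("design references unknown sample ids")
    X1 <- v[, i1, drop = FALSE]; X2 <- v[, i2, drop = FALSE]
    n1 <- length(i1); n2 <- length(i2)
    m1 <- rowMeans(X1); m2 <- rowMeans(X2)
    v1 <- apply(X1, 1L, stats::var); v2 <- apply(X2, 1L, stats::var)
    fc <- m1 - m2
    if (varEqual) {
        sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
        se <- sqrt(sp2 * (1 / n1 + 1 / n2))
        df <- rep(n1 + n2 - 2, nrow(v))
    } else {
        se <- sqrt(v1 / n1 + v2 / n2)
        df <- (v1 / n1 + v2 / n2)^2 /
            ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    }
    t <- fc / se
    p <- 2 * stats::pt(-abs(t), df)
    p[se == 0 & fc == 0] <- 1        # degenerate: no variance, no change
    p[se == 0 & fc != 0] <- 0
    bh <- stats::p.adjust(p, method = "BH")
    sig <- bh < alpha & abs(fc) > fcThreshold
    data.frame(feature_id = rownames(v), log2fc = fc, p_value = p,
               bh_adjusted_p = bh, significant = sig,
               direction = ifelse(!sig, "ns",
                                  ifelse(fc > 0, "up", "down")),
               row.names = NULL)
}

#' Replicate-subsampling differential-expression simulation
#'
#' Draws `kPerGroup` samples per group without replacement, runs
#' [differentialExpression()], and repeats `nRepeats` times (the
#' "Random 5" / "Random 3" designs with k = 5 or 3 against a 10 + 10
#' gold standard).  Reports the per-repeat significant counts and, for
#' volcano construction, the per-feature medians of the adjusted p-values
#' and fold changes across repeats (medians taken independently, so a
#' reported pair need not co-occur in any single repeat).
#'
#' @param m complete [ProteoSet-class].
#' @param design data.frame `sample_id`, `group_label`.
#' @param kPerGroup replicates drawn per group (<= group size).
#' @param nRepeats number of repeats (default 100).
#' @param seed integer seed for the draws.
#' @param alpha,fcThreshold,varEqual passed to
#'   [differentialExpression()].
#' @return list with `counts` (integer per repeat), `median_table`
#'   (data.frame `feature_id`, `median_log2fc`, `median_p`,
#'   `median_bh_p`, `significant`), `kPerGroup`, `nRepeats`.
#' @export
subsampleDE <- function(m, design, kPerGroup, nRepeats = 100L, seed = NULL,
                        alpha = 0.05, fcThreshold = 0.585,
                        varEqual = TRUE) {
    labs <- unique(design$group_label)
    if (length(labs) != 2L) stop("exactly 2 group labels required")
    byGroup <- split(design$sample_id, design$group_label)[labs]
    if (any(vapply(byGroup, length, 0L) < kPerGroup))
        stop("kPerGroup exceeds a group size")
    withSeed(seed, {
        counts <- integer(nRepeats)
        pMat <- fcMat <- bhMat <- NULL
        for (r in seq_len(nRepeats)) {
            sub <- data.frame(
                sample_id = c(sample(byGroup[[1L]], kPerGroup),
                              sample(byGroup[[2L]], kPerGroup)),
                group_label = rep(labs, each = kPerGroup))
            de <- differentialExpression(m, sub, alpha, fcThreshold,
                                         varEqual)
            counts[r] <- sum(de$significant)
            if (is.null(pMat)) {
                pMat <- fcMat <- bhMat <-
                    matrix(NA_real_, nrow(de), nRepeats)
                rownames(pMat) <- de$feature_id
            }
            pMat[, r] <- de$p_value
            fcMat[, r] <- de$log2fc
            bhMat[, r] <- de$bh_adjusted_p
        }
        medP <- apply(pMat, 1L, stats::median)
        medFc <- apply(fcMat, 1L, stats::median)
        medBh <- apply(bhMat, 1L, stats::median)
        medianTable <- data.frame(
            feature_id = rownames(pMat), median_log2fc = medFc,
            median_p = medP, median_bh_p = medBh,
            significant = medBh < alpha & abs(medFc) > fcThreshold,
            row.names = NULL)
        list(counts = counts, median_table = medianTable,
             kPerGroup = kPerGroup, nRepeats = nRepeats)
    })
}

#' Compare subsampled calls to the full-data gold standard
#'
#' The full-replicate analysis defines the gold-standard significant set;
#' the subsampling run is summarized by its median-based calls, and the
#' two sets are compared by overlap and Jaccard index.
#'
#' @param full output of [differentialExpression()] on the full design.
#' @param sub output of [subsampleDE()] on the same feature universe.
#' @return list `n_gold`, `n_sub_median`, `n_overlap`, `jaccard`.
#' @export
goldStandardCompare <- function(full, sub) {
    gold <- full$feature_id[full$significant]
    subSig <- sub$median_table$feature_id[sub$median_table$significant]
    inter <- length(intersect(gold, subSig))
    uni <- length(union(gold, subSig))
    list(n_gold = length(gold), n_sub_median = length(subSig),
         n_overlap = inter,
         jaccard = if (uni == 0L) 1 else inter / uni)
}
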