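#' Normalized root mean square error
#'
#' \deqn{NRMSE = \sqrt{mean((y_o - y_i)^2) / var(y_o)}}
#' where \eqn{y_o} are the hidden original values and \eqn{y_i} the
#' imputed values at the masked cells.  The variance is the sample
#' variance (n-1 denominator).  0 means perfect recovery; a constant
#' mean-level imputer tends to 1.
#'
#' @param ev a [MaskedEvaluation-class].
#' @return A [CriterionScore-class] (`lower_better`).
#' @examples
#' ev <- new("MaskedEvaluation", yo = c(2, 4, 6, 8), yi = c(3, 3, 7, 7),
#'           featureIndex = 1:4)
#' scoreValue(nrmse(ev))   # sqrt(1 / (20/3)) = 0.3873
#' @export
nrmse <- function(ev) {
    yo <- originalValues(ev)
    yi <- imputedValues(ev)
    n <- length(yo)
    if (n < 2L)
        return(.score("NRMSE", NA, "lower_better", n,
                      "fewer than 2 masked cells"))
    vy <- stats::var(yo)
    if (vy <= 0)
        return(.score("NRMSE", NA, "lower_better", n,
                      "zero variance of original values"))
    .score("NRMSE", sqrt(mean((yo - yi)^2) / vy), "lower_better", n)
}

#' NRMSE-based sum of ranks across missing variables
#'
#' For every variable (feature) with masked cells, the competing methods
#' are ranked by their error on that variable (1 = best, average ranks on
#' ties); SOR is each method's rank total over all such variables.  A
#' method that is consistently good scores near the minimum V (number of
#' variables); rank-sum conservation guarantees the per-variable totals
#' add to V*M*(M+1)/2 for M methods.  Because the per-variable NRMSE
#' denominator (variance of the hidden values of that variable) is the
#' same for every method, ranking by per-variable mean squared error is
#' rank-identical to per-variable NRMSE and is what is computed; this also
#' covers variables with a single masked cell, where a variance-normalized
#' error is undefined.
#'
#' @param evsByMethod named list of [MaskedEvaluation-class], all sharing
#'   the same masked coordinates (same mask, different methods).
#' @return named list of [CriterionScore-class] (`lower_better`), one per
#'   method; `nUsed` is the number of contributing variables.
#' @export
sor <- function(evsByMethod) {
    if (length(evsByMethod) < 2L)
        stop("SOR needs at least 2 methods to rank")
    fi <- evsByMethod[[1L]]@featureIndex
    for (ev in evsByMethod)
        if (!identical(ev@featureIndex, fi) ||
            !identical(ev@yo, evsByMethod[[1L]]@yo))
            stop("all methods must be evaluated on the same mask")
    f <- factor(fi)
    mseByVar <- vapply(evsByMethod, function(ev) {
        se <- (ev@yo - ev@yi)^2
        vapply(split(se, f), mean, 0)
    }, numeric(nlevels(f)))
    mseByVar <- matrix(mseByVar, nrow = nlevels(f),
                       dimnames = list(levels(f), names(evsByMethod)))
    ranks <- t(apply(mseByVar, 1L, rank))   # average ranks on ties
    sums <- colSums(ranks)
    out <- lapply(names(evsByMethod), function(m)
        .score("SOR", sums[[m]], "lower_better", nlevels(f)))
    names(out) <- names(evsByMethod)
    out
}

#' Correlation between original and imputed values
#'
#' Pearson correlation of \eqn{y_o} against \eqn{y_i} over the masked
#' cells.  Constant imputers (zero, minimum, ...) have zero imputed-value
#' spread, so the correlation is undefined and the score is reported
#' missing with that reason rather than as a number.
#'
#' @param ev a [MaskedEvaluation-class].
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A [CriterionScore-class] (`higher_better`).
#' @export
accOI <- function(ev, method = c("pearson", "spearman")) {
    method <- match.arg(method)
    yo <- originalValues(ev)
    yi <- imputedValues(ev)
    n <- length(yo)
    if (n < 3L)
        return(.score("ACC_OI", NA, "higher_better", n,
                      "fewer than 3 masked cells"))
    if (stats::sd(yi) == 0 || stats::sd(yo) == 0)
        return(.score("ACC_OI", NA, "higher_better", n,
                      "constant values: correlation undefined"))
    .score("ACC_OI", stats::cor(yo, yi, method = method),
           "higher_better", n)
}

#' Procrustes statistic on PCA sample configurations
#'
#' Samples of the original and the imputed matrix are each projected onto
#' their first `nComponents` principal components (features as variables,
#' centered, unscaled); the imputed configuration is then optimally
#' translated, rotated/reflected and isotropically scaled onto the
#' original one, and the criterion is the residual sum of squared
#' differences after superposition.  0 means the imputation did not
#' distort the sample-space geometry.  PCA axis sign indeterminacy is
#' absorbed by the rotation.
#'
#' @param original,imputed complete [ProteoSet-class] objects (or
#'   matrices) of identical dimension.
#' @param nComponents number of principal components (default 2; clamped
#'   to the available dimensions with a warning).
#' @return A [CriterionScore-class] (`lower_better`); `nUsed` is the
#'   number of samples.
#' @export
pssProcrustes <- function(original, imputed, nComponents = 2L) {
    vo <- .values(.asProteoSet(original))
    vi <- .values(.asProteoSet(imputed))
    if (!all(dim(vo) == dim(vi)))
        stop("matrices differ in dimension")
    if (anyNA(vo) || anyNA(vi))
        stop("Procrustes comparison needs complete matrices")
    kmax <- min(ncol(vo) - 1L, nrow(vo))   # samples are the observations
    if (nComponents > kmax) {
        warning("nComponents clamped to ", kmax)
        nComponents <- kmax
    }
    so <- stats::prcomp(t(vo), center = TRUE,
                        scale. = FALSE)$x[, seq_len(nComponents),
                                          drop = FALSE]
    si <- stats::prcomp(t(vi), center = TRUE,
                        scale. = FALSE)$x[, seq_len(nComponents),
                                          drop = FALSE]
    fit <- vegan::procrustes(so, si, scale = TRUE, symmetric = FALSE)
    .score("PSS", fit$ss, "lower_better", ncol(vo))
}
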