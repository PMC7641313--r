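#' Summarize data completeness
#'
#' Missing-value prevalence of a quantification matrix: overall counts, the
#' fraction of features carrying at least one missing cell (the headline
#' completeness figure for DIA/SWATH data), and per-sample missing counts.
#'
#' @param m a [ProteoSet-class] or numeric matrix.
#' @return list with `n_features`, `n_samples`, `n_missing_cells`,
#'   `fraction_features_with_any_na`, `per_sample_counts` (named integer).
#' @examples
#' v <- matrix(c(1, NA, 3, 4, 5, 6), 3, 2,
#'             dimnames = list(c("a", "b", "c"), c("s1", "s2")))
#' completenessSummary(ProteoSet(v))
#' @export
completenessSummary <- function(m) {
    v <- .values(.asProteoSet(m))
    miss <- is.na(v)
    list(n_features = nrow(v),
         n_samples = ncol(v),
         n_missing_cells = sum(miss),
         fraction_features_with_any_na = mean(rowSums(miss) > 0),
         per_sample_counts = colSums(miss))
}

#' Filter features by missing-value fraction
#'
#' Retains exactly the features whose fraction of missing cells is at most
#' `maxNaFraction`; feature order is preserved.  Features that are mostly
#' missing carry little information for imputation benchmarking and can be
#' discarded before the analysis.
#'
#' @param m a [ProteoSet-class].
#' @param maxNaFraction maximum tolerated missing fraction per feature, in
#'   `[0, 1]` (default 0.5).
#' @return The filtered [ProteoSet-class].
#' @export
filterByNA <- function(m, maxNaFraction = 0.5) {
    stopifnot(maxNaFraction >= 0, maxNaFraction <= 1)
    m <- .asProteoSet(m)
    frac <- rowMeans(is.na(.values(m)))
    keep <- frac <= maxNaFraction
    if (!any(keep))
        stop("all ", length(keep), " features exceed the NA threshold ",
             maxNaFraction, " (min observed fraction ",
             format(min(frac), digits = 3), ")")
    m[keep, ]
}

#' Filter features by coefficient of variation
#'
#' CV = 100 * sd/mean, computed on raw-scale intensities over observed
#' values only (log2-scale input is un-logged for the computation; a CV on
#' log values is not scale-meaningful).  With a design table, a feature is
#' removed only when its CV exceeds the threshold in *every* group, so
#' genuinely regulated features -- variable overall but tight within
#' groups -- survive.
#'
#' @param m a [ProteoSet-class].
#' @param maxCvPercent CV threshold in percent (> 0).
#' @param design optional data.frame (`sample_id`, `group_label`).
#' @return The filtered [ProteoSet-class].  Features with fewer than 2
#'   observed values (per group, when grouped) have an undefined CV and are
#'   retained with a warning.
#' @export
filterByCV <- function(m, maxCvPercent, design = NULL) {
    stopifnot(maxCvPercent > 0)
    m <- .asProteoSet(m)
    v <- .values(m)
    raw <- if (identical(scaleTag(m), "log2")) 2^v else v
    cvOf <- function(x) {
        x <- x[!is.na(x)]
        if (length(x) < 2L) return(NA_real_)
        100 * stats::sd(x) / mean(x)
    }
    if (is.null(design)) {
        cv <- apply(raw, 1L, cvOf)
        exceed <- !is.na(cv) & cv > maxCvPercent
        undef <- is.na(cv)
    } else {
        idx <- split(match(design$sample_id, colnames(v)),
                     design$group_label)
        cvs <- vapply(idx, function(j) apply(raw[, j, drop = FALSE], 1, cvOf),
                      numeric(nrow(raw)))
        cvs <- matrix(cvs, nrow = nrow(raw))
        # removed only when above threshold in every group with a defined CV
        exceed <- apply(cvs, 1L, function(x) {
            x <- x[!is.na(x)]
            length(x) > 0L && all(x > maxCvPercent)
        })
        undef <- apply(cvs, 1L, function(x) all(is.na(x)))
    }
    if (any(undef))
        warning(sum(undef), " feature(s) with < 2 observed values: ",
                "CV undefined, retained")
    keep <- !exceed
    if (!any(keep)) stop("all ", length(keep),
                         " features exceed the CV threshold")
    m[keep, ]
}
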