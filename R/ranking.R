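#' Score a batch of imputation results on all applicable criteria
#'
#' Runs the classic criteria (NRMSE, SOR, ACC_OI, PSS) against the masked
#' ground truth and the proteomic criteria (ACC_Charge, ACC_PepProt,
#' ACC_CORUM, ACC_PPI) on each completed matrix, then assembles the
#' [ScoreTable-class]: raw scores, max-normalized scores, per-criterion
#' ranks and per-family composite ranks.
#'
#' @param original the complete [ProteoSet-class] that was masked.
#' @param results named list of [ImputationResult-class] (from
#'   [runMethods()]).
#' @param spec the [MaskSpec-class].
#' @param ann optional feature annotation (enables charge/peptide
#'   criteria).
#' @param complexCatalog,ppiCatalog optional [GroupCatalog-class] objects
#'   (enable ACC_CORUM / ACC_PPI).
#' @param divisor passed to [groupPairwiseAcc()].
#' @param weights optional named per-criterion weights for the composite
#'   ranks.
#' @return A [ScoreTable-class].
#' @export
evaluateImputations <- function(original, results, spec, ann = NULL,
                                complexCatalog = NULL, ppiCatalog = NULL,
                                divisor = "pairs", weights = NULL) {
    stopifnot(length(results) >= 1L)
    methods <- names(results)
    evs <- lapply(results, function(r) pairEvaluation(original, r, spec))
    scoreList <- list()
    for (m in methods) {
        scoreList[[m]] <- list(nrmse(evs[[m]]), accOI(evs[[m]]),
                               pssProcrustes(original,
                                             imputedMatrix(results[[m]])))
    }
    if (length(results) >= 2L) {
        sors <- sor(evs)
        for (m in methods)
            scoreList[[m]] <- c(scoreList[[m]], list(sors[[m]]))
    }
    if (!is.null(ann)) {
        for (m in methods)
            scoreList[[m]] <- c(scoreList[[m]], list(
                accCharge(imputedMatrix(results[[m]]), ann,
                          divisor = divisor),
                accPepProt(imputedMatrix(results[[m]]), ann,
                           divisor = divisor)))
    }
    if (!is.null(complexCatalog))
        for (m in methods)
            scoreList[[m]] <- c(scoreList[[m]], list(
                accComplex(imputedMatrix(results[[m]]), ann, complexCatalog,
                           divisor = divisor)))
    if (!is.null(ppiCatalog))
        for (m in methods)
            scoreList[[m]] <- c(scoreList[[m]], list(
                accPpi(imputedMatrix(results[[m]]), ann, ppiCatalog,
                       divisor = divisor)))
    .assembleScoreTable(scoreList, weights)
}

.criterionFamily <- function(criteria) {
    ifelse(criteria %in% c("NRMSE", "SOR", "ACC_OI", "PSS"),
           "classic", "proteomic")
}

.assembleScoreTable <- function(scoreList, weights = NULL) {
    methods <- names(scoreList)
    criteria <- unique(unlist(lapply(scoreList, function(l)
        vapply(l, methods::slot, "", "criterion"))))
    raw <- matrix(NA_real_, length(methods), length(criteria),
                  dimnames = list(methods, criteria))
    reasons <- matrix("", length(methods), length(criteria),
                      dimnames = list(methods, criteria))
    directions <- stats::setNames(rep(NA_character_, length(criteria)),
                                  criteria)
    for (m in methods)
        for (sc in scoreList[[m]]) {
            raw[m, sc@criterion] <- sc@value
            reasons[m, sc@criterion] <- sc@reason
            directions[sc@criterion] <- sc@direction
        }
    normalized <- normalizeScores(raw, directions)
    ranks <- .perCriterionRanks(raw, directions)
    composite <- .compositeRanks(ranks, directions, weights)
    new("ScoreTable", raw = raw, normalized = normalized, ranks = ranks,
        directions = directions, reasons = reasons, composite = composite)
}

#' Max-normalize a raw score grid
#'
#' Higher-is-better criteria are divided by their maximum defined score;
#' lower-is-better criteria (NRMSE, SOR, PSS) are mapped to `min/value`,
#' so in both cases the best method scores 1 and the raw values stay
#' interpretable alongside.  Missing scores stay missing.  A
#' higher-is-better criterion whose maximum is 0 cannot be scaled and is
#' left unnormalized (all-NA column) with a warning.
#'
#' @param raw methods x criteria matrix.
#' @param directions named character vector (`"lower_better"` /
#'   `"higher_better"`) per criterion.
#' @return matrix of the same shape.
#' @export
normalizeScores <- function(raw, directions) {
    out <- raw
    for (cr in colnames(raw)) {
        x <- raw[, cr]
        if (all(is.na(x))) next
        if (directions[[cr]] == "higher_better") {
            mx <- max(x, na.rm = TRUE)
            if (mx == 0) {
                warning("criterion ", cr, ": max = 0, normalization skipped")
                out[, cr] <- NA_real_
            } else out[, cr] <- x / mx
        } else {
            mn <- min(x, na.rm = TRUE)
            norm <- mn / x
            norm[!is.na(x) & x == mn] <- 1   # covers a perfect 0 score
            out[, cr] <- norm
        }
    }
    out
}

.perCriterionRanks <- function(raw, directions) {
    ranks <- raw
    nM <- nrow(raw)
    for (cr in colnames(raw)) {
        x <- raw[, cr]
        key <- if (directions[[cr]] == "higher_better") -x else x
        r <- rep(NA_real_, nM)
        def <- !is.na(key)
        r[def] <- rank(key[def])
        r[!def] <- nM           # a method with no score ranks worst
        ranks[, cr] <- r
    }
    ranks
}

.compositeRanks <- function(ranks, directions, weights = NULL) {
    fam <- .criterionFamily(colnames(ranks))
    out <- list()
    for (f in c("classic", "proteomic")) {
        cols <- colnames(ranks)[fam == f]
        if (!length(cols)) next
        w <- if (is.null(weights)) stats::setNames(rep(1, length(cols)),
                                                   cols)
             else {
                 wi <- weights[cols]
                 wi[is.na(wi)] <- 1
                 stats::setNames(as.numeric(wi), cols)
             }
        use <- cols[w > 0]
        if (!length(use)) next
        R <- ranks[, use, drop = FALSE]
        meanRank <- as.vector(R %*% (w[use] / sum(w[use])))
        out[[f]] <- data.frame(method = rownames(ranks), family = f,
                               mean_rank = meanRank,
                               composite_rank = rank(meanRank))
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Composite ranking with custom weights
#'
#' Re-ranks the methods of a [ScoreTable-class] using per-criterion
#' weights: within the chosen family, the composite is the weighted mean
#' of per-criterion ranks, ranked again (1 = best).  A zero weight removes
#' a criterion; uniform weight scaling does not change the result.
#'
#' @param table a [ScoreTable-class].
#' @param weights named nonnegative per-criterion weights (default all 1).
#' @param family `"classic"`, `"proteomic"` or `"all"`.
#' @return data.frame `method`, `family`, `mean_rank`, `composite_rank`.
#' @export
rankMethods <- function(table, weights = NULL, family = "all") {
    comp <- .compositeRanks(table@ranks, table@directions, weights)
    if (identical(family, "all")) comp
    else comp[comp$family == family, , drop = FALSE]
}

#' Flag non-discriminative criteria
#'
#' If every method scores nearly the same on a criterion, that criterion
#' carries no selection signal on this dataset and the user should review
#' the run.  A criterion is flagged when the range of its normalized
#' scores across methods is below `spreadThreshold`.
#'
#' @param table a [ScoreTable-class].
#' @param spreadThreshold minimum normalized-score range (default 0.05).
#' @return data.frame `criterion`, `spread`, `flagged`.
#' @export
finalCheck <- function(table, spreadThreshold = 0.05) {
    if (nrow(table@raw) < 2L)
        stop("final check needs at least 2 methods")
    spread <- apply(table@normalized, 2L, function(x) {
        x <- x[!is.na(x)]
        if (length(x) < 2L) return(NA_real_)
        diff(range(x))
    })
    data.frame(criterion = colnames(table@normalized),
               spread = as.numeric(spread),
               flagged = !is.na(spread) & spread < spreadThreshold)
}

#' Inspect imputed values of selected features
#'
#' Per requested feature and method: how many cells were imputed, the
#' observed value range, the imputed value range, and a flag when any
#' imputed value falls outside the feature's observed min/max (e.g. a
#' zero fill on log2 data far below the detection range).
#'
#' @param original the [ProteoSet-class] with missing values.
#' @param results named list of [ImputationResult-class].
#' @param featureIds features to inspect.
#' @return data.frame with one row per (feature, method); unknown ids are
#'   reported with note `"unknown feature"` and are not an error.
#' @export
targetedCheck <- function(original, results, featureIds) {
    vo <- .values(.asProteoSet(original))
    rows <- list()
    for (fid in featureIds) {
        i <- match(fid, rownames(vo))
        for (m in names(results)) {
            if (is.na(i)) {
                rows[[length(rows) + 1L]] <- data.frame(
                    feature_id = fid, method = m, n_imputed = NA_integer_,
                    observed_min = NA_real_, observed_max = NA_real_,
                    imputed_min = NA_real_, imputed_max = NA_real_,
                    out_of_range = NA, note = "unknown feature")
                next
            }
            x <- vo[i, ]
            mis <- is.na(x)
            vi <- .values(imputedMatrix(results[[m]]))[i, ]
            if (!any(mis)) {
                rows[[length(rows) + 1L]] <- data.frame(
                    feature_id = fid, method = m, n_imputed = 0L,
                    observed_min = min(x), observed_max = max(x),
                    imputed_min = NA_real_, imputed_max = NA_real_,
                    out_of_range = FALSE, note = "no imputed cells")
                next
            }
            imp <- vi[mis]
            rows[[length(rows) + 1L]] <- data.frame(
                feature_id = fid, method = m, n_imputed = sum(mis),
                observed_min = min(x, na.rm = TRUE),
                observed_max = max(x, na.rm = TRUE),
                imputed_min = min(imp), imputed_max = max(imp),
                out_of_range = any(imp < min(x, na.rm = TRUE) |
                                   imp > max(x, na.rm = TRUE)),
                note = "")
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Write all score tables of a benchmark run
#'
#' Emits `raw_scores.tsv`, `normalized_scores.tsv`, `ranks.tsv`,
#' `ranks_classic.tsv`, `ranks_proteomic.tsv` and
#' `final_check_report.tsv` into `dir`.
#'
#' @param table a [ScoreTable-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeScoreTables <- function(table, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) {
        df <- data.frame(method = rownames(x), x, check.names = FALSE)
        utils::write.table(df, file.path(dir, f), sep = "\t",
                           quote = FALSE, row.names = FALSE)
    }
    wt(table@raw, "raw_scores.tsv")
    wt(table@normalized, "normalized_scores.tsv")
    wt(table@ranks, "ranks.tsv")
    utils::write.table(compositeRanks(table, "classic"),
                       file.path(dir, "ranks_classic.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(compositeRanks(table, "proteomic"),
                       file.path(dir, "ranks_proteomic.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(finalCheck(table),
                       file.path(dir, "final_check_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(dir)
}
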