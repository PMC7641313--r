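#' Run the full imputation benchmark end to end
#'
#' The whole workflow in one call: (optionally) filter the input matrix,
#' extract its complete submatrix, mask it at a proportion matched to the
#' input's own missing fraction (or an explicit one), run the requested
#' imputation methods, score them on every applicable criterion, and
#' write the score/rank tables plus a run manifest.
#'
#' @param m a [ProteoSet-class] with missing values.
#' @param outDir output directory for the TSV reports (`NULL` = don't
#'   write).
#' @param methods registry keys to benchmark (default [fastMethods()]).
#' @param ann,complexCatalog,ppiCatalog optional annotation/catalogs
#'   enabling the proteomic criteria.
#' @param maskProportion proportion of cells to mask; default matches the
#'   input matrix's observed missing fraction (floored at 0.05).
#' @param mechanism masking mechanism, see [applyMask()].
#' @param maxNaFraction pre-filter threshold, see [filterByNA()];
#'   `NULL` disables.
#' @param seed global seed; per-stage seeds are derived from it.
#' @param weights per-criterion weights for the composite ranks.
#' @return list: `table` ([ScoreTable-class]), `results`, `mask`
#'   ([MaskSpec-class]), `complete` (the masked ground-truth matrix),
#'   `finalCheck`, `rankClassic`, `rankProteomic`.
#' @export
runBenchmark <- function(m, outDir = NULL, methods = fastMethods(),
                         ann = NULL, complexCatalog = NULL,
                         ppiCatalog = NULL, maskProportion = NULL,
                         mechanism = "mcar", maxNaFraction = 0.5,
                         seed = 1L, weights = NULL) {
    m <- .asProteoSet(m)
    if (!is.null(maxNaFraction)) m <- filterByNA(m, maxNaFraction)
    naFrac <- mean(is.na(.values(m)))
    if (is.null(maskProportion))
        maskProportion <- max(naFrac, 0.05)
    complete <- completeSubmatrix(m)
    masked <- applyMask(complete, maskProportion,
                        seed = deriveSeed(seed, 1L), mechanism = mechanism)
    results <- runMethods(masked$masked, methods, seed = deriveSeed(seed, 2L))
    fails <- attr(results, "failures")
    if (length(fails))
        warning("method failure(s): ",
                paste(names(fails), fails, sep = ": ", collapse = "; "))
    if (!length(results)) stop("every method failed")
    table <- evaluateImputations(complete, results, masked$spec, ann = ann,
                                 complexCatalog = complexCatalog,
                                 ppiCatalog = ppiCatalog, weights = weights)
    fc <- finalCheck(table)
    out <- list(table = table, results = results, mask = masked$spec,
                complete = complete, finalCheck = fc,
                rankClassic = compositeRanks(table, "classic"),
                rankProteomic = compositeRanks(table, "proteomic"))
    if (!is.null(outDir)) {
        writeScoreTables(table, outDir)
        writeMaskSpec(masked$spec, complete, file.path(outDir, "mask.tsv"))
        jsonlite::write_json(
            list(n_features_input = nrow(m), n_complete = nrow(complete),
                 input_na_fraction = naFrac,
                 mask_proportion = maskProportion, mechanism = mechanism,
                 methods = methods, seed = seed,
                 failures = as.list(fails),
                 package_version =
                     as.character(utils::packageVersion("ImputeBenchMS"))),
            file.path(outDir, "manifest.json"), auto_unbox = TRUE)
    }
    out
}
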