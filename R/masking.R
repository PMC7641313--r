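#' Extract the complete submatrix
#'
#' The benchmark needs ground truth: only features quantified in every
#' sample can be masked and later compared to their imputed values.
#'
#' @param m a [ProteoSet-class].
#' @param minFeatures minimum number of complete features required
#'   (default 10).
#' @return A [ProteoSet-class] holding exactly the complete features, in
#'   their original order.
#' @export
completeSubmatrix <- function(m, minFeatures = 10L) {
    m <- .asProteoSet(m)
    keep <- rowSums(is.na(.values(m))) == 0L
    if (sum(keep) < minFeatures)
        stop("only ", sum(keep), " complete features (need >= ", minFeatures,
             "); consider relaxing the NA/CV filtration")
    m[keep, ]
}

#' Inject artificial missing values into a complete matrix
#'
#' Masks `round(proportion * n_cells)` cells (round half away from zero).
#' Mechanism `"mcar"` draws a uniform sample of cells without replacement,
#' emulating masking "at the whole data matrix level".  Mechanism
#' `"left_censored"` is an MNAR stress-test extension: cells are drawn
#' without replacement with inclusion probability proportional to
#' `plogis(strength * (tau - x))`, `tau` = the matrix's 10th percentile,
#' so low-intensity cells are preferentially removed -- the same censoring
#' model [injectMissingness()] uses.  Either way, a cell whose masking
#' would empty a whole feature row or sample column is skipped in favour
#' of the next candidate, since several imputers are undefined there; the
#' draw is otherwise exact uniform/weighted sampling without replacement.
#'
#' @param m a complete [ProteoSet-class].
#' @param proportion fraction of cells to mask, in (0, 1); values up to
#'   0.7 are the tested regime.
#' @param seed integer seed; the same (matrix, proportion, seed) always
#'   yields the same mask.
#' @param mechanism `"mcar"` or `"left_censored"`.
#' @param strength steepness of the censoring logistic per log2 unit
#'   (left_censored only; default 5).
#' @return list with `masked` (the [ProteoSet-class] with NAs) and `spec`
#'   (the [MaskSpec-class]).
#' @examples
#' ps <- ProteoSet(matrix(rnorm(200, 20), 20, 10,
#'                 dimnames = list(sprintf("f%02d", 1:20),
#'                                 sprintf("s%02d", 1:10))))
#' res <- applyMask(ps, 0.2, seed = 1)
#' res$spec
#' @export
applyMask <- function(m, proportion, seed,
                      mechanism = c("mcar", "left_censored"),
                      strength = 5) {
    mechanism <- match.arg(mechanism)
    m <- .asProteoSet(m)
    v <- .values(m)
    if (anyNA(v)) stop("matrix must be complete before masking")
    stopifnot(proportion > 0, proportion < 1)
    nCells <- length(v)
    nMask <- as.integer(roundHalfUp(proportion * nCells))
    if (nMask < 1L) stop("proportion too small: no cell would be masked")
    nr <- nrow(v); nc <- ncol(v)
    if (nMask > nCells - max(nr, nc))
        stop("proportion ", proportion, " cannot leave every feature and ",
             "sample with at least one observed cell")
    prob <- NULL
    if (mechanism == "left_censored") {
        tau <- stats::quantile(v, 0.10, names = FALSE)
        prob <- stats::plogis(strength * (tau - as.vector(v)))
    }
    coords <- withSeed(seed, {
        # random priority keys: with weights this is weighted sampling
        # without replacement (Efraimidis-Spirakis); without, uniform
        # log-scale keys avoid underflow for tiny weights
        key <- if (is.null(prob)) log(stats::runif(nCells))
               else log(stats::runif(nCells)) / pmax(prob, 1e-300)
        ord <- order(key, decreasing = TRUE)
        rowLeft <- rep(nc, nr)
        colLeft <- rep(nr, nc)
        sel <- integer(nMask)
        got <- 0L
        for (cell in ord) {
            r <- ((cell - 1L) %% nr) + 1L
            cc <- ((cell - 1L) %/% nr) + 1L
            if (rowLeft[r] > 1L && colLeft[cc] > 1L) {
                got <- got + 1L
                sel[got] <- cell
                rowLeft[r] <- rowLeft[r] - 1L
                colLeft[cc] <- colLeft[cc] - 1L
                if (got == nMask) break
            }
        }
        if (got < nMask)
            stop("could not mask ", nMask, " cells while leaving every ",
                 "feature and sample partially observed")
        cbind(feature = ((sel - 1L) %% nr) + 1L,
              sample = ((sel - 1L) %/% nr) + 1L)
    })
    # deterministic row-major order so evaluation vectors are reproducible
    ord <- order(coords[, 1L], coords[, 2L])
    coords <- coords[ord, , drop = FALSE]
    spec <- new("MaskSpec", coords = coords, proportion = proportion,
                seed = as.integer(seed), mechanism = mechanism)
    vm <- v
    vm[coords] <- NA_real_
    list(masked = .setValues(m, vm), spec = spec)
}

#' Robustness sweep over masking proportions
#'
#' One masked dataset per (proportion, seed) pair, drawn independently (a
#' higher-proportion mask is not a superset of a lower one).  The default
#' grid is 5% to 70% in steps of 5% -- 14 proportions.
#'
#' @param m a complete [ProteoSet-class].
#' @param proportions ascending masking proportions.
#' @param seeds integer seeds.
#' @param mechanism passed to [applyMask()].
#' @return list of `list(masked, spec)` entries, ordered by proportion then
#'   seed.
#' @export
maskSweep <- function(m, proportions = seq(0.05, 0.70, by = 0.05),
                      seeds = 1L, mechanism = "mcar") {
    stopifnot(!is.unsorted(proportions))
    out <- list()
    for (p in proportions)
        for (s in seeds)
            out[[length(out) + 1L]] <- applyMask(m, p, s, mechanism)
    out
}

#' Pair original and imputed values at the masked coordinates
#'
#' Every masked cell has a real reference (its hidden original value);
#' this aligns those references with what an imputation method filled in,
#' in the mask's deterministic row-major order.
#'
#' @param original the complete [ProteoSet-class] that was masked.
#' @param imputed a completed [ProteoSet-class] (or
#'   [ImputationResult-class]).
#' @param spec the [MaskSpec-class] from [applyMask()].
#' @return A [MaskedEvaluation-class].
#' @export
pairEvaluation <- function(original, imputed, spec) {
    if (is(imputed, "ImputationResult")) {
        name <- methodName(imputed)
        imputed <- imputedMatrix(imputed)
    } else name <- "imputed"
    vo <- .values(.asProteoSet(original))
    vi <- .values(.asProteoSet(imputed))
    if (!all(dim(vo) == dim(vi)))
        stop("original and imputed matrices differ in dimension")
    coords <- maskedCoords(spec)
    yi <- vi[coords]
    if (anyNA(yi))
        stop("method '", name, "' left ", sum(is.na(yi)),
             " masked cell(s) missing")
    new("MaskedEvaluation", yo = as.numeric(vo[coords]),
        yi = as.numeric(yi), featureIndex = as.integer(coords[, 1L]))
}

#' Serialize / replay a mask
#'
#' `writeMaskSpec()` writes the masked coordinates as TSV (`feature_id`,
#' `sample_id`) with a JSON sidecar (`<path>.json`: proportion, seed,
#' mechanism); `readMaskSpec()` reconstructs the [MaskSpec-class] against
#' the matrix it was drawn from.
#'
#' @param spec a [MaskSpec-class].
#' @param m the [ProteoSet-class] the mask addresses.
#' @param path TSV path.
#' @return `writeMaskSpec`: `path`, invisibly. `readMaskSpec`: a
#'   [MaskSpec-class].
#' @export
writeMaskSpec <- function(spec, m, path) {
    coords <- maskedCoords(spec)
    df <- data.frame(feature_id = rownames(m)[coords[, 1L]],
                     sample_id = colnames(m)[coords[, 2L]])
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(list(proportion = spec@proportion, seed = spec@seed,
                              mechanism = spec@mechanism),
                         paste0(path, ".json"), auto_unbox = TRUE)
    invisible(path)
}

#' @rdname writeMaskSpec
#' @export
readMaskSpec <- function(path, m) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = "character")
    side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    coords <- cbind(feature = match(df$feature_id, rownames(m)),
                    sample = match(df$sample_id, colnames(m)))
    if (anyNA(coords)) stop("mask references ids absent from the matrix")
    ord <- order(coords[, 1L], coords[, 2L])
    new("MaskSpec", coords = coords[ord, , drop = FALSE],
        proportion = side$proportion, seed = as.integer(side$seed),
        mechanism = side$mechanism)
}
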