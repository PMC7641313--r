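# Method registry: one uniform contract over all imputation algorithms.

.imputerRegistry <- new.env(parent = emptyenv())

.registerBuiltin <- function(key, fun, family, speedTier, stochastic,
                             defaults = list()) {
    assign(key, list(fun = fun, family = family, speedTier = speedTier,
                     stochastic = stochastic, defaults = defaults),
           envir = .imputerRegistry)
}

# SV = single value, GS = global structure, LS = local similarity
.registerBuiltin("zero",      .imp_zero,      "SV", "fast", FALSE)
.registerBuiltin("minimum",   .imp_minimum,   "SV", "fast", FALSE)
.registerBuiltin("colmedian", .imp_colmedian, "SV", "fast", FALSE)
.registerBuiltin("rowmedian", .imp_rowmedian, "SV", "fast", FALSE)
.registerBuiltin("mindet",    .imp_mindet,    "SV", "fast", FALSE,
                 list(q = 0.01))
.registerBuiltin("minprob",   .imp_minprob,   "SV", "fast", TRUE,
                 list(q = 0.01, tune = 1))
.registerBuiltin("pi",        .imp_pi,        "SV", "fast", TRUE,
                 list(shift = 1.8, width = 0.3))
.registerBuiltin("qrilc",     .imp_qrilc,     "SV", "fast", TRUE,
                 list(upperFraction = 0.75, q = 0.01))
.registerBuiltin("svd",       .imp_svd,       "GS", "fast", FALSE,
                 list(rank = 5L, tol = 1e-2, maxIter = 100L))
.registerBuiltin("mle",       .imp_mle,       "GS", "fast", FALSE,
                 list(ridge = 1e-6, tol = 1e-6, maxIter = 500L))
.registerBuiltin("impseq",    .imp_impseq,    "GS", "fast", FALSE,
                 list(robust = FALSE))
.registerBuiltin("impseqrob", .imp_impseq,    "GS", "fast", FALSE,
                 list(robust = TRUE))
.registerBuiltin("knn",       .imp_knn,       "LS", "fast", FALSE,
                 list(k = 10L))
.registerBuiltin("seqknn",    .imp_seqknn,    "LS", "fast", FALSE,
                 list(k = 10L))
.registerBuiltin("lls",       .imp_lls,       "LS", "fast", FALSE,
                 list(k = 10L, ridge = 1e-3))
.registerBuiltin("grr",       .imp_chained,   "LS", "fast", FALSE,
                 list(engine = "ridge", nIter = 3L, penalty = 1e-4))
.registerBuiltin("mice_norm", .imp_chained,   "LS", "slow", TRUE,
                 list(engine = "norm", nIter = 10L))
.registerBuiltin("mice_cart", .imp_chained,   "LS", "slow", FALSE,
                 list(engine = "cart", nIter = 10L))
.registerBuiltin("rf",        .imp_chained,   "LS", "slow", TRUE,
                 list(engine = "rf", nIter = 5L))
.registerBuiltin("irm",       .imp_chained,   "LS", "slow", FALSE,
                 list(engine = "robust", nIter = 10L))

# plugin slots: algorithms users can supply via registerImputer()
.pluginSlots <- c("bpca", "trknn", "gms")

#' List or extend the imputation method registry
#'
#' `listImputers()` returns the registered methods with family (SV =
#' single value, GS = global structure, LS = local similarity) and speed
#' tier.  `registerImputer()` adds a user method (e.g. filling one of the
#' documented plugin slots `bpca`, `trknn`, `gms`): `fun(values, params)`
#' must take a features x samples matrix with NAs plus a parameter list
#' and return `list(values = <complete matrix>, diagnostics = <list>)`.
#'
#' @param key registry key (string).
#' @param fun imputation engine (see above).
#' @param family `"SV"`, `"GS"` or `"LS"`.
#' @param speedTier `"fast"` or `"slow"`.
#' @param stochastic does the method draw random numbers (then a seed is
#'   required at run time)?
#' @param defaults named list of default parameters.
#' @return `listImputers()`: data.frame of registered methods.
#' @examples
#' listImputers()
#' @export
listImputers <- function() {
    keys <- sort(ls(.imputerRegistry))
    info <- lapply(keys, get, envir = .imputerRegistry)
    data.frame(method = keys,
               family = vapply(info, `[[`, "", "family"),
               speed_tier = vapply(info, `[[`, "", "speedTier"),
               stochastic = vapply(info, `[[`, TRUE, "stochastic"))
}

#' @rdname listImputers
#' @export
registerImputer <- function(key, fun, family = c("LS", "GS", "SV"),
                            speedTier = c("slow", "fast"),
                            stochastic = FALSE, defaults = list()) {
    stopifnot(is.character(key), length(key) == 1L, is.function(fun))
    .registerBuiltin(key, fun, match.arg(family), match.arg(speedTier),
                     stochastic, defaults)
    invisible(key)
}

#' The default fast-tier method set
#'
#' The sixteen methods cheap enough to run routinely on full matrices;
#' the chained-equations engines behind `mice_*`, `rf` and `irm` form the
#' slow tier.
#'
#' @return character vector of registry keys.
#' @export
fastMethods <- function() {
    c("zero", "minimum", "colmedian", "rowmedian", "mindet", "minprob",
      "pi", "qrilc", "svd", "mle", "impseq", "impseqrob", "knn", "seqknn",
      "lls", "grr")
}

#' Describe one imputation run
#'
#' @param method registry key.
#' @param params named list of parameter overrides.
#' @param seed integer seed (required for stochastic methods).
#' @return An `ImputerSpec` (list with class attribute).
#' @export
imputerSpec <- function(method, params = list(), seed = NULL) {
    structure(list(method = method, params = params, seed = seed),
              class = "ImputerSpec")
}

.lookupMethod <- function(method) {
    if (!exists(method, envir = .imputerRegistry, inherits = FALSE)) {
        extra <- if (method %in% .pluginSlots)
            paste0(" ('", method, "' is a plugin slot: supply it via ",
                   "registerImputer())") else ""
        stop("unknown imputation method '", method, "'", extra,
             "; registered: ",
             paste(sort(ls(.imputerRegistry)), collapse = ", "))
    }
    get(method, envir = .imputerRegistry)
}

#' Impute a matrix with one registered method
#'
#' Uniform contract over every method: observed cells are preserved
#' bit-for-bit, the result has zero missing cells, and identical
#' (input, method, params, seed) always gives an identical result.
#'
#' @param m a [ProteoSet-class] or numeric matrix (log2 scale).
#' @param method registry key (see [listImputers()]).
#' @param params named list of parameter overrides (merged over the
#'   method's defaults).
#' @param seed integer seed; required for stochastic methods.
#' @return An [ImputationResult-class].
#' @examples
#' v <- matrix(rnorm(60, 20), 12, 5,
#'             dimnames = list(sprintf("f%02d", 1:12), sprintf("s%d", 1:5)))
#' v[2, 3] <- NA
#' imputeMatrix(ProteoSet(v), "knn", params = list(k = 5))
#' @export
imputeMatrix <- function(m, method, params = list(), seed = NULL) {
    entry <- .lookupMethod(method)
    if (entry$stochastic && is.null(seed))
        stop("method '", method, "' is stochastic and requires a seed")
    ps <- .asProteoSet(m)
    v <- .values(ps)
    p <- utils::modifyList(entry$defaults, params)
    t0 <- proc.time()[["elapsed"]]
    res <- withSeed(seed, entry$fun(v, p))
    runtime <- proc.time()[["elapsed"]] - t0
    out <- res$values
    obs <- !is.na(v)
    out[obs] <- v[obs]       # observed cells are never altered
    if (anyNA(out))
        stop("method '", method, "' left ", sum(is.na(out)),
             " cell(s) missing")
    diag <- res$diagnostics %||% list()
    diag$runtime <- runtime
    new("ImputationResult", matrix = .setValues(ps, out),
        methodName = method, diagnostics = diag)
}

#' Run a batch of imputation methods
#'
#' Results come back in spec order; a per-method failure is captured as a
#' `try-error`-style record in the `failures` attribute instead of
#' aborting the batch.
#'
#' @param m a [ProteoSet-class] or numeric matrix.
#' @param specs character vector of registry keys, or list of
#'   [imputerSpec()] objects.
#' @param seed default seed applied to stochastic methods lacking one.
#' @return named list of [ImputationResult-class]; failed methods are
#'   dropped from the list and reported in `attr(, "failures")`.
#' @export
runMethods <- function(m, specs = fastMethods(), seed = NULL) {
    if (is.character(specs))
        specs <- lapply(specs, imputerSpec)
    names <- vapply(specs, `[[`, "", "method")
    for (sp in specs) .lookupMethod(sp$method)   # fail fast on unknown keys
    results <- list()
    failures <- character()
    for (i in seq_along(specs)) {
        sp <- specs[[i]]
        sd <- sp$seed %||% deriveSeed(seed, i)
        r <- tryCatch(imputeMatrix(m, sp$method, sp$params, sd),
                      error = function(e) conditionMessage(e))
        if (is.character(r)) failures[sp$method] <- r
        else results[[sp$method]] <- r
    }
    attr(results, "failures") <- failures
    results
}

#' Spec-level convenience wrappers
#'
#' Thin named entry points over [imputeMatrix()] for each algorithm
#' family.
#'
#' @param m a [ProteoSet-class] or numeric matrix.
#' @param method method key within the family.
#' @param params,seed as in [imputeMatrix()].
#' @param k,rank,tol,maxIter,robust,engine,nIter method parameters (see
#'   [imputeMatrix()] and [listImputers()]).
#' @return An [ImputationResult-class].
#' @name impute-wrappers
NULL

#' @rdname impute-wrappers
#' @export
imputeSingleValue <- function(m, method = c("zero", "minimum", "colmedian",
                                            "rowmedian")) {
    imputeMatrix(m, match.arg(method))
}

#' @rdname impute-wrappers
#' @export
imputeLeftCensored <- function(m, method = c("mindet", "minprob", "qrilc",
                                             "pi"),
                               params = list(), seed = NULL) {
    imputeMatrix(m, match.arg(method), params, seed)
}

#' @rdname impute-wrappers
#' @export
imputeKnn <- function(m, k = 10L) imputeMatrix(m, "knn", list(k = k))

#' @rdname impute-wrappers
#' @export
imputeSeqKnn <- function(m, k = 10L) imputeMatrix(m, "seqknn", list(k = k))

#' @rdname impute-wrappers
#' @param ridge relative shrinkage on the LLS neighbour coefficients.
#' @export
imputeLls <- function(m, k = 10L, ridge = 1e-3) {
    imputeMatrix(m, "lls", list(k = k, ridge = ridge))
}

#' @rdname impute-wrappers
#' @export
imputeSvd <- function(m, rank = 5L, tol = 1e-2, maxIter = 100L) {
    imputeMatrix(m, "svd", list(rank = rank, tol = tol, maxIter = maxIter))
}

#' @rdname impute-wrappers
#' @export
imputeMleEm <- function(m, params = list()) imputeMatrix(m, "mle", params)

#' @rdname impute-wrappers
#' @export
imputeImpseq <- function(m, robust = FALSE) {
    imputeMatrix(m, if (robust) "impseqrob" else "impseq")
}

#' @rdname impute-wrappers
#' @export
imputeChained <- function(m, engine = c("norm", "cart", "rf", "robust",
                                        "ridge"),
                          nIter = 10L, seed = NULL, params = list()) {
    engine <- match.arg(engine)
    params$engine <- engine
    params$nIter <- nIter
    key <- switch(engine, norm = "mice_norm", cart = "mice_cart",
                  rf = "rf", robust = "irm", ridge = "grr")
    if (engine %in% c("norm", "rf") && is.null(seed))
        stop("engine '", engine, "' is stochastic and requires a seed")
    imputeMatrix(m, key, params, seed)
}
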