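#' Accessors for the benchmark classes
#'
#' Small accessor generics so user code never touches slots directly:
#' `intensities()` returns the (log2) value grid of a [ProteoSet-class];
#' `scaleTag()` its scale; `maskedCoords()` the coordinate matrix of a
#' [MaskSpec-class]; `originalValues()` / `imputedValues()` the paired
#' vectors of a [MaskedEvaluation-class]; `methodName()`,
#' `imputedMatrix()` and `diagnostics()` the parts of an
#' [ImputationResult-class]; `rawScores()`, `normalizedScores()`,
#' `scoreRanks()` and `compositeRanks()` the grids of a
#' [ScoreTable-class]; `groupList()` and `catalogKind()` the contents of a
#' [GroupCatalog-class].
#'
#' @param x object to access.
#' @param ... unused.
#' @return The corresponding slot content (matrix, vector, list or
#'   data.frame; see the class documentation).
#' @name accessors
#' @examples
#' m <- matrix(1:6 + 0, 2, 3,
#'             dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
#' intensities(ProteoSet(m))
NULL

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setMethod("intensities", "ProteoSet", function(x) .values(x))

#' @rdname accessors
#' @export
setGeneric("scaleTag", function(x) standardGeneric("scaleTag"))
#' @rdname accessors
#' @export
setMethod("scaleTag", "ProteoSet", function(x) metadata(x)$scaleTag)

#' @rdname accessors
#' @export
setGeneric("maskedCoords", function(x) standardGeneric("maskedCoords"))
#' @rdname accessors
#' @export
setMethod("maskedCoords", "MaskSpec", function(x) x@coords)

#' @rdname accessors
#' @export
setGeneric("originalValues", function(x) standardGeneric("originalValues"))
#' @rdname accessors
#' @export
setMethod("originalValues", "MaskedEvaluation", function(x) x@yo)

#' @rdname accessors
#' @export
setGeneric("imputedValues", function(x) standardGeneric("imputedValues"))
#' @rdname accessors
#' @export
setMethod("imputedValues", "MaskedEvaluation", function(x) x@yi)

#' @rdname accessors
#' @export
setGeneric("methodName", function(x) standardGeneric("methodName"))
#' @rdname accessors
#' @export
setMethod("methodName", "ImputationResult", function(x) x@methodName)

#' @rdname accessors
#' @export
setGeneric("imputedMatrix", function(x) standardGeneric("imputedMatrix"))
#' @rdname accessors
#' @export
setMethod("imputedMatrix", "ImputationResult", function(x) x@matrix)

#' @rdname accessors
#' @export
setGeneric("diagnostics", function(x) standardGeneric("diagnostics"))
#' @rdname accessors
#' @export
setMethod("diagnostics", "ImputationResult", function(x) x@diagnostics)

#' @rdname accessors
#' @export
setGeneric("scoreValue", function(x) standardGeneric("scoreValue"))
#' @rdname accessors
#' @export
setMethod("scoreValue", "CriterionScore", function(x) x@value)

#' @rdname accessors
#' @export
setGeneric("scoreDirection", function(x) standardGeneric("scoreDirection"))
#' @rdname accessors
#' @export
setMethod("scoreDirection", "CriterionScore", function(x) x@direction)

#' @rdname accessors
#' @export
setGeneric("scoreReason", function(x) standardGeneric("scoreReason"))
#' @rdname accessors
#' @export
setMethod("scoreReason", "CriterionScore", function(x) x@reason)

#' @rdname accessors
#' @export
setGeneric("rawScores", function(x) standardGeneric("rawScores"))
#' @rdname accessors
#' @export
setMethod("rawScores", "ScoreTable", function(x) x@raw)

#' @rdname accessors
#' @export
setGeneric("normalizedScores", function(x) standardGeneric("normalizedScores"))
#' @rdname accessors
#' @export
setMethod("normalizedScores", "ScoreTable", function(x) x@normalized)

#' @rdname accessors
#' @export
setGeneric("scoreRanks", function(x) standardGeneric("scoreRanks"))
#' @rdname accessors
#' @export
setMethod("scoreRanks", "ScoreTable", function(x) x@ranks)

#' @rdname accessors
#' @param family `"classic"`, `"proteomic"` or `"all"`.
#' @export
setGeneric("compositeRanks",
           function(x, family = "all") standardGeneric("compositeRanks"))
#' @rdname accessors
#' @export
setMethod("compositeRanks", "ScoreTable", function(x, family = "all") {
    if (identical(family, "all")) return(x@composite)
    x@composite[x@composite$family == family, , drop = FALSE]
})

#' @rdname accessors
#' @export
setGeneric("groupList", function(x) standardGeneric("groupList"))
#' @rdname accessors
#' @export
setMethod("groupList", "GroupCatalog", function(x) x@groups)

#' @rdname accessors
#' @export
setGeneric("catalogKind", function(x) standardGeneric("catalogKind"))
#' @rdname accessors
#' @export
setMethod("catalogKind", "GroupCatalog", function(x) x@catalogKind)

setMethod("show", "ProteoSet", function(object) {
    v <- .values(object)
    cat(sprintf("ProteoSet: %d features x %d samples [%s scale], %d missing (%.1f%%)\n",
                nrow(v), ncol(v), scaleTag(object), sum(is.na(v)),
                100 * mean(is.na(v))))
    callNextMethod()
})

setMethod("show", "GroupCatalog", function(object) {
    sz <- lengths(object@groups)
    cat(sprintf("GroupCatalog (%s): %d groups, member counts %s\n",
                object@catalogKind, length(sz),
                if (length(sz)) paste0(min(sz), "-", max(sz)) else "-"))
})

setMethod("show", "MaskSpec", function(object) {
    cat(sprintf("MaskSpec: %d cells masked (proportion %.3f, %s, seed %d)\n",
                nrow(object@coords), object@proportion, object@mechanism,
                object@seed))
})

setMethod("show", "MaskedEvaluation", function(object) {
    cat(sprintf("MaskedEvaluation: %d masked cells over %d features\n",
                length(object@yo), length(unique(object@featureIndex))))
})

setMethod("show", "ImputationResult", function(object) {
    d <- object@diagnostics
    cat(sprintf("ImputationResult <%s>: %d x %d complete%s\n",
                object@methodName, nrow(object@matrix), ncol(object@matrix),
                if (!is.null(d$iterations))
                    sprintf(" (%d iterations, converged=%s)",
                            d$iterations, d$converged) else ""))
})

setMethod("show", "CriterionScore", function(object) {
    cat(sprintf("CriterionScore %s = %s (%s, n=%d)%s\n", object@criterion,
                format(object@value, digits = 4), object@direction,
                object@nUsed,
                if (nzchar(object@reason))
                    paste0(" [", object@reason, "]") else ""))
})

setMethod("show", "ScoreTable", function(object) {
    cat(sprintf("ScoreTable: %d methods x %d criteria\n",
                nrow(object@raw), ncol(object@raw)))
    print(round(object@raw, 4))
})
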