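#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- rowData
#'   colData rowData<- colData<-
#' @importFrom S4Vectors metadata metadata<- DataFrame
NULL

#' ProteoSet: a quantitative proteomics matrix with explicit missing cells
#'
#' `ProteoSet` extends [SummarizedExperiment::SummarizedExperiment] with a
#' single `"intensity"` assay holding a feature x sample grid of (log2)
#' intensities, `NA` marking missing cells.  Feature annotation (peptide
#' sequence, charge state, protein accession) lives in `rowData()`, the
#' two-group sample design in `colData()$group_label`, and the intensity
#' scale (`"raw"` or `"log2"`) in `metadata()$scaleTag`.
#'
#' Validity requires unique, non-empty feature and sample identifiers, at
#' least two samples, and -- on the raw scale -- strictly positive observed
#' values (zero intensity is non-detection and is coerced to `NA` on read).
#'
#' @name ProteoSet-class
#' @aliases ProteoSet-class
#' @exportClass ProteoSet
setClass("ProteoSet", contains = "SummarizedExperiment")

setValidity("ProteoSet", function(object) {
    msg <- character()
    if (!"intensity" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'intensity' is required")
    tag <- metadata(object)$scaleTag
    if (is.null(tag) || !tag %in% c("raw", "log2"))
        msg <- c(msg, "metadata scaleTag must be 'raw' or 'log2'")
    fid <- rownames(object); sid <- colnames(object)
    if (is.null(fid) || anyDuplicated(fid) || any(!nzchar(fid)))
        msg <- c(msg, "feature ids must be unique non-empty strings")
    if (is.null(sid) || anyDuplicated(sid) || any(!nzchar(sid)))
        msg <- c(msg, "sample ids must be unique non-empty strings")
    if (ncol(object) < 2L)
        msg <- c(msg, "at least 2 samples are required")
    if (length(msg) == 0L && identical(tag, "raw")) {
        v <- assay(object, "intensity")
        if (any(v[!is.na(v)] <= 0))
            msg <- c(msg, "raw-scale observed intensities must be > 0")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a ProteoSet
#'
#' @param values numeric matrix (features x samples) with `NA` for missing
#'   cells; must carry rownames (feature ids) and colnames (sample ids).
#' @param scaleTag `"log2"` (default) or `"raw"`.
#' @param rowData optional data.frame of feature annotation (columns
#'   `peptide_sequence`, `charge`, `protein_id`).
#' @param colData optional data.frame of sample annotation (column
#'   `group_label` for the two-group design).
#' @return A [ProteoSet-class] object.
#' @examples
#' m <- matrix(rnorm(12, 20), 3, 4,
#'             dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
#' ps <- ProteoSet(m)
#' ps
#' @export
ProteoSet <- function(values, scaleTag = c("log2", "raw"),
                      rowData = NULL, colData = NULL) {
    scaleTag <- match.arg(scaleTag)
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    args <- list(assays = list(intensity = values),
                 metadata = list(scaleTag = scaleTag))
    if (!is.null(rowData)) args$rowData <- rowData
    if (!is.null(colData)) args$colData <- colData
    se <- do.call(SummarizedExperiment, args)
    new("ProteoSet", se)
}

# coerce plain matrices in user-facing entry points
.asProteoSet <- function(x, scaleTag = "log2") {
    if (is(x, "ProteoSet")) return(x)
    if (is.matrix(x)) {
        if (is.null(rownames(x)))
            rownames(x) <- sprintf("F%04d", seq_len(nrow(x)))
        if (is.null(colnames(x)))
            colnames(x) <- sprintf("S%02d", seq_len(ncol(x)))
        return(ProteoSet(x, scaleTag = scaleTag))
    }
    stop("expected a ProteoSet or a numeric matrix")
}

.values <- function(x) assay(x, "intensity")

.setValues <- function(x, m) {
    dimnames(m) <- dimnames(.values(x))
    assay(x, "intensity", withDimnames = FALSE) <- m
    x
}

#' GroupCatalog: named groups of protein accessions
#'
#' Holds protein complexes (e.g. a CORUM-style catalog) or clusters of a
#' protein-protein interaction map (e.g. hu.MAP-style).  Groups with fewer
#' than two members matched in a dataset are dropped at scoring time, never
#' at load time.
#'
#' @slot groups named list; each element a character vector of protein ids.
#' @slot catalogKind `"complex"` or `"ppi_cluster"`.
#' @exportClass GroupCatalog
setClass("GroupCatalog",
         representation(groups = "list", catalogKind = "character"))

setValidity("GroupCatalog", function(object) {
    msg <- character()
    if (!object@catalogKind %in% c("complex", "ppi_cluster"))
        msg <- c(msg, "catalogKind must be 'complex' or 'ppi_cluster'")
    if (length(object@groups) &&
        (is.null(names(object@groups)) || anyDuplicated(names(object@groups))))
        msg <- c(msg, "groups must be uniquely named")
    if (!all(vapply(object@groups, is.character, logical(1))))
        msg <- c(msg, "each group must be a character vector of protein ids")
    if (length(msg)) msg else TRUE
})

#' @param groups named list of character vectors (protein ids per group).
#' @param catalogKind `"complex"` or `"ppi_cluster"`.
#' @rdname GroupCatalog-class
#' @export
GroupCatalog <- function(groups, catalogKind = c("complex", "ppi_cluster")) {
    catalogKind <- match.arg(catalogKind)
    groups <- lapply(groups, function(g) unique(as.character(g)))
    new("GroupCatalog", groups = groups, catalogKind = catalogKind)
}

#' MaskSpec: coordinates of artificially masked cells
#'
#' Records which observed cells of a complete matrix were hidden for the
#' benchmark, plus the masking proportion, mechanism and seed for exact
#' replay.  Coordinates are stored (and always iterated) in row-major
#' order so downstream evaluation vectors are reproducible.
#'
#' @slot coords integer matrix with columns `feature`, `sample`.
#' @slot proportion fraction of cells masked.
#' @slot seed integer seed used for the draw.
#' @slot mechanism `"mcar"` or `"left_censored"`.
#' @exportClass MaskSpec
setClass("MaskSpec",
         representation(coords = "matrix", proportion = "numeric",
                        seed = "integer", mechanism = "character"))

#' MaskedEvaluation: original/imputed value pairs at masked cells
#'
#' @slot yo numeric; true (hidden) values, row-major coordinate order.
#' @slot yi numeric; imputed values at the same coordinates, same order.
#' @slot featureIndex integer; source feature (row) of each entry.
#' @exportClass MaskedEvaluation
setClass("MaskedEvaluation",
         representation(yo = "numeric", yi = "numeric",
                        featureIndex = "integer"))

setValidity("MaskedEvaluation", function(object) {
    if (length(object@yo) != length(object@yi) ||
        length(object@yo) != length(object@featureIndex))
        "yo, yi and featureIndex must have equal length" else TRUE
})

#' ImputationResult: a completed matrix plus method diagnostics
#'
#' @slot matrix a complete [ProteoSet-class] (zero missing cells).
#' @slot methodName registry key of the imputation method.
#' @slot diagnostics list; `iterations`, `converged`, `runtime` (seconds)
#'   where the method defines them.
#' @exportClass ImputationResult
setClass("ImputationResult",
         representation(matrix = "ProteoSet", methodName = "character",
                        diagnostics = "list"))

#' CriterionScore: one criterion evaluated for one method
#'
#' @slot criterion criterion name, e.g. `"NRMSE"` or `"ACC_CORUM"`.
#' @slot value numeric score; `NA` when undefined (see `reason`).
#' @slot direction `"lower_better"` or `"higher_better"`.
#' @slot nUsed number of contributing items (masked cells, variables or
#'   groups, depending on the criterion).
#' @slot reason why the score is missing, or `""`.
#' @exportClass CriterionScore
setClass("CriterionScore",
         representation(criterion = "character", value = "numeric",
                        direction = "character", nUsed = "integer",
                        reason = "character"))

.score <- function(criterion, value, direction, nUsed, reason = "") {
    new("CriterionScore", criterion = criterion, value = as.numeric(value),
        direction = direction, nUsed = as.integer(nUsed), reason = reason)
}

#' ScoreTable: the benchmark's deliverable
#'
#' Methods x criteria grids of raw scores, max-normalized scores and
#' per-criterion ranks, plus composite ranks per criterion family
#' (classic / proteomic).
#'
#' @slot raw numeric matrix, methods x criteria (NA allowed).
#' @slot normalized same grid scaled so 1 is best per criterion.
#' @slot ranks same grid of per-criterion ranks (1 = best, average ties).
#' @slot directions named character; direction per criterion.
#' @slot reasons character matrix; why a raw score is missing, else `""`.
#' @slot composite data.frame with per-family composite ranks.
#' @exportClass ScoreTable
setClass("ScoreTable",
         representation(raw = "matrix", normalized = "matrix",
                        ranks = "matrix", directions = "character",
                        reasons = "matrix", composite = "data.frame"))
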