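#' Read a quantification matrix from delimited text
#'
#' The file must have a header row of sample names and a first column of
#' feature identifiers (header `feature_id` by convention, any name is
#' accepted).  Cells equal to one of `naTokens`, empty cells, and -- on the
#' raw scale -- values `<= 0` become missing: zero intensity in label-free
#' quantification means non-detection, not abundance zero.  Raw-scale input
#' is log2-transformed on ingest (`log2Transform = TRUE`), so downstream
#' computation is uniformly on the log2 scale.
#'
#' @param path delimited text file (tab or comma separated; autodetected
#'   from the header line).
#' @param scaleTag scale of the values in the file: `"raw"` or `"log2"`.
#' @param naTokens character vector of cell values read as missing.
#' @param log2Transform log2-transform raw-scale values on read (default
#'   `TRUE`; ignored for log2 input).
#' @return A [ProteoSet-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("feature_id,s1,s2", "p1,100,200", "p2,,400"), f)
#' readMatrix(f, scaleTag = "raw")
#' @export
readMatrix <- function(path, scaleTag = c("raw", "log2"),
                       naTokens = c("NA", "NaN", ""), log2Transform = TRUE) {
    scaleTag <- match.arg(scaleTag)
    if (!file.exists(path)) stop("no such file: ", path)
    sep <- .sniffSep(path)
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            colClasses = "character", check.names = FALSE,
                            quote = "\"", comment.char = "")
    if (ncol(df) < 3L)
        stop("matrix needs a feature-id column and at least 2 samples")
    fid <- df[[1L]]
    if (anyDuplicated(fid))
        stop("duplicate feature ids: ",
             paste(unique(fid[duplicated(fid)]), collapse = ", "))
    cells <- as.matrix(df[, -1L, drop = FALSE])
    cells[cells %in% naTokens] <- NA_character_
    suppressWarnings(vals <- matrix(as.numeric(cells), nrow = nrow(cells)))
    bad <- !is.na(cells) & is.na(vals)
    if (any(bad))
        stop("non-numeric cell(s) that are not NA tokens, e.g. '",
             cells[which(bad)[1L]], "'")
    dimnames(vals) <- list(fid, colnames(cells))
    if (scaleTag == "raw") {
        vals[!is.na(vals) & vals <= 0] <- NA_real_
        if (log2Transform) {
            vals <- log2(vals)
            return(ProteoSet(vals, scaleTag = "log2"))
        }
        return(ProteoSet(vals, scaleTag = "raw"))
    }
    ProteoSet(vals, scaleTag = "log2")
}

.sniffSep <- function(path) {
    hdr <- readLines(path, n = 1L)
    if (lengths(regmatches(hdr, gregexpr("\t", hdr))) > 0) "\t" else ","
}

#' Read feature annotation (feature id, peptide sequence, charge, protein)
#'
#' TSV with columns `feature_id`, `peptide_sequence`, `charge`,
#' `protein_id`.  Two rows may share a peptide sequence with different
#' charge states (distinct precursors of one peptide).  When a
#' [ProteoSet-class] is supplied, rows referencing unknown feature ids are
#' skipped with a warning.
#'
#' @param path TSV file.
#' @param ps optional [ProteoSet-class] to validate feature ids against.
#' @return data.frame with the four columns above (`charge` integer,
#'   `NA` when absent).
#' @export
readAnnotation <- function(path, ps = NULL) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = "character", check.names = FALSE,
                            quote = "\"", comment.char = "")
    need <- c("feature_id", "peptide_sequence", "charge", "protein_id")
    if (!all(need %in% colnames(df)))
        stop("annotation needs columns: ", paste(need, collapse = ", "))
    df <- df[, need]
    if (anyDuplicated(df$feature_id))
        stop("duplicate feature ids in annotation")
    df$charge <- suppressWarnings(as.integer(df$charge))
    if (any(!is.na(df$charge) & df$charge <= 0L))
        stop("charge states must be positive integers")
    if (!is.null(ps)) {
        unknown <- !df$feature_id %in% rownames(ps)
        if (any(unknown)) {
            warning(sum(unknown),
                    " annotation row(s) reference unknown feature ids; skipped")
            df <- df[!unknown, , drop = FALSE]
        }
    }
    rownames(df) <- NULL
    df
}

#' Read a group catalog (protein complexes or PPI clusters)
#'
#' TSV with columns `group_id`, `protein_id`, one member per row.  One-member
#' groups are loaded but excluded later at scoring time (a within-group
#' correlation needs at least two members).
#'
#' @param path TSV file.
#' @param catalogKind `"complex"` or `"ppi_cluster"`.
#' @return A [GroupCatalog-class].
#' @export
readGroups <- function(path, catalogKind = c("complex", "ppi_cluster")) {
    catalogKind <- match.arg(catalogKind)
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = "character", check.names = FALSE)
    if (!all(c("group_id", "protein_id") %in% colnames(df)))
        stop("group table needs columns group_id, protein_id")
    GroupCatalog(split(df$protein_id, factor(df$group_id,
                                             levels = unique(df$group_id))),
                 catalogKind = catalogKind)
}

#' Read a sample design table
#'
#' TSV with columns `sample_id`, `group_label`.  When a matrix is supplied,
#' every sample id must appear in it.
#'
#' @param path TSV file.
#' @param ps optional [ProteoSet-class] to validate sample ids against.
#' @return data.frame with columns `sample_id`, `group_label`.
#' @export
readDesign <- function(path, ps = NULL) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = "character", check.names = FALSE)
    if (!all(c("sample_id", "group_label") %in% colnames(df)))
        stop("design table needs columns sample_id, group_label")
    df <- df[, c("sample_id", "group_label")]
    if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in design")
    if (!is.null(ps) && !all(df$sample_id %in% colnames(ps)))
        stop("design references sample ids absent from the matrix")
    rownames(df) <- NULL
    df
}

#' Write benchmark objects to delimited text
#'
#' `ProteoSet` objects are written as a matrix table (`feature_id` first
#' column, `NA` for missing); annotation/design data.frames and
#' [GroupCatalog-class] objects as their documented TSV layouts.
#' `read*(writeTable(x))` round-trips.
#'
#' @param obj object to serialize.
#' @param path output file; the matrix layout uses the extension to pick
#'   the delimiter (`.csv` comma, otherwise tab).
#' @return `path`, invisibly.
#' @export
setGeneric("writeTable", function(obj, path) standardGeneric("writeTable"))

#' @rdname writeTable
#' @export
setMethod("writeTable", "ProteoSet", function(obj, path) {
    sep <- if (grepl("\\.csv$", path)) "," else "\t"
    v <- .values(obj)
    df <- data.frame(feature_id = rownames(v), v, check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
    invisible(path)
})

#' @rdname writeTable
#' @export
setMethod("writeTable", "data.frame", function(obj, path) {
    utils::write.table(obj, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
})

#' @rdname writeTable
#' @export
setMethod("writeTable", "GroupCatalog", function(obj, path) {
    g <- groupList(obj)
    df <- data.frame(group_id = rep(names(g), lengths(g)),
                     protein_id = unlist(g, use.names = FALSE))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
})
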