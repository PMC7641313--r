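# The proteomics-specific co-expression criteria: average pairwise
# correlation within groups defined at four biological levels.  Charge
# states of one peptide, peptides of one protein, proteins of one complex
# and proteins of one PPI cluster should all co-vary across samples;
# imputation that destroys that structure lowers these scores.

#' Build grouped expression profiles at a biological level
#'
#' Level `"charge"`: features sharing a peptide sequence with at least two
#' distinct charge states form a group (members = precursor features).
#' Level `"peptide"`: features are first aggregated (mean) to peptide
#' profiles, peptides sharing a protein form a group.  Levels `"complex"`
#' and `"ppi_cluster"`: features are aggregated to protein profiles, and a
#' [GroupCatalog-class] assigns proteins to groups; the aggregation takes
#' the mean of the top-3 most abundant member profiles (`aggregate =
#' "top3"`, the usual protein summarization) or of all members.
#' Groups with fewer than two matched members are dropped.
#'
#' @param m a [ProteoSet-class] (complete or not; correlations later use
#'   pairwise-complete samples).
#' @param ann feature annotation data.frame (`feature_id`,
#'   `peptide_sequence`, `charge`, `protein_id`); may be `NULL` for
#'   complex/cluster levels when the matrix rows already are proteins.
#' @param catalog a [GroupCatalog-class]; required for complex/cluster
#'   levels.
#' @param level `"charge"`, `"peptide"`, `"complex"` or `"ppi_cluster"`.
#' @param aggregate `"top3"` or `"mean"` protein summarization.
#' @return list with `groups` (named list of member x sample matrices) and
#'   `level`.
#' @export
buildGroups <- function(m, ann = NULL,
                        catalog = NULL,
                        level = c("charge", "peptide", "complex",
                                  "ppi_cluster"),
                        aggregate = c("top3", "mean")) {
    level <- match.arg(level)
    aggregate <- match.arg(aggregate)
    v <- .values(.asProteoSet(m))
    if (level %in% c("charge", "peptide")) {
        if (is.null(ann) || !any(nzchar(ann$peptide_sequence %||% "")))
            stop("no peptide annotation")
        ann <- ann[match(rownames(v), ann$feature_id), , drop = FALSE]
        ok <- !is.na(ann$feature_id)
        v <- v[ok, , drop = FALSE]
        ann <- ann[ok, , drop = FALSE]
    }
    groups <- switch(level,
        charge = {
            keep <- nzchar(ann$peptide_sequence) & !is.na(ann$charge)
            idx <- split(which(keep), ann$peptide_sequence[keep])
            idx <- lapply(idx, function(i)
                i[!duplicated(ann$charge[i])])
            lapply(idx, function(i) v[i, , drop = FALSE])
        },
        peptide = {
            keep <- nzchar(ann$peptide_sequence) & nzchar(ann$protein_id)
            pep <- .aggregateProfiles(v[keep, , drop = FALSE],
                                      ann$peptide_sequence[keep], "mean")
            prot <- ann$protein_id[keep][match(rownames(pep),
                                               ann$peptide_sequence[keep])]
            idx <- split(seq_len(nrow(pep)), prot)
            lapply(idx, function(i) pep[i, , drop = FALSE])
        },
        {
            if (is.null(catalog)) stop("a group catalog is required")
            protM <- .proteinProfiles(v, ann, aggregate)
            lapply(groupList(catalog), function(members) {
                hit <- intersect(members, rownames(protM))
                protM[hit, , drop = FALSE]
            })
        })
    groups <- groups[vapply(groups, nrow, 0L) >= 2L]
    list(groups = groups, level = level)
}

.aggregateProfiles <- function(v, by, how) {
    idx <- split(seq_len(nrow(v)), by)
    out <- t(vapply(idx, function(i) {
        M <- v[i, , drop = FALSE]
        if (how == "top3" && nrow(M) > 3L) {
            ab <- rowMeans(M, na.rm = TRUE)
            M <- M[order(-ab)[1:3], , drop = FALSE]
        }
        colMeans(M, na.rm = TRUE)
    }, numeric(ncol(v))))
    out[is.nan(out)] <- NA_real_
    out
}

# protein-level profiles: identity if rows already are proteins (no
# annotation), otherwise aggregate features per protein accession
.proteinProfiles <- function(v, ann, aggregate) {
    if (is.null(ann) || !any(nzchar(ann$protein_id %||% ""))) return(v)
    ann <- ann[match(rownames(v), ann$feature_id), , drop = FALSE]
    keep <- !is.na(ann$feature_id) & nzchar(ann$protein_id)
    .aggregateProfiles(v[keep, , drop = FALSE], ann$protein_id[keep],
                       aggregate)
}

#' Average within-group pairwise correlation
#'
#' Per group, the mean correlation across samples over all unordered
#' member pairs; pairs where either profile has zero variance are
#' skipped, and a group with no valid pair is dropped.  The criterion is
#' the mean of the group scores over the n retained groups.  The
#' `divisor = "m"` variant divides each group's pair-sum by the member
#' count m instead of the pair count (then group scores are not bounded
#' by 1 for m > 3).
#'
#' @param gps output of [buildGroups()].
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param divisor `"pairs"` (mean over unordered pairs, default) or
#'   `"m"`.
#' @param criterion criterion label for the score record.
#' @return A [CriterionScore-class] (`higher_better`); `nUsed` = number
#'   of groups entering the mean.
#' @export
groupPairwiseAcc <- function(gps, method = c("pearson", "spearman"),
                             divisor = c("pairs", "m"),
                             criterion = "ACC") {
    method <- match.arg(method)
    divisor <- match.arg(divisor)
    scores <- vapply(gps$groups, function(M) {
        cc <- suppressWarnings(
            stats::cor(t(M), method = method,
                       use = "pairwise.complete.obs"))
        pr <- cc[upper.tri(cc)]
        pr <- pr[!is.na(pr)]
        if (!length(pr)) return(NA_real_)
        if (divisor == "pairs") mean(pr) else sum(pr) / nrow(M)
    }, 0)
    scores <- scores[!is.na(scores)]
    if (!length(scores))
        return(.score(criterion, NA, "higher_better", 0L,
                      "no group with >= 2 matched members and a valid pair"))
    .score(criterion, mean(scores), "higher_better", length(scores))
}

#' The four proteomic criteria
#'
#' Thin compositions of [buildGroups()] and [groupPairwiseAcc()]:
#' `accCharge()` correlates charge states within peptides, `accPepProt()`
#' peptides within proteins, `accComplex()` proteins within complexes
#' (CORUM-style catalog) and `accPpi()` proteins within PPI clusters
#' (hu.MAP-style catalog).  Each is also computable on the un-imputed
#' original matrix to give the reference value an ideal imputation should
#' reproduce.
#'
#' @param m a [ProteoSet-class].
#' @param ann feature annotation data.frame; `NULL` allowed for
#'   protein-level matrices in `accComplex`/`accPpi`.
#' @param catalog a [GroupCatalog-class].
#' @param ... passed to [groupPairwiseAcc()] (`method`, `divisor`).
#' @return A [CriterionScore-class] (`higher_better`); missing with a
#'   reason when the level is inapplicable (e.g. no peptide annotation on
#'   a protein-level matrix).
#' @export
accCharge <- function(m, ann, ...) {
    gps <- tryCatch(buildGroups(m, ann, level = "charge"),
                    error = function(e) conditionMessage(e))
    if (is.character(gps))
        return(.score("ACC_Charge", NA, "higher_better", 0L, gps))
    groupPairwiseAcc(gps, criterion = "ACC_Charge", ...)
}

#' @rdname accCharge
#' @export
accPepProt <- function(m, ann, ...) {
    gps <- tryCatch(buildGroups(m, ann, level = "peptide"),
                    error = function(e) conditionMessage(e))
    if (is.character(gps))
        return(.score("ACC_PepProt", NA, "higher_better", 0L, gps))
    groupPairwiseAcc(gps, criterion = "ACC_PepProt", ...)
}

#' @rdname accCharge
#' @export
accComplex <- function(m, ann = NULL, catalog, ...) {
    gps <- tryCatch(buildGroups(m, ann, catalog, level = "complex"),
                    error = function(e) conditionMessage(e))
    if (is.character(gps))
        return(.score("ACC_CORUM", NA, "higher_better", 0L, gps))
    groupPairwiseAcc(gps, criterion = "ACC_CORUM", ...)
}

#' @rdname accCharge
#' @export
accPpi <- function(m, ann = NULL, catalog, ...) {
    gps <- tryCatch(buildGroups(m, ann, catalog, level = "ppi_cluster"),
                    error = function(e) conditionMessage(e))
    if (is.character(gps))
        return(.score("ACC_PPI", NA, "higher_better", 0L, gps))
    groupPairwiseAcc(gps, criterion = "ACC_PPI", ...)
}

#' Export per-group scores for distribution plots
#'
#' One row per retained group: its id, level, member count and mean
#' pairwise correlation -- the ingredients of a per-method score
#' distribution plot.
#'
#' @param gps output of [buildGroups()].
#' @param method,divisor as in [groupPairwiseAcc()].
#' @return data.frame with columns `group_id`, `level`, `m`,
#'   `group_score`.
#' @export
groupScoreTable <- function(gps, method = "pearson", divisor = "pairs") {
    rows <- lapply(names(gps$groups), function(g) {
        M <- gps$groups[[g]]
        cc <- suppressWarnings(
            stats::cor(t(M), method = method,
                       use = "pairwise.complete.obs"))
        pr <- cc[upper.tri(cc)]
        pr <- pr[!is.na(pr)]
        sc <- if (!length(pr)) NA_real_
              else if (divisor == "pairs") mean(pr) else sum(pr) / nrow(M)
        data.frame(group_id = g, level = gps$level, m = nrow(M),
                   group_score = sc)
    })
    do.call(rbind, rows)
}
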