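# Synthetic DIA-like data with the hierarchical correlation structure the
# proteomic criteria assume: charge states within peptides within proteins
# within complexes/clusters, plus a two-group design with spiked effects
# and intensity-dependent (left-censored) missingness.

#' Describe a synthetic dataset
#'
#' Defaults emulate a mid-size two-condition DIA experiment: 200 proteins
#' digested into 2-5 peptides observed at 1-3 charge states (~1400
#' precursor features), 10 biological replicates per group, log2
#' intensities around 22 +/- 2, peptide-level noise sd 0.3 log2 units,
#' within-protein correlation 0.8 and within-complex correlation 0.7 via
#' latent factors, 10% differential proteins at 1 log2 unit effect.
#'
#' @param nProteins number of proteins.
#' @param peptidesPerProtein integer range `c(min, max)`.
#' @param chargesPerPeptide integer range `c(min, max)`.
#' @param nSamplesPerGroup replicates per condition (2 conditions).
#' @param complexCount,complexSize protein-complex catalog shape.
#' @param ppiClusterCount,ppiClusterSize PPI-cluster catalog shape.
#' @param deFraction fraction of proteins with a group effect.
#' @param effectSize |log2 FC| of differential proteins.
#' @param noiseSd peptide-level noise sd (log2 units); charge-state noise
#'   is `noiseSd/2`.
#' @param withinProteinR target correlation between peptides of one
#'   protein.
#' @param withinComplexR target correlation between proteins of one
#'   complex/cluster.
#' @param mcarFraction,mnarStrength defaults handed to
#'   [injectMissingness()].
#' @param seed integer seed.
#' @return list of settings (class `FixtureSpec`).
#' @export
fixtureSpec <- function(nProteins = 200L,
                        peptidesPerProtein = c(2L, 5L),
                        chargesPerPeptide = c(1L, 3L),
                        nSamplesPerGroup = 10L,
                        complexCount = 30L, complexSize = c(3L, 6L),
                        ppiClusterCount = 25L, ppiClusterSize = c(3L, 8L),
                        deFraction = 0.1, effectSize = 1.0,
                        noiseSd = 0.3,
                        withinProteinR = 0.8, withinComplexR = 0.7,
                        mcarFraction = 0.1, mnarStrength = 5,
                        seed = 1L) {
    spec <- as.list(environment())
    stopifnot(nProteins > 0, nSamplesPerGroup >= 2,
              all(peptidesPerProtein >= 1), all(chargesPerPeptide >= 1),
              deFraction >= 0, deFraction <= 1, noiseSd > 0,
              withinProteinR > 0, withinProteinR < 1,
              withinComplexR > 0, withinComplexR < 1)
    structure(spec, class = "FixtureSpec")
}

.sampleRange <- function(n, range) {
    if (range[1L] == range[2L]) rep(range[1L], n)
    else sample(seq(range[1L], range[2L]), n, replace = TRUE)
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Protein base abundances are Normal(22, 2) on log2; each protein's
#' per-sample signal adds its group effect (for differential proteins), a
#' shared complex latent factor scaled for the target within-complex
#' correlation, and protein-level noise scaled so peptides of one protein
#' correlate at the target level given `noiseSd`.  Peptides add an
#' abundance offset and Normal(0, noiseSd) noise; charge states add a
#' smaller offset and Normal(0, noiseSd/2).  Fixed seed gives a
#' bitwise-identical dataset.
#'
#' @param spec a [fixtureSpec()].
#' @return list: `matrix` (complete log2 [ProteoSet-class] with
#'   annotation in `rowData` and design in `colData`), `annotation`
#'   (data.frame), `design` (data.frame), `complexCatalog`, `ppiCatalog`
#'   ([GroupCatalog-class]), `truth` (list: `deProteins`, `deFeatures`,
#'   `effects`, `complexAssignment`).
#' @export
generateDataset <- function(spec = fixtureSpec()) {
    withSeed(spec$seed, .generateDataset(spec))
}

.generateDataset <- function(spec) {
    nS <- 2L * spec$nSamplesPerGroup
    sampleIds <- sprintf("S%02d", seq_len(nS))
    groupLab <- rep(c("A", "B"), each = spec$nSamplesPerGroup)
    protIds <- sprintf("P%04d", seq_len(spec$nProteins))

    # per-sample protein signal sd from the within-protein target
    sigmaP <- spec$noiseSd *
        sqrt(spec$withinProteinR / (1 - spec$withinProteinR))

    # complexes partition a subset of the proteins (disjoint membership,
    # as the latent-factor model assumes); PPI clusters echo the same
    # co-abundance structure with a little membership noise, the way
    # interaction-map clusters recover complexes imperfectly
    avail <- sample(protIds)
    complexes <- list()
    for (k in seq_len(spec$complexCount)) {
        sz <- .sampleRange(1L, spec$complexSize)
        if (length(avail) < max(2L, sz)) break
        complexes[[sprintf("CPX%03d", k)]] <- sort(avail[seq_len(sz)])
        avail <- avail[-seq_len(sz)]
    }
    nClu <- min(spec$ppiClusterCount, length(complexes))
    cluFrom <- sample(seq_along(complexes), nClu)
    clusters <- lapply(seq_len(nClu), function(j) {
        g <- complexes[[cluFrom[j]]]
        extra <- sample(setdiff(protIds, g),
                        min(.sampleRange(1L, c(0L, 2L)),
                            spec$nProteins - length(g)))
        sort(c(g, extra))
    })
    names(clusters) <- sprintf("PPI%03d", seq_len(nClu))

    # complex membership drives a protein's latent factor
    cpxOf <- rep(NA_integer_, spec$nProteins)
    for (k in seq_along(complexes)) {
        i <- match(complexes[[k]], protIds)
        cpxOf[i] <- k
    }
    factors <- matrix(stats::rnorm(length(complexes) * nS),
                      length(complexes), nS)

    nDE <- roundHalfUp(spec$deFraction * spec$nProteins)
    deProteins <- if (nDE > 0) sort(sample(protIds, nDE)) else character()
    effects <- stats::setNames(rep(0, spec$nProteins), protIds)
    if (nDE > 0)
        effects[deProteins] <- spec$effectSize *
            sample(c(-1, 1), nDE, replace = TRUE)

    base <- stats::rnorm(spec$nProteins, 22, 2)
    lamC <- sigmaP * sqrt(spec$withinComplexR)
    sdE <- sigmaP * sqrt(1 - spec$withinComplexR)
    protSig <- matrix(0, spec$nProteins, nS)
    for (i in seq_len(spec$nProteins)) {
        shared <- if (is.na(cpxOf[i])) 0 else lamC * factors[cpxOf[i], ]
        own <- if (is.na(cpxOf[i])) stats::rnorm(nS, 0, sigmaP)
               else stats::rnorm(nS, 0, sdE)
        protSig[i, ] <- base[i] + shared + own +
            effects[i] * (groupLab == "B")
    }

    nPep <- .sampleRange(spec$nProteins, spec$peptidesPerProtein)
    rows <- list(); ann <- list()
    for (i in seq_len(spec$nProteins)) {
        for (p in seq_len(nPep[i])) {
            pepSeq <- sprintf("%s_PEP%02d", protIds[i], p)
            pepOffset <- stats::rnorm(1L, 0, 1.5)
            pepVal <- protSig[i, ] + pepOffset +
                stats::rnorm(nS, 0, spec$noiseSd)
            nz <- .sampleRange(1L, spec$chargesPerPeptide)
            zs <- seq(2L, length.out = nz)
            for (z in zs) {
                fid <- sprintf("%s_z%d", pepSeq, z)
                chOffset <- stats::rnorm(1L, 0, 0.5)
                rows[[fid]] <- pepVal + chOffset +
                    stats::rnorm(nS, 0, spec$noiseSd / 2)
                ann[[fid]] <- data.frame(
                    feature_id = fid, peptide_sequence = pepSeq,
                    charge = z, protein_id = protIds[i])
            }
        }
    }
    v <- do.call(rbind, rows)
    colnames(v) <- sampleIds
    annotation <- do.call(rbind, ann)
    rownames(annotation) <- NULL
    design <- data.frame(sample_id = sampleIds, group_label = groupLab)

    ps <- ProteoSet(v, scaleTag = "log2",
                    rowData = annotation[, c("peptide_sequence", "charge",
                                             "protein_id")],
                    colData = design)
    list(matrix = ps, annotation = annotation, design = design,
         complexCatalog = GroupCatalog(complexes, "complex"),
         ppiCatalog = GroupCatalog(clusters, "ppi_cluster"),
         truth = list(deProteins = deProteins,
                      deFeatures = annotation$feature_id[
                          annotation$protein_id %in% deProteins],
                      effects = effects, complexAssignment = cpxOf))
}

#' Inject MCAR and/or left-censored (MNAR) missingness
#'
#' MCAR cells are a uniform draw; MNAR cells are drawn without
#' replacement with probability proportional to
#' `plogis(mnarStrength * (tau - x))`, `tau` = the matrix's 10th
#' percentile, so low-intensity cells are censored preferentially.  The
#' total missing fraction equals `mcarFraction + mnarFraction` within
#' rounding.
#'
#' @param m a complete [ProteoSet-class].
#' @param mcarFraction fraction of cells missing completely at random.
#' @param mnarFraction fraction of cells censored by intensity.
#' @param mnarStrength steepness of the censoring logistic (per log2
#'   unit).
#' @param seed integer seed.
#' @return A [ProteoSet-class] with NAs.
#' @export
injectMissingness <- function(m, mcarFraction = 0.1, mnarFraction = 0,
                              mnarStrength = 5, seed = NULL) {
    m <- .asProteoSet(m)
    v <- .values(m)
    if (anyNA(v)) stop("matrix must be complete")
    stopifnot(mcarFraction >= 0, mnarFraction >= 0,
              mcarFraction + mnarFraction < 1)
    nCells <- length(v)
    nMcar <- as.integer(roundHalfUp(mcarFraction * nCells))
    nMnar <- as.integer(roundHalfUp(mnarFraction * nCells))
    withSeed(seed, {
        drop <- integer()
        if (nMnar > 0L) {
            tau <- stats::quantile(v, 0.10, names = FALSE)
            w <- stats::plogis(mnarStrength * (tau - as.vector(v)))
            drop <- sample.int(nCells, nMnar, prob = w)
        }
        if (nMcar > 0L) {
            left <- setdiff(seq_len(nCells), drop)
            drop <- c(drop, sample(left, nMcar))
        }
        v[drop] <- NA_real_
    })
    .setValues(m, v)
}

#' Write a full fixture to disk
#'
#' Emits the standard matrix/annotation/design TSVs, both catalog TSVs
#' and a `truth.json` into `dir`.
#'
#' @param data output of [generateDataset()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeFixture <- function(data, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeTable(data$matrix, file.path(dir, "matrix.tsv"))
    writeTable(data$annotation, file.path(dir, "annotation.tsv"))
    writeTable(data$design, file.path(dir, "design.tsv"))
    writeTable(data$complexCatalog, file.path(dir, "complexes.tsv"))
    writeTable(data$ppiCatalog, file.path(dir, "ppi_clusters.tsv"))
    jsonlite::write_json(
        list(deProteins = data$truth$deProteins,
             deFeatures = data$truth$deFeatures,
             effects = as.list(data$truth$effects)),
        file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
    invisible(dir)
}
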