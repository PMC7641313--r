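test_that("matrix parsing marks NA tokens, empties and raw zeros missing", {
    f <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("feature_id,s1,s2,s3",
                 "p1,100,200,300",
                 "p2,,NA,400",
                 "p3,0,50,NaN"), f)
    ps <- readMatrix(f, scaleTag = "raw")
    v <- intensities(ps)
    expect_equal(scaleTag(ps), "log2")
    expect_equal(sum(is.na(v)), 4L)   # empty, NA, zero, NaN
    expect_equal(v["p1", "s1"], log2(100))
    # without the log2 transform, raw positivity is enforced
    raw <- readMatrix(f, scaleTag = "raw", log2Transform = FALSE)
    expect_equal(scaleTag(raw), "raw")
    expect_true(all(intensities(raw) > 0, na.rm = TRUE))
})

test_that("parsing rejects duplicate ids, bad cells and too few samples", {
    f <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("feature_id,s1,s2", "p1,1,2", "p1,3,4"), f)
    expect_error(readMatrix(f), "duplicate")
    writeLines(c("feature_id,s1,s2", "p1,1,oops"), f)
    expect_error(readMatrix(f), "non-numeric")
    writeLines(c("feature_id,s1", "p1,1"), f)
    expect_error(readMatrix(f), "2 samples")
})

test_that("matrix and table round-trips are identity and idempotent", {
    v <- makeStructuredMatrix(5, 3)
    v[c(2, 9)] <- NA
    ps <- asPS(v)
    f <- withr::local_tempfile(fileext = ".tsv")
    writeTable(ps, f)
    back <- readMatrix(f, scaleTag = "log2")
    expect_equal(intensities(back), intensities(ps))
    # read(write(read(f))) = read(f)
    f2 <- withr::local_tempfile(fileext = ".tsv")
    writeTable(back, f2)
    expect_equal(intensities(readMatrix(f2, "log2")), intensities(back))

    cat <- GroupCatalog(list(g1 = c("P1", "P2"), g2 = c("P3", "P2")),
                        "complex")
    fg <- withr::local_tempfile(fileext = ".tsv")
    writeTable(cat, fg)
    expect_equal(groupList(readGroups(fg, "complex")), groupList(cat))
})

test_that("annotation reader keeps charge variants and skips unknown ids", {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("feature_id\tpeptide_sequence\tcharge\tprotein_id",
                 "f1\tPEPTIDEK\t2\tP1",
                 "f2\tPEPTIDEK\t3\tP1",
                 "zz\tOTHERK\t2\tP2"), f)
    ann <- readAnnotation(f)
    expect_equal(sum(ann$peptide_sequence == "PEPTIDEK"), 2L)
    ps <- asPS(makeStructuredMatrix(2, 3))
    rownames(ps) <- c("f1", "f2")
    expect_warning(ann2 <- readAnnotation(f, ps), "unknown feature")
    expect_equal(ann2$feature_id, c("f1", "f2"))
})

test_that("one-member groups load but are excluded from scoring", {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("group_id\tprotein_id",
                 "cpx1\tf0001", "cpx1\tf0002", "lonely\tf0003"), f)
    cat <- readGroups(f, "complex")
    expect_length(groupList(cat), 2L)
    v <- makeStructuredMatrix(4, 6)
    gps <- buildGroups(asPS(v), catalog = cat, level = "complex")
    expect_named(gps$groups, "cpx1")
})

test_that("completeness summary counts features, cells and per-sample NAs", {
    v <- makeStructuredMatrix(10, 10, seed = 4)
    expect_equal(completenessSummary(asPS(v))$fraction_features_with_any_na,
                 0)
    v[cbind(1:5, c(2, 4, 6, 8, 10))] <- NA   # 5 cells in 5 features
    s <- completenessSummary(asPS(v))
    expect_equal(s$n_missing_cells, 5L)
    expect_equal(s$fraction_features_with_any_na, 0.5)
    expect_equal(sum(s$per_sample_counts), s$n_missing_cells)

    v2 <- makeStructuredMatrix(4, 5, seed = 5)
    v2[2, c(1, 3)] <- NA
    expect_equal(completenessSummary(asPS(v2))$fraction_features_with_any_na,
                 0.25)
})

test_that("NA filtration matches a brute-force recount and edge thresholds", {
    set.seed(11)
    v <- makeStructuredMatrix(100, 10, seed = 11)
    naPer <- sample(0:7, 100, replace = TRUE)
    for (i in seq_len(100)) if (naPer[i] > 0)
        v[i, sample(10, naPer[i])] <- NA
    ps <- asPS(v)
    kept <- rownames(filterByNA(ps, 0.5))
    oracle <- rownames(v)[rowSums(is.na(v)) / 10 <= 0.5]
    expect_identical(kept, oracle)
    expect_identical(rownames(filterByNA(ps, 1.0)), rownames(v))
    expect_identical(rownames(filterByNA(ps, 0)),
                     rownames(v)[rowSums(is.na(v)) == 0])
    # 3 NAs of 10 at threshold 0.2 is out
    v3 <- makeStructuredMatrix(2, 10)
    v3[1, 1:3] <- NA
    expect_identical(rownames(filterByNA(asPS(v3), 0.2)), rownames(v3)[2])
})

test_that("CV filtration computes raw-scale CV and honours groups", {
    # log2 of [5,15]: CV = 100*sd/mean = 70.71% > 50 -> removed
    v <- rbind(f1 = log2(c(5, 15)), f2 = log2(c(10, 10)))
    colnames(v) <- c("s1", "s2")
    kept <- filterByCV(ProteoSet(v), 50)
    expect_identical(rownames(kept), "f2")
    # constant matrix survives even a 1% threshold
    vc <- matrix(log2(10), 3, 4,
                 dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
    expect_equal(nrow(filterByCV(ProteoSet(vc), 1)), 3L)
    # per-group: variable overall, tight within each group -> kept
    vg <- rbind(reg = log2(c(10, 10.4, 100, 101)),
                noisy = log2(c(10, 90, 100, 9)))
    colnames(vg) <- paste0("s", 1:4)
    design <- data.frame(sample_id = paste0("s", 1:4),
                         group_label = c("A", "A", "B", "B"))
    kept <- filterByCV(ProteoSet(vg), 30, design)
    expect_identical(rownames(kept), "reg")
    # undefined CV (single observed value) retains with warning
    vu <- rbind(u = c(log2(10), NA), ok = log2(c(5, 6)))
    colnames(vu) <- c("s1", "s2")
    expect_warning(keptU <- filterByCV(ProteoSet(vu), 50), "undefined")
    expect_true("u" %in% rownames(keptU))
})

test_that("ProteoSet validity enforces ids, scale and sample count", {
    v <- makeStructuredMatrix(3, 3)
    expect_s4_class(asPS(v), "ProteoSet")
    bad <- v; rownames(bad) <- c("a", "a", "b")
    expect_error(ProteoSet(bad), "unique")
    expect_error(ProteoSet(v[, 1, drop = FALSE]), "2 samples")
    neg <- v; neg[1, 1] <- -2
    expect_error(ProteoSet(neg, scaleTag = "raw"), "> 0")
})
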