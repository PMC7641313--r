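dirs2 <- c(A = "higher_better", B = "lower_better")

test_that("score normalization maps the best method to 1 per criterion", {
    raw <- matrix(c(2, 4, 0.2, 0.4), 2, 2,
                  dimnames = list(c("m1", "m2"), c("A", "B")))
    norm <- normalizeScores(raw, dirs2)
    expect_equal(norm[, "A"], c(m1 = 0.5, m2 = 1.0))
    expect_equal(norm[, "B"], c(m1 = 1.0, m2 = 0.5))
    # single method normalizes to 1 either way
    one <- matrix(c(3, 0.7), 1, 2, dimnames = list("m", c("A", "B")))
    expect_equal(as.vector(normalizeScores(one, dirs2)), c(1, 1))
    # a perfect 0 on a lower_better criterion stays the best
    rawz <- matrix(c(0, 0.4), 2, 1, dimnames = list(c("m1", "m2"), "B"))
    nz <- normalizeScores(rawz, c(B = "lower_better"))
    expect_equal(nz[, "B"], c(m1 = 1, m2 = 0))
    # missing stays missing; zero max is flagged
    rawm <- matrix(c(NA, 2, 0, 0), 2, 2,
                   dimnames = list(c("m1", "m2"), c("A", "B")))
    expect_warning(nm <- normalizeScores(matrix(c(0, 0), 2, 1,
        dimnames = list(c("m1", "m2"), "A")), c(A = "higher_better")),
        "skipped")
    expect_true(all(is.na(nm)))
})

test_that("normalization preserves the raw-score ordering per direction", {
    set.seed(1)
    raw <- matrix(abs(rnorm(12, 2)), 4, 3,
                  dimnames = list(paste0("m", 1:4), c("A", "B", "C")))
    dirs <- c(A = "higher_better", B = "lower_better", C = "lower_better")
    norm <- normalizeScores(raw, dirs)
    for (cr in colnames(raw)) {
        key <- if (dirs[cr] == "higher_better") raw[, cr] else -raw[, cr]
        expect_equal(order(-norm[, cr]), order(-key))
    }
})

test_that("composite ranks follow hand computation and weight rules", {
    scoreList <- list(
        m1 = list(.sc("NRMSE", 0.2), .sc("ACC_OI", 0.9, "higher_better")),
        m2 = list(.sc("NRMSE", 0.5), .sc("ACC_OI", 0.8, "higher_better")),
        m3 = list(.sc("NRMSE", 0.9, reason = ""),
                  .sc("ACC_OI", NA, "higher_better", reason = "constant")))
    st <- ImputeBenchMS:::.assembleScoreTable(scoreList)
    r <- scoreRanks(st)
    expect_equal(unname(r[, "NRMSE"]), c(1, 2, 3))
    # missing score ranks worst
    expect_equal(unname(r["m3", "ACC_OI"]), 3)
    comp <- compositeRanks(st, "classic")
    expect_equal(comp$method[comp$composite_rank == 1], "m1")
    expect_equal(comp$method[comp$composite_rank == 3], "m3")
    # zero weight on a criterion = ranking without it
    w0 <- rankMethods(st, weights = c(NRMSE = 1, ACC_OI = 0), "classic")
    expect_equal(w0$mean_rank, unname(r[, "NRMSE"]))
    # uniform weight scaling changes nothing
    wa <- rankMethods(st, weights = c(NRMSE = 1, ACC_OI = 1), "classic")
    wb <- rankMethods(st, weights = c(NRMSE = 5, ACC_OI = 5), "classic")
    expect_equal(wa$composite_rank, wb$composite_rank)
    # rank-sum conservation within each criterion
    expect_equal(unname(colSums(r)), rep(6, ncol(r)))
})

test_that("the final check flags only criteria without spread", {
    scoreList <- list(
        m1 = list(.sc("NRMSE", 0.4), .sc("ACC_OI", 0.90, "higher_better")),
        m2 = list(.sc("NRMSE", 0.4), .sc("ACC_OI", 0.45, "higher_better")))
    st <- ImputeBenchMS:::.assembleScoreTable(scoreList)
    fc <- finalCheck(st, spreadThreshold = 0.05)
    expect_true(fc$flagged[fc$criterion == "NRMSE"])
    expect_false(fc$flagged[fc$criterion == "ACC_OI"])
    # all-identical scores flag every criterion
    same <- list(m1 = list(.sc("NRMSE", 0.3)), m2 = list(.sc("NRMSE", 0.3)))
    st2 <- ImputeBenchMS:::.assembleScoreTable(same)
    expect_true(all(finalCheck(st2)$flagged))
    expect_error(finalCheck(ImputeBenchMS:::.assembleScoreTable(same[1])),
                 "2 methods")
})

test_that("targeted check reports imputed ranges and out-of-range flags", {
    v <- makeStructuredMatrix(5, 4, seed = 2)
    v[] <- v + 2   # keep range around 20+
    truth <- v
    v[2, 3] <- NA
    ps <- asPS(v)
    res <- list(zero = imputeMatrix(ps, "zero"),
                rowmedian = imputeMatrix(ps, "rowmedian"),
                knn = imputeKnn(ps, k = 2))
    tc <- targetedCheck(ps, res, rownames(v)[c(1, 2)])
    expect_equal(nrow(tc), 6L)   # 2 features x 3 methods
    f1 <- tc[tc$feature_id == rownames(v)[1], ]
    expect_true(all(f1$note == "no imputed cells"))
    # zero fill far below the observed log2 range is flagged
    f2z <- tc[tc$feature_id == rownames(v)[2] & tc$method == "zero", ]
    expect_true(f2z$out_of_range)
    f2r <- tc[tc$feature_id == rownames(v)[2] & tc$method == "rowmedian", ]
    expect_false(f2r$out_of_range)
    # unknown ids are reported, not fatal
    tcu <- targetedCheck(ps, res["zero"], "nope")
    expect_equal(tcu$note, "unknown feature")
})

test_that("the assembled benchmark writes coherent score tables", {
    d <- generateDataset(fixtureSpec(nProteins = 30, seed = 9))
    dir <- withr::local_tempdir()
    out <- runBenchmark(injectMissingness(d$matrix, 0.05, seed = 2),
                        outDir = dir,
                        methods = c("zero", "rowmedian", "knn", "svd"),
                        ann = d$annotation,
                        complexCatalog = d$complexCatalog,
                        ppiCatalog = d$ppiCatalog, seed = 5)
    st <- out$table
    expect_setequal(rownames(rawScores(st)),
                    c("zero", "rowmedian", "knn", "svd"))
    expect_true(all(c("NRMSE", "SOR", "ACC_OI", "PSS", "ACC_Charge",
                      "ACC_PepProt", "ACC_CORUM", "ACC_PPI")
                    %in% colnames(rawScores(st))))
    nv <- normalizedScores(st)
    expect_true(all(nv[!is.na(nv)] <= 1 + 1e-12))
    expect_true(all(file.exists(file.path(dir,
        c("raw_scores.tsv", "normalized_scores.tsv", "ranks_classic.tsv",
          "ranks_proteomic.tsv", "final_check_report.tsv",
          "manifest.json")))))
    # deterministic under the same seed
    out2 <- runBenchmark(injectMissingness(d$matrix, 0.05, seed = 2),
                         methods = c("zero", "rowmedian", "knn", "svd"),
                         ann = d$annotation,
                         complexCatalog = d$complexCatalog,
                         ppiCatalog = d$ppiCatalog, seed = 5)
    expect_identical(rawScores(out$table), rawScores(out2$table))
})
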