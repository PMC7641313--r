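test_that("single-value imputers fill their defining constants", {
    v <- rbind(f1 = c(3, NA, 7), f2 = c(5, NA, 4), f3 = c(6, 8, NA))
    colnames(v) <- paste0("s", 1:3)
    ps <- ProteoSet(v)
    # global minimum of observed {3,7,5,4,6,8} = 3 fills every NA
    mi <- intensities(imputedMatrix(imputeSingleValue(ps, "minimum")))
    expect_equal(mi[is.na(v)], rep(3, 3))
    expect_equal(intensities(imputedMatrix(imputeSingleValue(ps,
                                                             "zero")))[is.na(v)],
                 rep(0, 3))
    # column medians over observed values
    cm <- intensities(imputedMatrix(imputeSingleValue(ps, "colmedian")))
    expect_equal(cm["f1", "s2"], 8)
    v2 <- rbind(a = c(2, NA), b = c(4, 5), c = c(6, 7))
    colnames(v2) <- c("s1", "s2")
    expect_equal(intensities(imputedMatrix(
        imputeSingleValue(ProteoSet(v2), "colmedian")))["a", "s2"], 6)
    rm <- intensities(imputedMatrix(imputeSingleValue(ps, "rowmedian")))
    expect_equal(rm["f1", "s2"], 5)
    # a sample with no observation is an error for colmedian
    v3 <- rbind(a = c(1, NA), b = c(2, NA))
    colnames(v3) <- c("s1", "s2")
    expect_error(imputeSingleValue(ProteoSet(v3), "colmedian"),
                 "no observed")
})

test_that("mindet at q = 0 equals the per-sample minimum", {
    v <- makeStructuredMatrix(20, 4, seed = 3)
    v[cbind(c(2, 5, 9), c(1, 2, 4))] <- NA
    r <- intensities(imputedMatrix(
        imputeLeftCensored(asPS(v), "mindet", params = list(q = 0))))
    for (j in c(1, 2, 4)) {
        filled <- r[is.na(v[, j]), j]
        expect_equal(unname(filled), rep(min(v[, j], na.rm = TRUE),
                                         length(filled)))
    }
})

test_that("pi with zero width is the deterministic downshifted mean", {
    v <- makeStructuredMatrix(30, 3, seed = 6)
    v[4, 2] <- NA
    r <- imputeLeftCensored(asPS(v), "pi", params = list(width = 0),
                            seed = 1)
    obs <- v[-4, 2]
    obs <- c(obs, v[4, 2])
    x <- v[, 2][!is.na(v[, 2])]
    expected <- mean(x) - 1.8 * sd(x)
    expect_equal(intensities(imputedMatrix(r))[4, 2], expected)
})

test_that("minprob draws match the truncated-normal closed form", {
    # one sample with many censored cells: empirical mean of the draws
    # must match E[X | X < upper] for X ~ N(center, sd)
    set.seed(2)
    obs <- rnorm(60, 20, 1.5)
    v <- matrix(NA_real_, 5060, 2)
    v[, 2] <- rnorm(5060, 20, 1.5)
    v[seq_len(60), 1] <- obs
    dimnames(v) <- list(sprintf("f%04d", 1:5060), c("s1", "s2"))
    tune <- 0.5
    r <- imputeLeftCensored(asPS(v), "minprob",
                            params = list(tune = tune), seed = 9)
    draws <- intensities(imputedMatrix(r))[is.na(v[, 1]), 1]
    center <- quantile(obs, 0.01, names = FALSE)
    featSd <- apply(v, 1, sd, na.rm = TRUE)
    sdDraw <- tune * median(featSd, na.rm = TRUE)
    z <- (min(obs) - center) / sdDraw
    truncMean <- center - sdDraw * dnorm(z) / pnorm(z)
    expect_equal(mean(draws), truncMean, tolerance = 0.02)
    expect_true(all(draws <= min(obs)))
})

test_that("qrilc draws live in the censored tail and small samples fall back", {
    set.seed(5)
    full <- rnorm(400, 20, 2)
    censored <- full
    censored[full < quantile(full, 0.3)] <- NA
    v <- cbind(s1 = censored, s2 = rnorm(400, 20, 2))
    rownames(v) <- sprintf("f%03d", seq_len(400))
    r <- imputeMatrix(asPS(v), "qrilc", seed = 4)
    draws <- intensities(imputedMatrix(r))[is.na(v[, 1]), 1]
    expect_true(all(draws <= min(censored, na.rm = TRUE)))
    expect_lt(mean(draws), quantile(full, 0.3))
    # < 5 observed values: deterministic fallback with warning
    v2 <- rbind(a = c(1, 20), b = c(NA, 21), c = c(2, 19), d = c(3, 22),
                e = c(4, 23))
    colnames(v2) <- c("s1", "s2")
    expect_warning(imputeMatrix(ProteoSet(v2), "qrilc", seed = 1),
                   "fell back")
})

test_that("knn reproduces its brute-force neighbour oracle", {
    # k=1 with an identical complete neighbour: copy its value
    v <- makeStructuredMatrix(12, 5, seed = 8)
    v[2, ] <- v[1, ]
    v[2, 3] <- NA
    r <- imputeKnn(asPS(v), k = 1)
    expect_equal(intensities(imputedMatrix(r))[2, 3], v[1, 3])
    # duplicate feature: zero-distance neighbour dominates at any k
    r5 <- imputeKnn(asPS(v), k = 5)
    expect_equal(intensities(imputedMatrix(r5))[2, 3], v[1, 3])
    # k >= n-1: distance-weighted mean over all other features
    v2 <- makeStructuredMatrix(8, 4, seed = 10)
    v2[3, 2] <- NA
    r <- imputeKnn(asPS(v2), k = 7)
    x <- v2[3, ]
    other <- setdiff(seq_len(8), 3)
    d <- vapply(other, function(j)
        sqrt(mean((v2[j, !is.na(x)] - x[!is.na(x)])^2)), 0)
    oracle <- sum(v2[other, 2] / d) / sum(1 / d)
    expect_equal(intensities(imputedMatrix(r))[3, 2], oracle)
})

test_that("sequential knn grows its pool and reduces to knn when trivial", {
    # only one incomplete feature: same as knn restricted to the complete
    # pool, which here is every other feature
    v <- makeStructuredMatrix(15, 6, seed = 12)
    v[4, 2] <- NA
    a <- intensities(imputedMatrix(imputeSeqKnn(asPS(v), k = 5)))
    b <- intensities(imputedMatrix(imputeKnn(asPS(v), k = 5)))
    expect_equal(a[4, 2], b[4, 2])
    # complete matrix -> identity
    full <- makeStructuredMatrix(10, 4)
    expect_identical(intensities(imputedMatrix(imputeSeqKnn(asPS(full)))),
                     full)
    # second target may borrow from the first: both get imputed
    v2 <- makeStructuredMatrix(12, 6, seed = 13)
    v2[1, 2] <- NA
    v2[2, 5] <- NA
    out <- intensities(imputedMatrix(imputeSeqKnn(asPS(v2), k = 3)))
    expect_false(anyNA(out))
})

test_that("local least squares solves the normal equations", {
    # target an exact linear function of one complete feature: residual-free
    v <- makeStructuredMatrix(20, 8, seed = 14)
    v[2, ] <- 3 * v[1, ] - 5
    v[2, c(3, 6)] <- NA
    r <- imputeLls(asPS(v), k = 1, ridge = 0)
    expect_equal(intensities(imputedMatrix(r))[2, c(3, 6)],
                 3 * v[1, c(3, 6)] - 5)
    # constant target stays constant
    vc <- makeStructuredMatrix(15, 6, seed = 15)
    vc[3, ] <- 7
    vc[3, 4] <- NA
    expect_equal(intensities(imputedMatrix(imputeLls(asPS(vc), k = 5,
                                                     ridge = 0)))[3, 4], 7)
    # k=3 toy instance equals the hand-computed least-squares solution
    v3 <- makeStructuredMatrix(10, 7, seed = 16)
    v3[5, 7] <- NA
    r3 <- imputeLls(asPS(v3), k = 3, ridge = 0)
    x <- v3[5, ]
    obs <- which(!is.na(x))
    C <- v3[-5, , drop = FALSE][apply(v3[-5, ], 1, function(z) !anyNA(z)), ]
    cors <- abs(as.vector(cor(x[obs], t(C[, obs]))))
    sel <- order(-cors)[1:3]
    X <- cbind(1, t(C[sel, obs]))
    beta <- solve(t(X) %*% X, t(X) %*% x[obs])
    oracle <- as.numeric(c(1, C[sel, 7]) %*% beta)
    expect_equal(intensities(imputedMatrix(r3))[5, 7], oracle,
                 tolerance = 1e-10)
})

test_that("iterative svd completes exact low-rank matrices", {
    # rank-1: outer([1,2],[1,2,3]) with cell (2,3) masked -> 6
    v <- outer(c(1, 2), c(1, 2, 3))
    dimnames(v) <- list(c("a", "b"), c("s1", "s2", "s3"))
    v[2, 3] <- NA
    r <- imputeSvd(ProteoSet(v), rank = 1, tol = 1e-8, maxIter = 500)
    expect_equal(intensities(imputedMatrix(r))[2, 3], 6, tolerance = 1e-2)
    # complete matrix: identity, 0 iterations
    full <- makeStructuredMatrix(10, 5)
    rf <- imputeSvd(asPS(full), rank = 3)
    expect_identical(intensities(imputedMatrix(rf)), full)
    expect_equal(diagnostics(rf)$iterations, 0L)
    # noise-free rank-2, 10% masked: near-exact completion
    set.seed(17)
    U <- matrix(rnorm(40 * 2), 40)
    W <- matrix(rnorm(2 * 8), 2)
    v2 <- U %*% W + 20
    dimnames(v2) <- list(sprintf("f%02d", 1:40), sprintf("s%d", 1:8))
    truth <- v2
    v2[sample(length(v2), 32)] <- NA
    r2 <- imputeSvd(asPS(v2), rank = 3, tol = 1e-9, maxIter = 2000)
    expect_lt(max(abs(intensities(imputedMatrix(r2)) - truth)), 1e-4)
})

test_that("EM conditional means recover exact linear dependence", {
    # second sample = 2 * first + noise-free: conditional mean is linear
    set.seed(18)
    x <- rnorm(300, 10, 2)
    v <- cbind(s1 = x, s2 = 2 * x, s3 = rnorm(300, 5, 1))
    rownames(v) <- sprintf("f%03d", seq_len(300))
    truth <- v
    v[sample(300, 30), 2] <- NA
    r <- imputeMleEm(asPS(v), params = list(ridge = 1e-8))
    miss <- is.na(v[, 2])
    expect_equal(intensities(imputedMatrix(r))[miss, 2], truth[miss, 2],
                 tolerance = 1e-3)
    # complete matrix is untouched
    full <- makeStructuredMatrix(20, 4)
    expect_identical(intensities(imputedMatrix(imputeMleEm(asPS(full)))),
                     full)
})

test_that("impseq single-step fill equals the EM conditional mean", {
    set.seed(19)
    v <- makeStructuredMatrix(60, 5, seed = 19)
    v[10, 3] <- NA   # one incomplete feature; complete-seeding path
    a <- intensities(imputedMatrix(imputeImpseq(asPS(v))))[10, 3]
    b <- intensities(imputedMatrix(imputeMleEm(asPS(v),
        params = list(ridge = 1e-10))))[10, 3]
    expect_equal(a, b, tolerance = 1e-4)
    # robust variant resists gross outliers (masked-cell NRMSE comparison)
    worse <- 0
    for (s in 1:10) {
        v <- makeStructuredMatrix(80, 6, seed = 100 + s)
        vo <- v
        v[sample(length(v), 24)] <- vo[sample(length(v), 24)] + 40  # gross
        mk <- applyMask(asPS(v), 0.1, seed = s)
        nr <- function(key) scoreValue(nrmse(pairEvaluation(
            asPS(v), imputeMatrix(mk$masked, key), mk$spec)))
        worse <- worse + (nr("impseqrob") > nr("impseq"))
    }
    expect_lte(worse, 5)
})

test_that("chained ridge in the small-penalty limit matches least squares", {
    set.seed(20)
    v <- makeStructuredMatrix(8, 12, seed = 20)
    v[2, ] <- 2 * v[1, ] + 0.5 * v[3, ] + 1
    v[2, c(4, 9)] <- NA
    r <- imputeChained(asPS(v), engine = "ridge", nIter = 1,
                       params = list(penalty = 1e-10,
                                     maxPredictors = 7L))
    expect_equal(intensities(imputedMatrix(r))[2, c(4, 9)],
                 2 * v[1, c(4, 9)] + 0.5 * v[3, c(4, 9)] + 1,
                 tolerance = 1e-4)
    # nIter = 0 returns the row-mean initialization
    v0 <- makeStructuredMatrix(6, 5, seed = 21)
    v0[3, 2] <- NA
    r0 <- imputeChained(asPS(v0), engine = "cart", nIter = 0)
    expect_equal(intensities(imputedMatrix(r0))[3, 2],
                 mean(v0[3, ], na.rm = TRUE))
})

test_that("every method preserves observed cells and completes the matrix", {
    v <- makeStructuredMatrix(60, 8, seed = 22)
    v[sample(length(v), 48)] <- NA
    v[rowSums(!is.na(v)) == 0, 1] <- 20   # keep every feature observed
    ps <- asPS(v)
    obs <- !is.na(v)
    for (key in setdiff(listImputers()$method, c("rf", "mice_cart"))) {
        r <- suppressWarnings(imputeMatrix(ps, key, seed = 42))
        out <- intensities(imputedMatrix(r))
        expect_false(anyNA(out), info = key)
        expect_identical(out[obs], v[obs], info = key)
    }
})

test_that("stochastic methods are reproducible under a fixed seed", {
    v <- makeStructuredMatrix(40, 6, seed = 23)
    v[sample(length(v), 24)] <- NA
    ps <- asPS(v)
    for (key in c("minprob", "pi", "qrilc", "mice_norm")) {
        a <- intensities(imputedMatrix(suppressWarnings(
            imputeMatrix(ps, key, seed = 7))))
        b <- intensities(imputedMatrix(suppressWarnings(
            imputeMatrix(ps, key, seed = 7))))
        expect_identical(a, b, info = key)
        expect_error(imputeMatrix(ps, key), "seed", info = key)
    }
})

test_that("the registry runs batches, reports failures and rejects unknowns", {
    v <- makeStructuredMatrix(50, 6, seed = 24)
    v[sample(length(v), 30)] <- NA
    ps <- asPS(v)
    res <- runMethods(ps, c("zero", "minimum"))
    expect_named(res, c("zero", "minimum"))
    expect_false(anyNA(intensities(imputedMatrix(res$zero))))
    expect_error(runMethods(ps, c("zero", "nonsense")), "nonsense")
    expect_error(imputeMatrix(ps, "bpca"), "plugin slot")
    # a registered plugin becomes a first-class method
    registerImputer("testplug", function(values, params) {
        values[is.na(values)] <- -1
        list(values = values, diagnostics = list())
    })
    r <- imputeMatrix(ps, "testplug")
    expect_true(all(intensities(imputedMatrix(r))[is.na(v)] == -1))
})

test_that("structure-aware methods beat constant fills on correlated data", {
    # correlated Gaussian fixture; a reduced-rep version of the
    # GS/LS-over-SV ordering property
    winners <- c("knn", "seqknn", "lls", "svd", "mle", "impseq")
    losers <- c("zero", "minimum", "mindet")
    ok <- 0L
    nSeeds <- 5L
    for (s in seq_len(nSeeds)) {
        v <- makeStructuredMatrix(200, 10, r = 0.8, seed = 400 + s)
        mk <- applyMask(asPS(v), 0.2, seed = s)
        nr <- vapply(c(winners, losers), function(key)
            scoreValue(nrmse(pairEvaluation(asPS(v),
                suppressWarnings(imputeMatrix(mk$masked, key, seed = s)),
                mk$spec))), 0)
        ok <- ok + all(max(nr[winners]) < min(nr[losers]))
    }
    expect_gte(ok, nSeeds - 1L)
})
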