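# Sequential covariance-based imputation: seed location/scatter, then fill
# incomplete features (ascending NA count) with their Gaussian conditional
# means, updating the running moments after each feature.  Seeding uses
# the complete-feature moments when at least n_samples+1 features are
# complete; with fewer (heavily masked matrices), pairwise-complete
# moments over all features seed the covariance instead.  robust = TRUE
# uses median/MAD-winsorized seeding and winsorizes each completed
# feature before it enters the running moments.

.winsorize <- function(M, center, scale, c = 3) {
    lo <- center - c * scale
    hi <- center + c * scale
    M <- pmax(M, matrix(lo, nrow(M), ncol(M), byrow = TRUE))
    pmin(M, matrix(hi, nrow(M), ncol(M), byrow = TRUE))
}

# A pairwise-complete covariance need not be positive definite and its
# small eigenvalues are pure estimation noise; floor them at a fraction of
# the average eigenvalue so conditional means stay stable.
.makePD <- function(Sigma, rel = 0.05) {
    Sigma[is.na(Sigma)] <- 0
    Sigma <- (Sigma + t(Sigma)) / 2
    e <- eigen(Sigma, symmetric = TRUE)
    floorVal <- max(rel * mean(pmax(e$values, 0)), 1e-8)
    e$vectors %*% (pmax(e$values, floorVal) * t(e$vectors))
}

.imp_impseq <- function(v, params) {
    robust <- isTRUE(params$robust)
    S <- ncol(v)
    naCount <- rowSums(is.na(v))
    complete <- which(naCount == 0L)
    if (length(complete) >= S + 1L) {
        base <- v[complete, , drop = FALSE]
        if (robust) {
            med <- apply(base, 2L, stats::median)
            mad <- apply(base, 2L, stats::mad)
            mad[mad <= 0] <- stats::sd(base)
            base <- .winsorize(base, med, mad)
        }
        n <- nrow(base)
        mu <- colMeans(base)
        Sigma <- stats::cov(base) * (n - 1) / n
    } else {
        if (any(naCount == S))
            stop("feature(s) with no observed value cannot be imputed")
        n <- S + 1L
        mu <- if (robust) apply(v, 2L, stats::median, na.rm = TRUE)
              else colMeans(v, na.rm = TRUE)
        Sigma <- .makePD(stats::cov(v, use = "pairwise.complete.obs"))
    }
    sumX <- n * mu
    sumXX <- n * (Sigma + tcrossprod(mu))
    ridgeUsed <- FALSE
    out <- v
    ord <- order(naCount)
    for (i in ord[naCount[ord] > 0L]) {
        mu <- sumX / n
        Sigma <- sumXX / n - tcrossprod(mu)
        x <- v[i, ]
        m <- which(is.na(x))
        o <- which(!is.na(x))
        Soo <- Sigma[o, o, drop = FALSE]
        B <- tryCatch(
            Sigma[m, o, drop = FALSE] %*% solve(Soo),
            error = function(e) NULL)
        if (is.null(B)) {
            ridgeUsed <- TRUE
            B <- Sigma[m, o, drop = FALSE] %*%
                solve(Soo + 1e-8 * diag(length(o)))
        }
        x[m] <- mu[m] + as.vector(B %*% (x[o] - mu[o]))
        out[i, ] <- x
        xu <- if (robust) {
            sdv <- sqrt(pmax(diag(Sigma), 1e-12))
            pmin(pmax(x, mu - 3 * sdv), mu + 3 * sdv)
        } else x
        sumX <- sumX + xu
        sumXX <- sumXX + tcrossprod(xu)
        n <- n + 1L
    }
    if (ridgeUsed)
        warning("impseq: singular scatter; ridge fallback (1e-8)")
    list(values = out, diagnostics = list())
}
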