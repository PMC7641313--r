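# Iterative chained-equations engine behind the slow-tier methods: in each
# round every incomplete feature is regressed on its most-correlated peers
# and its missing cells re-predicted.  Engines: norm (Bayesian linear with
# noise draw), cart (regression tree), rf (random forest), robust (Huber
# M-regression), ridge (L2-penalized linear; the generalized-ridge
# stand-in).  Predictors are pre-selected by absolute correlation
# (maxPredictors, default 10) so every engine stays well-posed when
# features far outnumber samples.

.engineFit <- function(engine, Xtr, ytr, Xte, penalty) {
    p <- ncol(Xtr)
    switch(engine,
        ridge = {
            A <- cbind(1, Xtr)
            pen <- diag(c(0, rep(penalty, p)))
            beta <- solve(crossprod(A) + pen, crossprod(A, ytr))
            as.vector(cbind(1, Xte) %*% beta)
        },
        norm = {
            A <- cbind(1, Xtr)
            XtX <- crossprod(A) + 1e-8 * diag(p + 1L)
            XtXinv <- solve(XtX)
            beta <- XtXinv %*% crossprod(A, ytr)
            res <- ytr - A %*% beta
            df <- max(length(ytr) - p - 1L, 1L)
            sigma <- sqrt(sum(res^2) / df)
            betaDraw <- beta + t(chol(XtXinv)) %*%
                stats::rnorm(p + 1L) * sigma
            as.vector(cbind(1, Xte) %*% betaDraw) +
                stats::rnorm(nrow(Xte), 0, sigma)
        },
        cart = {
            df <- data.frame(y = ytr, Xtr)
            fit <- rpart::rpart(y ~ ., data = df, method = "anova",
                                control = rpart::rpart.control(
                                    minsplit = 5, cp = 1e-4))
            stats::predict(fit, data.frame(Xte))
        },
        rf = {
            df <- data.frame(y = ytr, Xtr)
            fit <- ranger::ranger(y ~ ., data = df, num.trees = 100,
                                  seed = sample.int(.Machine$integer.max, 1))
            stats::predict(fit, data.frame(Xte))$predictions
        },
        robust = {
            fit <- MASS::rlm(cbind(1, Xtr), ytr, maxit = 50)
            as.vector(cbind(1, Xte) %*% fit$coefficients)
        },
        stop("unknown chained engine: ", engine))
}

.imp_chained <- function(v, params) {
    engine <- params$engine %||% "norm"
    nIter <- params$nIter %||% 10L
    maxPredictors <- params$maxPredictors %||% 10L
    penalty <- params$penalty %||% 1e-4
    miss <- is.na(v)
    if (nrow(v) < 2L) stop("chained imputation needs >= 2 features")
    if (any(rowSums(!miss) == 0L))
        stop("feature(s) with no observed value cannot be imputed")
    rowM <- rowMeans(v, na.rm = TRUE)
    X <- v
    X[miss] <- rowM[row(v)[miss]]
    if (nIter <= 0L)
        return(list(values = X, diagnostics = list(iterations = 0L)))
    naCount <- rowSums(miss)
    ord <- order(naCount)
    targets <- ord[naCount[ord] > 0L]
    failed <- FALSE
    for (round in seq_len(nIter)) {
        for (i in targets) {
            o <- which(!miss[i, ])
            mi <- which(miss[i, ])
            others <- setdiff(seq_len(nrow(X)), i)
            cors <- suppressWarnings(
                as.vector(stats::cor(X[i, ], t(X[others, , drop = FALSE]))))
            cors[is.na(cors)] <- 0
            np <- min(maxPredictors, length(others), length(o) - 2L)
            if (np < 1L) next
            pred <- others[order(-abs(cors))[seq_len(np)]]
            Xtr <- t(X[pred, o, drop = FALSE])
            Xte <- t(X[pred, mi, drop = FALSE])
            est <- tryCatch(
                .engineFit(engine, Xtr, v[i, o], Xte, penalty),
                error = function(e) NULL)
            if (is.null(est)) { failed <- TRUE; est <- rep(rowM[i],
                                                           length(mi)) }
            X[i, mi] <- est
        }
    }
    if (failed)
        warning("chained(", engine, "): engine failure on some feature(s); ",
                "mean-filled those cells for the round")
    list(values = X, diagnostics = list(iterations = nIter))
}
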