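# Neighbour- and local-regression-based imputers: KNN, sequential KNN and
# local least squares.  Distances are normalized Euclidean over jointly
# observed samples: sqrt(mean((x_s - y_s)^2)) so features with different
# overlap counts are comparable.

.featDist <- function(x, candM) {
    ox <- which(!is.na(x))
    if (!length(ox)) return(rep(Inf, nrow(candM)))
    D <- candM[, ox, drop = FALSE]
    diff2 <- (D - matrix(x[ox], nrow(D), length(ox), byrow = TRUE))^2
    cnt <- rowSums(!is.na(diff2))
    d <- sqrt(rowSums(diff2, na.rm = TRUE) / cnt)
    d[cnt == 0L] <- Inf
    d
}

# weighted neighbour average for one feature; neighbours are rows of nbM
# (aligned with distances d), used at each missing sample where observed
.knnFill <- function(x, nbM, d) {
    fallback <- mean(x, na.rm = TRUE)
    for (s in which(is.na(x))) {
        val <- nbM[, s]
        ok <- !is.na(val)
        if (!any(ok)) { x[s] <- fallback; next }
        ds <- d[ok]; vs <- val[ok]
        if (any(ds == 0)) x[s] <- mean(vs[ds == 0])
        else x[s] <- sum(vs / ds) / sum(1 / ds)
    }
    x
}

.imp_knn <- function(v, params) {
    k <- params$k %||% 10L
    if (nrow(v) < k + 1L) stop("KNN needs at least k+1 features")
    if (any(rowSums(!is.na(v)) == 0L))
        stop("feature(s) with no observed value cannot be imputed")
    out <- v
    for (i in which(rowSums(is.na(v)) > 0L)) {
        d <- .featDist(v[i, ], v)
        d[i] <- Inf
        cand <- which(is.finite(d))
        # stable order: ties in distance broken by feature input order
        cand <- cand[order(d[cand])]
        nb <- cand[seq_len(min(k, length(cand)))]
        out[i, ] <- .knnFill(v[i, ], v[nb, , drop = FALSE], d[nb])
    }
    list(values = out, diagnostics = list())
}

.imp_seqknn <- function(v, params) {
    k <- params$k %||% 10L
    naCount <- rowSums(is.na(v))
    poolIdx <- which(naCount == 0L)
    if (!length(poolIdx)) stop("sequential KNN needs >= 1 complete feature")
    work <- v
    # ascending NA count, ties by input order (order() is stable)
    for (i in order(naCount)[naCount[order(naCount)] > 0L]) {
        pool <- work[poolIdx, , drop = FALSE]
        d <- .featDist(work[i, ], pool)
        ord <- order(d)
        nb <- ord[seq_len(min(k, length(ord)))]
        work[i, ] <- .knnFill(work[i, ], pool[nb, , drop = FALSE], d[nb])
        poolIdx <- c(poolIdx, i)
    }
    list(values = work, diagnostics = list())
}

# Local least squares with a small relative ridge on the neighbour
# coefficients (default 1e-3 of the mean regressor energy): with few
# observed samples an unpenalized local regression extrapolates wildly,
# and the shrinkage costs nothing when the system is well determined.
.imp_lls <- function(v, params) {
    k <- params$k %||% 10L
    ridge <- params$ridge %||% 1e-3
    complete <- which(rowSums(is.na(v)) == 0L)
    if (!length(complete))
        stop("LLS needs at least one complete feature")
    if (length(complete) < k) {
        warning("LLS: only ", length(complete),
                " complete features; k reduced from ", k)
        k <- length(complete)
    }
    out <- v
    ridgeUsed <- FALSE
    C <- v[complete, , drop = FALSE]
    for (i in which(rowSums(is.na(v)) > 0L)) {
        x <- v[i, ]
        obs <- which(!is.na(x))
        mis <- which(is.na(x))
        if (length(obs) < 2L) { out[i, mis] <- mean(x, na.rm = TRUE); next }
        cors <- suppressWarnings(
            as.vector(stats::cor(x[obs], t(C[, obs, drop = FALSE]))))
        cors[is.na(cors)] <- 0
        # keep the system determined: at most n_obs - 1 regressors
        ki <- min(k, length(obs) - 1L)
        sel <- order(-abs(cors))[seq_len(ki)]
        X <- cbind(1, t(C[sel, obs, drop = FALSE]))
        XtX <- crossprod(X)
        Xty <- crossprod(X, x[obs])
        pen <- ridge * mean(diag(XtX)[-1L]) * diag(c(0, rep(1, ki)))
        beta <- tryCatch(solve(XtX + pen, Xty), error = function(e) NULL)
        if (is.null(beta)) {
            ridgeUsed <- TRUE
            beta <- solve(XtX + pen + 1e-6 * diag(ki + 1L), Xty)
        }
        out[i, mis] <- cbind(1, t(C[sel, mis, drop = FALSE])) %*% beta
    }
    if (ridgeUsed)
        warning("LLS: singular neighbour design(s); ridge fallback (1e-8)")
    list(values = out, diagnostics = list())
}
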