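# Covariance- and low-rank-structure imputers: iterative truncated SVD and
# EM for a multivariate normal over the sample dimension (features treated
# as i.i.d. observations of a sample-dimensional Gaussian).

.imp_svd <- function(v, params) {
    rank <- params$rank %||% 5L
    tol <- params$tol %||% 1e-2
    maxIter <- params$maxIter %||% 100L
    rmax <- min(dim(v)) - 1L
    if (rank > rmax) {
        warning("svd: rank clamped to ", rmax)
        rank <- rmax
    }
    miss <- is.na(v)
    if (!any(miss))
        return(list(values = v,
                    diagnostics = list(iterations = 0L, converged = TRUE)))
    if (any(rowSums(!miss) == 0L))
        stop("feature(s) with no observed value cannot be imputed")
    rowM <- rowMeans(v, na.rm = TRUE)
    X <- v
    X[miss] <- rowM[row(v)[miss]]
    converged <- FALSE
    iter <- 0L
    repeat {
        iter <- iter + 1L
        s <- svd(X, nu = rank, nv = rank)
        recon <- s$u %*% (s$d[seq_len(rank)] * t(s$v))
        old <- X[miss]
        X[miss] <- recon[miss]
        delta <- sqrt(sum((X[miss] - old)^2)) /
            max(sqrt(sum(old^2)), 1e-12)
        if (delta < tol) { converged <- TRUE; break }
        if (iter >= maxIter) break
    }
    list(values = X,
         diagnostics = list(iterations = iter, converged = converged))
}

# one E-step: conditional means per missing pattern plus the summed
# conditional covariance; used inside the EM loop and once at the end
.emEstep <- function(v, miss, mu, Sigma, patIdx, patCols) {
    Xhat <- v
    Xhat[miss] <- 0
    S <- ncol(v)
    Csum <- matrix(0, S, S)
    for (p in seq_along(patIdx)) {
        m <- patCols[[p]]
        if (!length(m)) {
            next
        }
        r <- patIdx[[p]]
        o <- setdiff(seq_len(S), m)
        Soo <- Sigma[o, o, drop = FALSE]
        B <- Sigma[m, o, drop = FALSE] %*%
            solve(Soo + 1e-10 * diag(length(o)))
        dev <- t(v[r, o, drop = FALSE]) - mu[o]
        Xhat[r, m] <- t(mu[m] + B %*% dev)
        condCov <- Sigma[m, m, drop = FALSE] -
            B %*% t(Sigma[m, o, drop = FALSE])
        Csum[m, m] <- Csum[m, m] + length(r) * condCov
    }
    list(Xhat = Xhat, Csum = Csum)
}

.imp_mle <- function(v, params) {
    ridge <- params$ridge %||% 1e-6
    tol <- params$tol %||% 1e-6
    maxIter <- params$maxIter %||% 500L
    miss <- is.na(v)
    S <- ncol(v)
    nF <- nrow(v)
    if (!any(miss))
        return(list(values = v,
                    diagnostics = list(iterations = 0L, converged = TRUE)))
    if (any(rowSums(!miss) == 0L))
        stop("feature(s) with no observed value cannot be imputed")
    pat <- apply(miss, 1L, function(z) paste(as.integer(z), collapse = ""))
    patIdx <- split(seq_len(nF), pat)
    patCols <- lapply(patIdx, function(r) which(miss[r[1L], ]))
    mu <- colMeans(v, na.rm = TRUE)
    X0 <- v
    X0[miss] <- matrix(mu, nF, S, byrow = TRUE)[miss]
    Sigma <- stats::cov(X0) + ridge * diag(S)
    converged <- FALSE
    iter <- 0L
    repeat {
        iter <- iter + 1L
        e <- .emEstep(v, miss, mu, Sigma, patIdx, patCols)
        muNew <- colMeans(e$Xhat)
        Xc <- sweep(e$Xhat, 2L, muNew)
        SigmaNew <- (crossprod(Xc) + e$Csum) / nF + ridge * diag(S)
        delta <- max(max(abs(muNew - mu)), max(abs(SigmaNew - Sigma)))
        mu <- muNew
        Sigma <- SigmaNew
        if (delta < tol) { converged <- TRUE; break }
        if (iter >= maxIter) break
    }
    e <- .emEstep(v, miss, mu, Sigma, patIdx, patCols)
    out <- v
    out[miss] <- e$Xhat[miss]
    list(values = out,
         diagnostics = list(iterations = iter, converged = converged,
                            mu = mu, Sigma = Sigma))
}
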