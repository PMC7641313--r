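# Single-value and left-censored (MNAR-oriented) imputers.  All internal
# engines take a features x samples numeric matrix on the log2 scale and
# return list(values = completed matrix, diagnostics = list()); the public
# entry point is imputeMatrix() / runMethods() in registry.R.

.imp_zero <- function(v, params) {
    v[is.na(v)] <- 0
    list(values = v, diagnostics = list())
}

.imp_minimum <- function(v, params) {
    obs <- v[!is.na(v)]
    if (!length(obs)) stop("no observed values: global minimum undefined")
    v[is.na(v)] <- min(obs)
    list(values = v, diagnostics = list())
}

.imp_colmedian <- function(v, params) {
    for (j in seq_len(ncol(v))) {
        x <- v[, j]
        if (all(is.na(x)))
            stop("sample ", colnames(v)[j] %||% j,
                 " has no observed value: column median undefined")
        v[is.na(x), j] <- stats::median(x, na.rm = TRUE)
    }
    list(values = v, diagnostics = list())
}

.imp_rowmedian <- function(v, params) {
    miss <- is.na(v)
    if (any(rowSums(!miss) == 0L))
        stop("feature(s) with no observed value: row median undefined")
    med <- apply(v, 1L, stats::median, na.rm = TRUE)
    idx <- which(miss, arr.ind = TRUE)
    v[idx] <- med[idx[, 1L]]
    list(values = v, diagnostics = list())
}

# deterministic low-quantile replacement, per sample
.imp_mindet <- function(v, params) {
    q <- params$q %||% 0.01
    for (j in seq_len(ncol(v))) {
        x <- v[, j]
        if (all(is.na(x))) stop("sample with no observed value")
        v[is.na(x), j] <- stats::quantile(x, q, na.rm = TRUE, names = FALSE)
    }
    list(values = v, diagnostics = list())
}

# stochastic low-quantile replacement: draws centred at the per-sample
# q-quantile with spread from the typical per-feature sd, truncated above
# at the sample minimum so draws stay in the censored tail
.imp_minprob <- function(v, params) {
    q <- params$q %||% 0.01
    tune <- params$tune %||% 1
    featSd <- apply(v, 1L, stats::sd, na.rm = TRUE)
    featSd <- featSd[!is.na(featSd)]
    sdDraw <- tune * if (length(featSd)) stats::median(featSd) else 0.1
    if (!is.finite(sdDraw) || sdDraw <= 0) sdDraw <- 0.1
    for (j in seq_len(ncol(v))) {
        x <- v[, j]
        nj <- sum(is.na(x))
        if (nj == 0L) next
        if (all(is.na(x))) stop("sample with no observed value")
        center <- stats::quantile(x, q, na.rm = TRUE, names = FALSE)
        v[is.na(x), j] <- rtruncnormUpper(nj, center, sdDraw,
                                          min(x, na.rm = TRUE))
    }
    list(values = v, diagnostics = list())
}

# Perseus-style downshifted-normal draw, per sample
.imp_pi <- function(v, params) {
    shift <- params$shift %||% 1.8
    width <- params$width %||% 0.3
    for (j in seq_len(ncol(v))) {
        x <- v[, j]
        nj <- sum(is.na(x))
        if (nj == 0L) next
        mu <- mean(x, na.rm = TRUE)
        s <- stats::sd(x, na.rm = TRUE)
        if (is.na(s)) stop("sample needs >= 2 observed values for pi")
        v[is.na(x), j] <- stats::rnorm(nj, mu - shift * s, width * s)
    }
    list(values = v, diagnostics = list())
}

# Left-censored tail model fitted by quantile-quantile regression: the
# upper observed quantiles (p >= 1 - upperFraction of the censoring-free
# range) determine mu and sigma of the underlying normal; imputed values
# are drawn from that normal truncated above at the sample minimum.
.imp_qrilc <- function(v, params) {
    upperFraction <- params$upperFraction %||% 0.75
    fellBack <- FALSE
    for (j in seq_len(ncol(v))) {
        x <- v[, j]
        nj <- sum(is.na(x))
        if (nj == 0L) next
        obs <- sort(x[!is.na(x)])
        if (length(obs) < 5L) {
            fellBack <- TRUE
            v[is.na(x), j] <- stats::quantile(obs, params$q %||% 0.01,
                                              names = FALSE)
            next
        }
        p <- stats::ppoints(length(obs))
        use <- p >= (1 - upperFraction)
        fit <- stats::lm.fit(cbind(1, stats::qnorm(p[use])), obs[use])
        mu <- fit$coefficients[1L]
        sigma <- max(fit$coefficients[2L], 1e-8)
        v[is.na(x), j] <- rtruncnormUpper(nj, mu, sigma, min(obs))
    }
    if (fellBack)
        warning("qrilc: sample(s) with < 5 observed values fell back to ",
                "deterministic low-quantile replacement")
    list(values = v, diagnostics = list())
}
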