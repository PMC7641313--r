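# internal helpers shared across modules

# round() in R is round-half-even; mask cell counts need half-away-from-zero
roundHalfUp <- function(x) sign(x) * floor(abs(x) + 0.5)

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL evaluates as-is.
withSeed <- function(seed, expr) {
    if (is.null(seed)) return(eval.parent(substitute(expr)))
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    genv <- globalenv()
    if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        old <- get(".Random.seed", envir = genv)
        on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
    } else {
        on.exit(
            if (exists(".Random.seed", envir = genv, inherits = FALSE))
                rm(".Random.seed", envir = genv),
            add = TRUE
        )
    }
    set.seed(as.integer(seed))
    eval.parent(substitute(expr))
}

# derive per-stage child seeds from one global seed (documented: stage
# index offsets a fixed multiplier, kept below .Machine$integer.max)
deriveSeed <- function(seed, stage) {
    if (is.null(seed)) return(NULL)
    as.integer((as.numeric(seed) * 48271 + stage * 7919) %% 2147483647)
}

# draw n values from Normal(mean, sd) truncated above at `upper`
rtruncnormUpper <- function(n, mean, sd, upper) {
    if (sd <= 0) return(rep(min(mean, upper), n))
    pUp <- stats::pnorm(upper, mean, sd)
    if (pUp <= 0) return(rep(upper, n))
    stats::qnorm(stats::runif(n, 0, pUp), mean, sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
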