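# Small deterministic fixtures shared across test files.

# features x samples matrix with a common latent factor so features
# correlate pairwise at roughly r; log2-intensity-like level around 20
makeStructuredMatrix <- function(nFeat = 60, nSamp = 10, r = 0.8,
                                 seed = 1, level = 20, levelSd = 2) {
    set.seed(seed)
    f <- rnorm(nSamp)
    lam <- sqrt(r / (1 - r))
    base <- rnorm(nFeat, level, levelSd)
    v <- base + lam * matrix(f, nFeat, nSamp, byrow = TRUE) +
        matrix(rnorm(nFeat * nSamp), nFeat, nSamp)
    dimnames(v) <- list(sprintf("f%04d", seq_len(nFeat)),
                        sprintf("s%02d", seq_len(nSamp)))
    v
}

asPS <- function(v) ProteoSet(v)

maskedEval <- function(yo, yi, featureIndex = seq_along(yo)) {
    new("MaskedEvaluation", yo = as.numeric(yo), yi = as.numeric(yi),
        featureIndex = as.integer(featureIndex))
}

.sc <- function(criterion, value, direction = "lower_better",
                nUsed = 10L, reason = "") {
    new("CriterionScore", criterion = criterion, value = as.numeric(value),
        direction = direction, nUsed = as.integer(nUsed), reason = reason)
}

# two-group design for a matrix with samples split in half
halfDesign <- function(v) {
    n <- ncol(v)
    data.frame(sample_id = colnames(v),
               group_label = rep(c("A", "B"), each = n / 2))
}
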