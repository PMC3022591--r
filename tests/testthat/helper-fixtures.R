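# Small fixtures built in code; kept deliberately tiny so the default
# suite stays fast.

smallConfig <- function(seed = 1L, ...) {
    generatorConfig(seed = seed, n_features = 150L, ...)
}

# a hand-sized replicate-level experiment: nFeat features, one source,
# explicit intensity matrix
tinyReplicateExperiment <- function(intensity, n_rep = 2L, source = "A",
                                    classes = NULL) {
    nobs <- ncol(intensity)
    nsamp <- nobs / n_rep
    stopifnot(nsamp == round(nsamp))
    if (is.null(classes))
        classes <- rep(c("control", "cancer"), length.out = nsamp)
    pd <- data.frame(
        sample_id = rep(sprintf("s%02d", seq_len(nsamp)), each = n_rep),
        replicate_id = rep(sprintf("r%d", seq_len(n_rep)), nsamp),
        source = source, class = rep(classes, each = n_rep),
        stringsAsFactors = FALSE)
    colnames(intensity) <- paste(pd$sample_id, pd$replicate_id, sep = ".")
    if (is.null(rownames(intensity)))
        rownames(intensity) <- as.character(1000 + seq_len(nrow(intensity)))
    PeptidomeExperiment(intensity, pd)
}

# sample-level experiment straight from a matrix (features x samples)
tinySampleExperiment <- function(intensity, classes, source = "A") {
    pd <- data.frame(sample_id = sprintf("s%02d", seq_len(ncol(intensity))),
                     source = source, class = classes,
                     stringsAsFactors = FALSE)
    colnames(intensity) <- pd$sample_id
    if (is.null(rownames(intensity)))
        rownames(intensity) <- as.character(1000 + seq_len(nrow(intensity)))
    PeptidomeExperiment(intensity, pd, level = "sample")
}

# separable two-class sample-level dataset: feature 1 separates perfectly
separableExperiment <- function(n_per_class = 10L, n_noise = 3L, seed = 42L) {
    set.seed(seed)
    n <- 2L * n_per_class
    classes <- rep(c("control", "cancer"), each = n_per_class)
    sig <- ifelse(classes == "control", 10, 2) + rnorm(n, 0, 0.3)
    m <- rbind(sig, matrix(runif(n_noise * n, 1, 5), n_noise, n))
    rownames(m) <- as.character(c(1500, 2000 + seq_len(n_noise)))
    tinySampleExperiment(m, classes)
}

# brute-force two-sided Mann-Whitney p by enumerating all group labelings
bruteForceMWP <- function(x, y) {
    n1 <- length(x); n <- n1 + length(y)
    pooled <- c(x, y)
    r <- rank(pooled)
    uStat <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
    obs <- uStat(seq_len(n1))
    mid <- n1 * (n - n1) / 2
    combos <- utils::combn(n, n1)
    us <- apply(combos, 2L, uStat)
    mean(abs(us - mid) >= abs(obs - mid) - 1e-12)
}
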