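.resolveMatrixLabels <- function(x, labels) {
    if (is(x, "PeptidomeExperiment")) {
        if (is.null(labels)) labels <- classLabels(x)
        x <- intensities(x)
    }
    if (is.null(labels)) stop("class labels are required")
    if (length(labels) != ncol(x))
        stop("labels must have one entry per observation")
    list(m = x, labels = as.character(labels))
}

.mwPValue <- function(g1, g2) {
    n1 <- length(g1); n2 <- length(g2)
    pooled <- c(g1, g2)
    if (length(unique(pooled)) == 1L) return(1)
    r <- rank(pooled)
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    ties <- any(duplicated(pooled))
    if (max(n1, n2) <= 8 && !ties) {
        # exact null distribution of U
        p <- 2 * min(stats::pwilcox(U, n1, n2),
                     1 - stats::pwilcox(U - 1, n1, n2))
        return(min(1, p))
    }
    # tie-corrected normal approximation with continuity correction
    mu <- n1 * n2 / 2
    tieTab <- table(pooled)
    n <- n1 + n2
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(tieTab^3 - tieTab) / (n * (n - 1)))
    if (sig2 <= 0) return(1)
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
    min(1, 2 * stats::pnorm(-abs(z)))
}

#' Per-feature Mann-Whitney p-values
#'
#' Two-sided Mann-Whitney U test of control vs cancer for every feature.
#' For group sizes of at most 8 without ties the exact null distribution
#' of U is used; otherwise a tie-corrected normal approximation with
#' continuity correction. A feature constant across all samples gets
#' p = 1.
#'
#' @param x sample-level \linkS4class{PeptidomeExperiment} or numeric
#'   matrix (features x samples)
#' @param labels "control"/"cancer" per sample; taken from \code{x} when it
#'   is a PeptidomeExperiment
#' @return named numeric vector of p-values
#' @export
mannWhitneyPValues <- function(x, labels = NULL) {
    d <- .resolveMatrixLabels(x, labels)
    ctl <- d$labels == "control"
    if (!any(ctl) || all(ctl)) stop("both classes must be non-empty")
    apply(d$m, 1L, function(v) .mwPValue(v[ctl], v[!ctl]))
}

#' Intensity filter on features
#'
#' A feature is kept iff at least one sample's averaged reading exceeds
#' the cutoff, i.e. the filter removes features whose signal never rises
#' above the cutoff — it never removes samples. \code{cutoff = NA} means
#' the filter is disabled (all features kept), the convention used when
#' intensities have been decile-normalized.
#'
#' @param x sample-level \linkS4class{PeptidomeExperiment} or matrix
#' @param cutoff intensity cutoff, or \code{NA} to disable
#' @return character vector of kept feature labels
#' @export
intensityFilter <- function(x, cutoff) {
    m <- if (is(x, "PeptidomeExperiment")) intensities(x) else x
    if (is.na(cutoff)) return(rownames(m))
    rownames(m)[apply(m, 1L, max) > cutoff]
}

#' Default Mann-Whitney p-value search grid
#'
#' 15 log-spaced points from 0.001 to 0.1.
#' @return numeric vector
#' @export
defaultPGrid <- function()
    exp(seq(log(0.001), log(0.1), length.out = 15))

#' Default intensity-cutoff search grid
#'
#' 0, 50, 100, ..., 500 intensity units (raw scale).
#' @return numeric vector
#' @export
defaultIntensityGrid <- function() seq(0, 500, by = 50)

.selectFeatures <- function(pvals, keptByIntensity, pCutoff) {
    names(pvals)[pvals <= pCutoff & names(pvals) %in% keptByIntensity]
}

#' Optimize the feature-selection cutoffs by cross-validated accuracy
#'
#' Exhaustive two-step search over the grid of (Mann-Whitney p-value
#' cutoff, intensity cutoff) pairs. Step 1 scores every combination:
#' features passing both filters are selected, a linear-margin classifier
#' is trained on them, and its stratified ten-fold cross-validated
#' accuracy recorded (a combination selecting no features scores 0).
#' Step 2 returns, among combinations within 1e-12 of the maximum
#' accuracy, the one selecting the fewest features; remaining ties break
#' toward the smaller p cutoff, then the larger intensity cutoff. When
#' \code{x} is decile-normalized the intensity grid collapses to
#' \code{NA} (disabled). Folds are fixed across combinations, so the
#' search is deterministic given (data, grids, seed).
#'
#' @param x sample-level \linkS4class{PeptidomeExperiment}
#' @param labels optional explicit labels
#' @param p_grid,i_grid search grids (see \code{\link{defaultPGrid}})
#' @param cv_folds number of stratified folds
#' @param seed fold-assignment seed
#' @param cost margin-softness constant C of the classifier
#' @return a \linkS4class{SelectionResult}
#' @export
optimizeFilters <- function(x, labels = NULL, p_grid = defaultPGrid(),
                            i_grid = defaultIntensityGrid(), cv_folds = 10,
                            seed = 1L, cost = 1) {
    d <- .resolveMatrixLabels(x, labels)
    if (!length(p_grid)) stop("p_grid must be non-empty")
    if (is(x, "PeptidomeExperiment") && isNormalized(x))
        i_grid <- NA_real_
    if (!length(i_grid)) stop("i_grid must be non-empty")
    pvals <- mannWhitneyPValues(d$m, d$labels)
    keptBy <- lapply(i_grid, function(ic) intensityFilter(d$m, ic))
    folds <- stratifiedFolds(d$labels, cv_folds, seed)
    cache <- new.env(parent = emptyenv())
    grid <- expand.grid(p_cutoff = p_grid, intensity_cutoff = i_grid,
                        KEEP.OUT.ATTRS = FALSE)
    grid$n_features <- NA_integer_
    grid$accuracy <- NA_real_
    for (i in seq_len(nrow(grid))) {
        ii <- match(grid$intensity_cutoff[i], i_grid)
        feats <- .selectFeatures(pvals, keptBy[[ii]], grid$p_cutoff[i])
        grid$n_features[i] <- length(feats)
        key <- paste(sort(feats), collapse = "\r")
        if (!length(feats)) {
            grid$accuracy[i] <- 0  # no majority-class fallback
        } else if (!is.null(cache[[key]])) {
            grid$accuracy[i] <- cache[[key]]
        } else {
            acc <- .cvAccuracy(d$m[feats, , drop = FALSE], d$labels, folds,
                               cost)
            cache[[key]] <- acc
            grid$accuracy[i] <- acc
        }
    }
    best <- max(grid$accuracy)
    cand <- which(grid$accuracy >= best - 1e-12)
    cand <- cand[order(grid$n_features[cand], grid$p_cutoff[cand],
                       -grid$intensity_cutoff[cand])]
    w <- cand[1]
    ii <- match(grid$intensity_cutoff[w], i_grid)
    feats <- .selectFeatures(pvals, keptBy[[ii]], grid$p_cutoff[w])
    new("SelectionResult", pCutoff = unname(grid$p_cutoff[w]),
        intensityCutoff = unname(grid$intensity_cutoff[w]), features = feats,
        pValues = pvals, cvAccuracy = grid$accuracy[w], grid = grid)
}
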