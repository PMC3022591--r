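#' Fit per-source control-decile thresholds
#'
#' For each source and feature, the nine thresholds X1..X9 are the
#' 0.1..0.9 quantiles of that source's nonzero control-class readings,
#' using linear interpolation between order statistics (position
#' h = (n - 1) p + 1, i.e. \code{stats::quantile} type 7). Zeros are
#' missing readings and are excluded from fitting. A (source, feature)
#' pair with fewer than two nonzero control readings cannot be fitted; it
#' is flagged and later passed through unnormalized.
#'
#' @param x replicate-level \linkS4class{PeptidomeExperiment} (fitting on
#'   sample-level data is also permitted)
#' @param sources sources to fit; default all sources present
#' @return a \linkS4class{QuantileMap}
#' @examples
#' # controls 1..11 for one feature: thresholds 2, 3, ..., 10
#' m <- matrix(1:11, 1, 11, dimnames = list("1000", paste0("s", 1:11, ".r1")))
#' pd <- data.frame(sample_id = paste0("s", 1:11), replicate_id = "r1",
#'                  source = "A", class = "control")
#' quantileThresholds(fitQuantileMap(PeptidomeExperiment(m, pd)), "A")
#' @export
fitQuantileMap <- function(x, sources = NULL) {
    cd <- sampleInfo(x)
    if (is.null(sources)) sources <- unique(cd$source)
    m <- intensities(x)
    thresholds <- list()
    unmapped <- list()
    for (s in sources) {
        ctl <- cd$source == s & cd$class == "control"
        if (sum(ctl) < 2 && sum(ctl) * 1 < 2)
            warning("source '", s, "' has fewer than 2 control observations")
        ms <- m[, ctl, drop = FALSE]
        th <- matrix(NA_real_, nrow(m), 9L,
                     dimnames = list(rownames(m), paste0("X", 1:9)))
        for (f in seq_len(nrow(m))) {
            v <- ms[f, ]
            v <- v[v > 0]
            if (length(v) >= 2)
                th[f, ] <- quantile(v, probs = (1:9) / 10, type = 7,
                                    names = FALSE)
        }
        bad <- rownames(m)[rowSums(is.na(th)) > 0]
        if (length(bad))
            warning(length(bad), " feature(s) in source '", s,
                    "' have < 2 nonzero control readings; ",
                    "they will pass through unnormalized")
        thresholds[[s]] <- th
        unmapped[[s]] <- bad
    }
    new("QuantileMap", thresholds = thresholds,
        features = rownames(m), unmapped = unmapped)
}

#' Map intensities to control decile bins
#'
#' Every nonzero reading x of a feature in source s becomes
#' \code{bin(x) = 1 + #\{i : X_i < x\}}, an integer in 1..10, where the
#' X_i are that source's own control-decile thresholds — including for a
#' control-only validation source, which is normalized by its own map.
#' A value exactly equal to a threshold falls in the lower bin. Zero
#' readings remain 0 (missing). Features flagged as unfittable keep their
#' raw intensities.
#'
#' The transform is invariant to any positive rescaling of one source's
#' intensities for a feature, which is the mechanism that removes
#' per-source multiplicative intensity bias while preserving (and never
#' inverting) within-source class trends.
#'
#' @param x \linkS4class{PeptidomeExperiment} (replicate level in the
#'   standard pipeline, i.e. before averaging)
#' @param map a \linkS4class{QuantileMap} fitted for every source present
#' @return \code{x} with intensities replaced by bins;
#'   \code{isNormalized()} becomes \code{TRUE}
#' @export
applyQuantileMap <- function(x, map) {
    cd <- sampleInfo(x)
    m <- intensities(x)
    for (s in unique(cd$source)) {
        if (!s %in% names(map@thresholds))
            stop("no quantile map fitted for source '", s, "'")
        th <- map@thresholds[[s]]
        miss <- setdiff(rownames(m), rownames(th))
        if (length(miss))
            stop("quantile map for source '", s, "' lacks feature(s): ",
                 paste(head(miss, 5), collapse = ", "))
        cols <- which(cd$source == s)
        for (f in rownames(m)) {
            thf <- th[f, ]
            if (anyNA(thf)) next  # flagged: pass through unnormalized
            v <- m[f, cols]
            nz <- v > 0
            if (any(nz)) {
                bins <- rowSums(outer(v[nz], thf, ">")) + 1
                m[f, cols[nz]] <- bins
            }
        }
    }
    out <- SummarizedExperiment::`assay<-`(x, "intensity", value = m)
    S4Vectors::metadata(out)$normalized <- TRUE
    out
}
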