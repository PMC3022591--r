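#' Collapse replicate readings to sample-level intensities
#'
#' Per (sample, feature): the arithmetic mean of the nonzero replicate
#' readings, treating 0 as a missing reading; 0 if every reading is zero.
#' The mean is unweighted even when samples differ in replicate count.
#'
#' @param x replicate-level \linkS4class{PeptidomeExperiment}
#' @return sample-level \linkS4class{PeptidomeExperiment}; colData gains
#'   \code{n_replicates}
#' @examples
#' m <- matrix(c(0, 4, 6), 1, 3, dimnames = list("1520", paste0("s1.r", 1:3)))
#' pd <- data.frame(sample_id = "s1", replicate_id = paste0("r", 1:3),
#'                  source = "A", class = "control")
#' intensities(averageReplicates(PeptidomeExperiment(m, pd)))  # 5
#' @export
averageReplicates <- function(x) {
    if (!identical(dataLevel(x), "replicate"))
        stop("averageReplicates expects replicate-level data")
    cd <- sampleInfo(x)
    m <- intensities(x)
    sid <- factor(cd$sample_id, levels = unique(cd$sample_id))
    sums <- t(rowsum(t(m), sid))
    cnts <- t(rowsum(t(m > 0) + 0, sid))
    avg <- ifelse(cnts > 0, sums / pmax(cnts, 1), 0)
    dimnames(avg) <- list(rownames(m), levels(sid))
    first <- !duplicated(cd$sample_id)
    cds <- data.frame(sample_id = cd$sample_id[first],
                      source = cd$source[first], class = cd$class[first],
                      n_replicates = as.integer(table(sid)[unique(cd$sample_id)]),
                      stringsAsFactors = FALSE)
    rownames(cds) <- cds$sample_id
    out <- PeptidomeExperiment(avg, cds, mz = featureMz(x), level = "sample",
                               normalized = isNormalized(x))
    S4Vectors::metadata(out)$generator <- S4Vectors::metadata(x)$generator
    out
}

#' Drop features with residual missing readings
#'
#' After replicate averaging a feature may still hold zeros (samples whose
#' readings were all missing). A classifier could exploit such zeros as a
#' missingness pattern rather than true intensity, so features with a zero
#' in at least one sample are removed. The removal log records, per removed
#' feature, the per-class zero counts and a two-sided Fisher exact test of
#' zero-vs-class association — reported only, never used to filter — so
#' the absence of a class preference among removed features can be audited.
#'
#' @param x sample-level \linkS4class{PeptidomeExperiment}
#' @return list with \code{experiment} (features all strictly positive) and
#'   \code{removed} (data.frame: feature, zeros per class, totals,
#'   \code{fisher_p})
#' @export
filterZeroFeatures <- function(x) {
    if (!identical(dataLevel(x), "sample"))
        stop("filterZeroFeatures expects sample-level data; run averageReplicates first")
    m <- intensities(x)
    cls <- classLabels(x)
    hasZero <- rowSums(m == 0) > 0
    if (all(hasZero))
        stop("all ", nrow(m), " features contain zeros in at least one sample; ",
             "check dropout level or replicate count")
    removed <- data.frame(feature = rownames(m)[hasZero],
                          stringsAsFactors = FALSE)
    nCtl <- sum(cls == "control"); nCan <- sum(cls == "cancer")
    if (nrow(removed)) {
        zc <- rowSums(m[hasZero, cls == "control", drop = FALSE] == 0)
        zk <- rowSums(m[hasZero, cls == "cancer", drop = FALSE] == 0)
        removed$zeros_control <- as.integer(zc)
        removed$zeros_cancer <- as.integer(zk)
        removed$n_control <- nCtl
        removed$n_cancer <- nCan
        removed$fisher_p <- vapply(seq_len(nrow(removed)), function(i) {
            if (nCtl == 0 || nCan == 0) return(NA_real_)
            tab <- matrix(c(removed$zeros_control[i],
                            nCtl - removed$zeros_control[i],
                            removed$zeros_cancer[i],
                            nCan - removed$zeros_cancer[i]), 2L, 2L)
            fisher.test(tab)$p.value
        }, numeric(1))
    } else {
        removed$zeros_control <- integer(0); removed$zeros_cancer <- integer(0)
        removed$n_control <- integer(0); removed$n_cancer <- integer(0)
        removed$fisher_p <- numeric(0)
    }
    list(experiment = x[!hasZero, ], removed = removed)
}
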