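#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData rowData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats approx fisher.test mad p.adjust quantile rbinom rlnorm
#'   rnorm rgamma runif runmed sd setNames wilcox.test cor.test predict
#' @importFrom utils read.delim write.table head modifyList
NULL

#' Container for peptidome intensity data
#'
#' \code{PeptidomeExperiment} extends
#' \linkS4class{SummarizedExperiment} and stores a MALDI-TOF peptide
#' intensity matrix (features in rows, observations in columns) together
#' with the per-observation metadata the cross-source analysis needs:
#' \code{sample_id}, \code{replicate_id} (at replicate level), \code{source}
#' (the biorepository) and \code{class} (\code{"control"} or
#' \code{"cancer"}). A value of exactly \code{0} is the sentinel for a
#' missing reading, not a measured zero intensity.
#'
#' Objects exist at one of two levels, recorded in
#' \code{metadata(x)$level}: \code{"replicate"} (one column per
#' sample-by-replicate reading) or \code{"sample"} (replicates collapsed by
#' \code{\link{averageReplicates}}). \code{metadata(x)$normalized} records
#' whether intensities have been mapped to control decile bins.
#'
#' @seealso \code{\link{averageReplicates}}, \code{\link{fitQuantileMap}},
#'   \code{\link{simulatePeptidome}}
#' @export
setClass("PeptidomeExperiment", contains = "SummarizedExperiment")

.validPeptidomeExperiment <- function(object) {
    msg <- character()
    if (!"intensity" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'intensity' is required")
    else {
        m <- SummarizedExperiment::assay(object, "intensity")
        if (any(m < 0, na.rm = TRUE))
            msg <- c(msg, "intensities must be nonnegative (0 = missing reading)")
    }
    cd <- SummarizedExperiment::colData(object)
    need <- c("sample_id", "source", "class")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("colData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    lvl <- S4Vectors::metadata(object)$level
    if (is.null(lvl) || !lvl %in% c("replicate", "sample"))
        msg <- c(msg, "metadata()$level must be 'replicate' or 'sample'")
    if (!length(miss)) {
        bad <- setdiff(unique(as.character(cd$class)), c("control", "cancer"))
        if (length(bad))
            msg <- c(msg, paste0("class labels must be 'control'/'cancer', got: ",
                                 paste(bad, collapse = ", ")))
        if (identical(lvl, "replicate")) {
            if (!"replicate_id" %in% colnames(cd))
                msg <- c(msg, "replicate-level data need a replicate_id column")
            else if (anyDuplicated(paste(cd$sample_id, cd$replicate_id)))
                msg <- c(msg, "duplicate (sample_id, replicate_id) pairs")
        } else if (identical(lvl, "sample") && anyDuplicated(cd$sample_id)) {
            msg <- c(msg, "duplicate sample_id at sample level")
        }
    }
    if (length(msg)) msg else TRUE
}
setValidity("PeptidomeExperiment", .validPeptidomeExperiment)

#' Construct a PeptidomeExperiment
#'
#' @param intensity numeric matrix, features x observations; row names are
#'   feature labels (integer-rounded m/z), column names observation ids.
#' @param sampleData data.frame with one row per column of
#'   \code{intensity}; must contain \code{sample_id}, \code{source},
#'   \code{class}, and \code{replicate_id} when \code{level = "replicate"}.
#' @param mz numeric vector of feature m/z values; parsed from
#'   \code{rownames(intensity)} when \code{NULL}.
#' @param level \code{"replicate"} or \code{"sample"}.
#' @param normalized logical, have intensities been decile-binned?
#'
#' @return a \linkS4class{PeptidomeExperiment}
#' @examples
#' m <- matrix(c(10, 0, 5, 7), 2, 2,
#'             dimnames = list(c("1520", "6431"), c("s1_r1", "s1_r2")))
#' pd <- data.frame(sample_id = "s1", replicate_id = c("r1", "r2"),
#'                  source = "A", class = "control")
#' PeptidomeExperiment(m, pd)
#' @export
PeptidomeExperiment <- function(intensity, sampleData, mz = NULL,
                                level = c("replicate", "sample"),
                                normalized = FALSE) {
    level <- match.arg(level)
    intensity <- as.matrix(intensity)
    if (is.null(mz)) {
        mz <- suppressWarnings(as.numeric(sub("\\..*$", "", rownames(intensity))))
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = intensity),
        colData = S4Vectors::DataFrame(sampleData, row.names = colnames(intensity)),
        rowData = S4Vectors::DataFrame(mz = mz, row.names = rownames(intensity)))
    S4Vectors::metadata(se)$level <- level
    S4Vectors::metadata(se)$normalized <- normalized
    new("PeptidomeExperiment", se)
}

#' A single mass spectrum
#'
#' Continuous (profile-mode) spectrum of one replicate reading: intensity as
#' a function of m/z, with the observation metadata needed to route it
#' through preprocessing.
#'
#' @export
setClass("MassSpectrum",
         representation(mz = "numeric", intensity = "numeric",
                        sampleId = "character", replicateId = "character",
                        source = "character"))

setValidity("MassSpectrum", function(object) {
    msg <- character()
    if (length(object@mz) != length(object@intensity))
        msg <- c(msg, "mz and intensity must have equal length")
    if (length(object@mz) > 1L && any(diff(object@mz) <= 0))
        msg <- c(msg, "mz must be strictly increasing")
    if (any(object@intensity < 0))
        msg <- c(msg, "intensity must be nonnegative")
    if (length(msg)) msg else TRUE
})

#' @rdname MassSpectrum-class
#' @param mz,intensity numeric vectors of equal length; \code{mz} strictly
#'   increasing (Da), \code{intensity} nonnegative.
#' @param sampleId,replicateId,source observation metadata.
#' @export
MassSpectrum <- function(mz, intensity, sampleId = NA_character_,
                         replicateId = NA_character_, source = NA_character_) {
    new("MassSpectrum", mz = as.numeric(mz), intensity = as.numeric(intensity),
        sampleId = as.character(sampleId), replicateId = as.character(replicateId),
        source = as.character(source))
}

#' Detected peak list
#'
#' Apex m/z values with per-peak integration half-widths. Windows are
#' non-overlapping by construction: overlapping windows are truncated at the
#' midpoint between adjacent apexes.
#'
#' @export
setClass("PeakList",
         representation(mz = "numeric", halfWidth = "numeric"))

setValidity("PeakList", function(object) {
    msg <- character()
    if (length(object@mz) != length(object@halfWidth))
        msg <- c(msg, "mz and halfWidth must have equal length")
    if (length(object@mz) > 1L && any(diff(object@mz) <= 0))
        msg <- c(msg, "apex m/z must be strictly increasing")
    if (any(object@halfWidth <= 0))
        msg <- c(msg, "halfWidth must be positive")
    if (length(msg)) msg else TRUE
})

#' @rdname PeakList-class
#' @param mz apex m/z values (Da), any order; sorted on construction.
#' @param halfWidth per-peak window half-width (Da), recycled.
#' @export
PeakList <- function(mz, halfWidth) {
    o <- order(mz)
    mz <- as.numeric(mz[o])
    halfWidth <- rep_len(as.numeric(halfWidth), length(mz))[o]
    if (length(mz) > 1L) {
        # truncate overlapping windows at the midpoint between apexes
        gap <- diff(mz) / 2
        halfWidth[-length(mz)] <- pmin(halfWidth[-length(mz)], gap)
        halfWidth[-1L] <- pmin(halfWidth[-1L], gap)
    }
    new("PeakList", mz = mz, halfWidth = halfWidth)
}

#' Per-source control-decile thresholds
#'
#' For every (source, feature) pair, the nine thresholds X1..X9 that divide
#' the source's nonzero control-class readings into ten decile bins.
#' Features with fewer than two nonzero control readings in a source cannot
#' be fitted; they are recorded in \code{unmapped} and passed through
#' unnormalized by \code{\link{applyQuantileMap}}.
#'
#' @seealso \code{\link{fitQuantileMap}}, \code{\link{applyQuantileMap}}
#' @export
setClass("QuantileMap",
         representation(thresholds = "list", features = "character",
                        unmapped = "list"))

setValidity("QuantileMap", function(object) {
    msg <- character()
    for (s in names(object@thresholds)) {
        th <- object@thresholds[[s]]
        if (!is.matrix(th) || ncol(th) != 9L)
            msg <- c(msg, sprintf("thresholds[['%s']] must be a features x 9 matrix", s))
        else {
            ok <- apply(th, 1L, function(r) all(is.na(r)) || !is.unsorted(r))
            if (!all(ok))
                msg <- c(msg, sprintf("non-ascending thresholds in source '%s'", s))
        }
    }
    if (length(msg)) msg else TRUE
})

#' Linear maximum-margin classifier
#'
#' A linear decision function d(x) = w.x + b fitted with a hinge-loss
#' maximum-margin objective (LIBSVM, linear kernel). The class encoding is
#' +1 = control, -1 = cancer, so positive decision values predict control;
#' this makes per-feature influence signs read "minus: cancer; plus:
#' control".
#'
#' @seealso \code{\link{trainClassifier}}, \code{\link{featureInfluence}}
#' @export
setClass("MarginClassifier",
         representation(weights = "numeric", intercept = "numeric",
                        features = "character", cost = "numeric"))

#' Confusion counts with accuracy and Matthews correlation
#'
#' Cancer is the positive class: TP = cancers called cancer, TN = controls
#' called control.
#'
#' @export
setClass("EvaluationReport",
         representation(tp = "numeric", fp = "numeric", tn = "numeric",
                        fn = "numeric", accuracy = "numeric", mcc = "numeric"))

setValidity("EvaluationReport", function(object) {
    cnt <- c(object@tp, object@fp, object@tn, object@fn)
    if (any(cnt < 0)) return("confusion counts must be nonnegative")
    if (sum(cnt) == 0) return("at least one prediction is required")
    TRUE
})

#' @rdname EvaluationReport-class
#' @param tp,fp,tn,fn nonnegative confusion counts (cancer = positive).
#' @export
evaluationReport <- function(tp, fp, tn, fn) {
    new("EvaluationReport", tp = tp, fp = fp, tn = tn, fn = fn,
        accuracy = (tp + tn) / (tp + tn + fp + fn),
        mcc = mcc(tp, fp, tn, fn))
}

#' Result of filter-parameter optimization
#'
#' The winning Mann-Whitney p-value cutoff and intensity cutoff, the
#' features they select, per-feature p-values, the cross-validated accuracy
#' of the winning model and the full search grid.
#'
#' @seealso \code{\link{optimizeFilters}}
#' @export
setClass("SelectionResult",
         representation(pCutoff = "numeric", intensityCutoff = "numeric",
                        features = "character", pValues = "numeric",
                        cvAccuracy = "numeric", grid = "data.frame"))

#' Decision-rule panel on clinical markers
#'
#' A binary decision tree over the four derived clinical features
#' (apoC-I/apoB-100, apoC-III/apoB-100, CRP, CA19-9), grown greedily on Gini
#' impurity with deterministic tie-breaking.
#'
#' @seealso \code{\link{trainRules}}, \code{\link{evaluateRules}}
#' @export
setClass("RuleSet",
         representation(tree = "list", features = "character",
                        trainingSummary = "list"))

#' Plan for a cross-source classification experiment
#'
#' Describes one row of the single-source / mixed-source experiment grid:
#' which sources train, which validate, whether control-decile
#' normalization is applied, how many cancer samples to hold out of a mixed
#' training set, the filter search grids and the seed.
#'
#' @seealso \code{\link{experimentPlan}}, \code{\link{runExperiment}}
#' @export
setClass("ExperimentPlan",
         representation(trainSources = "character",
                        validationSources = "character",
                        thirdSource = "character",
                        normalize = "logical", holdoutCancer = "integer",
                        pGrid = "numeric", iGrid = "numeric",
                        cvFolds = "integer", seed = "integer",
                        cost = "numeric"))

#' Report of one cross-source experiment
#'
#' Mirrors the columns of the published experiment table: chosen cutoffs,
#' number of features, ten-fold CV accuracy, per-set correct counts, and
#' training / pooled-validation MCC.
#'
#' @export
setClass("ExperimentReport",
         representation(plan = "ExperimentPlan", pCutoff = "numeric",
                        intensityCutoff = "numeric", nFeatures = "integer",
                        cvAccuracy = "numeric", training = "EvaluationReport",
                        validation = "ANY", counts = "list",
                        selectedFeatures = "character", model = "ANY"))
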