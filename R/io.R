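# deterministic 6-significant-digit formatting, element-wise (no padding)
.fmt6 <- function(x) vapply(x, function(v) sprintf("%.6g", v), character(1))

.metaCols <- function(level) {
    if (level == "replicate") c("sample_id", "replicate_id", "source", "class")
    else c("sample_id", "source", "class")
}

#' Write an intensity matrix as TSV
#'
#' One row per observation: the metadata columns (\code{sample_id},
#' \code{replicate_id} at replicate level, \code{source}, \code{class})
#' followed by one column per feature, labeled by integer-rounded m/z.
#' UTF-8, LF line endings, 6-significant-digit numbers.
#'
#' @param x a \linkS4class{PeptidomeExperiment}
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeIntensityMatrix <- function(x, path) {
    cd <- sampleInfo(x)
    lvl <- dataLevel(x)
    meta <- cd[, .metaCols(lvl), drop = FALSE]
    m <- t(intensities(x))
    fm <- matrix(.fmt6(m), nrow = nrow(m), ncol = ncol(m))
    df <- cbind(meta, as.data.frame(fm, stringsAsFactors = FALSE))
    colnames(df) <- c(colnames(meta), rownames(intensities(x)))
    con <- file(path, open = "wb")
    on.exit(close(con))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                eol = "\n", fileEncoding = "UTF-8")
    invisible(path)
}

.readMatrixTSV <- function(path, level) {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    need <- .metaCols(level)
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("schema error in '", path, "': missing column(s) ",
             paste(miss, collapse = ", "))
    featCols <- setdiff(colnames(df), need)
    if (!length(featCols)) stop("no feature columns in '", path, "'")
    m <- t(as.matrix(df[, featCols, drop = FALSE]))
    storage.mode(m) <- "double"
    if (any(m < 0)) {
        ij <- which(m < 0, arr.ind = TRUE)[1L, ]
        stop("negative intensity in '", path, "' at row ", ij[2L],
             " (", df$sample_id[ij[2L]], "), feature ", featCols[ij[1L]])
    }
    if (level == "replicate") {
        key <- paste(df$sample_id, df$replicate_id)
        if (anyDuplicated(key))
            stop("duplicate (sample_id, replicate_id) in '", path, "': ",
                 key[duplicated(key)][1L])
        colnames(m) <- paste(df$sample_id, df$replicate_id, sep = ".")
    } else {
        if (anyDuplicated(df$sample_id))
            stop("duplicate sample_id in '", path, "'")
        colnames(m) <- df$sample_id
    }
    PeptidomeExperiment(m, df[, need, drop = FALSE], level = level)
}

#' Read a replicate-level intensity matrix from TSV
#'
#' Validates the schema (metadata columns present, intensities
#' nonnegative, (sample, replicate) pairs unique) and preserves zeros as
#' the missing sentinel.
#'
#' @param path TSV written by \code{\link{writeIntensityMatrix}}
#' @return replicate-level \linkS4class{PeptidomeExperiment}
#' @export
readReplicateMatrix <- function(path) .readMatrixTSV(path, "replicate")

#' @rdname readReplicateMatrix
#' @export
readSampleMatrix <- function(path) .readMatrixTSV(path, "sample")

#' Write / read a quantile map as TSV
#'
#' Columns: source, feature, X1..X9 (NA for unfittable features).
#'
#' @param map a \linkS4class{QuantileMap}
#' @param path file path
#' @return \code{path} / a \linkS4class{QuantileMap}
#' @export
writeQuantileMap <- function(map, path) {
    rows <- do.call(rbind, lapply(names(map@thresholds), function(s) {
        th <- map@thresholds[[s]]
        data.frame(source = s, feature = rownames(th),
                   as.data.frame(th), stringsAsFactors = FALSE)
    }))
    write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
                eol = "\n", fileEncoding = "UTF-8")
    invisible(path)
}

#' @rdname writeQuantileMap
#' @export
readQuantileMap <- function(path) {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    df$feature <- as.character(df$feature)
    feats <- unique(df$feature)
    thresholds <- lapply(split(df, df$source), function(d) {
        th <- as.matrix(d[, paste0("X", 1:9)])
        rownames(th) <- d$feature
        th[feats, , drop = FALSE]
    })
    unmapped <- lapply(thresholds,
                       function(th) rownames(th)[rowSums(is.na(th)) > 0])
    new("QuantileMap", thresholds = thresholds, features = feats,
        unmapped = unmapped)
}

#' Read a clinical-marker table from TSV
#'
#' Expects columns \code{sample_id}, \code{source}, \code{class},
#' \code{apoC_I}, \code{apoC_III}, \code{apoB_100}, \code{CRP},
#' \code{CA19_9}; empty cells become \code{NA}.
#'
#' @param path TSV file
#' @return data.frame
#' @export
readClinicalTable <- function(path) {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    miss <- setdiff(c("sample_id", "source", "class", .CLINICAL_MARKERS),
                    colnames(df))
    if (length(miss))
        stop("clinical table lacks column(s): ", paste(miss, collapse = ", "))
    df
}

#' Write spectra as two-column text files with a manifest
#'
#' Each spectrum becomes \code{<sample>.<replicate>.txt} (m/z TAB
#' intensity, no header) in \code{dir}; \code{manifest.tsv} lists path,
#' sample_id, replicate_id, source and class.
#'
#' @param spectra list of \linkS4class{MassSpectrum}
#' @param dir output directory (created if needed)
#' @param classes optional class per spectrum for the manifest
#' @return manifest path, invisibly
#' @export
writeSpectra <- function(spectra, dir, classes = NA_character_) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    classes <- rep_len(classes, length(spectra))
    rows <- lapply(seq_along(spectra), function(i) {
        s <- spectra[[i]]
        fn <- sprintf("%s.%s.txt", s@sampleId, s@replicateId)
        write.table(data.frame(.fmt6(s@mz), .fmt6(s@intensity)),
                    file.path(dir, fn), sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE, eol = "\n")
        data.frame(path = fn, sample_id = s@sampleId,
                   replicate_id = s@replicateId, source = s@source,
                   class = classes[i], stringsAsFactors = FALSE)
    })
    mf <- file.path(dir, "manifest.tsv")
    write.table(do.call(rbind, rows), mf, sep = "\t", quote = FALSE,
                row.names = FALSE, eol = "\n")
    invisible(mf)
}

#' Read spectra listed in a manifest
#'
#' @param manifest path to a \code{manifest.tsv} written by
#'   \code{\link{writeSpectra}}
#' @return list of \linkS4class{MassSpectrum} with attribute
#'   \code{"classes"}
#' @export
readSpectra <- function(manifest) {
    mf <- read.delim(manifest, stringsAsFactors = FALSE)
    dir <- dirname(manifest)
    out <- lapply(seq_len(nrow(mf)), function(i) {
        d <- read.delim(file.path(dir, mf$path[i]), header = FALSE)
        MassSpectrum(d[[1]], d[[2]], sampleId = mf$sample_id[i],
                     replicateId = mf$replicate_id[i], source = mf$source[i])
    })
    attr(out, "classes") <- mf$class
    out
}

#' Write a feature-truth table as TSV
#'
#' @param truth data.frame from \code{\link{simulatePeptidome}}
#' @param path file path
#' @return \code{path}, invisibly
#' @export
writeFeatureTruth <- function(truth, path) {
    write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE,
                eol = "\n", fileEncoding = "UTF-8")
    invisible(path)
}
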