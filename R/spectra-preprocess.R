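#' Resample a spectrum onto a common m/z grid
#'
#' Linear interpolation of intensity onto \code{grid}. The grid must lie
#' within the span of the spectrum.
#'
#' @param s a \linkS4class{MassSpectrum}
#' @param grid ascending numeric m/z grid (Da)
#' @return a \linkS4class{MassSpectrum} on \code{grid}
#' @export
resampleSpectrum <- function(s, grid) {
    if (min(grid) < min(s@mz) || max(grid) > max(s@mz))
        stop("grid extends outside the span of the spectrum")
    y <- approx(s@mz, s@intensity, xout = grid)$y
    MassSpectrum(grid, y, sampleId = s@sampleId, replicateId = s@replicateId,
                 source = s@source)
}

.crossCorrLag <- function(x, ref, maxLag) {
    lags <- -maxLag:maxLag
    n <- length(x)
    cc <- vapply(lags, function(k) {
        if (k >= 0) sum(x[seq_len(n - k) + k] * ref[seq_len(n - k)])
        else        sum(x[seq_len(n + k)] * ref[seq_len(n + k) - k])
    }, numeric(1))
    lags[which.max(cc)]
}

#' Align spectra to a reference by integer-bin cross-correlation
#'
#' Every spectrum must already be resampled to the reference's grid. Each
#' spectrum is shifted by the integer-bin lag (at most \code{max_shift} Da)
#' that maximizes its cross-correlation with the reference; the shift is
#' applied losslessly as an index offset with zero-filled edges. The
#' applied (corrective) lags are attached as attribute \code{"lags"}: a
#' spectrum displaced by +3 bins relative to the reference gets lag -3.
#'
#' @param spectra list of \linkS4class{MassSpectrum} on a common grid
#' @param reference a \linkS4class{MassSpectrum} on the same grid
#' @param max_shift maximum allowed shift (Da); must not exceed 10\% of the
#'   grid span (guards pathological alignment)
#' @return list of aligned spectra with attribute \code{"lags"} (bins)
#' @export
alignSpectra <- function(spectra, reference, max_shift = 5) {
    grid <- reference@mz
    step <- grid[2] - grid[1]
    span <- diff(range(grid))
    if (max_shift > 0.1 * span)
        stop("max_shift exceeds 10% of the grid span")
    maxLag <- max(1L, as.integer(floor(max_shift / step)))
    n <- length(grid)
    out <- lapply(spectra, function(s) {
        if (length(s@mz) != n || any(abs(s@mz - grid) > step / 2))
            stop("spectra must be resampled to the reference grid first")
        lag <- -.crossCorrLag(s@intensity, reference@intensity, maxLag)
        y <- numeric(n)
        if (lag >= 0) y[seq_len(n - lag) + lag] <- s@intensity[seq_len(n - lag)]
        else          y[seq_len(n + lag)] <- s@intensity[seq_len(n + lag) - lag]
        list(spec = MassSpectrum(grid, y, sampleId = s@sampleId,
                                 replicateId = s@replicateId, source = s@source),
             lag = lag)
    })
    aligned <- lapply(out, `[[`, "spec")
    attr(aligned, "lags") <- vapply(out, `[[`, integer(1), "lag")
    aligned
}

.rollingBaseline <- function(y, step, window) {
    k <- max(3L, round(window / step))
    if (k %% 2L == 0L) k <- k + 1L
    k <- min(k, if (length(y) %% 2L) length(y) else length(y) - 1L)
    runmed(y, k, endrule = "median")
}

#' Detect peaks in a mean spectrum
#'
#' Local maxima of the baseline-subtracted signal whose height exceeds
#' \code{snr_threshold} times the noise scale are accepted greedily in
#' order of decreasing height, excluding any candidate closer than
#' \code{min_separation} to an accepted apex. The baseline is a rolling
#' median (window \code{baseline_window} Da) and the noise scale is the
#' median absolute deviation of the baseline-subtracted signal.
#'
#' @param mean_spectrum a \linkS4class{MassSpectrum}, typically the mean
#'   over all aligned replicates
#' @param snr_threshold signal-to-noise acceptance threshold
#' @param min_separation minimum apex separation (Da)
#' @param baseline_window rolling-median window (Da)
#' @return a \linkS4class{PeakList} (window half-width =
#'   \code{min_separation / 2})
#' @export
detectPeaks <- function(mean_spectrum, snr_threshold = 5, min_separation = 5,
                        baseline_window = 50) {
    y <- mean_spectrum@intensity
    if (!length(y)) stop("empty spectrum")
    grid <- mean_spectrum@mz
    step <- grid[2] - grid[1]
    resid <- y - .rollingBaseline(y, step, baseline_window)
    noise <- mad(resid)
    if (noise == 0) noise <- .Machine$double.eps
    n <- length(y)
    isMax <- c(FALSE, resid[2:(n - 1)] > resid[1:(n - 2)] &
                      resid[2:(n - 1)] >= resid[3:n], FALSE)
    cand <- which(isMax & resid > snr_threshold * noise)
    cand <- cand[order(resid[cand], decreasing = TRUE)]
    keep <- numeric(0)
    for (i in cand) {
        if (!length(keep) || all(abs(grid[i] - keep) >= min_separation))
            keep <- c(keep, grid[i])
    }
    if (!length(keep))
        return(new("PeakList", mz = numeric(0), halfWidth = numeric(0)))
    PeakList(keep, min_separation / 2)
}

#' Build the replicate-level intensity matrix from aligned spectra
#'
#' For each spectrum and each peak window, the matrix entry is the maximum
#' baseline-subtracted intensity within the window; values below the noise
#' floor (\code{floor_snr} times the spectrum's MAD noise scale) or below
#' zero are recorded as 0, the missing-reading sentinel. Columns are
#' labeled by integer-rounded apex m/z; duplicate labels are disambiguated
#' with ".1", ".2", ... suffixes.
#'
#' @param spectra list of aligned \linkS4class{MassSpectrum} on a common
#'   grid
#' @param peaks a \linkS4class{PeakList}
#' @param sampleData optional data.frame (one row per spectrum) with
#'   \code{sample_id}, \code{replicate_id}, \code{source}, \code{class};
#'   derived from the spectrum slots (class \code{NA}) when \code{NULL}
#' @param floor_snr noise-floor multiple of the MAD noise scale
#' @param baseline_window rolling-median window (Da), as in
#'   \code{\link{detectPeaks}}
#' @return a replicate-level \linkS4class{PeptidomeExperiment}
#' @export
buildIntensityMatrix <- function(spectra, peaks, sampleData = NULL,
                                 floor_snr = 2, baseline_window = 50) {
    if (!length(peaks@mz)) stop("empty PeakList")
    grid <- spectra[[1]]@mz
    step <- grid[2] - grid[1]
    labs <- as.character(round(peaks@mz))
    if (anyDuplicated(labs)) {
        for (l in unique(labs[duplicated(labs)])) {
            i <- which(labs == l)
            labs[i[-1]] <- paste0(l, ".", seq_along(i[-1]))
        }
    }
    win <- lapply(seq_along(peaks@mz), function(p)
        which(abs(grid - peaks@mz[p]) <= peaks@halfWidth[p]))
    m <- vapply(spectra, function(s) {
        resid <- s@intensity - .rollingBaseline(s@intensity, step,
                                                baseline_window)
        noise <- mad(resid)
        v <- vapply(win, function(w) max(resid[w]), numeric(1))
        v[v < floor_snr * noise | v < 0] <- 0
        v
    }, numeric(length(win)))
    m <- matrix(m, nrow = length(win),
                dimnames = list(labs, NULL))
    if (is.null(sampleData))
        sampleData <- data.frame(
            sample_id = vapply(spectra, slot, character(1), "sampleId"),
            replicate_id = vapply(spectra, slot, character(1), "replicateId"),
            source = vapply(spectra, slot, character(1), "source"),
            class = NA_character_, stringsAsFactors = FALSE)
    colnames(m) <- paste(sampleData$sample_id, sampleData$replicate_id,
                         sep = ".")
    PeptidomeExperiment(m, sampleData, mz = round(peaks@mz),
                        level = "replicate")
}

#' Full spectrum-to-matrix preprocessing
#'
#' Convenience wrapper: resample all spectra to a uniform grid, align them
#' to the first spectrum, detect peaks on the mean aligned spectrum and
#' quantify every replicate in the detected windows.
#'
#' @param spectra list of \linkS4class{MassSpectrum} (raw)
#' @param sampleData as in \code{\link{buildIntensityMatrix}}
#' @param grid_step uniform resampling step (Da)
#' @param max_shift alignment limit (Da)
#' @param snr_threshold,min_separation,baseline_window,floor_snr see
#'   \code{\link{detectPeaks}} and \code{\link{buildIntensityMatrix}}
#' @return list with \code{experiment} (the matrix), \code{peaks} and
#'   \code{lags}
#' @export
preprocessSpectra <- function(spectra, sampleData = NULL, grid_step = 0.5,
                              max_shift = 5, snr_threshold = 5,
                              min_separation = 5, baseline_window = 50,
                              floor_snr = 2) {
    lo <- max(vapply(spectra, function(s) min(s@mz), numeric(1)))
    hi <- min(vapply(spectra, function(s) max(s@mz), numeric(1)))
    grid <- seq(lo, hi, by = grid_step)
    res <- lapply(spectra, resampleSpectrum, grid = grid)
    aligned <- alignSpectra(res, res[[1]], max_shift = max_shift)
    meanInt <- rowMeans(vapply(aligned, slot, numeric(length(grid)),
                               "intensity"))
    peaks <- detectPeaks(MassSpectrum(grid, pmax(meanInt, 0)),
                         snr_threshold = snr_threshold,
                         min_separation = min_separation,
                         baseline_window = baseline_window)
    expt <- buildIntensityMatrix(aligned, peaks, sampleData = sampleData,
                                 floor_snr = floor_snr,
                                 baseline_window = baseline_window)
    list(experiment = expt, peaks = peaks, lags = attr(aligned, "lags"))
}
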