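test_that("resampling is exact on the original grid and linear in between", {
    s <- MassSpectrum(c(100, 102), c(0, 10))
    expect_equal(resampleSpectrum(s, c(100, 101, 102))@intensity, c(0, 5, 10))
    s2 <- MassSpectrum(seq(100, 110, 0.5), runif(21))
    expect_equal(resampleSpectrum(s2, s2@mz)@intensity, s2@intensity)
    expect_error(resampleSpectrum(s2, seq(99, 105, 0.5)), "outside")
})

test_that("a planted Gaussian survives resampling at 4x density", {
    grid <- seq(900, 1100, 1)
    y <- 80 * exp(-(grid - 1000)^2 / (2 * 3^2))
    s <- MassSpectrum(grid, y)
    fine <- resampleSpectrum(s, seq(900, 1100, 0.25))
    expect_lt(abs(max(fine@intensity) - 80) / 80, 0.01)
})

test_that("alignment recovers constructed shifts exactly", {
    grid <- seq(1000, 2000, 0.5)
    set.seed(1)
    y <- 50 * exp(-(grid - 1200)^2 / 8) + 90 * exp(-(grid - 1700)^2 / 8)
    ref <- MassSpectrum(grid, y)
    self <- alignSpectra(list(ref), ref, max_shift = 5)
    expect_identical(attr(self, "lags"), 0L)
    shifted <- MassSpectrum(grid, c(rep(0, 3), y[seq_len(length(y) - 3)]))
    al <- alignSpectra(list(shifted), ref, max_shift = 5)
    expect_identical(attr(al, "lags"), -3L)
    expect_equal(al[[1]]@intensity[10:1900], y[10:1900])
    expect_error(alignSpectra(list(ref), ref, max_shift = 200), "10%")
})

test_that("alignment tolerates noise at 5% of the apex", {
    grid <- seq(1000, 1500, 0.5)
    y <- 100 * exp(-(grid - 1250)^2 / 8)
    ref <- MassSpectrum(grid, y)
    set.seed(99)
    hits <- 0L
    for (i in 1:100) {
        k <- sample(-6:6, 1)
        ys <- numeric(length(y))
        idx <- seq_along(y) - k
        ok <- idx >= 1 & idx <= length(y)
        ys[ok] <- y[idx[ok]]
        ys <- pmax(ys + rnorm(length(ys), 0, 5), 0)
        al <- alignSpectra(list(MassSpectrum(grid, ys)), ref, max_shift = 5)
        if (attr(al, "lags") == -k) hits <- hits + 1L
    }
    expect_gte(hits, 95)
})

test_that("peak detection finds planted peaks and resists noise", {
    grid <- seq(1000, 3000, 0.5)
    set.seed(7)
    # noise-only: at SNR threshold 5, false peaks are rare
    falseCounts <- vapply(1:100, function(i)
        length(detectPeaks(MassSpectrum(grid, pmax(rnorm(length(grid), 10, 2), 0)),
                           snr_threshold = 5)), integer(1))
    expect_gte(sum(falseCounts <= 1), 95)
    # three well-separated planted Gaussians at high SNR
    y <- 10 + 40 * exp(-(grid - 1300)^2 / 8) +
         60 * exp(-(grid - 1900)^2 / 8) +
         80 * exp(-(grid - 2500)^2 / 8)
    y <- y + rnorm(length(grid), 0, 2)
    pk <- detectPeaks(MassSpectrum(grid, pmax(y, 0)), snr_threshold = 5,
                      min_separation = 5)
    expect_identical(length(pk), 3L)
    expect_true(all(abs(peakMz(pk) - c(1300, 1900, 2500)) <= 0.5))
    expect_error(detectPeaks(MassSpectrum(numeric(0), numeric(0))), "empty")
})

test_that("peaks closer than min_separation merge to the taller one", {
    grid <- seq(1000, 1100, 0.5)
    y <- 50 * exp(-(grid - 1048)^2 / 2) + 90 * exp(-(grid - 1051)^2 / 2)
    pk <- detectPeaks(MassSpectrum(grid, y), snr_threshold = 3,
                      min_separation = 8, baseline_window = 60)
    expect_identical(length(pk), 1L)
    expect_lt(abs(peakMz(pk) - 1051), 1.1)
})

test_that("matrix building quantifies windows and flags absent signal as 0", {
    grid <- seq(1000, 1200, 0.5)
    mk <- function(amp, sid, rid) {
        y <- 5 + amp * exp(-(grid - 1100)^2 / 8)
        MassSpectrum(grid, y, sampleId = sid, replicateId = rid, source = "A")
    }
    peaks <- PeakList(1100, 2.5)
    sp <- list(mk(100, "s1", "r1"), mk(0, "s1", "r2"))
    pd <- data.frame(sample_id = c("s1", "s1"), replicate_id = c("r1", "r2"),
                     source = "A", class = "control")
    x <- buildIntensityMatrix(sp, peaks, pd)
    m <- intensities(x)
    expect_identical(dim(m), c(1L, 2L))
    expect_gt(m[1, 1], 0)
    expect_identical(unname(m[1, 2]), 0)   # peak present in replicate 1 only
    expect_identical(rownames(m), "1100")
    expect_error(buildIntensityMatrix(sp, PeakList(numeric(0), numeric(0)), pd),
                 "empty")
})

test_that("duplicate integer m/z labels get disambiguating suffixes", {
    grid <- seq(1000, 1200, 0.5)
    y <- 5 + 50 * exp(-(grid - 1100.3)^2 / 2) + 70 * exp(-(grid - 1099.6)^2 / 2)
    peaks <- PeakList(c(1099.6, 1100.3), 0.3)
    sp <- list(MassSpectrum(grid, y, "s1", "r1", "A"))
    pd <- data.frame(sample_id = "s1", replicate_id = "r1", source = "A",
                     class = "control")
    x <- buildIntensityMatrix(sp, peaks, pd)
    expect_identical(rownames(intensities(x)), c("1100", "1100.1"))
})

test_that("simulate -> render -> preprocess round-trips the planted features", {
    cfg <- generatorConfig(seed = 21, n_features = 60L,
                           sources = list(A = c(control = 3L, cancer = 3L)),
                           mz_range = c(1000, 6000), source_bias_sd = 0.5,
                           dropout_midpoint = 2)
    sim <- simulatePeptidome(cfg)
    sp <- renderSpectra(sim$experiment, peak_width = 2, noise_sd = 2,
                        baseline_intensity = 25, seed = 2)
    res <- preprocessSpectra(sp, sampleData = sampleInfo(sim$experiment),
                             snr_threshold = 5, min_separation = 6)
    planted <- featureMz(sim$experiment)
    found <- peakMz(res$peaks)
    hit <- vapply(planted, function(mz) any(abs(found - mz) <= 0.5), logical(1))
    expect_gte(mean(hit), 0.9)
    # recovered intensities within 10% of planted amplitudes at high SNR
    m0 <- intensities(sim$experiment)
    m1 <- intensities(res$experiment)
    lab <- as.character(round(found))
    relErr <- c()
    for (f in which(hit)) {
        j <- which(abs(found - planted[f]) <= 0.5)[1]
        planted_amp <- m0[f, ]
        got <- m1[lab[j], ]
        big <- planted_amp > 10 * 2  # SNR >= 10 at noise sd 2
        if (any(big))
            relErr <- c(relErr, abs(got[big] - planted_amp[big]) /
                                planted_amp[big])
    }
    expect_lt(median(relErr), 0.1)
    expect_gt(mean(relErr < 0.1), 0.8)
    # matrix shape invariant: one column per spectrum, one row per peak
    expect_identical(nrow(intensities(res$experiment)), length(found))
    expect_true(all(intensities(res$experiment) >= 0))
})
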