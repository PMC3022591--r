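test_that("invalid configurations are rejected", {
    expect_error(generatorConfig(frac_concordant = 0.6, frac_discordant = 0.6,
                                 frac_null = -0.2),
                 "proportions")
    expect_error(generatorConfig(frac_concordant = 0.1, frac_discordant = 0.1,
                                 frac_null = 0.5),
                 "sum to 1")
    expect_error(generatorConfig(n_features = 0), "positive")
    expect_error(generatorConfig(dropout_midpoint = -1), "positive")
    expect_error(simulatePeptidome(list(seed = 1)), "generatorConfig")
})

test_that("the same seed reproduces the dataset exactly", {
    cfg <- smallConfig(seed = 7)
    a <- simulatePeptidome(cfg)
    b <- simulatePeptidome(smallConfig(seed = 7))
    expect_identical(intensities(a$experiment), intensities(b$experiment))
    expect_identical(a$truth, b$truth)
    c3 <- simulatePeptidome(smallConfig(seed = 8))
    expect_false(identical(intensities(a$experiment),
                           intensities(c3$experiment)))
})

test_that("generated data respect the design's structural invariants", {
    sim <- simulatePeptidome(smallConfig(seed = 3))
    x <- sim$experiment
    expect_true(all(intensities(x) >= 0))
    cd <- sampleInfo(x)
    expect_identical(dataLevel(x), "replicate")
    # third source is control-only
    expect_true(all(cd$class[cd$source == "C"] == "control"))
    # cohort sizes follow the configured design
    tab <- table(cd$source, cd$class) / 2L  # two replicates
    expect_equal(unname(tab["A", "control"]), 21)
    expect_equal(unname(tab["B", "cancer"]), 40)
    expect_equal(unname(tab["C", "cancer"]), 0)
})

test_that("discordant features have opposite class trends in the two case sources", {
    sim <- simulatePeptidome(smallConfig(seed = 5))
    tr <- sim$truth
    disc <- tr[tr$class_of_feature == "discordant", ]
    expect_gt(nrow(disc), 0)
    expect_true(all(sign(disc$effect_A) == -sign(disc$effect_B)))
    nullf <- tr[tr$class_of_feature == "null", ]
    expect_true(all(nullf$effect_A == 0 & nullf$effect_B == 0))
    # the planted trend is visible in the data: sign of
    # (mean control - mean cancer) differs between sources A and B
    m <- intensities(sim$experiment)
    cd <- sampleInfo(sim$experiment)
    logm <- log(m + 1)
    for (f in head(disc$feature_id, 4)) {
        dAB <- vapply(c("A", "B"), function(s) {
            ctl <- cd$source == s & cd$class == "control"
            can <- cd$source == s & cd$class == "cancer"
            mean(logm[f, ctl]) - mean(logm[f, can])
        }, numeric(1))
        expect_true(prod(sign(dAB)) < 0,
                    label = sprintf("feature %s trend signs %s", f,
                                    paste(sign(dAB), collapse = "/")))
    }
})

test_that("dropout is monotone: zero rate decreases with underlying intensity", {
    sim <- simulatePeptidome(smallConfig(seed = 11))
    m <- intensities(sim$experiment)
    # proxy for underlying intensity: the per-feature mean of nonzero readings
    lvl <- apply(m, 1L, function(v) mean(v[v > 0]))
    zr <- rowMeans(m == 0)
    dec <- cut(rank(lvl, ties.method = "first"), 10)
    byDec <- tapply(zr, dec, mean)
    # non-increasing across intensity deciles up to small sampling noise
    expect_true(all(diff(byDec) <= 0.02))
    expect_gt(byDec[1], byDec[10])
})

test_that("with zero effect (and no batch structure) feature p-values are calibrated", {
    fr <- vapply(1:10, function(s) {
        cfg <- generatorConfig(seed = s, n_features = 300,
                               effect_size = 0, discordant_effect_size = 0,
                               discordant_source_offset = 0,
                               source_bias_sd = 0, source_batches = 1L,
                               sample_sd = 0.7)
        sim <- simulatePeptidome(cfg)
        sm <- filterZeroFeatures(averageReplicates(sim$experiment))$experiment
        cd <- sampleInfo(sm)
        mixed <- cd$source %in% c("A", "B")
        pv <- mannWhitneyPValues(intensities(sm)[, mixed], cd$class[mixed])
        mean(pv < 0.05)
    }, numeric(1))
    expect_lt(abs(median(fr) - 0.05), 0.02)
})

test_that("rendered spectra place peaks where the matrix says", {
    m <- matrix(c(100, 0), 2, 1, dimnames = list(c("2000", "5000"), "s1.r1"))
    pd <- data.frame(sample_id = "s1", replicate_id = "r1", source = "A",
                     class = "control")
    x <- PeptidomeExperiment(m, pd)
    sp <- renderSpectra(x, peak_width = 2, noise_sd = 0,
                        baseline_intensity = 0)[[1]]
    expect_lt(abs(sp@mz[which.max(sp@intensity)] - 2000), 2)
    # zero-intensity feature produces no peak: spectrum is flat near 5000
    near5000 <- abs(sp@mz - 5000) < 10
    expect_true(all(sp@intensity[near5000] == 0))
    expect_error(renderSpectra(x, peak_width = 0), "positive")
    expect_error(renderSpectra(x, mz_range = c(1900, 3000)), "inside")
})

test_that("an all-zero row renders as baseline plus noise only", {
    m <- matrix(0, 1, 1, dimnames = list("3000", "s1.r1"))
    pd <- data.frame(sample_id = "s1", replicate_id = "r1", source = "A",
                     class = "control")
    sp <- renderSpectra(PeptidomeExperiment(m, pd), noise_sd = 0,
                        baseline_intensity = 30, baseline_scale = 3000)[[1]]
    base <- 30 * exp(-(sp@mz - sp@mz[1]) / 3000)
    expect_equal(sp@intensity, base, tolerance = 1e-12)
})

test_that("apex heights above baseline reproduce planted amplitudes", {
    m <- matrix(c(50, 100), 2, 1, dimnames = list(c("2000", "8000"), "s1.r1"))
    pd <- data.frame(sample_id = "s1", replicate_id = "r1", source = "A",
                     class = "control")
    x <- PeptidomeExperiment(m, pd)
    sp <- renderSpectra(x, peak_width = 2, noise_sd = 0,
                        baseline_intensity = 20, baseline_scale = 3000)[[1]]
    base <- 20 * exp(-(sp@mz - sp@mz[1]) / 3000)
    resid <- sp@intensity - base
    h1 <- max(resid[abs(sp@mz - 2000) < 10])
    h2 <- max(resid[abs(sp@mz - 8000) < 10])
    expect_lt(abs(h1 - 50) / 50, 0.05)
    expect_lt(abs(h2 - 100) / 100, 0.05)
})

test_that("clinical cohorts reproduce the marker structure", {
    coh <- simulateClinicalCohort(seed = 1,
                                  sizes = list(A = c(control = 200, cancer = 200)))
    expect_true(all(unlist(coh[, c("apoC_I", "apoC_III", "apoB_100",
                                   "CRP", "CA19_9")]) > 0))
    # apoC-III higher in controls
    p <- groupCompare(coh$apoC_III[coh$class == "control"],
                      coh$apoC_III[coh$class == "cancer"], "greater")$p
    expect_lt(p, 0.01)
    # apoB-100 carries no class signal: two-sided p roughly uniform over seeds
    ps <- vapply(1:10, function(s) {
        co <- simulateClinicalCohort(seed = s,
                                     sizes = list(A = c(control = 60, cancer = 60)))
        suppressWarnings(wilcox.test(apoB_100 ~ class, data = co)$p.value)
    }, numeric(1))
    expect_gt(mean(ps > 0.05), 0.7)
    expect_gt(min(ps), 0.001)
    # determinism
    expect_identical(coh, simulateClinicalCohort(seed = 1,
        sizes = list(A = c(control = 200, cancer = 200))))
    bad <- clinicalMarkerDefaults()
    bad$CRP$control["sdlog"] <- 0
    expect_error(simulateClinicalCohort(1, marker_params = bad),
                 "sdlog")
})
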