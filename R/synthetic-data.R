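#' Configuration of the synthetic two-source peptidome generator
#'
#' Defines the statistical structure of a simulated two-biorepository
#' serum-peptidome study: per-feature multiplicative source biases, features
#' whose cancer-vs-control trend is concordant across the two case/control
#' sources, features with opposite (discordant) trends, null features,
#' log-normal replicate noise, and intensity-dependent dropout recorded as
#' the 0 sentinel. A third source contains controls only and serves as an
#' independent validation set.
#'
#' All intensity parameters act on the natural-log scale. Default cohort
#' sizes mirror the study design the pipeline targets: source A 21 controls
#' / 22 cancers, source B 20 controls / 40 cancers, source C 12 controls,
#' 637 features, two replicates per sample.
#'
#' @param seed integer seed; identical configurations generate
#'   byte-identical data.
#' @param n_features number of mass peaks.
#' @param sources named list; each element a vector
#'   \code{c(control = , cancer = )}.
#' @param n_replicates replicate readings per sample (2 or 3 in practice).
#' @param frac_concordant,frac_discordant,frac_null proportions of feature
#'   classes; must sum to 1.
#' @param frac_up_in_control among concordant features, the probability
#'   that the peak is higher in controls (reduced in cancer); serum
#'   peptidome signatures of consumptive disease are dominated by
#'   reductions, as for the apolipoprotein fragments this design targets.
#' @param effect_size log-scale shift applied to cancer samples for
#'   concordant features (same sign in every case/control source).
#' @param discordant_effect_size log-scale magnitude, in the first
#'   case/control source, of the source-by-disease interaction for
#'   discordant features. The second source receives the opposite sign
#'   with magnitude scaled by the ratio of cancer cohort sizes, so the
#'   pooled (mixed-set) trend cancels; per-source magnitudes of a
#'   trend-reversing peak differ in real data too.
#' @param discordant_source_offset extra fixed log offset between the two
#'   case/control sources for discordant features: trend reversal arises
#'   from pre-analytical (e.g. tube-brand) chemistry, which also makes the
#'   overall level of such peaks strongly source-dependent.
#' @param source_bias_sd s.d. of the per-(feature, source) log
#'   multiplicative bias; either a scalar or a named vector with one
#'   entry per source (the control-only validation source is collected
#'   under different conditions — e.g. non-fasting donors — and so may
#'   deviate more).
#' @param source_batches named integer vector: number of acquisition
#'   batches per source. Each batch draws its own per-feature bias
#'   (samples collected and measured over separate dates deviate
#'   independently); samples are assigned to batches round-robin.
#' @param severity_shape shape of the Gamma(shape, rate = shape)
#'   per-sample disease-severity multiplier applied to every cancer
#'   sample's effects (mean 1); cancer cohorts span clinical stages, so
#'   per-patient effect magnitude varies. \code{Inf} disables
#'   heterogeneity.
#' @param sample_sd between-sample biological log-s.d. within a class;
#'   scalar or named per-source vector (non-fasting donors show larger
#'   inter-individual serum variation than fasting cohorts).
#' @param replicate_cv coefficient of variation of the multiplicative
#'   log-normal replicate noise (log-s.d. for small values).
#' @param dropout_midpoint,dropout_steepness parameters of the logistic
#'   dropout curve: a reading of intensity I is recorded as 0 with
#'   probability 1 / (1 + exp(steepness * (log I - log midpoint))).
#' @param source_log_shift named vector, global log-intensity offset per
#'   source (spectrum-wide sensitivity differences between collection
#'   sites and acquisition batches); absorbed exactly by per-source
#'   control-decile normalization.
#' @param mz_range interval from which feature m/z labels are drawn (Da).
#' @param base_log_mean,base_log_sd distribution of per-feature baseline
#'   log intensity.
#' @param signal_abundance_shift log-scale increment of the baseline for
#'   discriminative (concordant and discordant) features. Signature
#'   peptides detectable in every sample of every cohort are fragments of
#'   abundant serum proteins; a trend planted on a peak that drops below
#'   the detection floor in one class would be eliminated by the zero
#'   filter rather than recovered.
#'
#' @return a list of class \code{"GeneratorConfig"}
#' @examples
#' cfg <- generatorConfig(seed = 7, n_features = 50)
#' sim <- simulatePeptidome(cfg)
#' sim$experiment
#' @export
generatorConfig <- function(seed = 1L, n_features = 637L,
                            sources = list(A = c(control = 21L, cancer = 22L),
                                           B = c(control = 20L, cancer = 40L),
                                           C = c(control = 12L, cancer = 0L)),
                            n_replicates = 2L,
                            frac_concordant = 0.05, frac_discordant = 0.015,
                            frac_null = 1 - frac_concordant - frac_discordant,
                            frac_up_in_control = 0.5,
                            effect_size = 1.2, discordant_effect_size = 1.2,
                            discordant_source_offset = 2.0,
                            source_bias_sd = c(A = 1.2, B = 1.2, C = 3.0),
                            source_batches = c(A = 1L, B = 1L, C = 3L),
                            severity_shape = Inf,
                            sample_sd = c(A = 0.7, B = 0.7, C = 1.8),
                            replicate_cv = 0.25,
                            dropout_midpoint = 8, dropout_steepness = 2,
                            source_log_shift = c(A = 0, B = 0, C = -0.8),
                            mz_range = c(900, 13500),
                            base_log_mean = log(500), base_log_sd = 0.7,
                            signal_abundance_shift = 1.2) {
    fr <- c(frac_concordant, frac_discordant, frac_null)
    if (any(fr < 0) || any(fr > 1) || abs(sum(fr) - 1) > 1e-9)
        stop("feature-class proportions must lie in [0, 1] and sum to 1")
    if (n_features < 1L || n_replicates < 1L)
        stop("n_features and n_replicates must be positive")
    if (!length(sources) || is.null(names(sources)))
        stop("sources must be a named list")
    for (s in names(sources)) {
        ns <- sources[[s]]
        if (!all(c("control", "cancer") %in% names(ns)) || any(ns < 0) ||
            sum(ns) < 1)
            stop("each source needs nonnegative control/cancer counts, ",
                 "at least one sample in total")
    }
    if (replicate_cv < 0 || any(sample_sd < 0) || any(source_bias_sd < 0))
        stop("noise parameters must be nonnegative")
    if (length(sample_sd) > 1L && !all(names(sources) %in% names(sample_sd)))
        stop("per-source sample_sd needs one named entry per source")
    if (length(source_bias_sd) > 1L &&
        !all(names(sources) %in% names(source_bias_sd)))
        stop("per-source source_bias_sd needs one named entry per source")
    if (dropout_midpoint <= 0)
        stop("dropout_midpoint must be positive")
    if (frac_up_in_control < 0 || frac_up_in_control > 1)
        stop("frac_up_in_control must lie in [0, 1]")
    if (length(source_log_shift) > 1L &&
        !all(names(sources) %in% names(source_log_shift)))
        stop("per-source source_log_shift needs one named entry per source")
    if (any(source_batches < 1) ||
        (length(source_batches) > 1L &&
         !all(names(sources) %in% names(source_batches))))
        stop("source_batches needs a positive count per source")
    structure(list(seed = as.integer(seed), n_features = as.integer(n_features),
                   sources = sources, n_replicates = as.integer(n_replicates),
                   frac_concordant = frac_concordant,
                   frac_discordant = frac_discordant, frac_null = frac_null,
                   frac_up_in_control = frac_up_in_control,
                   effect_size = effect_size,
                   discordant_effect_size = discordant_effect_size,
                   discordant_source_offset = discordant_source_offset,
                   source_bias_sd = source_bias_sd,
                   source_batches = source_batches,
                   severity_shape = severity_shape, sample_sd = sample_sd,
                   replicate_cv = replicate_cv,
                   dropout_midpoint = dropout_midpoint,
                   dropout_steepness = dropout_steepness,
                   source_log_shift = source_log_shift,
                   mz_range = mz_range, base_log_mean = base_log_mean,
                   base_log_sd = base_log_sd,
                   signal_abundance_shift = signal_abundance_shift),
              class = "GeneratorConfig")
}

# m/z labels: distinct integers with a minimum gap so rendered peaks are
# resolvable at typical linear-TOF peak widths
.drawFeatureMz <- function(n, mz_range, min_gap = 12) {
    grid <- seq(mz_range[1], mz_range[2] - 4, by = min_gap)
    if (length(grid) < n)
        stop("mz_range too narrow for ", n, " features")
    base <- sort(sample(grid, n))
    base + sample(0:3, n, replace = TRUE)
}

#' Simulate a two-source peptidome dataset with known ground truth
#'
#' Generates a replicate-level intensity matrix under the model described
#' in \code{\link{generatorConfig}}. For case/control source s, sample i of
#' class k, replicate r and feature f:
#' \deqn{\log I = \mu_f + b_{fs} + [k = cancer]\,e_{fs} + u_{if} + \epsilon_{ifr}}
#' with per-feature baseline \eqn{\mu_f}, per-(feature, source) bias
#' \eqn{b_{fs}}, disease effect \eqn{e_{fs}} (zero for null features, equal
#' across sources for concordant ones, opposite-signed for discordant
#' ones), biological noise \eqn{u} and replicate noise \eqn{\epsilon}.
#' Each reading is then zeroed with the logistic dropout probability, which
#' decreases with intensity, so zeros concentrate at low intensity.
#'
#' @param config a \code{\link{generatorConfig}}
#' @return list with elements \code{experiment} (replicate-level
#'   \linkS4class{PeptidomeExperiment}) and \code{truth} (data.frame with
#'   one row per feature: \code{feature_id}, \code{mz},
#'   \code{class_of_feature}, per-source effects and biases)
#' @export
simulatePeptidome <- function(config) {
    if (!inherits(config, "GeneratorConfig"))
        stop("config must come from generatorConfig()")
    set.seed(config$seed)
    nf <- config$n_features
    mz <- .drawFeatureMz(nf, config$mz_range)
    mu <- rnorm(nf, config$base_log_mean, config$base_log_sd)

    nc <- round(config$frac_concordant * nf)
    nd <- round(config$frac_discordant * nf)
    cls <- rep("null", nf)
    idx <- sample.int(nf)
    conc <- idx[seq_len(nc)]
    disc <- idx[nc + seq_len(nd)]
    up_in_control <- rep(NA, nf)
    up_in_control[conc] <- runif(nc) < config$frac_up_in_control
    cls[conc] <- ifelse(up_in_control[conc],
                        "concordant_up_in_control", "concordant_up_in_cancer")
    cls[disc] <- "discordant"

    mu[cls != "null"] <- mu[cls != "null"] + config$signal_abundance_shift

    srcs <- names(config$sources)
    caseSources <- srcs[vapply(config$sources,
                               function(x) x[["cancer"]] > 0, logical(1))]
    # disease effect on the cancer class, per feature x source (log scale)
    eff <- matrix(0, nf, length(srcs), dimnames = list(NULL, srcs))
    for (j in which(cls != "null")) {
        if (cls[j] == "discordant") {
            sgn <- sample(c(-1, 1), 1)
            e <- config$discordant_effect_size
            if (length(caseSources) >= 2) {
                s1 <- caseSources[1]; s2 <- caseSources[2]
                n1 <- config$sources[[s1]][["cancer"]]
                n2 <- config$sources[[s2]][["cancer"]]
                eff[j, s1] <- sgn * e
                eff[j, s2] <- -sgn * e * n1 / n2
                if (length(caseSources) > 2)
                    eff[j, caseSources[-(1:2)]] <-
                        sample(c(-1, 1), length(caseSources) - 2, TRUE) * e
            } else if (length(caseSources) == 1) {
                eff[j, caseSources] <- sgn * e
            }
        } else {
            sgn <- if (up_in_control[j]) -1 else 1
            eff[j, caseSources] <- sgn * config$effect_size
        }
    }
    bsd <- config$source_bias_sd
    if (length(bsd) == 1L) bsd <- setNames(rep(bsd, length(srcs)), srcs)
    ssd <- config$sample_sd
    if (length(ssd) == 1L) ssd <- setNames(rep(ssd, length(srcs)), srcs)
    gsh <- config$source_log_shift
    if (length(gsh) == 1L) gsh <- setNames(rep(gsh, length(srcs)), srcs)
    nbt <- config$source_batches
    if (length(nbt) == 1L) nbt <- setNames(rep(nbt, length(srcs)), srcs)
    # per (feature, source, batch) multiplicative bias on the log scale
    bias <- lapply(setNames(srcs, srcs), function(s)
        vapply(seq_len(nbt[[s]]),
               function(b) gsh[[s]] + rnorm(nf, 0, bsd[[s]]), numeric(nf)))
    if (length(caseSources) >= 2 && any(cls == "discordant")) {
        off <- sample(c(-1, 1), sum(cls == "discordant"), replace = TRUE) *
            config$discordant_source_offset / 2
        bias[[caseSources[1]]][cls == "discordant", ] <-
            bias[[caseSources[1]]][cls == "discordant", , drop = FALSE] + off
        bias[[caseSources[2]]][cls == "discordant", ] <-
            bias[[caseSources[2]]][cls == "discordant", , drop = FALSE] - off
    }

    cd <- do.call(rbind, lapply(srcs, function(s) {
        ns <- config$sources[[s]]
        n <- sum(ns)
        if (n == 0) return(NULL)
        kls <- rep(c("control", "cancer"), ns[c("control", "cancer")])
        data.frame(sample_id = sprintf("%s_%s_%02d", s,
                                       ifelse(kls == "control", "ctl", "can"),
                                       unlist(lapply(ns[c("control", "cancer")],
                                                     seq_len))),
                   source = s, class = kls, stringsAsFactors = FALSE)
    }))
    nrep <- config$n_replicates
    cdr <- cd[rep(seq_len(nrow(cd)), each = nrep), ]
    cdr$replicate_id <- sprintf("r%d", rep(seq_len(nrep), nrow(cd)))
    rownames(cdr) <- paste(cdr$sample_id, cdr$replicate_id, sep = ".")

    sampleIndexInSource <- stats::ave(seq_len(nrow(cd)), cd$source,
                                      FUN = seq_along)
    m <- matrix(0, nf, nrow(cdr),
                dimnames = list(as.character(mz), rownames(cdr)))
    for (i in seq_len(nrow(cd))) {
        s <- cd$source[i]
        sev <- if (cd$class[i] != "cancer") 0
               else if (is.finite(config$severity_shape))
                   stats::rgamma(1, shape = config$severity_shape,
                                 rate = config$severity_shape)
               else 1
        batch <- 1L + (sampleIndexInSource[i] - 1L) %% nbt[[s]]
        logSample <- mu + bias[[s]][, batch] + sev * eff[, s] +
            rnorm(nf, 0, ssd[[s]])
        for (r in seq_len(nrep)) {
            logI <- logSample + rnorm(nf, 0, config$replicate_cv)
            I <- exp(logI)
            pZero <- 1 / (1 + exp(config$dropout_steepness *
                                  (logI - log(config$dropout_midpoint))))
            I[runif(nf) < pZero] <- 0
            m[, (i - 1L) * nrep + r] <- I
        }
    }
    truth <- data.frame(feature_id = as.character(mz), mz = mz,
                        class_of_feature = cls, stringsAsFactors = FALSE)
    for (s in srcs) {
        truth[[paste0("effect_", s)]] <- eff[, s]
        truth[[paste0("bias_", s)]] <- rowMeans(bias[[s]])
    }
    expt <- PeptidomeExperiment(m, cdr, mz = mz, level = "replicate")
    S4Vectors::metadata(expt)$generator <- config
    list(experiment = expt, truth = truth)
}

#' Render replicate rows as continuous spectra
#'
#' Turns each replicate-level observation into a profile spectrum: a sum of
#' Gaussian peaks centered at the feature m/z values with the observation's
#' intensities as apex amplitudes, plus a smooth exponentially decaying
#' baseline and additive Gaussian noise (clipped at zero). Zero-intensity
#' (missing) entries produce no peak. This exists so the spectrum-level
#' preprocessing can be tested end-to-end against known amplitudes.
#'
#' @param x replicate-level \linkS4class{PeptidomeExperiment}
#' @param peak_width Gaussian s.d. of a peak (Da); must be positive.
#' @param mz_range span of the rendered axis; defaults to the feature span
#'   padded by 50 Da.
#' @param grid_step sampling step (Da).
#' @param baseline_intensity,baseline_scale baseline
#'   \eqn{b(m) = b_0 \exp(-(m - m_{min})/s)}.
#' @param noise_sd additive noise s.d.
#' @param seed seed for the noise.
#' @return list of \linkS4class{MassSpectrum}
#' @export
renderSpectra <- function(x, peak_width = 2, mz_range = NULL, grid_step = 0.5,
                          baseline_intensity = 30, baseline_scale = 3000,
                          noise_sd = 3, seed = 1L) {
    if (peak_width <= 0) stop("peak_width must be positive")
    mz <- featureMz(x)
    if (is.null(mz_range))
        mz_range <- c(min(mz) - 50, max(mz) + 50)
    if (any(mz <= mz_range[1]) || any(mz >= mz_range[2]))
        stop("all feature m/z labels must fall inside mz_range")
    grid <- seq(mz_range[1], mz_range[2], by = grid_step)
    base <- baseline_intensity * exp(-(grid - grid[1]) / baseline_scale)
    m <- intensities(x)
    cd <- sampleInfo(x)
    set.seed(seed)
    lapply(seq_len(ncol(m)), function(j) {
        y <- base
        amp <- m[, j]
        for (f in which(amp > 0)) {
            win <- which(abs(grid - mz[f]) <= 5 * peak_width)
            y[win] <- y[win] +
                amp[f] * exp(-(grid[win] - mz[f])^2 / (2 * peak_width^2))
        }
        if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
        MassSpectrum(grid, pmax(y, 0), sampleId = cd$sample_id[j],
                     replicateId = if ("replicate_id" %in% names(cd))
                         cd$replicate_id[j] else NA_character_,
                     source = cd$source[j])
    })
}

#' Default per-class marker distributions for the clinical cohort generator
#'
#' Log-normal location (meanlog) and scale (sdlog) per marker and class, in
#' clinical units: apoC-I ug/ml, apoC-III mg/dl, apoB-100 mg/dl, CRP ug/ml,
#' CA19-9 U/ml. Defaults encode the qualitative structure the panel
#' assumes: apoC-I and apoC-III higher in controls, CRP and CA19-9 elevated
#' in cancer, apoB-100 identically distributed in both classes.
#'
#' @return nested list marker -> class -> c(meanlog, sdlog)
#' @export
clinicalMarkerDefaults <- function() {
    list(apoC_I   = list(control = c(meanlog = log(80),  sdlog = 0.30),
                         cancer  = c(meanlog = log(55),  sdlog = 0.35)),
         apoC_III = list(control = c(meanlog = log(10),  sdlog = 0.30),
                         cancer  = c(meanlog = log(6.5), sdlog = 0.35)),
         apoB_100 = list(control = c(meanlog = log(100), sdlog = 0.25),
                         cancer  = c(meanlog = log(100), sdlog = 0.25)),
         CRP      = list(control = c(meanlog = log(3),   sdlog = 0.70),
                         cancer  = c(meanlog = log(15),  sdlog = 0.90)),
         CA19_9   = list(control = c(meanlog = log(10),  sdlog = 0.80),
                         cancer  = c(meanlog = log(60),  sdlog = 1.20)))
}

#' Simulate a clinical-marker cohort
#'
#' Draws per-sample values of the five immunoassay markers from per-class
#' log-normal distributions, for any number of sources. Default sizes
#' mirror the clinical arms of the study design (training source 33
#' controls / 70 cancers, validation source 19 controls / 20 cancers).
#'
#' @param seed integer seed.
#' @param sizes named list; each element \code{c(control = , cancer = )}.
#' @param marker_params as \code{\link{clinicalMarkerDefaults}}.
#' @return data.frame with columns \code{sample_id}, \code{source},
#'   \code{class} and the five markers (all values positive)
#' @export
simulateClinicalCohort <- function(seed = 1L,
                                   sizes = list(A = c(control = 33L, cancer = 70L),
                                                B = c(control = 19L, cancer = 20L)),
                                   marker_params = clinicalMarkerDefaults()) {
    for (mk in names(marker_params))
        for (k in names(marker_params[[mk]]))
            if (marker_params[[mk]][[k]][["sdlog"]] <= 0)
                stop("non-positive sdlog for marker ", mk, ", class ", k)
    set.seed(as.integer(seed))
    out <- do.call(rbind, lapply(names(sizes), function(s) {
        ns <- sizes[[s]]
        kls <- rep(c("control", "cancer"), ns[c("control", "cancer")])
        data.frame(sample_id = sprintf("%s_%s_%02d", s,
                                       ifelse(kls == "control", "ctl", "can"),
                                       unlist(lapply(ns[c("control", "cancer")],
                                                     seq_len))),
                   source = s, class = kls, stringsAsFactors = FALSE)
    }))
    for (mk in names(marker_params)) {
        v <- numeric(nrow(out))
        for (k in c("control", "cancer")) {
            i <- out$class == k
            pp <- marker_params[[mk]][[k]]
            v[i] <- rlnorm(sum(i), pp[["meanlog"]], pp[["sdlog"]])
        }
        out[[mk]] <- v
    }
    rownames(out) <- out$sample_id
    out
}
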