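---
title: "Cross-source serum peptidome classification: methods and design"
author: "SerumPeptidome package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-source serum peptidome classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SerumPeptidome)
```

# The problem

MALDI-TOF profiling of the serum peptidome — the pool of low-molecular-weight
peptides in blood serum — can separate cancer patients from cancer-free
controls within a single, carefully controlled cohort. The hard problem is
making such a signature survive a *change of biorepository*: serum collected
at a different site, in a different tube brand, from donors in a different
physiological state carries systematic, feature-specific intensity biases
that a raw-intensity classifier happily absorbs into its decision function
and that do not transfer. This package implements a complete, tested pipeline
for that setting:

1. **Spectrum preprocessing** — resampling, cross-correlation alignment,
   peak detection and windowed quantification into a replicate-level
   intensity matrix (`preprocessSpectra()`).
2. **Zero-aware replicate summarization** — readings of exactly 0 are
   treated as *missing*, not as measured zeros: replicate averages ignore
   them, and features that still contain zeros after averaging are dropped
   (`averageReplicates()`, `filterZeroFeatures()`).
3. **Control-decile normalization** — for every (source, feature) pair, nine
   thresholds fitted on the source's own control class map intensities to
   decile bins 1..10 (`fitQuantileMap()`, `applyQuantileMap()`).
4. **Filter-based feature selection** — Mann-Whitney p-value and intensity
   cutoffs, jointly optimized by exhaustive grid search against ten-fold
   cross-validated accuracy of a linear-margin classifier
   (`optimizeFilters()`).
5. **Classification and evaluation** — a linear-kernel soft-margin SVM
   (LIBSVM via e1071), evaluated by accuracy and the Matthews correlation
   coefficient, with label-permutation controls
   (`trainClassifier()`, `mcc()`, `permutationControl()`).
6. **Clinical decision rules** — a Gini decision tree on
   apoB-100-normalized apoC-I and apoC-III plus CRP and CA19-9
   (`trainRules()`, `evaluateRules()`).

A synthetic-data module (`generatorConfig()`, `simulatePeptidome()`,
`simulateClinicalCohort()`) reproduces the statistical structure of the
two-source design with known ground truth, so every stage can be tested
end to end without access to patient sera.

# Zeros are missing values

Linear-TOF MALDI instruments frequently report no signal for a peptide that
is present below the effective detection limit of a particular deposition.
The matrix therefore conflates "absent" with "missed". The pipeline keeps
this conflation deliberately — it is part of the method under test — and
handles it in two stages: per (sample, feature), the replicate average is
the mean of the *nonzero* readings (0 only if all readings are missing);
afterwards, any feature still showing a zero in at least one sample is
removed, because a margin classifier would otherwise exploit the missingness
pattern itself. The removal log records per-class zero counts with a
two-sided Fisher exact test so the absence of a class preference among
removed features can be audited; the test is reported, never used to filter.

# Control-decile normalization

For source $s$ and feature $f$, let $X_1 \le \dots \le X_9$ be the
$0.1,\dots,0.9$ quantiles of the *nonzero control-class* readings of $f$ in
$s$, computed with linear interpolation between order statistics
(position $h = (n-1)p + 1$; `stats::quantile` type 7). A nonzero reading
$x$ becomes

$$\mathrm{bin}(x) \;=\; 1 + \#\{i : X_i < x\} \;\in\; \{1,\dots,10\},$$

ties falling to the lower bin; zeros stay 0. Normalization runs at the
*replicate* level, before averaging, so averaged bins may be fractional.
Key properties, all asserted in the test suite:

* **Scale invariance.** Multiplying one source's intensities for a feature
  by any $c > 0$ leaves that source's bins unchanged — multiplicative
  source bias is removed exactly.
* **Monotonicity / trend preservation.** $x \le y \Rightarrow
  \mathrm{bin}(x) \le \mathrm{bin}(y)$ within a (source, feature), so a
  within-source class trend can never be inverted; a feature with opposite
  trends in two sources keeps them after normalization.
* **Self-calibration.** A source's own controls fill each bin with
  $n/10 \pm 2$ readings on tie-free data.

Design choices where the convention was genuinely open: thresholds are
fitted per feature (not on pooled intensities) because source bias is
feature-specific; fitting excludes zero readings, consistent with
zeros-as-missing; a control-only validation source is normalized by its own
map, which is well-defined precisely because the map needs only controls. A
(source, feature) pair with fewer than two nonzero control readings cannot
be fitted — it is flagged and passed through unnormalized with a warning.

# Feature selection and its optimization

Per feature, a two-sided Mann-Whitney U test compares controls with
cancers: exact null distribution for group sizes up to 8 without ties, a
tie-corrected normal approximation with continuity correction otherwise
(the exact path is cross-checked against brute-force enumeration of all
labelings in the tests). The intensity filter keeps a feature iff at least
one sample's averaged reading exceeds the cutoff — it removes features,
never samples; an alternative reading of that rule (mean-intensity) was
considered and rejected because the maximum is what guarantees "at least
one average reading above the cutoff". No multiple-testing correction is
applied: the cutoff itself is tuned against classification performance,
which is the method's own control for selection stringency.

`optimizeFilters()` evaluates every (p cutoff, intensity cutoff) pair on
the grid — defaults: 15 log-spaced p values on $[0.001, 0.1]$ and intensity
cutoffs $0, 50, \dots, 500$ — by stratified ten-fold CV of the classifier
on the selected features, then returns, among combinations within $10^{-12}$
of the best accuracy, the one selecting fewest features (ties: smaller p
cutoff, then larger intensity cutoff). Folds are fixed across combinations
and derived from a seed, so the search is deterministic. When intensities
are decile bins the intensity grid collapses to "disabled". Note that
features are selected on the same samples that are cross-validated —
faithful to the protocol under test — which is optimistically biased; the permutation control
(`permutationControl()`) exists to quantify exactly that bias, and the
test suite verifies that under a fully null configuration the shuffled and
unshuffled accuracy distributions are indistinguishable.

# Classification and evaluation

The classifier is a linear-kernel C-SVM (LIBSVM through e1071,
cost $C = 1$ by default, exposed in every entry point). Features are
standardized to training mean and unit variance before the fit — standard
LIBSVM practice — and the weights are folded back so the stored model is a
plain linear function $d(x) = w \cdot x + b$ of raw inputs. The class
encoding is $+1$ = control, $-1$ = cancer, so in the per-feature influence
probe $d(M_j e_j) - d(0) = w_j M_j$ (feature at its maximum observed value
against the all-zero vector), negative influence pushes toward cancer and
positive toward control.

Evaluation uses accuracy and the Matthews correlation coefficient
$$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},$$
with cancer as the positive class and the convention $\mathrm{MCC}=0$ when
a marginal factor vanishes. Cross-source experiments pool the validation
source's samples with the third source's controls (plus any held-out
cancers) into one confusion table; this pooling convention reproduces all
published worked examples in the acceptance suite to two decimals.

# The synthetic two-source design

`simulatePeptidome()` draws, for source $s$, sample $i$ of class $k$,
replicate $r$ and feature $f$,

$$\log I = \mu_f + b_{fs(i)} + \sigma_i\, e_{fs} \,[k=\mathrm{cancer}]
  + u_{if} + \epsilon_{ifr},$$

then zeroes each reading with probability
$1/(1+\exp(\beta(\log I - \log m)))$ — dropout concentrated at low
intensity. Defaults (all log-scale, all overridable):

* **Cohorts**: A = 21 controls / 22 cancers, B = 20 / 40, C = 12 controls
  only, 637 features, 2 replicates (3 available as an option; the
  replicate count of the motivating design is stated only as "two to
  three").
* **Baselines** $\mu_f \sim N(\log 500,\, 0.7)$; discriminative features
  get $+1.2$: signature peptides that are detectable in every sample of
  every cohort are fragments of abundant serum proteins (apolipoproteins,
  fibrinopeptide A, haptoglobin), and a trend planted on a peak that falls
  below the detection floor in one class would be eliminated by the zero
  filter rather than recovered.
* **Feature classes**: 5% concordant (same cancer-vs-control trend in A
  and B, effect $\pm 1.2$, direction up-in-control with probability 0.5),
  1.5% discordant, the rest null.
* **Discordant features** model peptides whose behaviour is dominated by
  pre-analytical (tube-brand) chemistry: opposite effect signs in A and B,
  with the second source's magnitude scaled by the cancer-cohort size
  ratio so the pooled mixed-set trend cancels (per-source magnitudes of a
  trend-reversing peak differ severalfold in real data too), plus a fixed
  $\pm 1$ log offset between A and B in overall level.
* **Source bias** $b_{fs}$: per-feature, s.d. 1.2 in A and B and 3.0 in C;
  C is additionally split into 3 acquisition batches with independent bias
  draws (its controls accumulate over separate collection dates) and its
  donors are non-fasting, modelled as a larger between-sample s.d. (1.8 vs
  0.7). These choices make the third source the kind of validation set the
  design is about: same biology, different measurement regime.
* **Noise**: between-sample biological s.d. 0.7; replicate CV 0.25;
  optional per-sample disease-severity multiplier (Gamma with mean 1,
  disabled by default) for cohorts spanning clinical stages.
* **Dropout**: midpoint 8 intensity units, steepness 2 — about 1% of
  readings zeroed overall, concentrated in faint peaks, removing roughly
  10% of features at the zero filter.

What the generator deliberately does **not** emulate: isotope envelopes and
adducts, detector saturation, correlated features (fragments of one
protein), drift within a run, and real cancer-stage structure. Passing
tests therefore demonstrate that the *pipeline's logic* behaves as designed
under the stated statistical structure — not that the signature itself
would validate in new patient sera.

`renderSpectra()` turns matrix rows back into continuous spectra (Gaussian
peaks on an exponentially decaying baseline plus additive noise) so that
resampling, alignment, peak detection and quantification can be tested
against known amplitudes; the suite requires ≥90% of planted peaks
recovered within half a grid step and intensities within 10% at SNR ≥ 10.

# Spectrum preprocessing defaults

The preprocessing constants are package decisions, not facts inherited
from any instrument protocol: linear interpolation onto a uniform 0.5 Da
grid; global alignment by integer-bin cross-correlation with a shift cap
(an error beyond 10% of the grid span guards pathological alignment);
rolling-median baseline over 50 Da; noise scale = MAD of the
baseline-subtracted signal; SNR threshold 5; greedy apex acceptance with a
5 Da separation window; quantification = windowed apex height above
baseline, with sub-floor values stored as 0 (the missing sentinel). Every
constant is an argument.

# Clinical decision rules

`deriveClinicalFeatures()` forms apoC-I/apoB-100 and apoC-III/apoB-100
(apoB-100 shows no disease trend and controls for overall lipoprotein
level) plus CRP and CA19-9. `trainRules()` grows a binary CART-style tree
by greedy best-split search under Gini impurity, with deterministic
tie-breaking (lowest feature index, then lowest threshold; candidate
thresholds are midpoints of consecutive observed values), maximum depth 4
and at least 5 records per leaf. The original analysis used a commercial
rule-induction tool that cannot be reproduced; the contribution being
tested is the four-feature panel and the cross-source train/validate
protocol, not the specific tree inducer. Records with a missing marker or
nonpositive apoB-100 are excluded and counted. The cohort generator's
marker distributions are log-normal with class-separated locations for
apoC-I, apoC-III (higher in controls), CRP and CA19-9 (higher in cancer)
and identical apoB-100, at clinically plausible scales (e.g. apoB-100
around 100 mg/dl, CA19-9 controls around 10 U/ml).

# Numerical and degenerate-input conventions

* Quantile convention: type 7 ($h = (n-1)p + 1$), for cross-implementation
  determinism.
* Bin ties go to the lower bin; prediction ties ($d = 0$) go to control.
* A constant feature gets Mann-Whitney $p = 1$; a constant pooled group
  comparison reports $p = 0.5$ with a flag; Kendall concordance on a
  constant vector is an error, not NA.
* A filter combination selecting zero features scores CV accuracy 0; no
  majority-class fallback.
* Duplicate integer m/z labels get ".1", ".2" suffixes.
* All file writers are deterministic: TSV, UTF-8, LF, 6 significant
  digits.

# Null calibration and the pooled test

With zero effect sizes *and* zero source bias, about 5% of features reach
$p < 0.05$ in the pooled two-source test and permuted labels reproduce the
unpermuted CV accuracy distribution — the no-leakage control. With source
bias present, the pooled Mann-Whitney test genuinely rejects in excess of
its nominal level even without any disease effect, because the sources
differ in both bias and class composition. That excess is not a pipeline
artifact: it is the cross-source confounding this whole design exists to
control, and the per-source decile normalization is the treatment.

# Problem sizes in the test suite

The statistical tests run at deliberately small scale: module tests use
120–200 features and single- or two-source designs of 20–40 samples per
class; the cross-source acceptance checks use the full default design
(637 features, 103 + 12 samples, 10 seeds); the preprocessing round-trip
uses 60–80 features over a reduced m/z range; permutation controls use 8
shuffles over reduced grids. These sizes keep the default suite fast while
leaving every statistical assertion comfortably powered.

# Known limitations

* The normalization requires enough nonzero control readings per
  (source, feature); sparse features pass through unnormalized and are
  flagged rather than imputed.
* Selection-then-CV reproduces the optimistic bias of the original
  protocol by design; the permutation control measures it but nothing
  corrects it.
* The unnormalized cross-source validation MCC on synthetic data has high
  seed-to-seed variance — with only 33 pooled validation samples a handful
  of flipped predictions moves the MCC by 0.1–0.2 — so the
  normalization-rescue margin is asserted on 10-seed medians.
* The decision-rule module fits shallow trees; it is a panel evaluator,
  not a general-purpose classifier.
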