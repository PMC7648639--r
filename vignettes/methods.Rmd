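---
title: "Methods: synthetic biofluid spectra and the discrimination pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic biofluid spectra and the discrimination pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`specdx` packages the chemometric workflow commonly applied to
attenuated-total-reflection FTIR spectra of biofluids in two-class
clinical studies: preprocessing, Kennard–Stone sample splitting, PCA and
wavenumber selection (SPA, GA) scored by a validation-set Mahalanobis
cost, discriminant classification (LDA/QDA/RBF-SVM) and confusion-matrix
figures of merit. This vignette documents the statistical model behind
each stage, the defaults and why they were chosen, the numerical
details, and the limits of what the synthetic-data experiments can show.

## The synthetic cohort model

Real case/control biofluid spectra are not generally deposited alongside
publications, so the package ships a generator whose output has the
statistical structure the pipeline assumes. A spectrum is a sum of
Gaussian absorbance bands plus nuisance terms:

$$A(\nu) = \sum_b m_b \, a_b \exp\!\left(-\frac{(\nu - c_b)^2}{2 w_b^2}\right)
          + \mathrm{baseline}(\nu) + \varepsilon(\nu)$$

* **Band library.** `default_band_library()` contains ten
  class-discriminating bands at 901, 1047, 1462, 1539, 1560, 1582,
  1645, 1661, 1693 and 1747 cm⁻¹ (water/glycogen and lipid/protein
  assignments typical of plasma) and ten non-discriminating envelope
  bands, including the Amide I anchor at 1650 cm⁻¹ which carries no
  class effect so that normalisation never divides out the signal of
  interest. Relative amplitudes follow the gross shape of a plasma
  infrared spectrum: the Amide I/II envelope dominates (amplitudes 1.0
  and 0.55 relative to Amide I), carbohydrate and phosphate bands are
  an order of magnitude weaker. This skewed amplitude structure, with
  heavily overlapping amide components, is what makes the spectra
  band-dominated and low-rank — the property the 90%-in-3-components
  parsimony rule relies on.
* **Class effect.** For a "case" subject every discriminating band's
  amplitude is scaled by `1 + class_effect` (default magnitude 0.15,
  mixed signs). 0.15 was chosen as a *strong* effect: about three times
  the between-subject coefficient of variation, so that the headline
  configuration is cleanly separable after preprocessing.
* **Variability.** Per subject, each band multiplier gets an
  independent relative Gaussian perturbation (`subject_sd = 0.05`, a
  realistic between-person biochemical CV); each replicate spectrum
  scales the whole profile by `1 + N(0, replicate_sd)` with
  `replicate_sd = 0.02`, emulating aliquot/contact-pressure variation
  (a scalar because pressure affects the whole spectrum, and it is
  exactly what Amide-I normalisation removes); additive white noise
  (`noise_sd = 0.002` absorbance units, i.e. instrument-level) and a
  random degree-3 polynomial baseline (`baseline_scale = 0.02`) mimic
  detector noise and ATR drift.
* **Design.** Defaults are 50 subjects per class × 3 replicates = 300
  spectra on a 600–4000 cm⁻¹ axis with 4 cm⁻¹ spacing (851 points).
  The grid spacing equals the nominal spectral resolution; the true
  interferogram point spacing of any given instrument may differ, but
  nothing downstream depends on it.

Generation is a pure function of the configuration, including its seed.

What the generator does **not** emulate: water-vapour and CO₂ lines,
wavelength-dependent ATR penetration depth, Mie scattering, and
correlated (rather than independent) between-subject band variation.
Consequently, passing tests demonstrate the pipeline's correctness and
calibration under a plausible variance model — not clinical performance
on real plasma.

## Preprocessing

Fixed order: cut → Savitzky–Golay → AWLS baseline → Amide-I
normalisation → (after splitting) mean-centring.

* **Cut**: closed interval 900–1800 cm⁻¹ (226 points on the default
  grid).
* **Savitzky–Golay**: 15-point window, order 2, via `signal::sgolayfilt`.
  Output length equals input length; edges use the standard off-centre
  polynomial fits, so any polynomial of degree ≤ 2 is reproduced to
  machine precision everywhere (asserted to < 1e-9 in tests).
* **AWLS**: iterative asymmetric reweighted polynomial fit (degree 4).
  Weights start at 1; after each fit, points with positive residual
  $r$ are down-weighted to $\exp(-r/s)$, $s$ the standard deviation of
  the positive residuals, so peaks stop attracting the baseline while
  points below keep full weight. Iteration ends when the baseline
  changes by < 1e-6 in relative L2 norm or after 50 iterations (then a
  warning, not an error — a slightly unconverged baseline is a quality
  signal, not a failure). A pure degree-≤4 polynomial input is
  annihilated to < 1e-8; adding a constant to a spectrum does not
  change the corrected result.
* **Normalisation**: each spectrum is divided by its *maximum* in
  1650 ± 10 cm⁻¹ rather than the value at exactly 1650 cm⁻¹ — robust to
  the Amide I peak sitting one or two grid points off the nominal
  position. After division the window maximum is exactly 1, and the
  operation is idempotent.
* **Mean-centring** is computed on the training subset only and applied
  to validation/test with the training means. Centring before the split
  would leak held-out information into every spectrum; the cost of this
  choice is that the centring constant is itself an estimate.

## Splitting

Kennard–Stone (max–min Euclidean selection, deterministic, ties to the
lowest row index) is run separately within each class so all three
subsets stay class-balanced; the first ⌈0.70 n⌉ ranked units go to
training, the next ⌈0.15 n⌉ to validation, the rest to test. Because KS
selects extremes first, the training set contains each class's convex
extremes by construction.

Two unit modes exist because replicate spectra are not independent:

* `"spectrum"` (default): each spectrum is a unit. Replicates of one
  subject can then straddle training and test. This matches the common
  practice of splitting "the pre-processed spectra", and with 300
  spectra gives the familiar 210/46/44 partition.
* `"sample"`: units are subjects (per-subject mean spectra drive KS),
  so no subject straddles subsets.

The difference matters: in spectrum mode a classifier can recognise a
test spectrum's *subject* from its training replicates, and since
subject determines class, even a null cohort (no class effect) yields
above-chance test accuracy. The package treats this as a documented
property of spectrum mode (there is a test demonstrating it), and runs
its null-calibration study in sample mode with subject-level
majority-vote evaluation, where all nine pipeline variants are
chance-level — the calibration guard targets leakage introduced by the
pipeline machinery, not the study-design choice of sharing subjects.

## PCA

SVD-based, fitted on training spectra only; validation/test are
projected. Loadings are orthonormal, ordered by variance, with each
loading's largest-magnitude element made positive so results are
reproducible. The number of components fed to the classifiers is the
smallest k whose cumulative explained variance exceeds 0.90 — the rule,
not a hard-coded 3, although on the default cohort the rule yields 3.

## The validation cost G and variable selection

For a validation object $x_n$ of class $I(n)$,

$$g_n = \frac{r^2(x_n, m_{I(n)})}{\min_{I(m) \ne I(n)} r^2(x_n, m_{I(m)})},
\qquad G = \frac{1}{N_V}\sum_n g_n,$$

with $r^2$ the squared Mahalanobis distance using class centres and the
pooled covariance estimated from the *training* rows restricted to the
candidate wavenumbers. $G$ is scale-invariant (any per-column affine
map applied to training and validation together leaves it unchanged)
and equals 0 when every validation object sits on its own class centre;
an object exactly on a wrong-class centre yields $g_n = \infty$, which
propagates rather than being masked.

* **SPA** builds, from every candidate start column, a chain in which
  each next variable maximises its residual norm after orthogonal
  projection off the span of the chain (computed on training data —
  i.e. the least collinear remaining variable), then scores every
  (start, length ≤ `max_vars`) prefix with G and returns the global
  minimum. Deterministic; exactly-collinear columns have zero residual
  norm and can never enter a chain.
* **GA** uses binary chromosomes over the 226 wavenumbers, population
  200, 100 generations, roulette-wheel selection on fitness
  $1/(G + 10^{-12})$, one-point crossover with probability 0.60,
  bitwise mutation, repair into 2–30 selected variables, and elitism 1
  (the best-so-far chromosome is reinjected, so best-so-far G is
  non-increasing — asserted per run). "Mutation probability 0.10" is
  ambiguous between per-bit and per-chromosome readings; the default
  flips each bit with probability 0.10/L so that roughly 10% of
  chromosomes mutate per generation, and `mutation = "per_bit"`
  exposes the literal per-bit reading. The subset-size cap of 30 keeps
  the pooled covariance comfortably invertible with ~100 training
  spectra per class.

**Numerical details.** Pooled covariances whose eigenvalue condition
number exceeds 1e10 (or that are not positive definite) receive a ridge
of $10^{-6}\,\mathrm{tr}(S)/p$ on the diagonal. Inside the two search
algorithms, a candidate subset whose covariance is degenerate beyond
repair (e.g. all-constant columns) scores $G = \infty$ and is simply
never selected; the user-facing `cost_G()` raises an error instead,
because there a singular covariance indicates a modelling mistake.

## Classifiers

* **LDA/QDA** assign the class minimising
  $d^2(x, m_k) - 2\log \pi_k$ (pooled covariance) or
  $d^2(x, m_k; S_k) + \log\det S_k - 2\log \pi_k$ (per-class), i.e. QDA
  is the full Gaussian discriminant rather than a bare distance rule.
  Priors default to equal (the cohort is balanced). Exact criterion
  ties go to the lexicographically first class label. For two classes
  the difference of the criteria is returned as a scalar discriminant
  score (positive = "case") for score plots.
* **RBF-SVM** (via `e1071`, libsvm) is trained on every (C, γ) pair
  with C ∈ 2^{-5..15}, γ ∈ 2^{-15..3} in powers of 4, the pair with the
  best validation accuracy selected (ties to smaller C, then smaller
  γ), and refitted on training data. Features are already normalised
  and centred, so libsvm's internal rescaling is disabled.

The test subset enters exactly once, at final evaluation. Metrics are
always recomputed from the stored confusion counts; spectra are the
default evaluation unit with subject-level majority voting available.

## Problem sizes used by the test-suite studies

These are the package's chosen experiment sizes for its own validation
studies: oracle-equivalence checks use 100 random instances per
primitive (5–12 observations, 2–5 variables); the null-calibration
study uses 20 subjects per class, 10 seeds, sample-mode splits and a
GA scaled to 25 generations × 40 chromosomes (the null property —
chance-level accuracy — does not depend on search effort); the
marker-recovery study uses 25 subjects per class with the full default
GA over 20 seeds; the headline run uses the full default cohort and GA.

## Known limitations

* **Minimising G does not reward marker completeness.** For a
  validation object, $g_n$ behaves like
  $p / (p + \sum_b \delta_b^2)$, where $p$ is the subset size and
  $\delta_b^2$ the per-variable class separation: adding a redundant
  marker of equal strength leaves the ratio essentially unchanged,
  while finite-sample covariance noise actively favours small subsets.
  Measured on a four-marker synthetic cohort, the G of the
  four-band-centre subset is statistically indistinguishable from that
  of the best two-band pair, and the GA legitimately returns compact
  subsets (often 2–6 variables) that omit planted bands, or sit on a
  band's shoulder rather than its centre (under multiplicative band
  noise all points within a band carry nearly identical information).
  A complete-marker-recovery expectation for a correctly minimising GA
  is therefore not attainable on such data, and the corresponding
  recovery test documents this as an expected failure. Selected
  wavenumber lists from G-minimising searches should be read as *a*
  sufficient discriminating subset, not as *the* set of affected bands.
* Chromosome-level GA behaviour (selection operator, subset bounds,
  repair) is conventional but not uniquely determined by the usual
  one-line descriptions in applied papers; all of it is configurable.
* Spectrum-mode splitting shares subjects across subsets; use sample
  mode whenever replicate leakage would compromise the question being
  asked (see the splitting section).
* The synthetic generator's independent per-band subject variability is
  a simplification; real biofluid spectra show correlated biochemical
  variation, which would concentrate even more variance in the leading
  principal components.
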