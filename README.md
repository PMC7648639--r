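# specdx — chemometric discrimination of biofluid ATR-FTIR spectra

`specdx` implements the complete chemometric pipeline used in clinical
infrared spectral-fingerprinting studies, where mid-infrared absorbance
spectra of a biofluid (for example blood plasma from case and control
subjects) are preprocessed, split, reduced to informative features and
classified, with accuracy, sensitivity and specificity reported on an
untouched test set. It is aimed at spectroscopists and chemometricians
who want a reproducible, scriptable version of this workflow — including
a synthetic cohort generator that emulates a case/control plasma study
design, so every stage can be exercised and validated without
instrument data.

## The pipeline

Given an absorbance matrix **X** (spectra × wavenumbers):

1. **Preprocessing** — cut to the 1800–900 cm⁻¹ biofingerprint region;
   Savitzky–Golay smoothing (15-point window, 2nd-order polynomial);
   automatic weighted least-squares (AWLS) baseline correction;
   normalisation to the Amide I band (1650 ± 10 cm⁻¹); training-set
   mean-centring.
2. **Splitting** — Kennard–Stone max–min selection, per class, into
   training (70%), validation (15%) and test (15%) sets, by spectrum or
   by subject.
3. **Feature extraction/selection** —
   * PCA: **X** = **TP**ᵀ + **E**, keeping the smallest number of
     components whose cumulative explained variance exceeds 90%;
   * SPA (successive projections algorithm): forward chains of
     minimally collinear wavenumber columns;
   * GA (genetic algorithm): binary chromosomes over wavenumbers,
     100 generations × 200 chromosomes, crossover 0.60, mutation 0.10.

   SPA and GA subsets are scored by the validation cost function

   G = (1/N_V) Σₙ gₙ,  gₙ = r²(xₙ, m_I(n)) / min_{m ≠ I(n)} r²(xₙ, m_I(m)),

   the mean over validation objects of the ratio of the squared
   Mahalanobis distance to the object's own class centre over the
   distance to the closest wrong-class centre (training-estimated
   centres and pooled covariance); smaller is better.
4. **Classification** — LDA (pooled covariance), QDA (per-class
   covariances) and an RBF-kernel SVM tuned on the validation set.
5. **Figures of merit** — from test-set TP/TN/FP/FN counts:
   AC = (TP+TN)/(TP+FP+TN+FN) × 100, SENS = TP/(TP+FN) × 100,
   SPEC = TN/(TN+FP) × 100.

## Worked example

```r
library(specdx)
report <- run_pipeline(cohort = cohort_config(seed = 1), seed = 1)
print(report)
```

```
<pipeline_report> test-set figures of merit (%):
 feature_method classifier n_features accuracy sensitivity specificity
            PCA        LDA          3    100.0       100.0       100.0
            PCA        QDA          3    100.0       100.0       100.0
            PCA        SVM          3    100.0       100.0       100.0
            SPA        LDA          1     95.5        95.5        95.5
            SPA        QDA          1     95.5        95.5        95.5
            SPA        SVM          1     95.5        95.5        95.5
             GA        LDA          5    100.0       100.0       100.0
             GA        QDA          5    100.0       100.0       100.0
             GA        SVM          5     97.7        95.5       100.0
```

With no dataset supplied, `run_pipeline()` simulates the default
synthetic cohort: 50 case and 50 control subjects, three replicate
spectra each (300 spectra), 600–4000 cm⁻¹ on a 4 cm⁻¹ grid, with a 15%
fractional class effect planted on ten marker bands (901–1747 cm⁻¹).
Each row is one feature-method × classifier variant evaluated on the
44 held-out test spectra; the GA-LDA row reaches 100% accuracy,
sensitivity and specificity because the planted effect is strong enough
to be fully separable after preprocessing. The fitted PCA model for the
same run explains 67.2 + 22.7 + 2.4 ≈ 92% of the training variance in
three components:

```r
report$pca
#> <spectra_pca> k = 226 | leading explained variance (%): 67.21, 22.69, 2.35
report$subsets$ga
#> <variable_subset> GA: 5 variables, G = 0.0865822
#>   wavenumbers (cm^-1): 1184, 1524, 1572, 1676, 1772
```

`run_pipeline(..., out_dir = "out")` additionally writes `report.json`,
a markdown results table, the selected wavenumbers and the PCA-scores /
discriminant-score plots. A thin command-line wrapper is installed at
`inst/cli/specdx` (`specdx simulate | preprocess | run`).

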