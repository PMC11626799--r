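# mirblood

Blood metabolic profiling of transition-period dairy cows is informative but
invasive and expensive, so it cannot be run herd-wide. Milk, however, is
sampled routinely, and its Fourier-transform mid-infrared (FT-MIR) spectrum
— 1,060 transmittance points between 5,000 and 900 cm⁻¹ — partially mirrors
the cow's blood chemistry. `mirblood` implements the two analyses this
setting calls for, end to end:

1. **Phenotypic variance of plasma traits.** After 3-SD editing and log₁₀
   transformation of the right-skewed traits (BHB, NEFA, AST, GGT, CK,
   cortisol), each blood trait *y* is modelled as

   *y* = μ + Pᵢ + Dₗ + (P×D)ᵢₗ + Mₖ + Hₘ + e,

   with parity class (1, 2, ≥3), days-in-milk class (3–8, 9–14, 15–20,
   21–38), their interaction and sampling season (May–Jun, Jul–Aug,
   Sep–Oct) fixed, herd random with Hₘ ~ N(0, σ²_H) and e ~ N(0, σ²_e).
   The fit is REML by profiling λ = σ²_H/σ²_e; least-squares means carry
   Bonferroni-grouped letters and are back-transformed (10^LSM) for log
   traits. Total bilirubin is binarized at 4 μmol/L and modelled by
   logistic regression with Wald 95% CIs on the odds ratios. Spearman
   correlations link plasma and milk traits.

2. **FT-MIR prediction and risk classification.** Spectra are converted to
   absorbance (A = log₁₀(1/T)), restricted to the three windows outside the
   water-absorption regions (945.5–1,585.6, 1,716.8–1,929.0,
   2,507.7–2,970.7 cm⁻¹), screened for anomalous samples by a PCA score
   rule, and scatter-corrected by the standard normal variate (SNV).
   Blood traits are predicted by NIPALS partial least squares with the
   component count tuned by leave-one-out cross-validation (capped at 20),
   a single-pass 3-SD residual-outlier filter, and a stratified 70/30
   external validation iterated 3 times (averaged R²/RMSE). PLS-DA against
   the published risk thresholds (blood BHB > 1.2 mmol/L, NEFA > 0.7
   mmol/L, BILT > 4 μmol/L) yields sensitivity, specificity, PPV, NPV and
   balanced accuracy = (sensitivity + specificity)/2.

Because herd datasets of this kind are not public, the package includes a
synthetic generator: a Gaussian copula reproduces the published
blood–blood and blood–milk rank correlations over the published marginal
means/SDs, with a herd-shared variance fraction, and spectra are built by
Beer–Lambert-style linear mixing of analyte signatures plus multiplicative
scatter and water-region noise. Every stage of the pipeline is therefore
testable offline.

## Worked example

```r
library(mirblood)

cfg <- synth_config(seed = 11)          # 14 herds, 349 cows, 3-38 DIM
records <- generate_records(cfg)
spectra <- generate_spectra(records, cfg)

sp <- transmittance_to_absorbance(spectra)
sp <- mask_water_regions(sp)            # message: retained 340 of 1060
sp <- snv(sp)

fs <- external_validation(sp, records, "blood_urea", n_iter = 3)
round(c(r2_cv = fs$r2_cv, r2_val = fs$r2_val, n_lv = fs$n_lv), 2)
#>  r2_cv r2_val   n_lv
#>   0.93   0.91   5.00
classify_r2_band(fs$r2_val)
#> [1] "punctual"
```

The synthetic urea trait is recovered with R² ≈ 0.91 in external
validation using about 5 latent variables: on this generator urea is the
most spectrally visible blood trait, and the banding function translates
the R² into its conventional interpretation (here sufficient for
per-sample prediction; real milk spectra are far less kind — see the
methods vignette for what the generator does and does not emulate).

The same objects drive the full report workflows:

```r
run_phenovariance(records, "out/pheno")        # LSM, F-tests, ORs, correlations
run_mir_prediction(records, spectra, "out/mir") # PLS + PLS-DA report tables
```

A thin command-line wrapper with verbs `synth`, `pheno`, `predict` and
`classify` is installed at `inst/scripts/mirblood`.

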