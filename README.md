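# plateqc

Statistical quality control and readout quantification for plate-based
high-throughput screening (HTS) assays.

Before screening an enzyme or compound library, the assay itself must
be qualified: a 96-well plate is filled half with positive controls
(the readout a full conversion would give, e.g. 2 mM HCl for a
pH-indicator assay) and half with negative controls (plain buffer),
giving 44–48 replicates per group. `plateqc` turns those two readout
distributions into the standard quality panel, classifies the assay,
ranks competing assays, and carries the winning assay's kinetic
readouts through to enzymology.

With group means μ, sample standard deviations σ, medians m and sizes
n (subscripts: positive/negative controls), the panel comprises

- **Z'-factor**: `Z' = 1 − 3(σ_pos + σ_neg) / |μ_pos − μ_neg|`
- **SSMD** `(μ_pos − μ_neg) / √(σ_pos² + σ_neg²)` as three estimators:
  method-of-moments, maximum-likelihood (`(n−1)/n` variances) and a
  robust median/MAD form with `MAD = 1.4826 · m(|x_i − m|)`
- **Welch's t** (statistic, Satterthwaite df, two-sided p)
- **Kolmogorov–Smirnov statistic** `D = max |F_pos − F_neg|`
- **S/B** `μ_pos/μ_neg`, **S/N** `(μ_pos − μ_neg)/σ_neg`, per-group
  **CV** `σ/μ`

plus the accepted performance bands (Z': ≥ 0.8 excellent, ≥ 0.5 good,
\> 0 weak, else yes/no; SSMD ≥ 3 excellent; t: null rejected at α) and
a best-to-worst ranking matrix across assays. The quantification
chain covers luminescence time-series summaries (mean, trapezoidal
integral), linear absorbance↔concentration calibration, initial-rate
fitting, specific activity (µmol·min⁻¹·mg⁻¹) and turnover number
(`kcat [s⁻¹] = specific activity × MW [kDa] / (60 × sites)`). A
seeded simulator generates half-plate control experiments (with
optional outlier contamination), decaying luminescence traces and
enzymatic progress curves, so the whole pipeline runs without
instrument data.

## Worked example

Evaluate the synthetic demonstration plate shipped with the package
(rows A–D positive, E–H negative):

```r
library(plateqc)

grid  <- system.file("extdata", "plate_grid_synthetic.csv", package = "plateqc")
roles <- setNames(rep(c("positive", "negative"), each = 48), well_labels())
panel <- metric_panel(extract_controls(read_plate_grid(grid, roles)))
panel
#> quality-metric panel (n_pos = 48, n_neg = 48)
#>  metric      value
#>  z_prime      7.417e-01
#>  ssmd_mm      1.637e+01
#>  ssmd_mle     1.654e+01
#>  ssmd_robust  1.721e+01
#>  t_stat       1.134e+02
#>  t_pvalue    4.148e-100
#>  ks_stat      1.000e+00
#>  sb_ratio     9.803e+00
#>  sn_ratio     2.141e+01
#>  cv_pos       3.537e-02
#>  cv_neg       4.112e-01
classify_panel(panel)$z_prime
#> z_prime = 0.7417 -> good
```

Z' of 0.74 sits in the "good" band: the 3-sigma envelopes of the two
control groups stay clearly apart, but not by the 0.8 margin of an
excellent assay. All three SSMDs are far above the excellence
threshold of 3, KS is saturated at 1 (fully disjoint control
distributions), and S/B ≈ 9.8 beats the > 3 rule of thumb.

Quantify a progress curve through a calibration line (0–2 mM HCl at
620 nm; synthetic points):

```r
cal <- fit_calibration(read_calibration_csv(system.file("extdata",
  "calibration_620nm_synthetic.csv", package = "plateqc")))
cal
#> linear calibration: absorbance = 0.900769 -0.298913 * conc_mM (r = -0.9997, n = 27)

sim <- simulate_progress_curve(kinetic_spec(0.1, calibration = cal,
                                            dt_min = 0.1, seed = 4))
quantify_activity(sim$absorbance, cal, volume_L = 200e-6,
                  enzyme_mass_mg = 0.01, mw_kDa = 29, window = 5)
#> initial rate 0.09901 mM/min (r^2 1.0000); specific activity 1.98 umol/min/mg; turnover 0.9571 1/s
```

The true simulated rate is 0.1 mM/min; the 5-point initial window
recovers it to 1% and converts it — for 10 µg of a 29 kDa hydrolase in
200 µL — to a turnover number of about 0.96 s⁻¹.

## Command line

An installed launcher wraps the same functions:

```sh
plateqc simulate --out plate.csv --seed 1 --assay-id demo
plateqc evaluate plate.csv --out report.json
plateqc calibrate --points points.csv --out cal.json
plateqc quantify --kinetics trace.csv --calibration cal.json \
        --enzyme-mass 0.01 --mw 29 --out activity.csv
```

Logs go to stderr, data only to `--out`; exit codes are 0 (success),
2 (input error), 3 (computation error).

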