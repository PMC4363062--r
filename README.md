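# ankledose

Organ and effective dose analysis for extremity x-ray imaging from
point-dosimeter measurements in a layered anthropomorphic phantom.

Medical physicists comparing ankle imaging protocols (multi-slice CT,
cone-beam CT, plain radiography) need the ICRP-103 effective dose, but only
a small, non-uniformly irradiated slice of each organ sits in the scanned
region. This package implements the point-dosimetry route: twenty MOSFET
dosimeters at known layers and depths, repeated exposures per protocol, and
the aggregation

- equivalent dose per tissue: *H_T = w_R · Σᵢ fᵢ · Dᵢ*, where *Dᵢ* are mean
  point doses (mGy), *fᵢ* the fractions irradiated (the share of the
  whole-body organ inside the exposed region) and *w_R = 1* Sv/Gy for
  x-rays;
- effective dose: *E = Σ_T w_T · H_T* with the ICRP-103 tissue weights,
  muscle and lymphatic nodes entering as remainder organs at
  *w_remainder / 13* each;

plus the full measurement-uncertainty budget: type-A (1SD of repeated
exposures), combined point uncertainty in quadrature with systematics
(phantom positioning 10%, dosimeter positioning 10%, source variation 5%,
cable irradiation 1%), tissue-level propagation including the 25%
fraction-irradiated uncertainty, and the expanded (k = 2) effective-dose
uncertainty. Helpers derive fractions irradiated (Du Bois body surface
area, skin-area and regional marrow compositions), and a seeded synthetic
generator produces complete studies — dose field, noisy readings, ground
truth — for end-to-end validation.

## Worked example

The package bundles a reference ankle study: twenty mean doses (six
exposures each) from a small-FOV high-resolution CBCT scan, together with
the default phantom, fraction and ICRP-103 weight configurations.

```r
library(ankledose)

est <- ankle_study_doses()           # dosimeter_no, mean_dose (mGy), rel_sd (%), n
ed  <- compute_effective_dose(est, default_ankle_phantom(),
                              default_ankle_fractions(), default_icrp_weights())
print(ed)
#>           tissue contribution_uSv pct
#>      bone_marrow              4.2  28
#>     bone_surface              7.4  51
#>             skin              2.2  15
#>           muscle              0.1   1
#>  lymphatic_nodes              0.8   5
#> effective dose: 14.6 uSv
```

Bone surface dominates (the two calcaneal-tuberosity sites each carry 4.9%
of the whole-body bone surface), followed by red marrow; skin contributes
2.2 μSv from its two sites; the remainder organs are minor. The budget:

```r
b <- uncertainty_budget(est, default_ankle_phantom(),
                        default_ankle_fractions(), default_icrp_weights())
round_half_up(b$expanded_pct)        # expanded (k=2) uncertainty: 30 (%)
```

Fold comparisons between protocols follow a stated display rule:

```r
dose_ratio(21.4, 1.5)$display        # MSCT vs AP+LAT radiography: "14-fold"
```

## Analysis workflow

The `analysis/` directory re-runs the complete study as numbered drivers
over the package functions, writing tables under `results/`:

1. `01_effective_dose.R` — effective dose and per-tissue report of the
   bundled CBCT study;
2. `02_uncertainty_budget.R` — per-dosimeter, per-tissue and expanded
   uncertainties;
3. `03_device_comparison.R` — internal consistency of the published
   six-protocol table and fold ratios versus plain radiography;
4. `04_synthetic_recovery.R` — 200-seed recovery study on synthetic data
   with known truth.

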