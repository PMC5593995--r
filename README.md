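# mipscsf

Analysis pipeline linking cerebrospinal-fluid (CSF) volume loss to magnetic
induction phase shift (MIPS) during intracerebral hematoma expansion.

MIPS is a non-contact monitoring technique: the phase lag of a
radio-frequency field through the head tracks the conductivity distribution
between an excitation and a sensor coil. CSF is the most conductive
intracranial tissue, and during early hematoma expansion the Monro–Kellie
compensation mechanism displaces CSF while intracranial pressure is still
stable — so the MIPS signal moves first. This package is for researchers
working with induction-based brain monitoring or with the constant-rate
blood-injection ICH model (3 ml over 54 min, observations every 6 min) who
want the full quantitative chain from raw signals and MR volumes to the
statistical summary:

* **Signal conditioning** — raw phase recordings (2700 samples / 54 min)
  block-averaged in 300-sample blocks and normalized to a pre-injection
  baseline (`block_smooth()`, `normalize_series()`).
* **CSF volumetry** — fuzzy c-means segmentation with a Markov-random-field
  (Potts/ICM) spatial prior on T2-like volumes, brightest-class selection,
  template masking and voxel volumetry (`segment_csf()`). The core update
  minimizes
  `J = Σᵢ Σₖ uᵢₖᵐ (xᵢ − vₖ)² + β Σᵢ Σₖ uᵢₖᵐ nᵢ^{≠k}`
  with per-voxel memberships summing to one.
* **Synchronization & statistics** — MIPS and CSF series aligned on injected
  blood volume; multiple regression with ANOVA, partial correlations
  `r_xy·z = (r_xy − r_xz r_yz) / √((1−r_xz²)(1−r_yz²))`, derivative-curve
  correlation, and reversal-point detection (`build_report()`,
  `detect_reversal()`).
* **Synthetic data** — seeded generators for compensation trajectories
  (piecewise-linear with one breakpoint), raw MIPS recordings (linear
  compartment response plus respiration/cardiac contamination) and MR
  phantoms with exact ground truth (`generate_cohort()`,
  `generate_phantom()`).

The published Tables of the eight-rabbit experiment (normalized MIPS and
quantified CSF volume, 8 animals × 9 time points) ship as packaged,
checksummed fixtures.

## Worked example

Recompute the published statistics from the packaged cohort tables:

```r
library(mipscsf)
rep <- reproduce_tables()
#> Computed vs published statistics (eight-rabbit cohort, n = 9 means)
#>                     statistic computed published
#>                             R 0.824290   0.82400
#>                     R squared 0.679460   0.68000
#>            adjusted R squared 0.572610   0.57300
#>                SE of estimate 0.339000   0.33882
#>                             F 6.359100   6.36900
#>                          Sig. 0.032936   0.03300
#>  partial r (MIPS,CSF | blood) 0.791510   0.79200
#>  partial r (MIPS,blood | CSF) 0.747740   0.74800
#>      derivative correlation r 0.458370   0.75100
#>  ...
```

Reading the output: the multiple correlation of mean MIPS with mean CSF and
injected blood is R = 0.824 (significant at 0.033), and MIPS correlates
more strongly with CSF (partial r = 0.792, controlling blood) than with
blood (0.748, controlling CSF) — CSF is the leading factor on the signal
before compensation fails. Two printed values differ knowingly: F is 6.359
from the printed (rounded) table data, and the derivative-curve correlation
is 0.458 at the default degree-4 convention; the published 0.751 is not
recoverable from the printed nine-point tables under any fitting convention
(see the methods vignette).

Simulate one animal and find its reversal point:

```r
sch    <- injection_schedule()                    # 3 ml over 54 min
csf    <- simulate_csf_compensation(compensation_params(), sch, seed = 42)
raw    <- simulate_mips(mips_params(), csf, sch, seed = 42)   # 2700 samples
blocks <- normalize_series(block_smooth(raw), pre_injection_baseline(raw))
round(blocks$value, 3)
#> [1] 99.747 99.248 98.760 98.267 97.767 97.289 97.140 97.384 97.614
detect_reversal(blocks)
#> Reversal at 2.33 ml injected blood (series argmin; derivative zero crossing at 2.397 ml)
#> Derivative maximum at index 7; reversal section: 8-8
```

The series falls while CSF compensates, reverses near the planted
compensation-failure point (2.0 ml blood), then rises as blood becomes the
dominant conductor.

Segment a phantom and quantify its CSF:

```r
ph  <- generate_phantom(phantom_spec(), csf_volume = 0.8, blood_volume = 1.0)
tpl <- generate_template(phantom_spec(), dilation_mm = 1)
segment_csf(ph$volume, tpl)
#> CSF volume: 0.7906 ml (5434 voxels of 0.1455 mm3)
```

A thin command-line wrapper ships in `inst/exec/mipscsf`
(`simulate`, `smooth`, `reversal`, `segment`, `quantify`, `analyze`,
`reproduce-tables`).

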