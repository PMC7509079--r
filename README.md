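# cordbsi

Measuring longitudinal spinal cord atrophy from paired MRI volumes.

Spinal cord atrophy runs at roughly 1–2 %/year in progressive multiple
sclerosis and is a candidate trial outcome — but the change at the cord
boundary over one year is a small fraction of a voxel, so *how* it is
measured decides whether a trial is feasible. `cordbsi` implements the two
competing measurement families end to end:

* **CSA** (segmentation-based): straighten the cord, average the
  cross-sectional area over a level window at each timepoint independently,
  and report `100·(CSA_w48 − CSA_bl)/CSA_bl`;
* **GBSI** (registration-based generalised boundary-shift integral):
  straighten both timepoints, register them with a symmetric
  inverse-consistent 9-DOF affine (translation, rotation, shear — no scale,
  which would absorb the atrophy signal) into the halfway space, estimate a
  probabilistic boundary-shift region from both masks, and convert the
  windowed intensity change integrated over that region into a percent
  volume change:

  `ΔV = voxvol/(I_high − I_low) · Σ w(x)·(clip(I_bl(x)) − clip(I_w48(x)))`,
  reported as `−100·ΔV/V_bl`, annualized over the actual scan interval.

Around the two estimators the package provides the full study toolchain: a
CSF-ring noise-floor estimator with Rayleigh-background correction
(`σ = σ_η/√(2−π/2)`) and median-split scan classification; the conjunctive
±5 %/year implausibility filter; two-arm sample-size calculators
(`n = ⌈2(z_{1−α/2}+z_{power})²σ²/Δ²⌉`) with CoV/MAD summaries and a
Monte-Carlo power verifier; EDSS and 20%-worsening progression rules with
covariate-adjusted cohort models and backward elimination; and a synthetic
longitudinal cord phantom generator (curved tube in a CSF ring, known
atrophy fraction, Rician noise) that gives every stage a ground truth.

## Worked example

Generate a phantom pair with 2% true volume loss over one year, then
measure it both ways:

```r
library(cordbsi)

spec <- phantom_spec(atrophy = 0.02, sigma = 0)   # noiseless
pair <- make_phantom_pair(spec)
pair$truth$percent_change
#> [1] -2.012432

m <- measure_atrophy(pair$baseline, pair$followup, interval = 365.25)
m
#> CSA : -2.014 %/year (63.65 -> 62.36 mm^2)
#> GBSI: -1.990 %/year
```

Both branches recover the constructed −2% loss: CSA from the straightened
mask areas (63.65 mm² ≈ π·4.5², the tube cross-section), GBSI from the
boundary-shift integral after registration. With noise at one twentieth of
the cord/CSF contrast the two branches separate — that is the point of the
comparison:

```r
co <- simulate_atrophy_cohort(10, phantom_spec(atrophy = 0.02, sigma = 20,
                                               seed = 100))
c(sd_csa = sd(co$csa_pct), sd_gbsi = sd(co$gbsi_pct))
#>     sd_csa    sd_gbsi
#> 0.40767571 0.06923071
```

Trial-design side, from an atrophy-rate summary of −0.9 ± 3.1 %/year:

```r
effect_grid(-0.9, 3.1)
#>   effect n_per_arm
#> 1    0.3      2070
#> 2    0.6       518
#> 3    0.9       230
```

A thin CLI (`exec/cordbsi`) exposes the same operations for shell use:
`cordbsi phantom`, `cordbsi gbsi`, `cordbsi noise`, `cordbsi qc`,
`cordbsi samplesize`, and friends; NIfTI in, JSON/CSV out.

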