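# mtcalf

Magnetization transfer contrast (MTC) mapping and cohort statistics for
skeletal muscle MRI.

## The problem

Macromolecules (myofibrillar proteins, collagen) are invisible in
conventional MRI because their protons relax too fast (T2 of microseconds),
but they exchange magnetization with free water. Saturating the bound
protons with an off-resonance RF pulse and watching the water signal drop
gives an indirect handle on the macromolecular content — the basis of a
family of indices that range from fully quantitative (the macromolecular
fraction *f* from two-pool model fitting) to simple signal ratios (MTR).
These indices are used as biomarkers of muscle quality, for instance to
track the age-related loss of myofibrillar protein in the calf muscles.

`mtcalf` implements the full estimation chain for five MTC methods plus the
supporting relaxometry, together with a synthetic acquisition simulator and
the nonparametric statistics needed for a two-cohort (young vs. senior)
comparison:

* **Multi-offset qMT** — least-squares fit of the pulsed two-pool model to a
  Z-spectrum (two MT flip angles × seven offsets), with the bound pool
  described by a super-Lorentzian lineshape, under either the Ramani
  continuous-wave power-equivalent RF approximation
  (ω₁CW² = (1/TR)∫ω₁²dt) or the Yarnykh RMS approximation
  (ω₁rms² = (1/t_mt)∫ω₁²dt). Yields F = M₀B/M₀A, R·M₀A, T2A, T2B and
  f = F/(1+F).
* **Single-offset qMT** — closed-form solve for F from one low-offset
  measurement with T2B = 6 µs, R_A·T2A = 0.025, R·M₀A = 48 s⁻¹ held fixed.
* **MT_sat** — the per-TR percentage saturation δ from a PDw/MTw/T1w
  spoiled-gradient-echo triplet (S_mt = Aα·R1·TR/(α²/2 + δ + R1·TR)), with
  the semi-empirical B1 correction δ_corr = δ(1−0.4)/(1−0.4·B1⁺).
* **MTR / MTR_corr** — 1 − S_mt/S_ref, and its reference-tissue correction
  MTR_corr = MTR/(k·B1_error + 1) with k fitted per subject in the tibialis
  posterior.
* **Relaxometry** — variable-flip-angle T1 mapping (linearized SPGR fit with
  B1-scaled flips) and B0 mapping from a dual-echo phase pair.
* **Statistics** — Shapiro–Wilk normality gating, Mann–Whitney age
  comparisons with Hodges–Lehmann estimates and rank-biserial effect sizes,
  Kruskal–Wallis regional comparisons with Bonferroni post hocs, two-way
  (age × region) ANOVA for T1 with Levene diagnostics, and index-vs-T1
  Pearson regression.

All of it is exercisable without scanner data: `make_leg_phantom()` builds
five-muscle calf cross-sections with per-cohort tissue distributions, smooth
B1 (±15%) and B0 (tens of Hz) fields, and `simulate_protocol()` produces
every acquisition with Rician noise.

## Worked example

Recover the macromolecular fraction of a muscle-like tissue
(f = 0.07, T1 = 1.4 s) from noiseless simulated signals, by both routes:

```r
library(mtcalf)

truth <- two_pool_params(F = 0.0753, rm0a = 48, ra = 1/1.4, rb = 1,
                         t2a = 0.035, t2b = 6e-6)

## single-offset: 650 deg pulse at 1 kHz, normalized by the 100 kHz volume
pulse <- rf_pulse(650, 1000)
sn <- ramani_signal(truth, pulse) / ramani_signal(truth, rf_pulse(650, 1e5))
solve_single_offset(sn, pulse, ra = 1/1.4)
#> qMT single_offset fit (ramani RF approximation)
#>   f = 0.0700  (F = 0.0753)

## multi-offset: 350/500 deg x {1,2,5,10,20,50,100} kHz
prot <- multioffset_pulses()
snv <- vapply(prot, function(p) ramani_signal(truth, p), numeric(1))
qmt_fit(snv, prot, ra = 1/1.4)
#> qMT multioffset fit (ramani RF approximation)
#>   f = 0.0700  (F = 0.0753)
#>   R*M0A = 48 /s, T2A = 35 ms, T2B = 6 us, RMS residual = 8.39e-17 (n = 14)
```

Both estimators return the ground truth: f = 0.070, and the multi-offset fit
recovers all four free parameters with a residual at numerical precision.

A full synthetic study — 15 young and 9 senior subjects, all protocols,
ROI extraction and statistics — is one call:

```r
report <- run_all(cohort_config(seed = 42))
report$age_comparisons
#>     index p_two_sided hl_estimate  ci_low ci_high rank_biserial_r magnitude direction
#>      f_so    8.34e-17     0.00721 0.00603 0.00848           0.911     large     Y > O
#>       mtr    2.36e-05     0.01313 0.00734 0.01928           0.463    medium     Y > O
#>  mtr_corr    9.43e-09     0.01094 0.00754 0.01419           0.628     large     Y > O
#>     mtsat    7.45e-07     0.60684 0.38764 0.81849           0.541     large     Y > O
```

Every index is higher in the young group (positive Hodges–Lehmann
difference, direction `Y > O`), T1 is longer in the senior group, and all
indices correlate negatively with T1 — the direction pattern expected when
a single macromolecular/inflammation ground truth drives all five methods.

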