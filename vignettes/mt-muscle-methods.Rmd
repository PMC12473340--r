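---
title: "Magnetization transfer contrast in muscle: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Magnetization transfer contrast in muscle: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science inside `mtcalf`: the signal models, the
assumptions they carry, the parameters a user may want to touch, what the
synthetic-data generator does and does not emulate, and the numerical and
design decisions that were genuinely open.

## 1. The two-pool exchange model

Muscle tissue is modelled as a free water pool A (T2 of tens of
milliseconds) exchanging longitudinal magnetization with a semi-solid
macromolecular pool B (T2 of microseconds). An off-resonance pulse at
offset $\Delta f$ saturates pool B at rate
$R_{RFB} = \pi\,\omega_1^2\,G(\Delta f; T_{2B})$, where $G$ is the
super-Lorentzian absorption lineshape — the standard choice for
orientationally disordered semi-solids, and the reason MT is usable at all:
$G$ is still appreciable kilohertz away from resonance where the water pool
is barely touched.

Under continuous-wave irradiation the steady-state signal, normalized to
the no-saturation acquisition, is

$$S_n=\frac{R_B X + R_B + R_{RFB} + RM_{0A}}
{X\,(R_B+R_{RFB}) + \Bigl(1+\bigl(\tfrac{\omega_1}{2\pi\Delta f}\bigr)^2
\tfrac{1}{R_A T_{2A}}\Bigr)(R_{RFB}+R_B+RM_{0A})},
\qquad X = \frac{RM_{0A}\,F}{R_A}.$$

Assumptions worth stating:

* **Steady state.** The acquisitions being modelled apply ~100 preparation
  pulses over 5 s before readout (TR 50 ms), several times the muscle T1,
  so transients are ignored and signals are exact steady states.
* **Pulsed-to-CW mapping.** A shaped pulse is replaced by an equivalent CW
  amplitude. Two conventions are implemented: power averaged over the whole
  TR (`mode = "ramani"`, $\omega_{1CWPE}$) or over the pulse only
  (`mode = "yarnykh"`, $\omega_{1rms}$). They satisfy
  $\omega_{1CWPE}^2\,TR = \omega_{1rms}^2\,t_{mt}$ identically, so the RMS
  convention always assumes at least as much saturation power and predicts
  lower signal at equal tissue parameters.
* **Fixed bound-pool relaxation.** $R_B = 1\,\mathrm{s^{-1}}$; the fit is
  insensitive to it. $R_A$ is not fitted either: it is constrained to the
  observed $1/T_1$ from VFA mapping, with no observed-to-free-pool
  correction (an explicit simplification).

### The Gaussian MT pulse

The protocols specify a Gaussian pulse by duration and spectral FWHM; the
time-domain width follows from the Fourier pair
$\sigma_t = 1/(2\pi\sigma_f)$, $\sigma_f = \mathrm{FWHM}/(2\sqrt{2\ln 2})$
(1.874 ms for 200 Hz). The envelope is truncated to the stated duration and
the peak amplitude calibrated so the truncated integral equals the flip
angle. Truncation is the one free choice here; integrating the truncated
envelope uses both printed numbers and keeps the flip-angle round trip
exact.

## 2. The two estimation routes

`qmt_fit()` estimates $(F, RM_{0A}, T_{2A}, T_{2B})$ by Levenberg–Marquardt
least squares on the normalized 14-point Z-spectrum. Parameters are fitted
in log space (positivity is structural) inside physiological boxes
($F \in [10^{-4}, 0.5]$, $RM_{0A} \in [1, 200]\,\mathrm{s^{-1}}$,
$T_{2A} \in [5, 200]$ ms, $T_{2B} \in [1, 30]$ µs), starting from
$F = 0.07$, $RM_{0A} = 48$, $T_{2A} = 0.025/R_A$, $T_{2B} = 6$ µs — the
muscle constants of the single-offset literature. Three deterministic
restarts (nominal, ±50 %) guard against local minima; the best-residual
solution wins and ties cannot occur because the restart order is fixed.
A non-converged optimizer is reported as `converged = FALSE`, never as a
silent number.

`solve_single_offset()` is the accelerated two-parameter variant: with
$T_{2B}$, $R_A T_{2A}$ and $RM_{0A}$ frozen at those constants, $F/R_A$
follows in closed form from a single low-offset measurement normalized by a
100 kHz acquisition (far enough off resonance that neither pool is
saturated). The closed form is the algebraic inversion of the Ramani
equation, so on data generated by the forward model the round trip is exact
to numerical precision — this mutual consistency is the package's primary
correctness oracle.

## 3. Semi-quantitative indices

**MT_sat.** The MT-weighted FLASH steady state is
$S = A\alpha\,R_1 TR/(\alpha^2/2 + \delta + R_1 TR)$ in the small-angle
regime; $A$ and $R_1$ come from the PDw/T1w pair via the rational
estimators, and $\delta$ (reported in percent units) is the per-TR
saturation. Because $\alpha$, $R_1 TR$ and $\delta$ enter separately,
$\delta$ is nearly independent of the readout flip angle and of T1 — the
property that makes MT_sat attractive clinically. Flip angles are B1-scaled
before estimation; the residual transmit-field dependence is then treated
with the semi-empirical factor $\delta_{corr} =
\delta\,(1-0.4)/(1-0.4\,B_1^+)$. Note the factor is *increasing* in
$B_1^+$ (0.9375 at $B_1^+=0.9$, identity at nominal); the package follows
the printed formula.

**MTR and its correction.** $\mathrm{MTR} = 1 - S_{mt}/S_{ref}$ is stored
as a fraction throughout (percent only in rendered reports). Its
transmit-field sensitivity is removed with the reference-tissue method:
within one tissue, $\mathrm{MTR}_{meas} = \mathrm{MTR}_{corr} +
k_{specific}\,B_{1,err}$; an ordinary least-squares line over the tibialis
posterior voxels of each subject gives $k = k_{specific}/\mathrm{intercept}$,
and $\mathrm{MTR}_{corr} = \mathrm{MTR}/(k\,B_{1,err}+1)$ is applied
everywhere. $B_{1,err} = B_1^+ - 1$, which makes the correction the
identity at nominal field.

## 4. Relaxometry

VFA T1 mapping linearises the SPGR equation ($S/\sin\alpha$ on
$S/\tan\alpha$; slope $E_1$), with flips B1-scaled before the fit. B0 comes
from a dual-echo phase pair, $\Delta f = \mathrm{wrap}(\varphi_2-\varphi_1)
/(2\pi\,\Delta TE)$, wrapped per voxel to $(-\pi,\pi]$; with
$\Delta TE = 2.46$ ms the unaliased range (±203 Hz) comfortably covers
muscle off-resonance at 3 T, so no spatial unwrapping is attempted. The B0
sign convention: positive $\Delta f$ means the voxel resonates above
nominal, and the effective saturation offset is
$\Delta f_{eff} = \Delta f_{nominal} - B_0$.

## 5. The synthetic-data generator

The generator exists so that every stage — physics, fitting, correction,
statistics — can be tested end to end with a known ground truth.

**Geometry.** Five elliptical "muscles" (SOL, MG, LG, TA, TP) on a
48×48×4 grid (32×32×2 in the fast test configurations; each region keeps
at least 50 voxels). Schematic, not anatomical; all volumes are generated
co-registered, so the registration step of a real pipeline is out of scope
by construction.

**Tissue truths.** Per-muscle young-group macromolecular fractions of
0.070 (LG) to 0.075 (TA) — the single-offset scale for calf muscle — with
the senior group shifted down by 0.006; T1 of 1.40 s (young) and 1.47 s
(senior). Between-subject scatter: σ_f ≈ 0.0025 and σ_T1 ≈ 0.025 s, the
scale implied by reported confidence intervals for such cohorts, plus a
small per-muscle jitter. A latent "inflammation" variable couples the two
within groups (higher T1 with lower f), reflecting the standard
interpretation that inflammation prolongs T1 while diluting the
macromolecular pool; this coupling is what gives the MTR-vs-T1 correlation
a stable negative sign, since the direct physics of MTR actually *rises*
slightly with T1 (≈ +0.11 per second at muscle scale). The free-pool T2 is
tied to T1 through $R_A T_{2A} = 0.025$ and the exchange constants are held
at $RM_{0A} = 48\,\mathrm{s^{-1}}$, $T_{2B} = 6$ µs, so all five methods
see one consistent ground truth and the single-offset constants are exact.

**Fields and noise.** Smooth low-order polynomial B1 (0.85–1.15) and B0
(±40 Hz) fields, one independent draw per subject. Magnitude volumes get
Rician noise with the noise level set on the reference volume's mean inside
muscle (`snr`, default 100); phase volumes get Gaussian phase noise; the
relative-B1 map is passed through noise-free (it is a derived product in
practice). Every draw derives from the mandatory config seed, so cohorts
are bit-reproducible.

**Forward models.** qMT volumes are simulated as the SPGR readout times the
two-pool steady-state attenuation $S_n$ under the Ramani CW convention —
the convention the single-offset solve assumes, which keeps the
closed-form/forward-model consistency exact. The MT-weighted MT_sat volume
is different: there the MT loss enters the FLASH steady state per TR,
$S = M_0\sin\alpha\,(1-E_1)/(1-E_1(1-\delta)\cos\alpha)$, with
$\delta = R_1 TR\,(1/S_n - 1)$ bridging the two-pool physics to the
saturation index. Simulating that volume multiplicatively instead would
make the recovered $\delta$ depend structurally on the readout flip
(changing the MTw readout from 10° to 12° shifts it by ~13 %), destroying
the flip-angle invariance the method is known for; the per-TR form restores
it to under 1 %.

**The agarose series.** Five homogeneous gels at 0.5–4 % agarose with
theoretical macromolecular fractions 0.002/0.004/0.009/0.013/0.017. The
preset is T1-matched at 1.8 s: such gels are nickel-doped precisely so T1
can be set independently of agarose content, and a strongly varying T1
series would bend the MTR- and MT_sat-versus-concentration lines through
their T1 sensitivity rather than their macromolecular sensitivity. The five
gels share one B1/B0 field draw (a single scan session).

**What passing tests do and do not show.** The generator draws tissue
values from clean unimodal distributions, uses schematic geometry, perfect
fat suppression, no motion, no partial-volume mixing and no fat
infiltration. Recovery and direction results on it validate the estimation
chain, not the biology; in vivo effect sizes will be noisier than the
simulated ones.

## 6. Statistical pipeline

The analysis convention is ROI-first: signals are averaged over each muscle
ROI and each index computed once per ROI (`mode = "roi_signal_mean"`), with
voxelwise maps (`"map_mean"`) available; on homogeneous tissue the two
agree. Age comparisons pool all five muscles' ROI values per group (one
comparison per index); regional comparisons pool both age groups. T1, which
passes the Shapiro–Wilk gate, goes to a two-way (age × region) ANOVA with
Levene diagnostics and Bonferroni t post hocs; the MT indices go to
Mann–Whitney/Kruskal–Wallis. Effect sizes are the Hodges–Lehmann median
difference — computed literally as the median of all pairwise young−senior
differences — with the exact rank-based 95 % interval from
`stats::wilcox.test` (exact for the 15×9 design; tie-corrected normal
approximation otherwise), and the rank-biserial correlation
$r = 1 - 2U/(n_1 n_2)$, labelled small/medium/large at 0.3 and 0.5. All
tests are two-sided at α = 0.05.

## 7. Numerical choices

* **Lineshape quadrature.** $G$ is integrated with a fixed 512-node
  Gauss–Legendre rule *split at the magic angle*
  ($3\cos^2\theta = 1$), where the integrand has a non-analytic kink; an
  unsplit rule of the same order self-converges only to ~3·10⁻⁵ relative,
  the split rule to machine precision. The denominator is guarded by
  ε = 10⁻¹², and offsets below 100 Hz are refused outright (the lineshape
  diverges on resonance; extrapolating silently would be worse than an
  error).
* **Degenerate inputs.** Under-determined Z-spectra (< 6 distinct points),
  attenuation-free signals, non-physical VFA slopes ($E_1 \notin (0,1)$),
  zero-variance B1 errors in the k-fit, and single-offset denominators near
  zero all raise named errors; a negative solved $F$ is returned flagged
  `nonphysical` with a warning rather than clipped.
* **Problem sizes.** The test suite and acceptance script run the cohort
  analyses at the study design (15/9 subjects, five muscles), Monte-Carlo
  noise checks at 120–500 repetitions, null calibrations at 1000–2000
  simulations, and direction-fidelity checks over 50 seeded cohorts —
  sizes chosen so every check is statistically meaningful while the whole
  suite stays in the minutes range.

## 8. Known limitations

* The Yarnykh mode shares the Ramani signal equation and differs only in
  the RF-power convention. Fitted to data generated under the CW
  power-equivalent convention it therefore compresses $F$ substantially
  (the full Yarnykh model restructures the saturation term and behaves
  differently on real data), and at gel-phantom concentrations its
  least-squares optimum is not even monotone in the true fraction — the
  one linearity property in the acceptance suite that fails, by
  construction rather than by implementation error.
* MTR is bounded above and visibly compresses at strong MT weighting; it is
  linear in $f$ over the dilute gel range but only approximately so over
  the muscle range — one reason it is the weakest of the five indices.
* The MT_sat B1-correction factor is applied after B1-scaling the flip
  angles, in that order, per the printed method; its direction amplifies
  rather than removes the MT-pulse power dependence in this simulator, but
  ROI averaging over symmetric B1 fields makes the effect negligible at
  cohort level.
* No fat infiltration, fascicle structure, motion, or coil-sensitivity
  modelling; no on-resonance (inhomogeneous) MT; no fitting of $R_B$ or
  $R_A$.
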