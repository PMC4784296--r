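---
title: "Calibrator-based absolute qPCR quantification: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrator-based absolute qPCR quantification: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpcrcal)
```

## The model

A qPCR reaction monitored with an intercalating dye (or a hydrolysis probe)
reports, at the end of each cycle $n$, a fluorescence $F(n)$ that is — over
the instrument's linear range — an affine function of the mass of
double-stranded DNA in the well:

$$F(n) = \beta + a \cdot \mathrm{pmol}(n),$$

with a well-specific baseline $\beta$ and a plate-wide gain $a$
(a.u. per pmol). A **non-amplified calibrator** — a dilution series of a
90 bp DNA fragment cycled on the same plate, never amplifying — measures
$a$ directly: after subtracting the mean fluorescence of the 0 ng wells,
the per-level mean fluorescences regress linearly on loaded pmols
(`fit_calibration()`), converting loaded ng via a flat 650 g/mol/bp
(`ng_to_pmol()`; the constant is configurable, GC correction is reserved).

During the exponential phase a reaction amplifies at a per-cycle
efficiency $E \in (1, 2]$, so the amount present at cycle $n$ satisfies
$\mathrm{pmol}(n) = pmz \cdot E^{\,n}$ where $pmz$ is the amount at cycle
zero. Inverting the calibration line at every cycle of the exponential
window and dividing by $E^n$ back-calculates $pmz$ independently at each
window cycle; the spread of those per-cycle estimates is an internal
consistency diagnostic, reported as a per-well SD/SEM alongside the
replicate-level statistics. Copies per reaction are
$pmz \times 6.022\times10^{23} \times 10^{-12}$.

**Assumptions inherited by the method.** Fluorescence per pmol is the same
for calibrator and amplicon (the dye reports mass, not sequence, and
amplicon lengths from roughly 90 to 500 bp are treated as equivalently
reported); amplification proceeds at a constant $E$ from cycle 1 through
the selected window; the calibrator's fluorescence is cycle-independent.
The exponent $n$ in $E^n$ is the absolute cycle number — counting from the
take-off instead would change results by orders of magnitude and is
inconsistent with "amount at cycle zero".

## Landmarks: take-off and second-derivative maximum

The usable exponential window is bounded below by the **take-off point**
(the curve leaves baseline; used as the Cq) and above by the
**second-derivative maximum** (SDM, the point of maximal acceleration,
after which plateau effects set in). Neither landmark has a universally
agreed operational definition, so the package fixes transparent ones:

* the second derivative is the central second difference
  $d_2(n) = F(n{+}1) - 2F(n) + F(n{-}1)$ on integer cycles
  (`second_derivative()`), computed on a lightly smoothed curve
  (centered local quadratic, window 5, `smooth_curve()`); ties in the
  maximum resolve to the earliest cycle;
* the SDM anchor is the interior integer cycle maximising that smoothed
  $d_2$; the fractional position is then refined on the *unsmoothed*
  series with a fourth-order central-difference stencil interpolated by a
  natural cubic spline and maximised on a 0.001-cycle grid within
  ±1.5 cycles of the anchor (`find_sdm()`). The simpler 3-point parabola
  refinement carries a systematic skew bias of several tenths of a cycle
  on logistic-shaped curves; the stencil-plus-spline refinement agrees
  with the dense analytic second-derivative maximum to better than
  0.1 cycles on logistic curves with midpoints 15–35 and slope parameters
  1–3 (asserted in the test suite);
* the take-off is the interpolated cycle where $d_2$, scanned upward,
  first reaches a fraction (default **0.2**, configurable
  `takeoff_fraction`) of its maximum and stays above it through the SDM
  (`find_takeoff()`). This matches the rotor-style "comparative
  quantitation" convention and is parameter-light;
* the window is the integer span $\lceil$takeoff$\rceil$ to
  $\lfloor$SDM$\rfloor$; if fewer than 3 cycles remain it widens to 3 only
  while the smoothed curve is still strictly increasing, otherwise the
  well is flagged (`select_window()`).

Smoothing is used *only* for landmark detection; the efficiency regression
runs on unsmoothed corrected fluorescence, because smoothing biases
slopes.

## Baseline estimation and refinement

Sample wells use their **own** pre-take-off fluorescence as baseline: the
mean of cycles 3 through $\max(5, \lfloor t_0 \rfloor - 3)$, where the
provisional take-off $t_0$ is found on lightly smoothed raw data using a
much smaller threshold fraction (0.005 of the $d_2$ maximum): the baseline
region must end where acceleration first becomes *detectable*, not where
it is already substantial. Curves that are accelerating from the first
cycles keep the minimal region (cycles 3–5). The 0 ng calibrator wells
serve only the calibration curve's background, not sample baselines —
sample wells contain primers and template and have their own background.

Even so, the pre-take-off mean slightly over-estimates the true baseline,
because exponential signal is present (if small) before the take-off.
`refine_baseline()` removes this bias by back-extrapolation: fit the
exponential over the window, extrapolate it into the baseline region,
subtract its predicted mean contribution from the baseline estimate, and
iterate to a fixed point (cap 12 iterations, tolerance
$10^{-10}\times$ signal scale). On noiseless
exponential-plus-constant data the fixed point is the exact baseline; under
noise the correction stays small and stable because the baseline is never
free-fitted (a free exponential-plus-offset fit over a 3–5 cycle window
would roughly quadruple the efficiency variance). The refinement is on by
default in `quantify_plate()` and can be disabled.

## Efficiency estimation and its precision

$E = 10^{\mathrm{slope}}$ from OLS of $\log_{10} F_\mathrm{corr}$ on cycle
over the window; window cycles with non-positive corrected fluorescence
are dropped and at least 3 must remain. Estimates are **flagged, never
clamped**: `low_r2` below $r^2 = 0.99$, `e_out_of_range` outside
$[1.5, 2.1]$, `short_window` at exactly 3 cycles — diagnostics must
surface pathology, not hide it.

Back-calculation amplifies efficiency noise: a relative error
$\varepsilon$ in $E$ scales $pmz$ by roughly $n\varepsilon$ at window
cycle $n$. With 1 % multiplicative fluorescence noise and 3–5-cycle
windows around cycle 20–35, per-well copy estimates scatter by roughly
10–20 % and quadruplicate level means by 5–10 % (SEM) — visible in the
worked example. This is intrinsic to per-reaction efficiencies; the
dilution-series *slope* (the accuracy measure) is far more stable than any
single level mean. The mismatch cost of ignoring this and assuming perfect
doubling is `efficiency_error_pct(E, n)` $= ((2^n/E^n)-1)\times 100$.

## The simulator

`simulate_plate()` generates plates with known truth. Defaults define the
reference conditions used throughout the tests: 40 cycles; six (or five)
ten-fold dilutions from $4.5\times10^6$ (or $4.5\times10^5$) down to
$4.5\times10^1$ starting copies in quadruplicate; calibrators at 0, 40,
60, 80, 120, 140 and 200 ng of a 90 bp fragment in duplicate; two
no-template controls; $E_0 = 1.9$; gain 2000 a.u./pmol, calibrator
background 300 a.u., sample baseline 50 a.u.; plateau capacity
$10^{12}$ copies (plateau fluorescence ≈ 3300 a.u., a realistic instrument
scale); 1 % multiplicative noise and no additive noise. Two kinetic
models separate correctness from robustness testing:

* **ideal** — $N(n) = \min(N_0 E_0^n, K)$: exactly exponential up to a
  hard plateau, so every pipeline quantity has a closed-form truth
  (noiseless recovery of $E$ and $N_0$ is asserted to $10^{-6}$ and
  0.1 %); the hard kink also means the take-off, anchored to the integer
  $d_2$ argmax, quantizes non-integer curve shifts by up to ~0.6 cycles —
  an artifact of the kink, not of real data;
* **logistic** — $E(n) = 1 + (E_0-1)/(1 + N(n{-}1)/K)$: efficiency
  declines smoothly as product accumulates; recovered $E$ is then biased
  low by construction (asserted, documented, not hidden).

Noise is seeded per well from the master seed, so adding wells never
perturbs existing ones and identical configurations reproduce
byte-identical plates. What the simulator does **not** emulate: probe
hydrolysis chemistry, passive-reference normalization, inter-platform gain
differences, pipetting error across the dilution series, or
reverse-transcription variability — so green tests demonstrate numerical
correctness of the pipeline under its stated model, not robustness to
every failure mode of real plates.

## Relative-quantification comparators

`delta_delta_cq()` implements the doubling-assumption fold change
$2^{-\Delta\Delta C_q}$; `pfaffl_ratio()` generalizes it with measured
efficiencies, averaged arithmetically within each (group, gene) — the
control group is exactly 1 by construction in both, and the Pfaffl ratio
reduces to ΔΔCq exactly when all efficiencies are 2 (asserted to
$10^{-12}$). `relative_from_absolute()` needs no reference gene at all;
its standard error propagates group SEMs by the delta method. The Cq used
is the take-off point (configurable to the SDM). When target *and*
reference are co-regulated — both truly 3× up — ΔΔCq reports ≈ 1 while
the absolute route reports ≈ 3; the acceptance script recomputes exactly
this contrast.

## Degenerate inputs and error handling

Non-amplifying wells (rise below ten baseline-region standard deviations,
e.g. NTCs) raise a classed `no_amplification` condition; `quantify_plate()`
converts per-well failures into flagged report rows rather than aborting
the plate. Cycles back-calculating to non-positive pmols are dropped, not
clamped (negative pmols are calibration noise, not signal); fewer than
3 surviving cycles is a `cannot_quantify` error. Calibrations require a
0 ng well and at least 5 distinct non-zero levels; the intercept is left
free (forcing it through the origin would hide pipetting faults) with a
warning above 5 % of the mid-range fit. Stored calibrations are refused
across runs by default.

## Problem sizes

The test suite and acceptance script run plates of 24–48 wells with 40
cycles, Monte-Carlo loops of 100–500 replicates for noise-robustness
properties, and a 9×5 grid of logistic curves for the landmark oracle —
sizes chosen so the full suite completes in well under a minute while
keeping Monte-Carlo assertions at the 95 % level statistically
comfortable.

## Known limitations

* Per-reaction efficiency from a 3–5-cycle window is noisy; downstream
  copy numbers inherit that noise amplified by the cycle number (see
  above). Replicates are essential.
* Multi-phasic or bi-modal amplification curves are out of scope; QC
  beyond the three flags is the user's task.
* Reverse-transcription efficiency is not corrected; absolute *mRNA*
  numbers are therefore cDNA-referenced.
* Dye-binding saturation and amplicon-length-dependent fluorescence are
  not modelled; the calibrator-equivalence assumption covers the typical
  90–500 bp amplicon range and inherits its limits.
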