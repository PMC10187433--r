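---
title: "Methods: the peroxiredoxin switch model and the synthetic single-cell pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the peroxiredoxin switch model and the synthetic single-cell pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`prdxswitch` studies how hydrogen peroxide dose is translated into the
temporal order of transcription-factor activation in single cells: p53 first
(often pulsatile) at low dose; at high dose a FOXO1 nuclear-residence window
first, with p53 deferred until the window closes. This vignette documents the
model, the generator that emulates the experimental readouts, the detection
and statistical rules, and the numerical and design choices behind them. It
states no result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The redox-cycle switch

The model tracks the composition of a single effective 2-Cys peroxiredoxin
pool as fractions — reduced thiol $r$, sulfenic acid $s$, disulfide $d$,
hyperoxidized sulfinic acid $h$ — together with the H2O2 concentration $H$
(µM), under mass-action kinetics:

$$\dot r = k_{red} d - k_{ox} H r, \quad
  \dot s = k_{ox} H r - k_{ss} s - k_{hyp} H s + k_{srx} h,$$
$$\dot d = k_{ss} s - k_{red} d, \quad
  \dot h = k_{hyp} H s - k_{srx} h,$$
$$\dot H = -(k_{clear,base} + k_{clear,cell}\, \mathrm{prdx}\,(1-h))\, H.$$

Assumptions worth making explicit:

* **One effective pool.** Whether FOXO1 activation reports hyperoxidation of
  PRDX1 itself or of a PRDX1-dependent relay partner is left open by the
  data; the model does not adjudicate and treats a single pool whose
  hyperoxidized fraction is the gating variable.
* **Clearance feedback is the dose amplifier.** H2O2 removal is proportional
  to the non-hyperoxidized pool, so a large bolus partially disables its own
  clearance. This self-amplification is what turns a ~2-fold dose change
  (60 → 100 µM) into an all-or-none difference in window opening, and makes
  the time above threshold grow steeply and monotonically with dose.
* **No explicit thioredoxin/NADPH pools, no spatial structure, no
  single-molecule stochasticity.** All cell-to-cell variability is injected
  downstream (Section 3).

The FOXO1 window opens at the first time $h \ge \theta_{on}$ and closes at
the first later time $h \le \theta_{off}$, with $\theta_{off} < \theta_{on}$
(hysteresis). Two thresholds rather than one prevent chatter when $h$ drifts
near a single cutoff; with the default gap (0.30 vs 0.47) re-entry within a
movie does not occur, matching the single-phase displays the analysis
targets. p53 onset follows window closure by $\tau_{p53} = 60$ min.

### Default parameters

| parameter | value | units | role |
|---|---|---|---|
| `k_ox` | 0.004 | /µM/min | Cp oxidation to SOH |
| `k_ss` | 0.6 | /min | disulfide formation |
| `k_red` | 0.3 | /min | thioredoxin-system reduction |
| `k_hyp` | 0.004 | /µM/min | hyperoxidation SOH → SO2H |
| `k_srx` | 0.0015 | /min | SRXN1 repair SO2H → SOH |
| `k_clear_cell`, `k_clear_base` | 0.06, 0.01 | /min | H2O2 clearance |
| `theta_on`, `theta_off` | 0.47, 0.30 | — | window thresholds |
| `tau_f` | 4 | min | FOXO1 shuttling relaxation |
| `tau_p53` | 60 | min | exit → p53 onset delay |

No rate constants for this system are published; the defaults are the
package's calibrated reference set, chosen once so the deterministic dose
response reproduces the qualitative single-cell phenomenology and then
frozen: the peak hyperoxidized fraction crosses `theta_on` between 60 and
100 µM (no window at ≤ 60 µM, a responder subset at 80 µM, near-universal
fast entry at ≥ 100 µM), window duration grows from ~5.5 h at 80 µM to
~16 h at 300 µM, and entry at 100 µM occurs within ~15 min. `tau_f` and the
p53 rise times are fast relative to the 20-min frame so that event detection
(Section 4) is accurate to one frame. The perturbation presets
(`perturb_params()`) scale these constants only: `prdx1ko` sets
`prdx_scale = 0.15` (activation from 40–50 µM), `srxn1oe` multiplies `k_srx`
by 8 (threshold moves above 80 µM, phases shorten several-fold), `j14`
multiplies `k_srx` by 0.1 (near zero — kept finite so exits and onsets remain
measurable in long integrations; `k_srx = 0` exactly makes SO2H absorbing and
is exercised in tests), `conoidinA` scales (`k_ox`, `k_ss`) by (0.7, 0.2),
which lets the sulfenic intermediate linger and lowers the activation dose.

### Integration

A hand-written fixed-step classical Runge–Kutta (RK4) integrator advances
the five states on a 1-min output grid over 24 h. Determinism and
reproducibility motivated a fixed-step scheme; the system is only briefly
stiff at the highest doses (the initial oxidation transient at 300 µM has a
rate ~1.2/min), so each output step is subdivided into
$\lceil dt\,\lambda_0/0.4 \rceil$ equal internal substeps, with $\lambda_0$
the fastest initial rate — a deterministic rule that keeps the explicit
scheme well inside its stability and accuracy region without changing the
output grid. Verification is dual-route: a 100×-finer self-integration
(agreement within $10^{-3}$ in every component) and the independent
`deSolve::lsoda` solver at tight tolerances (within $10^{-4}$) in the test
suite. Mass conservation ($r+s+d+h=1$) holds to ~$10^{-14}$ because the
right-hand side is exactly conservative in exact arithmetic.

## 2. What the generator emulates

`generate_population()` / `generate_snapshot()` / `render_field()` emulate,
respectively: 24-h fluorescent-reporter movies sampled every 20 min;
immunofluorescence snapshots fixed 5 h after treatment (FOXO1, p53, γH2AX);
and 16-bit multi-channel image fields with ground-truth nucleus masks. One
deterministic redox integration per dose drives every cell; per-cell
variability enters through:

* **Threshold jitter** — lognormal jitter (CV 0.1) on
  $\theta_{on}, \theta_{off}$ per cell. This is the sole source of the
  dose-dependent responder fraction: a cell responds iff the dose's peak $h$
  exceeds its jittered threshold, giving ~0 % responders at 50 µM, roughly
  half at 80 µM and ~100 % at ≥ 100 µM.
* **FOXO1 kinetics** — piecewise-exponential relaxation (time constant
  `tau_f`) from a baseline nuclear fraction (0.30 ± 0.02 between cells)
  toward an active target (~0.78) inside the window.
* **p53 waveforms** — at onset, each cell is oscillatory or sustained.
  Oscillatory: a raised-cosine pulse train (amplitude 3 a.u., period 330 min
  — the period is a display default, never an acceptance quantity) on a small
  fast saturating shift (0.8 a.u., τ = 10 min) so activation is detectable
  within minutes and the troughs stay above the control tail. Sustained: a
  saturating ramp to 2× the pulse amplitude (6 a.u., τ = 60 min), encoding
  that p53 reaches higher levels in cells that die. The probability of the
  sustained mode is logistic in dose (midpoint 100 µM, scale 40 µM),
  mirroring the loss of oscillations with dose. Phase-less cells activate
  p53 through a low-dose route at the first frame with a dose-dependent
  probability (logistic, midpoint 30 µM, scale 12 µM); the two-route
  biochemistry is not otherwise modelled.
* **Death** — a discrete-time hazard on the frame grid,
  $\lambda(t) = \mathrm{mult}\,(a\,[t \ge t_{exit}]\,D + b\,p53(t))$ with
  $D$ the completed window duration, $a = 2\times10^{-7}$,
  $b = 1.5\times10^{-4}$. Two design points: the duration term acts *after*
  exit, so phases are observed in full and death associates with long
  residence and high p53 (hazards active inside the window would instead
  truncate exactly the cells they are meant to mark, reversing both
  associations); and the p53 term dominates, so sustained-mode cells die
  preferentially. The per-dose scale `mult` is calibrated by
  `calibrate_death()` — bisection against a 20,000-cell Monte-Carlo estimate
  of the 24-h death fraction — to the reference fractions 1 % (50 µM), 11 %
  (80 µM), 34 % (100 µM), 98 % (300 µM); unreferenced doses use monotone
  interpolations (0.2/0.5/3/60/80 % at 20/40/60/150/200 µM) fixed once. The
  resulting multipliers are frozen in the package as versioned defaults.
* **Measurement noise** — multiplicative lognormal (σ = 0.1) on every
  measured series, Gaussian jitter (sd 8 min) on the onset delay. Setting
  `noise_sd = 0` disables both, making event times exact for oracle tests.
* **Snapshots** — trajectories evaluated at `t_fix = 300` min with snapshot
  noise, conditional on survival to fixation (dead cells are not stained, so
  they are resampled); γH2AX is drawn from a saturating monotone function of
  dose (base 120, 6-fold saturation, half-saturation 150 µM, lognormal
  σ = 0.35) — monotone where p53 is not, which is the point of that channel.
* **Rendering** — disc nuclei inside disc cytoplasms on a regular grid;
  channel intensities are constructed so the programmed quantities are
  exactly recoverable by the quantifier in the noise-free case, with
  optional Poisson photon noise.

Ground truth (entry/exit/onset/mode/dose, death) is carried with every cell.
Mutual exclusivity is structural: onset is defined as exit + delay, so no
cell is ever simultaneously in its window and past onset.

**What the generator does not emulate** — and what passing tests therefore do
not show about real data: no mitosis, migration, lineage or tracking errors;
no real point-spread function, illumination bias or segmentation error (masks
are ground truth); no cell-density dependence of the effective dose; no
re-entry phases; waveforms are stylized (raised cosine rather than the
irregular pulses of real p53). Parameter-recovery results certify the
pipeline's internal consistency at realistic noise, not robustness to the
full failure modes of microscopy.

## 3. Quantification and gating

`measure_cells()` reproduces the standard ring-based readout: per nucleus
label, the mean intensity over nucleus pixels and over a cytoplasmic ring —
the morphological dilation of the nucleus by 3 px (disc kernel) minus all
nucleus pixels, with a pixel claimed by two rings assigned to the nearer
nucleus centroid, so rings are pairwise disjoint. Mean (not median) intensity
is used. Localization is summarized as the bounded nuclear fraction
nuc/(nuc + ring) ∈ [0, 1]; the unbounded nuclear/cytoplasmic ratio was
rejected because population displays and thresholds live naturally on a
bounded axis. Its scale invariance (illumination cancels) is asserted in
tests.

`fit_thresholds()` sets activation cutoffs at the 0.99 quantile of an
untreated control (≥ 100 cells) for the FOXO1 nuclear fraction and log10
nuclear p53; mean + 3 sd is available as an alternative (`method =
"mean_sd"`). Classification is strict (`>`): a cell exactly at a cutoff is
not active, so a degenerate constant control marks nothing. Quadrant tables
report the four label fractions per dose (they sum to 1 by construction) and
carry the maximum dual-activation fraction as the mutual-exclusivity
summary.

## 4. Trajectory features and oscillation analysis

Events on the 20-min frame grid are called with a run-length rule: entry =
start of the first run of ≥ 2 frames above the FOXO1 cutoff; exit = start of
the first subsequent run of ≥ 2 frames at or below it; p53 onset = start of
the first run of ≥ 2 frames above baseline mean + 3 sd (baseline = first 3
observed frames; a zero-sd baseline falls back to a 20 %-above-baseline rule,
recorded in the output). Two frames reject single-frame noise excursions at
σ = 0.1. Phases open at death or movie end are censored, not imputed; the lag
is defined only when both exit and onset are detected. The heatmap ordering
is: no-phase cells first, completed phases by ascending duration (ties by
cell id), movie-end-censored phases by entry time, death-censored phases by
death time — the placement of censored cells is a package decision, as the
displays it imitates do not state one.

Autocorrelation is computed per cell on the linearly detrended, mean-centred
p53 series, normalized by the lag-0 autocovariance (biased-denominator
estimator; it agrees with `stats::acf` to machine precision on complete
series, which the test suite uses as the independent cross-check). Linear
detrending is the default because rising baselines masquerade as long-range
correlation. Series are truncated at death; at least 12 observed frames are
required, and excluded counts are reported. `pooled_acf()` averages cells
pointwise with a percentile bootstrap band (cells resampled, B = 1000,
seeded); shorter (death-truncated) cells contribute to the lags they cover.
The oscillation score is the acf value at the first positive local maximum
within a period window (default 260–400 min, bracketing the programmed
period); a monotone-decaying acf scores 0. Fate comparisons use two-sided
Wilcoxon rank-sum tests (the choice of a rank test is a package decision);
completely tied groups are reported with p = 1. The duration metric in
`compare_fates()` is the observed in-phase time, with censored phases
included at their censoring time.

## 5. Numerical choices, degenerate inputs, determinism

* Quantile type 7 (R default) for thresholds; strict inequality at cutoffs.
* `nuclear_fraction(0, 0)` is an error (undefined measure), as are empty
  masks, mismatched mask/image dimensions, non-uniform time grids, unordered
  state tables, and windows outside the lag range.
* All generators consume a caller-supplied seed and restore the caller's RNG
  state on exit; `run_pipeline()` derives a named substream per stage from
  the master seed, so stage results do not depend on execution order.
  Identical seeds give bitwise-identical tables end to end (asserted).
* CSV schemas are validated on read with the missing column named; unknown
  columns are preserved with a warning; `#` lines carry run metadata.
* The package ships no stored data: every fixture in the tests is generated
  by the seeded generator at run time.

## 6. Problem sizes

The test suite and acceptance script run at the sizes the analyses need and
no larger: full dose responses at 2000 cells/dose for gating summaries,
movie populations of 150–300 cells/dose for feature recovery and fate
comparisons (pooled 80 + 100 µM, the condition used for dying-vs-surviving
contrasts), 24-h integrations at 1-min steps with a 0.01-min self-oracle at
two doses, Monte-Carlo death calibration at 20,000 cells, and 100-cell
Poisson-noise rendering for quantification error. Death percentages are
reported at the reference sample sizes (n = 196/250/300/206) to match the
uncertainty of the quantities they reproduce.

## 7. Known limitations

* The ODE parameters are effective, not measured; only their induced
  phenomenology is constrained. Different rate sets could produce the same
  orderings.
* The low-dose p53 route is a single fixed-delay rule, not a mechanism; the
  SRXN1-overexpression reduction of p53 activation at *low* dose is outside
  the model's scope.
* The oscillation period (330 min) and all waveform amplitudes are stylized
  defaults; the oscillation analysis is validated for discrimination
  (oscillatory vs sustained), not for period estimation, which the package
  deliberately does not attempt (no spectral methods).
* Within a single dose the duration–death association is weak by
  construction (threshold jitter is the only duration spread); the
  dying-vs-surviving duration contrast is a pooled-dose phenomenon here, as
  in the displays it mirrors.
* Image quantification assumes the provided masks are correct; there is no
  segmentation of real images.
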