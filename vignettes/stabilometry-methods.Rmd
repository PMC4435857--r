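---
title: "Stabilometric sway variables and test-retest reliability: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stabilometric sway variables and test-retest reliability: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabilometry)
```

This vignette documents the models and numerical choices behind the
package: what each sway variable is, how the two sway-area estimators and
the Higuchi fractal dimension are computed, how reliability is quantified,
what the synthetic cohort generator does and does not emulate, and where
the design was genuinely open.

## Trials and conventions

A trial is a 2-D CoP series (medio-lateral and antero-posterior, cm) at a
fixed sampling rate. The canonical acquisition is 60 s at 50 Hz, stored
under the half-open convention: N = 3000 samples at t = 0, 0.02, ...,
59.98 s, so that N = rate × duration exactly and mean velocity × 60 s
reproduces the total path length to machine precision. Units are cm
throughout; the first spatial column is ML, the second AP. Files are plain
delimited text (comma or tab, autodetected, decimal point only), with an
optional leading time column from which the rate is inferred and checked
for uniformity. Any settling period before acquisition is assumed already
excluded from the file; a leading-trim option exists but defaults to 0 s.

## Time-domain variables

Positional variability is the per-axis sample SD (n − 1 denominator; at
N = 3000 the distinction from the population SD is below 0.02% and no
reported 2-decimal value discriminates). Path lengths are total variations
(per axis) and the Euclidean trajectory length (total); mean velocity is
total path over duration, which for uniform sampling equals the mean
absolute CoP speed. No filtering or detrending is applied before any
metric: the variables are defined on the recorded series as-is.

## Sway area

**PCA ellipse.** The 2 × 2 covariance matrix of (ML, AP) is
eigen-decomposed; with s₀ the square roots of the eigenvalues, the 95%
ellipse has *semi*-axes 1.96 s₀ and area π · 1.96² · s₀₁ · s₀₂. Two readings
of "1.96 s₀" are possible (semi-axis or full axis); the semi-axis reading
is dimensionally the conventional 95% confidence ellipse and is the one
consistent with published per-trial areas, which sit at or below the bound
π · 1.96² · s_ML · s_AP implied by det Σ ≤ σ²_ML σ²_AP. Note that this bound
is a *per-trial* identity: group means of per-subject areas can (and in
published group tables occasionally do) exceed the product of group-mean
SDs, because the mean of a product of positively correlated per-subject
quantities exceeds the product of their means. The full-axis reading is
available via the `multiplier` argument for sensitivity analysis. Perfectly
collinear clouds give a zero-area ellipse; an all-identical cloud
additionally warns.

**Fourier-analysis outline (FAO).** The plane around the CoP centroid is
divided into 100 equal angular bins; in each non-empty bin the most distant
sample is kept (ties to the first occurrence). The radius function is then
fitted by ordinary least squares on the basis {1, cos mφ, sin mφ},
m = 1..20. The constant term A₀ is required — a pure sinusoid sum cannot
represent a closed outline of nonzero mean radius. The enclosed area has
the closed form ½∮r² dφ = πA₀² + (π/2)Σ(Aₘ² + Bₘ²), used directly instead
of quadrature. Open choices, fixed as follows: the outline centre is the
centroid of all samples; empty bins are skipped (the fit uses non-empty
bins only and refuses when fewer than 2·m_max + 1 remain); the angle
entering the fit is the angle of the extreme point itself rather than the
bin centre (closer to the data; the difference is below one bin width, and
the bin-centre variant is selectable with `use_bin_centre = TRUE`). The
fitted radius must be non-negative on a 1000-point angle grid, otherwise
the area is refused with the offending angle named — an order-20 fit of
noisy radii can dip negative when the outline is extremely irregular.

Both areas are translation-invariant exactly, and scale as c² under
scaling. The PCA area is exactly rotation-invariant; the FAO area is
invariant under rotations by whole bins and only approximately under
arbitrary rotations, since bin membership of individual samples changes.

## Higuchi fractal dimension

For lag k and offset m = 1..k, the normalized curve length is
L_m(k) = [Σᵢ |x(m + ik) − x(m + (i−1)k)|] · (N − 1)/(⌊(N − m)/k⌋ · k), and
L(k) is the mean over offsets divided by k. On a log/log plot L(k) falls as
k^(−D): D = 1 for a smooth ramp (exactly, independent of floor effects),
D = 2 for white noise, D = 2 − H for fractional Brownian motion. Empirical
CoP log/log curves show two regimes, so the regression is run separately
over lag-duration windows 0–0.3 s (short) and 0.8–12 s (long), boundaries
inclusive, the transition region excluded. The default lag grid is every
integer k with k/fs ≤ 0.3 s (k = 1..15 at 50 Hz) plus ~25 log-spaced
integers spanning 0.8–12 s (k = 40..600), capped at ⌊(N − 1)/4⌋ so each
offset keeps several increments; grid and windows are arguments. The
regression is unweighted OLS; R² is reported per fit. The estimator is
exactly invariant under affine transforms of the series. Implementation
note: for each k all lag-k increments are computed once and summed per
offset class (`rowsum`), which equals the nested-loop definition to
1e-12 — the test suite checks this against a brute-force oracle.

## Reliability

ICC(2,1) — two-way random effects, absolute agreement, single measures —
is computed from the two-way ANOVA mean squares of the n-subject × 2-session
matrix: (MS_R − MS_E)/(MS_R + MS_E + (2/n)(MS_C − MS_E)), with the
Shrout–Fleiss approximate F-based 95% CI. Confidence bounds may be
negative; identical sessions yield ICC = CI = 1. The CI's empirical
coverage at n = 26 and designed reliability 0.8 is checked by simulation
(500 replicates) in the acceptance suite.

Two different "standard errors" coexist in reporting practice and are both
emitted, clearly separated: the SE of the mean, SD/√n, printed beside group
means; and the standard error of measurement, SEM = pooled SD · √(1 − ICC)
with pooled SD = √((sd₁² + sd₂²)/2), the within-subject noise scale. A
negative ICC is allowed in the SEM (argument of the root then exceeds 1).

Romberg quotients are computed per subject as the eyes-closed/eyes-open
ratio and summarised as mean ± SD across subjects (mean-of-ratios, not
ratio-of-means — an SD across subjects is only defined for the former).
The firm-surface pair (FO, FC) is the default; the compliant pair is
selectable. Reliability tables exclude, per condition, subjects missing a
session (warning with names), and refuse cells with fewer than 3 complete
pairs. No multiple-testing adjustment is applied: ICCs are descriptive
estimates, not tests.

## Synthetic cohorts and what they do (not) show

The generator draws, per subject, a between-subject effect
u_j ~ N(0, σ²ᵤ) and per session an effect v_js ~ N(0, σ²ᵥ), both on the log
sway-scale; a trial's per-axis scale is base_group × mult_condition ×
exp(u_j + v_js). The *designed* ICC on the log scale is σ²ᵤ/(σ²ᵤ + σ²ᵥ),
exact by construction, which is why recovery tests evaluate the pipeline on
log-transformed metrics; raw metrics are used everywhere else. Axes are
independent by default (a correlation parameter exists to exercise the gap
between the PCA and FAO areas).

Defaults, chosen once as the package's reference conditions: cohorts of
26 + 15 subjects (young, elderly); base scales 0.44/0.51 cm (young ML/AP)
and 0.57/0.62 cm (elderly), matching published session-1 firm-surface
variabilities; condition multipliers 1, 1.2, 1.5, 2.7 for FO, FC, CO, CC,
matching the published SD ratios so mean path lengths order
FO < FC < CO < CC; σᵤ = 0.5 and σᵥ = 1/6, i.e. designed ICC = 0.9, in the
"excellent" band that repeated mSIT measurements show in demanding
conditions.

Trace models: `ou` (default) is an exact discrete Ornstein–Uhlenbeck
process with unit stationary variance and mean-reversion rate θ = 2 /s;
`fgn` is integrated fractional Gaussian noise (Davies–Harte circulant
embedding, exact autocovariance), sample-standardized, whose graph has
fractal dimension 2 − H; `mixture` is their equal-power sum. Two
deliberate departures from human CoP data follow from these choices and
are worth stating plainly. First, real between-subject spread is nearer
σᵤ ≈ 0.2; the default 0.5 is larger so that the designed variance
components dominate the within-trial sampling noise of the per-trial SD
estimate (≈ 0.09 on the log scale at θ = 2), keeping designed and
recovered ICC close. Second, the OU model cannot simultaneously match
human sway SD and mean velocity: matching both would need a correlation
time near 20 s, which would leave a 60-s trial with ~1.5 effective degrees
of freedom and make the per-trial SD estimate useless for reliability
recovery. The default favours the variance-components structure, so
generated velocities are several times higher relative to SD than human
values, and the OU short-lag dimension is ≈ 1.5 rather than the ≈ 1.1 of
human CoP; the `fgn` model with H ≈ 0.9 produces the smoother,
CoP-like short-lag geometry when fractal behaviour is the object of study.
Passing recovery tests therefore demonstrates correctness of the
estimators and of the reliability machinery under a known ground truth,
not biomechanical realism of the traces.

Determinism: a cohort is a pure function of its config (one RNG stream
seeded by `config$seed`); regenerating gives bitwise-identical trials.

## Problem sizes and numerical tolerances

The validation suite uses standard 3000-sample trials for single-trial
checks; ICC calibration uses 500 two-session replicates at n = 26; the
designed-ICC recovery grid uses 200 replicate cohorts per design point
(ICC ∈ {0.4, 0.6, 0.8, 0.95}, n = 26, one condition, the per-trial SD as
the metric) and tracks the mean recovered ICC to within 0.05; the
end-to-end check runs one full default cohort (328 trials) and requires
every magnitude-variable cell of the reliability table to sit within 0.1
of the designed ICC. The four fractal-dimension variables are excluded
from that per-cell check: the generator's ground truth is a pure scale
model and the Higuchi estimator is affine-invariant, so FD carries no
designed between-subject variance and has no designed ICC. A single
cohort's cell ICCs fluctuate with subject sampling (SE ≈ 0.04 at n = 26
and ≈ 0.05–0.1 at n = 15 around a designed 0.9), which is the dominant
source of variation in the end-to-end numbers.

Key numeric tolerances: curve lengths match their brute-force definition
to 1e-12; the closed-form outline area matches dense quadrature to 1e-8;
the closed-form ICC matches ANOVA mean squares to 1e-10; write/read round
trips preserve series to 1e-9 (12 printed significant digits). Degenerate
inputs fail loudly and early: constant series (fractal fit), all-identical
clouds (warned zero ellipse), under-determined outline fits, fewer than 3
subjects, zero total variance in scores.
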