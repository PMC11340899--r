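---
title: "Quantifying movement and immobility after post-contact immobility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying movement and immobility after post-contact immobility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcimove)
```

## The behavioural problem

Many animals respond to physical contact with a predator by becoming
completely immobile for a long and unpredictable time — post-contact
immobility (PCI), also known as thanatosis or tonic immobility. What an
animal does *after* PCI ends is equally informative: it must trade the
residual danger from the predator against the opportunity to reach safety.
`pcimove` implements a complete analysis pipeline for experiments of the
following design: an antlion larva (or comparable small arthropod) is
dropped at the centre of a 225 × 225 mm arena onto one of three substrates —
paper (impenetrable), shallow sand (2.3 mm, partial burial possible) or deep
sand (4.6 mm, full burial possible) — and filmed for 90 minutes while it
alternates immobility and movement bouts, of which at most the first 16
pairs are scored.

Four statistical questions structure the pipeline:

1. Do immobility and movement durations *trend* with the sequential bout
   number, and does the trend depend on the substrate?
2. Which family — exponential, power law or log-normal — best describes the
   pooled *distribution* of bout durations per substrate?
3. How does the animal *disperse* from the point where PCI ended — is its
   mean squared displacement (MSD) sub-diffusive, diffusive or
   super-diffusive, and how does its instantaneous speed change?
4. How far does it get, start to finish, on each substrate?

## Data model and preprocessing

Tracks are time-stamped 2-D centroid positions (mm) at a fixed sampling
interval; bout tables follow the manual-scoring sheet layout (`ALid`,
`Weight_g`, `Treat`, `ArrT_s` and per-period `StTMk_s`, `Ikdur_s`,
`EnTMk_s`, `Mkdur_s` columns). `read_bout_table()` recomputes every duration
from the start/end timestamps and rejects the sheet if any stored duration
disagrees by more than the 1 s manual-scoring precision, naming the cell.

Raw tracks are coarse-grained by recursive pairwise averaging
(`coarse_grain()`): each level replaces successive pairs of time, x and y by
their means, halving the series; a trailing odd sample is dropped so that
applying levels $a$ then $b$ equals applying $a+b$ at once. Four levels on a
10 frames/s track give an effective interval of 1.6 s, which suppresses
fictive sub-resolution movement while retaining every behavioural feature of
interest. Sand-substrate tracks are additionally smoothed with a centred
running average (`smooth_track()`, default window 3 samples — the smallest
centred window; the window length is an assumption, exposed as a parameter,
because centroid noise on sand approaches the movement length scale).

## Bout segmentation

A coarse-grained frame is *moving* when its step displacement exceeds a
threshold; a movement bout ends only after at least `still_gap = 3.2` s (two
coarse frames — the operationalisation of "more than a couple of seconds")
of consecutive still frames, and that terminal gap belongs to the following
immobility bout. The bout list starts with the immobility period containing
the first frame: the PCI itself.

The default threshold is estimated per track from the first 10 s of the
record, when the animal is reliably still and all apparent displacement is
centroid noise. Isotropic noise makes still-step lengths Rayleigh
distributed, so the noise scale is estimated robustly as median/1.177 (at
1.6 s sampling only ~6 steps fall in the window, ruling out tail quantiles)
and the threshold is set 10σ above zero. The wide guard band matters: a
threshold placed *at* a high noise quantile is exceeded by construction a
fixed fraction of the time, and over the ~3 400 still frames of a record
even a 6σ band produced occasional single-frame phantom movement bouts in
simulation. At 10σ a false positive is expected well under once per record,
while genuine coarse steps are an order of magnitude larger on every
substrate (≈3.2 mm on paper, ≈1 mm on sand, versus a ≈0.1 mm threshold).

Sequences are truncated at 16 pairs and, when the wall rule is active, at
the first frame within 5 mm (≈ one body length) of an arena edge — on the
impenetrable substrate animals that reach the wall stay there, and scoring
stops at arrival.

## Duration trend models

Durations are modelled on the log10–log10 scale:

$$\log_{10} t_{ik} = \alpha_{s(i)} + \beta_{s(i)} \log_{10} k + u_i + v_i
\log_{10} k + \varepsilon_{ik},$$

for bout $k$ of individual $i$ on substrate $s(i)$, with a random
per-individual intercept $u_i$ (and slope $v_i$ for immobility — the richer
structure is the better model for immobility but is singular for movement)
reflecting the repeated design in which every sand-tested animal is also
tested on paper. Fitting is by REML through `lmerTest`; per-substrate slope
tests use Satterthwaite degrees of freedom, which is why fractional df are
reported. A singular random-slope fit falls back to intercept-only with a
warning rather than failing.

The three pairwise slope differences are tested on the fixed-effects
covariance with $Z = \Delta\hat\beta / \mathrm{SE}$ and a single-step
max-|Z| joint-normal multiplicity adjustment (the adjustment used by
standard post-hoc machinery; Bonferroni is available as a fallback — the
choice between them is a documented decision, not an inference from data).
Start-to-finish displacement is analysed the same way with
$\log_{10}$(displacement) as response, treatment means instead of slopes,
zero displacements floored at the 0.1 mm measurement resolution, and
per-substrate medians reported alongside.

## Tail-distribution comparison

`fit_tail()` fits the continuous exponential, power-law and log-normal
models to all durations at or above a lower bound `xmin`, by maximum
likelihood on the truncated densities: closed forms
$\hat\alpha = 1 + n / \sum_i \ln(x_i/x_{\min})$ (power law) and
$\hat\lambda = 1/(\bar x - x_{\min})$ (exponential); the truncated
log-normal likelihood is maximised numerically (Nelder–Mead, multiple
starts spread around the log-moment estimates, 1e-10 relative tolerance).
Durations carry 1 s precision but are treated as continuous. `xmin` is
chosen over the grid of observed values (excluding the two largest, so at
least two tail points remain) to minimise the Kolmogorov–Smirnov distance
between fitted and empirical tail distributions, with ties broken toward
the smaller bound because it discards less data.

`vuong_compare()` tests which of two non-nested fitted models is closer to
the truth: with pointwise log-density differences $d_i$ above a shared
bound, the statistic $\sum_i d_i / (s_d \sqrt n)$ is asymptotically standard
normal under the null that both are equally close; p-values are two-sided
plain-normal, without a degrees-of-freedom correction. `compare_all()` runs
the three pairwise comparisons with the shared-bound convention used in the
substrate tables — exponential-vs-log-normal above the log-normal's own
estimated bound, both power-law pairs above the power law's — and flags
significance at the Bonferroni level $\alpha' = 0.05/3 \approx 0.017$.

A power note: when the shared bound is itself the power law's KS-estimated
bound it typically lands deep in the tail (on simulated exponential data of
n = 2000, the median retained tail is ~180 points), where the exponential
and power-law densities are locally similar; in simulation the comparison
then favours the true exponential only ~78% of the time. Above a fixed
moderate bound the sign is essentially always correct and the statistic an
order of magnitude larger. Direction, not magnitude, is the robust feature
of these tests at field sample sizes, and the test suite asserts
accordingly.

## Dispersal profiles

Each individual's time axis is re-zeroed at the end of its PCI, and its
squared displacement from the position at that moment (MSD, mm²) or its
per-step speed (MIS, mm/s) is averaged within 14 log-spaced time bins
spanning 1.6 s (one coarse frame — the finest resolvable lag; the lower
edge is a documented choice, exposed as a parameter) to 5 400 s, each bin's
midpoint being the geometric mean of its edges. The across-individual mean
per bin is taken over the animals that have samples in the bin *and* have
moved by the bin's upper edge; the upper 95% t-confidence limit accompanies
it, and bins with fewer than two contributing individuals are dropped from
regression.

MSD profiles are fitted on log–log axes with a one-breakpoint segmented
regression (`segmented_fit()`): iterative linearisation of the working
model $y \sim x + (x-\psi)_+ + \mathbb{1}(x>\psi)$ with the update
$\psi \leftarrow \psi + \hat\gamma/\hat\beta_2$, step-halving damping, and —
because the update can 2-cycle on noisy 14-point profiles — a deterministic
fallback that profiles the residual sum of squares over 201 candidate
breakpoints. Whether a breakpoint exists at all is tested first with a
Davies-type supremum test of the hinge term over the interior design
points; when the null of no breakpoint survives at α = 0.05 the simple
regression is returned with both slopes equal. MIS profiles are fitted with
a simple regression on semi-log axes.

The diffusion regime is classified from the segment covering the most bins:
its 95% CI entirely below 1 is sub-diffusive, entirely above 1
super-diffusive, straddling 1 diffusive. On 2-D Brownian simulations the
binned MSD tracks the analytic $4Dt$ and classifies as diffusive.

## The synthetic study generator

`scenario_spec()` and `simulate_study()` generate a full three-substrate
study so that every stage of the pipeline is testable without any recording:
22 individuals on paper, 8 on each sand, with every sand-tested animal also
appearing on paper (ids are shared, enabling the random individual effect).
Per individual, bout $k$ durations are $10^{a_i + b_i \log_{10} k +
\varepsilon}$ with random intercept/slope deviations and log10-normal
residuals; sequences stop at 16 pairs or when the 90 min window is filled
(right-censoring, as in the arena). Tracks are rendered at 10 frames/s:
immobility is exact stillness plus isotropic 0.05 mm centroid jitter (to
exercise threshold logic), movement bout $k$ is a correlated random walk at
speed $\text{base} \times \text{trend}^{k-1}$ with wrapped-normal turning
angles and reflective walls; an animal reaching within 5 mm of a wall stops
for the rest of the record, and its bout record is clipped at arrival.

Default conditions (all overridable) encode the experimental design the
generator emulates: trend slopes −1.18 / −1.00 / −0.36 for immobility and
+1.16 / +0.38 / +0.01 for movement on paper / shallow / deep; immobility
intercept $10^{2.45} \approx 280$ s, putting PCI at the few-hundred-second
scale of this species (individual PCIs span roughly a second to over an
hour); first movements at the ~1 s scale on paper; random intercept SD 0.35,
random slope SD 0.15 and residual SD 0.45 on the log10 scale; substrate
speeds and turning noise (2.0 mm/s, accelerating, nearly straight on paper;
0.75 mm/s, decelerating, moderately tortuous on shallow sand; 0.8 mm/s,
strongly decelerating and tortuous on deep sand) calibrated once so the
median start-to-finish displacements come out near the design values of
114.5, 12.4 and 4.1 mm. Seeds derive per individual from a single root
seed, so cohorts are byte-reproducible and individuals independently
re-drawable.

### What the generator does and does not emulate

It reproduces the trend structure, the censoring mechanisms (window, wall,
16-pair cap), the repeated design, the sampling cascade (10 fps →
coarse-graining → thresholding) and the dispersal regimes. It does **not**
reproduce every marginal feature of field data: the trend-implied duration
marginals are log-normal mixtures whose tails are lighter than real
immobility-duration tails, so Vuong statistics on synthetic sand cohorts
are directionally right but much smaller in magnitude than on field data;
and because simulated paper-substrate animals stop at the wall, the late
accelerating phase of their speed profile is censored and the sign of the
fitted MIS-vs-log-time slope on paper varies between replicates. Passing
tests therefore demonstrate correctness of the estimators and the
direction of substrate effects, not magnitudes of field statistics.

## Numerical choices and degenerate inputs

* Times are seconds stored as doubles; comparisons with manually scored
  bouts use ±1 s plus one coarse step.
* Coarse-graining requires length ≥ 2^levels; shorter tracks error.
* `segment_bouts()` accepts a zero threshold (any positive step is
  movement) so noise-free synthetic tracks segment exactly.
* An all-still track is a single immobility bout spanning the record; bout
  durations always sum exactly to the segmented span.
* A bout table row whose record ends during an immobility period yields one
  fewer movement than immobility periods (`kM = kI − 1`), including the
  degenerate `kM = 0` of an animal that never moved again.
* Vuong comparison of a family with itself (zero variance of the pointwise
  ratio) returns statistic 0, p 1 rather than 0/0.
* The log-normal tail fit is the only numerical optimisation; everything
  else is closed-form or linear algebra.
* `pmvnorm` (single-step adjustment) is quasi-Monte-Carlo with ~1e-6
  absolute error; adjusted p-values are reproducible to that tolerance.

## Problem sizes used by the test suite

The suite regenerates everything it tests: the design-scale study (38
individuals, ~2 million raw track samples) once per seed; 200 replicates of
the bout-only cohort for the slope-coverage check; 100 replicates of n =
2000 samples for the Vuong sign check; 50 Brownian walkers of 2 000 samples
for the MSD calibration. These sizes keep a full run within a few minutes
on one CPU while leaving the Monte-Carlo assertions comfortable margins.

## Known limitations

* Burial state on sand (partial vs full submergence) is not inferable from
  centroid tracks and is out of scope.
* The breakpoint-existence test uses Davies' upper bound over the interior
  bin midpoints; with 14 bins its p-values are conservative.
* The pooled tail comparisons treat all bouts of a substrate as exchangeable
  (individuals pooled), matching the per-substrate sample sizes of the
  design; within-individual correlation of bout durations is ignored there
  (it is modelled in the trend LMMs).
* GAMM spline robustness checks of the trend models are intentionally not
  implemented; the log–log LMM is the primary model.
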