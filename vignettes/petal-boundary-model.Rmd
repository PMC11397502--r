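---
title: "A two-fate cell-array model of petal bullseye proportions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-fate cell-array model of petal bullseye proportions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bullseye)
```

## The problem

Many petals carry a bullseye: a pigmented proximal centre sharply separated
from an unpigmented distal periphery. In *Hibiscus trionum* the boundary
between the two zones sits at one third of the petal length from the base
and stays there while the petal grows roughly a hundredfold. The two
domains nevertheless behave very differently — distal cells keep dividing
for longer, proximal cells expand faster and end up about twice as large —
so the constancy of the *relative* boundary position is something to be
explained, not assumed. This package implements a one-dimensional
stochastic model of that growth, the observables and parameter scans used
to map which rate combinations maintain or shift the boundary, the
measurement pipeline that extracts boundary positions from segmented-cell
tables, rate estimators for staged summaries, and the analyses of
bumblebee choice experiments with bullseye-patterned discs. Because the
underlying microscopy datasets are not redistributable, a seeded
synthetic-data module emulates every input table with the statistical
structure reported for the real data; the synthetic generators are
first-class, tested code and serve as ground-truth oracles for the
pipeline.

## The model

The petal is a 1D array of cells from base to tip. Each cell carries a
fate, distal (0) or proximal (1), fixed at creation and inherited by
daughters; proximal cells form a contiguous block at the base. Two rules
drive the dynamics.

**Expansion.** A cell of length $l$ and fate $f$ grows logistically,
$$\frac{dl}{dt} = r_g(f)\, l \left(1 - \frac{l}{l_{max}}\right),$$
so relative growth slows as the cell approaches the maximum length
$l_{max}$. The logistic form is the canonical reading of "growth
proportional to length and to the distance from a maximal length", and
matches the sigmoid single-cell growth literature.

**Division.** A cell of fate $f$ divides at rate
$$d(f, L) = r_d(f)\, e^{-L / L_0(f)},$$
where $L$ is the *total* tissue length. Division halves the mother and
inserts the daughter immediately to her right, conserving length exactly.
The exponential factor shuts divisions down as the tissue grows, creating
the observed two-phase development — division-heavy early, expansion-heavy
late — and its fate-dependent scale $L_0(f)$ lets the two domains exit the
division phase at different times.

Simulations start from 21 cells of 0.1 µm (total 2.1 µm), the first seven
proximal, so the fate boundary starts at one third. They stop when $L$
reaches $L_{max} = 300$ µm, a ~140-fold increase mirroring the relative
growth of the real organ at a computationally convenient absolute scale.

### Parameters

| parameter | default | meaning |
|---|---|---|
| $r_g(0)$ | 0.91 /day | basal relative expansion rate, distal |
| $r_d(0)$ | 1.1 /day | basal division rate, distal |
| $l_{max}$ | 20 µm | maximum cell length |
| $L_0(0)$ | 30 µm (= 0.1 $L_{max}$) | division-decay scale, distal |
| $L_0(1)/L_0(0)$ | 0.6 | proximal cells exit the division phase earlier |
| $L_{max}$ | 300 µm | termination threshold |
| expansion ratio $r_g(1)/r_g(0)$ | 1 | scanned |
| division ratio $r_d(1)/r_d(0)$ | 1 | scanned |

Rates are per day. Proximal rates are defined relative to the distal ones
through the two ratios, which are the axes of all parameter scans.

**Orientation of the division-decay ratio.** The ratio of the two decay
scales could in principle be applied in either direction. We set
$L_0(1) = 0.6\, L_0(0) = 18$ µm — the proximal domain exits the
division phase earlier — because that orientation is the one consistent
with the observed biology: divisions persist longer in the distal region,
and the transient boundary rise mid-development traces to the proximal
domain stopping first. Under this orientation the model reproduces the
distal-longer division phase, an early transient boundary bump, and
end-to-end rate-ordering recovery; the opposite orientation reproduces
none of these.

### The engine

Division propensities depend on the continuously increasing $L$, so an
exact event-driven simulation would need time-varying propensities. We use
a fixed-step hybrid instead: per step of $dt = 0.01$ day, lengths are
updated deterministically from start-of-step values (clipped at
$l_{max}$ to guard the discretisation), then every cell divides
independently with probability $1 - e^{-d(f, L_{start})\,dt}$, divisions
applied at the end of the step in base-to-tip order with sequentially
assigned fresh identifiers. With the default rates the per-step division
probability stays near $10^{-2}$, where the Bernoulli approximation to the
inhomogeneous process is accurate; halving $dt$ moves ensemble-mean final
boundaries by well under 0.01, and a step whose maximum propensity times
$dt$ exceeds 0.5 triggers a warning. The per-step division count at frozen
length is verified against the analytic branching law in the test suite.
Replicate $i$ of an ensemble is seeded with $\mathrm{seed} + i - 1$, so
every trajectory is exactly reproducible.

Whether the original rule engine treated growth stochastically is not
documented; we chose deterministic growth because the growth rule has no
natural event quantum and the stochasticity of interest (division timing
and placement) is preserved.

## Observables, scans and the objective

Per snapshot the model reports the cell counts `nc0`, `nc1` and summed
lengths `tl0`, `tl1` of the two fate blocks. The three derived observables
are the boundary position $tl_1/(tl_0 + tl_1)$, the mean-length ratio
$(tl_1/nc_1)/(tl_0/nc_0)$ and the cell-number ratio $nc_1/nc_0$.
Trajectories are binned into 100 equal windows of simulation time (window
means), and additionally resampled at the window whose total length is
nearest to each tenth of the final length (earlier window on ties),
because tissue length, not wall-clock time, is the natural developmental
coordinate. The objective distance between two frames is the mean absolute
percentage error per observable over those ten points, averaged with equal
weight across the three observables.

`scan_ratios()` maps the ensemble-mean deviation of the final boundary
from its initial value (positive = tipward) over a grid of the two ratios.
The scanned ranges are free choices; we default to exploration
grids that are fine along the expansion axis (which dominates the
response) and log-spaced along the division axis, with a $[1,2]^2$ preset
for the boundary-shift regime. `maintenance_contour()` returns the grid
points with $|\mathrm{deviation}| \le 0.05$ and the Spearman correlation
of the log ratios over that set; in our runs the maintenance region shows
a clear anti-correlation (one rate compensating the other), the expansion
ratio moves the boundary far more than the division ratio, and the upper
corner of the $[1,2]^2$ grid shifts the boundary upward by well over 0.2
— the large-bullseye regime. Replicate counts are reported in every
result; we default to 50 replicates for trajectory ensembles with smaller counts inside
large scans, recording the exact number used alongside each estimate.

## Rate estimation

Between consecutive stages both cell counts and cell sizes are treated as
exponential, so the interval rate is
$k = (\ln v_{i} - \ln v_{i-1}) / (t_i - t_{i-1})$, converted to per-day
(stage times are entered in hours: S0a 1 h through S5 416 h). No rate is
computed into the first stage. Length-based rates are *effective* rates —
division halves lengths, so they conflate expansion and proliferation —
and approximate the basal expansion rate only in the final interval, once
divisions have essentially stopped; the test suite checks that the distal
late-phase length rate recovers the planted 0.91/day within 20%. Plotting
count rates against tissue length and fitting
$k = r_d e^{-L/L_0}$ by linear least squares on $\log k$ recovers the
division parameters; the fit is exact on noise-free points, while rates
averaged over long stage intervals flatten the apparent decay and inflate
$L_0$, which is inherent to the staged-summary design rather than to the
fitter. Genotype comparisons of ratios use the independence moment
formulas $E(X/Y) = E(X)E(1/Y)$ and
$\mathrm{Var}(X/Y) = E(X^2)E(1/Y^2) - E^2(X)E^2(1/Y)$, verified against a
$10^6$-draw Monte-Carlo oracle.

## The measurement pipeline

Boundary detection from cell tables follows the window-average procedure:
cells from a central lateral stripe (20% of the width) are binned into 5%
windows along the normalized base-to-tip axis (half-open, last window
closed); empty windows are filled by linear interpolation; the profile is
smoothed with a Savitzky-Golay filter (window 7 bins, polynomial order 2 —
chosen as the shortest filter that suppresses
single-window noise without flattening a one-window peak, and exposed as
arguments); and the boundary is the mean centre of all windows whose
smoothed value is within 2.5% of the maximum. We read "within 2.5% of the
window with the highest cell area" as 2.5% in smoothed *value* — the
positional reading would make both the smoothing and the averaging
pointless, since it would always return the argmax window. The value
reading also makes the estimate invariant to uniform rescaling of areas
and robust to plateau-shaped profiles. Planted-peak recovery over 100
synthetic profiles with peaks anywhere in [0.1, 0.5] achieves a mean
absolute error at or below half a window (0.025).

For pigmented stages the boundary is the midpoint between the last
pigmented and first unpigmented cell position, with an explicit
contiguity check. EdU nucleus densities are Gaussian kernel estimates
with Silverman bandwidth, reflected at both ends of the unit interval and
renormalized on the grid; bullseye proportions are plain pigmented/total
area percentages.

## Synthetic data: what it does and does not emulate

The generators plant the *reported statistical structure*: area-profile
peak positions per stage and genotype (one third for the wild type, 0.15
for the small-bullseye relative, a 0.2–0.5 plateau for the
overexpression line at S2E), flat profiles at S0a, distally biased
(Beta(3, 1.2)) versus uniform EdU positions, mature region contrasts
(proximal cells about twice as large; proximal:distal count ratios near
0.2 wild-type and 0.35 for the overexpressor, planted by two-piece
position sampling), pigment flags basal of the transition, multiplicative
lognormal area noise ($\sigma = 0.15$, set to match the replicate spread
visible in the published profiles), and logistic-in-visit-index learning
curves for bee choices. Functional forms (Gaussian bumps, smoothed
top-hat plateaus, the sigmoid proximal elevation at mature stages) and
per-stage cell counts (hundreds at S0a to thousands at S2E) are package
choices where no measured value is available. The generators do **not** emulate
spatial cell packing, cell-neighbour correlations, the croissant-shaped
lateral asymmetry (available only as an optional lateral phase shift),
curvature or 2D geometry. Tests passing on synthetic tables therefore
validate the *pipeline computations*, not claims about real petals:
in-planta quantities that depend on unavailable raw data (the
14.5%/2.1%/25% bullseye proportions, learning-curve endpoints and
chi-square values) are deliberately out of reach and are covered only by
property-style checks.

`gen_stage_series()` closes the loop between simulator and estimators: it
samples a simulated trajectory at the standard stage times rescaled to
the simulation duration and emits the per-stage, per-region summary table
the rate estimators consume, with the generating parameters attached.
Recovery is assessed on the simulation clock, which the table carries
alongside the nominal stage hours. The regional aggregation here uses the
simulator's own fate blocks; `region_summary()` provides the equivalent
split for measured cell tables.

## Behavioural analyses

Disc geometry is exact: a bullseye of inner diameter $d_i$ on a disc of
diameter $d_o$ pigments $100 (d_i/d_o)^2$ percent of the area (4, 16 and
36% for the three designs used with bumblebees). Preference tests use an exact
two-sided binomial test against 0.5 rather than a one-sample t test on
proportions — for binary counts at $n = 30$ the exact test avoids the
normality approximation. Learning
curves pool all bees and fit a binomial-logit
regression of correct choice on visit index; the likelihood-ratio
chi-square against the intercept-only model tests whether foragers learn,
and the 95% bands are pointwise Wald intervals computed on the link scale
(link-scale Wald is the standard construction for pooled GLM fits). Complete separation is detected and
flagged rather than silently reported.

## Numerical choices and degenerate inputs

* Time step $dt = 0.01$ day; hard upper bound 0.05; coarse-step warning.
* Growth clipped at $l_{max}$; simulations abort with a no-progress error
  after a configurable step budget when parameters cannot reach
  $L_{max}$ (e.g. zero expansion).
* Resampling tie-break: earlier time window.
* Empty profile windows: linear interpolation; edge windows extend the
  nearest observed value. Fewer windows than the filter length falls back
  to the unsmoothed profile with a warning.
* Ratios guard their denominators: empty fate blocks, empty regions and
  zero reference observables raise errors rather than returning NaN.
* All ensembles derive replicate seeds as base + replicate index.

## Problem sizes

The shipped analyses and tests run at desk scale, chosen to keep full
reruns fast while leaving Monte-Carlo error well inside every asserted
tolerance: 50-replicate ensembles for baseline trajectories, 12–20
replicates per grid point in scans (standard errors on final boundaries
of about 0.003–0.01), 100 profiles for detector recovery, $10^6$ draws
for the moment-formula oracle, and 20 seeds for end-to-end recovery.

## Known limitations

* The model is 1D: it addresses relative boundary position only, not
  petal width, curvature, or the lateral asymmetry of the early pattern.
* Fates are fixed initial conditions; fate specification dynamics and any
  signalling are outside scope.
* The scan characterises the maintenance and shift regimes
  qualitatively (deviation ≈ 0 versus ≥ 0.2); it does not pin particular
  scenario coordinates.
* Division-decay parameters recovered from staged summaries inherit the
  interval-averaging bias discussed above.
* The synthetic bee choices assume independent Bernoulli visits with a
  shared population learning curve; individual heterogeneity (fast and
  slow learners) is not modelled.
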