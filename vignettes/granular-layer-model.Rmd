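---
title: "The granular-layer recoding model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The granular-layer recoding model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(granulayer)
library(dplyr)
```

This vignette is the package's own account of the model it implements: the
assumptions behind each component, the parameters that matter and why their
defaults are what they are, the numerical choices in the fixed-point
iteration, and what the simulated conditions do and do not say about real
cerebellar circuits.

## The per-field recruitment model

A *cluster field* is the territory of one mossy fiber's terminal cluster.
The model fixes its census: `n_mf_per_field = 100` mossy fibers innervate
the field and `n_grc_per_field = 8750` granule cells live in it. Each
granule cell carries `n_dendrites = 4` dendrites, each contacted by exactly
one mossy fiber, and fires when at least `input_threshold = 3` of its
inputs are simultaneously active and not vetoed by Golgi inhibition at the
glomerulus.

Three independence assumptions make the recruitment count binomial:

1. **Random contact.** Which mossy fiber contacts which dendrite is
   uniform at random, so each dendrite is active with probability `x / y`
   when `x` of the field's `y` fibers are active.
2. **Per-glomerulus veto.** Golgi inhibition acts independently at each
   glomerulus with probability `p_veto`; a granule cell may be inhibited
   by a different Golgi cell on each dendrite, so vetoes are independent
   across dendrites *and* independent of which fiber is active.
3. **Cell independence.** Cells recruit independently. In the tissue one
   terminal contacts ~50 granule cells, which correlates their inputs;
   the model (like the equation it implements) ignores this. The
   *expected* count is unaffected; only trial-to-trial dispersion would
   change.

Under these assumptions the number of effective inputs per cell is
`Binomial(n, (1 - p_veto) x / y)` and the expected firing count is `N`
times its upper tail at `m`. `expected_firing_count()` evaluates the tail
with `pbinom`; the test suite checks it against an independent oracle that
enumerates all `2^n` dendrite configurations, and
`realize_threshold_counts()` gives the stochastic twin used in
realization-mode experiments (active dendrites per cell, then a binomial
thinning by the veto, so the firing count can never exceed the threshold
count within a draw).

## The Golgi feedback loop

Parallel-fiber activity is regulated by a loop: granule-cell firing raises
parallel-fiber density, Golgi cells read that density and raise the veto
probability, which lowers granule-cell firing. The package iterates this
map to a fixed point on a grid of `n_beams = 5` beams of
`fields_per_beam = 20` fields; the middle beam is the reported one, the
outer beams existing to give it realistic neighbors.

**Density to veto.** A Golgi cell receives `pf_per_golgi = 1600` of the
`pf_per_purkinje = 350000` parallel fibers crossing the territory, so its
expected active-input count is linear in beam activity
(`golgi_active_inputs()`). The translation to a veto probability is a
logistic in active inputs with hard anatomical anchors: no effect at or
below 4 active inputs, full effect at or above 16. Because only the floor
and saturation are anatomically given, the logistic's midpoint is set at
10 (the centre of the response range), and the curve is affinely rescaled
to hit exactly 0 at the floor and exactly `veto_max` at saturation —
without the rescaling the anchors would only be approached asymptotically
and the floor/saturation statements would be false at finite steepness.

**The drive on one field** (`field_drive()`) sums three terms:

* the field's whole-beam active-cell total, with the same-field
  contribution counted `local_weight = 2` times — a Golgi cell is much
  more likely to receive contact from a granule cell in its own field;
* `neighbor_weight = 0.1` times the corresponding drive of the sagittally
  adjacent field in each adjacent beam. The Golgi axonal plexus is
  sagittally elongated (~650 µm against a 200 µm field), so it reaches
  into the neighboring fields — but only with its outer fringe, and only
  over part of the neighbor, hence a weak coupling. Outer beams have one
  neighbor (no wraparound);
* a direct basal-dendrite term: Golgi basal dendrites sample
  `basal_contacts = 12` of the field's 100 mossy fibers, and direct input
  has an effect when at least `basal_mf_min = 4` of them are active — a
  hypergeometric tail probability, multiplied by `basal_boost`. The
  default `basal_boost = 2625` parallel-fiber equivalents equates a full
  basal effect with the width of the apical dynamic range: 16 − 4 = 12
  active parallel-fiber inputs, each worth `350000 / 1600` fibers of beam
  activity. The reasoning is that a Golgi cell sits near threshold, so
  direct mossy-fiber drive sufficient "for an effect" is comparable to
  driving its apical tree across its whole operating range. This term is
  what caps the regulated total at high input: the apical pathway alone
  reaches sigmoid saturation and cannot compensate further, while the
  basal tail probability keeps growing steeply with `x`.

**Iteration schedule.** All vetoes start at 0 (so the first pass computes
the unregulated baseline), and the update is damped:
`p <- (1 - damping) p + damping p_new` with `damping = 0.5`. The
count-to-veto-to-count map is decreasing, so undamped iteration can cycle;
halving the step converges on every grid in the test matrix. Iteration
stops when no field's firing count changes by more than `tol = 0.01`
relative (counts below 1 are compared against 1 to avoid division blow-up
in nearly silent fields), with a cap of `max_iter = 50`; hitting the cap
flags the result `converged = FALSE` rather than erroring, because a
diagnosable non-convergence is data, not a crash. Expectation mode (the
default) uses analytic per-field counts and is bit-reproducible given the
input grid; realization mode draws Monte-Carlo counts inside the loop for
stochastic experiments.

## Calibrating the free gain

The anatomy pins the sigmoid's floor and saturation but not its maximum
`veto_max` or steepness. What the model does specify is *behaviour*:
across wide per-field input ranges the regulated beam total should sit on
a flat plateau while the unregulated total climbs steeply, and a very high
input range should push the regulated total slightly *down* again, as the
direct basal pathway overshoots.

`calibrate_gain()` therefore grid-searches `veto_max` and
`sigmoid_steepness` to minimize the coefficient of variation of mean
regulated middle-beam totals across the plateau ranges (5–25, 10–25,
15–30 active fibers per field), subject to two eligibility constraints:

1. every trial's fixed point must converge — a non-converged state is not
   a regulated state, however flat the resulting means look; and
2. the 20–30 range must regulate strictly below the 15–30 range — the
   basal-pathway signature. Without this constraint the minimum-spread
   candidates park the loop at sigmoid saturation, where the plateau is
   flat but the high-range fall is structurally impossible (a stable
   decreasing-feedback equilibrium can only fall with rising input
   through a separate pathway, and at saturation there is none).

The same per-trial input draws are reused for every candidate, so the
comparison is paired and deterministic given the seed. The package
defaults `veto_max = 0.6`, `sigmoid_steepness = 0.6` were frozen from this
procedure at build time and are not re-derived at run time; the
calibration remains available (`calibrate` subcommand) for users who
change the anatomy.

## Rate recoding and the top slice

The second recoding channel treats each threshold-eligible granule cell as
a random sample of `sample_size = 3` distinct mossy-fiber rates — one per
dendrite, without replacement within a cell (a cell's dendrites contact
different fibers), with replacement across cells. With `n_samples = 4500`
eligible cells per beam (the standard estimate of cells receiving three or
four active inputs) the distribution of per-cell mean input rates
approaches a normal distribution by the central limit theorem whatever the
parent shape. Four parent shapes spanning 50–300 Hz over
`n_active_mf = 300` fibers are built in: an even grid, i.i.d. uniform
draws, uniform draws with excluded bands (defaults 100–130 and 200–240 Hz),
and draws weighted toward the top of the range (density ∝ u², drawn by
inverse CDF). The 300 active fibers are treated as an independent
parameter of this experiment, not derived from the beam simulation's input
range.

Only the `top_slice_size = 1200` cells with the highest mean input fire
after glomerular competition — the regulated count from the feedback
experiment. `select_top_slice()` is an exact top-k order statistic with
stable tie-breaking (earlier-indexed cells win), so its minimum equals the
k-th largest sample mean by construction.

`recoding_summary()` generates one rate population and **one set of
sampling draws per shape**, then applies location shifts to the shared
population. This makes translation equivariance exact — shifting the
population by +c shifts the top-slice mean by exactly +c — so the linear
fit of top-slice mean against population mean has unit slope and R² = 1 up
to floating-point error, and R² is computed directly from residuals
because `summary.lm()` warns on exact fits. Resampling per shift would
only blur this with Monte-Carlo noise around the same line.

One testing subtlety: the approach to normality is asserted on skewness
for the top-weighted shape (parent skew ≈ −0.57, far above estimator
noise) but on excess kurtosis for the discontinuous shape. With the
default gap bands the gapped uniform is almost symmetric (theoretical skew
+0.03, below the ≈0.14 standard error of a skew estimate at n = 300), so
a skew comparison there is dominated by noise; its strong platykurtosis
(excess kurtosis ≈ −1.2) is the feature the sampling distribution
measurably loses.

## Pattern overlap

With a fraction `p_active` of parallel fibers active per stored pattern
and membership independent across patterns, the share of a pattern's
synapses lying in exactly `k` of `n_other` other patterns is the binomial
mass `C(n,k) p^k (1-p)^(n-k)` (`overlap_proportions()`). The Monte-Carlo
oracle (`simulate_pattern_overlap()`) instead stores patterns as
fixed-size random subsets — the density is functionally fixed in the
model — which is hypergeometric rather than Bernoulli membership; at the
standard densities (1200 to 17,500 of 350,000) the discrepancy is far
inside the total-variation tolerance used to compare them. The
law-of-large-numbers check compares total-variation distance at a fixed
activity fraction while scaling the fiber count tenfold; growing the
active count at fixed total fibers would also raise the density, spreading
the spectrum and raising absolute multinomial error, which is why the
naive "more active fibers, closer agreement" comparison is not the right
test.

## What the generator emulates, and what it does not

The synthetic input is exactly the model's stated regime: per-field active
mossy-fiber counts uniform on 3–30 (the standard experiment) or on the
plateau ranges, firing rates drawn from the four stylized shapes, patterns
as uniform random subsets. It does **not** emulate temporal dynamics
(feedback lag, spillover integration windows, burst structure), spatial
correlation of mossy-fiber activity along a beam, stratified
superficial/deep Golgi populations, gap-junction coordination, or any
synaptic plasticity. Passing tests therefore show that the *population
arithmetic* of the model behaves as claimed under its own assumptions —
they are silent on whether real granular-layer tissue satisfies those
assumptions.

## Problem sizes and runtime choices

The standard experiments use 100 trials of the 5 × 20 grid in expectation
mode (a few seconds), 40 trials per input range for the homeostasis
checks, 4500 samples of size 3 with a 1200-cell top slice for rate
recoding, and 5 stored patterns of 1200 of 350,000 fibers for the overlap
oracle; the Monte-Carlo/analytic agreement checks use a few thousand
realizations per grid point, enough for three-standard-error comparisons.
These sizes are the model's own stated conditions wherever it states them;
where a count is free (oracle repetitions, calibration trials) it was
chosen to make the relevant standard error small against the tolerance
being asserted.

## Known limitations

* The expectation-mode fixed point treats per-field counts as continuous;
  realization mode exists but is slower and noisier, and calibration is
  defined on expectation mode.
* The veto sigmoid's midpoint, the local/neighbor weights and the basal
  anchoring are design choices constrained only by qualitative anatomy;
  all are exposed in `golgi_feedback_params()` and the JSON config, and
  different choices rescale the regulated level while preserving the
  plateau behaviour the calibration enforces.
* The top slice is selected by mean input rate (top-k); selecting by
  realized veto outcomes instead would blur the slice's lower edge but
  leave its mean tracking the population mean.
* At input threshold 2 with the veto disabled the maximum unregulated
  beam total over 100 trials sits near 10% of the parallel-fiber count by
  construction, and its sampling distribution straddles that round figure;
  it is reported as computed rather than forced under it.
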