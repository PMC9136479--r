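# granulayer

A seeded, testable simulator of how the granular layer of the cerebellar
cortex recodes mossy-fiber input into parallel-fiber activity. It is aimed
at computational neuroscientists who want a compact, reproducible
implementation of the binomial threshold/veto population model of granule
cell recruitment, the Golgi-cell feedback loop that holds parallel-fiber
activity in a narrow homeostatic range, the central-limit-theorem conversion
of mossy-fiber firing rates into granule-cell "sample means" with top-slice
selection, and the binomial overlap spectrum of stored parallel-fiber
patterns.

## The model

**Per-field recruitment.** A cluster field contains N = 8750 granule cells
and receives y = 100 mossy fibers, of which x are active on a given trial.
Each granule cell has n = 4 dendrites, each contacted by one mossy fiber;
Golgi inhibition at a glomerulus vetoes the effect of an active input with
probability P(v), independently per dendrite. A cell fires if at least
m = 3 of its inputs are active and un-vetoed, so the expected number of
firing cells is

    E(f) = N * P( Binomial(n, (1 - P(v)) * x / y) >= m )

`expected_firing_count()` computes this; `realize_threshold_counts()` is its
Monte-Carlo twin.

**Golgi feedback.** Granule-cell axons form parallel fibers whose activity
density drives Golgi cells (1600 parallel-fiber contacts each, of the
350,000 fibers crossing a Purkinje territory), which in turn set the veto
probability through a sigmoid with no effect below 4 active inputs and
saturation above 16. `run_beam_regulation()` iterates this loop to its fixed
point on a grid of 5 beams x 20 fields (with same-field weighting, weak
sagittal-neighbor coupling, and a direct basal mossy-fiber effect on Golgi
cells); `run_trials()` repeats it over trials with per-field input drawn
uniformly from 3..30. `calibrate_gain()` tunes the free sigmoid parameters
against the homeostasis plateau.

**Rate recoding.** Each granule cell that meets threshold averages the
rates of the 3 mossy fibers it samples, so the distribution of mean input
rates across ~4500 eligible cells approaches a normal distribution whatever
the parent distribution of mossy-fiber rates (50-300 Hz, four shapes
provided). Only the "top slice" (the 1200 cells with the highest mean
input) fires after glomerular competition; its mean tracks the mossy-fiber
population mean linearly. See `recode_rates()` and `recoding_summary()`.

**Pattern overlap.** With a fraction p of parallel fibers active per stored
pattern, the proportion of a pattern's synapses shared with exactly k of n
other patterns is C(n, k) p^k (1-p)^(n-k); `overlap_proportions()` computes
the spectrum and `simulate_pattern_overlap()` checks it by simulated
pattern storage.

## Worked example

```r
library(granulayer)

tr <- run_trials(n_trials = 100, seed = 1)
glance(tr)
#> # A tibble: 1 x 9
#>   n_trials mean_regulated sd_regulated mean_unregulated sd_unregulated
#>      <int>          <dbl>        <dbl>            <dbl>          <dbl>
#> 1      100          1174.         78.7            4253.           970.
#>   regulated_density mean_all_inputs n_converged mean_iterations
#>               <dbl>           <dbl>       <int>           <dbl>
#> 1           0.00335            313.         100            11.5
```

Of the ~4250 granule cells per beam that meet the input threshold on an
average trial, Golgi regulation lets about 1174 fire — roughly 0.34% of the
350,000 parallel fibers crossing a Purkinje territory — and the regulated
total varies far less across trials (sd 79) than the unregulated one
(sd 970). All 100 fixed-point iterations converged.

```r
glance(recoding_summary(seed = 1))
#> # A tibble: 4 x 4
#>   shape          slope intercept r_squared
#>   <chr>          <dbl>     <dbl>     <dbl>
#> 1 discontinuous      1      54.9         1
#> 2 top_weighted       1      31.1         1
#> 3 uniform_grid       1      52.4         1
#> 4 uniform_random     1      53.3         1
```

For every rate-population shape the top-slice mean follows the mossy-fiber
population mean with unit slope: the recoded rate signal is a faithful
linear code for the input mean.

```r
overlap_proportions(4, 0.00343)
#> # A tibble: 5 x 2
#>       k proportion
#>   <int>      <dbl>
#> 1     0   9.86e- 1
#> 2     1   1.36e- 2
#> ...
```

At the regulated activity density, 98.6% of a stored pattern's synapses
participate in no other pattern of five stored.

A thin CLI (`exec/granulayer`, a two-line Rscript over `run_cli()`) wraps
the same functions:

```sh
exec/granulayer beam --threshold 3 --trials 100 --seed 1 --out out/
exec/granulayer overlap --seed 1 --out out/
```

Every run writes RFC-4180 CSVs plus a `run_meta.json` sidecar (seed,
parameter hash, package version); identical configuration and seed
reproduce all outputs byte for byte.

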