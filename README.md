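# punctakit

Quantitative analysis of starvation-induced protein agglomeration
("body" formation) in budding yeast. When glucose runs out, the
TORC1 subunit Kog1 (Raptor in mammals) leaves the vacuolar membrane and
condenses into a single perivacuolar body per cell; body formation
depends on AMPK/Snf1-dependent phosphorylation and on two
glutamine/asparagine-rich prion-like motifs, and it modulates TORC1
reactivation. Studies of this kind lean on four quantitative workhorses,
all of which this package implements as a tested, composable toolchain
for experimentalists and for anyone benchmarking such analyses on
simulated data:

1. **Band-shift densitometry** — TORC1 activity is read out from the
   electrophoretic mobility of its substrate Sch9: phosphorylated
   species migrate more slowly. Each gel lane is collapsed to a 1-D
   trace, total-signal normalized to the t = 0 control, and scored with
   a position-weighted sum in which the first pixel (top of gel) carries
   weight 100 ("100% phosphorylated"), the last carries 0, and interior
   pixels interpolate linearly. Raw scores are then mapped through the
   affine transform `s ↦ A·s + B` fixed by two anchor lanes, so that
   wild type in 2% glucose reads exactly 1.0 and wild type after 60 min
   at 0% glucose reads exactly 0.0.
2. **Exponential kinetics** — the fraction `f(t)` of cells containing a
   body is fit by nonlinear least squares to
   `f(t) = A·(1 − e^(−t/τ)) + c` (starvation / formation) or
   `f(t) = A·e^(−t/τ) + c` (repletion / dissociation), where `A` is the
   responding fraction, `τ` the apparent time constant in minutes and
   `c` the baseline; conditions with no change are fit to a line.
3. **Prion-like motif (Q/N) quantitation** — Q/N counts and percentages
   for stated sequence intervals (the Table-style quantitation), a
   transparent sliding-window compositional scanner for Q/N-rich
   intervals, and in-silico glutamine→alanine motif disruption.
4. **Exact viability inference** — Fisher's exact test for 2×2
   clone-count tables (e.g. 7/10 loop-out clones retain a
   non-phosphorylatable allele while 0/20 retain a phosphomimetic one),
   with the hypergeometric kernel built from exact integer
   combinatorics.

Because the raw micrographs and gels behind such experiments are rarely
deposited, a first-class **simulation module** generates every input
with known ground truth — two-band gel lanes, binomially sampled time
courses, motif-bearing protein sequences, and two-channel 3-D cell
stacks with membrane rings and planted foci — so the whole pipeline is
testable end to end, including automated foci counting and two-channel
co-localization on maximum projections.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` / `augment()` on fitted objects, `autoplot()` figures, and a
YAML-configured `run_pipeline()` with per-stage seed substreams,
provenance headers and byte-reproducible outputs.

## Worked example

Simulate a glucose-starvation time course at a typical design (3
replicates, 200 cells scored per timepoint), fit the formation model,
score a simulated gel, and test a clone-count table:

```r
library(punctakit)

tc  <- simulate_timecourse("formation", A = 0.49, tau = 11, c = 0.08,
                           seed = 42)
fit <- fit_body_kinetics(tc, "formation")
tidy(fit)
#> # A tibble: 3 × 3
#>   term  estimate std_error
#>   <chr>    <dbl>     <dbl>
#> 1 A       0.476     0.0270
#> 2 tau     9.59      1.25
#> 3 c       0.0771    0.0238
```

The true parameters (A = 0.49, τ = 11 min, c = 0.08) are recovered
within roughly one standard error each: at this design about half the
cells form a body, with a ~10-minute apparent time constant, on an 8%
baseline. `autoplot(fit)` draws the data with the fitted curve.

```r
batch <- simulate_lane_batch(tibble::tibble(
  lane_id = c("wt_2pct", "snf1", "wt_0pct"),
  phospho_fraction = c(1, 0.55, 0)), noise_sd = 6, seed = 42)
score_bandshift_batch(batch, "wt_2pct", "wt_0pct")
#> # A tibble: 3 × 3
#>   lane_id    raw normalized
#>   <chr>    <dbl>      <dbl>
#> 1 snf1    73641.      0.530
#> 2 wt_0pct 51591.      0
#> 3 wt_2pct 93178.      1
```

The anchors land on exactly 1 and 0 by construction; the mutant lane's
normalized score (0.53) estimates its true phosphorylated fraction
(0.55) up to gel noise.

```r
fisher_exact(c(7, 3, 0, 20))
#> # A tibble: 1 × 6
#>       a     b     c     d alternative   p_value
#>   <int> <int> <int> <int> <chr>           <dbl>
#> 1     7     3     0    20 greater     0.0000589
```

Observing 7/10 retained clones for one allele but 0/20 for another is
incompatible with chance at p ≈ 5.9 × 10⁻⁵ — the exact enumeration
behind a "p < 0.0001" claim.

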