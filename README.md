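# chipnorm

Data-adaptive normalization of ChIP-seq samples against their matched
controls.

## The problem

Reads in a ChIP-seq sample are a mixture: a fraction Π₀ comes from
non-specific background and the rest from genuine enrichment (transcription
factor binding sites, histone-modification domains). To test enrichment
against an input/control sample, the control must be scaled — not by the raw
sequencing depth ratio N₁/N₂, but by the **normalization factor**

    r = Π₀ · N₁ / N₂ ,

the ratio that aligns the *background* component of the ChIP sample with the
control. Because Π₀ ≤ 1, the depth ratio is only an upper limit; using it
directly makes peak calling conservative and distorts sample-swap FDR
estimates. Π₀ itself is an experiment quality indicator (antibody
specificity, enrichment efficiency).

`chipnorm` estimates r and Π₀ with a data-adaptive search, and ships the
surrounding machinery needed to study such estimators: four classical
comparator estimators, a ground-truth simulator, a two-stage binomial peak
caller, and sample-swap empirical-FDR evaluation.

## The estimator

The genome is partitioned into bins of width w; n₁ᵢ and n₂ᵢ are the ChIP and
control counts of bin i and nᵢ = n₁ᵢ + n₂ᵢ. Given a set B of background
bins, the plug-in estimate is

    r̂ = Σ_{i∈B} n₁ᵢ / Σ_{i∈B} n₂ᵢ .

Low-total bins are the most likely to be pure background (low bias), but few
of them means high variance. For each fixed w, the package scans thresholds
t over the ascending distinct observed totals with B_w(t) = {i : nᵢ ≤ t},
starting at the upper quartile of the non-empty bins (|B_w(t)| ≥ 0.75·m_w),
and stops at the first t whose estimate is ≥ the estimate at the previous
total — the point where the flat background limb ends and signal reads start
inflating the ratio. Bin widths are then searched over the grid
{100, 200, 500, 1000, 2000, 5000, 10000} bp, stopping at the first width
whose successor no longer decreases the estimate (the estimates are bound to
rise towards the depth ratio as w grows towards the genome size).

Comparators implemented behind the same interface:

| method | background set | convention |
|---|---|---|
| `cisgenome` | bins with total count ≤ 1 | w = 100 bp |
| `spp` | bins not Poisson-extreme in either sample (p > 1e-5) | w = 1000 bp |
| `ccat` | iterative: B from +strand counts, r̂ from −strand counts | w = 1000 bp |
| `peakseq` | OLS slope of ChIP on control bin counts | w = 10 Kbp, Pf = 0 |

## Worked example

Simulate a paired sample with known ground truth (shared non-uniform
background, 1000 point-source sites, 20 control-only artifact piles), then
estimate r with all five methods and call sites with sample-swap FDR
control:

```r
library(chipnorm)
genome <- genome_layout(c("chrI", "chrII"), c(3e6, 3e6))
sim <- simulate_dataset(genome, setting = 2, background_depth = 1e5,
                        c_signal = 0.5, seed = 11)
sim
#> <simulated_dataset> setting 2: N1 = 147745, N2 = 100500, true r = 1.0000, true pi0 = 0.6768

est <- estimate_all(sim$chip, sim$control, genome)
est$summary[, c("method", "r_hat", "pi0_hat", "w_star", "t_star")]
#>      method  r_hat pi0_hat w_star t_star
#> 1      ncis 1.0120  0.6884    100      5
#> 2 cisgenome 0.9951  0.6769    100      1
#> 3       spp 1.0842  0.7375   1000     NA
#> 4      ccat 1.0070  0.6850   1000     NA
#> 5   peakseq 0.8102  0.5511  10000     NA

r <- est$results$ncis$r_hat
sw <- swap_fdr_call(sim$chip, sim$control, genome, r)
sw
#> <swap_fdr_result> declared 750 site(s); R_C = 750, R_I = 35, empirical FDR = 0.04667
evaluate_calls(sw$declared, sim$true_sites)
#> <eval_result> declared 750: TP 745, FP 5, realized FDR 0.006667, power 745
```

The adaptive estimate (1.012) and the low-count estimate (0.995) sit near
the true factor 1 despite the artifacts; the strand-split iteration is
pulled slightly low by them and the regression slope is attenuated by count
noise. With r̂ in hand, the two-stage binomial caller (100 bp scan at
p ≤ 0.05, 20 bp localization, ±110 bp windows, success probability
r̂/(1+r̂)) declares 750 sites at nominal swap-FDR 0.05; 745 of them fall
within 100 bp of a true site (realized FDR 0.007).

From a shell, the same run is:

```sh
chipnorm estimate --chip chip.tagAlign --control control.tagAlign \
    --chrom-sizes genome.sizes --method all --out results/
```

## Documentation

The methods vignette (`vignettes/normalization-methods.Rmd`) describes the
model and its assumptions, what the simulator does and does not emulate,
the numerical conventions (tie-breaks, fallbacks, degenerate inputs) and
known limitations of each estimator.
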