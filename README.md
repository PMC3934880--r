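# bsnorm

Between-sample normalization for RNA-seq when the total (polyA+) mRNA
content per cell or embryo differs between the samples being compared —
as it does across early embryonic stages, after transcriptional
amplification, between tissues, or under cellular stress.

Depth-targeted sequencing erases global content differences: every
library is sampled to its own read total, so methods that equalize totals
(reads per million, TMM-scaled expression) silently assume equal mRNA
content and bias every fold change when that assumption fails — changes
are underestimated while content rises and overestimated while it falls.

**Biological scaling normalization (BSN)** reintroduces the global signal
from an explicit per-sample scale. With raw counts $R_{ij}$, library
sizes $R_j$, and global fold-change scales $Z_j$ (content relative to a
reference sample):

$$E_{ij} = \frac{R_{ij}}{R_j}, \qquad \bar R = \frac{1}{n}\sum_j R_j,
\qquad L_j = \bar R\,Z_j, \qquad N_{ij} = E_{ij}\,L_j .$$

Column $j$ of the normalized matrix sums to $L_j$: sample totals track
the biology instead of being flattened. The scales come either from
laboratory measurements of polyA+ RNA percentages (`bio_scales()`) or
from the counts themselves via TMM factors (`tmm_content_scales()`),
which work when a minority of genes changes but are blind to uniform
global shifts.

The package also provides the baselines and benchmark machinery needed to
evaluate any of this: RPM/RPKM and voom-style TMM log2 values, Livak
(2^-ΔΔCt) and Pfaffl (efficiency-calibrated) RT-qPCR fold changes against
a spike-in reference, a negative-binomial simulator of global expression
shifts with known ground truth, and closest-method / percent-excess
comparisons. Everything is tibble-in, tibble-out and pipe-friendly, with
`tidy()`/`glance()` summaries and ggplot2 `autoplot()` methods.

## Worked example

Simulate the pre-ZGA polyadenylation regime (70% of genes gain polyA+
representation; content rises ~1.55x while sequencing depth stays flat),
then compare the three normalizations against the known truth:

```r
library(bsnorm)

cfg   <- sim_config(scenario = "pre_zga_polyadenylation", seed = 1)
truth <- simulate_truth(cfg)
truth
#> <sim_truth> pre_zga_polyadenylation: 5000 genes x 5 stages, f=0.70, phi=0.1
#> realized content ratios: 1-cell=1.000, 16-cell=1.193, 128-cell=1.392,
#>   3.5hpf=1.540, 5.3hpf=1.540

counts <- simulate_counts(truth)
lib_sizes(counts)          # depth is decoupled from content
#>  1-cell  16-cell 128-cell   3.5hpf   5.3hpf
#> 5026132  4951764  4971264  4993719  5023105

pair <- "3.5hpf/1-cell"
fc <- combine_fold_changes(
  bsn = fold_changes(bsn(counts, truth$scales), pair),
  rpm = fold_changes(rpm(counts), pair),
  tmm = fold_changes(tmm_log2(counts, tmm_factors(counts)), pair),
  benchmark = true_fold_changes(truth, pair))

glance(compare_to_benchmark(fc))
#> # A tibble: 3 × 4
#>   method credit closest_share mean_abs_delta
#>   <chr>   <dbl>         <dbl>          <dbl>
#> 1 bsn      3335         0.667          0.534
#> 2 rpm       945         0.189          0.748
#> 3 tmm       720         0.144          0.719

mean(fc$bsn - fc$benchmark)   #  0.0098  (BSN: unbiased)
mean(fc$rpm - fc$benchmark)   # -0.614   (RPM: ~ -log2(1.54), the content shift)
percent_excess(fc, "bsn", "rpm")
#> 54.0  # BSN fold changes exceed RPM by the content shift, ~54%
```

BSN with the true scales estimates per-gene log2 fold changes without
bias; RPM inherits a bias of exactly −log2 of the content ratio on every
gene, and the TMM-normalized values fare slightly worse still. The same
run shows the count-derived scale estimator's documented blind spot: with
70% of genes shifted, `tmm_content_scales(counts, "1-cell")` reports
scales near 1 despite the 1.54x true content rise — which is why
laboratory scales are worth measuring.

Fold-change panels and per-sample distribution plots come from
`plot_fold_changes(fc)` and `autoplot()` on any normalized table; the
vignette (`vignettes/biological-scaling-normalization.Rmd`) documents the
model, the scale estimators, the qPCR benchmark math, the simulator's
assumptions and the package's numerical choices.

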