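---
title: "Normalizing RNA-seq when total mRNA content differs between samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalizing RNA-seq when total mRNA content differs between samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsnorm)
library(dplyr)
```

## The problem

Standard between-sample normalization of RNA-seq counts — reads per million
(RPM/RPKM), or scaling by trimmed-mean-of-M-values (TMM) factors — assumes
that the compared samples contain roughly equal amounts of (polyA+) mRNA
per biological unit, so that any global difference in counts is technical.
That assumption fails in many real designs. In early zebrafish
embryogenesis, cytoplasmic polyadenylation moves a large share of maternal
transcripts into the polyA+ pool before zygotic genome activation (ZGA),
raising the polyA+ mRNA amount per embryo by half or more; after ZGA,
miRNA-driven decay shrinks it again. Sequencing cannot see any of this: a
library is sampled to a target depth, so the per-sample read total reflects
the sequencer, not the embryo. Normalizing such samples toward equal totals
actively *removes* the biology — fold changes are underestimated while
content rises and overestimated while it falls.

Biological scaling normalization (BSN) keeps the global signal by
reintroducing it from an external estimate of each sample's relative mRNA
content, the *global fold-change* $Z_j$.

## The model

Let $R_{ij}$ be the raw read count of gene $i$ in sample $j$ and $R_j =
\sum_i R_{ij}$ the library size. BSN proceeds in four steps:

1. concentrations $E_{ij} = R_{ij} / R_j$ (each column sums to 1);
2. average library size $\bar R = \tfrac1n \sum_j R_j$;
3. pseudo library sizes $L_j = \bar R \, Z_j$;
4. normalized values $N_{ij} = E_{ij} \, L_j$.

Column $j$ of the result sums to $L_j$, so sample totals follow the scales
instead of being equalized. Two algebraic identities anchor the test suite:

* **Scaling identity.** For every gene, the linear BSN fold change between
  samples $j_1, j_2$ equals the RPM fold change times $Z_{j_2}/Z_{j_1}$.
  BSN and RPM differ *only* by the global scale ratio; with constant
  scales they coincide up to the factor $\bar R/10^6$.
* **Conservation.** $\sum_i N_{ij} = \bar R Z_j$ exactly.

The consequence for benchmarking is a closed form: the mean percent excess
of BSN over RPM fold changes, $\mathrm{mean}_i(FC^{BSN}_i/FC^{RPM}_i - 1)
\times 100$, equals $(Z_{j_2}/Z_{j_1} - 1) \times 100$ for any gene set
that involves no zero-count offsets.

## Where the scales come from

**Laboratory scales** (`bio_scales()`). From replicated measurements of
total and polyA+ RNA amounts (ng, from a fixed number of embryos) per
stage, the polyA+ percentage $p_j = \overline{\text{polyA}} /
\overline{\text{total}} \times 100$ is formed — amounts are averaged across
replicates *before* the ratio, giving one percentage per stage — and
$Z_j^{Bio} = p_j / p_{ref}$ with the 1-cell stage as reference.
Percentages rather than absolute amounts are used because absolute yields
have high replicate variance; the ratio also makes the scales
unit-invariant. A polyA+ amount exceeding its paired total is flagged, not
rejected: on nanogram quantities this is ordinary measurement noise.

**Count-derived scales** (`tmm_factors()`, `tmm_content_scales()`). The
TMM factor between a sample and a reference column is the doubly trimmed
(30% on M-ranks, 5% on A-ranks, union of drops), inverse-variance-weighted
mean of per-gene log2 fraction ratios, computed over genes positive in
both samples, with the reference column chosen as the one whose upper
quartile of count fractions is nearest the mean (ties to the lowest
index). Factors are renormalized to geometric mean 1. These are
*normalization factors*: a sample whose content rose gets a factor below
1, because the unchanged genes' fractions are diluted. The content-ratio
view needed for comparison with $Z^{Bio}$ — and for use in BSN — is the
reciprocal, optionally rebased so the earliest stage equals 1
(`tmm_content_scales()`). The factor view feeds `tmm_log2()`, which
produces the familiar offset log2-CPM values over effective library sizes
$R_j Z_j^{TMM}$; those are the third method in the comparison and their
fold changes are plain differences.

The square-root transform of scales (`sqrt_transform()`) is retained as
the conservative historical variant; on benchmark comparisons the
untransformed scales are the more accurate choice, so it is not a default
anywhere.

**Replicated designs** (`bsn_replicates()`). With several replicates per
stage, replicates are first put on their stage's mean library size,
averaged genewise into one column per stage, scales are estimated on that
stage-averaged matrix (count-derived by default; a supplied laboratory
scale set is equally valid), and every replicate is then reassigned its
stage's pseudo library $L_s = \bar R Z_s$, with $\bar R$ the mean over all
original samples. With one replicate per stage and supplied scales this
reduces exactly to `bsn()`.

## The qPCR benchmark

RT-qPCR against an exogenous spike-in (polyadenylated kanamycin RNA added
at a fixed amount per embryo pool) provides per-embryo fold changes that
are independent of sequencing depth. `livak()` implements
$2^{-\Delta\Delta Ct}$: per stage and replicate, $\Delta Ct$ against the
spike-in reference (replicates paired by id; unpaired replicates fall
back to the stage-mean reference Ct), then $\Delta\Delta Ct$ against the
control stage's mean, aggregated as the geometric mean across replicates
with the sd of the replicate log2 values as dispersion. `pfaffl()`
replaces the assumed doubling with measured primer efficiencies,
$E_t^{\Delta Ct_t} / E_r^{\Delta Ct_r}$, and reduces exactly to Livak at
$E = 2$. Replicate $\Delta Ct$ spreads above one cycle are flagged but not
rejected. Fold changes between arbitrary stage pairs are differences of
control-referenced log2 values (`qpcr_pair_fold_changes()`).

## What the simulator emulates — and what it does not

`sim_config()` / `simulate_truth()` build a five-stage developmental
series (1-cell through 5.3 hpf) with known per-embryo abundances
$T_{ij}$:

* **pre_zga_polyadenylation** — 70% of genes shift upward, with per-stage
  content targets (1, 1.2, 1.4, 1.55, 1.55). The 70% matches the measured
  share of maternal transcripts gaining polyA+ representation, and the
  1.55x plateau sits centrally in the reported 50–70% content increase.
* **post_zga_decay** — 30% of genes decay strongly in the final stage,
  content target 0.75. With a shifted fraction $f$ the reachable decay
  floor is $1 - f$ (shifted genes cannot fall below zero), so at
  $f = 0.3$ the measured 0.6–0.7x fall is unreachable; 0.75 is the
  closest round value that keeps the minority-change regime (and with it
  the TMM-recovery property) intact. Stronger decays are available by
  raising $f$ in a custom configuration.

Baseline abundances are log-normal (meanlog $\log 200$, sdlog 1 — a
realistic four-decade dynamic range with essentially no zero-count genes
at the default depth). Per stage, the mean multiplier over shifted genes
is solved exactly from the realized baseline so the expected content hits
the target; individual multipliers are log-normal around it (sdlog 0.25)
with a per-gene responsiveness shared across stages. The *realized*
content ratios from summation, not the nominal targets, are stored as
truth.

Counts allocate depth by relative abundance, $\mu_{ij} = D_j \,
T_{ij}/C_j$ — the mechanism that erases global shifts from raw counts —
with negative binomial noise, variance $\mu + \phi\mu^2$, $\phi = 0.1$ by
default (a typical bulk RNA-seq overdispersion; $\phi = 0$ gives
Poisson). Depths default to $5\times10^6$ per stage, equal across stages
to isolate the composition effect. The matched qPCR simulator inverts
$T_{ij}$ into Ct values with a constant spike-in reference, so noise-free
tables recover true fold changes exactly.

The simulator does *not* model read-level effects (GC or length bias,
mappability), transcript isoforms, batch structure, or replicate-level
biological variation within a stage; passing tests demonstrate the
normalization algebra and the composition mechanism, not robustness to
those nuisances.

## Numerical choices and edge cases

* TMM trimming uses average ranks with bounds
  $\lfloor n\,t \rfloor + 1 \le \text{rank} \le n - \lfloor n\,t
  \rfloor$; if everything is trimmed, or no gene is positive in both
  samples, the factor falls back to 1 with a warning. When all $|M| <
  10^{-6}$ the factor is returned as exactly 1, so identical profiles and
  pure depth changes are fixed points.
* The *unweighted* trimmed mean is exactly invariant to rescaling a
  column (M values are depth-free); the default inverse-variance weights
  depend on counts, so the weighted factor is only asymptotically
  depth-invariant. Both variants are exposed.
* Known blind spot, reproduced as a property: under a uniform global
  shift of *all* genes, count fractions do not move and the TMM factor
  stays at 1 regardless of the true content change. Laboratory validation
  of scales remains advisable.
* A second, subtler limitation: with one-sided changes occupying a
  fraction of genes near the trim fraction *and* substantial gene-wise
  overdispersion, the changed and unchanged M-clusters overlap and the
  doubly-trimmed mean is pulled toward 1 (at $\phi = 0.1$ the M noise is
  ~0.65 log2 units, and the post-ZGA recovery error reaches ~25%). In
  the depth-limited regime ($\phi = 0$, Poisson noise at $5\times10^6$
  reads) recovery of the content ratio is within a few percent. The
  package's recovery checks therefore run depth-limited, and the
  overdispersed case is stated here as a limitation of count-derived
  scales rather than tested as if it held.
* BSN outputs are real-valued; pseudo-libraries are not rounded. Zeros
  are kept as zeros by all linear methods; only fold-change computation
  applies an offset (+0.5, matching the magnitude used in the log2-CPM
  transform) and only to genes with a zero in the pair, flagged in the
  output. Value space (linear vs log2) is carried on every normalized
  table and fold changes refuse unknown spaces.
* Closest-method comparisons credit exact ties fractionally ($1/k$ to
  each of $k$ tied methods) so per-pair credits always sum to the number
  of genes; percent excess averages per-gene ratios (not the ratio of
  means), which is what makes the BSN/RPM closed form exact.

## Problem sizes used in the checks

The package's end-to-end checks simulate 5,000 genes at depth
$5\times10^6$ across 5 stages; the bias and closest-method properties are
evaluated over 10 independent seeds (50,000 gene-level comparisons), and
the exact identities over 100 random 30-gene matrices. A full run of the
suite takes well under a minute on a single core.
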