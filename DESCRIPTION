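Package: bsnorm
Title: Biological Scaling Normalization for RNA-Seq with Global mRNA Shifts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Between-sample normalization of RNA-seq count data when the
    total or polyA+ mRNA content per biological unit differs between
    samples, as during early embryogenesis. Implements biological scaling
    normalization (BSN), which rescales per-sample transcript
    concentrations by experimentally or mathematically derived global
    fold-change scales, alongside the standard reads-per-million (RPM,
    RPKM) and trimmed-mean-of-M-values (TMM) approaches that assume equal
    content. Includes scale estimators from polyA+ RNA measurements and
    from counts (TMM factors), RT-qPCR benchmark fold changes
    (delta-delta-Ct and efficiency-calibrated), a negative-binomial
    simulator of global expression shifts with known ground truth, and
    tools to compare normalization methods against a benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    edgeR,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
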