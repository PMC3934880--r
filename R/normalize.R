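new_norm_tbl <- function(tbl, method, value_space, scale_note = NULL,
                         extra = list()) {
  attr(tbl, "method") <- method
  attr(tbl, "value_space") <- value_space
  attr(tbl, "scale_note") <- scale_note
  for (nm in names(extra)) attr(tbl, nm) <- extra[[nm]]
  class(tbl) <- c("bsn_norm", setdiff(class(tbl), "bsn_counts"))
  tbl
}

#' Normalization method and value space of a normalized table
#' @param x A normalized table.
#' @return `"bsn"`, `"rpm"`, `"rpkm"` or `"tmm-log2"`; `"linear"` or `"log2"`.
#' @export
norm_method <- function(x) attr(x, "method")

#' @rdname norm_method
#' @export
value_space <- function(x) attr(x, "value_space")

#' Per-sample transcript concentrations
#'
#' E_ij = R_ij / R_j: the relative abundance of transcript i in sample j.
#' Every column sums to 1.
#'
#' @param counts A [count_tbl()].
#' @return A tibble (gene plus one column per sample) of concentrations.
#' @export
concentrations <- function(counts) {
  m <- values_matrix(counts)
  ls <- colSums(m)
  if (any(ls == 0)) {
    abort(sprintf("zero library size for sample(s): %s",
                  paste(colnames(m)[ls == 0], collapse = ", ")))
  }
  matrix_to_tbl(sweep(m, 2, ls, "/"), counts$gene)
}

#' Biological scaling normalization (BSN)
#'
#' Rescales transcript concentrations to pseudo libraries whose sizes
#' follow the global fold-change scales: with concentrations
#' E_ij = R_ij / R_j, average library size Rbar = mean_j(R_j) and
#' per-sample scales Z_j, the normalized value is
#' N_ij = E_ij x Rbar x Z_j, so column j sums to the pseudo library size
#' L_j = Rbar x Z_j. Unlike RPM or TMM, which drive all samples toward
#' equal totals, BSN preserves the measured differences in mRNA content.
#'
#' @param counts A [count_tbl()].
#' @param scales A [scale_set()] covering every sample, typically from
#'   [bio_scales()] or [tmm_content_scales()].
#' @return A normalized tibble (method `"bsn"`, linear space) with
#'   attributes `avg_lib_size` (Rbar) and `pseudo_lib_sizes` (L_j).
#' @examples
#' counts <- count_tbl(data.frame(gene = c("g1", "g2", "g3"),
#'                                s1 = c(50, 30, 20), s2 = c(100, 60, 40)))
#' z <- scale_set(c("s1", "s2"), c(1, 1.5), kind = "user", reference = "s1")
#' bsn(counts, z)
#' @export
bsn <- function(counts, scales) {
  m <- values_matrix(counts)
  ls <- colSums(m)
  if (any(ls == 0)) {
    abort(sprintf("zero library size for sample(s): %s",
                  paste(colnames(m)[ls == 0], collapse = ", ")))
  }
  z <- scale_lookup(scales, colnames(m))
  if (any(z <= 0)) abort("scales must be positive")
  rbar <- mean(ls)
  pseudo <- rbar * z
  e <- sweep(m, 2, ls, "/")
  out <- matrix_to_tbl(sweep(e, 2, pseudo, "*"), counts$gene)
  new_norm_tbl(out, "bsn", "linear",
               scale_note = sprintf("kind=%s", scale_kind(scales)),
               extra = list(avg_lib_size = rbar, pseudo_lib_sizes = pseudo))
}

#' Replicate-aware BSN
#'
#' For designs with several replicate samples per stage the normalization
#' proceeds in five steps: (a) within each stage, concentrations are
#' multiplied by the mean library size of that stage's replicates; (b)
#' those values are averaged genewise into one column per stage; (c)
#' global scales are estimated on the stage-averaged matrix (count-derived
#' by default, or supplied, e.g. biological); (d) the overall average
#' library size Rbar across all original samples gives stage pseudo
#' libraries L_s = Rbar x Z_s; (e) every replicate is reassigned its
#' stage's pseudo library, N_ij = E_ij x L_stage(j). With one replicate
#' per stage and supplied scales this reduces exactly to [bsn()].
#'
#' @param counts A [count_tbl()].
#' @param groups Sample-to-stage map: a data frame with columns `sample`,
#'   `stage`, or a named character vector (names = samples).
#' @param scales `NULL` (estimate count-derived content scales on the
#'   stage-averaged matrix) or a [scale_set()] keyed by stage.
#' @return A normalized tibble (method `"bsn"`, linear space) with one
#'   column per original sample and attributes `avg_lib_size`,
#'   `pseudo_lib_sizes` (per stage), `stage_scales` and `stage_means`
#'   (the step-(b) matrix).
#' @export
bsn_replicates <- function(counts, groups, scales = NULL) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("sample", "stage") %in% names(groups)))
    map <- setNames(as.character(groups$stage), as.character(groups$sample))
  } else {
    map <- setNames(as.character(groups), names(groups))
  }
  m <- values_matrix(counts)
  miss <- setdiff(colnames(m), names(map))
  if (length(miss)) {
    abort(sprintf("no stage for sample(s): %s", paste(miss, collapse = ", ")))
  }
  stage_of <- map[colnames(m)]
  stages <- unique(stage_of)
  ls <- colSums(m)
  if (any(ls == 0)) abort("zero library size")
  e <- sweep(m, 2, ls, "/")

  # (a) within-stage pseudo counts at the stage's mean library size,
  # (b) genewise mean across the stage's replicates
  stage_means <- vapply(stages, function(st) {
    js <- which(stage_of == st)
    rowMeans(e[, js, drop = FALSE] * mean(ls[js]))
  }, double(nrow(m)))
  colnames(stage_means) <- stages
  stage_tbl <- matrix_to_tbl(stage_means, counts$gene)

  # (c) scales on the stage-averaged matrix
  if (is.null(scales)) {
    if (length(stages) < 2L) abort("need >=2 stages to estimate scales")
    scales <- invert_scales(tmm_factors(count_like(stage_tbl)))
  }
  z <- scale_lookup(scales, stages)

  # (d) overall average library size and stage pseudo libraries
  rbar <- mean(ls)
  pseudo <- rbar * z

  # (e) reassign each replicate its stage's pseudo library
  out <- matrix_to_tbl(sweep(e, 2, pseudo[stage_of], "*"), counts$gene)
  new_norm_tbl(out, "bsn", "linear",
               scale_note = sprintf("kind=%s (per stage)", scale_kind(scales)),
               extra = list(avg_lib_size = rbar, pseudo_lib_sizes = pseudo,
                            stage_scales = scales, stage_means = stage_tbl))
}

# wrap a gene+samples tibble of non-negative reals so TMM helpers accept it
count_like <- function(x) {
  class(x) <- unique(c("bsn_counts", class(x)))
  x
}

#' Reads per million (RPM)
#'
#' N_ij = R_ij / R_j x 1e6. Every column sums to one million: depth and any
#' global content difference are both normalized away.
#'
#' @param counts A [count_tbl()].
#' @return A normalized tibble (method `"rpm"`, linear space).
#' @export
rpm <- function(counts) {
  e <- concentrations(counts)
  out <- matrix_to_tbl(values_matrix(e) * 1e6, counts$gene)
  new_norm_tbl(out, "rpm", "linear")
}

#' Reads per kilobase per million (RPKM)
#'
#' N_ij = R_ij / (R_j/1e6 x length_i/1e3).
#'
#' @param counts A [count_tbl()].
#' @param lengths Data frame with columns `gene` and `length` (transcript
#'   length in bases, >= 1) covering every gene in `counts`.
#' @return A normalized tibble (method `"rpkm"`, linear space).
#' @export
rpkm <- function(counts, lengths) {
  stopifnot(all(c("gene", "length") %in% names(lengths)))
  len <- setNames(as.double(lengths$length), as.character(lengths$gene))
  miss <- setdiff(counts$gene, names(len))
  if (length(miss)) {
    abort(sprintf("no length for gene(s): %s",
                  paste(utils::head(miss, 5L), collapse = ", ")))
  }
  len <- len[counts$gene]
  if (any(!is.finite(len)) || any(len < 1)) abort("lengths must be >= 1")
  e <- values_matrix(rpm(counts))
  out <- matrix_to_tbl(e / (len / 1e3), counts$gene)
  new_norm_tbl(out, "rpkm", "linear")
}

#' TMM-normalized log2 expression values
#'
#' Log2 counts per million over TMM effective library sizes, with the
#' usual small offsets keeping zeros finite:
#' N_ij = log2( (R_ij + 0.5) / (R_j x Z_j + 1) x 1e6 ),
#' where Z_j are the TMM normalization factors (geometric mean 1).
#'
#' @param counts A [count_tbl()].
#' @param factors A [scale_set()] of kind `"tmm"` in geometric-mean-1
#'   convention, as returned by [tmm_factors()].
#' @return A normalized tibble (method `"tmm-log2"`, log2 space). Fold
#'   changes between samples are computed by subtraction.
#' @export
tmm_log2 <- function(counts, factors = tmm_factors(counts)) {
  if (!identical(scale_kind(factors), "tmm") ||
      !identical(scale_convention(factors), "geometric-mean-1")) {
    abort("factors must be TMM normalization factors with geometric mean 1")
  }
  m <- values_matrix(counts)
  ls <- colSums(m)
  z <- scale_lookup(factors, colnames(m))
  out <- log2(sweep(m + 0.5, 2, ls * z + 1, "/") * 1e6)
  out <- matrix_to_tbl(out, counts$gene)
  new_norm_tbl(out, "tmm-log2", "log2", scale_note = "kind=tmm")
}
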