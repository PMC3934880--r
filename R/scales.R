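#' Construct a set of global fold-change scales
#'
#' A scale set carries one positive scale Z_j per sample. Z_j is the
#' global fold-change: the ratio of a sample's total (here, polyA+) mRNA
#' content to that of a reference sample. Two conventions are tracked:
#' `"relative-to-reference"` (Z at the reference is 1, as for scales from
#' laboratory measurements) and `"geometric-mean-1"` (as for TMM
#' normalization factors).
#'
#' @param sample Character vector of sample/stage ids.
#' @param scale Positive finite scales Z_j, same length as `sample`.
#' @param kind One of `"bio"`, `"tmm"`, `"user"`.
#' @param reference Reference sample id, or `NA` when the convention is
#'   geometric-mean-1.
#' @param convention `"relative-to-reference"` or `"geometric-mean-1"`.
#' @param notes Character vector of provenance notes.
#' @return A tibble of class `scale_set` with columns `sample`, `scale`.
#' @export
scale_set <- function(sample, scale, kind = c("user", "bio", "tmm"),
                      reference = NA_character_,
                      convention = c("relative-to-reference", "geometric-mean-1"),
                      notes = character()) {
  kind <- match.arg(kind)
  convention <- match.arg(convention)
  sample <- as.character(sample)
  if (anyDuplicated(sample)) abort("duplicate sample ids in scale set")
  if (length(scale) != length(sample)) abort("sample and scale lengths differ")
  if (!is.numeric(scale) || any(!is.finite(scale)) || any(scale <= 0)) {
    abort("all scales must be positive and finite")
  }
  if (convention == "relative-to-reference") {
    if (is.na(reference) || !reference %in% sample) {
      abort("relative-to-reference scales need a reference sample in the set")
    }
    if (kind == "bio" && scale[match(reference, sample)] != 1) {
      abort("bio scales must be exactly 1 at the reference sample")
    }
  }
  if (kind == "tmm" && convention == "geometric-mean-1") {
    gm <- exp(mean(log(scale)))
    if (abs(gm - 1) > 1e-12) {
      abort(sprintf("tmm factors must have geometric mean 1 (got %.15g)", gm))
    }
  }
  out <- tibble(sample = sample, scale = as.double(scale))
  attr(out, "kind") <- kind
  attr(out, "reference") <- reference
  attr(out, "convention") <- convention
  attr(out, "notes") <- notes
  class(out) <- c("scale_set", class(out))
  out
}

scale_kind <- function(scales) attr(scales, "kind")
scale_convention <- function(scales) attr(scales, "convention")

# named vector of scales for a required set of samples
scale_lookup <- function(scales, samples) {
  miss <- setdiff(samples, scales$sample)
  if (length(miss)) {
    abort(sprintf("no scale for sample(s): %s", paste(miss, collapse = ", ")))
  }
  setNames(scales$scale, scales$sample)[samples]
}

#' Biological scales from polyA+ RNA measurements
#'
#' For each stage the polyA+ percentage p_j = mean(polyA+ ng) /
#' mean(total ng) x 100 is computed across replicates (amounts are averaged
#' before the ratio is taken), and the scales are the percentages relative
#' to the reference stage: Z_j = p_j / p_ref, so Z at the reference is
#' exactly 1. Because only percentages enter, the result is invariant to
#' the measurement units.
#'
#' @param meas An [rna_measurements()] table.
#' @param reference_stage Stage label used as the denominator (e.g.
#'   `"1-cell"`).
#' @return A [scale_set()] of kind `"bio"`.
#' @examples
#' m <- rna_measurements(data.frame(
#'   stage = c("1-cell", "3.5hpf"), replicate = c("r1", "r1"),
#'   total_ng = c(100, 90), polya_ng = c(2, 2.7)))
#' bio_scales(m, "1-cell")
#' @export
bio_scales <- function(meas, reference_stage) {
  if (!inherits(meas, "rna_measurements")) meas <- rna_measurements(meas)
  per_stage <- meas |>
    group_by(.data$stage) |>
    summarise(total = mean(.data$total_ng), polya = mean(.data$polya_ng),
              .groups = "drop")
  if (!reference_stage %in% per_stage$stage) {
    abort(sprintf("reference stage '%s' absent from measurements", reference_stage))
  }
  if (any(per_stage$total == 0)) {
    abort(sprintf("zero mean total RNA for stage(s): %s",
                  paste(per_stage$stage[per_stage$total == 0], collapse = ", ")))
  }
  per_stage$pct <- per_stage$polya / per_stage$total * 100
  p_ref <- per_stage$pct[match(reference_stage, per_stage$stage)]
  if (p_ref == 0) abort("reference stage has zero polyA+ percentage")
  z <- per_stage$pct / p_ref
  z[match(reference_stage, per_stage$stage)] <- 1  # exact at the reference
  if (any(z <= 0)) {
    abort(sprintf("zero polyA+ percentage for stage(s): %s",
                  paste(per_stage$stage[z <= 0], collapse = ", ")))
  }
  # keep first-seen stage order from the input
  ord <- match(unique(meas$stage), per_stage$stage)
  scale_set(per_stage$stage[ord], z[ord], kind = "bio",
            reference = reference_stage,
            notes = "polyA+ percentage of total RNA, replicate amounts averaged")
}

#' Square-root transform of scales
#'
#' A conservative damping of the global fold-change scales (Z' = sqrt(Z))
#' that halves every log2 scale. Provided for comparison; on benchmark
#' data the untransformed scales are the more accurate choice.
#'
#' @param scales A [scale_set()].
#' @return A [scale_set()] with square-rooted scales; kind is preserved and
#'   the transform is recorded in the provenance notes.
#' @export
sqrt_transform <- function(scales) {
  stopifnot(inherits(scales, "scale_set"))
  out <- scales
  out$scale <- sqrt(out$scale)
  attr(out, "notes") <- c(attr(scales, "notes"), "sqrt transform applied")
  # geometric-mean-1 is preserved by sqrt; reference value 1 likewise
  out
}

#' Re-express scales relative to a chosen reference sample
#'
#' Divides every scale by the scale of `reference_sample`, so the reference
#' becomes exactly 1. Used to put TMM-derived scales on the same axis as
#' biological scales (levels relative to the 1-cell stage).
#'
#' @param scales A [scale_set()].
#' @param reference_sample Sample id present in the set.
#' @return A [scale_set()] in `"relative-to-reference"` convention.
#' @export
rebase_scales <- function(scales, reference_sample) {
  stopifnot(inherits(scales, "scale_set"))
  if (!reference_sample %in% scales$sample) {
    abort(sprintf("reference sample '%s' not in scale set", reference_sample))
  }
  z_ref <- scales$scale[match(reference_sample, scales$sample)]
  out <- scales
  out$scale <- scales$scale / z_ref
  out$scale[match(reference_sample, scales$sample)] <- 1
  attr(out, "reference") <- reference_sample
  attr(out, "convention") <- "relative-to-reference"
  attr(out, "notes") <- c(attr(scales, "notes"),
                          sprintf("rebased to reference '%s'", reference_sample))
  out
}

#' Invert scales between normalization-factor and content-ratio views
#'
#' A TMM normalization factor shrinks the effective library of a sample
#' whose mRNA content grew: it is the reciprocal of the global fold-change
#' it detects. `invert_scales()` maps between the two views (Z' = 1/Z).
#'
#' @param scales A [scale_set()].
#' @return A [scale_set()] with reciprocal scales.
#' @export
invert_scales <- function(scales) {
  stopifnot(inherits(scales, "scale_set"))
  out <- scales
  out$scale <- 1 / scales$scale
  attr(out, "notes") <- c(attr(scales, "notes"), "inverted (Z' = 1/Z)")
  out
}

#' TMM reference sample choice
#'
#' Returns the sample whose 75th percentile of count fractions R_ij / R_j
#' (over genes, linear interpolation between order statistics) is closest
#' to the mean of those 75th percentiles across samples; ties go to the
#' lowest column index.
#'
#' @param counts A [count_tbl()].
#' @return A sample id.
#' @export
tmm_reference <- function(counts) {
  m <- values_matrix(counts)
  if (ncol(m) < 2L) abort("need >=2 samples to pick a TMM reference")
  ls <- colSums(m)
  if (any(ls == 0)) {
    abort(sprintf("zero library size for sample(s): %s",
                  paste(colnames(m)[ls == 0], collapse = ", ")))
  }
  f75 <- vapply(seq_len(ncol(m)), function(j) {
    unname(quantile(m[, j] / ls[j], probs = 0.75, type = 7))
  }, double(1))
  colnames(m)[which.min(abs(f75 - mean(f75)))]
}

#' Pairwise TMM factor between a sample and a reference
#'
#' The trimmed mean of M-values between sample k and reference r, over
#' genes with positive counts in both. Per gene g:
#' M_g = log2((R_gk/R_k) / (R_gr/R_r)), A_g = 0.5 log2((R_gk/R_k) (R_gr/R_r)),
#' and the delta-method precision weight w_g = (R_k - R_gk)/(R_k R_gk) +
#' (R_r - R_gr)/(R_r R_gr). Genes in the top or bottom `trim_m` fraction by
#' M rank, or the top or bottom `trim_a` fraction by A rank, are dropped
#' (union of drops; ranks use average ties, the trim bounds are
#' floor(n trim)+1 .. n-floor(n trim)). The factor is 2 to the
#' 1/w_g-weighted mean of the retained M_g. Degenerate cases (no shared
#' positive gene, empty trim set, non-finite result, or all |M| below
#' 1e-6) fall back to a factor of exactly 1.
#'
#' The factor is a normalization factor: a sample whose content rose
#' relative to the reference gets a factor below 1 (see [invert_scales()]).
#'
#' @param counts A [count_tbl()].
#' @param sample,ref Sample ids (columns of `counts`).
#' @param trim_m,trim_a Two-sided trim fractions on M and A ranks.
#' @param weighted Use 1/w_g precision weights (`TRUE`) or an unweighted
#'   trimmed mean (`FALSE`).
#' @return A positive scalar.
#' @export
tmm_pair_factor <- function(counts, sample, ref, trim_m = 0.30, trim_a = 0.05,
                            weighted = TRUE) {
  m <- values_matrix(counts)
  for (s in c(sample, ref)) {
    if (!s %in% colnames(m)) abort(sprintf("sample '%s' not in counts", s))
  }
  obs <- m[, sample]
  rfc <- m[, ref]
  n_obs <- sum(obs)
  n_ref <- sum(rfc)
  if (n_obs == 0 || n_ref == 0) abort("zero library size")
  pos <- obs > 0 & rfc > 0
  if (!any(pos)) {
    warn(sprintf("no gene with positive counts in both '%s' and '%s'; factor set to 1",
                 sample, ref))
    return(1)
  }
  p_obs <- obs[pos] / n_obs
  p_ref <- rfc[pos] / n_ref
  M <- log2(p_obs / p_ref)
  A <- 0.5 * log2(p_obs * p_ref)
  w <- (n_obs - obs[pos]) / (n_obs * obs[pos]) +
       (n_ref - rfc[pos]) / (n_ref * rfc[pos])
  if (max(abs(M)) < 1e-6) return(1)  # identical profiles up to depth
  n <- length(M)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  rm_ <- rank(M)
  ra_ <- rank(A)
  keep <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
  if (!any(keep)) {
    warn("trimming removed all genes; factor set to 1")
    return(1)
  }
  lf <- if (weighted) {
    sum(M[keep] / w[keep]) / sum(1 / w[keep])
  } else {
    mean(M[keep])
  }
  if (!is.finite(lf)) return(1)
  2^lf
}

#' TMM normalization factors for all samples
#'
#' Chooses a reference column with [tmm_reference()], computes the pairwise
#' factor of every sample against it with [tmm_pair_factor()] (the
#' reference gets factor 1), and renormalizes the factors to geometric
#' mean 1.
#'
#' @inheritParams tmm_pair_factor
#' @param ref Optional reference sample id; default is [tmm_reference()].
#' @return A [scale_set()] of kind `"tmm"`, convention geometric-mean-1.
#'   These are normalization factors in the effective-library-size sense
#'   and feed [tmm_log2()] directly; use [tmm_content_scales()] for the
#'   content-ratio view.
#' @export
tmm_factors <- function(counts, ref = NULL, trim_m = 0.30, trim_a = 0.05,
                        weighted = TRUE) {
  samples <- sample_ids(counts)
  if (length(samples) < 2L) abort("need >=2 samples")
  if (is.null(ref)) ref <- tmm_reference(counts)
  f <- vapply(samples, function(s) {
    if (identical(s, ref)) 1 else
      tmm_pair_factor(counts, s, ref, trim_m = trim_m, trim_a = trim_a,
                      weighted = weighted)
  }, double(1))
  f <- f / exp(mean(log(f)))
  scale_set(samples, f, kind = "tmm", reference = NA_character_,
            convention = "geometric-mean-1",
            notes = sprintf("TMM factors (trim M %.2f, A %.2f, %s), reference '%s'",
                            trim_m, trim_a,
                            if (weighted) "weighted" else "unweighted", ref))
}

#' Count-derived global fold-change scales (content-ratio view)
#'
#' The TMM factor of a sample is the reciprocal of the global content
#' change it detects, so the count-derived analogue of the biological
#' scales is 1/factor, optionally rebased so a chosen stage (typically the
#' earliest) equals 1. This is the quantity comparable to [bio_scales()]
#' and the one to pass to [bsn()].
#'
#' @inheritParams tmm_factors
#' @param reference_stage Optional sample id to rebase to (Z = 1 there).
#' @return A [scale_set()] of kind `"tmm"`.
#' @export
tmm_content_scales <- function(counts, reference_stage = NULL, trim_m = 0.30,
                               trim_a = 0.05, weighted = TRUE) {
  z <- invert_scales(tmm_factors(counts, trim_m = trim_m, trim_a = trim_a,
                                 weighted = weighted))
  if (!is.null(reference_stage)) z <- rebase_scales(z, reference_stage)
  z
}
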