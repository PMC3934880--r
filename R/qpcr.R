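#' Construct an RT-qPCR Ct table
#'
#' Holds cycle-threshold (Ct) values per gene, stage and replicate,
#' together with the spike-in reference gene (an exogenous polyadenylated
#' RNA, e.g. kanamycin RNA, added at a fixed amount per embryo pool so
#' that its Ct anchors yields across stages) and optional per-primer-pair
#' amplification efficiencies.
#'
#' @param ct Data frame with columns `gene`, `stage`, `replicate`, `ct`.
#'   Must include rows for `reference_gene` in every stage that has target
#'   Ct values.
#' @param reference_gene Spike-in reference gene id (default
#'   `"kanamycin"`).
#' @param efficiencies Optional data frame with columns `gene`,
#'   `efficiency`; efficiencies must lie in (1, 2.2] (2 = perfect
#'   doubling per cycle).
#' @return A tibble of class `qpcr_tbl` with attributes `reference_gene`
#'   and `efficiencies`.
#' @export
qpcr_table <- function(ct, reference_gene = "kanamycin", efficiencies = NULL) {
  ct <- as_tibble(ct)
  need <- c("gene", "stage", "replicate", "ct")
  miss <- setdiff(need, names(ct))
  if (length(miss)) {
    abort(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (nrow(ct) == 0L) abort("empty Ct table")
  ct$gene <- as.character(ct$gene)
  ct$stage <- as.character(ct$stage)
  ct$replicate <- as.character(ct$replicate)
  if (!is.numeric(ct$ct) || any(!is.finite(ct$ct)) || any(ct$ct <= 0)) {
    abort("Ct values must be finite and > 0")
  }
  target_stages <- unique(ct$stage[ct$gene != reference_gene])
  ref_stages <- unique(ct$stage[ct$gene == reference_gene])
  no_ref <- setdiff(target_stages, ref_stages)
  if (length(no_ref)) {
    abort(sprintf("no reference ('%s') Ct for stage(s): %s", reference_gene,
                  paste(no_ref, collapse = ", ")))
  }
  if (!is.null(efficiencies)) {
    efficiencies <- as_tibble(efficiencies)
    stopifnot(all(c("gene", "efficiency") %in% names(efficiencies)))
    e <- efficiencies$efficiency
    if (!is.numeric(e) || any(!is.finite(e)) || any(e <= 1) || any(e > 2.2)) {
      abort("efficiencies must lie in (1, 2.2]")
    }
    efficiencies$gene <- as.character(efficiencies$gene)
  }
  attr(ct, "reference_gene") <- reference_gene
  attr(ct, "efficiencies") <- efficiencies
  class(ct) <- c("qpcr_tbl", class(ct))
  ct
}

#' Read an RT-qPCR Ct table from CSV
#'
#' The CSV must have columns `gene`, `stage`, `replicate`, `ct` and may
#' carry a per-gene `efficiency` column (constant within gene), which is
#' split off into the efficiency table.
#'
#' @param path CSV file path.
#' @inheritParams qpcr_table
#' @return A [qpcr_table()].
#' @export
read_qpcr_table <- function(path, reference_gene = "kanamycin") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  eff <- NULL
  if ("efficiency" %in% names(x)) {
    eff <- distinct(x[!is.na(x$efficiency), c("gene", "efficiency")])
    x$efficiency <- NULL
  }
  qpcr_table(x, reference_gene = reference_gene, efficiencies = eff)
}

# per (gene, stage, replicate) delta-Ct vs the spike-in reference.
# Target and reference replicates are paired by replicate id; when a
# replicate id has no matching reference measurement the stage-mean
# reference Ct is used instead.
delta_ct <- function(table) {
  ref_gene <- attr(table, "reference_gene")
  ref <- table |>
    filter(.data$gene == ref_gene) |>
    select(stage = "stage", replicate = "replicate", ct_ref = "ct")
  ref_mean <- ref |>
    group_by(.data$stage) |>
    summarise(ct_ref_mean = mean(.data$ct_ref), .groups = "drop")
  targets <- filter(table, .data$gene != ref_gene)
  out <- targets |>
    left_join(ref, by = c("stage", "replicate")) |>
    left_join(ref_mean, by = "stage") |>
    mutate(ct_ref = dplyr::coalesce(.data$ct_ref, .data$ct_ref_mean),
           dct = .data$ct - .data$ct_ref)
  spread <- out |>
    group_by(.data$gene, .data$stage) |>
    summarise(spread = if (n() > 1) max(.data$dct) - min(.data$dct) else 0,
              .groups = "drop")
  wide <- spread$spread > 1
  if (any(wide)) {
    warn(sprintf("delta-Ct replicate spread exceeds 1 cycle for %d gene/stage pair(s)",
                 sum(wide)))
  }
  out
}

finish_fc <- function(per_rep, method, control_stage) {
  out <- per_rep |>
    group_by(.data$gene, .data$stage) |>
    summarise(log2_fc = mean(.data$log2_fc_rep),
              sd_log2 = if (n() > 1) sd(.data$log2_fc_rep) else NA_real_,
              n_replicates = n(), .groups = "drop") |>
    mutate(fold_change = 2^.data$log2_fc, method = method)
  out <- out[, c("gene", "stage", "fold_change", "log2_fc", "sd_log2",
                 "n_replicates", "method")]
  attr(out, "control_stage") <- control_stage
  attr(out, "method") <- method
  class(out) <- c("qpcr_fc", class(out))
  out
}

#' Livak (2^-ddCt) fold changes from a Ct table
#'
#' Per gene and stage, delta-Ct vs the spike-in reference is computed per
#' replicate, the control stage's mean delta-Ct is subtracted
#' (delta-delta-Ct), and the fold change 2^-ddCt is aggregated as the
#' geometric mean over replicates (arithmetic mean of log2 values) with
#' the standard deviation of the replicate log2 values. The control
#' stage's reported fold change is exactly 1 by construction.
#'
#' @param table A [qpcr_table()].
#' @param control_stage Stage label used as the control (fold change 1).
#' @return A tibble of class `qpcr_fc` with columns `gene`, `stage`,
#'   `fold_change`, `log2_fc`, `sd_log2`, `n_replicates`, `method`.
#' @examples
#' tb <- qpcr_table(data.frame(
#'   gene = c("g", "g", "kanamycin", "kanamycin"),
#'   stage = c("ctl", "s", "ctl", "s"),
#'   replicate = "r1", ct = c(20, 18, 15, 15)))
#' livak(tb, "ctl")  # fold change 4
#' @export
livak <- function(table, control_stage) {
  dct <- delta_ct(table)
  if (!control_stage %in% dct$stage) {
    abort(sprintf("control stage '%s' absent from Ct table", control_stage))
  }
  ctl <- dct |>
    filter(.data$stage == control_stage) |>
    group_by(.data$gene) |>
    summarise(dct_ctl = mean(.data$dct), .groups = "drop")
  per_rep <- dct |>
    inner_join(ctl, by = "gene") |>
    mutate(log2_fc_rep = -(.data$dct - .data$dct_ctl))
  finish_fc(per_rep, "livak", control_stage)
}

#' Efficiency-calibrated (Pfaffl) fold changes from a Ct table
#'
#' FC = E_target^(Ct_target,ctl - Ct_target,s) /
#' E_ref^(Ct_ref,ctl - Ct_ref,s), using the measured amplification
#' efficiencies of the target and reference primer pairs instead of
#' assuming perfect doubling. Control-stage Ct values enter as stage
#' means; replicates of the compared stage are aggregated geometrically
#' as in [livak()]. With all efficiencies equal to 2 the result reduces
#' exactly to the Livak values.
#'
#' @inheritParams livak
#' @return A tibble of class `qpcr_fc`.
#' @export
pfaffl <- function(table, control_stage) {
  effs <- attr(table, "efficiencies")
  if (is.null(effs)) abort("Ct table has no primer efficiencies")
  ref_gene <- attr(table, "reference_gene")
  e_lookup <- setNames(effs$efficiency, effs$gene)
  genes <- unique(table$gene)
  miss <- setdiff(genes, names(e_lookup))
  if (length(miss)) {
    abort(sprintf("no efficiency for gene(s): %s", paste(miss, collapse = ", ")))
  }
  ref <- table |>
    filter(.data$gene == ref_gene) |>
    group_by(.data$stage) |>
    summarise(ct_ref = mean(.data$ct), .groups = "drop")
  if (!control_stage %in% ref$stage) {
    abort(sprintf("control stage '%s' absent from Ct table", control_stage))
  }
  ct_ref_ctl <- ref$ct_ref[match(control_stage, ref$stage)]
  e_ref <- unname(e_lookup[ref_gene])
  targets <- filter(table, .data$gene != ref_gene)
  ctl <- targets |>
    filter(.data$stage == control_stage) |>
    group_by(.data$gene) |>
    summarise(ct_ctl = mean(.data$ct), .groups = "drop")
  per_rep <- targets |>
    inner_join(ctl, by = "gene") |>
    left_join(ref, by = "stage") |>
    mutate(e_target = unname(e_lookup[.data$gene]),
           log2_fc_rep = (.data$ct_ctl - .data$ct) * log2(.data$e_target) -
             (ct_ref_ctl - .data$ct_ref) * log2(e_ref))
  finish_fc(per_rep, "pfaffl", control_stage)
}

#' Long table of log2 fold changes from qPCR results
#'
#' @param fc A `qpcr_fc` tibble from [livak()] or [pfaffl()].
#' @return Tibble with columns `gene`, `stage`, `log2_fc`.
#' @export
log2_fold_changes <- function(fc) {
  stopifnot(inherits(fc, "qpcr_fc"))
  fc[, c("gene", "stage", "log2_fc")]
}

#' qPCR fold changes between stage pairs
#'
#' Converts control-referenced qPCR fold changes into fold changes between
#' arbitrary stage pairs via log2FC(num) - log2FC(den), for direct
#' comparison with RNA-seq fold changes over the same pairs.
#'
#' @param fc A `qpcr_fc` tibble.
#' @param pairs Character vector `"numerator/denominator"` of stage labels
#'   (e.g. `"3.5hpf/1-cell"`).
#' @return Tibble with columns `gene`, `pair`, `log2_fc`.
#' @export
qpcr_pair_fold_changes <- function(fc, pairs) {
  stopifnot(inherits(fc, "qpcr_fc"))
  parsed <- parse_pairs(pairs)
  purrr::pmap_dfr(parsed, function(pair, num, den) {
    a <- fc[fc$stage == num, c("gene", "log2_fc")]
    b <- fc[fc$stage == den, c("gene", "log2_fc")]
    if (nrow(a) == 0L || nrow(b) == 0L) {
      abort(sprintf("stage pair '%s': stage absent from qPCR results", pair))
    }
    j <- inner_join(a, b, by = "gene", suffix = c("_num", "_den"))
    tibble(gene = j$gene, pair = pair,
           log2_fc = j$log2_fc_num - j$log2_fc_den)
  })
}
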