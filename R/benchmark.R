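parse_pairs <- function(pairs) {
  if (is.data.frame(pairs)) {
    stopifnot(all(c("num", "den") %in% names(pairs)))
    pair <- if ("pair" %in% names(pairs)) pairs$pair else
      paste(pairs$num, pairs$den, sep = "/")
    return(tibble(pair = pair, num = as.character(pairs$num),
                  den = as.character(pairs$den)))
  }
  parts <- strsplit(pairs, "/", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    abort(sprintf("pair '%s' is not of the form 'numerator/denominator'",
                  pairs[bad][1L]))
  }
  tibble(pair = pairs,
         num = vapply(parts, `[`, character(1), 1L),
         den = vapply(parts, `[`, character(1), 2L))
}

#' Per-gene log2 fold changes from a normalized table
#'
#' For linear-space values the fold change is log2((N_num + c)/(N_den + c))
#' with an offset c = 0.5 applied only when either value is zero (flagged
#' in `offset_used`); values already in log2 space (TMM-log2) are
#' subtracted directly.
#'
#' @param norm A normalized table from [bsn()], [rpm()], [rpkm()] or
#'   [tmm_log2()].
#' @param pairs Character vector `"numerator/denominator"` of sample ids,
#'   or a data frame with columns `num`, `den` (optionally `pair`).
#' @return Tibble with columns `gene`, `pair`, `log2_fc`, `offset_used`,
#'   and attribute `method`.
#' @examples
#' counts <- count_tbl(data.frame(gene = c("g1", "g2"),
#'                                s1 = c(50, 50), s2 = c(150, 50)))
#' fold_changes(rpm(counts), "s2/s1")
#' @export
fold_changes <- function(norm, pairs) {
  if (!inherits(norm, "bsn_norm")) {
    abort("fold_changes() needs a normalized table with a known value space")
  }
  m <- values_matrix(norm)
  space <- value_space(norm)
  parsed <- parse_pairs(pairs)
  out <- purrr::pmap_dfr(parsed, function(pair, num, den) {
    for (s in c(num, den)) {
      if (!s %in% colnames(m)) abort(sprintf("unknown sample/stage '%s'", s))
    }
    a <- m[, num]
    b <- m[, den]
    if (space == "log2") {
      tibble(gene = rownames(m), pair = pair, log2_fc = unname(a - b),
             offset_used = FALSE)
    } else {
      zero <- a == 0 | b == 0
      c_off <- ifelse(zero, 0.5, 0)
      tibble(gene = rownames(m), pair = pair,
             log2_fc = unname(log2((a + c_off) / (b + c_off))),
             offset_used = unname(zero))
    }
  })
  attr(out, "method") <- norm_method(norm)
  out
}

#' Assemble a method-by-benchmark fold-change table
#'
#' Joins per-method fold-change tables (from [fold_changes()]) and a
#' benchmark table (from [qpcr_pair_fold_changes()] or
#' [true_fold_changes()]) on gene and pair into one wide table, one
#' column of log2 fold changes per method plus `benchmark`.
#'
#' @param ... Named fold-change tibbles (name = method label), each with
#'   columns `gene`, `pair`, `log2_fc`.
#' @param benchmark Benchmark tibble with columns `gene`, `pair`,
#'   `log2_fc`. Only genes/pairs present in all inputs are kept.
#' @return A tibble of class `fc_table`: `gene`, `pair`, one column per
#'   method, `benchmark`.
#' @export
combine_fold_changes <- function(..., benchmark) {
  methods <- list(...)
  if (length(methods) == 0L) abort("supply at least one method fold-change table")
  if (is.null(names(methods)) || any(names(methods) == "")) {
    abort("method fold-change tables must be named")
  }
  pick <- function(tb, nm) {
    stopifnot(all(c("gene", "pair", "log2_fc") %in% names(tb)))
    tb <- tb[, c("gene", "pair", "log2_fc")]
    names(tb)[3L] <- nm
    tb
  }
  out <- pick(methods[[1L]], names(methods)[1L])
  for (k in seq_along(methods)[-1L]) {
    out <- inner_join(out, pick(methods[[k]], names(methods)[k]),
                      by = c("gene", "pair"))
  }
  out <- inner_join(out, pick(benchmark, "benchmark"), by = c("gene", "pair"))
  attr(out, "methods") <- names(methods)
  class(out) <- c("fc_table", class(out))
  out
}

#' Which method's fold change is closest to the benchmark?
#'
#' Per gene, the closest method is the argmin of |log2FC_method -
#' log2FC_benchmark|; exact ties share one credit equally (1/k each), so
#' per pair and direction the credits sum to the number of genes. Results
#' are aggregated per stage pair and per benchmark direction (up: > 0,
#' down: < 0, flat: = 0).
#'
#' @param fc An [combine_fold_changes()] table.
#' @return A list of class `method_comparison`: `closest` (pair,
#'   direction, method, credit, n_genes), `deltas` (per gene and method,
#'   |log2FC - benchmark|), and `methods`.
#' @export
compare_to_benchmark <- function(fc) {
  stopifnot(inherits(fc, "fc_table"))
  methods <- attr(fc, "methods")
  if (nrow(fc) == 0L) {
    return(structure(list(closest = tibble(), deltas = tibble(),
                          methods = methods),
                     class = "method_comparison"))
  }
  dmat <- abs(as.matrix(fc[methods]) - fc$benchmark)
  dmin <- do.call(pmin, as.data.frame(dmat))
  credit <- (dmat == dmin) / rowSums(dmat == dmin)
  direction <- dplyr::case_when(fc$benchmark > 0 ~ "up",
                                fc$benchmark < 0 ~ "down",
                                TRUE ~ "flat")
  deltas <- dplyr::bind_cols(fc[, c("gene", "pair")],
                             as_tibble(as.data.frame(dmat))) |>
    tidyr::pivot_longer(all_of(methods), names_to = "method",
                        values_to = "abs_delta")
  closest <- dplyr::bind_cols(tibble(pair = fc$pair, direction = direction),
                              as_tibble(as.data.frame(credit))) |>
    tidyr::pivot_longer(all_of(methods), names_to = "method",
                        values_to = "credit") |>
    group_by(.data$pair, .data$direction, .data$method) |>
    summarise(credit = sum(.data$credit), .groups = "drop")
  n_genes <- tibble(pair = fc$pair, direction = direction) |>
    dplyr::count(.data$pair, .data$direction, name = "n_genes")
  closest <- left_join(closest, n_genes, by = c("pair", "direction"))
  structure(list(closest = closest, deltas = deltas, methods = methods),
            class = "method_comparison")
}

#' Mean percent excess of one method's fold changes over another's
#'
#' Mean over genes of (FC_a / FC_b - 1) x 100 on the linear scale
#' (FC = 2^log2FC). For BSN versus RPM this equals
#' (Z_num / Z_den - 1) x 100 exactly for any offset-free gene set,
#' because the two methods share counts and differ only by the scale
#' ratio.
#'
#' @param fc An [combine_fold_changes()] table (or any tibble with `gene`,
#'   `pair` and the two method columns).
#' @param method_a,method_b Column names of the two methods.
#' @param pair Optional stage pair to restrict to.
#' @param genes Optional gene subset.
#' @return Signed percentage (scalar).
#' @export
percent_excess <- function(fc, method_a, method_b, pair = NULL, genes = NULL) {
  for (mcol in c(method_a, method_b)) {
    if (!mcol %in% names(fc)) abort(sprintf("no column '%s'", mcol))
  }
  if (!is.null(pair)) fc <- fc[fc$pair %in% pair, ]
  if (!is.null(genes)) fc <- fc[fc$gene %in% genes, ]
  if (nrow(fc) == 0L) abort("empty gene set")
  ratio <- 2^(fc[[method_a]] - fc[[method_b]])
  mean(ratio - 1) * 100
}
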