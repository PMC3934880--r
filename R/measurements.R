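#' Read replicated total / polyA+ RNA measurements
#'
#' Expects a CSV with columns `stage`, `replicate`, `total_ng`, `polya_ng`:
#' the amounts of total RNA and of polyA+ RNA (in ng, from a fixed number of
#' embryos or cells) measured per developmental stage and replicate. A
#' polyA+ amount exceeding its paired total is flagged with a warning, not
#' rejected: on the small amounts involved, measurement noise routinely
#' produces such inversions.
#'
#' @param path CSV file path.
#' @return A tibble of class `rna_measurements` grouped conceptually by
#'   stage (one row per replicate measurement).
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  rna_measurements(x)
}

#' Construct an RNA measurement table
#'
#' @param x Data frame with columns `stage`, `replicate`, `total_ng`,
#'   `polya_ng`.
#' @return A validated tibble of class `rna_measurements`.
#' @export
rna_measurements <- function(x) {
  x <- as_tibble(x)
  need <- c("stage", "replicate", "total_ng", "polya_ng")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    abort(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  }
  if (nrow(x) == 0L) abort("no measurements")
  x$stage <- as.character(x$stage)
  for (col in c("total_ng", "polya_ng")) {
    v <- x[[col]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0)) {
      abort(sprintf("'%s' must be finite and non-negative", col))
    }
  }
  inverted <- x$polya_ng > x$total_ng
  if (any(inverted)) {
    warn(sprintf(
      "polyA+ amount exceeds total RNA amount in %d replicate(s) (stage %s); keeping as measured",
      sum(inverted), paste(unique(x$stage[inverted]), collapse = ", ")))
  }
  class(x) <- c("rna_measurements", class(x))
  x
}
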