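#' Tidy a scale set
#'
#' @param x A [scale_set()].
#' @param ... Unused.
#' @return Tibble with columns `sample`, `scale`, `log2_scale`, `kind`.
#' @method tidy scale_set
#' @export
tidy.scale_set <- function(x, ...) {
  tibble(sample = x$sample, scale = x$scale, log2_scale = log2(x$scale),
         kind = scale_kind(x))
}

#' One-row summary of a scale set
#'
#' @inheritParams tidy.scale_set
#' @return Tibble with `kind`, `convention`, `reference`, `n_samples`,
#'   `geometric_mean`, `max_scale`, `min_scale`.
#' @method glance scale_set
#' @export
glance.scale_set <- function(x, ...) {
  tibble(kind = scale_kind(x), convention = scale_convention(x),
         reference = attr(x, "reference"), n_samples = nrow(x),
         geometric_mean = exp(mean(log(x$scale))),
         min_scale = min(x$scale), max_scale = max(x$scale))
}

#' Tidy a method comparison
#'
#' @param x A [compare_to_benchmark()] result.
#' @param ... Unused.
#' @return The closest-method credit table (pair, direction, method,
#'   credit, n_genes).
#' @method tidy method_comparison
#' @export
tidy.method_comparison <- function(x, ...) x$closest

#' One-row-per-method summary of a comparison
#'
#' @inheritParams tidy.method_comparison
#' @return Tibble with per-method total credit, share of genes where the
#'   method is closest to the benchmark, and mean absolute log2 error.
#' @method glance method_comparison
#' @export
glance.method_comparison <- function(x, ...) {
  if (nrow(x$closest) == 0L) {
    return(tibble(method = x$methods, credit = 0, closest_share = NA_real_,
                  mean_abs_delta = NA_real_))
  }
  credit <- x$closest |>
    group_by(.data$method) |>
    summarise(credit = sum(.data$credit), .groups = "drop")
  err <- x$deltas |>
    group_by(.data$method) |>
    summarise(mean_abs_delta = mean(.data$abs_delta), .groups = "drop")
  total <- sum(credit$credit)
  credit |>
    mutate(closest_share = .data$credit / total) |>
    left_join(err, by = "method") |>
    arrange(dplyr::desc(.data$credit))
}

#' One-row summary of a simulated experiment
#'
#' @param x A [simulate_truth()] result.
#' @param ... Unused.
#' @return Tibble with the scenario, sizes, dispersion, shifted fraction
#'   and the realized content-ratio range.
#' @method glance sim_truth
#' @export
glance.sim_truth <- function(x, ...) {
  cfg <- x$config
  tibble(scenario = cfg$scenario, n_genes = cfg$n_genes,
         n_stages = length(cfg$stages),
         shifted_fraction = cfg$shifted_fraction,
         dispersion = cfg$dispersion,
         z_min = min(x$content$z), z_max = max(x$content$z))
}

#' @export
print.scale_set <- function(x, ...) {
  cat(sprintf("<scale_set> kind=%s, convention=%s\n", scale_kind(x),
              scale_convention(x)))
  NextMethod()
}

#' @export
print.sim_truth <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<sim_truth> %s: %d genes x %d stages, f=%.2f, phi=%.3g\n",
              cfg$scenario, cfg$n_genes, length(cfg$stages),
              cfg$shifted_fraction, cfg$dispersion))
  cat("realized content ratios:",
      paste(sprintf("%s=%.3f", x$content$stage, x$content$z), collapse = ", "),
      "\n")
  invisible(x)
}
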