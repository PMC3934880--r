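#' Configuration for a synthetic global-shift experiment
#'
#' Builds the parameters of a simulated developmental series in which a
#' fraction of genes changes abundance per embryo, shifting the total
#' polyA+ mRNA content, while sequencing depth stays decoupled from
#' content. Two named scenarios emulate the two regimes around zygotic
#' genome activation:
#' \describe{
#'   \item{`pre_zga_polyadenylation`}{70% of genes gain polyA+ abundance
#'     by cytoplasmic polyadenylation; the total content rises to about
#'     1.55x the 1-cell level by 3.5 hpf (stage targets 1, 1.2, 1.4,
#'     1.55, 1.55).}
#'   \item{`post_zga_decay`}{30% of genes undergo strong miRNA-driven
#'     decay in the final stage; the total content falls to 0.75x
#'     (stage targets 1, 1, 1, 1, 0.75).}
#' }
#' For `custom`, supply `stages`, `content_targets` and
#' `shifted_fraction` yourself.
#'
#' @param scenario `"pre_zga_polyadenylation"`, `"post_zga_decay"` or
#'   `"custom"`.
#' @param n_genes Number of genes.
#' @param stages Stage labels; first stage is the reference.
#' @param content_targets Target content ratio per stage relative to the
#'   first stage (first element must be 1).
#' @param shifted_fraction Fraction f of genes affected by the shift.
#' @param effect_sdlog Log-normal sd (log scale) of per-gene shift
#'   magnitudes around the level needed to hit the content target; 0
#'   makes the shift uniform across shifted genes.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of
#'   baseline per-embryo abundances (arbitrary molecule units).
#' @param depths Sequencing depth per stage; a scalar is recycled. Depths
#'   are deliberately independent of content.
#' @param dispersion Negative-binomial dispersion phi (variance
#'   mu + phi mu^2); 0 gives Poisson counts.
#' @param seed Integer seed used by [simulate_truth()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(scenario = c("pre_zga_polyadenylation",
                                    "post_zga_decay", "custom"),
                       n_genes = 5000,
                       stages = c("1-cell", "16-cell", "128-cell",
                                  "3.5hpf", "5.3hpf"),
                       content_targets = NULL,
                       shifted_fraction = NULL,
                       effect_sdlog = 0.25,
                       baseline_meanlog = log(200),
                       baseline_sdlog = 1,
                       depths = 5e6,
                       dispersion = 0.1,
                       seed = 1L) {
  scenario <- match.arg(scenario)
  defaults <- switch(scenario,
    pre_zga_polyadenylation = list(f = 0.70,
                                   targets = c(1, 1.2, 1.4, 1.55, 1.55)),
    post_zga_decay = list(f = 0.30, targets = c(1, 1, 1, 1, 0.75)),
    custom = list(f = NULL, targets = NULL))
  if (is.null(shifted_fraction)) shifted_fraction <- defaults$f
  if (is.null(content_targets)) content_targets <- defaults$targets
  if (is.null(shifted_fraction) || is.null(content_targets)) {
    abort("custom scenario needs shifted_fraction and content_targets")
  }
  if (shifted_fraction < 0 || shifted_fraction > 1) {
    abort("shifted_fraction must lie in [0, 1]")
  }
  if (length(content_targets) != length(stages)) {
    abort("content_targets must match stages in length")
  }
  if (content_targets[1] != 1) abort("first content target must be 1 (reference)")
  if (any(content_targets <= 0)) abort("content targets must be positive")
  depths <- rep_len(depths, length(stages))
  if (any(depths <= 0)) abort("depths must be positive")
  if (dispersion < 0) abort("dispersion must be >= 0")
  structure(list(scenario = scenario, n_genes = as.integer(n_genes),
                 stages = stages, content_targets = content_targets,
                 shifted_fraction = shifted_fraction,
                 effect_sdlog = effect_sdlog,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 depths = setNames(depths, stages),
                 dispersion = dispersion, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate ground-truth per-embryo abundances
#'
#' Draws baseline abundances T_i at the reference stage from a log-normal
#' distribution, selects round(f x n_genes) shifted genes, and applies
#' per-gene multiplicative shifts at each later stage. Per stage the mean
#' shift is solved exactly from the realized baseline so that the
#' expected total content hits the configured target; individual shift
#' magnitudes are log-normal around it with a per-gene random effect that
#' is shared across stages (so a strongly responding gene responds
#' strongly throughout). The realized content totals C_j = sum_i T_ij and
#' scales Z_j = C_j / C_ref - not the nominal targets - are stored as
#' truth.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_truth` with elements `abundance` (tibble,
#'   gene by stage), `content` (tibble stage, content, z), `scales` (a
#'   [scale_set()] of the true Z_j), `shifted_genes`, and `config`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  stages <- config$stages
  f <- config$shifted_fraction
  genes <- sprintf("g%04d", seq_len(n))
  t_ref <- rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
  n_shift <- round(f * n)
  if (f > 0 && n_shift < 1) {
    warn("shifted fraction rounds to zero genes; simulating a null shift")
  }
  shifted <- if (n_shift >= 1) sort(sample.int(n, n_shift)) else integer()
  u <- rnorm(n)  # shared per-gene responsiveness
  tt <- matrix(t_ref, nrow = n, ncol = length(stages),
               dimnames = list(genes, stages))
  c_ref <- sum(t_ref)
  base_unshifted <- sum(t_ref) - sum(t_ref[shifted])
  for (s in seq_along(stages)[-1L]) {
    z_target <- config$content_targets[s]
    if (length(shifted) == 0L) next  # null shift: realized Z stays 1
    if (z_target == 1) next
    # mean multiplier over shifted genes needed to hit the target exactly
    mbar <- (z_target * c_ref - base_unshifted) / sum(t_ref[shifted])
    if (mbar <= 0) {
      abort(sprintf(
        "content target %.3g at stage '%s' is unreachable with shifted fraction %.2f",
        z_target, stages[s], f))
    }
    sdl <- config$effect_sdlog
    m <- mbar * exp(sdl * u[shifted] - sdl^2 / 2)
    tt[shifted, s] <- t_ref[shifted] * m
  }
  content <- colSums(tt)
  z <- content / content[1L]
  truth <- list(
    abundance = matrix_to_tbl(tt, genes),
    content = tibble(stage = stages, content = unname(content),
                     z = unname(z)),
    scales = scale_set(stages, unname(z), kind = "user",
                       reference = stages[1L],
                       notes = "simulation ground truth (realized content ratios)"),
    shifted_genes = genes[shifted],
    config = config)
  class(truth) <- "sim_truth"
  truth
}

#' Simulate sequencing counts from ground truth
#'
#' Depth is allocated by relative abundance: mu_ij = D_j x T_ij / C_j, the
#' mechanism by which library-size-limited sequencing erases global
#' content shifts from raw counts. Counts are negative binomial with
#' variance mu + phi mu^2 (Poisson when phi = 0).
#'
#' @param truth A [simulate_truth()] result.
#' @param seed Integer seed (defaults to the config seed + 1).
#' @return A [count_tbl()] with one column per stage.
#' @export
simulate_counts <- function(truth, seed = truth$config$seed + 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(seed)
  tt <- values_matrix(truth$abundance)
  cfg <- truth$config
  mu <- sweep(sweep(tt, 2, colSums(tt), "/"), 2, cfg$depths, "*")
  phi <- cfg$dispersion
  draw <- if (phi == 0) {
    function(m) rpois(length(m), m)
  } else {
    function(m) rnbinom(length(m), mu = m, size = 1 / phi)
  }
  counts <- matrix(draw(mu), nrow = nrow(mu), dimnames = dimnames(mu))
  count_tbl(matrix_to_tbl(counts, truth$abundance$gene))
}

#' Simulate a matched RT-qPCR experiment
#'
#' Target Ct values invert the true per-embryo abundances,
#' Ct = ct0 - log_E(T_ij) + noise, and the spike-in reference keeps a
#' constant Ct across stages (+ noise), emulating a fixed amount of
#' exogenous kanamycin RNA per embryo pool. With zero noise and matching
#' efficiency, [livak()] / [pfaffl()] fold changes recover the true
#' per-embryo fold changes exactly.
#'
#' @param truth A [simulate_truth()] result.
#' @param genes Genes to assay (default: 20 drawn at random, or all if
#'   fewer).
#' @param efficiency Amplification efficiency E used to generate (and
#'   reported for) all primer pairs, in (1, 2].
#' @param ct_noise_sd Gaussian noise sd on every Ct value, in cycles.
#' @param n_replicates Replicates per gene and stage.
#' @param ct0 Ct of one abundance unit (intercept).
#' @param ref_ct Constant spike-in reference Ct.
#' @param seed Integer seed (defaults to the config seed + 2).
#' @return A [qpcr_table()] with efficiencies attached.
#' @export
simulate_qpcr <- function(truth, genes = NULL, efficiency = 2,
                          ct_noise_sd = 0, n_replicates = 3, ct0 = 40,
                          ref_ct = 18, seed = truth$config$seed + 2L) {
  stopifnot(inherits(truth, "sim_truth"))
  if (efficiency <= 1 || efficiency > 2) abort("efficiency must lie in (1, 2]")
  set.seed(seed)
  all_genes <- truth$abundance$gene
  if (is.null(genes)) {
    genes <- if (length(all_genes) > 20L) sort(sample(all_genes, 20L)) else all_genes
  }
  miss <- setdiff(genes, all_genes)
  if (length(miss)) {
    abort(sprintf("unknown gene(s): %s", paste(miss, collapse = ", ")))
  }
  tt <- values_matrix(truth$abundance)
  stages <- truth$config$stages
  grid <- tidyr::expand_grid(gene = genes, stage = stages,
                             replicate = sprintf("r%d", seq_len(n_replicates)))
  grid$ct <- ct0 - log(tt[cbind(grid$gene, grid$stage)]) / log(efficiency) +
    rnorm(nrow(grid), 0, ct_noise_sd)
  ref <- tidyr::expand_grid(gene = "kanamycin", stage = stages,
                            replicate = sprintf("r%d", seq_len(n_replicates)))
  ref$ct <- ref_ct + rnorm(nrow(ref), 0, ct_noise_sd)
  effs <- tibble(gene = c(genes, "kanamycin"), efficiency = efficiency)
  qpcr_table(bind_rows(grid, ref), reference_gene = "kanamycin",
             efficiencies = effs)
}

#' Ground-truth log2 fold changes between stage pairs
#'
#' @param truth A [simulate_truth()] result.
#' @param pairs Character vector `"numerator/denominator"` of stage
#'   labels.
#' @param genes Optional subset of genes.
#' @return Tibble with columns `gene`, `pair`, `log2_fc` (exact
#'   log2(T_num / T_den)).
#' @export
true_fold_changes <- function(truth, pairs, genes = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  tt <- values_matrix(truth$abundance)
  if (!is.null(genes)) tt <- tt[genes, , drop = FALSE]
  parsed <- parse_pairs(pairs)
  purrr::pmap_dfr(parsed, function(pair, num, den) {
    for (s in c(num, den)) {
      if (!s %in% colnames(tt)) abort(sprintf("unknown stage '%s'", s))
    }
    tibble(gene = rownames(tt), pair = pair,
           log2_fc = unname(log2(tt[, num] / tt[, den])))
  })
}
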