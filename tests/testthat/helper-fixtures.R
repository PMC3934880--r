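# Shared fixtures and independent oracles for the test suite.

# small deterministic count table: genes g1..g3, samples s1, s2
tiny_counts <- function() {
  count_tbl(data.frame(gene = c("g1", "g2", "g3"),
                       s1 = c(50, 30, 20),
                       s2 = c(100, 60, 40)))
}

# random negative-binomial count table; `shift` adds 1 to every count so
# instances can be made zero-free for offset-free identities
rand_counts <- function(n_genes, n_samples, seed, mu = 200, size = 2,
                        zero_free = FALSE) {
  set.seed(seed)
  m <- matrix(rnbinom(n_genes * n_samples, mu = mu, size = size),
              nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%d", seq_len(n_samples))))
  if (zero_free) m <- m + 1
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  count_tbl(df)
}

rand_scales <- function(samples, seed) {
  set.seed(seed)
  scale_set(samples, exp(rnorm(length(samples), 0, 0.4)), kind = "user",
            reference = samples[1L],
            convention = "relative-to-reference") |>
    rebase_scales(samples[1L])
}

# ---- independent brute-force TMM oracle ------------------------------------
# Explicit per-gene loops, counting-based average ranks, literal trim
# bounds; shares nothing with the package implementation beyond the
# definition itself.

oracle_avg_rank <- function(v) {
  vapply(seq_along(v), function(i) {
    sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
  }, double(1))
}

oracle_tmm_pair <- function(m, sample, ref, trim_m = 0.30, trim_a = 0.05,
                            weighted = TRUE) {
  obs <- m[, sample]
  rfc <- m[, ref]
  n_obs <- sum(obs)
  n_ref <- sum(rfc)
  idx <- which(obs > 0 & rfc > 0)
  if (length(idx) == 0L) return(1)
  M <- A <- w <- double(length(idx))
  for (t in seq_along(idx)) {
    g <- idx[t]
    po <- obs[g] / n_obs
    pr <- rfc[g] / n_ref
    M[t] <- log2(po / pr)
    A[t] <- 0.5 * log2(po * pr)
    w[t] <- (n_obs - obs[g]) / (n_obs * obs[g]) +
            (n_ref - rfc[g]) / (n_ref * rfc[g])
  }
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  r_m <- oracle_avg_rank(M)
  r_a <- oracle_avg_rank(A)
  kept <- which(r_m >= lo_m & r_m <= hi_m & r_a >= lo_a & r_a <= hi_a)
  if (length(kept) == 0L) return(1)
  lf <- if (weighted) {
    num <- 0
    den <- 0
    for (t in kept) {
      num <- num + M[t] / w[t]
      den <- den + 1 / w[t]
    }
    num / den
  } else {
    s <- 0
    for (t in kept) s <- s + M[t]
    s / length(kept)
  }
  if (!is.finite(lf)) return(1)
  2^lf
}

# 75th percentile by explicit linear interpolation between order statistics
oracle_q75 <- function(x) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * 0.75 + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

oracle_tmm_reference <- function(m) {
  ls <- colSums(m)
  f75 <- vapply(seq_len(ncol(m)), function(j) oracle_q75(m[, j] / ls[j]),
                double(1))
  colnames(m)[which.min(abs(f75 - mean(f75)))]
}

oracle_tmm_factors <- function(m, trim_m = 0.30, trim_a = 0.05) {
  ref <- oracle_tmm_reference(m)
  f <- vapply(colnames(m), function(s) {
    if (identical(s, ref)) 1 else oracle_tmm_pair(m, s, ref, trim_m, trim_a)
  }, double(1))
  f / exp(mean(log(f)))
}

# ---- literal step-by-step replicate-aware BSN oracle -----------------------
oracle_bsn_replicates <- function(m, stage_of, scales = NULL) {
  ls <- colSums(m)
  e <- m
  for (j in seq_len(ncol(m))) e[, j] <- m[, j] / ls[j]
  stages <- unique(stage_of)
  # (a) + (b)
  stage_mat <- matrix(0, nrow(m), length(stages),
                      dimnames = list(rownames(m), stages))
  for (st in stages) {
    js <- which(stage_of == st)
    mean_lib <- mean(ls[js])
    acc <- 0
    for (j in js) acc <- acc + e[, j] * mean_lib
    stage_mat[, st] <- acc / length(js)
  }
  # (c)
  if (is.null(scales)) scales <- 1 / oracle_tmm_factors(stage_mat)
  # (d)
  rbar <- mean(ls)
  pseudo <- rbar * scales[stages]
  # (e)
  out <- e
  for (j in seq_len(ncol(m))) out[, j] <- e[, j] * pseudo[stage_of[j]]
  out
}

# matrix view of a gene+samples tibble
as_mat <- function(x) {
  m <- as.matrix(x[setdiff(names(x), "gene")])
  rownames(m) <- x$gene
  m
}
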