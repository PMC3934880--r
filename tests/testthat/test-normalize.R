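test_that("concentrations divide by library size and sum to one", {
  counts <- tiny_counts()
  e <- concentrations(counts)
  expect_equal(e$s1, c(0.5, 0.3, 0.2))
  expect_equal(colSums(as_mat(e)), c(s1 = 1, s2 = 1), tolerance = 1e-9)

  one <- count_tbl(data.frame(gene = "g1", s1 = 7, s2 = 9))
  expect_equal(unname(as_mat(concentrations(one))[1, ]), c(1, 1))

  zero_gene <- count_tbl(data.frame(gene = c("g1", "g2"), s1 = c(0, 5)))
  expect_equal(concentrations(zero_gene)$s1, c(0, 1))

  bad <- count_tbl(data.frame(gene = "g1", s1 = 0, s2 = 3))
  expect_error(concentrations(bad), "s1")
})

test_that("BSN reassigns pseudo libraries per the four-step procedure", {
  counts <- tiny_counts()
  z <- scale_set(c("s1", "s2"), c(1, 1.5), kind = "user", reference = "s1")
  n <- bsn(counts, z)
  expect_equal(attr(n, "avg_lib_size"), 150)
  expect_equal(unname(attr(n, "pseudo_lib_sizes")), c(150, 225))
  expect_equal(unname(as_mat(n)["g1", ]), c(75, 112.5))
  # conservation: column sums equal the pseudo library sizes
  expect_equal(colSums(as_mat(n)), attr(n, "pseudo_lib_sizes"),
               tolerance = 1e-9)
  expect_identical(norm_method(n), "bsn")
  expect_identical(value_space(n), "linear")
})

test_that("BSN with unit scales and equal libraries is the identity", {
  counts <- count_tbl(data.frame(gene = c("g1", "g2"),
                                 s1 = c(70, 30), s2 = c(20, 80)))
  z <- scale_set(c("s1", "s2"), c(1, 1), kind = "user", reference = "s1")
  expect_equal(as_mat(bsn(counts, z)), as_mat(counts))
})

test_that("BSN with unit scales equals RPM rescaled by Rbar/1e6", {
  for (seed in 1:5) {
    counts <- rand_counts(40, 3, seed = seed)
    z <- scale_set(sample_ids(counts), rep(1, 3), kind = "user",
                   reference = "s1")
    rbar <- mean(lib_sizes(counts))
    expect_equal(as_mat(bsn(counts, z)), as_mat(rpm(counts)) * rbar / 1e6,
                 tolerance = 1e-12)
  }
})

test_that("BSN errors on missing or non-positive scales", {
  counts <- tiny_counts()
  z1 <- scale_set("s1", 1, kind = "user", reference = "s1")
  expect_error(bsn(counts, z1), "s2")
})

test_that("replicate-aware BSN reduces to plain BSN for singleton stages", {
  counts <- tiny_counts()
  z <- scale_set(c("A", "B"), c(1, 1.5), kind = "user", reference = "A")
  groups <- data.frame(sample = c("s1", "s2"), stage = c("A", "B"))
  n_rep <- bsn_replicates(counts, groups, scales = z)
  z_sample <- scale_set(c("s1", "s2"), c(1, 1.5), kind = "user",
                        reference = "s1")
  expect_equal(as_mat(n_rep), as_mat(bsn(counts, z_sample)), tolerance = 1e-12)
})

test_that("two identical replicates average to each replicate's step-(a) values", {
  counts <- count_tbl(data.frame(gene = c("g1", "g2"),
                                 r1 = c(30, 70), r2 = c(30, 70),
                                 o1 = c(50, 50)))
  groups <- data.frame(sample = c("r1", "r2", "o1"),
                       stage = c("A", "A", "B"))
  z <- scale_set(c("A", "B"), c(1, 2), kind = "user", reference = "A")
  n <- bsn_replicates(counts, groups, scales = z)
  stage_means <- attr(n, "stage_means")
  # step (a) value for r1 = E * mean lib of stage A = the raw counts here
  expect_equal(stage_means$A, c(30, 70))
})

test_that("replicate-aware BSN matches the literal five-step oracle", {
  for (seed in 1:4) {
    counts <- rand_counts(60, 4, seed = 100 + seed)
    stage_of <- c(s1 = "A", s2 = "A", s3 = "B", s4 = "B")
    groups <- data.frame(sample = names(stage_of), stage = unname(stage_of))
    got <- bsn_replicates(counts, groups)
    want <- oracle_bsn_replicates(as_mat(counts), stage_of)
    expect_equal(as_mat(got), want, tolerance = 1e-9)
  }
  expect_error(bsn_replicates(tiny_counts(), data.frame(sample = "s1",
                                                        stage = "A")),
               "s2")
})

test_that("RPM columns sum to one million and ignore depth", {
  counts <- tiny_counts()
  n <- rpm(counts)
  expect_equal(n$s1[1], 5e5)
  expect_equal(colSums(as_mat(n)), c(s1 = 1e6, s2 = 1e6), tolerance = 1e-6)
  doubled <- count_tbl(data.frame(gene = counts$gene,
                                  s1 = counts$s1 * 2, s2 = counts$s2))
  expect_equal(as_mat(rpm(doubled)), as_mat(n), tolerance = 1e-12)
})

test_that("RPKM scales inversely with transcript length", {
  counts <- count_tbl(data.frame(gene = c("g1", "g2"),
                                 s1 = c(50, 999950)))
  lengths <- data.frame(gene = c("g1", "g2"), length = c(1000, 500))
  n <- rpkm(counts, lengths)
  expect_equal(n$s1[1], 50)
  halved <- rpkm(counts, data.frame(gene = c("g1", "g2"),
                                    length = c(500, 500)))
  expect_equal(halved$s1[1], 100)
  # uniform 1 kb lengths make RPKM equal RPM / 1 (per kb)
  kb <- data.frame(gene = counts$gene, length = 1000)
  expect_equal(as_mat(rpkm(counts, kb)), as_mat(rpm(counts)) / 1,
               tolerance = 1e-12)
  expect_error(rpkm(counts, data.frame(gene = "g1", length = 1000)), "g2")
})

test_that("TMM-log2 values follow the offset cpm formula and stay finite", {
  counts <- count_tbl(data.frame(gene = c("g1", "g2"),
                                 s1 = c(100, 999900), s2 = c(100, 999900)))
  z <- tmm_factors(counts)
  n <- tmm_log2(counts, z)
  expect_identical(value_space(n), "log2")
  expect_equal(n$s1[1], log2(100.5 * 1e6 / (1e6 + 1)), tolerance = 1e-12)

  zero <- count_tbl(data.frame(gene = c("g1", "g2"),
                               s1 = c(0, 100), s2 = c(50, 50)))
  expect_true(all(is.finite(as_mat(tmm_log2(zero, tmm_factors(zero))))))

  wrong <- scale_set(c("s1", "s2"), c(1, 1.5), kind = "user",
                     reference = "s1")
  expect_error(tmm_log2(counts, wrong), "geometric mean")
})

test_that("TMM-log2 differences approach RPM log2 fold changes at high counts", {
  set.seed(4)
  big <- count_tbl(data.frame(gene = sprintf("g%d", 1:20),
                              s1 = rpois(20, 5e4) + 1e4,
                              s2 = rpois(20, 5e4) + 1e4))
  unit <- scale_set(c("s1", "s2"), c(1, 1), kind = "tmm",
                    convention = "geometric-mean-1")
  tl <- tmm_log2(big, unit)
  fc_tmm <- tl$s2 - tl$s1
  r <- rpm(big)
  fc_rpm <- log2(r$s2 / r$s1)
  expect_equal(fc_tmm, fc_rpm, tolerance = 1e-3)
})

test_that("normalizations are equivariant under gene and sample permutation", {
  counts <- rand_counts(30, 3, seed = 77, zero_free = TRUE)
  perm_g <- sample(nrow(counts))
  perm_s <- c("s3", "s1", "s2")
  shuffled <- count_tbl(counts[perm_g, c("gene", perm_s)])
  z <- rand_scales(sample_ids(counts), seed = 8)
  expect_equal(as_mat(bsn(shuffled, z)),
               as_mat(bsn(counts, z))[perm_g, perm_s])
  expect_equal(as_mat(rpm(shuffled)), as_mat(rpm(counts))[perm_g, perm_s])
})
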