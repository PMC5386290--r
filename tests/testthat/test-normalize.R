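test_that("median-of-ratios size factors match hand computation", {
  design <- toy_design(conditions = c("ctrl", "a"), n_rep = 1, times = "t1")
  # rows (2,8) and (2,8): geomeans 4; per-sample ratios 0.5 and 2
  counts <- matrix(c(2L, 2L, 8L, 8L), nrow = 2,
                   dimnames = list(c("g1", "g2"), design$sample))
  em <- expression_matrix(counts, design)
  expect_equal(unname(compute_size_factors(em, rescale = FALSE)), c(0.5, 2))
  expect_equal(unname(compute_size_factors(em)), c(0.5, 2))  # geomean already 1

  # zero-containing row excluded from the reference set
  counts2 <- matrix(as.integer(c(0, 4, 3, 3, 12, 3)), nrow = 3, byrow = TRUE,
                    dimnames = list(paste0("g", 1:3), design$sample))
  em2 <- expression_matrix(counts2, design)
  expect_equal(unname(compute_size_factors(em2, rescale = FALSE)), c(1.5, 0.75))

  # identical columns -> equal factors, all 1 after rescaling
  counts3 <- matrix(c(5L, 9L, 5L, 9L), nrow = 2,
                    dimnames = list(c("g1", "g2"), design$sample))
  em3 <- expression_matrix(counts3, design)
  expect_equal(unname(compute_size_factors(em3)), c(1, 1))

  # no all-positive reference gene is a hard error
  counts4 <- matrix(as.integer(c(0, 4, 12, 0)), nrow = 2, byrow = TRUE,
                    dimnames = list(c("g1", "g2"), design$sample))
  em4 <- expression_matrix(counts4, design)
  expect_error(compute_size_factors(em4), "pseudocount")
})

test_that("log2 normalization applies the closed form with pseudocount 1", {
  design <- toy_design(conditions = c("ctrl", "a"), n_rep = 1, times = "t1")
  counts <- matrix(c(7L, 0L, 1L, 3L), nrow = 2,
                   dimnames = list(c("g1", "g2"), design$sample))
  em <- expression_matrix(counts, design)
  nm <- normalize_log2(em, factors = c(0.5, 1))
  expect_equal(nm$log2["g1", 1], log2(7 / 0.5 + 1))  # 3.906891
  expect_equal(unname(nm$log2["g2", 1]), 0)          # count 0 -> 0
  expect_equal(unname(nm$log2["g1", 2]), 1)          # count 1, factor 1
  expect_true(all(nm$log2 >= 0))
  expect_error(normalize_log2(em, factors = c(-1, 1)), "positive")
})

test_that("fold changes are replicate-mean differences against control at each time", {
  design <- toy_design(conditions = c("ctrl", "trt"), n_rep = 3, times = "t1")
  v <- matrix(c(1, 2, 3, 4, 5, 6,       # g1: ctrl reps then trt reps
                3, 3, 3, 5, 5, 5,       # g2: means 3 vs 5
                2, 2, 2, 2, 2, 2),      # g3: identical
              nrow = 3, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), design$sample))
  nm <- nm_from_log2(v, design)
  fc <- fold_change_vs_control(nm)
  expect_equal(unname(fc$fc["g1", "trt.t1"]), 3)   # 5 - 2
  expect_equal(unname(fc$fc["g2", "trt.t1"]), 2)
  expect_equal(unname(fc$fc["g3", "trt.t1"]), 0)
  expect_identical(colnames(fc$fc), "trt.t1")

  # a condition whose replicate values equal the control's has FC == 0
  design2 <- toy_design(conditions = c("ctrl", "same"), n_rep = 2, times = "t1")
  v2 <- matrix(c(4, 6, 4, 6), nrow = 1,
               dimnames = list("g1", design2$sample))
  expect_equal(unname(fold_change_vs_control(nm_from_log2(v2, design2))$fc["g1", ]), 0)

  # missing control at a time point is a hard error
  design3 <- toy_design(conditions = c("ctrl", "trt"), n_rep = 1, times = c("t1", "t2"))
  keep <- !(design3$condition == "ctrl" & design3$time == "t2")
  d3 <- design3[keep, ]; class(d3) <- class(design3)
  v3 <- matrix(1:3, nrow = 1, dimnames = list("g1", d3$sample))
  expect_error(fold_change_vs_control(nm_from_log2(v3, d3)), "t2")
})

test_that("scaling one sample rescales its factor and leaves fold changes invariant", {
  design <- toy_design(conditions = c("ctrl", "trt"), n_rep = 2, times = "t1")
  set.seed(42)
  counts <- matrix(as.integer(round(2^stats::runif(200 * 4, 6, 12))), ncol = 4,
                   dimnames = list(sprintf("g%03d", 1:200), design$sample))
  em <- expression_matrix(counts, design)
  f1 <- compute_size_factors(em, rescale = FALSE)
  fc1 <- fold_change_vs_control(normalize_log2(em, compute_size_factors(em)))

  lambda <- 3L
  counts2 <- counts
  counts2[, 2] <- counts2[, 2] * lambda
  em2 <- expression_matrix(counts2, design)
  f2 <- compute_size_factors(em2, rescale = FALSE)
  # factors are relative scalings: the scaled sample's factor grows by lambda
  # against every other sample (the per-gene geometric means absorb
  # lambda^(1/m), so the absolute factors shift together)
  expect_equal(unname(f2[2] / f2[-2]), unname(lambda * f1[2] / f1[-2]),
               tolerance = 1e-12)

  fc2 <- fold_change_vs_control(normalize_log2(em2, compute_size_factors(em2)))
  expect_equal(fc2$fc, fc1$fc, tolerance = 0.01)  # counts >> 1, pseudocount negligible
})

test_that("replicate-level significance flags behave at the edges and under the null", {
  design <- toy_design(conditions = c("ctrl", "trt"), n_rep = 3, times = "t1")

  # identical replicate vectors in both groups -> p = 1, never flagged
  v <- matrix(rep(c(5, 6, 7), 2), nrow = 1, dimnames = list("g1", design$sample))
  flags <- flag_significant_genes(nm_from_log2(v, design))
  expect_equal(flags$p, 1)
  expect_false(flags$significant)

  # planted 8-log2-unit shift at sigma 0.1 is flagged
  set.seed(7)
  v2 <- rbind(g1 = c(stats::rnorm(3, 2, 0.1), stats::rnorm(3, 10, 0.1)),
              g2 = stats::rnorm(6, 5, 0.1))
  colnames(v2) <- design$sample
  flags2 <- flag_significant_genes(nm_from_log2(v2, design))
  expect_true(flags2$significant[flags2$gene == "g1"])
  expect_false(flags2$significant[flags2$gene == "g2"])

  # Monte-Carlo null: Bonferroni family-wise error rate near alpha = 0.05
  set.seed(11)
  n_rep <- 500
  any_flag <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    vn <- matrix(stats::rnorm(200 * 6, 8, 0.5), nrow = 200,
                 dimnames = list(sprintf("g%03d", 1:200), design$sample))
    fl <- flag_significant_genes(nm_from_log2(vn, design))
    any_flag[i] <- any(fl$p_bonf < 0.05)
  }
  expect_lt(mean(any_flag), 0.08)  # 0.05 plus 3 binomial standard errors
})

test_that("BH-adjusted p-values never exceed Bonferroni-adjusted ones", {
  design <- toy_design(conditions = c("ctrl", "trt"), n_rep = 3, times = c("t1", "t2"))
  set.seed(3)
  v <- matrix(stats::rnorm(150 * nrow(design), 8, 1), nrow = 150,
              dimnames = list(sprintf("g%03d", 1:150), design$sample))
  flags <- flag_significant_genes(nm_from_log2(v, design))
  expect_true(all(flags$p_bh <= flags$p_bonf + 1e-15))
  expect_identical(attr(flags, "method"), "welch_log2")
})

test_that("fewer than two replicates yields undefined flags with a warning", {
  design <- toy_design(conditions = c("ctrl", "trt"), n_rep = 1, times = "t1")
  v <- matrix(c(1, 5), nrow = 1, dimnames = list("g1", design$sample))
  expect_warning(flags <- flag_significant_genes(nm_from_log2(v, design)),
                 "replicates")
  expect_true(is.na(flags$p))
})
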