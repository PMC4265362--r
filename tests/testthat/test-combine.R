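test_that("the Fisher transform matches closed forms and is monotone", {
  expect_equal(fisher_T(c(0.5, 0.5)), -4 * log(0.5))
  expect_equal(fisher_T(c(0.5, 0.5)), 2.77259, tolerance = 1e-5)
  expect_equal(fisher_T(c(1, 1, 1)), 0)
  p <- c(0.2, 0.8, 0.05)
  p2 <- p; p2[2] <- 0.4
  expect_gt(fisher_T(p2), fisher_T(p))
  expect_error(fisher_T(c(0.5, 0)), "floor")
})

test_that("the Stouffer transform matches normal quantiles and is antisymmetric", {
  expect_equal(stouffer_T(rep(0.5, 7)), 0)
  expect_equal(stouffer_T(0.025), 1.959964, tolerance = 1e-6)
  p <- c(0.1, 0.37, 0.81)
  expect_equal(stouffer_T(p), -stouffer_T(1 - p))
  expect_error(stouffer_T(c(0.2, 1)), "strictly inside")
})

test_that("the Gamma transform interpolates between Fisher and soft truncation", {
  # shape 1: qgamma(1 - p, 1) = -log(p), so T = fisher_T / 2 exactly
  expect_equal(gamma_T(exp(-1), 1), 1)
  set.seed(4)
  p <- runif(25, 0.001, 0.999)
  expect_equal(gamma_T(p, 1), fisher_T(p) / 2, tolerance = 1e-12)
  # fixed point at the soft truncation threshold: H(stt) = w
  w <- stt_to_shape(0.05)
  expect_equal(qgamma(0.05, shape = w, scale = 1, lower.tail = FALSE), w,
               tolerance = 1e-6)
  expect_lt(abs(gamma_T(0.05, w) - 0.0137), 1e-3)
})

test_that("stt_to_shape solves the published fixed points and is monotone", {
  expect_equal(stt_to_shape(0.05), 0.0137, tolerance = 0.0005 / 0.0137)
  expect_equal(stt_to_shape(exp(-1)), 1, tolerance = 1e-6)
  grid <- c(0.01, 0.05, 0.1, 0.2, 0.3, exp(-1), 0.45, 0.49)
  sol <- vapply(grid, stt_to_shape, numeric(1))
  expect_true(all(diff(sol) > 0))
  # each solution satisfies its own fixed point
  for (i in seq_along(grid)) {
    expect_equal(qgamma(grid[i], shape = sol[i], scale = 1, lower.tail = FALSE),
                 sol[i], tolerance = 1e-6)
  }
  expect_error(stt_to_shape(0.5), "Stouffer limit")
  expect_error(stt_to_shape(0))
  # round trip with the inverse
  expect_equal(shape_to_stt(stt_to_shape(0.12)), 0.12, tolerance = 1e-6)
})

test_that("combiner_spec ties the GM shape and STT together", {
  spec <- combiner_spec("GM", stt = 0.05)
  expect_equal(spec$shape, 0.0137, tolerance = 0.0005 / 0.0137)
  spec2 <- combiner_spec("GM", shape = 1)
  expect_equal(spec2$stt, exp(-1), tolerance = 1e-6)
  expect_error(combiner_spec("GM", stt = 0.3, shape = 1), "disagree")
  expect_null(combiner_spec("FM")$shape)
})

test_that("the combiner transforms show their qualitative shapes", {
  # Fisher: unbounded near 0, finite at 1
  expect_gt(fisher_T(1e-12), 50)
  expect_equal(fisher_T(1), 0)
  # Stouffer: antisymmetric about one half
  expect_equal(stouffer_T(0.2), -stouffer_T(0.8))
  # Gamma with STT 0.05 ignores everything but tiny P-values
  w <- stt_to_shape(0.05)
  expect_lt(gamma_T(0.2, w) / gamma_T(1e-5, w), 0.01)
})

test_that("GM with shape 1 ranks gene sets exactly like Fisher", {
  set.seed(10)
  scores_fm <- scores_gm <- numeric(40)
  for (i in 1:40) {
    p <- runif(sample(5:20, 1), 1e-4, 0.999)
    scores_fm[i] <- fisher_T(p)
    scores_gm[i] <- gamma_T(p, 1)
  }
  expect_equal(cor(rank(scores_fm), rank(scores_gm)), 1)
})

test_that("the built-in Welch gene test is calibrated and symmetric", {
  set.seed(6)
  vals <- matrix(rnorm(2000 * 12), 2000, 12,
                 dimnames = list(sprintf("g%04d", 1:2000), sprintf("s%02d", 1:12)))
  em <- raw_expression(vals, log_transformed = TRUE)
  labels <- setNames(rep(c("X", "Y"), each = 6), colnames(vals))
  p <- default_gene_test(em, labels)
  expect_identical(nrow(p), 2000L)
  expect_true(all(p$p.value > 0 & p$p.value <= 1))
  # uniform under the null
  expect_lt(suppressWarnings(ks.test(p$p.value, "punif"))$statistic, 0.05)
  # label swap leaves two-sided P unchanged
  labels_swapped <- setNames(rep(c("Y", "X"), each = 6), colnames(vals))
  p_sw <- default_gene_test(em, labels_swapped)
  expect_equal(p_sw$p.value, p$p.value)
  # a strongly shifted gene is detected
  vals2 <- vals
  vals2["g0001", 7:12] <- vals2["g0001", 7:12] + 5
  em2 <- raw_expression(vals2, log_transformed = TRUE)
  p2 <- default_gene_test(em2, labels)
  expect_lt(p2$p.value[p2$gene_id == "g0001"], 1e-3)
  # matches t.test gene by gene
  for (g in c("g0002", "g0100")) {
    expect_equal(p$p.value[p$gene_id == g],
                 t.test(vals[g, 1:6], vals[g, 7:12])$p.value,
                 tolerance = 1e-10)
  }
})

test_that("combine_and_permute reduces to the single-gene permutation test", {
  set.seed(14)
  vals <- matrix(rnorm(3 * 14), 3, 14,
                 dimnames = list(sprintf("g%d", 1:3), sprintf("s%02d", 1:14)))
  vals[1, 8:14] <- vals[1, 8:14] + 1.5
  em <- raw_expression(vals, log_transformed = TRUE)
  labels <- setNames(rep(c("X", "Y"), each = 7), colnames(vals))
  outs <- lapply(list(combiner_spec("FM"), combiner_spec("SM"),
                      combiner_spec("GM", stt = 0.05)),
                 function(sp) combine_and_permute(em, "g1", labels, sp,
                                                  B = 200, seed = 3))
  # one gene: any monotone transform gives the same permutation P
  expect_equal(outs[[1]]$p.value, outs[[2]]$p.value)
  expect_equal(outs[[1]]$p.value, outs[[3]]$p.value)
})

test_that("combine_and_permute accepts a plug-in gene test", {
  set.seed(15)
  vals <- matrix(rnorm(4 * 10), 4, 10,
                 dimnames = list(sprintf("g%d", 1:4), sprintf("s%02d", 1:10)))
  em <- raw_expression(vals, log_transformed = TRUE)
  labels <- setNames(rep(c("X", "Y"), each = 5), colnames(vals))
  # plug-in that reproduces the built-in: identical outcome
  plug <- function(x, g) mstgsa:::welch_p_matrix(x, matrix(g, ncol = 1))[, 1]
  a <- combine_and_permute(em, rownames(vals), labels, combiner_spec("FM"),
                           gene_test = plug, B = 100, seed = 5)
  b <- combine_and_permute(em, rownames(vals), labels, combiner_spec("FM"),
                           B = 100, seed = 5)
  expect_equal(a$p.value, b$p.value)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  # zero P-values from a degenerate plug-in are floored, not fatal
  zero_test <- function(x, g) rep(0, nrow(x))
  z <- combine_and_permute(em, rownames(vals), labels, combiner_spec("FM"),
                           gene_test = zero_test, B = 50, seed = 6)
  expect_true(is.finite(z$statistic))
  expect_equal(z$p.value, 1)  # constant under permutation
})
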