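test_that("run_type1_table produces a reproducible grid and recounts at new levels", {
  pool <- synth_param_pool(2000, seed = 2)
  tbl <- run_type1_table(pool, tests = c("N", "WW"), normalizations = "rpkm",
                         N = c(12L, 16L), p = 6L, n_sets = 10L, B = 60L,
                         alpha = 0.05, seed = 5)
  expect_identical(nrow(tbl), 4L)  # 2 tests x 2 sample sizes
  expect_setequal(unique(tbl$N), c(12L, 16L))
  tbl2 <- run_type1_table(pool, tests = c("N", "WW"), normalizations = "rpkm",
                          N = c(12L, 16L), p = 6L, n_sets = 10L, B = 60L,
                          alpha = 0.05, seed = 5)
  expect_identical(tbl$type1, tbl2$type1)

  # recount at a stricter level without re-simulation
  strict <- type1_at(tbl, 0.01)
  res <- attr(tbl, "results")
  manual <- mean(res$p.prop[res$method == "N" & res$N == 12L] <= 0.01)
  expect_equal(strict$type1[strict$method == "N" & strict$N == 12L], manual)
  joined <- dplyr::inner_join(
    tibble::as_tibble(strict)[c("method", "N", "type1")],
    tibble::as_tibble(tbl)[c("method", "N", "type1")],
    by = c("method", "N"), suffix = c("_strict", "_nominal")
  )
  expect_true(all(joined$type1_strict <= joined$type1_nominal))
})

test_that("run_type1_table caches cells and resumes from the cache", {
  pool <- synth_param_pool(1500, seed = 4)
  cache <- withr::local_tempdir()
  args <- list(pool, tests = "N", normalizations = "rpkm", N = 12L, p = 4L,
               n_sets = 6L, B = 40L, alpha = 0.05, seed = 9, cache_dir = cache)
  t1 <- do.call(run_type1_table, args)
  expect_gt(length(list.files(cache)), 0L)
  t2 <- do.call(run_type1_table, args)
  expect_identical(t1$type1, t2$type1)
})

test_that("run_power_curves matches a direct estimate_power call", {
  pool <- synth_param_pool(1500, seed = 6)
  pw <- run_power_curves(pool, tests = "N", normalizations = "rpkm",
                         fc = 2, gamma = 0.5, N = 12L, p = 6L,
                         n_sets = 10L, B = 50L, seed = 7)
  design <- simulation_design(N = 12, p = 6, gamma = 0.5, fc = 2,
                              n_sets = 10, B = 50, seed = 7)
  direct <- estimate_power(pool, design, fc = 2, gamma = 0.5, test = "N",
                           normalization = "rpkm")
  expect_equal(pw$power, direct$power)
})

test_that("pathway_bias_summary flags constructed gene-length separation", {
  set.seed(30)
  n_sets <- 40; p <- 8
  genes <- sprintf("g%03d", seq_len(n_sets * p))
  vals <- matrix(rnorm(length(genes) * 12), length(genes), 12,
                 dimnames = list(genes, sprintf("s%02d", 1:12)))
  labels <- setNames(rep(c("X", "Y"), each = 6), colnames(vals))
  set_names <- sprintf("S%02d", seq_len(n_sets))
  sets <- gene_set_collection(setNames(
    split(genes, rep(set_names, each = p))[set_names], set_names))
  # long-gene half of the collection; shift its genes so it is detected
  long_half <- set_names[1:20]
  lengths <- setNames(rep(500, length(genes)), genes)
  lengths[unlist(unclass(sets)[long_half])] <- 5000
  for (s in long_half) vals[sets[[s]], labels == "Y"] <-
    vals[sets[[s]], labels == "Y"] + 3
  em <- raw_expression(vals, log_transformed = TRUE)
  res <- gsa_test(em, sets, labels, method = "N", B = 100, seed = 3)

  bias <- pathway_bias_summary(res, em, sets, labels, lengths, alpha = 0.05)
  # every shifted long-gene set is detected; chance detections of null sets
  # are possible but rare, so the rank-sum comparison still separates
  expect_true(all(long_half %in% bias$pathways$set))
  expect_lt(bias$ranksum_p, 0.01)
  in_long <- bias$pathways$set %in% long_half
  expect_true(all(bias$pathways$frac_de[in_long] > 0.5))

  # detected = all sets -> rank-sum degenerates to 1
  res_all <- res
  res_all$p.value <- 0.001
  bias_all <- pathway_bias_summary(res_all, em, sets, labels, lengths)
  expect_equal(bias_all$ranksum_p, 1)

  # nothing detected -> empty table, flag P of 1
  res_none <- res
  res_none$p.value <- 0.99
  bias_none <- pathway_bias_summary(res_none, em, sets, labels, lengths)
  expect_identical(bias_none$n_detected, 0L)
  expect_equal(bias_none$ranksum_p, 1)
  expect_identical(nrow(glance(bias_none)), 1L)
})

test_that("a null pathway has near-zero DE fraction at FDR 0.05", {
  set.seed(44)
  genes <- sprintf("g%03d", 1:200)
  vals <- matrix(rnorm(200 * 16), 200, 16,
                 dimnames = list(genes, sprintf("s%02d", 1:16)))
  em <- raw_expression(vals, log_transformed = TRUE)
  labels <- setNames(rep(c("X", "Y"), each = 8), colnames(vals))
  sets <- gene_set_collection(list(NULLSET = genes[1:50]))
  res <- tibble::tibble(set = "NULLSET", p.value = 0.01)
  bias <- pathway_bias_summary(res, em, sets, labels,
                               setNames(rep(1000, 200), genes))
  expect_lt(bias$pathways$frac_de, 0.05)
})

test_that("overlap_counts books Venn cells by inclusion-exclusion", {
  mk <- function(p) tibble::tibble(set = sprintf("S%d", 1:6), p.value = p)
  a <- mk(c(0.01, 0.01, 0.2, 0.2, 0.01, 0.6))
  b <- mk(c(0.01, 0.2, 0.01, 0.2, 0.01, 0.6))
  c3 <- mk(c(0.2, 0.2, 0.2, 0.01, 0.01, 0.6))
  out <- overlap_counts(list(A = a, B = b, C = c3), alpha = 0.05)
  # union = S1..S5; cells: A only (S2), B only (S3), C only (S4), AB (S1), ABC (S5)
  expect_equal(sum(out$n_sets), 5L)
  expect_equal(out$n_sets[out$A & out$B & out$C], 1L)
  expect_equal(out$n_sets[out$A & !out$B & !out$C], 1L)

  # identical tables: all mass in the full intersection
  out2 <- overlap_counts(list(A = a, B = a), alpha = 0.05)
  expect_identical(nrow(out2), 1L)
  expect_true(out2$A & out2$B)
  expect_equal(out2$n_sets, 3L)

  # disjoint detections: no joint cell
  d1 <- mk(c(0.01, 0.2, 0.2, 0.2, 0.2, 0.2))
  d2 <- mk(c(0.2, 0.01, 0.2, 0.2, 0.2, 0.2))
  out3 <- overlap_counts(list(A = d1, B = d2), alpha = 0.05)
  expect_equal(sum(out3$n_sets[out3$A & out3$B]), 0L)

  # mismatched collections error
  expect_error(overlap_counts(list(A = a, B = mk(0.01 + numeric(6)) |>
                                     dplyr::mutate(set = sprintf("T%d", 1:6)))),
               "different gene set collections")
})

test_that("null rejection rates are insensitive to the pathway size", {
  pool <- synth_param_pool(8000, seed = 17)
  rates <- vapply(c(16L, 100L), function(p) {
    design <- simulation_design(N = 20, p = p, gamma = 0, fc = 1,
                                n_sets = 150, B = 250, seed = 18)
    estimate_type1(pool, design, test = "N", normalization = "rpkm")$type1
  }, numeric(1))
  se2 <- 2 * sqrt(2 * 0.05 * 0.95 / 150)
  expect_lt(abs(rates[1] - rates[2]), 0.02 + se2)
})

test_that("tidiers and autoplot methods return the expected shapes", {
  cm <- random_count_matrix(20, 8, seed = 50)
  em <- normalize_counts(cm, "rpkm")
  sets <- gene_set_collection(list(S1 = rownames(cm$counts)[1:10],
                                   S2 = rownames(cm$counts)[11:20]))
  labels <- setNames(rep(c("X", "Y"), each = 4), colnames(cm$counts))
  res <- gsa_test(em, sets, labels, method = c("N", "KS"), B = 50, seed = 1)
  td <- tidy(res)
  expect_false(inherits(td, "gsa_result"))
  expect_identical(nrow(td), 4L)
  gl <- glance(res)
  expect_identical(nrow(gl), 2L)
  expect_true(all(c("n_sets", "n_detected", "detection_rate") %in% names(gl)))
  expect_s3_class(autoplot(res), "ggplot")

  pool <- synth_param_pool(1000, seed = 3)
  pw <- run_power_curves(pool, tests = "N", normalizations = "rpkm",
                         fc = c(1.5, 2), gamma = 0.5, N = 10L, p = 4L,
                         n_sets = 5L, B = 30L, seed = 2)
  expect_s3_class(autoplot(pw), "ggplot")
  expect_s3_class(plot_combiner_transforms(0.05), "ggplot")

  t1 <- run_type1_table(pool, tests = "N", normalizations = "rpkm",
                        N = 10L, p = 4L, n_sets = 5L, B = 30L, seed = 2)
  expect_s3_class(autoplot(t1), "ggplot")
})
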