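make_counts <- function(a_ctrl, a_ind, b_ctrl, b_ind, ids = NULL) {
  n <- length(a_ctrl)
  if (is.null(ids)) ids <- sprintf("p%03d", seq_len(n))
  tibble::tibble(
    pair_id = rep(ids, 4),
    allele = rep(c("A", "A", "B", "B"), each = n),
    condition = rep(c("ctrl", "induced", "ctrl", "induced"), each = n),
    count = c(a_ctrl, a_ind, b_ctrl, b_ind))
}

test_that("per-allele calls follow the fold-change and floor rules", {
  counts <- make_counts(a_ctrl = c(100, 10, 100),
                        a_ind  = c(100, 100, 100),
                        b_ctrl = c(100, 50, 1),
                        b_ind  = c(100, 50, 2))
  resp <- call_allele_response(counts, normalize = "none")
  expect_equal(resp$call_a, c("none", "up", "none"))
  expect_equal(resp$call_b, c("none", "none", "none"))
  # the floor blocks a call regardless of the ratio
  expect_false(resp$expressed_b[3])
  expect_false(resp$candidate[3])
  expect_error(call_allele_response(dplyr::mutate(counts, count = -count)),
               "negative")
})

test_that("type assignment implements the five-way definition totally", {
  calls <- expand.grid(a = c("up", "down", "none"),
                       b = c("up", "down", "none"),
                       stringsAsFactors = FALSE)
  ty <- assign_type(calls$a, calls$b)
  expect_false(anyNA(ty))
  expect_equal(assign_type("none", "none"), 0L)
  expect_equal(assign_type("up", "none"), 1L)
  expect_equal(assign_type("down", "none"), 1L)
  expect_equal(assign_type("up", "down"), 2L)
  expect_equal(assign_type("down", "up"), 2L)
  expect_equal(assign_type("none", "down"), 3L)
  expect_equal(assign_type("up", "up"), 4L)
  expect_equal(assign_type("down", "down"), 4L)
})

test_that("swapping allele labels maps types 1 and 3 onto each other", {
  cfg <- sim_config(seed = 71, n_genes = 400)
  expr <- simulate_expression(cfg)
  typed <- type_genes(expr$counts)
  swapped_counts <- dplyr::mutate(expr$counts,
                                  allele = c(A = "B", B = "A")[allele])
  typed_sw <- type_genes(swapped_counts)
  joined <- dplyr::inner_join(typed, typed_sw, by = "pair_id")
  map <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 4L)
  expect_equal(joined$type.y, unname(map[as.character(joined$type.x)]))
})

test_that("median-ratio size factors agree with the DESeq2 estimator", {
  cfg <- sim_config(seed = 72, n_genes = 300)
  expr <- simulate_expression(cfg)
  counts <- dplyr::mutate(expr$counts,
                          library = paste(condition, 1L, sep = "."),
                          feature = paste(pair_id, allele, sep = "."))
  sf <- cisdiverge:::library_size_factors(counts, "median_ratio")
  mat <- tidyr::pivot_wider(counts[c("feature", "library", "count")],
                            names_from = library, values_from = count)
  m <- as.matrix(mat[, sf$library])
  oracle <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(sf$size_factor, unname(oracle), tolerance = 1e-10)
})

test_that("planted regulation types are recovered at the study conditions", {
  cfg <- sim_config(seed = 73, n_genes = 1000, dispersion = 0.005)
  expr <- simulate_expression(cfg)
  typed <- type_genes(expr$counts)
  joined <- dplyr::inner_join(typed, expr$truth, by = "pair_id")
  expect_gte(mean(joined$type.x == joined$type.y), 0.95)
  planted <- tabulate(expr$truth$type + 1L, 5) / cfg$n_genes
  recovered <- tabulate(typed$type + 1L, 5) / nrow(typed)
  expect_true(all(abs(planted - recovered) < 0.02))
})

test_that("the native Welch t matches stats::t.test to 1e-6", {
  x <- c(2.1, 2.4, 1.9, 2.6, 2.2)
  y <- c(1.1, 1.5, 0.9, 1.2, 1.4)
  ours <- welch_t(x, y)
  ref <- stats::t.test(x, y)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-6)
  expect_equal(ours$parameter, unname(ref$parameter), tolerance = 1e-6)
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-6)

  same <- welch_t(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  dir <- welch_t(c(2, 2, 2, 2) + rnorm(4, 0, 1e-6), c(1, 1, 1, 1))
  expect_gt(dir$statistic, 100)
  expect_lt(dir$p.value, 1e-4)
  expect_error(welch_t(1, c(1, 2)), "n >= 2")
})

test_that("magnitude_test compares type 4 against allele-specific types", {
  set.seed(74)
  typed <- tibble::tibble(
    type = rep(c(1L, 3L, 4L), each = 20),
    log2fc_a = c(rnorm(20, 1.5, 0.2), rnorm(20, 0, 0.2), rnorm(20, 3, 0.2)),
    log2fc_b = c(rnorm(20, 0, 0.2), rnorm(20, 1.5, 0.2), rnorm(20, 3, 0.2)))
  mt <- magnitude_test(typed)
  td <- tidy(mt)
  expect_equal(nrow(td), 2L)
  expect_true(all(td$statistic > 0))   # type 4 magnitudes are larger
  expect_true(all(td$p.value < 0.01))
  gl <- glance(mt)
  expect_equal(gl$n_type4, 20L)
  p <- ggplot2::autoplot(mt)
  expect_s3_class(p, "ggplot")
})

test_that("expression correlation matches the covariance formula exactly", {
  x <- c(1.2, 2.3, 3.1, 4.8, 5.2, 6.9, 7.1, 8.4, 9.9, 10.5)
  set.seed(75)
  y <- 2 * x + rnorm(10)
  ours <- expression_correlation(x, y)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(ours$estimate, r_direct, tolerance = 1e-12)
  expect_equal(expression_correlation(x, 2 * x + 1)$estimate, 1)
  expect_equal(expression_correlation(x, -x)$estimate, -1)
  expect_error(expression_correlation(x, y[1:5]), "equal length")
})
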