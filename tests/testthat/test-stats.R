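# Pixel-wise and scalar group statistics.

make_stack <- function(n_animals, nz = 20, nt = 18, gen = function(i)
  matrix(rnorm(nz * nt), nz, nt)) {
  maps <- lapply(seq_len(n_animals), function(i) {
    v <- gen(i)
    structure(list(values = v, valid = matrix(TRUE, nrow(v), ncol(v)),
                   grid_z = seq_len(nrow(v)) * 0.02,
                   grid_theta = seq(0, by = 2, length.out = ncol(v))),
              class = "projection_map")
  })
  map_stack(maps)
}

test_that("identical constant groups give zero difference and undefined p", {
  set.seed(1)
  a <- make_stack(3, gen = function(i) matrix(2, 10, 10))
  cmp <- pixelwise_compare(a, a)
  expect_true(all(cmp$difference[cmp$valid] == 0))
  expect_true(all(is.na(cmp$p_map)))  # zero variance everywhere
})

test_that("a 1 Pa shift at tiny noise is detected almost everywhere", {
  set.seed(2)
  a <- make_stack(5, gen = function(i) matrix(1 + rnorm(400, 0, 0.01), 20, 20))
  b <- make_stack(5, gen = function(i) matrix(0 + rnorm(400, 0, 0.01), 20, 20))
  cmp <- pixelwise_compare(a, b)
  expect_gt(cmp$sig_fraction, 0.99)
  expect_equal(mean(cmp$difference), 1, tolerance = 0.01)
})

test_that("difference maps are antisymmetric and shapes must agree", {
  set.seed(3)
  a <- make_stack(4); b <- make_stack(4)
  ab <- pixelwise_compare(a, b); ba <- pixelwise_compare(b, a)
  expect_equal(ab$difference, -ba$difference)
  expect_equal(ab$p_map, ba$p_map, tolerance = 1e-12)
  small <- make_stack(4, nz = 5, nt = 18)
  expect_error(pixelwise_compare(a, small), "different grid shapes")
  one <- make_stack(1)
  expect_error(pixelwise_compare(a, one), "at least 2 animals")
})

test_that("mann_whitney option produces valid p-values", {
  set.seed(4)
  a <- make_stack(5, nz = 6, nt = 6,
                  gen = function(i) matrix(rnorm(36, 2), 6, 6))
  b <- make_stack(5, nz = 6, nt = 6,
                  gen = function(i) matrix(rnorm(36, 0), 6, 6))
  cmp <- pixelwise_compare(a, b, test = "mann_whitney")
  expect_true(all(cmp$p_map[cmp$valid] > 0 & cmp$p_map[cmp$valid] <= 1))
  expect_gt(cmp$sig_fraction, 0.5)
})

test_that("dispersion summary matches the small-sample SD expectation", {
  set.seed(5)
  # identical maps: all summaries zero
  s0 <- make_stack(4, gen = function(i) matrix(3, 10, 10))
  d0 <- dispersion_summary(s0)
  expect_equal(d0$median_sd, 0)
  expect_equal(d0$upper_quartile_sd, 0)
  # iid noise sd = 0.3, n = 6 animals: E[s] = c4(6) * sigma = 0.9515 sigma
  s1 <- make_stack(6, nz = 120, nt = 120,
                   gen = function(i) matrix(rnorm(14400, 0, 0.3), 120, 120))
  d1 <- dispersion_summary(s1)
  c4 <- sqrt(2 / 5) * gamma(3) / gamma(2.5)
  expect_equal(d1$median_sd, c4 * 0.3, tolerance = 0.02)
  expect_true(d1$lower_quartile_sd <= d1$median_sd)
  expect_true(d1$median_sd <= d1$upper_quartile_sd)
  # invariances: adding a constant, scaling by s > 0
  s2 <- s1
  s2$data <- s1$data + 5
  expect_equal(dispersion_summary(s2)$median_sd, d1$median_sd)
  s3 <- s1
  s3$data <- s1$data * 2
  expect_equal(dispersion_summary(s3)$median_sd, 2 * d1$median_sd)
})

test_that("Grubbs removes a gross outlier and respects its critical value", {
  set.seed(6)
  x <- c(rnorm(9), 10)  # a ~10 SD outlier
  g <- grubbs_test(x)
  expect_equal(g$outlier_index, 10L)
  # critical value at n = 10, alpha = 0.05 is 2.290 (standard table)
  expect_equal(g$critical, 2.290, tolerance = 0.001)
  clean <- archflow:::remove_outliers(x)
  expect_equal(clean$removed, 10L)
  expect_lt(length(clean$removed), 3)  # capped at 2
  g2 <- grubbs_test(rnorm(10))
  expect_true(is.na(g2$outlier_index) || g2$g > g2$critical)
})

test_that("scalar_test gates on normality and reports its branch", {
  set.seed(7)
  a <- rnorm(10); b <- rnorm(10, 3)
  r <- scalar_test(list(a, b))
  expect_equal(r$test, "unpaired_t")
  expect_true(r$normal)
  expect_lt(r$p, 0.001)
  # identical groups: p = 1 under t
  x <- c(1.2, 1.9, 2.4, 3.1, 3.8)
  r2 <- scalar_test(list(x, x))
  expect_equal(r2$p, 1, tolerance = 1e-9)
  # heavy-tailed data fail the gate and take the non-parametric branch
  set.seed(8)
  c1 <- exp(rnorm(12, 0, 1.5)); c2 <- exp(rnorm(12, 1.5, 1.5))
  r3 <- scalar_test(list(c1, c2))
  expect_equal(r3$test, "mann_whitney")
  # multi-group designs route to ANOVA / Kruskal-Wallis
  r4 <- scalar_test(list(rnorm(8), rnorm(8, 1), rnorm(8, 2)))
  expect_true(r4$test %in% c("anova", "kruskal_wallis"))
  # a gross outlier is excluded before testing
  r5 <- scalar_test(list(c(rnorm(9), 50), rnorm(10, 0.2)))
  expect_equal(r5$removed[[1]], 10L)
})

test_that("Pearson correlation handles exact, noisy and degenerate input", {
  x <- 1:10
  expect_equal(correlate_metrics(x, 2 * x)$r, 1)
  expect_equal(correlate_metrics(x, -x + rnorm(10, 0, 1e-9))$r, -1,
               tolerance = 1e-6)
  expect_error(correlate_metrics(x, rep(1, 10)), "zero variance")
  expect_error(correlate_metrics(c(1, 2, NA), c(1, NA, 3)), "3 complete pairs")
  # NA pairs are dropped listwise
  r <- correlate_metrics(c(x, NA), c(2 * x, 5))
  expect_equal(r$n, 10)
})

test_that("independent normals exceed the r critical value at ~ the alpha rate", {
  set.seed(9)
  crit <- sqrt(stats::qt(0.975, 18)^2 / (stats::qt(0.975, 18)^2 + 18))
  hits <- replicate(400, abs(correlate_metrics(rnorm(20), rnorm(20))$r) > crit)
  expect_lt(abs(mean(hits) - 0.05), 0.035)
})
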