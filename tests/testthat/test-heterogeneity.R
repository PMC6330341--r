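test_that("QCoD matches interpolated-quartile closed forms", {
  expect_equal(qcod(c(1, 2, 3, 4, 5)), 1 / 3)
  expect_equal(qcod(rep(7, 10)), 0)
  expect_error(qcod(3), "fewer than 2")
  expect_error(qcod(c(-1, 1)), "Q1 \\+ Q3")
})

test_that("QCoD is scale invariant and zero only for zero IQR", {
  set.seed(91)
  for (i in 1:20) {
    v <- rlnorm(sample(5:50, 1))
    c0 <- runif(1, 0.1, 100)
    expect_equal(qcod(c0 * v), qcod(v), tolerance = 1e-12)
    expect_gte(qcod(v), 0)
    expect_lt(qcod(v), 1)
  }
  # widening an IQR-symmetric distribution strictly increases dispersion
  base <- c(2, 4, 6, 8, 10)
  widened <- c(2, 3, 6, 9, 10)  # same median, wider quartiles
  expect_gt(qcod(widened), qcod(base))
})

test_that("QCoD is permutation invariant", {
  set.seed(92)
  v <- rlnorm(31)
  expect_equal(qcod(sample(v)), qcod(v), tolerance = 1e-12)
})

test_that("intra-tumoral summaries respect convergence and exclusion filters", {
  wt <- data.frame(density_mm2 = c(100, 200, 300, 1e9),
                   mu = c(10, 12, 14, 1e9),
                   mean_dist = c(30, 31, 32, 1e9),
                   cluster_area = c(0.01, 0.02, 0.03, 1e9),
                   converged = c(TRUE, TRUE, TRUE, FALSE))
  ct <- data.frame(density_mm2 = c(500, 700), n = c(40, 60),
                   A_alpha = c(1e4, 2e4), A_ellipse = c(2e4, 3e4),
                   f_circ = c(0.4, 0.5), f_conv = c(0.7, 0.8),
                   e = c(0.85, 0.9), excluded = c(FALSE, FALSE))
  s <- intra_tumoral(wt, ct, patient_id = "p")
  mu_row <- s[s$metric == "mu", ]
  expect_equal(mu_row$n, 3)           # non-converged window dropped
  expect_equal(mu_row$median, 12)
  expect_equal(s[s$metric == "density_all_mm2", "n"], 4)
  expect_equal(s[s$branch == "cluster" & s$metric == "n", "median"], 50)
})

test_that("identical slides give zero inter-tumoral dispersion", {
  wt <- data.frame(density_mm2 = c(100, 200, 300), mu = c(10, 12, 14),
                   mean_dist = c(30, 31, 32), cluster_area = c(1, 2, 3),
                   converged = TRUE)
  s1 <- intra_tumoral(wt, NULL, patient_id = "a")
  s2 <- intra_tumoral(wt, NULL, patient_id = "b")
  s3 <- intra_tumoral(wt, NULL, patient_id = "c")
  inter <- inter_tumoral(list(s1, s2, s3))
  expect_true(all(inter$qcod[inter$n_patients >= 2] == 0))
})

test_that("two-slide inter-tumoral dispersion follows the quartile convention", {
  wt <- function(m) data.frame(density_mm2 = rep(m, 3), mu = rep(m, 3),
                               mean_dist = rep(m, 3), cluster_area = rep(m, 3),
                               converged = TRUE)
  inter <- inter_tumoral(list(intra_tumoral(wt(10), NULL, "a"),
                              intra_tumoral(wt(30), NULL, "b")))
  # type-7 quartiles of {m, 3m} are 1.5m and 2.5m
  expect_equal(unique(inter$qcod), (2.5 - 1.5) / (2.5 + 1.5), tolerance = 1e-12)
})

test_that("a dense/sparse two-zone slide shows density dispersion above shape dispersion", {
  set.seed(93)
  dense <- data.frame(x = runif(2400, 0, 2000), y = runif(2400, 0, 1000))
  sparse <- data.frame(x = runif(300, 0, 2000), y = runif(300, 1000, 2000))
  pp <- point_pattern(c(dense$x, sparse$x), c(dense$y, sparse$y),
                      window = c(0, 2000, 0, 2000))
  wins <- extract_windows(pp, window_grid(500, 500, 500, 500))
  dens <- vapply(wins, function(w) w$pp$n / 0.25, 0)
  expect_gt(qcod(dens), 0.3)
})
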