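test_that("phenotype thresholds reproduce the circular and elongated rules", {
  ph <- classify_cluster(e = c(0.5, 0.95, 0.85),
                         f_conv = c(0.9, 0.7, 0.5),
                         f_circ = c(0.6, 0.4, 0.4))
  expect_equal(ph$is_circular, c(TRUE, FALSE, FALSE))
  expect_equal(ph$is_elongated, c(FALSE, TRUE, FALSE))
  # degenerate descriptors propagate as NA
  ph2 <- classify_cluster(NA, 0.5, 0.5)
  expect_true(is.na(ph2$is_circular) && is.na(ph2$is_elongated))
})

test_that("maximum cluster density excludes small clusters", {
  ct <- data.frame(n = c(60, 200), density_mm2 = c(600, 200))
  expect_equal(max_cluster_density(ct, min_cells = 50), 600)
  ct40 <- data.frame(n = c(40, 45), density_mm2 = c(900, 800))
  expect_true(is.na(max_cluster_density(ct40, min_cells = 50)))
  one <- data.frame(n = 80, density_mm2 = 123)
  expect_equal(max_cluster_density(one), 123)
})

test_that("responder derivation differs between MSI and MSS cohorts", {
  oc <- data.frame(patient_id = letters[1:6],
                   cohort = c("MSI", "MSI", "MSI", "MSS", "MSS", "MSS"),
                   recist = c("CR", "SD", "PD", "SD", "PR", "PD"))
  out <- group_responders(oc)
  expect_equal(out$responder, c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_error(group_responders(data.frame(cohort = "XX", recist = "CR")),
               "cohort")
})

test_that("rank-sum comparison reproduces the exact enumeration case", {
  res <- compare_groups(c(1, 2, 3, 10, 11, 12),
                        c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(res$W, 6)          # minimal rank sum of group 1
  expect_equal(res$p_value, 0.1)  # 2/C(6,3) * ... = 2/20
  same <- compare_groups(c(1, 2, 3, 1, 2, 3), rep(c(TRUE, FALSE), each = 3))
  expect_gt(same$p_value, 0.9)
})

test_that("rank-sum test holds its nominal size under the null", {
  set.seed(111)
  n_rep <- 1000
  rej <- 0
  flags <- rep(c(TRUE, FALSE), each = 7)
  for (i in seq_len(n_rep)) {
    p <- compare_groups(rnorm(14), flags)$p_value
    if (p < 0.05) rej <- rej + 1
  }
  expect_lt(abs(rej / n_rep - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep) + 0.01)
})

test_that("trend test reproduces the full-enumeration oracle on three singletons", {
  tt <- trend_test(c(1, 2, 3), factor(c("PD", "SD", "PR"),
                                      levels = c("PD", "SD", "PR"),
                                      ordered = TRUE))
  expect_equal(tt$J, 3)
  expect_equal(tt$p_value, 1 / 6)
  expect_equal(tt$method, "exact")
})

test_that("trend test is directional and inert for constant data", {
  g <- factor(rep(c("PD", "SD", "PR"), each = 3),
              levels = c("PD", "SD", "PR"), ordered = TRUE)
  inc <- trend_test(c(1, 2, 3, 4, 5, 6, 7, 8, 9), g)
  dec <- trend_test(c(9, 8, 7, 6, 5, 4, 3, 2, 1), g)
  expect_lt(inc$p_value, 0.05)
  expect_gt(dec$p_value, 0.9)
  flat <- trend_test(rep(2, 9), g)
  expect_equal(flat$p_value, 1)
})

test_that("detecting a planted outcome shift in a synthetic cohort", {
  set.seed(112)
  # responders carry ~2x the cluster count of non-responders
  hits <- 0
  for (i in 1:30) {
    resp <- rpois(14, 12)
    nonr <- rpois(14, 6)
    p <- compare_groups(c(resp, nonr), rep(c(TRUE, FALSE), each = 14))$p_value
    if (p < 0.05) hits <- hits + 1
  }
  expect_gt(hits / 30, 0.7)
})
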