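test_that("matching handles identity, empty and ambiguous configurations", {
  pts <- data.frame(x = c(0, 50, 100), y = c(0, 0, 0))
  m <- match_points(pts, pts, radius = 10)
  expect_equal(c(m$TP, m$FP, m$FN), c(3, 0, 0))

  m <- match_points(pts[0, ], pts, radius = 10)
  expect_equal(c(m$TP, m$FP, m$FN), c(0, 0, 3))

  # the closest unmatched pair wins: reference (1,0) pairs with (0,0)
  det <- data.frame(x = c(0, 100), y = c(0, 0))
  ref <- data.frame(x = 1, y = 0)
  m <- match_points(det, ref, radius = 10)
  expect_equal(c(m$TP, m$FP, m$FN), c(1, 1, 0))
  expect_equal(m$pairs$detected, 1)
})

test_that("greedy matching equals optimal assignment when spacing exceeds twice the radius", {
  set.seed(42)
  for (rep in 1:20) {
    # points with pairwise spacing > 2 * radius = 20
    base <- expand.grid(x = seq(0, 200, by = 50), y = seq(0, 200, by = 50))
    keep <- sample(nrow(base), 5)
    ref <- base[keep, ] + runif(10, -4, 4)
    det <- ref + matrix(runif(10, -4, 4), ncol = 2)
    det <- det[sample(nrow(det), 4), ]   # drop one -> FN
    m <- match_points(det, ref, radius = 10)
    expect_equal(m$TP, optimal_match_count(det, ref, 10))
  }
})

test_that("recall, precision and their standard errors follow the defining formulas", {
  expect_equal(recall(0, 5), 0)
  expect_equal(recall(7, 0), 1)
  expect_equal(precision(0, 3), 0)
  expect_equal(precision(1, 0), 1)
  expect_equal(se_proportion(0.5, 100), 0.05)
  expect_equal(se_proportion(0, 17), 0)
  expect_equal(se_proportion(1, 17), 0)
  expect_error(recall(0, 0), "undefined")
  expect_error(se_proportion(0.5, 0), "undefined")
})

test_that("evaluate_samples pools counts and is order invariant", {
  # sample 1: TP = 3, FP = 1, FN = 1
  s1 <- list(reference = data.frame(x = c(0, 20, 40, 60), y = rep(0, 4)),
             detected = data.frame(x = c(0, 20, 40, 500), y = c(0, 0, 0, 500)))
  # sample 2: TP = 1, FP = 0, FN = 1
  s2 <- list(reference = data.frame(x = c(0, 50), y = c(0, 50)),
             detected = data.frame(x = 0, y = 0))
  ev <- evaluate_samples(list(s1, s2), radius = 10)
  expect_equal(ev$R, 4 / 6)
  expect_equal(ev$P, 4 / 5)
  ev2 <- evaluate_samples(list(s2, s1), radius = 10)
  expect_equal(ev2$R, ev$R)
  expect_equal(ev2$P, ev$P)
})

test_that("Spearman rho is 1 for perfect detection with varying counts and NA when degenerate", {
  mk <- function(n) {
    p <- data.frame(x = seq(0, by = 40, length.out = n), y = rep(0, n))
    list(detected = p, reference = p)
  }
  ev <- evaluate_samples(list(mk(3), mk(5), mk(9)), radius = 10)
  expect_equal(ev$spearman_rho, 1)
  expect_equal(ev$R, 1)
  ev <- evaluate_samples(list(mk(4), mk(4)), radius = 10)
  expect_true(is.na(ev$spearman_rho))
})

test_that("detection noise rates are recovered from synthetic miss/false processes", {
  set.seed(31)
  q <- 0.2
  n_true <- 2000
  truth <- data.frame(x = runif(n_true, 0, 4000), y = runif(n_true, 0, 4000))
  kept <- runif(n_true) >= q
  n_false <- 150
  obs <- rbind(truth[kept, ],
               data.frame(x = runif(n_false, 0, 4000),
                          y = runif(n_false, 0, 4000)))
  ev <- evaluate_samples(list(list(detected = obs, reference = truth)),
                         radius = 10)
  expect_lt(abs((1 - ev$R) - q), 3 * ev$se_R + 0.01)
  exp_false_frac <- n_false / (sum(kept) + n_false)
  expect_lt(abs((1 - ev$P) - exp_false_frac), 3 * ev$se_P + 0.01)
})

test_that("evaluation region samplers cover the slide and respect bounds", {
  win <- c(0, 10000, 0, 8000)
  for (scheme in c("lhs", "systematic")) {
    rg <- sample_eval_regions(win, 20, size = 500, scheme = scheme, seed = 3)
    expect_equal(nrow(rg), 20)
    expect_true(all(rg$x0 >= 0 & rg$x0 + 500 <= 10000))
    expect_true(all(rg$y0 >= 0 & rg$y0 + 500 <= 8000))
  }
  expect_error(sample_eval_regions(c(0, 400, 0, 400), 5, size = 500), "exceeds")
})
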