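test_that("a convex point cloud keeps the starting alpha and equals its hull", {
  g <- expand.grid(x = seq(0, 100, by = 10), y = seq(0, 100, by = 10))
  ash <- alpha_shape_escalate(g, alpha_start = 500)
  expect_equal(ash$alpha, 500)
  expect_equal(ash$area, 100 * 100, tolerance = 1e-9)
  expect_equal(ash$perimeter, 400, tolerance = 1e-9)
  expect_equal(convexity(ash$area, convex_hull_area(g)), 1)
})

test_that("escalation bridges separated patches and keeps every point", {
  set.seed(71)
  a <- disk_points(80, radius = 60, cx = 0)
  b <- disk_points(80, radius = 60, cx = 500)
  xy <- rbind(a, b)
  ash <- alpha_shape_escalate(xy, alpha_start = 10)
  expect_gt(ash$alpha, 10)
  expect_setequal(unique(as.vector(ash$triangles)), seq_len(nrow(xy)))
  # escalation is monotone: the step just below the final alpha fails
  expect_gt(ash$area, 0)
  expect_gt(ash$perimeter, 0)
})

test_that("three non-collinear points give their triangle; degenerate sets error", {
  tri <- data.frame(x = c(0, 40, 0), y = c(0, 0, 30))
  ash <- alpha_shape_escalate(tri, alpha_start = 10)
  expect_equal(ash$area, 600, tolerance = 1e-9)
  expect_equal(ash$perimeter, 40 + 30 + 50, tolerance = 1e-9)
  expect_error(alpha_shape_escalate(data.frame(x = 1:5, y = 2 * (1:5) + 1)),
               "degenerate|collinear")
  expect_error(alpha_shape_escalate(data.frame(x = c(0, 0, 1), y = c(0, 0, 1))),
               "degenerate")
  expect_error(alpha_shape_escalate(data.frame(x = c(0, 1), y = c(0, 1))),
               "degenerate")
})

test_that("convexity and circularity match hand-computed closed forms", {
  expect_equal(convexity(3, 4.5), 2 / 3)
  expect_equal(circularity(1, 4), pi / 4)
  expect_equal(circularity(10, 22), 40 * pi / 484)
  # fine polygonal circle approaches the isoperimetric limit from below
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  A <- abs(sum(cos(th) * c(sin(th[-1]), sin(th[1])) -
               c(cos(th[-1]), cos(th[1])) * sin(th)) / 2)
  P <- sum(sqrt(diff(c(cos(th), cos(th[1])))^2 +
                diff(c(sin(th), sin(th[1])))^2))
  f <- circularity(A, P)
  expect_gt(f, 0.9999)
  expect_lte(f, 1)
  expect_error(circularity(1, 0), "degenerate")
  expect_error(convexity(1, 0), "degenerate")
})

test_that("shape descriptors are invariant under rigid motion and scaling", {
  set.seed(72)
  xy <- rbind(disk_points(120, radius = 100),
              strip_points(60, len = 300, wid = 40, cx = 250, cy = 150))
  s0 <- summarize_cluster(xy)
  s1 <- summarize_cluster(rigid_motion(xy, theta = 0.83, dx = 3000, dy = -500))
  expect_equal(s1$f_conv, s0$f_conv, tolerance = 1e-6)
  expect_equal(s1$f_circ, s0$f_circ, tolerance = 1e-6)
  expect_equal(s1$e, s0$e, tolerance = 1e-6)
  expect_equal(s1$A_alpha, s0$A_alpha, tolerance = 1e-6)
  # uniform scaling preserves the dimensionless descriptors only
  s2 <- summarize_cluster(data.frame(x = 3 * xy$x, y = 3 * xy$y),
                          alpha_start = 30)
  expect_equal(s2$f_conv, s0$f_conv, tolerance = 1e-6)
  expect_equal(s2$f_circ, s0$f_circ, tolerance = 1e-6)
  expect_equal(s2$e, s0$e, tolerance = 1e-6)
  expect_equal(s2$A_alpha, 9 * s0$A_alpha, tolerance = 1e-6)
})

test_that("the alpha-shape area never exceeds the convex hull area", {
  set.seed(73)
  for (i in 1:10) {
    xy <- rbind(disk_points(50, radius = runif(1, 40, 120)),
                disk_points(50, radius = 60, cx = runif(1, 100, 400)))
    ash <- alpha_shape_escalate(xy)
    expect_lte(ash$area, convex_hull_area(xy) * (1 + 1e-9))
  }
})
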