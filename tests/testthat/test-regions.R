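test_that("invasive-front band area matches a fine rasterization oracle", {
  rm <- square_tumor_regions(slide = c(0, 6000, 0, 6000),
                             tumor = c(2000, 4000, 2000, 4000))
  rm <- build_invasive_front(rm, 250)
  band_mm2 <- unname(region_areas(rm)["invasive_front"])

  # oracle: 5 um rasterization, counting pixels within 250 um of the
  # tumor-rectangle boundary (all of it faces normal tissue here)
  gx <- seq(2.5, 5997.5, by = 5)
  cnt <- 0
  for (yv in gx) {
    dx <- pmax(pmax(2000 - gx, 0), pmax(gx - 4000, 0))
    dy <- max(max(2000 - yv, 0), yv - 4000)
    outside <- sqrt(dx^2 + dy^2)
    inside_x <- pmin(abs(gx - 2000), abs(gx - 4000))
    inside_y <- min(abs(yv - 2000), abs(yv - 4000))
    inside <- pmin(inside_x, inside_y)
    d <- ifelse(outside > 0, outside, inside)
    cnt <- cnt + sum(d <= 250)
  }
  oracle_mm2 <- cnt * 25 / 1e6
  expect_lt(abs(band_mm2 - oracle_mm2) / oracle_mm2, 0.01)
})

test_that("band points stay within the half-width of the tumor boundary", {
  rm <- build_invasive_front(square_tumor_regions(), 250)
  set.seed(101)
  x <- runif(4000, 0, 6000); y <- runif(4000, 0, 6000)
  lab <- assign_cells(data.frame(x = x, y = y), rm)
  # distance to the boundary of the tumor rectangle
  dx <- pmax(pmax(2000 - x, 0), pmax(x - 4000, 0))
  dy <- pmax(pmax(2000 - y, 0), pmax(y - 4000, 0))
  outside <- sqrt(dx^2 + dy^2)
  inside <- pmin(pmin(abs(x - 2000), abs(x - 4000)),
                 pmin(abs(y - 2000), abs(y - 4000)))
  d <- ifelse(outside > 0, outside, inside)
  peri <- lab$label == "peritumoral"
  expect_true(all(d[peri] <= 255))   # 5 um round-join tolerance
  expect_true(all(d[!peri] >= 245))
})

test_that("a slide without normal tissue has no invasive front", {
  tum <- list(x = c(0, 1000, 1000, 0), y = c(0, 0, 1000, 1000))
  rm <- region_map(list(list(label = "tumor", paths = list(tum))))
  rm <- build_invasive_front(rm)
  expect_length(rm$invasive_front, 0)
  expect_equal(select_roi(rm), "tumor")
})

test_that("ROI selection follows the three-way fallback and is total", {
  rm <- build_invasive_front(square_tumor_regions())
  expect_equal(select_roi(rm), "invasive_front")

  nor <- list(x = c(0, 1000, 1000, 0), y = c(0, 0, 1000, 1000))
  rm2 <- build_invasive_front(
    region_map(list(list(label = "normal", paths = list(nor)))))
  expect_equal(select_roi(rm2), "normal")

  expect_error(select_roi(region_map(list())), "invasive front|no regions")
})

test_that("cell labels follow band precedence and flag unannotated cells", {
  rm <- build_invasive_front(square_tumor_regions())
  cells <- data.frame(x = c(3000, 2100, 1600, 500, 7000),
                      y = c(3000, 3000, 3000, 500, 7000))
  lab <- assign_cells(cells, rm)
  expect_equal(lab$label,
               c("intratumoral", "peritumoral", "stromal", "stromal",
                 "stromal"))
  expect_equal(lab$out_of_annotation, c(FALSE, FALSE, FALSE, FALSE, TRUE))
})

test_that("cluster association applies the peritumoral-first precedence rule", {
  labels <- c("stromal", "stromal", "peritumoral", "intratumoral",
              "intratumoral", "stromal")
  members <- list(c(1, 2), c(2, 3, 4), c(4, 5), c(1, 6))
  assoc <- associate_clusters(members, labels)
  expect_equal(assoc, c("normal", "invasive_front", "tumor", "normal"))
  # invariant to member ordering
  assoc2 <- associate_clusters(lapply(members, rev), labels)
  expect_equal(assoc2, assoc)
})
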