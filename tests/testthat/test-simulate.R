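test_that("a fixed seed reproduces the virtual slide exactly", {
  sc <- slide_scenario(follicles = list(count = 2, radius = 150, n_cells = 200),
                       miss_rate = 0.2, false_rate_mm2 = 10)
  a <- simulate_slide(sc, seed = 17)
  b <- simulate_slide(sc, seed = 17)
  expect_identical(a$true, b$true)
  expect_identical(a$observed, b$observed)
})

test_that("a zero-noise scenario observes exactly the true cells", {
  sc <- slide_scenario(tumor = list(),
                       tumor_process = list(type = "none"),
                       normal_process = list(type = "poisson",
                                             lambda_mm2 = 100))
  sim <- simulate_slide(sc, seed = 18)
  expect_equal(nrow(sim$observed), nrow(sim$true))
  expect_equal(sim$observed$x, sim$true$x)
  expect_true(all(!is.na(sim$observed$true_index)))
})

test_that("the noise model delivers the planted miss and false rates", {
  sc <- slide_scenario(tumor = list(),
                       tumor_process = list(type = "none"),
                       normal_process = list(type = "poisson",
                                             lambda_mm2 = 200),
                       miss_rate = 0.25, false_rate_mm2 = 20)
  sim <- simulate_slide(sc, seed = 19)
  n_true <- nrow(sim$true)
  miss_hat <- sim$manifest$n_missed / n_true
  expect_lt(abs(miss_hat - 0.25), 3 * sqrt(0.25 * 0.75 / n_true))
  expect_lt(abs(sim$manifest$n_false - 20 * 16) / (20 * 16), 0.4)
})

test_that("region-conditional processes respect the annotation geometry", {
  sc <- slide_scenario()  # Thomas tumor, Poisson normal
  sim <- simulate_slide(sc, seed = 20)
  rm <- build_invasive_front(sim$regions, 250)
  lab <- assign_cells(sim$true, rm)
  tum_pts <- sim$true$origin == "tumor_process"
  # tumor-process points never land outside the tumor polygon
  expect_true(all(lab$label[tum_pts] %in% c("intratumoral", "peritumoral")))
  expect_true(all(lab$label[sim$true$origin == "normal_process"] !=
                  "intratumoral"))
})

test_that("written slides are loadable through the standard readers", {
  dir <- withr::local_tempdir()
  sc <- slide_scenario(follicles = list(count = 1, radius = 100, n_cells = 100))
  sim <- simulate_slide(sc, seed = 21)
  write_slide(sim, dir)
  pp <- read_cells(file.path(dir, "cells_observed.csv"))
  expect_equal(pp$n, nrow(sim$observed))
  rm <- read_regions(file.path(dir, "regions.geojson"))
  expect_length(rm$polygons, 2)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$n_true, nrow(sim$true))
})

test_that("infeasible archetype placement is rejected with a clear error", {
  sc <- slide_scenario(slide = c(0, 800, 0, 800),
                       strips = list(count = 1, length = 2000, width = 100,
                                     n_cells = 10))
  expect_error(simulate_slide(sc, seed = 22), "does not fit")
})
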