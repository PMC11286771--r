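test_that("degree-4 spline interpolation is exact on quartics and interpolates the data", {
  # irregular sampling of a quartic polynomial
  set.seed(4)
  t <- sort(c(0, 0.0125, stats::runif(80, 0, 0.0125)))
  p <- function(x) 3 - 2e3 * x + 5e5 * x^2 - 1e7 * x^3 + 9e8 * x^4
  wf <- list(t = t, w = p(t))
  out <- interpolate_waveform(wf)
  expect_length(out, 1001)
  tout <- seq(0, 0.0125, length.out = 1001)
  expect_equal(out, p(tout), tolerance = 1e-9)

  # passes through original samples at their own abscissae (data times are a
  # subset of the output grid here)
  t2 <- seq(0, 0.014, length.out = 121)
  wf2 <- list(t = t2, w = sin(t2 * 900))
  grid_hit <- interpolate_waveform(wf2, n_out = 961, t_max = 0.014)
  expect_equal(grid_hit[seq(1, 961, by = 8)], wf2$w, tolerance = 1e-9)

  expect_equal(interpolate_waveform(list(t = c(0, 1e-3, 3e-3, 6e-3, 9e-3, 0.013),
                                         w = rep(0, 6))),
               rep(0, 1001))
  expect_error(interpolate_waveform(list(t = seq(0, 0.01, length.out = 50),
                                         w = rep(1, 50))), "cover")
})

test_that("feature assembly keeps block order and shape", {
  b <- as.numeric(seq_len(1001)); d0 <- b + 2000; d35 <- b + 4000
  f <- assemble_features(b, d0, d35)
  expect_length(f, 3003)
  expect_identical(f[1:1001], b)
  expect_identical(f[1002:2002], d0)
  expect_identical(f[2003:3003], d35)
  expect_equal(assemble_features(rep(0, 1001), rep(0, 1001), rep(0, 1001)),
               rep(0, 3003))
  expect_error(assemble_features(b[-1], d0, d35), "1001")
})

test_that("5x5 coarsening picks region-centre cells in row-major order", {
  g <- build_patch(nx = 40, ny = 30)
  expect_equal(coarsen_5x5(matrix(2.5, g$nx, g$ny), g), rep(2.5, 25))

  # linear field f(x, y) = x: values are the 5 column-centre x coordinates
  fx <- matrix(rep(g$x_cells, g$ny), g$nx, g$ny)
  got <- coarsen_5x5(fx, g)
  centres_x <- (1:5 - 0.5) * g$lx / 5
  nearest_x <- vapply(centres_x, function(c0) g$x_cells[which.min(abs(g$x_cells - c0))],
                      numeric(1))
  expect_equal(got, rep(nearest_x, times = 5))

  # independent partition-and-lookup oracle on a random field
  set.seed(9)
  fld <- matrix(stats::runif(g$nx * g$ny), g$nx, g$ny)
  oracle <- numeric(25)
  for (j in 1:5) for (i in 1:5) {
    cx <- (i - 0.5) * g$lx / 5; cy <- (j - 0.5) * g$ly / 5
    ii <- which.min(abs(g$x_cells - cx)); jj <- which.min(abs(g$y_cells - cy))
    oracle[(j - 1) * 5 + i] <- fld[ii, jj]
  }
  expect_equal(coarsen_5x5(fld, g), oracle)
})

test_that("extra area integrates growth over the reference patch", {
  g <- build_patch(nx = 40, ny = 30)
  expect_equal(extra_area(matrix(1, g$nx, g$ny), g), 0)
  expect_equal(extra_area(matrix(1.1, g$nx, g$ny), g), 187.5)

  # smooth random field vs refined-grid quadrature
  f <- function(x, y) 1 + 0.2 * sin(x / 11) * cos(y / 7) + 0.05 * (x / 50)
  coarse <- outer(g$x_cells, g$y_cells, f)
  g2 <- build_patch(nx = 80, ny = 60)
  fine <- outer(g2$x_cells, g2$y_cells, f)
  expect_lt(abs(extra_area(coarse, g) - extra_area(fine, g2)) /
              extra_area(fine, g2), 1e-3)
})

test_that("dataset build produces consistent shapes and physically coherent targets", {
  ds <- tiny_dataset()
  expect_equal(dim(ds$features), c(5, 3003))
  expect_equal(dim(ds$targets), c(5, 28))
  expect_true(all(is.finite(ds$features)))
  expect_true(all(ds$targets[, 1:25] >= 1))
  # parameter targets equal the manifest
  expect_equal(ds$targets[, "mu_mpa"], ds$manifest$mu_mpa, ignore_attr = TRUE)
  expect_equal(ds$targets[, "k_per_day"], ds$manifest$k_per_day,
               ignore_attr = TRUE)
  # no all-zero waveform block when the expander is inflated
  for (b in 0:2)
    expect_gt(max(abs(ds$features[, b * 1001 + 1:1001])), 0)
})

test_that("day-3.5 growth never exceeds the day-7 targets for the same subject", {
  g <- tiny_grid()
  subs <- sample_subjects(population_spec(n = 2, seed = 5))
  for (i in 1:2) {
    mp <- subject_params(subs, i)
    Th <- total_area_stretch(g, expander_profile(), mp$theta_nat)
    g35 <- coarsen_5x5(evolve_growth(growth_field(Th), mp, 3.5)$theta_g, g)
    g7 <- coarsen_5x5(evolve_growth(growth_field(Th), mp, 7)$theta_g, g)
    expect_true(all(g35 <= g7 + 1e-12))
  }
})

test_that("the dataset container round-trips bit-exactly and validates shapes", {
  ds <- tiny_dataset()
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_identical(back$features, ds$features)
  expect_identical(back$targets, ds$targets)
  expect_equal(back$manifest$seed[1], ds$manifest$seed[1])
  expect_equal(as.data.frame(back$manifest), as.data.frame(ds$manifest),
               tolerance = 1e-12)

  # schema violations are caught by name
  file.remove(file.path(dir, "targets.feather"))
  expect_error(read_dataset(dir), "targets.feather")
  dir2 <- withr::local_tempdir()
  bad <- ds; bad$features <- bad$features[, 1:100]
  write_dataset(bad, dir2)
  expect_error(read_dataset(dir2), "3003")
})
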