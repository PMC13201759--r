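# The synthetic-tissue generator: GRF, inhibited point pattern, areas
# and rates, grid aggregation, perturbations, error terms, rendering.

test_that("the GRF is scaled to [0, 1] and reproducible", {
  f1 <- sample_grf(40, 40, 10, 150, seed = 61)
  expect_equal(range(f1), c(0, 1))
  f2 <- sample_grf(40, 40, 10, 150, seed = 61)
  expect_identical(f1, f2)
  expect_false(identical(f1, sample_grf(40, 40, 10, 150, seed = 62)))
})

test_that("the GRF empirical correlation at one length scale is near exp(-1)", {
  set.seed(63)
  ell <- 60; res <- 10; lag <- ell / res
  # the process mean is known to be zero, so estimate the correlation
  # without per-field centring (which would bias it down on small fields)
  cors <- vapply(1:50, function(i) {
    f <- sample_grf(50, 50, res, ell, scale01 = FALSE)
    a <- as.vector(f[, 1:(50 - lag)]); b <- as.vector(f[, (lag + 1):50])
    mean(a * b) / sqrt(mean(a^2) * mean(b^2))
  }, 0)
  expect_equal(mean(cors), exp(-1), tolerance = 0.08)
})

test_that("sequential inhibition respects distance and exact counts", {
  set.seed(64)
  grf <- sample_grf(50, 50, 10, 150)
  cells <- sample_cells(grf, 10, 500, n_per_type = c(30, 30), inhibition_um = 12)
  expect_equal(as.numeric(table(cells$type)), c(30, 30))
  dm <- as.matrix(dist(cbind(cells$x, cells$y)))
  diag(dm) <- Inf
  expect_gte(min(dm), 12)
  expect_error(sample_cells(grf, 10, 100, n_per_type = 500, inhibition_um = 20,
                            max_proposals = 50),
               "packing failure")
})

test_that("type 1 follows the field and other types its complement", {
  ok <- 0
  for (s in 1:10) {
    set.seed(100 + s)
    grf <- sample_grf(50, 50, 10, 120)
    cells <- sample_cells(grf, 10, 500, n_per_type = c(60, 60),
                          inhibition_um = 5)
    at <- function(t) {
      sub <- cells[cells$type == t, ]
      grf[cbind(pmin(pmax(round(sub$y / 10 + 0.5), 1), 50),
                pmin(pmax(round(sub$x / 10 + 0.5), 1), 50))]
    }
    ok <- ok + (mean(at(1)) > mean(at(2)))
  }
  expect_gte(ok, 9)
})

test_that("area and rate distributions match their parameters", {
  a <- sample_areas(1e4, mu = 80, size = 2, seed = 65)
  se <- sqrt((80 + 80^2 / 2) / 1e4)
  expect_lt(abs(mean(a) - 81), 3 * se)  # +1 shift
  expect_gte(min(a), 1)

  r <- sample_rates(rep(1, 5000), meanlog = 1.2, sdlog = 0.4, seed = 66)
  expect_gt(shapiro.test(sample(log(r), 500))$p.value, 0.001)
  expect_equal(sample_rates(rep(1, 10), meanlog = 2, sdlog = 0, seed = 1),
               rep(exp(2), 10))
})

test_that("grid aggregation is exact for a cell inside one pixel", {
  cells <- tibble::tibble(x = 45, y = 45, type = 1,
                          area_um2 = 50, rate = 3)
  g <- aggregate_to_grid(cells, field_um = 90, stepsize_um = 30,
                         pixelsize_um = 30)
  expect_equal(sum(g$y), 150, tolerance = 1e-9)
  expect_equal(g$y[g$col == 2 & g$row == 2], 150, tolerance = 1e-9)
  expect_equal(g$frac_1[g$col == 2 & g$row == 2], 50 / 900, tolerance = 1e-9)
  # with no translation the covariate is the signal's own geometry
  expect_equal(g$y, 3 * 900 * g$frac_1, tolerance = 1e-9)
})

test_that("the x-translation decouples covariates from the signal", {
  set.seed(67)
  cells <- tibble::tibble(x = runif(30, 50, 350), y = runif(30, 50, 350),
                          type = rep(1:2, 15),
                          area_um2 = runif(30, 30, 120), rate = runif(30, 1, 5))
  g0 <- aggregate_to_grid(cells, 400, 30, 24, translation_x_um = 0)
  g10 <- aggregate_to_grid(cells, 400, 30, 24, translation_x_um = 10)
  expect_equal(g0$y, g10$y)  # the signal never moves
  expect_gt(sum(abs(g0$frac_1 - g10$frac_1)), 0)
})

test_that("area perturbations preserve the multiset of areas", {
  a <- c(5, 1, 9, 3, 7, 2, 8, 4, 6, 10)
  expect_identical(perturb_areas(a, "none"), a)
  rs <- perturb_areas(a, "reshuffle", seed = 68)
  expect_setequal(rs, a)
  rr <- perturb_areas(a, "rank-reorder", bins = 4)
  expect_setequal(rr, a)
  # one bin reverses the rank order completely
  rr1 <- perturb_areas(a, "rank-reorder", bins = 1)
  expect_identical(rr1[order(a)], sort(a, decreasing = TRUE))
})

test_that("error terms behave at their switch-off points and bounds", {
  g <- tibble::tibble(col = rep(1:5, 5), row = rep(1:5, each = 5),
                      y = runif(25, 10, 20))
  off <- add_errors(g, smooth_lambda = 0, noise_meanlog = NULL,
                    grf_error_max = 0)
  expect_equal(off$y, g$y)
  # full smoothing of a constant field is a fixed point
  gc <- g; gc$y <- rep(7, 25)
  sm <- add_errors(gc, smooth_lambda = 1, noise_meanlog = NULL, grf_error_max = 0)
  expect_equal(sm$y, rep(7, 25))
  # the correlated error never exceeds its bound
  ge <- add_errors(g, smooth_lambda = 0, noise_meanlog = NULL,
                   grf_error_max = 500, seed = 69)
  expect_true(all(ge$y - g$y >= 0 & ge$y - g$y <= 500))
})

test_that("datasets regenerate bit-identically from (config, seed)", {
  cfg <- sim_config(field_um = 300, n_per_type = 20, n_types = 2)
  a <- simulate_dataset(cfg, seed = 70)
  b <- simulate_dataset(cfg, seed = 70)
  expect_identical(a$cells, b$cells)
  expect_identical(a$grid, b$grid)
  c2 <- simulate_dataset(cfg, seed = 71)
  expect_false(identical(a$grid$y, c2$grid$y))
})

test_that("rendered fixtures place marks exactly at the stated truth", {
  fx <- render_postmsi_fixture(n_col = 3, n_row = 3, stepsize_um = 30,
                               jitter_sd_um = 0, theta_deg = 0,
                               offset_um = c(0, 0), margin_um = 30, seed = 72)
  grid <- msi_grid_centers(fx$truth$col, fx$truth$row, 30)
  expect_equal(fx$truth$x, grid$x + 30)
  expect_equal(fx$truth$y, grid$y + 30)
  fx2 <- render_postmsi_fixture(n_col = 3, n_row = 3, seed = 72, margin_um = 30,
                                stepsize_um = 30)
  expect_identical(fx$image$values, fx2$image$values)
})
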