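# Grid-to-marks registration: coarse search, concave hulls, boundary
# identifiers, CPD, pixel assignment.

test_that("concave hull of a full 5x5 grid has 16 boundary points", {
  hull <- build_concave_hull(grid_points(5, 5, 30), 30)
  expect_equal(nrow(hull), 16)
  expect_equal(sum(hull$angle == 90), 4)
  expect_equal(sum(hull$angle == 180), 12)
})

test_that("a 2x2 grid is all boundary with right angles", {
  hull <- build_concave_hull(grid_points(2, 2, 20), 20)
  expect_equal(nrow(hull), 4)
  expect_true(all(hull$angle == 90))
})

test_that("removing a corner introduces a 270-degree turn", {
  P <- grid_points(5, 5, 30)
  P <- P[!(P[, 1] == 135 & P[, 2] == 135), ]  # drop the (5,5) corner
  hull <- build_concave_hull(P, 30)
  expect_equal(sum(hull$angle == 270), 1)
})

test_that("boundary identifiers are angle windows in walk order", {
  hull <- build_concave_hull(grid_points(5, 5, 30), 30)
  ids <- boundary_identifiers(hull, 1, 1)
  expect_true("180,180,180" %in% ids)           # straight edge
  expect_true("180,90,180" %in% ids)            # corner
  expect_error(boundary_identifiers(hull, 10, 10), "window longer")
})

test_that("a notched grid yields reflex (270) angles in 7-angle windows", {
  P <- grid_points(8, 8, 30)
  # notch: remove one edge point on the top row (not a corner)
  P <- P[!(P[, 1] == 105 & P[, 2] == 15), ]
  hull <- build_concave_hull(P, 30)
  ids7 <- boundary_identifiers(hull, 3, 3)
  expect_true(all(nchar(gsub("[^,]", "", ids7)) == 6))  # 7 angles each
  expect_true(any(grepl("270", ids7)))
})

test_that("identifier matching maps identical grids onto themselves", {
  hull <- build_concave_hull(grid_points(6, 4, 30), 30, source = "marks")
  hull2 <- build_concave_hull(grid_points(6, 4, 30), 30, source = "msi")
  m <- match_identifiers(hull, hull2, affine_transform(), max_dist = 15)
  expect_equal(nrow(m), nrow(hull))
  expect_equal(m$mark_x, m$msi_x)
  expect_equal(m$mark_y, m$msi_y)
})

test_that("pairs beyond the distance gate are excluded", {
  hull <- build_concave_hull(grid_points(6, 4, 30), 30)
  shifted <- build_concave_hull(grid_points(6, 4, 30) + 200, 30)
  expect_error(match_identifiers(hull, shifted, affine_transform(),
                                 max_dist = 10),
               "boundary matching failed")
})

test_that("ambiguous short identifiers are resolved at longer lengths", {
  # L-shaped grid: several corners share the short corner identifier;
  # with a permissive distance gate the unique-match rule forces a
  # longer window, which yields more matches than the shortest one
  P <- grid_points(8, 8, 30)
  P <- P[!(P[, 1] > 120 & P[, 2] > 120), ]
  hull_a <- build_concave_hull(P, 30, source = "marks")
  hull_b <- build_concave_hull(P, 30, source = "msi")
  m <- match_identifiers(hull_a, hull_b, affine_transform(), max_dist = 1e6)
  expect_gt(attr(m, "k"), 1)
  expect_gt(nrow(m), 4)
})

test_that("CPD recovers rigid maps, tolerates outliers, and inverts", {
  set.seed(11)
  Y <- cbind(runif(50, 0, 300), runif(50, 0, 300))
  truth <- rigid_transform(9, 25, -40)
  X <- transform_points(truth, Y)

  same <- cpd_register(Y, Y)
  expect_lt(max(abs(same$M - diag(3))), 1e-6)
  expect_lt(same$sigma2, 1e-10)

  tf <- cpd_register(Y, X, "rigid")
  expect_lt(max(abs(transform_points(tf, Y) - X)), 1e-6 * 30)

  X_out <- rbind(X, cbind(runif(3, 0, 300), runif(3, 0, 300)))
  tf2 <- cpd_register(Y, X_out, "rigid", omega = 0.1)
  expect_lt(max(abs(transform_points(tf2, Y) - X)), 0.1 * 30)

  fwd <- cpd_register(Y, X, "rigid")
  bwd <- cpd_register(X, Y, "rigid")
  round <- transform_points(bwd, transform_points(fwd, Y))
  expect_lt(max(abs(round - Y)), 1e-5 * 30)
})

test_that("CPD affine model recovers shears", {
  set.seed(12)
  Y <- cbind(runif(40, 0, 100), runif(40, 0, 100))
  A <- matrix(c(1.05, 0.1, -0.04, 0.97), 2)
  X <- Y %*% t(A) + matrix(c(5, -3), 40, 2, byrow = TRUE)
  tf <- cpd_register(Y, X, "affine")
  expect_lt(max(abs(transform_points(tf, Y) - X)), 1e-5)
})

test_that("pixel assignment is mutual-nearest within half a pitch", {
  grid <- msi_grid_centers(rep(1:5, 5), rep(1:5, each = 5), 30)
  marks <- tibble::tibble(x = grid$x, y = grid$y)
  asg <- assign_pixels(marks, grid, affine_transform(source = "MSI", target = "PostMSI"), 30)
  expect_true(all(!is.na(asg$mark_id)))
  expect_equal(max(asg$residual_um), 0)
  expect_false(attr(asg, "low_assignment"))

  asg2 <- assign_pixels(marks[-13, ], grid, affine_transform(source = "MSI", target = "PostMSI"), 30)
  expect_equal(sum(is.na(asg2$mark_id)), 1)
  expect_true(is.na(asg2$mark_id[13]))
})

test_that("assignment residuals under jitter follow the Rayleigh median", {
  set.seed(13)
  grid <- msi_grid_centers(rep(1:20, 20), rep(1:20, each = 20), 30)
  sigma <- 1
  marks <- tibble::tibble(x = grid$x + rnorm(400, 0, sigma),
                          y = grid$y + rnorm(400, 0, sigma))
  asg <- assign_pixels(marks, grid, affine_transform(source = "MSI", target = "PostMSI"), 30)
  rayleigh_median <- sigma * sqrt(2 * log(2))
  expect_equal(median(asg$residual_um, na.rm = TRUE), rayleigh_median,
               tolerance = 0.15)
})

test_that("coarse search finds identity for marks already on the grid", {
  grid <- msi_grid_centers(rep(1:6, 6), rep(1:6, each = 6), 30)
  marks <- tibble::tibble(x = grid$x, y = grid$y)
  attr(marks, "frame") <- "PostMSI"
  tf <- coarse_transform_search(marks, msi_grid_mask(grid$col, grid$row, 30), 30)
  expect_lt(max(abs(tf$M - diag(3))), 1e-6)
})

test_that("coarse search recovers a rotation within grid resolution", {
  grid <- msi_grid_centers(rep(1:8, 8), rep(1:8, each = 8), 30)
  truth <- rigid_transform(3, 10, -14, center = c(120, 120),
                           source = "MSI", target = "PostMSI")
  marks <- tibble::tibble(
    x = transform_points(truth, cbind(grid$x, grid$y))[, 1],
    y = transform_points(truth, cbind(grid$x, grid$y))[, 2])
  tf <- coarse_transform_search(marks, msi_grid_mask(grid$col, grid$row, 30), 30)
  # residual after the recovered coarse transform is within grid resolution
  back <- transform_points(tf, cbind(marks$x, marks$y))
  res <- sqrt((back[, 1] - grid$x)^2 + (back[, 2] - grid$y)^2)
  expect_lt(median(res), 15)
})

test_that("manual landmark mode drives CPD and assignment", {
  grid <- msi_grid_centers(rep(1:6, 6), rep(1:6, each = 6), 30)
  truth <- rigid_transform(0, 40, 25, source = "MSI", target = "PostMSI")
  moved <- transform_points(truth, cbind(grid$x, grid$y))
  marks <- tibble::tibble(x = moved[, 1], y = moved[, 2])
  lm_idx <- c(1, 6, 31, 36, 15, 22)
  manual <- tibble::tibble(msi_col = grid$col[lm_idx], msi_row = grid$row[lm_idx],
                           x_um = moved[lm_idx, 1], y_um = moved[lm_idx, 2])
  reg <- register_msi_grid(marks, grid$col, grid$row, 30,
                           manual_landmarks = manual)
  expect_true(all(!is.na(reg$assignment$mark_id)))
  expect_lt(max(reg$assignment$residual_um), 1e-4)
})
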