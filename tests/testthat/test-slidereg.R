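# Slide-chain registration: affine, b-spline, IMC ablation region,
# Euler registration of the IMC footprint.

test_that("registering an image to itself gives the identity", {
  img <- make_texture(128, 21)
  tf <- register_affine(img, phys_image(img$values, 2, "moving"))
  probe <- cbind(runif(50, 30, 220), runif(50, 30, 220))
  err <- sqrt(rowSums((transform_points(tf, probe) - probe)^2))
  expect_lt(max(err), 0.2)  # 0.1 px at 2 um/px
})

test_that("a pure translation is recovered to sub-pixel accuracy", {
  fixed <- make_texture(200, 22)
  truth <- affine_transform(t = c(12, -7), source = "moving", target = "fixed")
  moving <- transform_image(invert_transform(truth), fixed)
  moving$frame <- "moving"
  tf <- register_affine(fixed, moving)
  probe <- cbind(runif(100, 50, 350), runif(100, 50, 350))
  err <- sqrt(rowSums((transform_points(tf, probe) -
                         transform_points(truth, probe))^2))
  expect_lt(median(err), 0.5)
})

test_that("rotation and scale are recovered within tight tolerances", {
  fixed <- make_texture(220, 23)
  truth <- compose_chain(
    affine_transform(diag(2) * 1.02, c(0, 0), "moving", "mid"),
    rigid_transform(4, 5, -3, center = c(220, 220), source = "mid",
                    target = "fixed"))$transforms[[1]]
  moving <- transform_image(invert_transform(truth), fixed)
  moving$frame <- "moving"
  tf <- register_affine(fixed, moving)
  A <- tf$M[1:2, 1:2]
  theta <- atan2(A[2, 1], A[1, 1]) * 180 / pi
  scale <- sqrt(abs(det(A)))
  expect_lt(abs(theta - 4), 0.2)
  expect_lt(abs(scale - 1.02), 0.005)
})

test_that("b-spline on identical images leaves a zero field", {
  img <- make_texture(96, 24)
  tf <- register_bspline(img, phys_image(img$values, 2, "moving"),
                         affine_transform(source = "moving", target = "fixed"),
                         grid_spacing_um = 40, maxit = 40)
  expect_lt(max(abs(tf$forward$ctrl_dx), abs(tf$forward$ctrl_dy)), 1e-6)
})

test_that("a rigid-only difference leaves tiny b-spline displacements", {
  fixed <- make_texture(128, 25)
  truth <- rigid_transform(3, 8, -5, center = c(128, 128),
                           source = "moving", target = "fixed")
  moving <- transform_image(invert_transform(truth), fixed)
  moving$frame <- "moving"
  tf <- register_bspline(fixed, moving, truth, grid_spacing_um = 40,
                         maxit = 40)
  # displacements over the image interior stay well below a pixel
  probe <- cbind(runif(100, 40, 215), runif(100, 40, 215))
  u <- bspline_displacement(tf$forward, transform_points(invert_transform(truth), probe))
  expect_lt(median(sqrt(rowSums(u^2))), 1)
})

test_that("the IMC ablation region is found by its desaturation", {
  n <- 150  # 300 x 300 um at 2 um/px
  r <- array(0, c(n, n, 3))
  set.seed(26)
  # colourful tissue: red-ish with variation
  r[, , 1] <- 0.8 + matrix(rnorm(n^2, 0, 0.03), n, n)
  r[, , 2] <- 0.3; r[, , 3] <- 0.35
  # desaturated (gray) ablated square 100 x 100 um
  sq <- 26:75
  for (k in 1:3) r[sq, sq, k] <- 0.55 + matrix(rnorm(50^2, 0, 0.01), 50, 50)
  img <- phys_image(r, 2, "PostIMC")
  mask <- detect_imc_ablation_region(img, expected_area_um2 = 100^2)
  area <- sum(mask$values > 0) * 4
  expect_lt(abs(area / 1e4 - 1), 0.02)

  # fully saturated image: nothing desaturated to find
  r2 <- array(0, c(n, n, 3)); r2[, , 1] <- 1
  expect_error(detect_imc_ablation_region(phys_image(r2, 2, "PostIMC"), 1e4))

  # two desaturated candidates: the area-compatible one wins
  r3 <- r
  for (k in 1:3) r3[100:145, 100:145, k] <- 0.5  # 92x92 um distractor
  mask3 <- detect_imc_ablation_region(phys_image(r3, 2, "PostIMC"),
                                      expected_area_um2 = 100^2,
                                      area_tol = 0.1)
  ctr <- mask_centroid <- which(mask3$values > 0, arr.ind = TRUE)
  expect_lt(max(ctr[, 1]), 90)  # the first square, not the distractor
})

test_that("Euler registration of mask distance images recovers pose", {
  n <- 160
  m <- matrix(0, n, n); m[50:110, 45:115] <- 1
  imc <- phys_image(m, 2, "IMC")
  truth <- rigid_transform(2, 15, 6, center = c(160, 160),
                           source = "IMC", target = "PostIMC")
  abl <- transform_image(truth, imc, interp = "nearest")
  res <- register_imc_to_postimc(imc, abl)
  A <- res$transform$M[1:2, 1:2]
  theta <- atan2(A[2, 1], A[1, 1]) * 180 / pi
  expect_lt(abs(theta - 2), 0.3)
  expect_lt(median(res$boundary_dist_after), 2)
  expect_lt(median(res$boundary_dist_after), median(res$boundary_dist_before))
})

test_that("identical masks register to identity with zero boundary error", {
  m <- matrix(0, 100, 100); m[30:70, 25:75] <- 1
  imc <- phys_image(m, 2, "IMC")
  abl <- phys_image(m, 2, "PostIMC")
  res <- register_imc_to_postimc(imc, abl)
  expect_lt(max(res$boundary_dist_after), 2.1)
  expect_lt(median(res$boundary_dist_after), 1e-6 + median(res$boundary_dist_before) + 1)
})

test_that("manual ROI mode fits the rectangle in closed form", {
  m <- matrix(0, 100, 100); m[40:60, 30:80] <- 1  # 42 x 102 um rectangle
  imc <- phys_image(m, 2, "IMC")
  template <- phys_image(matrix(0, 150, 150), 2, "PostIMC")
  # ROI: the same rectangle translated by (40, 30) um
  roi <- cbind(c(58, 160, 160, 58), c(108, 108, 150, 150))
  res <- register_imc_to_postimc(imc, template, manual_roi = roi)
  # the ROI is the IMC rectangle translated by (0, +30) um
  moved <- transform_points(res$transform, cbind(110, 100))
  expect_equal(as.vector(moved), c(110, 130), tolerance = 3)
})
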