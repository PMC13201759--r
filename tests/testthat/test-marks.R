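# Ablation-mark enhancement, detection, parameter search, region-core
# pairing.

test_that("constant images pass the enhancement unchanged in shape", {
  img <- phys_image(matrix(0.7, 30, 30), 2, "PostMSI")
  out <- enhance_marks(img, detection_params(w = 0.5))
  expect_equal(diff(range(out$values)), 0)
})

test_that("w = 0 returns the polarity image itself", {
  set.seed(1)
  img <- phys_image(matrix(runif(900), 30, 30), 2, "PostMSI")
  out <- enhance_marks(img, detection_params(w = 0, marks_darker = FALSE))
  expect_equal(out$values, img$values)
})

test_that("oversized kernels are rejected", {
  img <- phys_image(matrix(0, 8, 8), 2, "PostMSI")
  expect_error(enhance_marks(img, detection_params(median_radius_px = 10)),
               "kernel larger than image")
})

test_that("enhancement is translation-equivariant away from the border", {
  fx <- render_postmsi_fixture(n_col = 4, n_row = 4, stepsize_um = 30,
                               img_pixelsize_um = 2, noise_sd = 0, seed = 2)
  p <- detection_params(w = 0.7, disk_radius_px = 4)
  e1 <- enhance_marks(fx$image, p)
  e2 <- enhance_marks(shift_content(fx$image, dc = 3), p)
  inner_r <- 15:85; inner_c <- 15:85
  expect_equal(e2$values[inner_r, inner_c + 3], e1$values[inner_r, inner_c],
               tolerance = 1e-10)
})

test_that("a rendered grid is detected with sub-micron centroids", {
  fx <- render_postmsi_fixture(n_col = 10, n_row = 10, stepsize_um = 30,
                               mark_radius_um = 6, img_pixelsize_um = 2,
                               jitter_sd_um = 0, seed = 4)
  p <- detection_params(w = 0.5, t = 0.12, disk_radius_px = 4)
  mk <- detect_marks(enhance_marks(fx$image, p), p, 30)
  expect_equal(nrow(mk), 100)
  nn <- apply(cbind(fx$truth$x, fx$truth$y), 1, function(v) {
    min(sqrt((mk$x - v[1])^2 + (mk$y - v[2])^2))
  })
  expect_lt(max(nn), 1)
  expect_lt(sqrt(mean(nn^2)), 0.5)
})

test_that("isolated blobs and blank images produce no detections", {
  img <- matrix(0.8, 100, 100)
  img[50:54, 50:54] <- 0.2  # one lonely blob
  p <- detection_params(w = 0, t = 0.3, min_subgraph = 4)
  mk <- detect_marks(enhance_marks(phys_image(img, 2, "PostMSI"), p), p, 30)
  expect_equal(nrow(mk), 0)
  blank <- phys_image(matrix(0.8, 60, 60), 2, "PostMSI")
  mk2 <- detect_marks(enhance_marks(blank, p), p, 30)
  expect_equal(nrow(mk2), 0)
})

test_that("the detection grid search prefers full-grid settings and is deterministic", {
  # realistic geometry: 24 um spots on a 30 um pitch (marks nearly touch,
  # so too-low thresholds merge neighbours and fail the size filter)
  fx <- render_postmsi_fixture(n_col = 8, n_row = 8, stepsize_um = 30,
                               mark_radius_um = 11, img_pixelsize_um = 2,
                               seed = 5)
  m <- matrix(0, nrow(fx$image$values), ncol(fx$image$values))
  m[23:128, 23:128] <- 1  # tissue covers the grid footprint
  tm <- phys_image(m, 2, "PostMSI")
  base <- detection_params(disk_radius_px = 6, area_bounds_um2 = c(200, 550),
                           min_subgraph = 8)
  r1 <- optimize_detection(fx$image, tm, w_grid = c(0.25, 0.75),
                           params = base, stepsize_um = 30)
  r2 <- optimize_detection(fx$image, tm, w_grid = c(0.25, 0.75),
                           params = base, stepsize_um = 30)
  expect_equal(nrow(r1$marks), 64)
  expect_identical(r1$params[c("w", "t")], r2$params[c("w", "t")])
  expect_error(
    optimize_detection(phys_image(matrix(0.8, 64, 64), 2, "PostMSI"), tm,
                       w_grid = c(0, 1), t_grid = c(0.9, 0.95),
                       stepsize_um = 30),
    "zero detections")
})

test_that("MSI regions pair with their cores and recover the offset", {
  mk_mask <- function(r0, c0, h, w, n = 80) {
    m <- matrix(0, n, n); m[r0:(r0 + h), c0:(c0 + w)] <- 1
    phys_image(m, 5, "PostMSI")
  }
  regions <- list(mk_mask(10, 10, 20, 15), mk_mask(45, 50, 18, 18))
  cores <- list(mk_mask(45, 50, 18, 18), mk_mask(10, 10, 20, 15),
                mk_mask(60, 5, 10, 10))
  res <- match_msi_regions_to_cores(regions, cores)
  r1 <- res[res$region == 1, ]
  expect_equal(r1$core, 2)
  expect_true(r1$matched)
  expect_equal(res$core[res$region == 2], 1)
  expect_false(3 %in% res$core[res$matched])

  # a region translated 100 um from its core: translation recovered
  reg2 <- list(mk_mask(10, 10, 20, 20))
  core2 <- list(mk_mask(10 + 20, 10, 20, 20))  # 20 rows * 5 um = 100 um down
  res2 <- match_msi_regions_to_cores(reg2, core2)
  tf <- res2$transform[[1]]
  moved <- transform_points(tf, cbind(100, 100))
  expect_equal(as.vector(moved - c(100, 100)), c(0, 100), tolerance = 5)
})

test_that("identical mask sets give identity pairing and transforms", {
  m <- matrix(0, 40, 40); m[10:25, 12:28] <- 1
  masks <- list(phys_image(m, 5, "PostMSI"))
  res <- match_msi_regions_to_cores(masks, masks)
  expect_equal(res$core, 1)
  tf <- res$transform[[1]]
  expect_equal(tf$M, diag(3), tolerance = 1e-8)
})

test_that("a fine 10 um pitch grid with small marks is fully recovered", {
  fx <- render_postmsi_fixture(n_col = 12, n_row = 12, stepsize_um = 10,
                               mark_radius_um = 3.5, img_pixelsize_um = 1,
                               jitter_sd_um = 0, margin_um = 20, seed = 6)
  p <- detection_params(w = 0.5, t = 0.15, disk_radius_px = 4,
                        area_bounds_um2 = pi * 3.5^2 * c(0.4, 1.8))
  mk <- detect_marks(enhance_marks(fx$image, p), p, 10)
  nn <- apply(cbind(fx$truth$x, fx$truth$y), 1, function(v) {
    min(sqrt((mk$x - v[1])^2 + (mk$y - v[2])^2))
  })
  expect_gte(mean(nn < 2.5), 0.99)
  expect_lt(sqrt(mean(nn^2)), 0.5)
  # nothing detected outside the grid hull
  expect_true(all(mk$x > min(fx$truth$x) - 5 & mk$x < max(fx$truth$x) + 5 &
                    mk$y > min(fx$truth$y) - 5 & mk$y < max(fx$truth$y) + 5))
})
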