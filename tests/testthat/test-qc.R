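# Registration QC: MLD, DICE, automatic landmarks, grid-artifact
# suppression, Hu-moment region matching, nuclei overlap.

test_that("MLD matches its definition on the boundary cases", {
  expect_equal(mld(c(1, 2, 3)), 2)
  expect_equal(mld(c(1, 2, 3, 4)), 2.5)
  pairs <- tibble::tibble(x1 = c(0, 1), y1 = c(0, 0), x2 = c(0, 1), y2 = c(0, 0))
  expect_equal(mld(pairs), 0)
  expect_error(mld(numeric()), "no landmark")
})

test_that("MLD and DICE agree with brute force on 1,000 random instances", {
  set.seed(31)
  for (i in 1:500) {
    d <- runif(sample(1:9, 1), 0, 100)
    expect_identical(mld(d), oracle_mld(d))
  }
  for (i in 1:500) {
    nr <- sample(2:5, 1); nc <- sample(2:5, 1)
    S <- matrix(rbinom(nr * nc, 1, 0.4), nr, nc)
    T <- matrix(rbinom(nr * nc, 1, 0.4), nr, nc)
    expect_identical(dice(S, T), oracle_dice(S, T))
  }
})

test_that("DICE handles the degenerate and standard cases", {
  m <- matrix(c(1, 1, 0, 0), 2)
  expect_equal(dice(m, m), 1)
  expect_equal(dice(m, 1 - m), 0)
  z <- matrix(0, 2, 2)
  expect_equal(dice(z, z), 1)
  expect_equal(dice(m, z), 0)
  S <- matrix(0, 20, 20); S[1:10, 1:10] <- 1
  T <- matrix(0, 20, 20); T[6:15, 1:10] <- 1
  expect_equal(dice(S, T), 0.5)
  expect_error(dice(S, matrix(0, 3, 3)), "shapes differ")
})

test_that("QC reports flag results with fewer than 100 landmarks", {
  expect_true(qc_report("x", 1, NA, 99)$excluded)
  expect_false(qc_report("x", 1, NA, 100)$excluded)
  for (n in c(0, 5, 99, 100, 250)) {
    expect_identical(qc_report("x", 1, NA, n)$excluded, n < 100)
  }
})

test_that("auto landmarks on identical images are near-zero distance", {
  img <- make_texture(200, 32, pixelsize_um = 1, blur = 2)
  lp <- auto_landmarks(img, phys_image(img$values, 1, img$frame))
  expect_gt(nrow(lp), 20)
  expect_lt(mld(lp[lp$inlier, ]), 1e-6)
})

test_that("auto landmark MLD recovers a planted shift", {
  img <- make_texture(220, 33, pixelsize_um = 1, blur = 2)
  shifted <- shift_content(img, dc = 5)
  lp <- auto_landmarks(img, shifted)
  expect_equal(mld(lp[lp$inlier, ]), 5, tolerance = 0.1)
})

test_that("planted wrong matches are removed by the inlier selection", {
  img <- make_texture(220, 34, pixelsize_um = 1, blur = 2)
  shifted <- shift_content(img, dc = 5)
  lp <- auto_landmarks(img, shifted)
  n_bad <- ceiling(nrow(lp) * 0.2)
  bad <- lp[seq_len(n_bad), ]
  bad$x2 <- bad$x2 + 40 * rep_len(c(1, -1), n_bad)  # 40 um wrong offsets
  bad$dist <- sqrt((bad$x1 - bad$x2)^2 + (bad$y1 - bad$y2)^2)
  corrupted <- rbind(lp, bad)
  rs <- msimclink:::ransac_affine(cbind(corrupted$x1, corrupted$y1),
                                  cbind(corrupted$x2, corrupted$y2),
                                  corrupted$descr_dist)
  kept <- corrupted[rs$inlier, ]
  expect_lt(max(abs(kept$dist - 5)), 3)
  expect_equal(mld(kept), 5, tolerance = 0.5)
})

test_that("grid artifacts are suppressed while preserving content", {
  set.seed(35)
  n <- 128
  base <- EBImage::gblur(EBImage::Image(matrix(rnorm(n^2), n, n)), 4)@.Data + 1
  gx <- outer(rep(1, n), 1:n); gy <- outer(1:n, rep(1, n))
  periodic <- 0.5 * sin(2 * pi * gx / 8) * sin(2 * pi * gy / 8)
  out <- suppress_grid_artifact(phys_image(base + periodic, 2, "PostMSI"))
  amp <- function(m) Mod(stats::fft(m))[17, 17]  # the planted frequency
  expect_gt(1 - amp(out$values) / amp(base + periodic), 0.9)
  # DC (mean) preserved
  expect_equal(mean(out$values), mean(base + periodic), tolerance = 1e-9)
  # aperiodic content passes through
  out2 <- suppress_grid_artifact(phys_image(base, 2, "PostMSI"))
  expect_gt(cor(as.vector(base), as.vector(out2$values)), 0.99)
})

test_that("Hu moments are translation and rotation invariant", {
  set.seed(36)
  th <- 0.7
  xs <- runif(200, -10, 10); ys <- 0.5 * xs + runif(200, -3, 3)
  h1 <- hu_moments(xs, ys)
  h2 <- hu_moments(xs + 50, ys - 20)
  xr <- xs * cos(th) - ys * sin(th); yr <- xs * sin(th) + ys * cos(th)
  h3 <- hu_moments(xr, yr)
  expect_equal(h1, h2, tolerance = 1e-10)
  expect_equal(h1[1:4], h3[1:4], tolerance = 1e-6)
})

test_that("region matching pairs identical masks and applies its gates", {
  m <- matrix(0, 120, 120)
  m[10:40, 10:40] <- 1   # 31x31 px at 2 um = 62x62 um -> 3844 um2
  m[60:100, 50:100] <- 2
  masks <- phys_image(m, 2, "A")
  res <- match_regions(masks, phys_image(m, 2, "B"))
  expect_equal(nrow(res), 2)
  expect_equal(res$I, c(0, 0))
  expect_equal(res$dice, c(1, 1))

  # area ratio 2 is rejected even with overlap
  m2 <- matrix(0, 120, 120); m2[10:40, 10:40] <- 1
  m3 <- matrix(0, 120, 120); m3[10:40, 10:71] <- 1  # double the area
  expect_equal(nrow(match_regions(phys_image(m2, 2, "A"),
                                  phys_image(m3, 2, "B"))), 0)

  # centroids 60 um apart are rejected
  m4 <- matrix(0, 120, 120); m4[10:40, 40:70] <- 1  # shifted 60 um
  expect_equal(nrow(match_regions(phys_image(m2, 2, "A"),
                                  phys_image(m4, 2, "B"))), 0)
})

test_that("nuclei overlap evaluation uses only overlapping label pairs", {
  a <- matrix(0L, 60, 60)
  for (k in 1:9) {
    r <- 6 + 18 * ((k - 1) %/% 3); c <- 6 + 18 * ((k - 1) %% 3)
    a[r:(r + 7), c:(c + 7)] <- k
  }
  ia <- phys_image(a, 1, "F")
  res <- nuclei_overlap_eval(ia, phys_image(a, 1, "F"))
  expect_equal(res$mld_um, 0)
  expect_equal(res$dice, 1)
  expect_equal(res$n_landmarks, 9)

  # shift by 2 um: nuclei of 8 um still overlap; MLD equals the shift
  b <- matrix(0L, 60, 60)
  b[, 3:60] <- a[, 1:58]
  res2 <- nuclei_overlap_eval(ia, phys_image(b, 1, "F"))
  expect_equal(res2$mld_um, 2, tolerance = 1e-9)

  # a non-overlapping nucleus is excluded from the count
  a2 <- a; a2[a2 == 9] <- 0L
  a2[50:57, 50:57] <- 9L  # moved far away in image a only
  b2 <- a; b2[b2 == 9] <- 0L
  b2[1:8, 40:47] <- 9L
  res3 <- nuclei_overlap_eval(phys_image(a2, 1, "F"), phys_image(b2, 1, "F"))
  expect_equal(res3$n_landmarks, 8)
})

test_that("centroid MLD over matched tissue masks is the median shift", {
  mk <- function(r, c) {
    m <- matrix(0, 50, 50); m[r:(r + 9), c:(c + 9)] <- 1
    phys_image(m, 1, "F")
  }
  a <- list(mk(5, 5), mk(20, 20), mk(35, 10))
  expect_equal(centroid_mld(a, a), 0)
  b <- list(mk(5, 6), mk(20, 22), mk(35, 19))  # shifts 1, 2, 9 um
  expect_equal(centroid_mld(a, b), 2)
  expect_error(centroid_mld(a, b[1:2]), "length")
})
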