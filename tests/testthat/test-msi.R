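# MSI spectrum preprocessing: TIC normalization, reference alignment,
# peak binning, log transform, imzML round trips.

make_spectra <- function(ints, mzs = NULL) {
  n <- length(ints)
  if (is.null(mzs)) mzs <- replicate(n, c(100, 200, 300)[seq_along(ints[[1]])],
                                     simplify = FALSE)
  msi_spectra(col = seq_len(n), row = rep(1L, n), mz = mzs, intensity = ints,
              stepsize_um = 30, pixelsize_um = 24)
}

test_that("TIC normalization scales every spectrum to the mean total", {
  sp <- make_spectra(list(c(1, 1), c(2, 2)), list(c(100, 200), c(100, 200)))
  out <- tic_normalize(sp)
  expect_equal(vapply(out$intensity, sum, 0), c(3, 3))

  single <- make_spectra(list(c(2, 5)), list(c(100, 200)))
  expect_equal(tic_normalize(single)$intensity[[1]], c(2, 5))

  # within-spectrum ratios preserved, idempotent
  set.seed(1)
  sp2 <- make_spectra(lapply(1:5, function(i) runif(3, 0.1, 10)))
  out2 <- tic_normalize(sp2)
  for (i in 1:5) {
    expect_equal(out2$intensity[[i]] / out2$intensity[[i]][1],
                 sp2$intensity[[i]] / sp2$intensity[[i]][1])
  }
  out3 <- tic_normalize(out2)
  expect_equal(out3$intensity, out2$intensity)
})

test_that("zero spectra are flagged and all-zero input errors", {
  sp <- make_spectra(list(c(0, 0), c(1, 3)), list(c(100, 200), c(100, 200)))
  out <- tic_normalize(sp)
  expect_identical(out$tic_zero, c(TRUE, FALSE))
  expect_equal(out$intensity[[1]], c(0, 0))
  allz <- make_spectra(list(c(0, 0)), list(c(100, 200)))
  expect_error(tic_normalize(allz), "no signal")
})

test_that("alignment recovers a constant m/z shift and ignores far peaks", {
  # peaks exactly at references: identity warp
  sp <- make_spectra(list(c(0, 5, 0, 8, 0)),
                     list(c(99, 100, 150, 200, 250)))
  out <- align_spectra(sp, c(100, 200))
  expect_equal(out$mz[[1]], sp$mz[[1]])

  # all peaks offset by +0.05 Da with one reference: -0.05 shift applied
  sp2 <- make_spectra(list(c(0, 5, 0)), list(c(99.5, 100.05, 150.05)))
  out2 <- align_spectra(sp2, 100)
  expect_equal(out2$mz[[1]], sp2$mz[[1]] - 0.05)

  # reference far outside the tolerance window leaves the axis alone
  sp3 <- make_spectra(list(c(0, 5, 0)), list(c(99, 100.5, 150)))
  expect_warning(out3 <- align_spectra(sp3, 105, tol = 0.2), "identity")
  expect_equal(out3$mz[[1]], sp3$mz[[1]])
})

test_that("binning takes the window maximum and flags empty windows", {
  sp <- make_spectra(list(c(7)), list(c(1419.47)))
  st <- bin_peaks(sp, 1419.475, tol = 0.1)
  expect_equal(st$values[1, 1], 7)

  sp2 <- make_spectra(list(c(3, 5, 2)), list(c(499.95, 500.02, 600)))
  st2 <- bin_peaks(sp2, c(500, 550), tol = 0.1)
  expect_equal(st2$values[1, ], c(5, NA))

  expect_error(bin_peaks(sp, c(500, 500.1), tol = 0.1), "overlapping")
})

test_that("align then bin recovers unshifted bin values exactly", {
  refs <- c(100, 200, 300)
  ints <- list(c(4, 9, 2), c(1, 3, 8))
  truth <- bin_peaks(make_spectra(ints, list(refs, refs)), refs, tol = 0.1)
  shifted <- make_spectra(ints, list(refs + 0.07, refs + 0.07))
  recovered <- bin_peaks(align_spectra(shifted, refs, tol = 0.2), refs, tol = 0.1)
  expect_equal(recovered$values, truth$values)
})

test_that("binning an already-binned stack re-expressed as spectra is identity", {
  set.seed(2)
  refs <- c(100, 250, 412.5)
  sp <- make_spectra(lapply(1:4, function(i) runif(3, 1, 9)),
                     replicate(4, refs, simplify = FALSE))
  st <- bin_peaks(sp, refs, tol = 0.2)
  st$values[2, 3] <- NA  # inject a missing value; it must survive
  st2 <- bin_peaks(stack_to_spectra(st), refs, tol = 0.2)
  expect_equal(st2$values, st$values)
})

test_that("log2 transform uses a pseudocount and keeps missing values", {
  st <- msi_stack(matrix(c(3, 0, NA), 1), c(100, 200, 300), 1, 1, 30)
  out <- log2_transform(st)
  expect_equal(out$values[1, ], c(2, 0, NA))
  st$values[1, 1] <- -1
  expect_error(log2_transform(st), "negative")
})

test_that("imzML round trip preserves spectra in both storage modes", {
  set.seed(3)
  ax <- sort(runif(20, 100, 2000))
  sp <- msi_spectra(col = c(1, 2, 2), row = c(1, 1, 2),
                    mz = list(ax, ax, ax),
                    intensity = replicate(3, round(runif(20, 0, 100), 2),
                                          simplify = FALSE),
                    stepsize_um = 30, pixelsize_um = 24)
  for (mode in c("processed", "continuous")) {
    f <- tempfile(fileext = ".imzML")
    write_imzml(sp, f, mode = mode)
    back <- read_imzml(f)
    expect_equal(back$col, sp$col)
    expect_equal(back$row, sp$row)
    expect_equal(back$mz, sp$mz)
    # intensities stored as 32-bit floats
    expect_equal(unlist(back$intensity), unlist(sp$intensity), tolerance = 1e-6)
    expect_equal(attr(back, "stepsize_um"), 30)
    unlink(c(f, sub("imzML$", "ibd", f)))
  }
})

test_that("channel images and tibble views agree with the stack", {
  st <- msi_stack(matrix(c(1, 2, 3, 4), 2), c(100, 200),
                  col = c(1, 2), row = c(1, 1), stepsize_um = 30)
  img <- stack_channel_image(st, 2)
  expect_equal(img[1, ], c(3, 4))
  tb <- tibble::as_tibble(st)
  expect_equal(nrow(tb), 4)
  expect_equal(tb$value[tb$mz == 200 & tb$col == 2], 4)
})

test_that("stack TIFF export writes pages plus a quantitative sidecar", {
  st <- msi_stack(matrix(c(1, 2, 3, NA), 2), c(100, 200),
                  col = c(1, 2), row = c(1, 1), stepsize_um = 30,
                  pixelsize_um = 24)
  f <- tempfile(fileext = ".tiff")
  write_stack_tiff(st, f)
  expect_true(file.exists(f))
  side <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_equal(side$stepsize_um, 30)
  expect_equal(side$channel_max, c(2, 3))
  pages <- tiff::readTIFF(f, all = TRUE)
  expect_equal(length(pages), 2)
  # 8-bit storage: values round-trip to within one grey level
  expect_equal(pages[[1]][1, 1] * side$channel_max[1], 1, tolerance = 0.01)
  unlink(c(f, paste0(f, ".json")))
})
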