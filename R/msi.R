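#' MSI spectra container
#'
#' One row per MSI pixel (ablation position): integer grid indices
#' `col`/`row` plus list-columns `mz` (strictly increasing, Da) and
#' `intensity` (non-negative). Grid geometry travels as attributes:
#' `stepsize_um` (grid pitch) and `pixelsize_um` (ablation spot size).
#'
#' @param col,row integer grid indices (unique pairs).
#' @param mz list of numeric vectors, strictly increasing within a spectrum.
#' @param intensity list of numeric vectors, same lengths as `mz`.
#' @param stepsize_um grid pitch in micrometres.
#' @param pixelsize_um nominal ablation spot size (<= stepsize).
#' @return A tibble of class `msi_spectra`.
#' @examples
#' sp <- msi_spectra(col = 1:2, row = c(1, 1),
#'                   mz = list(c(100, 200), c(100, 200)),
#'                   intensity = list(c(1, 1), c(2, 2)),
#'                   stepsize_um = 30, pixelsize_um = 24)
#' @export
msi_spectra <- function(col, row, mz, intensity, stepsize_um, pixelsize_um = stepsize_um) {
  stopifnot(length(col) == length(row), length(mz) == length(col),
            length(intensity) == length(col), pixelsize_um <= stepsize_um)
  if (anyDuplicated(paste(col, row))) stop("grid indices must be unique")
  for (i in seq_along(mz)) {
    if (length(mz[[i]]) != length(intensity[[i]]))
      stop("mz and intensity lengths differ in spectrum ", i)
    if (length(mz[[i]]) > 1 && any(diff(mz[[i]]) <= 0))
      stop("mz must be strictly increasing in spectrum ", i)
    if (any(intensity[[i]] < 0)) stop("negative intensity in spectrum ", i)
  }
  out <- tibble::tibble(col = as.integer(col), row = as.integer(row),
                        mz = mz, intensity = intensity)
  attr(out, "stepsize_um") <- stepsize_um
  attr(out, "pixelsize_um") <- pixelsize_um
  class(out) <- c("msi_spectra", class(out))
  out
}

keep_msi_attrs <- function(out, template) {
  attr(out, "stepsize_um") <- attr(template, "stepsize_um")
  attr(out, "pixelsize_um") <- attr(template, "pixelsize_um")
  if (!inherits(out, "msi_spectra")) class(out) <- c("msi_spectra", class(out))
  out
}

#' Total-ion-current normalization
#'
#' Each spectrum is rescaled so that its summed intensity (TIC) equals
#' the mean pre-normalization TIC over all non-empty spectra. The global
#' target keeps intensities on their original scale; the operation is
#' idempotent. Zero-sum spectra pass through unchanged and are flagged in
#' a logical `tic_zero` column.
#'
#' @param spectra an [msi_spectra].
#' @return An [msi_spectra] with rescaled intensities and a `tic_zero`
#'   column.
#' @export
tic_normalize <- function(spectra) {
  stopifnot(inherits(spectra, "msi_spectra"))
  tic <- vapply(spectra$intensity, sum, 0)
  if (all(tic == 0)) stop("no signal: all spectra have zero total intensity")
  target <- mean(tic[tic > 0])
  out <- spectra
  out$intensity <- purrr::map2(spectra$intensity, tic, function(v, s) {
    if (s == 0) v else v * (target / s)
  })
  out$tic_zero <- tic == 0
  keep_msi_attrs(out, spectra)
}

# local maxima indices of an intensity vector (plateaus keep first index)
local_maxima <- function(v) {
  n <- length(v)
  if (n == 0) return(integer())
  if (n <= 2) return(which.max(v))
  left <- c(-Inf, v[-n]); right <- c(v[-1], -Inf)
  which(v > left & v >= right)
}

#' Recalibrate spectra against reference m/z values
#'
#' Each spectrum's m/z axis is shifted (default) or piecewise-linearly
#' warped so that its local maxima land on the nearest reference within
#' `tol`. References with no peak inside the tolerance window are ignored
#' by the fit; if no spectrum matches any reference at all, a warning is
#' emitted and the axes are returned unchanged.
#'
#' @param spectra an [msi_spectra].
#' @param reference_mz numeric vector of reference m/z values (Da).
#' @param tol match tolerance window half-width (Da).
#' @param model `"shift"` (single additive shift per spectrum) or
#'   `"piecewise"` (linear interpolation between matched peaks).
#' @return An [msi_spectra] with recalibrated (still strictly monotone)
#'   m/z axes.
#' @export
align_spectra <- function(spectra, reference_mz, tol = 0.2,
                          model = c("shift", "piecewise")) {
  stopifnot(inherits(spectra, "msi_spectra"), length(reference_mz) >= 1, tol > 0)
  model <- match.arg(model)
  reference_mz <- sort(reference_mz)
  any_match <- FALSE
  new_mz <- purrr::map(seq_len(nrow(spectra)), function(i) {
    mz <- spectra$mz[[i]]; ity <- spectra$intensity[[i]]
    if (length(mz) == 0) return(mz)
    pk <- local_maxima(ity)
    # for each reference, nearest peak within tol
    matched_peak <- numeric(); matched_ref <- numeric()
    for (r in reference_mz) {
      d <- abs(mz[pk] - r)
      j <- which.min(d)
      if (length(j) && d[j] <= tol) {
        matched_peak <- c(matched_peak, mz[pk[j]])
        matched_ref <- c(matched_ref, r)
      }
    }
    if (length(matched_ref) == 0) return(mz)
    any_match <<- TRUE
    if (model == "shift") {
      mz + mean(matched_ref - matched_peak)
    } else {
      # piecewise-linear warp through (peak, ref); constant shift outside
      o <- order(matched_peak)
      xp <- matched_peak[o]; yp <- matched_ref[o]
      keep <- !duplicated(xp)
      xp <- xp[keep]; yp <- yp[keep]
      if (length(xp) == 1) return(mz + (yp - xp))
      warped <- stats::approx(xp, yp - xp, xout = mz, rule = 2)$y + mz
      if (any(diff(warped) <= 0)) mz + mean(yp - xp) else warped
    }
  })
  if (!any_match) {
    warning("no reference peak found in any spectrum; identity alignment")
    return(spectra)
  }
  out <- spectra
  out$mz <- new_mz
  keep_msi_attrs(out, spectra)
}

#' MSI image stack: one channel per reference m/z
#'
#' Per-pixel, per-channel peak-height values. Empty bin windows are
#' `NA` ("missing"), never 0, so downstream model fits can drop them.
#'
#' @param values numeric matrix, pixels x channels (may contain `NA`).
#' @param channels numeric reference m/z per channel.
#' @param col,row integer grid indices per pixel.
#' @param stepsize_um,pixelsize_um grid geometry (micrometres).
#' @param channel_names optional channel labels.
#' @return An object of class `msi_stack`.
#' @export
msi_stack <- function(values, channels, col, row, stepsize_um,
                      pixelsize_um = stepsize_um, channel_names = NULL) {
  stopifnot(is.matrix(values), ncol(values) == length(channels),
            nrow(values) == length(col), length(col) == length(row))
  if (is.null(channel_names)) channel_names <- format(channels, trim = TRUE)
  structure(list(values = values, channels = channels,
                 channel_names = channel_names,
                 col = as.integer(col), row = as.integer(row),
                 stepsize_um = stepsize_um, pixelsize_um = pixelsize_um),
            class = "msi_stack")
}

#' @exportS3Method base::print
print.msi_stack <- function(x, ...) {
  cat(sprintf("<msi_stack> %d pixels x %d channels, step %g um, spot %g um, %.1f%% missing\n",
              nrow(x$values), ncol(x$values), x$stepsize_um, x$pixelsize_um,
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.msi_stack <- function(x, ...) {
  tibble::tibble(
    col = rep(x$col, times = ncol(x$values)),
    row = rep(x$row, times = ncol(x$values)),
    mz = rep(x$channels, each = nrow(x$values)),
    value = as.vector(x$values)
  )
}

#' Bin spectra at reference m/z values (peak height)
#'
#' The channel value is the maximum intensity observed inside
#' `[ref - tol, ref + tol]`; an empty window yields `NA`. Overlapping
#' reference windows are an error.
#'
#' @param spectra an [msi_spectra].
#' @param reference_mz numeric reference m/z values (Da).
#' @param tol window half-width; Da if `tol_unit = "da"`, parts-per-million
#'   otherwise.
#' @param tol_unit `"da"` or `"ppm"`.
#' @param channel_names optional labels (e.g. glycan names).
#' @return An [msi_stack].
#' @export
bin_peaks <- function(spectra, reference_mz, tol = 0.1,
                      tol_unit = c("da", "ppm"), channel_names = NULL) {
  stopifnot(inherits(spectra, "msi_spectra"), tol > 0)
  tol_unit <- match.arg(tol_unit)
  o <- order(reference_mz)
  reference_mz <- reference_mz[o]
  if (!is.null(channel_names)) channel_names <- channel_names[o]
  half <- if (tol_unit == "da") rep(tol, length(reference_mz)) else reference_mz * tol * 1e-6
  lo <- reference_mz - half; hi <- reference_mz + half
  if (length(reference_mz) > 1) {
    ov <- which(hi[-length(hi)] > lo[-1])
    if (length(ov)) {
      stop(sprintf("overlapping reference windows: %.6g and %.6g",
                   reference_mz[ov[1]], reference_mz[ov[1] + 1]))
    }
  }
  vals <- matrix(NA_real_, nrow(spectra), length(reference_mz))
  for (i in seq_len(nrow(spectra))) {
    mz <- spectra$mz[[i]]; ity <- spectra$intensity[[i]]
    if (length(mz) == 0) next
    i1 <- findInterval(lo, mz) + 1L  # first index with mz >= lo
    i2 <- findInterval(hi, mz)       # last index with mz <= hi
    for (k in seq_along(reference_mz)) {
      if (i1[k] <= i2[k]) vals[i, k] <- max(ity[i1[k]:i2[k]])
    }
  }
  msi_stack(vals, reference_mz, spectra$col, spectra$row,
            attr(spectra, "stepsize_um"), attr(spectra, "pixelsize_um"),
            channel_names)
}

#' Log2 transform of a binned stack
#'
#' `value -> log2(value + 1)`; a one-count pseudocount keeps zeros at
#' zero. Missing values stay missing; negative values are an error.
#'
#' @param stack an [msi_stack].
#' @return An [msi_stack] on the log2 scale.
#' @export
log2_transform <- function(stack) {
  stopifnot(inherits(stack, "msi_stack"))
  if (any(stack$values < 0, na.rm = TRUE)) stop("negative value in stack")
  stack$values <- log2(stack$values + 1)
  stack
}

#' Re-express a binned stack as spectra
#'
#' Each pixel becomes a centroided spectrum with one point per non-missing
#' channel. Binning such spectra at the same references is the identity.
#'
#' @param stack an [msi_stack].
#' @return An [msi_spectra].
#' @export
stack_to_spectra <- function(stack) {
  stopifnot(inherits(stack, "msi_stack"))
  msi_spectra(
    col = stack$col, row = stack$row,
    mz = lapply(seq_len(nrow(stack$values)), function(i) {
      stack$channels[!is.na(stack$values[i, ])]
    }),
    intensity = lapply(seq_len(nrow(stack$values)), function(i) {
      v <- stack$values[i, ]; v[!is.na(v)]
    }),
    stepsize_um = stack$stepsize_um, pixelsize_um = stack$pixelsize_um
  )
}

#' Render one stack channel as a grid image
#'
#' @param stack an [msi_stack].
#' @param channel channel index or reference m/z value.
#' @return A matrix indexed `[row, col]` over the bounding grid, `NA`
#'   where no pixel was measured.
#' @export
stack_channel_image <- function(stack, channel = 1) {
  stopifnot(inherits(stack, "msi_stack"))
  k <- if (channel %in% seq_len(ncol(stack$values)) && channel == round(channel)) {
    as.integer(channel)
  } else which.min(abs(stack$channels - channel))
  img <- matrix(NA_real_, max(stack$row), max(stack$col))
  img[cbind(stack$row, stack$col)] <- stack$values[, k]
  img
}

#' Read a reference peak list
#'
#' @param path CSV with columns `name` and `mz`.
#' @return A tibble with columns `name`, `mz` sorted by m/z.
#' @export
read_peak_list <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "mz") %in% names(df)))
  tibble::as_tibble(df[order(df$mz), c("name", "mz")])
}
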