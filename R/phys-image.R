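#' Physical image: a raster with a pixel size in micrometres
#'
#' A `phys_image` wraps a numeric matrix (grayscale) or a 3-d array
#' (rows x cols x channels) together with its physical pixel size and a
#' named coordinate frame. All geometry in the package is expressed in
#' micrometres, y-down, with the centre of pixel `(row, col)` at
#' `((col - 0.5) * pixelsize, (row - 0.5) * pixelsize)`.
#'
#' @param values numeric matrix or 3-d array of pixel values.
#' @param pixelsize_um edge length of one pixel in micrometres.
#' @param frame name of the coordinate frame this image lives in
#'   (e.g. `"PostMSI"`, `"IMC"`).
#' @param channels optional character vector of channel names for 3-d arrays.
#' @return An object of class `phys_image`.
#' @examples
#' img <- phys_image(matrix(0, 10, 10), pixelsize_um = 2, frame = "PostMSI")
#' dim(img)
#' @export
phys_image <- function(values, pixelsize_um = 1, frame = "image", channels = NULL) {
  stopifnot(is.numeric(values) || is.logical(values))
  if (is.logical(values)) values <- values * 1
  nd <- length(dim(values))
  if (is.null(dim(values)) || !(nd %in% c(2L, 3L))) {
    stop("`values` must be a matrix or a rows x cols x channels array")
  }
  if (!is.null(channels)) {
    stopifnot(nd == 3L, length(channels) == dim(values)[3])
  }
  stopifnot(is.numeric(pixelsize_um), pixelsize_um > 0)
  structure(
    list(values = values, pixelsize_um = pixelsize_um, frame = frame,
         channels = channels),
    class = "phys_image"
  )
}

#' @export
dim.phys_image <- function(x) dim(x$values)

#' @exportS3Method base::print
print.phys_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<phys_image> %d x %d px%s, %.3g um/px, frame '%s' (%.4g x %.4g um)\n",
    d[1], d[2],
    if (length(d) == 3) sprintf(" x %d channels", d[3]) else "",
    x$pixelsize_um, x$frame, d[2] * x$pixelsize_um, d[1] * x$pixelsize_um
  ))
  invisible(x)
}

#' Physical centre coordinates of every pixel
#'
#' @param img a [phys_image].
#' @return A tibble with columns `row`, `col`, `x`, `y` (micrometres).
#' @export
pixel_centers <- function(img) {
  stopifnot(inherits(img, "phys_image"))
  d <- dim(img$values)
  g <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  tibble::tibble(
    row = g$row, col = g$col,
    x = (g$col - 0.5) * img$pixelsize_um,
    y = (g$row - 0.5) * img$pixelsize_um
  )
}

#' Convert a colour image to grayscale
#'
#' Uses the usual luminance weights for RGB input; single-channel images
#' pass through.
#'
#' @param img a [phys_image].
#' @return A single-channel [phys_image].
#' @export
to_gray <- function(img) {
  stopifnot(inherits(img, "phys_image"))
  v <- img$values
  if (length(dim(v)) == 2L) return(img)
  stopifnot(dim(v)[3] >= 3)
  g <- 0.299 * v[, , 1] + 0.587 * v[, , 2] + 0.114 * v[, , 3]
  phys_image(g, img$pixelsize_um, img$frame)
}

#' @exportS3Method base::as.matrix
as.matrix.phys_image <- function(x, ...) {
  v <- x$values
  if (length(dim(v)) == 3L) stop("multichannel image; subset a channel first")
  v
}

# map physical (x, y) um to fractional (row, col) index space of an image
phys_to_index <- function(img, xy) {
  cbind(row = xy[, 2] / img$pixelsize_um + 0.5,
        col = xy[, 1] / img$pixelsize_um + 0.5)
}

# bilinear sample of a matrix at fractional (row, col); outside -> `fill`
bilinear_sample <- function(m, rc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  r <- rc[, 1]; cc <- rc[, 2]
  r0 <- floor(r); c0 <- floor(cc)
  fr <- r - r0; fc <- cc - c0
  out <- rep(fill, length(r))
  ok <- r0 >= 1 & c0 >= 1 & r0 <= nr - 1 & c0 <= nc - 1
  # clamp the one-past edge so points on the last row/col still sample
  edge <- (r >= 1 & cc >= 1 & r <= nr & cc <= nc) & !ok
  if (any(ok)) {
    i00 <- cbind(r0[ok], c0[ok]); i01 <- cbind(r0[ok], c0[ok] + 1)
    i10 <- cbind(r0[ok] + 1, c0[ok]); i11 <- cbind(r0[ok] + 1, c0[ok] + 1)
    out[ok] <- m[i00] * (1 - fr[ok]) * (1 - fc[ok]) +
      m[i01] * (1 - fr[ok]) * fc[ok] +
      m[i10] * fr[ok] * (1 - fc[ok]) +
      m[i11] * fr[ok] * fc[ok]
  }
  if (any(edge)) {
    out[edge] <- m[cbind(pmin(pmax(round(r[edge]), 1), nr),
                         pmin(pmax(round(cc[edge]), 1), nc))]
  }
  out
}

# nearest-neighbour sample (for label masks)
nn_sample <- function(m, rc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  r <- round(rc[, 1]); cc <- round(rc[, 2])
  out <- rep(fill, nrow(rc))
  ok <- r >= 1 & cc >= 1 & r <= nr & cc <= nc
  out[ok] <- m[cbind(r[ok], cc[ok])]
  out
}

# block-mean downsample by integer factor (pyramid level builder)
downsample2 <- function(m, f = 2L) {
  nr <- (nrow(m) %/% f) * f
  nc <- (ncol(m) %/% f) * f
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  a <- array(m, dim = c(f, nr %/% f, f, nc %/% f))
  apply(a, c(2, 4), mean)
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.phys_image <- function(object, ...) {
  df <- pixel_centers(object)
  v <- object$values
  if (length(dim(v)) == 3L) v <- v[, , 1]
  df$value <- as.vector(v)[(df$col - 1) * dim(v)[1] + df$row]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x [um]", y = "y [um]", fill = "value")
}
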