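# IMC pixel-level cleanup and cell-table construction. Segmentation
# masks and cluster labels are inputs (produced upstream); only the
# stated pixel/cell filters live here.

# max over the 8-neighbourhood of each pixel, per channel
neighbor_max8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  shift <- function(dr, dc) {
    out <- matrix(-Inf, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  res <- matrix(-Inf, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    res <- pmax(res, shift(dr, dc))
  }
  res
}

#' Suppress hot pixels in an IMC image
#'
#' A pixel whose value exceeds the maximum of its 8 neighbours by more
#' than `delta` counts is set to that local threshold
#' (`neighbour max + delta`), per channel.
#'
#' @param img a [phys_image] with one channel per marker (counts).
#' @param delta hot-pixel margin in counts.
#' @return A [phys_image] of the same shape.
#' @export
remove_hot_pixels <- function(img, delta = 50) {
  stopifnot(inherits(img, "phys_image"), delta > 0)
  v <- img$values
  fix_one <- function(m) {
    thr <- neighbor_max8(m) + delta
    pmin(m, thr)
  }
  if (length(dim(v)) == 3L) {
    for (k in seq_len(dim(v)[3])) v[, , k] <- fix_one(v[, , k])
  } else v <- fix_one(v)
  img$values <- v
  img
}

#' Threshold-based pixel denoising
#'
#' In `"as-stated"` mode every pixel (all channels) with a value above
#' `thr` is set to 0; `"clip"` mode instead caps such pixels at `thr`.
#' The zero-out rule is kept as the default because it is the documented
#' behaviour of the upstream pixel pipeline; it is appropriate for
#' probability-like channels where values above the threshold indicate
#' artefacts. `mode = "clip"` is offered for count-like channels.
#'
#' @param img a [phys_image].
#' @param thr threshold (same units as the image values).
#' @param mode `"as-stated"` or `"clip"`.
#' @return A [phys_image].
#' @export
threshold_denoise <- function(img, thr = 1.5, mode = c("as-stated", "clip")) {
  stopifnot(inherits(img, "phys_image"), thr >= 0)
  mode <- match.arg(mode)
  v <- img$values
  if (mode == "as-stated") v[v > thr] <- 0 else v[v > thr] <- thr
  img$values <- v
  img
}

#' Build a cell table from an image and a segmentation mask
#'
#' Per labelled cell: pixel-count area (1 um^2 pixels), centroid at the
#' mean of pixel centres, and the mean intensity of every channel.
#'
#' @param img a [phys_image] (markers as channels, 1 um pixels).
#' @param mask integer label matrix, same rows/cols as `img` (0 =
#'   background).
#' @param sample_id identifier copied into the table.
#' @return A tibble of class `cell_table` with columns `cell_id`,
#'   `sample_id`, `area_um2`, `x`, `y` and one column per channel.
#' @export
aggregate_cells <- function(img, mask, sample_id = "sample") {
  stopifnot(inherits(img, "phys_image"))
  d <- dim(img$values)
  stopifnot(all(dim(mask) == d[1:2]))
  labs <- sort(unique(as.vector(mask)))
  labs <- labs[labs > 0]
  px <- img$pixelsize_um
  if (length(labs) == 0) {
    out <- tibble::tibble(cell_id = integer(), sample_id = character(),
                          area_um2 = numeric(), x = numeric(), y = numeric())
    class(out) <- c("cell_table", class(out))
    return(out)
  }
  idx <- which(mask > 0)
  lab_at <- mask[idx]
  rows <- (idx - 1L) %% d[1] + 1L
  cols <- (idx - 1L) %/% d[1] + 1L
  f <- factor(lab_at, levels = labs)
  area <- as.vector(table(f)) * px^2
  cx <- tapply((cols - 0.5) * px, f, mean)
  cy <- tapply((rows - 0.5) * px, f, mean)
  out <- tibble::tibble(cell_id = as.integer(labs),
                        sample_id = sample_id,
                        area_um2 = as.numeric(area),
                        x = as.numeric(cx), y = as.numeric(cy))
  v <- img$values
  ch_names <- img$channels
  if (length(d) == 2L) {
    out$mean_intensity <- as.numeric(tapply(v[idx], f, mean))
  } else {
    if (is.null(ch_names)) ch_names <- paste0("ch", seq_len(d[3]))
    for (k in seq_len(d[3])) {
      vk <- v[, , k]
      out[[ch_names[k]]] <- as.numeric(tapply(vk[idx], f, mean))
    }
  }
  class(out) <- c("cell_table", class(out))
  out
}

#' Arcsinh-transform marker intensities of a cell table
#'
#' `intensity -> asinh(intensity / cofactor)`, the usual variance
#' stabilisation for mass cytometry counts.
#'
#' @param table a `cell_table` (from [aggregate_cells()]).
#' @param markers character vector of intensity columns to transform;
#'   defaults to every column that is not an identifier/geometry column.
#' @param cofactor arcsinh cofactor.
#' @return The table with transformed marker columns.
#' @export
arcsinh_transform <- function(table, markers = NULL, cofactor = 1) {
  stopifnot(cofactor > 0)
  reserved <- c("cell_id", "sample_id", "area_um2", "x", "y", "type_label")
  if (is.null(markers)) markers <- setdiff(names(table), reserved)
  for (m in markers) table[[m]] <- asinh(table[[m]] / cofactor)
  table
}

#' Filter cells by area, border contact and marker intensity
#'
#' Removes cells that (i) are smaller than `min_area_px` pixels,
#' (ii) touch the image border, (iii) have zero mean intensity for every
#' cell-type marker, or (iv) have any cell-type marker mean above that
#' marker's `median + 5 * MAD` across cells (MAD unscaled). DNA and
#' segmentation channels should not be listed in `type_markers` so they
#' are exempt from the intensity rules.
#'
#' @param table a `cell_table`.
#' @param mask the label matrix the table was built from.
#' @param type_markers character vector of cell-type marker columns.
#' @param min_area_px minimum area in pixels.
#' @param mad_factor multiplier on the unscaled MAD.
#' @return The filtered table, with an attribute `removal_counts`
#'   (named integer vector per rule; a cell can fail several rules).
#' @export
filter_cells <- function(table, mask, type_markers,
                         min_area_px = 10, mad_factor = 5) {
  stopifnot(all(type_markers %in% names(table)))
  px_area <- table$area_um2 / 1  # 1 um pixels by contract
  fail_area <- px_area < min_area_px

  border_labels <- unique(c(mask[1, ], mask[nrow(mask), ],
                            mask[, 1], mask[, ncol(mask)]))
  fail_border <- table$cell_id %in% border_labels[border_labels > 0]

  X <- as.matrix(table[, type_markers, drop = FALSE])
  fail_zero <- rowSums(X != 0) == 0

  med <- apply(X, 2, stats::median)
  mad_raw <- apply(X, 2, function(v) stats::median(abs(v - stats::median(v))))
  hi <- sweep(X, 2, med + mad_factor * mad_raw, ">")
  fail_mad <- rowSums(hi) > 0

  keep <- !(fail_area | fail_border | fail_zero | fail_mad)
  out <- table[keep, , drop = FALSE]
  attr(out, "removal_counts") <- c(
    area = sum(fail_area), border = sum(fail_border),
    all_zero = sum(fail_zero), mad_outlier = sum(fail_mad)
  )
  out
}
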