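# Cell-to-MSI-pixel integration: label masks are traced into exact
# pixel-boundary polygons, mapped through the transform chain, and
# intersected with the MSI pixel squares (Sutherland-Hodgman clipping
# against axis-aligned rectangles + shoelace areas, which is exact for
# this geometry).

shoelace_area <- function(ring) {
  # signed area; our tracing orientation gives outer rings > 0, holes < 0
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

# trace the boundary rings of one label in a mask; vertices in
# pixel-corner units (to be scaled by the pixel size)
trace_label_rings <- function(mask, label) {
  inside <- mask == label
  nr <- nrow(inside); nc <- ncol(inside)
  idx <- which(inside)
  if (!length(idx)) return(list())
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  at <- function(r, c) r >= 1 & r <= nr & c >= 1 & c <= nc & inside[cbind(pmax(pmin(r, nr), 1), pmax(pmin(c, nc), 1))]
  # directed boundary edges; vertex key = col_corner * (nr + 1) + row_corner
  # corner (ci, ri) sits at x = ci * px, y = ri * px with ci in 0..nc, ri in 0..nr
  starts <- integer(0); ends <- integer(0); dirs <- integer(0) # dir: 1=+x,2=+y,3=-x,4=-y
  key <- function(ci, ri) ci * (nr + 1L) + ri
  top <- !at(rows - 1L, cols)
  bot <- !at(rows + 1L, cols)
  lef <- !at(rows, cols - 1L)
  rig <- !at(rows, cols + 1L)
  # top edge: (c-1, r-1) -> (c, r-1), dir +x
  starts <- c(starts, key(cols[top] - 1L, rows[top] - 1L))
  ends <- c(ends, key(cols[top], rows[top] - 1L))
  dirs <- c(dirs, rep(1L, sum(top)))
  # right edge: (c, r-1) -> (c, r), dir +y
  starts <- c(starts, key(cols[rig], rows[rig] - 1L))
  ends <- c(ends, key(cols[rig], rows[rig]))
  dirs <- c(dirs, rep(2L, sum(rig)))
  # bottom edge: (c, r) -> (c-1, r), dir -x
  starts <- c(starts, key(cols[bot], rows[bot]))
  ends <- c(ends, key(cols[bot] - 1L, rows[bot]))
  dirs <- c(dirs, rep(3L, sum(bot)))
  # left edge: (c-1, r) -> (c-1, r-1), dir -y
  starts <- c(starts, key(cols[lef] - 1L, rows[lef]))
  ends <- c(ends, key(cols[lef] - 1L, rows[lef] - 1L))
  dirs <- c(dirs, rep(4L, sum(lef)))

  n_e <- length(starts)
  used <- logical(n_e)
  by_start <- split(seq_len(n_e), starts)
  dir_ang <- c(0, 90, 180, 270)
  rings <- list()
  for (e0 in seq_len(n_e)) {
    if (used[e0]) next
    ring_keys <- integer(0)
    e <- e0
    repeat {
      used[e] <- TRUE
      ring_keys <- c(ring_keys, starts[e])
      nxt_cands <- by_start[[as.character(ends[e])]]
      nxt_cands <- nxt_cands[!used[nxt_cands]]
      if (!length(nxt_cands)) break
      if (length(nxt_cands) > 1) {
        # ambiguous (checkerboard) corner: take the smallest absolute turn
        rel <- (dir_ang[dirs[nxt_cands]] - dir_ang[dirs[e]] + 180) %% 360 - 180
        nxt_cands <- nxt_cands[order(abs(rel))]
      }
      e <- nxt_cands[1]
    }
    ci <- ring_keys %/% (nr + 1L); ri <- ring_keys %% (nr + 1L)
    rings[[length(rings) + 1]] <- cbind(ci, ri)
  }
  rings
}

#' Trace cells into polygons and map them into a target frame
#'
#' Each labelled cell is traced along its pixel boundaries (holes
#' preserved as oppositely oriented rings) and the vertices are mapped
#' pointwise through the transform chain -- exact for points, so areas
#' are exactly preserved under rigid chains and scale with the
#' determinant under affine chains. Cells that degenerate to (near)
#' zero area after transformation are dropped.
#'
#' @param mask integer label matrix (0 background), pixels of size
#'   `pixelsize_um`.
#' @param chain transform or chain mapping the mask frame (um) to the
#'   target (MSI) frame; `NULL` keeps coordinates.
#' @param pixelsize_um mask pixel size.
#' @return A tibble of class `cell_polygons`: `cell_id`, `area_um2`,
#'   list-column `rings` (matrices of x, y vertices in the target
#'   frame).
#' @export
cells_to_polygons <- function(mask, chain = NULL, pixelsize_um = 1) {
  labs <- sort(unique(as.vector(mask))); labs <- labs[labs > 0]
  if (length(labs) == 0) {
    out <- tibble::tibble(cell_id = numeric(), area_um2 = numeric(),
                          rings = list())
    class(out) <- c("cell_polygons", class(out))
    return(out)
  }
  out <- purrr::map_dfr(labs, function(l) {
    rings <- trace_label_rings(mask, l)
    rings <- lapply(rings, function(r) {
      xy <- cbind(x = r[, 1] * pixelsize_um, y = r[, 2] * pixelsize_um)
      if (!is.null(chain)) xy <- transform_points(chain, xy)
      xy
    })
    a <- sum(vapply(rings, shoelace_area, 0))
    tibble::tibble(cell_id = l, area_um2 = abs(a), rings = list(rings))
  })
  dropped <- out$area_um2 < 1e-9
  if (any(dropped)) {
    message(sum(dropped), " cell(s) degenerate after transform; dropped")
    out <- out[!dropped, , drop = FALSE]
  }
  class(out) <- c("cell_polygons", class(out))
  out
}

#' MSI pixel footprint polygons
#'
#' Squares of side `pixelsize_um` centred on grid positions spaced
#' `stepsize_um` apart (the ablation spot can be smaller than the
#' pitch, leaving gaps).
#'
#' @param col,row measured grid indices.
#' @param stepsize_um grid pitch.
#' @param pixelsize_um ablation spot side; must not exceed the pitch.
#' @return A tibble of class `pixel_polygons`: `pixel_id`, `col`,
#'   `row`, centre `x`, `y` and bounds `xmin`, `xmax`, `ymin`, `ymax`.
#' @export
pixel_polygons <- function(col, row, stepsize_um, pixelsize_um = stepsize_um) {
  if (pixelsize_um > stepsize_um) stop("pixelsize must not exceed stepsize")
  g <- msi_grid_centers(col, row, stepsize_um)
  h <- pixelsize_um / 2
  out <- tibble::tibble(pixel_id = seq_len(nrow(g)), col = g$col, row = g$row,
                        x = g$x, y = g$y,
                        xmin = g$x - h, xmax = g$x + h,
                        ymin = g$y - h, ymax = g$y + h)
  attr(out, "pixel_area_um2") <- pixelsize_um^2
  attr(out, "stepsize_um") <- stepsize_um
  attr(out, "pixelsize_um") <- pixelsize_um
  class(out) <- c("pixel_polygons", class(out))
  out
}

# Sutherland-Hodgman clip of a (possibly non-convex) ring against an
# axis-aligned rectangle; exact areas via the signed shoelace sum
clip_ring_rect <- function(ring, xmin, xmax, ymin, ymax) {
  clip_halfplane <- function(pts, inside, intersect) {
    n <- nrow(pts)
    if (n == 0) return(pts)
    out <- matrix(0, 0, 2)
    ins <- inside(pts)
    for (i in seq_len(n)) {
      j <- i %% n + 1
      if (ins[i]) {
        out <- rbind(out, pts[i, ])
        if (!ins[j]) out <- rbind(out, intersect(pts[i, ], pts[j, ]))
      } else if (ins[j]) {
        out <- rbind(out, intersect(pts[i, ], pts[j, ]))
      }
    }
    out
  }
  ix <- function(p, q, at, coord) {
    t <- (at - p[coord]) / (q[coord] - p[coord])
    p + t * (q - p)
  }
  r <- ring
  r <- clip_halfplane(r, function(p) p[, 1] >= xmin, function(p, q) ix(p, q, xmin, 1))
  r <- clip_halfplane(r, function(p) p[, 1] <= xmax, function(p, q) ix(p, q, xmax, 1))
  r <- clip_halfplane(r, function(p) p[, 2] >= ymin, function(p, q) ix(p, q, ymin, 2))
  r <- clip_halfplane(r, function(p) p[, 2] <= ymax, function(p, q) ix(p, q, ymax, 2))
  r
}

#' Exact cell x MSI-pixel intersection areas
#'
#' Every cell polygon is clipped against every candidate pixel square
#' (bounding boxes prune the candidates); zero-area pairs are omitted.
#'
#' @param cells a `cell_polygons` tibble.
#' @param pixels a `pixel_polygons` tibble.
#' @return A tibble of class `overlap_table` with columns `pixel_id`,
#'   `cell_id`, `area_um2`; pixel geometry travels in attributes.
#' @export
intersect_cells_pixels <- function(cells, pixels) {
  res_pix <- integer(0); res_cell <- numeric(0); res_area <- numeric(0)
  for (i in seq_len(nrow(cells))) {
    rings <- cells$rings[[i]]
    bb <- sapply(rings, function(r) c(min(r[, 1]), max(r[, 1]), min(r[, 2]), max(r[, 2])))
    xmin <- min(bb[1, ]); xmax <- max(bb[2, ])
    ymin <- min(bb[3, ]); ymax <- max(bb[4, ])
    cand <- which(pixels$xmax > xmin & pixels$xmin < xmax &
                    pixels$ymax > ymin & pixels$ymin < ymax)
    for (j in cand) {
      a <- sum(vapply(rings, function(r) {
        cl <- clip_ring_rect(r, pixels$xmin[j], pixels$xmax[j],
                             pixels$ymin[j], pixels$ymax[j])
        if (nrow(cl) < 3) 0 else shoelace_area(cl)
      }, 0))
      a <- abs(a)
      if (a > 1e-9) {
        res_pix <- c(res_pix, pixels$pixel_id[j])
        res_cell <- c(res_cell, cells$cell_id[i])
        res_area <- c(res_area, a)
      }
    }
  }
  out <- tibble::tibble(pixel_id = res_pix, cell_id = res_cell,
                        area_um2 = res_area)
  attr(out, "pixel_area_um2") <- attr(pixels, "pixel_area_um2")
  attr(out, "n_pixels") <- nrow(pixels)
  class(out) <- c("overlap_table", class(out))
  out
}

#' Per-pixel cell-type design matrix from overlaps
#'
#' Builds the covariate block of the pixel-level association model: per
#' MSI pixel the area fraction of each cell type (intersection area over
#' pixel area), plus the cell count and the total filled fraction.
#' Unlabelled cells contribute to `fill_frac` but to no type column; the
#' model intercept absorbs the uncovered pixel area.
#'
#' @param overlaps an `overlap_table`.
#' @param pixels the `pixel_polygons` the overlaps were computed on.
#' @param cell_types data frame with `cell_id`, `type_label`
#'   (`NA` = unlabelled); `NULL` for a single unnamed type.
#' @return A tibble keyed by `pixel_id`, `col`, `row` with one fraction
#'   column per type plus `n_cells` and `fill_frac`.
#' @export
pixel_design <- function(overlaps, pixels, cell_types = NULL) {
  pa <- attr(overlaps, "pixel_area_um2")
  df <- overlaps
  if (!is.null(cell_types)) {
    df <- dplyr::left_join(df, cell_types, by = "cell_id")
  } else {
    df$type_label <- "cell"
  }
  base <- tibble::tibble(pixel_id = pixels$pixel_id, col = pixels$col,
                         row = pixels$row)
  agg <- df |>
    dplyr::group_by(.data$pixel_id) |>
    dplyr::summarise(n_cells = dplyr::n_distinct(.data$cell_id),
                     fill_frac = sum(.data$area_um2) / pa, .groups = "drop")
  typed <- df |>
    dplyr::filter(!is.na(.data$type_label)) |>
    dplyr::group_by(.data$pixel_id, .data$type_label) |>
    dplyr::summarise(frac = sum(.data$area_um2) / pa, .groups = "drop") |>
    tidyr::pivot_wider(names_from = "type_label", values_from = "frac",
                       values_fill = 0)
  out <- base |>
    dplyr::left_join(agg, by = "pixel_id") |>
    dplyr::left_join(typed, by = "pixel_id")
  out$n_cells[is.na(out$n_cells)] <- 0L
  out$fill_frac[is.na(out$fill_frac)] <- 0
  for (cn in setdiff(names(out), c("pixel_id", "col", "row", "n_cells", "fill_frac"))) {
    out[[cn]][is.na(out[[cn]])] <- 0
  }
  out
}

#' Overlap distribution summaries
#'
#' The three standard summaries of a cell/pixel overlap table: how many
#' pixels a cell overlaps, how many cells an MSI pixel overlaps, and the
#' fraction of each pixel's area filled by cells.
#'
#' @param table an `overlap_table`.
#' @return List with tibbles `pixels_per_cell`, `cells_per_pixel`,
#'   `fill_fraction`, and their means (`mean_pixels_per_cell`,
#'   `mean_cells_per_pixel`, `mean_fill_fraction`). Pixels without any
#'   cell count as zero cells and zero fill.
#' @export
overlap_summaries <- function(table) {
  pa <- attr(table, "pixel_area_um2")
  n_pixels <- attr(table, "n_pixels")
  if (nrow(table) == 0) {
    return(list(
      pixels_per_cell = tibble::tibble(n = integer(), count = integer()),
      cells_per_pixel = tibble::tibble(n = integer(), count = integer()),
      fill_fraction = numeric(),
      mean_pixels_per_cell = 0, mean_cells_per_pixel = 0,
      mean_fill_fraction = 0))
  }
  ppc <- table |>
    dplyr::count(.data$cell_id, name = "n_pixels") |>
    dplyr::count(.data$n_pixels, name = "count") |>
    dplyr::rename(n = "n_pixels")
  cpp_vec <- table |>
    dplyr::count(.data$pixel_id, name = "n_cells")
  n_empty <- max(0, (n_pixels %||% max(table$pixel_id)) - nrow(cpp_vec))
  cpp_all <- c(cpp_vec$n_cells, rep(0L, n_empty))
  cpp <- tibble::tibble(n = as.integer(names(table(cpp_all))),
                        count = as.integer(table(cpp_all)))
  fill_vec <- table |>
    dplyr::group_by(.data$pixel_id) |>
    dplyr::summarise(fill = sum(.data$area_um2) / pa, .groups = "drop")
  fills <- c(fill_vec$fill, rep(0, n_empty))
  list(pixels_per_cell = ppc,
       cells_per_pixel = cpp,
       fill_fraction = fills,
       mean_pixels_per_cell = mean(rep(ppc$n, ppc$count)),
       mean_cells_per_pixel = mean(cpp_all),
       mean_fill_fraction = mean(fills))
}

#' @importFrom rlang %||% .data
NULL
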