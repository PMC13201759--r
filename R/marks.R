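#' Detection parameters for ablation-mark finding
#'
#' @param w blend weight of the processed image against the raw
#'   grayscale, in `[0, 1]`.
#' @param t detection threshold on the blended score image.
#' @param median_radius_px radius of the square median kernel.
#' @param disk_radius_px radius of the disk used by the rank-threshold
#'   (background-removal) filter; should be about the mark radius in
#'   image pixels.
#' @param cross_radius_px radius of the cross-shaped mean kernel.
#' @param rank_frac which order statistic the rank-threshold filter
#'   subtracts (fraction of the window size; 0 = local minimum).
#' @param area_bounds_um2 admissible component area range.
#' @param ecc_max maximum component eccentricity.
#' @param angle_tol_deg tolerance of neighbour angles around the two
#'   grid axes.
#' @param min_subgraph minimum connected-subgraph size a centroid must
#'   belong to.
#' @param marks_darker are marks darker than the background (brightfield
#'   ablation)? Set `FALSE` to invert polarity.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(w = 0.5, t = 0.1,
                             median_radius_px = 1, disk_radius_px = 3,
                             cross_radius_px = 1, rank_frac = 0.1,
                             area_bounds_um2 = c(4, 400), ecc_max = 0.9,
                             angle_tol_deg = 20, min_subgraph = 4,
                             marks_darker = TRUE) {
  stopifnot(w >= 0, w <= 1, is.finite(t))
  structure(list(w = w, t = t, median_radius_px = median_radius_px,
                 disk_radius_px = disk_radius_px, cross_radius_px = cross_radius_px,
                 rank_frac = rank_frac, area_bounds_um2 = area_bounds_um2,
                 ecc_max = ecc_max, angle_tol_deg = angle_tol_deg,
                 min_subgraph = min_subgraph, marks_darker = marks_darker),
            class = "detection_params")
}

#' Enhance ablation marks in a grayscale microscopy image
#'
#' Works on the mark-polarity image (darkness for brightfield). The
#' processed branch chains a square-kernel median filter, a disk-kernel
#' rank-threshold filter (pixel value minus the k-th local rank,
#' clamped at zero -- a rank-robust top-hat that removes slowly varying
#' background) and a cross-kernel mean filter. The result is blended
#' pixelwise with the raw polarity image: `w * processed + (1 - w) * raw`.
#'
#' @param gray single-channel [phys_image].
#' @param params a [detection_params].
#' @return A [phys_image] score image of the same geometry.
#' @export
enhance_marks <- function(gray, params = detection_params()) {
  stopifnot(inherits(gray, "phys_image"), length(dim(gray$values)) == 2L)
  m <- gray$values
  if (max(c(params$median_radius_px, params$disk_radius_px,
            params$cross_radius_px)) * 2 + 1 > min(dim(m))) {
    stop("kernel larger than image")
  }
  if (params$marks_darker) m <- max(m) - m
  med <- local_median_filter(m, kernel_offsets("square", params$median_radius_px))
  off_d <- kernel_offsets("disk", params$disk_radius_px)
  k <- max(1L, ceiling(params$rank_frac * nrow(off_d)))
  rk <- pmax(med - local_kth_filter(med, off_d, k), 0)
  proc <- local_mean_filter(rk, kernel_offsets("cross", params$cross_radius_px))
  out <- params$w * proc + (1 - params$w) * m
  phys_image(out, gray$pixelsize_um, gray$frame)
}

# connected components of a binary matrix (EBImage::bwlabel)
label_components <- function(bin) {
  EBImage::bwlabel(EBImage::Image(bin * 1))
}

# principal grid axis (degrees in [0, 90)) from candidate edge angles,
# via circular mean on 4*theta (axes have period 90 degrees)
estimate_grid_axis <- function(angles_deg) {
  a4 <- angles_deg * 4 * pi / 180
  (atan2(mean(sin(a4)), mean(cos(a4))) * 180 / pi / 4) %% 90
}

#' Detect ablation-mark candidates on a score image
#'
#' Thresholds the score image, measures connected components, filters
#' them by area and eccentricity, and keeps only centroids participating
#' in a regular-grid neighbour subgraph: edges link centroids whose
#' distance is within `[0.5, 1.5] * stepsize` and whose direction lies
#' within the angular tolerance of either estimated grid axis;
#' components of that graph smaller than `min_subgraph` are dropped.
#' Centroids are score-weighted, giving sub-pixel positions.
#'
#' @param score_img score [phys_image] from [enhance_marks()].
#' @param params a [detection_params].
#' @param stepsize_um expected grid pitch.
#' @return A tibble of class `mark_candidates`: `id`, `x`, `y` (um),
#'   `area_um2`, `eccentricity`, plus the neighbour graph in attribute
#'   `graph` (igraph) and `stepsize_um`.
#' @export
detect_marks <- function(score_img, params, stepsize_um) {
  stopifnot(inherits(score_img, "phys_image"))
  px <- score_img$pixelsize_um
  bin <- score_img$values > params$t
  empty <- tibble::tibble(id = integer(), x = numeric(), y = numeric(),
                          area_um2 = numeric(), eccentricity = numeric())
  class(empty) <- c("mark_candidates", class(empty))
  attr(empty, "stepsize_um") <- stepsize_um
  if (!any(bin)) return(empty)
  lab <- label_components(bin)
  labv <- as.integer(lab@.Data)
  idx <- which(labv > 0)
  if (!length(idx)) return(empty)
  d <- dim(score_img$values)
  rows <- (idx - 1L) %% d[1] + 1L
  cols <- (idx - 1L) %/% d[1] + 1L
  wgt <- score_img$values[idx]
  f <- factor(labv[idx])
  xs <- (cols - 0.5) * px; ys <- (rows - 0.5) * px
  sw <- tapply(wgt, f, sum)
  cx <- tapply(wgt * xs, f, sum) / sw
  cy <- tapply(wgt * ys, f, sum) / sw
  area <- as.vector(table(f)) * px^2
  # eccentricity from weighted second moments
  ecc <- vapply(levels(f), function(l) {
    sel <- f == l
    if (sum(sel) < 2) return(0)
    X <- cbind(xs[sel], ys[sel])
    C <- stats::cov.wt(X, wt = wgt[sel], method = "ML")$cov
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    if (ev[1] <= 0) return(0)
    sqrt(max(0, 1 - ev[2] / ev[1]))
  }, 0)
  cand <- tibble::tibble(id = seq_along(cx), x = as.numeric(cx), y = as.numeric(cy),
                         area_um2 = as.numeric(area), eccentricity = as.numeric(ecc))
  cand <- cand[cand$area_um2 >= params$area_bounds_um2[1] &
               cand$area_um2 <= params$area_bounds_um2[2] &
               cand$eccentricity <= params$ecc_max, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  # neighbour graph on the grid structure
  P <- cbind(cand$x, cand$y)
  dm <- as.matrix(stats::dist(P))
  lo <- 0.5 * stepsize_um; hi <- 1.5 * stepsize_um
  pairs <- which(dm > lo & dm < hi, arr.ind = TRUE)
  pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
  if (nrow(pairs) > 0) {
    ang <- atan2(P[pairs[, 2], 2] - P[pairs[, 1], 2],
                 P[pairs[, 2], 1] - P[pairs[, 1], 1]) * 180 / pi
    axis0 <- estimate_grid_axis(ang)
    dev <- abs(((ang - axis0) %% 90 + 45) %% 90 - 45)
    pairs <- pairs[dev <= params$angle_tol_deg, , drop = FALSE]
  }
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(cand) - igraph::vcount(g)))
  comp <- igraph::components(g)
  keep <- comp$csize[comp$membership] >= params$min_subgraph
  cand <- cand[keep, , drop = FALSE]
  cand$id <- seq_len(nrow(cand))
  g <- igraph::induced_subgraph(g, which(keep))
  class(cand) <- c("mark_candidates", class(cand))
  attr(cand, "graph") <- g
  attr(cand, "stepsize_um") <- stepsize_um
  cand
}

# minimum distance from points to the boundary of a binary mask (um)
dist_to_mask_edge <- function(points_xy, mask_img) {
  stopifnot(inherits(mask_img, "phys_image"))
  m <- mask_img$values > 0
  dm_in <- EBImage::distmap(EBImage::Image(m * 1))@.Data
  dm_out <- EBImage::distmap(EBImage::Image((!m) * 1))@.Data
  edge_dist <- pmax(dm_in, dm_out) # one of the two is 0 off/on the mask
  fin <- is.finite(edge_dist)
  if (!all(fin)) {
    edge_dist[!fin] <- if (any(fin)) max(edge_dist[fin]) else 0
  }
  rc <- phys_to_index(mask_img, as_xy_matrix(points_xy))
  bilinear_sample(edge_dist, rc, fill = 0) * mask_img$pixelsize_um
}

#' Grid-search detection parameters
#'
#' Runs [detect_marks()] over a `(w, t)` grid and scores each setting
#' with `n_hat + 4 * e_hat + 2 * d_hat` where, each min-max normalized
#' over the grid, `n` is the number of detected points, `e` the number
#' of points near the tissue edge, and `d` the mean distance of points
#' to the tissue edge. Ties break towards the lexicographically smallest
#' `(w, t)`, making the search deterministic.
#'
#' @param gray single-channel [phys_image].
#' @param tissue_mask binary [phys_image] of the tissue (same frame).
#' @param w_grid,t_grid candidate blend weights / thresholds; `t_grid`
#'   defaults to deciles of the enhanced image.
#' @param params base [detection_params] (its `w` and `t` are swept).
#' @param stepsize_um expected grid pitch.
#' @param edge_band_um how close to the tissue edge a point must be to
#'   count as an edge point.
#' @return List with `params` (winning [detection_params]), `marks`
#'   (its [detect_marks()] result) and `grid` (a tibble of scores).
#' @export
optimize_detection <- function(gray, tissue_mask, w_grid = seq(0, 1, 0.25),
                               t_grid = NULL, params = detection_params(),
                               stepsize_um, edge_band_um = 1.5 * stepsize_um) {
  stopifnot(length(w_grid) >= 1)
  results <- list()
  stats <- NULL
  for (w in sort(w_grid)) {
    p <- params; p$w <- w
    enh <- enhance_marks(gray, p)
    tg <- if (is.null(t_grid)) {
      stats::quantile(enh$values, probs = seq(0.1, 0.9, 0.1), names = FALSE)
    } else t_grid
    for (t in sort(tg)) {
      p$t <- t
      mk <- detect_marks(enh, p, stepsize_um)
      de <- if (nrow(mk) > 0) dist_to_mask_edge(cbind(mk$x, mk$y), tissue_mask) else numeric()
      stats <- rbind(stats, data.frame(
        w = w, t = t, n = nrow(mk),
        n_edge = sum(de <= edge_band_um),
        mean_edge_dist = if (length(de)) mean(de) else 0))
      results[[length(results) + 1]] <- list(params = p, marks = mk)
    }
  }
  if (all(stats$n == 0)) stop("all grid points yield zero detections")
  mm <- function(v) {
    v[!is.finite(v)] <- 0
    if (diff(range(v)) == 0) rep(0, length(v)) else (v - min(v)) / diff(range(v))
  }
  score <- mm(stats$n) + 4 * mm(stats$n_edge) + 2 * mm(stats$mean_edge_dist)
  best <- order(-score, stats$w, stats$t)[1]
  list(params = results[[best]]$params, marks = results[[best]]$marks,
       grid = tibble::as_tibble(cbind(stats, score = score)))
}

mask_centroid <- function(mask_img) {
  idx <- which(mask_img$values > 0)
  d <- dim(mask_img$values)
  rows <- (idx - 1L) %% d[1] + 1L
  cols <- (idx - 1L) %/% d[1] + 1L
  px <- mask_img$pixelsize_um
  c(mean((cols - 0.5) * px), mean((rows - 0.5) * px))
}

#' Pair MSI acquisition regions with tissue cores
#'
#' Each MSI region mask (rendered from the acquisition grid) is matched
#' greedily to the tissue core whose mask it best explains after a
#' coarse affine alignment (centroid translation plus isotropic scaling
#' by the area ratio); the figure of merit is the correlation of the
#' aligned binary masks. Pairs below the correlation floor stay
#' unmatched.
#'
#' @param msi_region_masks list of binary [phys_image]s (MSI regions).
#' @param core_masks list of binary [phys_image]s (tissue cores), all in
#'   one common frame.
#' @param cor_floor minimum mask correlation to accept a pair.
#' @return A tibble with columns `region`, `core`, `correlation`,
#'   `matched` and a list-column `transform` (coarse affine mapping the
#'   region frame onto the core frame).
#' @export
match_msi_regions_to_cores <- function(msi_region_masks, core_masks,
                                       cor_floor = 0.3) {
  stopifnot(length(msi_region_masks) >= 1, length(core_masks) >= 1)
  nr <- length(msi_region_masks); nc <- length(core_masks)
  corr <- matrix(-Inf, nr, nc)
  score <- matrix(-Inf, nr, nc)
  tfs <- vector("list", nr * nc); dim(tfs) <- c(nr, nc)
  for (i in seq_len(nr)) {
    ri <- msi_region_masks[[i]]
    c_r <- mask_centroid(ri)
    a_r <- sum(ri$values > 0) * ri$pixelsize_um^2
    for (j in seq_len(nc)) {
      cj <- core_masks[[j]]
      c_c <- mask_centroid(cj)
      a_c <- sum(cj$values > 0) * cj$pixelsize_um^2
      s <- sqrt(a_c / a_r)
      tf <- affine_transform(diag(2) * s, c_c - s * c_r,
                             source = ri$frame, target = cj$frame)
      moved <- transform_image(tf, ri, out_dim = dim(cj$values)[1:2],
                               out_pixelsize_um = cj$pixelsize_um,
                               interp = "nearest")
      a <- as.vector(moved$values > 0) * 1
      b <- as.vector(cj$values > 0) * 1
      corr[i, j] <- if (stats::sd(a) == 0 || stats::sd(b) == 0) 0 else stats::cor(a, b)
      # the coarse affine absorbs scale, so the greedy score also has to
      # reward similar physical areas or same-shape pairs tie
      score[i, j] <- corr[i, j] * min(a_r, a_c) / max(a_r, a_c)
      tfs[[i, j]] <- tf
    }
  }
  out <- tibble::tibble(region = integer(), core = integer(),
                        correlation = numeric(), matched = logical(),
                        transform = list())
  cmat <- score
  repeat {
    best <- which.max(cmat)
    if (!length(best) || !is.finite(cmat[best]) || cmat[best] == -Inf) break
    ij <- arrayInd(best, dim(cmat))
    i <- ij[1]; j <- ij[2]
    out <- dplyr::bind_rows(out, tibble::tibble(
      region = i, core = j, correlation = corr[i, j],
      matched = corr[i, j] >= cor_floor, transform = list(tfs[[i, j]])))
    cmat[i, ] <- -Inf; cmat[, j] <- -Inf
    if (nrow(out) >= min(nr, nc)) break
  }
  # unmatched leftovers
  for (i in setdiff(seq_len(nr), out$region)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      region = i, core = NA_integer_, correlation = NA_real_,
      matched = FALSE, transform = list(NULL)))
  }
  out
}
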