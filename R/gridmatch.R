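# Registering the MSI pixel grid to detected ablation marks: coarse
# rigid search, concave-hull boundary identifiers, identifier matching,
# CPD refinement and the final pixel<->mark assignment.

#' Physical centres of MSI grid positions
#'
#' @param col,row integer grid indices.
#' @param stepsize_um grid pitch.
#' @return A tibble `col`, `row`, `x`, `y` in the `"MSI"` frame.
#' @export
msi_grid_centers <- function(col, row, stepsize_um) {
  tibble::tibble(col = as.integer(col), row = as.integer(row),
                 x = (col - 0.5) * stepsize_um,
                 y = (row - 0.5) * stepsize_um)
}

#' Binary mask of measured MSI grid positions
#'
#' One mask pixel per grid position (pixel size = stepsize).
#'
#' @inheritParams msi_grid_centers
#' @return A binary [phys_image] in the `"MSI"` frame.
#' @export
msi_grid_mask <- function(col, row, stepsize_um) {
  m <- matrix(0, max(row), max(col))
  m[cbind(row, col)] <- 1
  phys_image(m, stepsize_um, frame = "MSI")
}

# inverse-local-density weights from the k-NN distance (scaled to mean 1)
density_weights <- function(P, k = 4) {
  n <- nrow(P)
  if (n <= k) return(rep(1, n))
  dm <- as.matrix(stats::dist(P))
  diag(dm) <- Inf
  knn <- apply(dm, 1, function(v) sort(v)[k])
  w <- knn^2  # inverse density ~ knn distance squared in 2-d
  w / mean(w)
}

#' Coarse rigid search aligning ablation marks to the MSI grid
#'
#' Exhaustive search over x/y translation and rotation of a rigid map
#' from the marks (PostMSI) frame onto the MSI frame. Each candidate is
#' scored by the proportion of marks falling inside the MSI mask, plus
#' the min-max-normalized number of marks matched to a grid centre
#' (within half a pitch), minus the normalized mean density-weighted
#' distance of matched marks to their grid centre.
#'
#' @param marks a `mark_candidates` tibble (columns `x`, `y`).
#' @param msi_mask binary [phys_image] from [msi_grid_mask()].
#' @param stepsize_um grid pitch.
#' @param theta_grid_deg candidate rotations.
#' @param t_step_um translation grid step (defaults to half a pitch).
#' @param t_extra_um extra translation range searched around the
#'   centroid-aligning translation.
#' @return The best rigid `affine_transform` (marks frame -> `"MSI"`),
#'   with a `score` field and the searched grid in `$search`.
#' @export
coarse_transform_search <- function(marks, msi_mask, stepsize_um,
                                    theta_grid_deg = seq(-6, 6, by = 1.5),
                                    t_step_um = stepsize_um / 2,
                                    t_extra_um = 2 * stepsize_um) {
  stopifnot(nrow(marks) >= 1)
  P <- cbind(marks$x, marks$y)
  wts <- density_weights(P)
  grid_idx <- which(msi_mask$values > 0, arr.ind = TRUE)
  centers <- msi_grid_centers(grid_idx[, 2], grid_idx[, 1], stepsize_um)
  mark_ctr <- colMeans(P)
  msi_ctr <- c(mean(centers$x), mean(centers$y))
  t0 <- msi_ctr - mark_ctr
  offs <- seq(-t_extra_um, t_extra_um, by = t_step_um)
  res <- NULL
  for (th in theta_grid_deg) for (dx in offs) for (dy in offs) {
    tf <- rigid_transform(th, t0[1] + dx, t0[2] + dy, center = mark_ctr,
                          source = marks_frame(marks), target = "MSI")
    Q <- transform_points(tf, P)
    inm <- nn_sample(msi_mask$values, phys_to_index(msi_mask, Q), fill = 0) > 0
    gc_col <- round(Q[, 1] / stepsize_um + 0.5)
    gc_row <- round(Q[, 2] / stepsize_um + 0.5)
    gx <- (gc_col - 0.5) * stepsize_um; gy <- (gc_row - 0.5) * stepsize_um
    d <- sqrt((Q[, 1] - gx)^2 + (Q[, 2] - gy)^2)
    on_grid <- inm & d <= 0.5 * stepsize_um
    res <- rbind(res, data.frame(
      theta = th, tx = t0[1] + dx, ty = t0[2] + dy,
      p_in = mean(inm), n_match = sum(on_grid),
      wdist = if (any(on_grid)) stats::weighted.mean(d[on_grid], wts[on_grid]) else NA))
  }
  if (all(res$p_in == 0)) stop("no transform places any mark in the MSI mask")
  mm <- function(v) {
    v[is.na(v)] <- max(v, na.rm = TRUE)
    if (diff(range(v)) == 0) rep(0, length(v)) else (v - min(v)) / diff(range(v))
  }
  score <- res$p_in + mm(res$n_match) - mm(res$wdist)
  best <- order(-score, abs(res$theta), abs(res$tx), abs(res$ty))[1]
  tf <- rigid_transform(res$theta[best], res$tx[best], res$ty[best],
                        center = mark_ctr,
                        source = marks_frame(marks), target = "MSI")
  tf$score <- score[best]
  tf$search <- tibble::as_tibble(cbind(res, score = score))
  tf
}

marks_frame <- function(marks) {
  f <- attr(marks, "frame")
  if (is.null(f)) "PostMSI" else f
}

# grid-axis neighbours of each point: distance in [0.5, 1.5] * pitch and
# direction within angle_tol of either grid axis
grid_neighbors <- function(P, pitch, angle_tol = 20) {
  dm <- as.matrix(stats::dist(P))
  pairs <- which(dm > 0.5 * pitch & dm < 1.5 * pitch, arr.ind = TRUE)
  pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
  if (nrow(pairs) == 0) return(pairs)
  ang <- atan2(P[pairs[, 2], 2] - P[pairs[, 1], 2],
               P[pairs[, 2], 1] - P[pairs[, 1], 1]) * 180 / pi
  axis0 <- estimate_grid_axis(ang)
  dev <- abs(((ang - axis0) %% 90 + 45) %% 90 - 45)
  pairs[dev <= angle_tol, , drop = FALSE]
}

#' Concave hull of a regular point grid, with quantized turn angles
#'
#' Boundary points are those with fewer than four grid-axis neighbours.
#' The boundary is ordered by walking neighbour links around the
#' outline; the interior angle at each point (between the incoming and
#' outgoing boundary edges) is quantized to 45-degree steps in the grid
#' frame.
#'
#' @param points two-column matrix or data frame of grid point
#'   coordinates (um).
#' @param pitch grid pitch (um).
#' @param angle_tol neighbour-direction tolerance (degrees).
#' @param source label recorded on the result (`"marks"` or `"msi"`).
#' @return A tibble of class `boundary_sequence`: ordered columns
#'   `point_id`, `x`, `y`, `angle`; attribute `disconnected` flags a
#'   boundary that fell into several cycles (largest returned).
#' @export
build_concave_hull <- function(points, pitch, angle_tol = 20, source = "marks") {
  P <- as_xy_matrix(points)
  stopifnot(nrow(P) >= 4)
  # boundary = any point missing one of its 8 grid neighbours; this
  # includes the reflex corner of a notch (which keeps all 4 axis
  # neighbours but loses a diagonal one) so concave turns are traced
  dm_all <- as.matrix(stats::dist(P))
  deg8 <- rowSums(dm_all > 0.25 * pitch & dm_all < 1.6 * pitch)
  boundary <- which(deg8 < 8)
  if (length(boundary) < 3) stop("no usable boundary found")
  Pb <- P[boundary, , drop = FALSE]
  dmb <- as.matrix(stats::dist(Pb))
  adj <- dmb > 0.25 * pitch & dmb < 1.6 * pitch
  axis_step <- dmb > 0.25 * pitch & dmb < 1.3 * pitch
  nbr_list <- apply(adj, 1, which, simplify = FALSE)

  walk_cycle <- function(start, visited_edges) {
    # virtual previous point to the west of the start
    ang_to <- function(i, j) atan2(Pb[j, 2] - Pb[i, 2], Pb[j, 1] - Pb[i, 1])
    path <- integer()
    cur <- start
    prev_ang <- pi  # direction towards the virtual west predecessor
    repeat {
      path <- c(path, cur)
      cand <- nbr_list[[cur]]
      if (!length(cand)) break
      # prefer single-pitch (axis) steps; diagonals only bridge gaps
      ax <- cand[axis_step[cur, cand]]
      if (length(ax)) cand <- ax
      rel <- vapply(cand, function(q) {
        a <- (ang_to(cur, q) - prev_ang) %% (2 * pi)
        if (a < 1e-9) a <- 2 * pi
        a
      }, 0)
      nxt <- cand[order(rel)][1]
      edge <- paste(cur, nxt)
      if (edge %in% visited_edges) break
      visited_edges <- c(visited_edges, edge)
      prev_ang <- ang_to(nxt, cur)
      if (nxt == start) break
      cur <- nxt
    }
    path
  }
  start <- order(Pb[, 2], Pb[, 1])[1]  # topmost, then leftmost
  cycle <- walk_cycle(start, character())
  disconnected <- length(unique(cycle)) < length(boundary)
  if (disconnected) {
    # collect remaining cycles, keep the largest
    remaining <- setdiff(seq_len(nrow(Pb)), cycle)
    best <- cycle
    while (length(remaining) >= 3) {
      s <- remaining[order(Pb[remaining, 2], Pb[remaining, 1])[1]]
      cyc <- walk_cycle(s, character())
      if (length(unique(cyc)) > length(unique(best))) best <- cyc
      remaining <- setdiff(remaining, cyc)
    }
    cycle <- best
  }
  cycle <- cycle[!duplicated(cycle)]
  n <- length(cycle)
  if (n < 3) stop("degenerate boundary cycle")
  xy <- Pb[cycle, , drop = FALSE]
  # interior angle = 180 - signed turn, quantized to 45 degrees
  ang <- numeric(n)
  for (i in seq_len(n)) {
    p_prev <- xy[(i - 2) %% n + 1, ]
    p_cur <- xy[i, ]
    p_next <- xy[i %% n + 1, ]
    a_in <- atan2(p_cur[2] - p_prev[2], p_cur[1] - p_prev[1])
    a_out <- atan2(p_next[2] - p_cur[2], p_next[1] - p_cur[1])
    turn <- ((a_out - a_in) * 180 / pi + 180) %% 360 - 180
    interior <- 180 - turn
    ang[i] <- (round(interior / 45) * 45) %% 360
  }
  out <- tibble::tibble(point_id = boundary[cycle],
                        x = xy[, 1], y = xy[, 2], angle = ang)
  class(out) <- c("boundary_sequence", class(out))
  attr(out, "source") <- source
  attr(out, "disconnected") <- disconnected
  out
}

#' Angle-window identifiers along a boundary
#'
#' The identifier of a boundary point is the comma-joined sequence of
#' quantized angles in a circular window around it: `k_cw` points
#' clockwise (preceding in walk order), the point itself, and `k_acw`
#' points anticlockwise.
#'
#' @param seq a `boundary_sequence`.
#' @param k_cw,k_acw window extent on each side.
#' @return Character vector of identifiers, one per boundary point.
#' @export
boundary_identifiers <- function(seq, k_cw = 2, k_acw = 2) {
  stopifnot(inherits(seq, "boundary_sequence"), k_cw >= 0, k_acw >= 0)
  n <- nrow(seq)
  if (k_cw + 1 + k_acw > n) stop("identifier window longer than boundary")
  vapply(seq_len(n), function(i) {
    idx <- ((i - k_cw - 1):(i + k_acw - 1)) %% n + 1
    paste(seq$angle[idx], collapse = ",")
  }, "")
}

#' Match boundary points between marks and MSI grid by identifier
#'
#' For each candidate window half-width the identifiers of both
#' boundaries are compared; only pairs whose identifiers are unique on
#' both sides and whose physical distance after the initial transform is
#' below `max_dist` survive. The half-width maximizing first the number
#' of matches, then the covered fraction of the boundary, wins.
#'
#' @param seq_marks,seq_msi `boundary_sequence`s of the detected marks
#'   and of the MSI grid.
#' @param init initial transform (marks frame -> MSI frame).
#' @param max_dist physical gate after `init` (um).
#' @param k_range candidate window half-widths.
#' @return A tibble of matched pairs: mark and MSI coordinates, the
#'   selected window half-width in attribute `k`, coverage in attribute
#'   `coverage`.
#' @export
match_identifiers <- function(seq_marks, seq_msi, init, max_dist,
                              k_range = 1:7) {
  best <- NULL; best_key <- c(-1, -1); best_k <- NA
  marks_in_msi <- transform_points(init, cbind(seq_marks$x, seq_marks$y))
  for (k in k_range) {
    if (k + 1 + k > min(nrow(seq_marks), nrow(seq_msi))) next
    id_a <- boundary_identifiers(seq_marks, k, k)
    id_b <- boundary_identifiers(seq_msi, k, k)
    # candidate pairs: equal identifiers within the physical gate; the
    # distance filter comes first, so uniqueness is local, not global
    ia <- integer(0); ib <- integer(0); dd <- numeric(0)
    for (i in seq_along(id_a)) {
      js <- which(id_b == id_a[i])
      if (!length(js)) next
      d <- sqrt((marks_in_msi[i, 1] - seq_msi$x[js])^2 +
                  (marks_in_msi[i, 2] - seq_msi$y[js])^2)
      ok <- d <= max_dist
      ia <- c(ia, rep(i, sum(ok))); ib <- c(ib, js[ok]); dd <- c(dd, d[ok])
    }
    if (!length(ia)) next
    uniq <- !(ia %in% ia[duplicated(ia)]) & !(ib %in% ib[duplicated(ib)])
    if (!any(uniq)) next
    ia <- ia[uniq]; ib <- ib[uniq]; dd <- dd[uniq]
    cov <- mean(c(length(ia) / nrow(seq_marks), length(ib) / nrow(seq_msi)))
    key <- c(length(ia), cov)
    if (key[1] > best_key[1] || (key[1] == best_key[1] && key[2] > best_key[2])) {
      best_key <- key; best_k <- k
      best <- tibble::tibble(
        mark_x = seq_marks$x[ia], mark_y = seq_marks$y[ia],
        msi_x = seq_msi$x[ib], msi_y = seq_msi$y[ib],
        identifier = id_a[ia], dist_after_init = dd)
    }
  }
  if (is.null(best)) stop("boundary matching failed: zero matches at all identifier lengths")
  attr(best, "k") <- best_k
  attr(best, "coverage") <- best_key[2]
  best
}

#' Final MSI pixel to ablation mark assignment
#'
#' Transforms every MSI grid centre into the marks frame and pairs grid
#' centres and mark centroids by mutual nearest neighbours within half a
#' pitch. Residual distances feed the registration QC.
#'
#' @param marks `mark_candidates` (or any tibble with `x`, `y`).
#' @param msi_grid tibble from [msi_grid_centers()].
#' @param transform transform mapping the `"MSI"` frame to the marks
#'   frame.
#' @param stepsize_um grid pitch.
#' @return A tibble of class `grid_assignment`: `col`, `row`, `mark_id`
#'   (`NA` when unassigned), `residual_um`; attribute `low_assignment`
#'   is set when under half the pixels found a mark.
#' @export
assign_pixels <- function(marks, msi_grid, transform, stepsize_um) {
  G <- transform_points(transform, cbind(msi_grid$x, msi_grid$y))
  P <- cbind(marks$x, marks$y)
  n <- nrow(G); m <- nrow(P)
  # cross-distances
  d2 <- outer(rowSums(G^2), rep(1, m)) + outer(rep(1, n), rowSums(P^2)) -
    2 * G %*% t(P)
  d2[d2 < 0] <- 0
  nn_g <- apply(d2, 1, which.min)            # nearest mark per pixel
  nn_p <- apply(d2, 2, which.min)            # nearest pixel per mark
  mutual <- nn_p[nn_g] == seq_len(n)
  dist_gm <- sqrt(d2[cbind(seq_len(n), nn_g)])
  ok <- mutual & dist_gm <= 0.5 * stepsize_um
  out <- tibble::tibble(
    col = msi_grid$col, row = msi_grid$row,
    mark_id = ifelse(ok, nn_g, NA_integer_),
    residual_um = ifelse(ok, dist_gm, NA_real_))
  class(out) <- c("grid_assignment", class(out))
  attr(out, "low_assignment") <- mean(ok) < 0.5
  out
}

#' Register an MSI grid to detected ablation marks end-to-end
#'
#' Chains the coarse rigid search, concave-hull construction, boundary
#' identifier matching, coherent-point-drift refinement on the matched
#' boundary points, and the final pixel assignment. In manual mode a
#' table of landmark pairs (`msi_col`, `msi_row`, `x_um`, `y_um`)
#' replaces the automatic stages and CPD runs on the landmark sets.
#'
#' @param marks `mark_candidates` in the PostMSI frame.
#' @param col,row measured MSI grid indices.
#' @param stepsize_um grid pitch.
#' @param max_dist identifier-match distance gate (defaults to one
#'   pitch).
#' @param cpd_model `"rigid"` or `"affine"`.
#' @param manual_landmarks optional data frame with columns `msi_col`,
#'   `msi_row`, `x_um`, `y_um`.
#' @return List with `transform` (MSI -> PostMSI `affine_transform`),
#'   `assignment` ([assign_pixels()] result), `matches` and `coarse`.
#' @export
register_msi_grid <- function(marks, col, row, stepsize_um,
                              max_dist = stepsize_um, cpd_model = "rigid",
                              manual_landmarks = NULL) {
  grid <- msi_grid_centers(col, row, stepsize_um)
  if (!is.null(manual_landmarks)) {
    lg <- msi_grid_centers(manual_landmarks$msi_col, manual_landmarks$msi_row,
                           stepsize_um)
    cpd <- cpd_register(cbind(manual_landmarks$x_um, manual_landmarks$y_um),
                        cbind(lg$x, lg$y), model = cpd_model,
                        source_frame = marks_frame(marks), target_frame = "MSI")
    tf_msi_to_marks <- invert_transform(cpd)
    assignment <- assign_pixels(marks, grid, tf_msi_to_marks, stepsize_um)
    return(list(transform = tf_msi_to_marks, assignment = assignment,
                matches = NULL, coarse = NULL))
  }
  mask <- msi_grid_mask(col, row, stepsize_um)
  coarse <- coarse_transform_search(marks, mask, stepsize_um)
  hull_marks <- build_concave_hull(cbind(marks$x, marks$y), stepsize_um,
                                   source = "marks")
  hull_msi <- build_concave_hull(cbind(grid$x, grid$y), stepsize_um,
                                 source = "msi")
  matches <- match_identifiers(hull_marks, hull_msi, coarse, max_dist)
  cpd <- cpd_register(cbind(matches$mark_x, matches$mark_y),
                      cbind(matches$msi_x, matches$msi_y), model = cpd_model,
                      source_frame = marks_frame(marks), target_frame = "MSI")
  tf_msi_to_marks <- invert_transform(cpd)
  assignment <- assign_pixels(marks, grid, tf_msi_to_marks, stepsize_um)
  list(transform = tf_msi_to_marks, assignment = assignment,
       matches = matches, coarse = coarse)
}
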