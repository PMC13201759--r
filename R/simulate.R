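# Synthetic tissue simulator: ground-truth engine for the integration
# and modeling stages, and renderer of PostMSI-like fixtures for the
# registration stages. The generative model: a Gaussian random field
# drives an inhomogeneous multitype point pattern with simple
# sequential inhibition; cells are discs with negative-binomial areas
# and log-normal per-area analyte rates; an MSI grid aggregates
# rate x overlap per pixel; three error terms (neighbour smoothing,
# uncorrelated log-normal, correlated GRF) corrupt the signal.

#' Simulation configuration
#'
#' Defaults reproduce the reference study conditions: a 1000 x 1000 um
#' field, grid pitch 30 um with 24 um ablation spots, inhibition at the
#' 0.975 quantile of observed cell radii, and a correlated error field
#' bounded by 500. Cell counts, negative-binomial area parameters and
#' the per-type log-normal rate parameters are stand-ins chosen at
#' realistic scales (the source parameters were fitted to unpublished
#' data) and are fully configurable.
#'
#' @param field_um field side length.
#' @param n_types number of cell types; the first type follows the GRF,
#'   all others its complement.
#' @param n_per_type cells per type (recycled).
#' @param grf_length_scale_um exponential-covariance length scale.
#' @param grf_res_um resolution at which the GRF is sampled.
#' @param inhibition_q quantile of `sqrt(area / pi)` used as the
#'   inhibition distance.
#' @param area_nb_mu,area_nb_size negative-binomial area parameters
#'   (um^2); areas are shifted to be at least 1.
#' @param rate_meanlog,rate_sdlog per-type log-normal parameters of the
#'   analyte rate per um^2 (recycled over types).
#' @param stepsize_um,pixelsize_um MSI grid pitch and spot size.
#' @param translation_x_um registration-error translation applied to
#'   the covariate grid.
#' @param area_perturbation `"none"`, `"rank-reorder"` or `"reshuffle"`.
#' @param rank_bins quantile bins for the rank reordering.
#' @param smooth_lambda neighbour-smoothing weight of the first error
#'   term.
#' @param noise_meanlog,noise_sdlog log-normal uncorrelated error
#'   (`NULL` `noise_meanlog` disables it).
#' @param grf_error_max upper bound of the correlated GRF error.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(field_um = 1000, n_types = 3, n_per_type = 150,
                       grf_length_scale_um = 150, grf_res_um = 10,
                       inhibition_q = 0.975,
                       area_nb_mu = 80, area_nb_size = 2,
                       rate_meanlog = c(1.5, 0.5, 0), rate_sdlog = 0.25,
                       stepsize_um = 30, pixelsize_um = 24,
                       translation_x_um = 0,
                       area_perturbation = c("none", "rank-reorder", "reshuffle"),
                       rank_bins = 4,
                       smooth_lambda = 0.1,
                       noise_meanlog = 2, noise_sdlog = 0.5,
                       grf_error_max = 500) {
  area_perturbation <- match.arg(area_perturbation)
  stopifnot(pixelsize_um <= stepsize_um, grf_length_scale_um > 0)
  cfg <- list(field_um = field_um, n_types = n_types,
              n_per_type = rep(n_per_type, length.out = n_types),
              grf_length_scale_um = grf_length_scale_um, grf_res_um = grf_res_um,
              inhibition_q = inhibition_q,
              area_nb_mu = area_nb_mu, area_nb_size = area_nb_size,
              rate_meanlog = rep(rate_meanlog, length.out = n_types),
              rate_sdlog = rep(rate_sdlog, length.out = n_types),
              stepsize_um = stepsize_um, pixelsize_um = pixelsize_um,
              translation_x_um = translation_x_um,
              area_perturbation = area_perturbation, rank_bins = rank_bins,
              smooth_lambda = smooth_lambda,
              noise_meanlog = noise_meanlog, noise_sdlog = noise_sdlog,
              grf_error_max = grf_error_max)
  class(cfg) <- "sim_config"
  cfg
}

#' Sample a stationary Gaussian random field
#'
#' Circulant-embedding sampler with exponential covariance
#' `exp(-d / length_scale)`; the returned field is min-max scaled to
#' `[0, 1]` unless `scale01 = FALSE`.
#'
#' @param nrow,ncol grid size.
#' @param res_um grid spacing.
#' @param length_scale_um covariance length scale.
#' @param seed optional RNG seed.
#' @param scale01 scale the field to `[0, 1]`.
#' @return A matrix.
#' @export
sample_grf <- function(nrow, ncol, res_um, length_scale_um, seed = NULL,
                       scale01 = TRUE) {
  stopifnot(length_scale_um > 0)
  if (!is.null(seed)) set.seed(seed)
  # generous padding keeps the embedding's negative eigenvalues (and the
  # covariance bias their clipping would cause) negligible
  M <- 4 * nrow; N <- 4 * ncol
  di <- pmin(0:(M - 1), M - (0:(M - 1))) * res_um
  dj <- pmin(0:(N - 1), N - (0:(N - 1))) * res_um
  C <- exp(-sqrt(outer(di^2, dj^2, "+")) / length_scale_um)
  lam <- Re(stats::fft(C))
  lam[lam < 0] <- 0  # clip tiny negative embedding eigenvalues
  xi <- matrix(complex(real = stats::rnorm(M * N),
                       imaginary = stats::rnorm(M * N)), M, N)
  F <- stats::fft(sqrt(lam) * xi) / sqrt(M * N)
  field <- Re(F)[seq_len(nrow), seq_len(ncol)]
  if (scale01) {
    rng <- range(field)
    if (diff(rng) > 0) field <- (field - rng[1]) / diff(rng)
  }
  field
}

#' Sample cell areas (negative binomial, shifted to >= 1)
#'
#' @param n number of cells.
#' @param mu,size negative-binomial mean and dispersion (um^2).
#' @param seed optional RNG seed.
#' @return Numeric areas (um^2).
#' @export
sample_areas <- function(n, mu = 80, size = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stats::rnbinom(n, mu = mu, size = size) + 1
}

#' Sample per-cell analyte rates (log-normal per type)
#'
#' @param types integer type index per cell.
#' @param meanlog,sdlog per-type log-normal parameters.
#' @param seed optional RNG seed.
#' @return Numeric rates (analyte per um^2).
#' @export
sample_rates <- function(types, meanlog, sdlog, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stats::rlnorm(length(types), meanlog[types], sdlog[types])
}

#' Sample a multitype point pattern with simple sequential inhibition
#'
#' Candidate positions are drawn from the type's inhomogeneous
#' intensity (the scaled GRF for type 1, its complement for all other
#' types) and accepted if at least the inhibition distance from all
#' previously accepted cells; counts per type are exact.
#'
#' @param grf field in `[0, 1]` (matrix over the field at `res_um`).
#' @param res_um GRF grid spacing.
#' @param field_um field side length.
#' @param n_per_type cells per type.
#' @param inhibition_um inhibition distance.
#' @param seed optional RNG seed.
#' @param max_proposals proposal budget per cell.
#' @return Tibble `cell_id`, `x`, `y`, `type`.
#' @export
sample_cells <- function(grf, res_um, field_um, n_per_type, inhibition_um,
                         seed = NULL, max_proposals = 2000) {
  if (!is.null(seed)) set.seed(seed)
  xs <- numeric(0); ys <- numeric(0); ts <- integer(0)
  intensity_at <- function(x, y, type) {
    r <- pmin(pmax(y / res_um + 0.5, 1), nrow(grf))
    c <- pmin(pmax(x / res_um + 0.5, 1), ncol(grf))
    v <- grf[cbind(round(r), round(c))]
    if (type == 1) v else 1 - v
  }
  for (type in seq_along(n_per_type)) {
    placed <- 0
    while (placed < n_per_type[type]) {
      ok <- FALSE
      for (p in seq_len(max_proposals)) {
        cx <- stats::runif(1, 0, field_um)
        cy <- stats::runif(1, 0, field_um)
        if (stats::runif(1) > intensity_at(cx, cy, type)) next
        if (length(xs) && min((xs - cx)^2 + (ys - cy)^2) < inhibition_um^2) next
        ok <- TRUE
        break
      }
      if (!ok) {
        stop("packing failure: could not place all cells; reduce cell counts ",
             "or the inhibition distance")
      }
      xs <- c(xs, cx); ys <- c(ys, cy); ts <- c(ts, type)
      placed <- placed + 1
    }
  }
  tibble::tibble(cell_id = seq_along(xs), x = xs, y = ys, type = ts)
}

#' Perturb cell areas (registration-error emulation)
#'
#' `"reshuffle"` randomly permutes areas across cells (extreme case);
#' `"rank-reorder"` splits areas into quantile bins and reverses the
#' rank order within each bin (mild case, imitating area differences
#' between adjacent slices). The multiset of areas is preserved.
#'
#' @param areas numeric areas.
#' @param mode `"none"`, `"reshuffle"` or `"rank-reorder"`.
#' @param bins quantile bins for the rank reordering.
#' @param seed optional RNG seed (reshuffle only).
#' @return Perturbed areas.
#' @export
perturb_areas <- function(areas, mode = c("none", "reshuffle", "rank-reorder"),
                          bins = 4, seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "none") return(areas)
  if (!is.null(seed)) set.seed(seed)
  if (mode == "reshuffle") return(sample(areas))
  qs <- stats::quantile(areas, probs = seq(0, 1, length.out = bins + 1))
  bin <- cut(areas, unique(qs), include.lowest = TRUE)
  out <- areas
  for (b in levels(bin)) {
    idx <- which(bin == b)
    o <- order(areas[idx])
    out[idx[o]] <- areas[idx[o[length(o):1]]]
  }
  out
}

# exact area of discs (centres cx, cy, radii r) clipped to rectangles
# [x0, x1] x [y0, y1]; fully vectorized over pairs
circle_rect_overlap <- function(cx, cy, r, x0, x1, y0, y1) {
  # corner decomposition: g(x, y) = area of disc(0, r) in {u<=x, v<=y}
  Fint <- function(u, r) {
    (u * sqrt(pmax(r^2 - u^2, 0)) + r^2 * asin(pmin(pmax(u / r, -1), 1))) / 2
  }
  g <- function(x, y, r) {
    x <- pmin(pmax(x, -r), r)
    b <- sqrt(pmax(r^2 - pmin(abs(y), r)^2, 0))
    # y >= r: full chords over [-r, x]
    full <- 2 * (Fint(x, r) - Fint(-r, r))
    # 0 <= y < r
    a1 <- 2 * (Fint(pmin(x, -b), r) - Fint(-r, r))
    u2 <- pmin(x, b)
    a2 <- (x > -b) * (y * (u2 + b) + Fint(u2, r) - Fint(-b, r))
    a3 <- (x > b) * 2 * (Fint(x, r) - Fint(b, r))
    mid_pos <- a1 + a2 + a3
    # -r < y < 0
    hi <- pmin(x, b)
    mid_neg <- (hi > -b) * (y * (hi + b) + Fint(hi, r) - Fint(-b, r))
    out <- ifelse(y >= r, full, ifelse(y >= 0, mid_pos,
                                       ifelse(y > -r, mid_neg, 0)))
    out
  }
  gg <- function(x, y) g(x - cx, y - cy, r)
  pmax(gg(x1, y1) - gg(x0, y1) - gg(x1, y0) + gg(x0, y0), 0)
}

#' Aggregate simulated cells onto an MSI pixel grid
#'
#' Per pixel, `y` is the sum over cells of rate times the exact overlap
#' area of the cell disc with the pixel square (before any error
#' terms); the covariates `X` are per-type overlap areas normalised by
#' the pixel area. The x-translation (registration-error emulation)
#' shifts the grid used for `X` only, so `y` and `X` decouple exactly
#' as a misregistration would make them.
#'
#' @param cells tibble with `x`, `y`, `type`, `area_um2` and `rate`;
#'   an optional `area_obs_um2` column is used for `X` (perturbed
#'   areas).
#' @param field_um field side length.
#' @param stepsize_um,pixelsize_um grid pitch and spot size.
#' @param translation_x_um x shift of the covariate grid.
#' @return Tibble: `col`, `row`, `y` and one `frac_<type>` column per
#'   type.
#' @export
aggregate_to_grid <- function(cells, field_um, stepsize_um, pixelsize_um,
                              translation_x_um = 0) {
  n_side <- floor(field_um / stepsize_um)
  g <- expand.grid(col = seq_len(n_side), row = seq_len(n_side))
  h <- pixelsize_um / 2
  px_area <- pixelsize_um^2
  cxs <- (g$col - 0.5) * stepsize_um
  cys <- (g$row - 0.5) * stepsize_um
  types <- sort(unique(cells$type))
  y <- numeric(nrow(g))
  Xfrac <- matrix(0, nrow(g), length(types))
  r_true <- sqrt(cells$area_um2 / pi)
  area_obs <- if ("area_obs_um2" %in% names(cells)) cells$area_obs_um2 else cells$area_um2
  r_obs <- sqrt(area_obs / pi)
  # enumerate candidate (cell, pixel) pairs, then evaluate every exact
  # disc-square overlap in one vectorized call per grid
  r_max <- pmax(r_true, r_obs)
  pad <- abs(translation_x_um)
  ci <- integer(0); pk <- integer(0)
  for (i in seq_len(nrow(cells))) {
    lo_c <- max(1, floor((cells$x[i] - r_max[i] - h - pad) / stepsize_um))
    hi_c <- min(n_side, ceiling((cells$x[i] + r_max[i] + h + pad) / stepsize_um) + 1)
    lo_r <- max(1, floor((cells$y[i] - r_max[i] - h) / stepsize_um))
    hi_r <- min(n_side, ceiling((cells$y[i] + r_max[i] + h) / stepsize_um) + 1)
    cc <- rep(lo_c:hi_c, times = hi_r - lo_r + 1)
    rr <- rep(lo_r:hi_r, each = hi_c - lo_c + 1)
    ci <- c(ci, rep(i, length(cc)))
    pk <- c(pk, (rr - 1L) * n_side + cc)
  }
  pcx <- cxs[pk]; pcy <- cys[pk]
  a_sig <- circle_rect_overlap(cells$x[ci], cells$y[ci], r_true[ci],
                               pcx - h, pcx + h, pcy - h, pcy + h)
  a_cov <- circle_rect_overlap(cells$x[ci], cells$y[ci], r_obs[ci],
                               pcx - h + translation_x_um,
                               pcx + h + translation_x_um,
                               pcy - h, pcy + h)
  y_add <- tapply(cells$rate[ci] * a_sig, pk, sum)
  y[as.integer(names(y_add))] <- y[as.integer(names(y_add))] + as.numeric(y_add)
  ti <- match(cells$type, types)[ci]
  for (t in seq_along(types)) {
    sel <- ti == t & a_cov > 0
    if (any(sel)) {
      add <- tapply(a_cov[sel], pk[sel], sum) / px_area
      Xfrac[as.integer(names(add)), t] <- Xfrac[as.integer(names(add)), t] + as.numeric(add)
    }
  }
  out <- tibble::tibble(col = g$col, row = g$row, y = y)
  for (t in seq_along(types)) out[[paste0("frac_", types[t])]] <- Xfrac[, t]
  out
}

#' Add the three simulated error terms to a gridded signal
#'
#' In order: neighbour smoothing
#' `y <- (1 - lambda) y + lambda * neighbour-mean(y)` (queen
#' neighbourhood), additive uncorrelated log-normal noise (disabled
#' when `noise_meanlog` is `NULL`), and an additive correlated error
#' from a GRF scaled between 0 and `grf_error_max`.
#'
#' @param grid tibble from [aggregate_to_grid()] (columns `col`, `row`,
#'   `y`).
#' @param smooth_lambda smoothing weight in `[0, 1]`.
#' @param noise_meanlog,noise_sdlog log-normal noise parameters.
#' @param grf_error_max bound of the correlated error (0 disables).
#' @param grf_length_scale_um,grf_res_um correlated-error field
#'   geometry.
#' @param stepsize_um grid pitch (locates pixels in the error field).
#' @param seed optional RNG seed.
#' @return The grid tibble with a corrupted `y`.
#' @export
add_errors <- function(grid, smooth_lambda = 0.1,
                       noise_meanlog = 2, noise_sdlog = 0.5,
                       grf_error_max = 500, grf_length_scale_um = 150,
                       grf_res_um = 10, stepsize_um = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- grid$y
  if (smooth_lambda > 0) {
    W <- build_weights(grid$col, grid$row, "queen")
    nbm <- as.numeric(W %*% y)
    iso <- attr(W, "isolated")
    nbm[iso] <- y[iso]
    y <- (1 - smooth_lambda) * y + smooth_lambda * nbm
  }
  if (!is.null(noise_meanlog)) {
    y <- y + stats::rlnorm(length(y), noise_meanlog, noise_sdlog)
  }
  if (grf_error_max > 0) {
    nr <- max(grid$row); nc <- max(grid$col)
    f <- sample_grf(nr, nc, stepsize_um, grf_length_scale_um)
    y <- y + grf_error_max * f[cbind(grid$row, grid$col)]
  }
  grid$y <- y
  grid
}

#' Run the full generative model
#'
#' GRF, inhibited multitype point pattern, areas, rates, optional area
#' perturbation, grid aggregation with x-translation, and the error
#' terms. Fully reproducible from `(config, seed)`.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return List of class `sim_output`: `cells`, `grid` (the modelling
#'   table: `col`, `row`, `y`, `frac_*`), `grf`, `true_rate_mean`
#'   (expected per-type rate, the ground-truth association analogue:
#'   `beta_type ~ rate * pixel_area`), and `config`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  nr <- ceiling(config$field_um / config$grf_res_um)
  grf <- sample_grf(nr, nr, config$grf_res_um, config$grf_length_scale_um)
  n_total <- sum(config$n_per_type)
  areas <- sample_areas(n_total, config$area_nb_mu, config$area_nb_size)
  inhib <- stats::quantile(sqrt(areas / pi), config$inhibition_q)
  cells <- sample_cells(grf, config$grf_res_um, config$field_um,
                        config$n_per_type, inhib)
  cells$area_um2 <- areas
  cells$rate <- sample_rates(cells$type, config$rate_meanlog, config$rate_sdlog)
  cells$area_obs_um2 <- perturb_areas(cells$area_um2,
                                      config$area_perturbation,
                                      bins = config$rank_bins)
  grid <- aggregate_to_grid(cells, config$field_um, config$stepsize_um,
                            config$pixelsize_um, config$translation_x_um)
  grid <- add_errors(grid, config$smooth_lambda, config$noise_meanlog,
                     config$noise_sdlog, config$grf_error_max,
                     config$grf_length_scale_um, config$grf_res_um,
                     config$stepsize_um)
  structure(list(
    cells = cells, grid = grid, grf = grf,
    true_rate_mean = exp(config$rate_meanlog + config$rate_sdlog^2 / 2),
    config = config, seed = seed), class = "sim_output")
}

#' Render a PostMSI-like image with an ablation-mark grid
#'
#' A brightfield-like textured background with dark anti-aliased discs
#' at (optionally jittered and rigidly transformed) grid positions;
#' the ground-truth centroids are returned alongside. Disc coverage per
#' image pixel is computed exactly, so the rendered centroid equals the
#' intended one.
#'
#' @param n_col,n_row grid size.
#' @param stepsize_um grid pitch.
#' @param mark_radius_um ablation mark radius.
#' @param img_pixelsize_um image resolution.
#' @param contrast darkness of a fully covered pixel (background ~0.8).
#' @param noise_sd background texture standard deviation.
#' @param jitter_sd_um isotropic Gaussian jitter of mark centres.
#' @param theta_deg,offset_um rigid ground-truth transform applied to
#'   the grid (rotation about the grid centre, then translation) in
#'   addition to the rendering margin.
#' @param margin_um empty border around the grid.
#' @param seed RNG seed.
#' @return List: `image` ([phys_image], frame `"PostMSI"`), `truth`
#'   (tibble `col`, `row`, `x`, `y` of true centroids) and `transform`
#'   (the ground-truth rigid map, MSI frame -> image frame).
#' @export
render_postmsi_fixture <- function(n_col = 12, n_row = 12, stepsize_um = 30,
                                   mark_radius_um = 6, img_pixelsize_um = 2,
                                   contrast = 0.5, noise_sd = 0.02,
                                   jitter_sd_um = 0, theta_deg = 0,
                                   offset_um = c(0, 0), margin_um = 60,
                                   seed = 1) {
  set.seed(seed)
  grid <- msi_grid_centers(rep(seq_len(n_col), times = n_row),
                           rep(seq_len(n_row), each = n_col), stepsize_um)
  ctr <- c(n_col, n_row) * stepsize_um / 2
  truth_tf <- rigid_transform(theta_deg, offset_um[1] + margin_um,
                              offset_um[2] + margin_um, center = ctr,
                              source = "MSI", target = "PostMSI")
  pos <- transform_points(truth_tf, cbind(grid$x, grid$y))
  pos <- pos + matrix(stats::rnorm(2 * nrow(pos), 0, jitter_sd_um), ncol = 2)
  w_um <- n_col * stepsize_um + 2 * margin_um
  h_um <- n_row * stepsize_um + 2 * margin_um
  nc <- ceiling(w_um / img_pixelsize_um)
  nr <- ceiling(h_um / img_pixelsize_um)
  img <- matrix(0.8 + stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
  px <- img_pixelsize_um
  for (i in seq_len(nrow(pos))) {
    c0 <- max(1, floor((pos[i, 1] - mark_radius_um) / px))
    c1 <- min(nc, ceiling((pos[i, 1] + mark_radius_um) / px) + 1)
    r0 <- max(1, floor((pos[i, 2] - mark_radius_um) / px))
    r1 <- min(nr, ceiling((pos[i, 2] + mark_radius_um) / px) + 1)
    for (cc in c0:c1) for (rr in r0:r1) {
      cov <- circle_rect_overlap(pos[i, 1], pos[i, 2], mark_radius_um,
                                 (cc - 1) * px, cc * px,
                                 (rr - 1) * px, rr * px) / px^2
      if (cov > 0) img[rr, cc] <- img[rr, cc] - contrast * cov
    }
  }
  list(image = phys_image(img, img_pixelsize_um, frame = "PostMSI"),
       truth = tibble::tibble(col = grid$col, row = grid$row,
                              x = pos[, 1], y = pos[, 2]),
       transform = truth_tf)
}
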