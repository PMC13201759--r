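# Intensity-based registration of the microscopy chain
# (PostIMC -> PreIMC -> PreMSI -> PostMSI) and IMC -> PostIMC.
# Transforms map moving-frame um coordinates onto the fixed frame.

affine_from_params <- function(p, center, source, target) {
  # p = (theta_deg, log_sx, log_sy, shear, tx_um, ty_um)
  th <- p[1] * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  S <- matrix(c(exp(p[2]), 0, p[4], exp(p[3])), 2)
  A <- R %*% S
  t <- c(p[5], p[6]) + as.vector(center - A %*% center)
  affine_transform(A, t, source, target)
}

# factory: NCC of fixed against moving resampled through tf
# (moving -> fixed), over precomputed fixed-pixel samples with a
# deterministic stride
make_ncc_objective <- function(fixed, moving, center, stride, model) {
  d <- dim(fixed$values)
  rows <- seq(1, d[1], by = stride); cols <- seq(1, d[2], by = stride)
  g <- expand.grid(row = rows, col = cols)
  fxy <- cbind((g$col - 0.5) * fixed$pixelsize_um,
               (g$row - 0.5) * fixed$pixelsize_um)
  fv_all <- fixed$values[cbind(g$row, g$col)]
  mdim <- dim(moving$values)
  mvals <- moving$values
  mpx <- moving$pixelsize_um
  function(p) {
    pfull <- if (model == "euler") c(p[1], 0, 0, 0, p[2], p[3]) else p
    tf <- affine_from_params(pfull, center, moving$frame, fixed$frame)
    Mi <- solve(tf$M)
    src <- t(Mi[1:2, ] %*% rbind(t(fxy), 1))
    rc <- cbind(src[, 2] / mpx + 0.5, src[, 1] / mpx + 0.5)
    inside <- rc[, 1] >= 1 & rc[, 1] <= mdim[1] &
      rc[, 2] >= 1 & rc[, 2] <= mdim[2]
    if (mean(inside) < 0.25) return(2)  # penalty: almost no overlap
    mv <- bilinear_sample(mvals, rc[inside, , drop = FALSE])
    fv <- fv_all[inside]
    if (stats::sd(mv) == 0 || stats::sd(fv) == 0) return(1)
    -stats::cor(fv, mv)
  }
}

build_pyramid <- function(img, n_levels) {
  out <- list(img)
  for (l in seq_len(n_levels - 1)) {
    prev <- out[[l]]
    if (min(dim(prev$values)) < 32) break
    out[[l + 1]] <- phys_image(downsample2(prev$values),
                               prev$pixelsize_um * 2, prev$frame)
  }
  rev(out)  # coarsest first
}

# integer-pixel translation estimate by FFT cross-correlation on a
# common zero-padded canvas (both images resampled to `px` um/px)
fft_translation_init <- function(fixed, moving) {
  f <- fixed$values - mean(fixed$values)
  m <- moving$values - mean(moving$values)
  nr <- max(nrow(f), nrow(m)) * 2; nc <- max(ncol(f), ncol(m)) * 2
  pad <- function(x) { o <- matrix(0, nr, nc); o[seq_len(nrow(x)), seq_len(ncol(x))] <- x; o }
  cc <- Re(stats::fft(stats::fft(pad(f)) * Conj(stats::fft(pad(m))), inverse = TRUE))
  pk <- arrayInd(which.max(cc), dim(cc))
  dr <- pk[1] - 1; dc <- pk[2] - 1
  if (dr > nr / 2) dr <- dr - nr
  if (dc > nc / 2) dc <- dc - nc
  c(tx = dc * moving$pixelsize_um, ty = dr * moving$pixelsize_um)
}

#' Intensity-based affine registration of two slide images
#'
#' Multi-resolution (3 levels by default) maximization of the normalized
#' correlation between the fixed image and the moving image resampled
#' through the candidate transform. The coarsest level is initialized by
#' FFT cross-correlation, which makes large translations recoverable;
#' optimization uses Nelder-Mead on (rotation, log-scales, shear,
#' translation) with a deterministic sample stride, so results are fully
#' reproducible. If the metric cannot be improved over the identity a
#' warning is given and the identity returned.
#'
#' @param fixed,moving single-channel [phys_image]s with known pixel
#'   sizes.
#' @param model `"affine"` (default) or `"euler"` (rotation +
#'   translation only).
#' @param roi optional `c(xmin, xmax, ymin, ymax)` um restriction of the
#'   fixed image used for the metric.
#' @param n_levels pyramid depth.
#' @param init optional initial `affine_transform` (moving -> fixed).
#' @return An `affine_transform` mapping moving-frame to fixed-frame
#'   coordinates, with the achieved metric in `$metric`.
#' @export
register_affine <- function(fixed, moving, model = c("affine", "euler"),
                            roi = NULL, n_levels = 3, init = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(fixed, "phys_image"), inherits(moving, "phys_image"))
  fixed <- to_gray(fixed); moving <- to_gray(moving)
  if (!is.null(roi)) {
    d <- dim(fixed$values); px <- fixed$pixelsize_um
    rows <- max(1, floor(roi[3] / px)):min(d[1], ceiling(roi[4] / px))
    cols <- max(1, floor(roi[1] / px)):min(d[2], ceiling(roi[2] / px))
    sub <- fixed$values[rows, cols, drop = FALSE]
    fixed_off <- c((cols[1] - 1) * px, (rows[1] - 1) * px)
    fixed <- phys_image(sub, px, fixed$frame)
  } else fixed_off <- c(0, 0)

  pyr_f <- build_pyramid(fixed, n_levels)
  pyr_m <- build_pyramid(moving, n_levels)
  nl <- min(length(pyr_f), length(pyr_m))
  pyr_f <- pyr_f[seq_len(nl)]; pyr_m <- pyr_m[seq_len(nl)]

  center <- c(ncol(moving$values), nrow(moving$values)) * moving$pixelsize_um / 2
  p <- c(0, 0, 0, 0, 0, 0)
  if (!is.null(init)) {
    # decompose given affine around `center` into the parameter vector
    A <- init$M[1:2, 1:2]
    th <- atan2(A[2, 1], A[1, 1])
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    S <- solve(R, A)
    t_eff <- init$M[1:2, 3] - as.vector(center - A %*% center)
    p <- c(th * 180 / pi, log(max(S[1, 1], 1e-6)), log(max(S[2, 2], 1e-6)),
           S[1, 2], t_eff[1], t_eff[2])
  } else {
    # coarse initialization: sweep rotations, FFT-translate each
    f0 <- pyr_f[[1]]; m0 <- pyr_m[[1]]
    obj0 <- make_ncc_objective(f0, m0, center, 1, "euler")
    best <- c(val = Inf, th = 0, tx = 0, ty = 0)
    for (th in seq(-12, 12, by = 4)) {
      rot <- transform_image(rigid_transform(th, 0, 0, center = center,
                                             source = m0$frame, target = m0$frame),
                             m0, fill = mean(m0$values))
      tr <- unname(fft_translation_init(f0, rot))
      v <- obj0(c(th, tr[1], tr[2]))
      if (v < best[["val"]]) best <- c(val = v, th = th, tx = tr[1], ty = tr[2])
    }
    p[1] <- best[["th"]]
    p[5:6] <- c(best[["tx"]], best[["ty"]]) + fixed_off
  }
  p[5:6] <- p[5:6] - fixed_off  # metric works in the cropped frame

  sel <- if (model == "euler") c(1, 5, 6) else 1:6
  fine_obj <- make_ncc_objective(pyr_f[[nl]], pyr_m[[nl]], center,
                                 max(1, floor(sqrt(prod(dim(pyr_f[[nl]]$values)) / 2e4))),
                                 model)
  identity_val <- fine_obj(if (model == "euler") c(0, 0, 0) else rep(0, 6))
  for (l in seq_len(nl)) {
    f <- pyr_f[[l]]; m <- pyr_m[[l]]
    stride <- max(1, floor(sqrt(prod(dim(f$values)) / 6e3)))
    obj <- make_ncc_objective(f, m, center, stride, model)
    scl <- c(2, 0.05, 0.05, 0.05, 4 * f$pixelsize_um, 4 * f$pixelsize_um)[sel]
    opt <- stats::optim(p[sel], obj, method = "Nelder-Mead",
                        control = list(maxit = 200, parscale = scl,
                                       reltol = 1e-9))
    if (l == nl) {
      # a refinement pass helps Nelder-Mead escape its simplex collapse
      opt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                          control = list(maxit = 150, parscale = scl / 8,
                                         reltol = 1e-10))
    }
    p[sel] <- opt$par
  }
  final_val <- fine_obj(p[sel])
  if (final_val >= identity_val && identity_val <= 0) {
    # no warning when the identity already is a (near-)perfect alignment
    if (-identity_val < 0.999) {
      warning("metric not improved over identity; returning identity transform")
    }
    tf <- affine_transform(source = moving$frame, target = fixed$frame)
    tf$metric <- -identity_val
    return(tf)
  }
  pfull <- if (model == "euler") c(p[sel][1], 0, 0, 0, p[sel][2], p[sel][3]) else p
  pfull[5:6] <- pfull[5:6] + fixed_off
  tf <- affine_from_params(pfull, center, moving$frame, fixed$frame)
  tf$metric <- -final_val
  tf
}

# ---- b-spline free-form deformation refinement -----------------------------

#' Non-linear (b-spline) registration after an affine initialization
#'
#' Fits a cubic b-spline free-form deformation on a regular control grid
#' by minimizing the mean squared intensity difference with an analytic
#' gradient, plus a bending-energy (control-grid Laplacian) penalty.
#' Internally the deformation is estimated as a fixed-to-moving map (the
#' resampling direction); the returned transform maps moving to fixed
#' and inverts the field by fixed-point iteration when mapping points.
#'
#' @param fixed,moving single-channel [phys_image]s.
#' @param init affine `affine_transform` (moving -> fixed), e.g. from
#'   [register_affine()].
#' @param grid_spacing_um control grid spacing.
#' @param lambda bending-energy weight.
#' @param maxit L-BFGS iteration cap.
#' @return A transform mapping moving-frame to fixed-frame coordinates
#'   (class `inverse_bspline_transform`); `$forward` holds the fitted
#'   fixed-to-moving field, whose `fold_warning` flag is set when the
#'   deformation folds (negative Jacobian).
#' @export
register_bspline <- function(fixed, moving, init, grid_spacing_um,
                             lambda = 1e-2, maxit = 100, n_levels = 3) {
  stopifnot(inherits(fixed, "phys_image"), inherits(moving, "phys_image"))
  fixed <- to_gray(fixed); moving <- to_gray(moving)
  init_inv <- invert_transform(init)   # fixed -> moving

  # control grid (physical units, shared by all pyramid levels) covering
  # the moving-frame footprint of the fixed image
  ctr <- pixel_centers(fixed)
  q_full <- transform_points(init_inv, cbind(ctr$x, ctr$y))
  pad <- 2 * grid_spacing_um
  ox <- min(q_full[, 1]) - pad; oy <- min(q_full[, 2]) - pad
  ncx <- ceiling((max(q_full[, 1]) + pad - ox) / grid_spacing_um) + 3
  ncy <- ceiling((max(q_full[, 2]) + pad - oy) / grid_spacing_um) + 3
  nctrl <- ncx * ncy

  # control-grid Laplacian for the bending penalty
  idx <- matrix(seq_len(nctrl), ncy, ncx)
  li <- integer(0); lj <- integer(0); lv <- numeric(0)
  add <- function(a, b, w) { li <<- c(li, a); lj <<- c(lj, b); lv <<- c(lv, w) }
  for (cx in seq_len(ncx)) for (cy in seq_len(ncy)) {
    self <- idx[cy, cx]; nb <- c()
    if (cy > 1) nb <- c(nb, idx[cy - 1, cx])
    if (cy < ncy) nb <- c(nb, idx[cy + 1, cx])
    if (cx > 1) nb <- c(nb, idx[cy, cx - 1])
    if (cx < ncx) nb <- c(nb, idx[cy, cx + 1])
    add(self, self, length(nb))
    for (b in nb) add(self, b, -1)
  }
  L <- Matrix::sparseMatrix(i = li, j = lj, x = lv, dims = c(nctrl, nctrl))
  LtL <- Matrix::t(L) %*% L

  # sparse b-spline basis for a set of moving-frame anchors
  make_basis <- function(q) {
    sx <- (q[, 1] - ox) / grid_spacing_um
    sy <- (q[, 2] - oy) / grid_spacing_um
    ixf <- floor(sx); iyf <- floor(sy)
    Bx <- bspline_basis(sx - ixf); By <- bspline_basis(sy - iyf)
    npx <- nrow(q)
    ii <- integer(0); jj <- integer(0); vv <- numeric(0)
    for (a in 0:3) for (b in 0:3) {
      cx <- pmin(pmax(ixf + a, 1), ncx)
      cy <- pmin(pmax(iyf + b, 1), ncy)
      ii <- c(ii, seq_len(npx))
      jj <- c(jj, (cx - 1) * ncy + cy)
      vv <- c(vv, Bx[, a + 1] * By[, b + 1])
    }
    Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(npx, nctrl))
  }

  fit_level <- function(fx, mv_img, cc0, iters) {
    ctr_l <- pixel_centers(fx)
    q <- transform_points(init_inv, cbind(ctr_l$x, ctr_l$y))
    S <- make_basis(q)
    StT <- Matrix::t(S)
    npx <- nrow(q)
    fv <- as.vector(fx$values[cbind(ctr_l$row, ctr_l$col)])
    mval <- mv_img$values
    gx <- (cbind(mval[, -1], mval[, ncol(mval)]) -
             cbind(mval[, 1], mval[, -ncol(mval)])) / (2 * mv_img$pixelsize_um)
    gy <- (rbind(mval[-1, ], mval[nrow(mval), ]) -
             rbind(mval[1, ], mval[-nrow(mval), ])) / (2 * mv_img$pixelsize_um)
    eval_parts <- function(cc) {
      cxv <- cc[seq_len(nctrl)]; cyv <- cc[nctrl + seq_len(nctrl)]
      pos <- cbind(q[, 1] + as.vector(S %*% cxv),
                   q[, 2] + as.vector(S %*% cyv))
      rc <- phys_to_index(mv_img, pos)
      list(cxv = cxv, cyv = cyv, rc = rc,
           r = bilinear_sample(mval, rc, fill = 0) - fv)
    }
    pen_scale <- lambda / (nctrl * grid_spacing_um^2)  # dimensionless bending term
    obj <- function(cc) {
      p <- eval_parts(cc)
      mean(p$r^2) +
        pen_scale * (sum((L %*% p$cxv)^2) + sum((L %*% p$cyv)^2))
    }
    grad <- function(cc) {
      p <- eval_parts(cc)
      gxs <- bilinear_sample(gx, p$rc, fill = 0)
      gys <- bilinear_sample(gy, p$rc, fill = 0)
      c(as.vector(StT %*% (2 * p$r * gxs)) / npx +
          pen_scale * 2 * as.vector(LtL %*% p$cxv),
        as.vector(StT %*% (2 * p$r * gys)) / npx +
          pen_scale * 2 * as.vector(LtL %*% p$cyv))
    }
    stats::optim(cc0, obj, grad, method = "L-BFGS-B",
                 control = list(maxit = iters, factr = 1e5, pgtol = 0))$par
  }

  pyr_f <- build_pyramid(fixed, n_levels)
  pyr_m <- build_pyramid(moving, n_levels)
  nl <- min(length(pyr_f), length(pyr_m))
  cc <- rep(0, 2 * nctrl)
  for (l in seq_len(nl)) {
    cc <- fit_level(pyr_f[[l]], pyr_m[[l]], cc,
                    if (l < nl) ceiling(maxit / 2) else maxit)
  }
  ctrl_dx <- matrix(cc[seq_len(nctrl)], ncy, ncx)
  ctrl_dy <- matrix(cc[nctrl + seq_len(nctrl)], ncy, ncx)
  fw <- bspline_transform(ctrl_dx, ctrl_dy, grid_spacing_um, c(ox, oy),
                          init = init_inv,
                          source = fixed$frame, target = moving$frame)
  # fold check: Jacobian of (q + u(q)) on a coarse sample
  samp <- q_full[seq(1, nrow(q_full), length.out = min(400, nrow(q_full))), , drop = FALSE]
  h <- grid_spacing_um / 10
  u0 <- bspline_displacement(fw, samp)
  uxp <- bspline_displacement(fw, sweep(samp, 2, c(h, 0), "+"))
  uyp <- bspline_displacement(fw, sweep(samp, 2, c(0, h), "+"))
  j11 <- 1 + (uxp[, 1] - u0[, 1]) / h; j12 <- (uyp[, 1] - u0[, 1]) / h
  j21 <- (uxp[, 2] - u0[, 2]) / h; j22 <- 1 + (uyp[, 2] - u0[, 2]) / h
  if (any(j11 * j22 - j12 * j21 <= 0)) {
    fw$fold_warning <- TRUE
    warning("deformation folds (negative Jacobian) somewhere in the field")
  }
  invert_transform(fw)  # moving -> fixed
}

# ---- IMC ablation region ---------------------------------------------------

rgb_saturation <- function(img) {
  v <- img$values
  stopifnot(length(dim(v)) == 3L, dim(v)[3] >= 3)
  mx <- pmax(v[, , 1], v[, , 2], v[, , 3])
  mn <- pmin(v[, , 1], v[, , 2], v[, , 3])
  s <- ifelse(mx > 0, (mx - mn) / mx, 0)
  phys_image(s, img$pixelsize_um, img$frame)
}

#' Detect the IMC ablation region on a PostIMC scan
#'
#' The ablated square appears desaturated against the stained tissue:
#' the saturation channel of the HSV representation is thresholded
#' (Otsu), the mask morphologically closed, and the connected component
#' whose area best matches the known IMC acquisition area is kept.
#'
#' @param postimc RGB [phys_image].
#' @param expected_area_um2 known IMC acquisition area.
#' @param area_tol relative area tolerance for accepting a component.
#' @param closing_radius_um morphological closing radius.
#' @return Binary [phys_image] mask of the ablation region.
#' @export
detect_imc_ablation_region <- function(postimc, expected_area_um2,
                                       area_tol = 0.3, closing_radius_um = 5) {
  sat <- rgb_saturation(postimc)
  thr <- EBImage::otsu(EBImage::Image(sat$values), range = c(0, 1))
  mask <- sat$values < thr
  r_px <- max(1, round(closing_radius_um / postimc$pixelsize_um))
  kern <- EBImage::makeBrush(2 * r_px + 1, shape = "disc")
  mask <- EBImage::closing(EBImage::Image(mask * 1), kern)@.Data > 0
  lab <- label_components(mask)
  labv <- as.integer(lab@.Data)
  if (!any(labv > 0)) stop("no desaturated component found")
  areas <- table(labv[labv > 0]) * postimc$pixelsize_um^2
  rel <- abs(as.numeric(areas) / expected_area_um2 - 1)
  ok <- which(rel <= area_tol)
  if (!length(ok)) {
    stop(sprintf("no component within %.0f%% of the expected area (best: %.0f%% off)",
                 100 * area_tol, 100 * min(rel)))
  }
  keep <- as.integer(names(areas)[ok[which.min(rel[ok])]])
  out <- matrix(0, nrow(mask), ncol(mask))
  out[labv == keep] <- 1
  phys_image(out, postimc$pixelsize_um, postimc$frame)
}

# inverse-distance image: 0 off the mask, maximal at the mask boundary
inverse_distance_image <- function(mask_img) {
  m <- mask_img$values > 0
  d <- EBImage::distmap(EBImage::Image(m * 1))@.Data
  out <- ifelse(d > 0, 1 / d, 0)
  phys_image(out, mask_img$pixelsize_um, mask_img$frame)
}

# boundary pixel centres of a binary mask, subsampled to ~spacing um
mask_boundary_points <- function(mask_img, spacing_um = 2 * mask_img$pixelsize_um) {
  m <- mask_img$values > 0
  er <- EBImage::erode(EBImage::Image(m * 1), EBImage::makeBrush(3, "box"))@.Data > 0
  b <- which(m & !er)
  d <- dim(m)
  rows <- (b - 1L) %% d[1] + 1L
  cols <- (b - 1L) %/% d[1] + 1L
  px <- mask_img$pixelsize_um
  P <- cbind(x = (cols - 0.5) * px, y = (rows - 0.5) * px)
  k <- max(1L, round(spacing_um / px))
  o <- order(atan2(P[, 2] - mean(P[, 2]), P[, 1] - mean(P[, 1])))
  P[o, , drop = FALSE][seq(1, nrow(P), by = k), , drop = FALSE]
}

principal_axis_init <- function(moving_mask, fixed_mask) {
  ax <- function(img) {
    idx <- which(img$values > 0)
    d <- dim(img$values)
    px <- img$pixelsize_um
    X <- cbind(((idx - 1L) %/% d[1]) * px + px / 2,
               ((idx - 1L) %% d[1]) * px + px / 2)
    e <- eigen(stats::cov(X), symmetric = TRUE)
    list(ctr = colMeans(X), dir = e$vectors[, 1])
  }
  a <- ax(moving_mask); b <- ax(fixed_mask)
  th <- atan2(b$dir[2], b$dir[1]) - atan2(a$dir[2], a$dir[1])
  th <- ((th * 180 / pi + 90) %% 180) - 90  # axis, not direction
  tf <- rigid_transform(th, 0, 0, center = a$ctr,
                        source = moving_mask$frame, target = fixed_mask$frame)
  tf$M[1:2, 3] <- tf$M[1:2, 3] + (b$ctr - transform_points(tf, rbind(a$ctr))[1, ])
  tf
}

#' Register the IMC acquisition into the PostIMC ablation region
#'
#' Builds inverse-distance images (zero off the mask, maximal at the
#' boundary) of the IMC footprint and the detected ablation region,
#' estimates an Euler (rotation + translation) transform between them,
#' and optionally refines it with coherent point drift on regularly
#' spaced boundary points. If the Euler optimization cannot improve on
#' the identity, a centroid plus principal-axis alignment is used and
#' flagged.
#'
#' @param imc_mask binary [phys_image] of the IMC footprint (IMC frame).
#' @param ablation_mask binary [phys_image] from
#'   [detect_imc_ablation_region()] (PostIMC frame).
#' @param refine run the CPD boundary refinement.
#' @param manual_roi optional polygon (two-column matrix, um, PostIMC
#'   frame): the IMC rectangle is rigidly fitted into it (closed form)
#'   and no intensity optimization is run.
#' @return List: `transform` (IMC -> PostIMC), `boundary_dist_before`,
#'   `boundary_dist_after` (um, per boundary point), `fallback` flag.
#' @export
register_imc_to_postimc <- function(imc_mask, ablation_mask, refine = TRUE,
                                    manual_roi = NULL) {
  stopifnot(any(imc_mask$values > 0))
  if (!is.null(manual_roi)) {
    roi_img <- polygon_to_mask(manual_roi, ablation_mask)
    tf <- principal_axis_init(imc_mask, roi_img)
    tf$model <- "manual-roi"
    bp <- mask_boundary_points(imc_mask)
    return(list(transform = tf,
                boundary_dist_before = boundary_dists(bp, roi_img),
                boundary_dist_after = boundary_dists(transform_points(tf, bp), roi_img),
                fallback = FALSE))
  }
  stopifnot(any(ablation_mask$values > 0))
  idt_m <- inverse_distance_image(imc_mask)
  idt_f <- inverse_distance_image(ablation_mask)
  fallback <- FALSE
  tf <- tryCatch(
    withCallingHandlers(
      register_affine(idt_f, idt_m, model = "euler"),
      warning = function(w) {
        if (grepl("identity", conditionMessage(w))) fallback <<- TRUE
        invokeRestart("muffleWarning")
      }),
    error = function(e) { fallback <<- TRUE; NULL })
  if (fallback || is.null(tf)) {
    tf <- principal_axis_init(imc_mask, ablation_mask)
    fallback <- TRUE
  }
  bp <- mask_boundary_points(imc_mask)
  before <- boundary_dists(bp, ablation_mask)
  if (refine) {
    bp_f <- mask_boundary_points(ablation_mask)
    bp_moved <- transform_points(tf, bp)
    cpd <- tryCatch(
      cpd_register(bp_moved, bp_f, model = "rigid",
                   source_frame = tf$target, target_frame = tf$target),
      error = function(e) NULL)
    if (!is.null(cpd)) {
      # accept the refinement only if it actually tightens the boundary
      cand <- compose_chain(tf, cpd)$transforms[[1]]
      # require a clear improvement: at sub-pixel residuals the CPD can
      # chase boundary pixelation instead of true pose
      if (stats::median(boundary_dists(transform_points(cand, bp), ablation_mask)) <
            0.9 * stats::median(boundary_dists(bp_moved, ablation_mask))) {
        tf <- cand
      }
    }
  }
  after <- boundary_dists(transform_points(tf, bp), ablation_mask)
  list(transform = tf, boundary_dist_before = before,
       boundary_dist_after = after, fallback = fallback)
}

# distance of points to the nearest boundary pixel of a mask
boundary_dists <- function(points_xy, mask_img) {
  bp <- mask_boundary_points(mask_img, spacing_um = mask_img$pixelsize_um)
  P <- as_xy_matrix(points_xy)
  d2 <- outer(rowSums(P^2), rep(1, nrow(bp))) +
    outer(rep(1, nrow(P)), rowSums(bp^2)) - 2 * P %*% t(bp)
  sqrt(pmax(apply(d2, 1, min), 0))
}

# rasterize a polygon (um coordinates) onto the geometry of a template image
polygon_to_mask <- function(poly, template) {
  P <- as_xy_matrix(poly)
  d <- dim(template$values)
  ctr <- pixel_centers(template)
  inside <- point_in_polygon(ctr$x, ctr$y, P)
  phys_image(matrix(as.numeric(inside), d[1], d[2]),
             template$pixelsize_um, template$frame)
}

point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}
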