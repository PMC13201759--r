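# Registration precision metrics: median landmark distance, DICE,
# automatic landmark extraction/matching, FFT grid-artifact
# suppression, Hu-moment region matching, nuclei-overlap evaluation.

#' Median landmark distance
#'
#' The median of the Euclidean distances between paired landmarks:
#' middle element for odd counts, mean of the two middle elements for
#' even counts.
#'
#' @param pairs a data frame with columns `x1`, `y1`, `x2`, `y2` (um) or
#'   a numeric vector of precomputed distances.
#' @return MLD in micrometres.
#' @export
mld <- function(pairs) {
  d <- if (is.numeric(pairs)) pairs else {
    sqrt((pairs$x1 - pairs$x2)^2 + (pairs$y1 - pairs$y2)^2)
  }
  if (length(d) == 0) stop("no landmark pairs")
  d <- sort(d)
  n <- length(d)
  if (n %% 2 == 1) d[(n + 1) / 2] else (d[n / 2] + d[n / 2 + 1]) / 2
}

#' DICE coefficient of two binary masks
#'
#' `2 |S and T| / (|S| + |T|)`. Two empty masks agree perfectly (1);
#' one empty mask gives 0.
#'
#' @param S,T binary matrices (or [phys_image]s) of identical shape.
#' @return DICE in `[0, 1]`.
#' @export
dice <- function(S, T) {
  if (inherits(S, "phys_image")) S <- S$values
  if (inherits(T, "phys_image")) T <- T$values
  if (!all(dim(S) == dim(T))) stop("mask shapes differ")
  s <- S > 0; t <- T > 0
  ns <- sum(s); nt <- sum(t)
  if (ns + nt == 0) return(1)
  2 * sum(s & t) / (ns + nt)
}

#' Registration QC report entry
#'
#' @param link name of the registration step.
#' @param mld_um median landmark distance.
#' @param dice_val DICE coefficient (or `NA`).
#' @param n_landmarks number of landmark pairs the MLD is based on.
#' @param min_landmarks exclusion threshold: results based on fewer
#'   landmarks are flagged `excluded`.
#' @return A one-row tibble of class `qc_report`.
#' @export
qc_report <- function(link, mld_um, dice_val = NA_real_, n_landmarks,
                      min_landmarks = 100) {
  out <- tibble::tibble(link = link, mld_um = mld_um, dice = dice_val,
                        n_landmarks = as.integer(n_landmarks),
                        excluded = n_landmarks < min_landmarks)
  class(out) <- c("qc_report", class(out))
  out
}

# ---- automatic landmarks ---------------------------------------------------

gaussian_blur <- function(m, sigma_px) {
  EBImage::gblur(EBImage::Image(m), sigma = sigma_px)@.Data
}

# difference-of-Gaussian keypoints with sub-pixel quadratic refinement
dog_keypoints <- function(img, sigmas = c(1.2, 2.0, 3.2), tile_px = 64,
                          per_tile = 12, contrast_k = 1.5) {
  m <- img$values
  px <- img$pixelsize_um
  kps <- NULL
  for (s in sigmas) {
    D <- gaussian_blur(m, s) - gaussian_blur(m, s * 1.6)
    thr <- contrast_k * stats::sd(D)
    for (sign_d in c(1, -1)) {
      Ds <- sign_d * D
      ismax <- Ds > neighbor_max8(Ds) & Ds > thr
      idx <- which(ismax)
      if (!length(idx)) next
      d <- dim(m)
      rows <- (idx - 1L) %% d[1] + 1L
      cols <- (idx - 1L) %/% d[1] + 1L
      interior <- rows > 1 & rows < d[1] & cols > 1 & cols < d[2]
      rows <- rows[interior]; cols <- cols[interior]; idx <- idx[interior]
      if (!length(idx)) next
      # quadratic sub-pixel refinement along each axis
      cpos <- Ds[idx]
      up <- Ds[cbind(rows - 1, cols)]; dn <- Ds[cbind(rows + 1, cols)]
      lf <- Ds[cbind(rows, cols - 1)]; rt <- Ds[cbind(rows, cols + 1)]
      dr <- ifelse(abs(up - 2 * cpos + dn) > 1e-12,
                   0.5 * (up - dn) / (up - 2 * cpos + dn), 0)
      dc <- ifelse(abs(lf - 2 * cpos + rt) > 1e-12,
                   0.5 * (lf - rt) / (lf - 2 * cpos + rt), 0)
      dr <- pmax(pmin(dr, 0.5), -0.5); dc <- pmax(pmin(dc, 0.5), -0.5)
      kps <- rbind(kps, data.frame(
        x = (cols + dc - 0.5) * px, y = (rows + dr - 0.5) * px,
        response = cpos, sigma = s))
    }
  }
  if (is.null(kps)) return(data.frame(x = numeric(), y = numeric(),
                                      response = numeric(), sigma = numeric()))
  # per-tile cap spreads keypoints over the image
  tx <- floor(kps$x / (tile_px * px)); ty <- floor(kps$y / (tile_px * px))
  kps$tile <- paste(tx, ty)
  kps <- do.call(rbind, lapply(split(kps, kps$tile), function(g) {
    g[order(-g$response), ][seq_len(min(per_tile, nrow(g))), ]
  }))
  rownames(kps) <- NULL
  kps[, c("x", "y", "response", "sigma")]
}

# z-scored bilinear patch descriptor around each keypoint
patch_descriptors <- function(img, kps, half = 5) {
  m <- img$values
  px <- img$pixelsize_um
  offs <- expand.grid(dr = -half:half, dc = -half:half)
  n <- nrow(kps)
  desc <- matrix(0, n, nrow(offs))
  for (i in seq_len(n)) {
    r0 <- kps$y[i] / px + 0.5; c0 <- kps$x[i] / px + 0.5
    v <- bilinear_sample(m, cbind(r0 + offs$dr, c0 + offs$dc), fill = mean(m))
    s <- stats::sd(v)
    desc[i, ] <- if (s > 0) (v - mean(v)) / s else 0
  }
  desc
}

fit_affine_ls <- function(src, dst) {
  # least-squares affine src -> dst; needs >= 3 non-collinear points
  X <- cbind(src, 1)
  cf <- tryCatch(qr.solve(X, dst), error = function(e) NULL)
  if (is.null(cf)) return(NULL)
  affine_transform(t(cf[1:2, , drop = FALSE]), cf[3, ])
}

# robust affine inlier selection: progressive (quality-ordered) sampling
# with threshold-marginalized scoring
ransac_affine <- function(src, dst, quality, n_iter = 500,
                          thresholds = c(1, 2, 4, 8), seed = 1L) {
  n <- nrow(src)
  if (n < 4) return(list(inlier = rep(TRUE, n)))
  o <- order(quality)  # best first
  best_score <- -Inf; best_res <- NULL
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  for (it in seq_len(n_iter)) {
    # progressive pool: early iterations sample among the best-quality pairs
    pool_n <- min(n, max(4, ceiling(n * it / n_iter) + 3))
    take <- sample(o[seq_len(pool_n)], 3)
    tf <- fit_affine_ls(src[take, , drop = FALSE], dst[take, , drop = FALSE])
    if (is.null(tf)) next
    pred <- transform_points(tf, src)
    res <- sqrt(rowSums((pred - dst)^2))
    score <- sum(vapply(thresholds, function(th) sum(res < th) / th, 0))
    if (score > best_score) { best_score <- score; best_res <- res }
  }
  if (is.null(best_res)) return(list(inlier = rep(TRUE, n)))
  inlier <- best_res < max(thresholds)
  # refit on the consensus and re-score once
  if (sum(inlier) >= 3) {
    tf <- fit_affine_ls(src[inlier, , drop = FALSE], dst[inlier, , drop = FALSE])
    if (!is.null(tf)) {
      res <- sqrt(rowSums((transform_points(tf, src) - dst)^2))
      inlier <- res < max(thresholds)
    }
  }
  list(inlier = inlier)
}

#' Automatically extract and match landmarks between two aligned images
#'
#' Scale-space (difference-of-Gaussian) keypoints are detected in tiles,
#' described by normalized intensity patches, and matched with the
#' following gates, in order: physical distance below `max_pair_dist`
#' (the images are already registered, so true pairs are close);
#' descriptor nearest/second-nearest ratio below `ratio`; one-to-one by
#' best descriptor distance; minimum spacing `min_spacing` between kept
#' points on the same image; robust affine inlier selection
#' (progressive-sampling RANSAC with threshold-marginalized scoring).
#'
#' @param img_a,img_b single-channel [phys_image]s in a common frame.
#' @param max_pair_dist physical gate (um).
#' @param ratio descriptor ratio-test threshold.
#' @param min_spacing same-image minimum spacing (um).
#' @param tile_px detection tile size in pixels.
#' @return A tibble of class `landmark_pairs` with columns `x1`, `y1`,
#'   `x2`, `y2`, `dist`, `descr_dist`, `inlier`; empty (with a `reason`
#'   attribute) when fewer than 4 candidates survive.
#' @export
auto_landmarks <- function(img_a, img_b, max_pair_dist = 50, ratio = 0.8,
                           min_spacing = 10, tile_px = 64) {
  img_a <- to_gray(img_a); img_b <- to_gray(img_b)
  ka <- dog_keypoints(img_a, tile_px = tile_px)
  kb <- dog_keypoints(img_b, tile_px = tile_px)
  empty <- tibble::tibble(x1 = numeric(), y1 = numeric(), x2 = numeric(),
                          y2 = numeric(), dist = numeric(),
                          descr_dist = numeric(), inlier = logical())
  class(empty) <- c("landmark_pairs", class(empty))
  if (nrow(ka) < 4 || nrow(kb) < 4) {
    attr(empty, "reason") <- "fewer than 4 keypoints"
    return(empty)
  }
  da <- patch_descriptors(img_a, ka)
  db <- patch_descriptors(img_b, kb)
  # physical gate
  pd2 <- outer(ka$x^2 + ka$y^2, rep(1, nrow(kb))) +
    outer(rep(1, nrow(ka)), kb$x^2 + kb$y^2) -
    2 * (cbind(ka$x, ka$y) %*% t(cbind(kb$x, kb$y)))
  close_enough <- pd2 <= max_pair_dist^2
  dd <- sqrt(pmax(outer(rowSums(da^2), rep(1, nrow(db))) +
                    outer(rep(1, nrow(da)), rowSums(db^2)) - 2 * da %*% t(db), 0))
  dd[!close_enough] <- Inf
  cand <- NULL
  for (i in seq_len(nrow(ka))) {
    v <- dd[i, ]
    o <- order(v)[1:2]
    if (!is.finite(v[o[1]])) next
    r <- if (is.finite(v[o[2]]) && v[o[2]] > 0) v[o[1]] / v[o[2]] else 0
    if (r < ratio) cand <- rbind(cand, data.frame(a = i, b = o[1], dd = v[o[1]]))
  }
  if (is.null(cand) || nrow(cand) < 4) {
    attr(empty, "reason") <- "fewer than 4 candidates after ratio test"
    return(empty)
  }
  # one-to-one: keep the best pair per b-keypoint
  cand <- cand[order(cand$dd), ]
  cand <- cand[!duplicated(cand$b), ]
  # same-image spacing (greedy, best first)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    prev <- cand[keep, , drop = FALSE]
    d_a <- sqrt((ka$x[cand$a[i]] - ka$x[prev$a])^2 +
                  (ka$y[cand$a[i]] - ka$y[prev$a])^2)
    d_b <- sqrt((kb$x[cand$b[i]] - kb$x[prev$b])^2 +
                  (kb$y[cand$b[i]] - kb$y[prev$b])^2)
    keep[i] <- all(d_a >= min_spacing) && all(d_b >= min_spacing)
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) < 4) {
    attr(empty, "reason") <- "fewer than 4 candidates after spacing"
    return(empty)
  }
  src <- cbind(ka$x[cand$a], ka$y[cand$a])
  dst <- cbind(kb$x[cand$b], kb$y[cand$b])
  rs <- ransac_affine(src, dst, cand$dd)
  out <- tibble::tibble(
    x1 = src[, 1], y1 = src[, 2], x2 = dst[, 1], y2 = dst[, 2],
    dist = sqrt(rowSums((src - dst)^2)),
    descr_dist = cand$dd, inlier = rs$inlier)
  class(out) <- c("landmark_pairs", class(out))
  out
}

# ---- FFT grid-artifact suppression -----------------------------------------

fftshift2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  sr <- c((floor(nr / 2) + 1):nr, 1:floor(nr / 2))
  sc <- c((floor(nc / 2) + 1):nc, 1:floor(nc / 2))
  m[sr, sc]
}
ifftshift2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  sr <- c((nr - floor(nr / 2) + 1):nr, 1:(nr - floor(nr / 2)))
  sc <- c((nc - floor(nc / 2) + 1):nc, 1:(nc - floor(nc / 2)))
  m[sr, sc]
}

#' Suppress a periodic ablation-grid artifact in the frequency domain
#'
#' The image is Fourier-transformed; magnitude peaks are found by
#' thresholding the difference between the magnitude and a local-mean
#' threshold image at its 99% quantile, never touching the centre (DC)
#' region; the peak mask is median-filtered, dilated, and the masked
#' magnitudes replaced with the local mean magnitude before inverting
#' the transform with the original phase.
#'
#' @param postmsi_gray single-channel [phys_image].
#' @param q peak quantile.
#' @param local_radius_frac local-mean radius as a fraction of the
#'   smaller image dimension.
#' @param center_exclude_px radius of the protected DC region.
#' @return A [phys_image] with the periodic component attenuated.
#' @export
suppress_grid_artifact <- function(postmsi_gray, q = 0.99,
                                   local_radius_frac = 0.01,
                                   center_exclude_px = 4) {
  stopifnot(inherits(postmsi_gray, "phys_image"))
  m <- postmsi_gray$values
  FF <- stats::fft(m)
  magS <- fftshift2(Mod(FF))
  r <- max(2, round(local_radius_frac * min(dim(m))))
  offs <- kernel_offsets("disk", r)
  local_mean <- local_mean_filter(magS, offs)
  diffm <- magS - local_mean
  thr <- stats::quantile(diffm, q)
  # a flagged location must both clear the quantile threshold and stand
  # well above its local level, so smooth aperiodic spectra stay intact
  peak <- diffm > thr & magS > 3 * local_mean
  cr <- floor(nrow(m) / 2) + 1; cc <- floor(ncol(m) / 2) + 1
  rr <- row(magS) - cr; ccd <- col(magS) - cc
  peak[rr^2 + ccd^2 <= center_exclude_px^2] <- FALSE
  # clean: 3x3 median (majority) then dilation
  pm <- local_mean_filter(peak * 1, kernel_offsets("square", 1)) > 0.5
  pm <- pm | peak
  pm <- local_mean_filter(pm * 1, kernel_offsets("disk", 2)) > 1e-9  # dilate
  pm[rr^2 + ccd^2 <= center_exclude_px^2] <- FALSE
  magS[pm] <- local_mean[pm]
  newmag <- ifftshift2(magS)
  FF2 <- complex(modulus = newmag, argument = Arg(FF))
  out <- Re(stats::fft(matrix(FF2, nrow(m)), inverse = TRUE)) / length(m)
  phys_image(out, postmsi_gray$pixelsize_um, postmsi_gray$frame)
}

# ---- Hu-moment region matching ---------------------------------------------

#' Hu invariant moments of a point set / region
#'
#' @param xs,ys pixel-centre coordinates of the region's pixels (um).
#' @return Numeric vector of the seven Hu moments.
#' @export
hu_moments <- function(xs, ys) {
  n <- length(xs)
  xb <- mean(xs); yb <- mean(ys)
  mu <- function(p, q) sum((xs - xb)^p * (ys - yb)^q)
  m00 <- n
  eta <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  h1 <- n20 + n02
  h2 <- (n20 - n02)^2 + 4 * n11^2
  h3 <- (n30 - 3 * n12)^2 + (3 * n21 - n03)^2
  h4 <- (n30 + n12)^2 + (n21 + n03)^2
  h5 <- (n30 - 3 * n12) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
    (3 * n21 - n03) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2)
  h6 <- (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
    4 * n11 * (n30 + n12) * (n21 + n03)
  h7 <- (3 * n21 - n03) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
    (n30 - 3 * n12) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2)
  c(h1, h2, h3, h4, h5, h6, h7)
}

region_props <- function(mask_img) {
  m <- mask_img$values
  px <- mask_img$pixelsize_um
  labs <- sort(unique(as.vector(m))); labs <- labs[labs > 0]
  purrr::map_dfr(labs, function(l) {
    idx <- which(m == l)
    d <- dim(m)
    rows <- (idx - 1L) %% d[1] + 1L
    cols <- (idx - 1L) %/% d[1] + 1L
    xs <- (cols - 0.5) * px; ys <- (rows - 0.5) * px
    hu <- hu_moments(xs, ys)
    tibble::tibble(label = l, area_um2 = length(idx) * px^2,
                   cx = mean(xs), cy = mean(ys), hu = list(hu))
  })
}

#' Match tissue regions between two label masks by shape
#'
#' Regions within the admissible area window are paired when their areas
#' agree within a factor 1.5, their centroids lie within 50 um, they
#' overlap (DICE > 0), choosing per region the candidate minimizing the
#' summed absolute difference of the seven Hu invariant moments,
#' one-to-one.
#'
#' @param masks_a,masks_b integer label [phys_image]s in a common frame.
#' @param area_range admissible region area window (um^2).
#' @param max_centroid_dist centroid gate (um).
#' @param max_log10_area_ratio area-similarity gate.
#' @return A tibble of class `region_matches`: labels, areas, `I`
#'   (Hu-moment distance), centroid distance and DICE per accepted pair.
#' @export
match_regions <- function(masks_a, masks_b,
                          area_range = c(36^2, 512^2),
                          max_centroid_dist = 50,
                          max_log10_area_ratio = log10(1.5)) {
  pa <- region_props(masks_a)
  pb <- region_props(masks_b)
  pa <- pa[pa$area_um2 >= area_range[1] & pa$area_um2 <= area_range[2], ]
  pb <- pb[pb$area_um2 >= area_range[1] & pb$area_um2 <= area_range[2], ]
  out <- tibble::tibble(label_a = numeric(), label_b = numeric(),
                        area_a = numeric(), area_b = numeric(),
                        I = numeric(), centroid_dist = numeric(),
                        dice = numeric())
  class(out) <- c("region_matches", class(out))
  if (nrow(pa) == 0 || nrow(pb) == 0) return(out)
  cand <- NULL
  for (i in seq_len(nrow(pa))) for (j in seq_len(nrow(pb))) {
    if (abs(log10(pa$area_um2[i] / pb$area_um2[j])) >= max_log10_area_ratio) next
    cd <- sqrt((pa$cx[i] - pb$cx[j])^2 + (pa$cy[i] - pb$cy[j])^2)
    if (cd > max_centroid_dist) next
    dc <- dice(masks_a$values == pa$label[i], masks_b$values == pb$label[j])
    if (dc <= 0) next
    I <- sum(abs(pa$hu[[i]] - pb$hu[[j]]))
    cand <- rbind(cand, data.frame(i = i, j = j, I = I, cd = cd, dc = dc))
  }
  if (is.null(cand)) return(out)
  cand <- cand[order(cand$I), ]
  used_i <- used_j <- integer()
  for (k in seq_len(nrow(cand))) {
    if (cand$i[k] %in% used_i || cand$j[k] %in% used_j) next
    used_i <- c(used_i, cand$i[k]); used_j <- c(used_j, cand$j[k])
    out <- dplyr::bind_rows(out, tibble::tibble(
      label_a = pa$label[cand$i[k]], label_b = pb$label[cand$j[k]],
      area_a = pa$area_um2[cand$i[k]], area_b = pb$area_um2[cand$j[k]],
      I = cand$I[k], centroid_dist = cand$cd[k], dice = cand$dc[k]))
  }
  class(out) <- c("region_matches", class(out))
  out
}

#' Evaluate a registration by nuclei overlap
#'
#' Only nuclei that overlap in both label masks are used: overlapping
#' label pairs are matched one-to-one by maximum overlap, the MLD is the
#' median distance between paired centroids, and the DICE coefficient is
#' computed over the union of the paired nuclei.
#'
#' @param nuclei_a,nuclei_b integer label [phys_image]s in a common
#'   frame.
#' @param link name recorded in the report.
#' @return A [qc_report] row.
#' @export
nuclei_overlap_eval <- function(nuclei_a, nuclei_b, link = "IMC-to-PostIMC") {
  a <- nuclei_a$values; b <- nuclei_b$values
  stopifnot(all(dim(a) == dim(b)))
  both <- a > 0 & b > 0
  if (!any(both)) return(qc_report(link, NA_real_, NA_real_, 0))
  ov <- table(a[both], b[both])
  pairs <- NULL
  tab <- as.data.frame(ov, stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, ]
  tab <- tab[order(-tab$Freq), ]
  used_a <- used_b <- character()
  for (k in seq_len(nrow(tab))) {
    if (tab$Var1[k] %in% used_a || tab$Var2[k] %in% used_b) next
    used_a <- c(used_a, tab$Var1[k]); used_b <- c(used_b, tab$Var2[k])
    pairs <- rbind(pairs, tab[k, ])
  }
  pa <- region_props(nuclei_a); pb <- region_props(nuclei_b)
  la <- as.numeric(pairs$Var1); lb <- as.numeric(pairs$Var2)
  ia <- match(la, pa$label); ib <- match(lb, pb$label)
  d <- sqrt((pa$cx[ia] - pb$cx[ib])^2 + (pa$cy[ia] - pb$cy[ib])^2)
  dc <- dice(matrix(a %in% la, nrow(a)), matrix(b %in% lb, nrow(b)))
  qc_report(link, mld(d), dc, length(d))
}

#' MLD between centroids of matched tissue masks
#'
#' @param tissue_masks_a,tissue_masks_b equal-length lists of binary
#'   [phys_image]s, matched by position.
#' @return MLD (um).
#' @export
centroid_mld <- function(tissue_masks_a, tissue_masks_b) {
  if (length(tissue_masks_a) != length(tissue_masks_b)) {
    stop("mask lists have different lengths")
  }
  d <- vapply(seq_along(tissue_masks_a), function(i) {
    ca <- mask_centroid(tissue_masks_a[[i]])
    cb <- mask_centroid(tissue_masks_b[[i]])
    sqrt(sum((ca - cb)^2))
  }, 0)
  mld(d)
}

#' Otsu tissue mask of a brightfield image
#'
#' Default backend for tissue-mask extraction: tissue is darker than the
#' slide background, so the mask is the below-threshold region after
#' morphological closing.
#'
#' @param img single-channel or RGB [phys_image].
#' @param closing_radius_um morphological closing radius.
#' @return Binary [phys_image].
#' @export
tissue_mask <- function(img, closing_radius_um = 10) {
  g <- to_gray(img)
  v <- g$values
  rng <- range(v)
  vn <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
  thr <- EBImage::otsu(EBImage::Image(vn), range = c(0, 1))
  m <- vn < thr
  r_px <- max(1, round(closing_radius_um / g$pixelsize_um))
  m <- EBImage::closing(EBImage::Image(m * 1),
                        EBImage::makeBrush(2 * r_px + 1, "disc"))@.Data > 0
  phys_image(m * 1, g$pixelsize_um, g$frame)
}

#' Write a QC overlay PNG
#'
#' Renders a grayscale image with detected points (e.g. ablation-mark
#' centroids or landmark positions) marked in red, for visual
#' inspection of a registration step.
#'
#' @param img single-channel [phys_image].
#' @param points_xy two-column matrix or data frame with `x`, `y` (um).
#' @param path output PNG path.
#' @param radius_px marker radius in image pixels.
#' @return `path`, invisibly.
#' @export
write_qc_overlay <- function(img, points_xy, path, radius_px = 2) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required to write overlay PNGs")
  }
  g <- to_gray(img)
  v <- g$values
  rng <- range(v)
  vn <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
  rgb <- array(vn, c(nrow(vn), ncol(vn), 3))
  P <- as_xy_matrix(points_xy)
  rc <- round(phys_to_index(g, P))
  offs <- kernel_offsets("disk", radius_px)
  for (i in seq_len(nrow(rc))) {
    rr <- rc[i, 1] + offs$dr; cc <- rc[i, 2] + offs$dc
    ok <- rr >= 1 & rr <= nrow(vn) & cc >= 1 & cc <= ncol(vn)
    rgb[cbind(rr[ok], cc[ok], 1)] <- 1
    rgb[cbind(rr[ok], cc[ok], 2)] <- 0
    rgb[cbind(rr[ok], cc[ok], 3)] <- 0
  }
  png::writePNG(rgb, path)
  invisible(path)
}
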