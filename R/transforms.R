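#' Affine transforms between named coordinate frames
#'
#' Transforms map micrometre coordinates of the *source* frame onto the
#' *target* frame (y-down, origin at the slide-scan top-left). An affine
#' transform is stored as a 3x3 homogeneous matrix acting on column
#' vectors `(x, y, 1)'`.
#'
#' @param A 2x2 linear part.
#' @param t length-2 translation (micrometres).
#' @param source,target frame names.
#' @return An object of class `affine_transform`.
#' @seealso [rigid_transform()], [compose_chain()], [transform_points()]
#' @export
affine_transform <- function(A = diag(2), t = c(0, 0), source = "source",
                             target = "target") {
  stopifnot(is.matrix(A), all(dim(A) == 2), length(t) == 2)
  M <- rbind(cbind(A, matrix(t, 2)), c(0, 0, 1))
  structure(list(M = M, source = source, target = target),
            class = "affine_transform")
}

#' Rigid (Euler) transform: rotation followed by translation
#'
#' @param theta_deg rotation angle in degrees (positive = from +x towards
#'   +y, i.e. clockwise on a y-down display).
#' @param tx,ty translation in micrometres.
#' @param center optional rotation centre `(x, y)`; default origin.
#' @inheritParams affine_transform
#' @return An `affine_transform`.
#' @export
rigid_transform <- function(theta_deg = 0, tx = 0, ty = 0, center = c(0, 0),
                            source = "source", target = "target") {
  th <- theta_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  t <- c(tx, ty) + as.vector(center - R %*% center)
  affine_transform(R, t, source, target)
}

#' @exportS3Method base::print
print.affine_transform <- function(x, ...) {
  cat(sprintf("<affine_transform> %s -> %s\n", x$source, x$target))
  print(round(x$M, 6))
  invisible(x)
}

#' Map points through a transform or chain
#'
#' @param tf an `affine_transform`, `bspline_transform` or
#'   `transform_chain`.
#' @param xy a two-column matrix or a data frame with columns `x`, `y`
#'   (micrometres, in the transform's source frame).
#' @return A two-column matrix of transformed coordinates.
#' @export
transform_points <- function(tf, xy) UseMethod("transform_points")

as_xy_matrix <- function(xy) {
  if (is.data.frame(xy)) xy <- cbind(xy$x, xy$y)
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  storage.mode(xy) <- "double"
  colnames(xy) <- c("x", "y")
  xy
}

#' @export
transform_points.affine_transform <- function(tf, xy) {
  xy <- as_xy_matrix(xy)
  out <- t(tf$M %*% rbind(t(xy), 1))[, 1:2, drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

#' Invert a transform
#'
#' Affine transforms are inverted exactly; b-spline transforms by damped
#' fixed-point iteration on the displacement field (tolerance 0.01 um).
#'
#' @param tf a transform.
#' @return A transform mapping target-frame coordinates back to the source
#'   frame.
#' @export
invert_transform <- function(tf) UseMethod("invert_transform")

#' @export
invert_transform.affine_transform <- function(tf) {
  Mi <- solve(tf$M)
  structure(list(M = Mi, source = tf$target, target = tf$source),
            class = "affine_transform")
}

# ---- cubic b-spline free-form deformation ----------------------------------

# cubic B-spline basis values for fractional offsets t in [0,1)
bspline_basis <- function(t) {
  cbind((1 - t)^3 / 6,
        (3 * t^3 - 6 * t^2 + 4) / 6,
        (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6,
        t^3 / 6)
}

#' B-spline free-form deformation transform
#'
#' Represents `T(p) = q + u(q)` with `q = init(p)` and `u` a cubic
#' B-spline displacement field over a regular control grid in the target
#' frame. Used for non-linear registration between adjacent tissue
#' slices.
#'
#' @param ctrl_dx,ctrl_dy matrices of control-point displacements
#'   (micrometres), rows indexing y, columns indexing x.
#' @param spacing_um control grid spacing.
#' @param origin_um `(x, y)` of control point `[1, 1]`.
#' @param init affine transform applied before the deformation (identity
#'   by default).
#' @inheritParams affine_transform
#' @return An object of class `bspline_transform`.
#' @export
bspline_transform <- function(ctrl_dx, ctrl_dy, spacing_um, origin_um = c(0, 0),
                              init = NULL, source = "source", target = "target") {
  stopifnot(all(dim(ctrl_dx) == dim(ctrl_dy)), spacing_um > 0)
  if (is.null(init)) init <- affine_transform(source = source, target = target)
  structure(list(ctrl_dx = ctrl_dx, ctrl_dy = ctrl_dy, spacing_um = spacing_um,
                 origin_um = origin_um, init = init,
                 source = source, target = target, fold_warning = FALSE),
            class = "bspline_transform")
}

# evaluate the displacement field at physical points (n x 2)
bspline_displacement <- function(tf, xy) {
  xy <- as_xy_matrix(xy)
  ncp <- dim(tf$ctrl_dx)
  sx <- (xy[, 1] - tf$origin_um[1]) / tf$spacing_um
  sy <- (xy[, 2] - tf$origin_um[2]) / tf$spacing_um
  ix <- floor(sx); iy <- floor(sy)
  Bx <- bspline_basis(sx - ix)
  By <- bspline_basis(sy - iy)
  ux <- numeric(nrow(xy)); uy <- numeric(nrow(xy))
  for (a in 0:3) {
    ca <- pmin(pmax(ix + a, 1), ncp[2])  # clamp: field is flat past the grid
    for (b in 0:3) {
      rb <- pmin(pmax(iy + b, 1), ncp[1])
      w <- Bx[, a + 1] * By[, b + 1]
      idx <- cbind(rb, ca)
      ux <- ux + w * tf$ctrl_dx[idx]
      uy <- uy + w * tf$ctrl_dy[idx]
    }
  }
  cbind(ux, uy)
}

#' @export
transform_points.bspline_transform <- function(tf, xy) {
  q <- transform_points(tf$init, xy)
  out <- q + bspline_displacement(tf, q)
  colnames(out) <- c("x", "y")
  out
}

#' @exportS3Method base::print
print.bspline_transform <- function(x, ...) {
  cat(sprintf(
    "<bspline_transform> %s -> %s, %dx%d control grid @ %.3g um%s\n",
    x$source, x$target, nrow(x$ctrl_dx), ncol(x$ctrl_dx), x$spacing_um,
    if (isTRUE(x$fold_warning)) " [fold warning]" else ""))
  invisible(x)
}

#' @export
invert_transform.bspline_transform <- function(tf) {
  structure(list(forward = tf, source = tf$target, target = tf$source),
            class = c("inverse_bspline_transform"))
}

#' @export
invert_transform.inverse_bspline_transform <- function(tf) tf$forward

#' @export
transform_points.inverse_bspline_transform <- function(tf, xy) {
  # fixed point on q: q_{k+1} = y - u(q_k), then undo the affine init
  y <- as_xy_matrix(xy)
  fw <- tf$forward
  q <- y
  for (k in 1:100) {
    u <- bspline_displacement(fw, q)
    qn <- y - u
    if (max(abs(qn - q)) < 0.01) { q <- qn; break }
    q <- q + 0.8 * (qn - q)
  }
  out <- transform_points(invert_transform(fw$init), q)
  colnames(out) <- c("x", "y")
  out
}

# ---- chains ----------------------------------------------------------------

#' Compose transforms into a frame-to-frame chain
#'
#' Transforms are given in application order (first maps the chain source,
#' last lands in the chain target); adjacent frames must agree. Adjacent
#' affine links are collapsed into a single matrix so points pass through
#' the minimum number of maps.
#'
#' @param ... transforms, in application order.
#' @return A `transform_chain`.
#' @export
compose_chain <- function(...) {
  tfs <- list(...)
  if (length(tfs) == 1 && is.list(tfs[[1]]) && !inherits(tfs[[1]], c("affine_transform", "bspline_transform", "inverse_bspline_transform"))) {
    tfs <- tfs[[1]]
  }
  stopifnot(length(tfs) >= 1)
  for (i in seq_along(tfs)[-1]) {
    if (!identical(tfs[[i - 1]]$target, tfs[[i]]$source)) {
      stop(sprintf("missing link: chain reaches '%s' but next transform starts at '%s'",
                   tfs[[i - 1]]$target, tfs[[i]]$source))
    }
  }
  # collapse runs of affine links
  out <- list()
  for (tf in tfs) {
    n <- length(out)
    if (n > 0 && inherits(tf, "affine_transform") &&
        inherits(out[[n]], "affine_transform")) {
      out[[n]] <- structure(
        list(M = tf$M %*% out[[n]]$M, source = out[[n]]$source, target = tf$target),
        class = "affine_transform")
    } else {
      out[[length(out) + 1]] <- tf
    }
  }
  structure(list(transforms = out,
                 source = out[[1]]$source,
                 target = out[[length(out)]]$target),
            class = "transform_chain")
}

#' @exportS3Method base::print
print.transform_chain <- function(x, ...) {
  frames <- c(x$source, vapply(x$transforms, function(t) t$target, ""))
  cat("<transform_chain> ", paste(frames, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' @export
transform_points.transform_chain <- function(tf, xy) {
  out <- as_xy_matrix(xy)
  for (t in tf$transforms) out <- transform_points(t, out)
  colnames(out) <- c("x", "y")
  out
}

#' @export
invert_transform.transform_chain <- function(tf) {
  inv <- lapply(rev(tf$transforms), invert_transform)
  compose_chain(inv)
}

#' Resample an image through a transform (single interpolation)
#'
#' Every output pixel centre in the target frame is pulled back through
#' the inverse map and the source image sampled once: bilinear for
#' intensity images, nearest-neighbour for label masks.
#'
#' @param tf transform or chain mapping the image's frame to the target
#'   frame.
#' @param img a [phys_image] in the transform's source frame.
#' @param out_dim `c(rows, cols)` of the output raster.
#' @param out_pixelsize_um output pixel size (defaults to the input's).
#' @param interp `"bilinear"` or `"nearest"`.
#' @param fill value used outside the source image.
#' @return A [phys_image] in the target frame.
#' @export
transform_image <- function(tf, img, out_dim = dim(img$values)[1:2],
                            out_pixelsize_um = img$pixelsize_um,
                            interp = c("bilinear", "nearest"), fill = 0) {
  interp <- match.arg(interp)
  stopifnot(inherits(img, "phys_image"))
  inv <- invert_transform(tf)
  out_img <- phys_image(matrix(0, out_dim[1], out_dim[2]), out_pixelsize_um,
                        frame = tf$target)
  ctr <- pixel_centers(out_img)
  src_xy <- transform_points(inv, cbind(ctr$x, ctr$y))
  rc <- phys_to_index(img, src_xy)
  sample_one <- function(m) {
    v <- if (interp == "bilinear") bilinear_sample(m, rc, fill) else nn_sample(m, rc, fill)
    matrix(v, out_dim[1], out_dim[2])
  }
  v <- img$values
  if (length(dim(v)) == 3L) {
    res <- array(0, c(out_dim[1], out_dim[2], dim(v)[3]))
    for (k in seq_len(dim(v)[3])) res[, , k] <- sample_one(v[, , k])
    phys_image(res, out_pixelsize_um, tf$target, channels = img$channels)
  } else {
    phys_image(sample_one(v), out_pixelsize_um, tf$target)
  }
}

#' Serialize a transform to JSON (and back)
#'
#' @param tf a transform or chain.
#' @param path file path.
#' @return `write_transform_json` returns `path` invisibly;
#'   `read_transform_json` returns the transform.
#' @export
write_transform_json <- function(tf, path) {
  enc <- function(t) {
    if (inherits(t, "affine_transform")) {
      list(type = "affine", matrix = as.vector(t$M),
           source = t$source, target = t$target)
    } else if (inherits(t, "bspline_transform")) {
      list(type = "bspline",
           ctrl_dim = dim(t$ctrl_dx),
           ctrl_dx = as.vector(t$ctrl_dx), ctrl_dy = as.vector(t$ctrl_dy),
           spacing_um = t$spacing_um, origin_um = t$origin_um,
           init_matrix = as.vector(t$init$M),
           source = t$source, target = t$target)
    } else stop("unsupported transform type for serialization")
  }
  obj <- if (inherits(tf, "transform_chain")) {
    list(type = "chain", transforms = lapply(tf$transforms, enc))
  } else enc(tf)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  dec <- function(o) {
    if (o$type == "affine") {
      M <- matrix(unlist(o$matrix), 3, 3)
      affine_transform(M[1:2, 1:2], M[1:2, 3], o$source, o$target)
    } else if (o$type == "bspline") {
      d <- unlist(o$ctrl_dim)
      init_M <- matrix(unlist(o$init_matrix), 3, 3)
      bspline_transform(matrix(unlist(o$ctrl_dx), d[1], d[2]),
                        matrix(unlist(o$ctrl_dy), d[1], d[2]),
                        o$spacing_um, unlist(o$origin_um),
                        init = affine_transform(init_M[1:2, 1:2], init_M[1:2, 3],
                                                o$source, o$target),
                        source = o$source, target = o$target)
    } else stop("unknown transform type: ", o$type)
  }
  if (obj$type == "chain") {
    compose_chain(lapply(obj$transforms, dec))
  } else dec(obj)
}
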