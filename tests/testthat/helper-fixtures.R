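# Shared fixture builders and independent brute-force oracles.

# smooth random texture (unit variance-ish) as a phys_image
make_texture <- function(n, seed, pixelsize_um = 2, blur = 3, frame = "fixed") {
  set.seed(seed)
  m <- EBImage::gblur(EBImage::Image(matrix(stats::rnorm(n * n), n, n)), blur)@.Data
  phys_image(m, pixelsize_um, frame)
}

# shift image content by whole pixels (right/down positive), edge padded
shift_content <- function(img, dc = 0, dr = 0) {
  m <- img$values
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(mean(m), nr, nc)
  src_r <- seq_len(nr) - dr; src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1 & src_r <= nr; ok_c <- src_c >= 1 & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  phys_image(out, img$pixelsize_um, img$frame)
}

# independent MLD oracle: literal sort-then-middle definition
oracle_mld <- function(d) {
  d <- sort(d)
  n <- length(d)
  m <- n %/% 2
  if (n == 2 * m + 1) d[m + 1] else (d[m] + d[m + 1]) / 2
}

# independent DICE oracle: loop over every pixel
oracle_dice <- function(S, T) {
  inter <- 0; ns <- 0; nt <- 0
  for (i in seq_along(S)) {
    s <- S[i] > 0; t <- T[i] > 0
    inter <- inter + (s && t)
    ns <- ns + s; nt <- nt + t
  }
  if (ns + nt == 0) 1 else 2 * inter / (ns + nt)
}

# dense brute-force SAR ML oracle: rho grid at 1e-4 resolution with a
# direct log-determinant, then a bracketed refinement on the same
# dense objective (still independent of the eigenvalue path)
oracle_sar <- function(y, X, W) {
  Wd <- as.matrix(W)
  n <- length(y)
  qx <- qr(X)
  b0 <- qr.coef(qx, y); bL <- qr.coef(qx, as.numeric(Wd %*% y))
  e0 <- y - X %*% b0; eL <- Wd %*% y - X %*% bL
  cll <- function(r) {
    ld <- determinant(diag(n) - r * Wd, logarithm = TRUE)
    -n / 2 * log(sum((e0 - r * eL)^2) / n) + as.numeric(ld$modulus)
  }
  rhos <- seq(-0.99, 0.99, by = 1e-4)
  vals <- vapply(rhos, cll, 0)
  k <- which.max(vals)
  br <- c(rhos[max(1, k - 1)], rhos[min(length(rhos), k + 1)])
  opt <- stats::optimize(cll, br, maximum = TRUE, tol = 1e-12)
  rho <- opt$maximum
  list(rho = rho, beta = as.numeric(b0 - rho * bL))
}

# simple rectangular grid of points (um), col-major
grid_points <- function(n_col, n_row, pitch) {
  g <- expand.grid(col = seq_len(n_col), row = seq_len(n_row))
  cbind(x = (g$col - 0.5) * pitch, y = (g$row - 0.5) * pitch)
}
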