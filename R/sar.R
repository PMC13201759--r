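#' Row-standardized spatial weight matrix for an MSI pixel grid
#'
#' Binary adjacency between grid positions (queen: 8 neighbours; rook:
#' 4), row-standardized so each row sums to one. Isolated pixels keep a
#' zero row and are flagged: they contribute to the fit as non-spatial
#' observations.
#'
#' @param col,row integer grid indices of the modelled pixels.
#' @param scheme `"queen"` or `"rook"`.
#' @return A sparse `dgCMatrix` with attributes `isolated` (logical per
#'   pixel) and `eigenvalues` (of the row-standardized matrix, used by
#'   the likelihood).
#' @export
build_weights <- function(col, row, scheme = c("queen", "rook")) {
  scheme <- match.arg(scheme)
  n <- length(col)
  stopifnot(length(row) == n)
  key <- paste(col, row)
  id <- stats::setNames(seq_len(n), key)
  offs <- if (scheme == "rook") {
    cbind(c(1, -1, 0, 0), c(0, 0, 1, -1))
  } else {
    g <- expand.grid(dc = -1:1, dr = -1:1)
    as.matrix(g[!(g$dc == 0 & g$dr == 0), ])
  }
  ii <- integer(0); jj <- integer(0)
  for (k in seq_len(nrow(offs))) {
    nb <- id[paste(col + offs[k, 1], row + offs[k, 2])]
    ok <- !is.na(nb)
    ii <- c(ii, which(ok)); jj <- c(jj, unname(nb[ok]))
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  isolated <- deg == 0
  Dinv <- Matrix::Diagonal(x = ifelse(deg > 0, 1 / deg, 0))
  W <- Dinv %*% A
  W <- methods::as(W, "CsparseMatrix")
  attr(W, "isolated") <- isolated
  ev <- eigen(as.matrix(W), only.values = TRUE)$values
  attr(W, "eigenvalues") <- Re(ev)
  W
}

#' Fit a simultaneous autoregressive (spatial lag) model
#'
#' Maximum-likelihood fit of `y = rho W y + X beta + eps`,
#' `eps ~ N(0, sigma2 I)`: the log-likelihood is concentrated in `rho`
#' using the eigenvalue expansion of `log|I - rho W|`, optimized over
#' the admissible interval, with GLS-type `beta` and asymptotic standard
#' errors from the full information matrix at the optimum. With `W = 0`
#' (or `rho = 0` data) the fit reduces to ordinary least squares.
#'
#' @param y numeric response per pixel (no missing values; drop them and
#'   rebuild `W` on the remaining pixels first).
#' @param X design matrix including the intercept column.
#' @param W row-standardized weight matrix from [build_weights()].
#' @param se compute asymptotic standard errors (involves a dense
#'   `n x n` solve; switch off in large simulation loops).
#' @return An object of class `sar_fit`: `rho`, `beta`, `se_beta`,
#'   `se_rho`, `sigma2`, `loglik`, `n`, plus fitted values and
#'   residuals.
#' @export
fit_sar <- function(y, X, W, se = TRUE) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y); k <- ncol(X)
  stopifnot(nrow(X) == n, all(dim(W) == n))
  if (anyNA(y) || anyNA(X)) stop("missing values in y or X; drop them before fitting")
  if (n <= k + 2) stop("too few pixels for the number of covariates")
  qx <- qr(X)
  if (qx$rank < k) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):k]]
    stop("singular design: collinear column(s) ", paste(bad, collapse = ", "))
  }
  ev <- attr(W, "eigenvalues")
  if (is.null(ev)) ev <- Re(eigen(as.matrix(W), only.values = TRUE)$values)

  Wy <- as.numeric(W %*% y)
  b0 <- qr.coef(qx, y); bL <- qr.coef(qx, Wy)
  e0 <- y - X %*% b0; eL <- Wy - X %*% bL
  sse <- function(rho) sum((e0 - rho * eL)^2)
  cll <- function(rho) {
    -n / 2 * (log(2 * pi) + 1) - n / 2 * log(sse(rho) / n) +
      sum(log(pmax(1 - rho * ev, 1e-300)))
  }
  lo <- if (min(ev) < 0) 1 / min(ev) + 1e-6 else -0.9999
  hi <- if (max(ev) > 0) 1 / max(ev) - 1e-6 else 0.9999
  if (all(ev == 0)) { lo <- -0.9999; hi <- 0.9999 }  # W = 0: rho unidentified, LL flat
  opt <- stats::optimize(cll, c(lo, hi), maximum = TRUE, tol = 1e-9)
  rho <- opt$maximum
  if (all(ev == 0)) rho <- 0
  if (min(rho - lo, hi - rho) < 1e-5 && !all(ev == 0)) {
    stop(sprintf("likelihood maximization hit the rho boundary [%.4f, %.4f] at %.4f",
                 lo, hi, rho))
  }
  beta <- as.numeric(b0 - rho * bL)
  names(beta) <- colnames(X)
  sigma2 <- sse(rho) / n
  loglik <- cll(rho)
  Ay <- y - rho * Wy
  fitted <- as.numeric(X %*% beta)
  resid <- as.numeric(Ay - fitted)

  se_beta <- rep(NA_real_, k); se_rho <- NA_real_
  if (se) {
    Wd <- as.matrix(W)
    A <- diag(n) - rho * Wd
    WA <- Wd %*% solve(A)
    WAXb <- WA %*% (X %*% beta)
    I_bb <- crossprod(X) / sigma2
    I_br <- crossprod(X, WAXb) / sigma2
    I_rr <- sum(WA * t(WA)) + sum(WA * WA) + crossprod(WAXb) / sigma2
    I_rs <- sum(diag(WA)) / sigma2
    I_ss <- n / (2 * sigma2^2)
    info <- rbind(cbind(I_bb, I_br, rep(0, k)),
                  c(as.numeric(I_br), as.numeric(I_rr), I_rs),
                  c(rep(0, k), I_rs, I_ss))
    V <- tryCatch(solve(info), error = function(e) NULL)
    if (!is.null(V)) {
      se_beta <- sqrt(pmax(diag(V)[seq_len(k)], 0))
      se_rho <- sqrt(max(V[k + 1, k + 1], 0))
    }
    names(se_beta) <- colnames(X)
  }
  structure(list(rho = rho, beta = beta, se_beta = se_beta, se_rho = se_rho,
                 sigma2 = sigma2, loglik = loglik, n = n, k = k,
                 fitted = fitted, residuals = resid),
            class = "sar_fit")
}

#' @exportS3Method base::print
print.sar_fit <- function(x, ...) {
  cat(sprintf("Spatial lag (SAR) fit: n = %d pixels, rho = %.4f, sigma2 = %.4g\n",
              x$n, x$rho, x$sigma2))
  print(round(rbind(estimate = x$beta, se = x$se_beta), 4))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.sar_fit <- function(x, ...) {
  est <- c(x$beta, rho = x$rho)
  se <- c(x$se_beta, rho = x$se_rho)
  stat <- est / se
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(stat),
    p.value = 2 * stats::pnorm(-abs(unname(stat))))
}

#' @importFrom generics glance
#' @export
glance.sar_fit <- function(x, ...) {
  tibble::tibble(rho = x$rho, sigma2 = x$sigma2, logLik = x$loglik,
                 nobs = x$n, df = x$k)
}

#' Fit the pixel-level model for one sample and one m/z channel
#'
#' Convenience wrapper: joins a pixel design (from [pixel_design()] or
#' the simulator) with one channel of an [msi_stack] (or a plain `y`
#' column), drops missing pixels, builds the weight matrix on the kept
#' pixels and calls [fit_sar()].
#'
#' @param design tibble with `col`, `row` and covariate columns.
#' @param y response vector aligned with `design` (may contain `NA`).
#' @param covariates names of the covariate columns (type fractions or
#'   per-pixel mean marker intensities).
#' @param scheme neighbour scheme for [build_weights()].
#' @param se passed to [fit_sar()].
#' @param W optional precomputed weight matrix for the full design (only
#'   used when no pixels are dropped; saves the eigendecomposition in
#'   simulation loops).
#' @return A `sar_fit` (with `n_dropped` recording removed pixels).
#' @export
fit_pixel_model <- function(design, y, covariates, scheme = "queen", se = TRUE,
                            W = NULL) {
  keep <- !is.na(y)
  d <- design[keep, , drop = FALSE]
  X <- cbind(`(Intercept)` = 1, as.matrix(d[, covariates, drop = FALSE]))
  if (is.null(W) || any(!keep)) W <- build_weights(d$col, d$row, scheme)
  fit <- fit_sar(y[keep], X, W, se = se)
  fit$n_dropped <- sum(!keep)
  fit
}
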