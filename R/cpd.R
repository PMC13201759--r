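#' Coherent point drift registration
#'
#' EM registration of a source point set onto a target point set under a
#' Gaussian-mixture model with isotropic variance and a uniform outlier
#' component. Deterministic given its inputs. The rigid model estimates
#' rotation and translation (scale optionally); the affine model a full
#' linear map.
#'
#' @param source,target two-column matrices or data frames with `x`,
#'   `y` columns (micrometres).
#' @param model `"rigid"` or `"affine"`.
#' @param omega outlier weight in `[0, 1)`.
#' @param tol convergence tolerance on the change of `sigma2`.
#' @param max_iter iteration cap; hitting it raises an error reporting
#'   the last `sigma2`.
#' @param allow_scale estimate an isotropic scale in the rigid model
#'   (off by default: the MSI pitch fixes the scale).
#' @param source_frame,target_frame frame names for the returned
#'   transform.
#' @return An `affine_transform` with extra fields `sigma2`,
#'   `iterations` and `converged`.
#' @references Myronenko, A. and Song, X. (2010) Point set registration:
#'   coherent point drift. IEEE TPAMI 32(12), 2262-2275.
#' @export
cpd_register <- function(source, target, model = c("rigid", "affine"),
                         omega = 0.1, tol = 1e-8, max_iter = 300,
                         allow_scale = FALSE,
                         source_frame = "source", target_frame = "target") {
  model <- match.arg(model)
  Y_raw <- as_xy_matrix(source)   # moving
  X_raw <- as_xy_matrix(target)   # fixed
  M <- nrow(Y_raw); N <- nrow(X_raw); D <- 2
  stopifnot(M >= 3, N >= 3, omega >= 0, omega < 1)

  # normalize both sets with one similarity map (keeps the outlier
  # constant on a sane scale; the fitted transform is denormalized below)
  ctr <- colMeans(rbind(X_raw, Y_raw))
  s0 <- sqrt(mean(rowSums(sweep(rbind(X_raw, Y_raw), 2, ctr)^2)))
  if (s0 == 0) s0 <- 1
  X <- sweep(X_raw, 2, ctr) / s0
  Y <- sweep(Y_raw, 2, ctr) / s0

  TY <- Y
  sigma2 <- sum(outer(rowSums(X^2), rep(1, M)) + outer(rep(1, N), rowSums(Y^2)) -
                  2 * X %*% t(Y)) / (D * M * N)
  scale2 <- mean(rowSums(sweep(X, 2, colMeans(X))^2))  # target spread (um^2)
  R <- diag(2); s <- 1; B <- diag(2); tvec <- c(0, 0)
  converged <- FALSE; it <- 0
  for (it in seq_len(max_iter)) {
    # E-step
    d2 <- outer(rowSums(X^2), rep(1, M)) + outer(rep(1, N), rowSums(TY^2)) -
      2 * X %*% t(TY)                      # N x M squared distances
    num <- exp(-d2 / (2 * sigma2))
    cst <- (2 * pi * sigma2)^(D / 2) * omega / (1 - omega) * M / N
    den <- rowSums(num) + cst
    P <- num / den                          # N x M posteriors
    Np <- sum(P)
    P1 <- colSums(P)                        # length M
    Pt1 <- rowSums(P)                       # length N
    mu_x <- colSums(Pt1 * X) / Np
    mu_y <- colSums(P1 * Y) / Np
    Xh <- sweep(X, 2, mu_x)
    Yh <- sweep(Y, 2, mu_y)
    A <- t(Xh) %*% P %*% Yh                 # 2 x 2
    if (model == "rigid") {
      sv <- svd(A)
      C <- diag(c(1, sign(det(sv$u %*% t(sv$v)))))
      R <- sv$u %*% C %*% t(sv$v)
      trYPY <- sum(P1 * rowSums(Yh^2))
      trAR <- sum(diag(t(A) %*% R))
      trX <- sum(Pt1 * rowSums(Xh^2))
      s <- if (allow_scale) trAR / trYPY else 1
      tvec <- mu_x - s * as.vector(R %*% mu_y)
      TY <- s * Y %*% t(R) + matrix(tvec, M, 2, byrow = TRUE)
      new_sigma2 <- if (allow_scale) {
        (trX - s * trAR) / (Np * D)           # optimal-scale shortcut
      } else {
        (trX - 2 * trAR + trYPY) / (Np * D)   # full form: s is not optimal
      }
    } else {
      G <- t(Yh) %*% (P1 * Yh)
      B <- A %*% solve(G)
      tvec <- mu_x - as.vector(B %*% mu_y)
      TY <- Y %*% t(B) + matrix(tvec, M, 2, byrow = TRUE)
      new_sigma2 <- (sum(Pt1 * rowSums(Xh^2)) - sum(diag(A %*% t(B)))) / (Np * D)
    }
    new_sigma2 <- max(new_sigma2, 1e-300)
    # relative convergence, with an absolute floor for exact matches
    done <- abs(new_sigma2 - sigma2) < tol * sigma2 ||
      new_sigma2 < 1e-14 * scale2
    sigma2 <- new_sigma2
    if (done) { converged <- TRUE; break }
  }
  if (!converged) {
    stop(sprintf("coherent point drift did not converge in %d iterations (sigma2 = %.3g)",
                 max_iter, sigma2))
  }
  lin <- if (model == "rigid") s * R else B
  # denormalize: T = N^-1 o T_norm o N with N(p) = (p - ctr) / s0
  tvec <- s0 * tvec + as.vector(ctr - lin %*% ctr)
  tf <- affine_transform(lin, tvec, source = source_frame, target = target_frame)
  tf$sigma2 <- sigma2 * s0^2
  tf$iterations <- it
  tf$converged <- converged
  tf$model <- model
  tf
}
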