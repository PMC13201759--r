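# Local window filters used by the ablation-mark enhancer. All operate
# on plain matrices with edge-replicated padding and are exact (no
# histogram binning), so sub-pixel centroid accuracy downstream is not
# degraded.

kernel_offsets <- function(shape = c("square", "disk", "cross"), radius) {
  shape <- match.arg(shape)
  r <- as.integer(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  keep <- switch(shape,
    square = rep(TRUE, nrow(g)),
    disk = g$dr^2 + g$dc^2 <= r^2 + 1e-9,
    cross = g$dr == 0 | g$dc == 0
  )
  g[keep, , drop = FALSE]
}

shift_matrix <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1), nr)  # edge replication
  ci <- pmin(pmax(seq_len(nc) + dc, 1), nc)
  m[ri, ci, drop = FALSE]
}

local_mean_filter <- function(m, offsets) {
  acc <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(offsets))) {
    acc <- acc + shift_matrix(m, offsets$dr[i], offsets$dc[i])
  }
  acc / nrow(offsets)
}

# elementwise k-th smallest over the window, by partial selection:
# k passes of min-extraction over the stack of shifted copies
local_kth_filter <- function(m, offsets, k) {
  K <- nrow(offsets)
  stopifnot(k >= 1, k <= K)
  if (any(dim(m) > 1024)) {
    # guard: the partial-selection cost is k*K full-image passes
    stopifnot(prod(dim(m)) * K < 5e8)
  }
  shifts <- vector("list", K)
  for (i in seq_len(K)) shifts[[i]] <- shift_matrix(m, offsets$dr[i], offsets$dc[i])
  kth <- NULL
  for (pass in seq_len(k)) {
    cur <- shifts[[1]]
    for (i in seq_len(K)[-1]) cur <- pmin(cur, shifts[[i]])
    kth <- cur
    if (pass < k) {
      removed <- matrix(FALSE, nrow(m), ncol(m))
      for (i in seq_len(K)) {
        take <- (shifts[[i]] == cur) & !removed
        shifts[[i]][take] <- Inf
        removed <- removed | take
      }
    }
  }
  kth
}

local_median_filter <- function(m, offsets) {
  K <- nrow(offsets)
  k <- (K + 1L) %/% 2L
  lo <- local_kth_filter(m, offsets, k)
  if (K %% 2L == 1L) lo else (lo + local_kth_filter(m, offsets, k + 1L)) / 2
}
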