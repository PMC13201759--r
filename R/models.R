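# Second-stage (across-sample) models, compositional per-sample model,
# tissue-domain assignment and the domain pseudobulk test.

#' Weighted second-stage model across samples
#'
#' Regresses per-sample pixel-model coefficients on sample metadata with
#' inverse-variance weights (`1 / SE^2`). With a `patient` column and
#' repeated samples per patient a random intercept is added; if every
#' patient contributes a single sample the model falls back to weighted
#' least squares with a warning. P-values are Wald tests;
#' Benjamini-Hochberg q-values are computed across the channels in `by`.
#'
#' @param df tibble with columns `sample_id`, `estimate`, `se`, plus any
#'   grouping columns named in `by` (e.g. `mz`, `term`).
#' @param Z sample metadata (one row per `sample_id`).
#' @param formula_rhs right-hand side of the model, e.g. `~ condition`.
#' @param by grouping columns: one model is fitted per group and FDR is
#'   controlled across groups.
#' @param patient name of the patient column in `Z` for the random
#'   intercept.
#' @param var_floor variances below this are floored (down-weights
#'   zero-variance inputs instead of giving them infinite weight).
#' @return A tibble of class `second_stage_fit`: grouping columns,
#'   `term`, `gamma`, `se`, `statistic`, `p.value`, `q.value`,
#'   `n_samples`.
#' @export
fit_second_stage <- function(df, Z, formula_rhs = ~1, by = NULL,
                             patient = NULL, var_floor = 1e-8) {
  stopifnot(all(c("sample_id", "estimate", "se") %in% names(df)))
  if (length(unique(df$sample_id)) < 2) stop("need at least two samples")
  dat <- dplyr::left_join(df, Z, by = "sample_id")
  groups <- if (is.null(by)) list(dat) else {
    dplyr::group_split(dplyr::group_by(dat, dplyr::across(dplyr::all_of(by))))
  }
  fit_one <- function(g) {
    w <- 1 / pmax(g$se^2, var_floor)
    use_mixed <- !is.null(patient) &&
      any(table(g[[patient]][!duplicated(g$sample_id)]) > 1)
    fm <- stats::as.formula(paste("estimate", paste(deparse(formula_rhs), collapse = "")))
    if (use_mixed) {
      fmm <- stats::update(fm, paste(". ~ . + (1 |", patient, ")"))
      m <- lme4::lmer(fmm, data = g, weights = w, REML = TRUE)
      cf <- summary(m)$coefficients
      est <- cf[, "Estimate"]; se <- cf[, "Std. Error"]
    } else {
      if (!is.null(patient)) {
        warning("all patients are singletons; falling back to weighted least squares")
      }
      m <- stats::lm(fm, data = g, weights = w)
      cf <- summary(m)$coefficients
      est <- cf[, "Estimate"]; se <- cf[, "Std. Error"]
    }
    stat <- est / se
    out <- tibble::tibble(term = rownames(cf), gamma = unname(est),
                          se = unname(se), statistic = unname(stat),
                          p.value = 2 * stats::pnorm(-abs(unname(stat))),
                          n_samples = length(unique(g$sample_id)))
    if (!is.null(by)) for (b in by) out[[b]] <- g[[b]][1]
    out
  }
  res <- purrr::map_dfr(groups, fit_one)
  res <- res |>
    dplyr::group_by(.data$term) |>
    dplyr::mutate(q.value = stats::p.adjust(.data$p.value, "BH")) |>
    dplyr::ungroup()
  if (!is.null(by)) res <- dplyr::relocate(res, dplyr::all_of(by))
  class(res) <- c("second_stage_fit", class(res))
  res
}

# ---- compositional (pivot-coordinate) model --------------------------------

# ilr pivot coordinates with the given part first
pivot_coordinates <- function(P) {
  D <- ncol(P)
  Z <- matrix(0, nrow(P), D - 1)
  for (i in seq_len(D - 1)) {
    rest <- P[, (i + 1):D, drop = FALSE]
    gm <- exp(rowMeans(log(rest)))
    Z[, i] <- sqrt((D - i) / (D - i + 1)) * log(P[, i] / gm)
  }
  Z
}

#' Per-sample compositional regression in pivot coordinates
#'
#' Tests the association of a continuous response (per-sample mean m/z
#' value) with cell-type proportions. For each cell type the composition
#' is rotated so that type occupies the first pivot (isometric
#' log-ratio) coordinate, the least-squares model
#' `y ~ pivot coordinates + covariates` is fitted, and that type's
#' first-coordinate coefficient reported. Zero proportions are replaced
#' by half the smallest positive proportion before closure; types that
#' are zero everywhere are excluded.
#'
#' @param data tibble: one row per sample with proportion columns
#'   (`parts`), the response and any covariates.
#' @param parts names of the cell-type proportion columns.
#' @param response name of the response column.
#' @param covariates optional non-compositional covariate names (e.g.
#'   condition, TMA).
#' @return A tibble: `part`, `estimate`, `se`, `statistic`, `p.value`
#'   for each type's own-pivot coordinate.
#' @export
fit_compositional <- function(data, parts, response, covariates = NULL) {
  P <- as.matrix(data[, parts, drop = FALSE])
  always_zero <- colSums(P > 0) == 0
  if (any(always_zero)) {
    message("excluding all-zero type(s): ", paste(parts[always_zero], collapse = ", "))
    parts <- parts[!always_zero]
    P <- P[, parts, drop = FALSE]
  }
  if (ncol(P) < 2) stop("need at least two non-degenerate parts")
  if (any(P == 0)) {
    repl <- 0.5 * min(P[P > 0])
    P[P == 0] <- repl
  }
  P <- P / rowSums(P)
  y <- data[[response]]
  X_extra <- if (!is.null(covariates)) {
    stats::model.matrix(stats::as.formula(paste("~", paste(covariates, collapse = "+"))),
                        data = data)[, -1, drop = FALSE]
  } else NULL
  purrr::map_dfr(seq_along(parts), function(l) {
    ord <- c(l, setdiff(seq_along(parts), l))
    Z <- pivot_coordinates(P[, ord, drop = FALSE])
    colnames(Z) <- paste0("ilr", seq_len(ncol(Z)))
    df <- data.frame(y = y, Z)
    if (!is.null(X_extra)) df <- cbind(df, X_extra)
    m <- stats::lm(y ~ ., data = df)
    cf <- summary(m)$coefficients
    tibble::tibble(part = parts[l],
                   estimate = cf["ilr1", "Estimate"],
                   se = cf["ilr1", "Std. Error"],
                   statistic = cf["ilr1", "t value"],
                   p.value = cf["ilr1", "Pr(>|t|)"])
  })
}

# ---- tissue domains --------------------------------------------------------

#' Assign tissue domains to cells from two antagonist markers
#'
#' For each cell a neighbourhood-weighted intensity (Gaussian weight,
#' `sigma = radius / 2`, cut at `radius`) of both markers is computed,
#' each marker scaled by its 0.99 quantile, and the initial domain is
#' the marker with the higher scaled intensity. Labels are then
#' iteratively smoothed by majority vote over the same neighbourhoods
#' until stable (at most `max_iter` sweeps). A cell with no neighbours
#' uses its own intensities. All-equal intensities break ties towards
#' the first marker and are flagged.
#'
#' @param cells tibble with `x`, `y` (um) and the two marker columns.
#' @param markers length-2 character: marker column names (first wins
#'   ties).
#' @param labels domain names, parallel to `markers`.
#' @param radius_um neighbourhood radius.
#' @param max_iter smoothing sweep cap.
#' @return The input tibble with `domain` and `domain_tie` columns.
#' @export
assign_domains <- function(cells, markers, labels = markers, radius_um = 40,
                           max_iter = 10) {
  stopifnot(length(markers) == 2, all(markers %in% names(cells)))
  n <- nrow(cells)
  P <- cbind(cells$x, cells$y)
  d2 <- outer(rowSums(P^2), rep(1, n)) + outer(rep(1, n), rowSums(P^2)) -
    2 * P %*% t(P)
  d2[d2 < 0] <- 0
  sigma <- radius_um / 2
  Wn <- exp(-d2 / (2 * sigma^2))
  Wn[sqrt(d2) > radius_um] <- 0
  diag(Wn) <- 1  # a cell always counts itself
  sw <- rowSums(Wn)
  sm1 <- as.numeric(Wn %*% cells[[markers[1]]]) / sw
  sm2 <- as.numeric(Wn %*% cells[[markers[2]]]) / sw
  q1 <- stats::quantile(sm1, 0.99); q2 <- stats::quantile(sm2, 0.99)
  s1 <- if (q1 > 0) sm1 / q1 else sm1
  s2 <- if (q2 > 0) sm2 / q2 else sm2
  lab <- ifelse(s1 >= s2, 1L, 2L)
  tie <- s1 == s2
  nb <- Wn > 0
  for (it in seq_len(max_iter)) {
    votes1 <- nb %*% (lab == 1L)
    votes2 <- nb %*% (lab == 2L)
    new_lab <- ifelse(votes1 > votes2, 1L, ifelse(votes2 > votes1, 2L, lab))
    if (all(new_lab == lab)) break
    lab <- new_lab
  }
  cells$domain <- labels[lab]
  cells$domain_tie <- tie
  cells
}

#' Propagate cell domains to MSI pixels
#'
#' Each pixel takes the domain with the most overlapping labelled
#' cells; count ties go to the domain of the nearest cell centroid.
#' Pixels without any labelled cell inherit the domain of the closest
#' labelled pixel (Euclidean distance between pixel centres).
#'
#' @param cells tibble with `cell_id`, `domain` and centroid `x`, `y`
#'   (MSI frame).
#' @param overlaps an `overlap_table`.
#' @param pixels the `pixel_polygons` used for the overlaps.
#' @return Tibble `pixel_id`, `col`, `row`, `domain`, `imputed`.
#' @export
pixel_domains <- function(cells, overlaps, pixels) {
  dat <- dplyr::inner_join(overlaps, cells[, c("cell_id", "domain", "x", "y")],
                           by = "cell_id")
  dat <- dat[!is.na(dat$domain), , drop = FALSE]
  if (nrow(dat) == 0) stop("no labelled pixel: no overlapping labelled cells")
  vote <- function(g) {
    tab <- table(g$domain)
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) == 1) return(winners)
    px <- pixels[pixels$pixel_id == g$pixel_id[1], ]
    g <- g[g$domain %in% winners, ]
    g$domain[which.min((g$x - px$x)^2 + (g$y - px$y)^2)]
  }
  lab <- purrr::map_dfr(split(dat, dat$pixel_id), function(g) {
    tibble::tibble(pixel_id = g$pixel_id[1], domain = vote(g))
  })
  out <- dplyr::left_join(
    pixels[, c("pixel_id", "col", "row", "x", "y")], lab, by = "pixel_id")
  out$imputed <- is.na(out$domain)
  if (any(out$imputed)) {
    has <- which(!out$imputed); not <- which(out$imputed)
    for (i in not) {
      j <- has[which.min((out$x[has] - out$x[i])^2 + (out$y[has] - out$y[i])^2)]
      out$domain[i] <- out$domain[j]
    }
  }
  out[, c("pixel_id", "col", "row", "domain", "imputed")]
}

#' Domain pseudobulk test per m/z channel
#'
#' Averages pixel values per sample and domain ("pseudobulk"), then
#' fits, per m/z, a linear model of the means on the domain (categorical)
#' plus any sample-level covariates (e.g. the TMA the sample came
#' from); covariates with a single observed level are dropped. FDR is
#' controlled across m/z by Benjamini-Hochberg.
#'
#' @param df pixel-level tibble: `sample_id`, `domain`, `mz`, `value`
#'   (missing values allowed; dropped).
#' @param meta sample metadata with `sample_id` and the covariates.
#' @param covariates covariate names in `meta`.
#' @return Tibble per m/z and domain contrast: `mz`, `term`,
#'   `estimate`, `se`, `p.value`, `q.value`, `n_groups`.
#' @export
domain_test <- function(df, meta = NULL, covariates = NULL) {
  df <- df[!is.na(df$value), , drop = FALSE]
  pb <- df |>
    dplyr::group_by(.data$sample_id, .data$domain, .data$mz) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  n_dom <- length(unique(pb$domain))
  if (n_dom < 2) stop("need two domains")
  dom_per_sample <- pb |>
    dplyr::distinct(.data$sample_id, .data$domain) |>
    dplyr::count(.data$sample_id)
  partial <- dom_per_sample$sample_id[dom_per_sample$n < n_dom]
  if (length(partial)) {
    message("sample(s) missing a domain (their empty cells are dropped): ",
            paste(partial, collapse = ", "))
  }
  if (sum(dom_per_sample$n == n_dom) < 2) {
    stop("need at least two samples with all domains")
  }
  if (!is.null(meta)) pb <- dplyr::left_join(pb, meta, by = "sample_id")
  keep_cov <- character()
  if (!is.null(covariates)) {
    for (cv in covariates) {
      if (length(unique(pb[[cv]])) > 1) keep_cov <- c(keep_cov, cv)
    }
  }
  rhs <- paste(c("domain", keep_cov), collapse = " + ")
  res <- purrr::map_dfr(split(pb, pb$mz), function(g) {
    m <- stats::lm(stats::as.formula(paste("value ~", rhs)), data = g)
    cf <- summary(m)$coefficients
    rows <- grep("^domain", rownames(cf), value = TRUE)
    tibble::tibble(mz = g$mz[1], term = rows,
                   estimate = cf[rows, "Estimate"],
                   se = cf[rows, "Std. Error"],
                   p.value = cf[rows, "Pr(>|t|)"],
                   n_groups = nrow(g))
  })
  res |>
    dplyr::group_by(.data$term) |>
    dplyr::mutate(q.value = stats::p.adjust(.data$p.value, "BH")) |>
    dplyr::ungroup()
}
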