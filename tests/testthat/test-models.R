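# Second-stage weighted model, compositional model, domains, domain
# pseudobulk test.

test_that("intercept-only second stage is the inverse-variance weighted mean", {
  set.seed(51)
  df <- tibble::tibble(sample_id = paste0("s", 1:8),
                       estimate = rnorm(8), se = runif(8, 0.3, 3))
  Z <- tibble::tibble(sample_id = df$sample_id)
  fit <- fit_second_stage(df, Z, ~1)
  w <- 1 / df$se^2
  expect_equal(fit$gamma[1], sum(w * df$estimate) / sum(w), tolerance = 1e-12)
})

test_that("equal weights reproduce unweighted least squares", {
  set.seed(52)
  Z <- tibble::tibble(sample_id = paste0("s", 1:10),
                      condition = rep(c(0, 1), 5))
  df <- tibble::tibble(sample_id = Z$sample_id,
                       estimate = 2 + 3 * Z$condition + rnorm(10),
                       se = rep(1.7, 10))
  fit <- fit_second_stage(df, Z, ~condition)
  ref <- lm(df$estimate ~ Z$condition)
  expect_equal(fit$gamma, unname(coef(ref)), tolerance = 1e-10)
})

test_that("the mixed model engages for repeated patients and falls back otherwise", {
  set.seed(53)
  Z <- tibble::tibble(sample_id = paste0("s", 1:8),
                      condition = rep(c(0, 1), 4),
                      patient = rep(paste0("p", 1:4), each = 2))
  df <- tibble::tibble(sample_id = Z$sample_id,
                       estimate = 1 + 2 * Z$condition + rnorm(8, 0, 0.2),
                       se = runif(8, 0.5, 1))
  fit <- fit_second_stage(df, Z, ~condition, patient = "patient")
  expect_equal(fit$gamma[fit$term == "condition"], 2, tolerance = 1)

  Zs <- Z; Zs$patient <- paste0("q", 1:8)  # singletons
  expect_warning(fit_second_stage(df, Zs, ~condition, patient = "patient"),
                 "singleton")
  expect_error(fit_second_stage(df[1, ], Z, ~1), "two samples")
})

test_that("FDR is controlled across channels per term", {
  set.seed(54)
  ch <- purrr::map_dfr(1:20, function(k) {
    tibble::tibble(sample_id = paste0("s", 1:6), mz = k,
                   estimate = rnorm(6), se = runif(6, 0.5, 1))
  })
  Z <- tibble::tibble(sample_id = paste0("s", 1:6), condition = rep(0:1, 3))
  fit <- fit_second_stage(ch, Z, ~condition, by = "mz")
  one_term <- fit[fit$term == "condition", ]
  expect_equal(one_term$q.value, p.adjust(one_term$p.value, "BH"))
})

test_that("pivot coordinates follow the ilr definition for two parts", {
  set.seed(55)
  p1 <- runif(12, 0.2, 0.8)
  dat <- tibble::tibble(p1 = p1, p2 = 1 - p1, y = rnorm(12))
  fc <- fit_compositional(dat, c("p1", "p2"), "y")
  z1 <- sqrt(1 / 2) * log(dat$p1 / dat$p2)
  ref <- summary(lm(dat$y ~ z1))$coefficients
  expect_equal(fc$estimate[1], ref["z1", "Estimate"], tolerance = 1e-10)
  # the two-part model is antisymmetric
  expect_equal(fc$estimate[2], -fc$estimate[1], tolerance = 1e-10)
})

test_that("own-pivot coefficients are invariant to the order of other parts", {
  set.seed(56)
  P <- matrix(rgamma(60, 2), 15, 4)
  P <- P / rowSums(P)
  dat <- tibble::as_tibble(as.data.frame(P))
  names(dat) <- paste0("t", 1:4)
  dat$y <- rnorm(15)
  f1 <- fit_compositional(dat, c("t1", "t2", "t3", "t4"), "y")
  f2 <- fit_compositional(dat, c("t3", "t1", "t4", "t2"), "y")
  for (p in paste0("t", 1:4)) {
    expect_equal(f1$estimate[f1$part == p], f2$estimate[f2$part == p],
                 tolerance = 1e-10)
  }
})

test_that("a composition-independent response gives null coefficients", {
  set.seed(57)
  hits <- 0
  for (r in 1:30) {
    P <- matrix(rgamma(90, 2), 30, 3); P <- P / rowSums(P)
    dat <- tibble::as_tibble(as.data.frame(P))
    names(dat) <- c("a", "b", "c")
    dat$y <- rnorm(30)
    fc <- fit_compositional(dat, c("a", "b", "c"), "y")
    hits <- hits + sum(abs(fc$estimate / fc$se) > 3)
  }
  expect_lt(hits / (30 * 3), 0.05)
})

test_that("all-zero parts are excluded with a message", {
  dat <- tibble::tibble(a = c(0.5, 0.6), b = c(0.5, 0.4), z = c(0, 0),
                        y = c(1, 2))
  expect_message(fc <- fit_compositional(dat, c("a", "b", "z"), "y"),
                 "all-zero")
  expect_setequal(fc$part, c("a", "b"))
})

test_that("domain assignment follows markers, smooths, and flags ties", {
  # isolated cell with stronger first marker
  one <- tibble::tibble(x = 0, y = 0, m1 = 3, m2 = 1)
  d1 <- assign_domains(one, c("m1", "m2"), c("Hep", "Inf"))
  expect_equal(d1$domain, "Hep")

  # a single discordant cell flips to the neighbourhood majority
  set.seed(58)
  grid <- expand.grid(x = seq(0, 60, 15), y = seq(0, 60, 15))
  cells <- tibble::tibble(x = grid$x, y = grid$y, m1 = 5, m2 = 1)
  mid <- which(cells$x == 30 & cells$y == 30)
  cells$m1[mid] <- 0; cells$m2[mid] <- 20
  d2 <- assign_domains(cells, c("m1", "m2"), c("Hep", "Inf"), radius_um = 40)
  expect_equal(unique(d2$domain), "Hep")

  # all-equal intensities: tie to the first marker, flagged
  eq <- tibble::tibble(x = c(0, 100), y = c(0, 0), m1 = c(1, 1), m2 = c(1, 1))
  d3 <- assign_domains(eq, c("m1", "m2"), c("Hep", "Inf"))
  expect_true(all(d3$domain == "Hep"))
  expect_true(all(d3$domain_tie))
})

test_that("pixel domains take majority votes and impute empty pixels", {
  px <- pixel_polygons(col = 1:3, row = c(1, 1, 1), 30, 30)
  cells <- tibble::tibble(cell_id = 1:4, domain = c("Hep", "Hep", "Hep", "Inf"),
                          x = c(10, 12, 14, 20), y = rep(15, 4))
  ov <- tibble::tibble(pixel_id = c(1, 1, 1, 1), cell_id = 1:4,
                       area_um2 = c(10, 10, 10, 10))
  class(ov) <- c("overlap_table", class(ov))
  pd <- pixel_domains(cells, ov, px)
  expect_equal(pd$domain[1], "Hep")           # 3 vs 1 majority
  expect_equal(pd$domain[2:3], c("Hep", "Hep"))  # imputed from nearest
  expect_true(all(pd$imputed[2:3]))
})

test_that("the domain pseudobulk test recovers an exact noiseless contrast", {
  samples <- paste0("s", 1:4)
  df <- purrr::map_dfr(samples, function(s) {
    tibble::tibble(sample_id = s,
                   domain = rep(c("Hep", "Inf"), each = 5),
                   mz = rep(1419.5, 10),
                   value = rep(c(10, 17), each = 5))
  })
  res <- suppressWarnings(domain_test(df))  # lm warns on the perfect fit
  expect_equal(res$estimate, 7, tolerance = 1e-12)

  # a single-level covariate is dropped automatically
  meta <- tibble::tibble(sample_id = samples, tma = "A")
  res2 <- suppressWarnings(domain_test(df, meta, covariates = "tma"))
  expect_equal(res2$estimate, 7, tolerance = 1e-12)
})

test_that("domain test controls false positives on null data", {
  set.seed(59)
  fp <- 0; n_mz <- 60
  df <- purrr::map_dfr(seq_len(n_mz), function(k) {
    purrr::map_dfr(paste0("s", 1:6), function(s) {
      tibble::tibble(sample_id = s, domain = rep(c("A", "B"), each = 4),
                     mz = k, value = rnorm(8))
    })
  })
  res <- domain_test(df)
  expect_lt(mean(res$q.value < 0.05), 0.1)
})
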