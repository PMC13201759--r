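# Workflow orchestration: named steps with content-hash caching and QC
# gating. Steps are idempotent: rerunning with an unchanged config and
# unchanged upstream artifacts hits the cache.

content_hash <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Pipeline run configuration
#'
#' @param config a named list (or path to a YAML file) with at least
#'   `mode` (`"two-slice"` or `"single-slice"`), a `simulate` block (a
#'   [sim_config()]-compatible list) and optional `qc` thresholds
#'   (`min_landmarks`, default 100).
#' @param seed global RNG seed for the run.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(config = list(), seed = 1) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config$mode <- config$mode %||% "two-slice"
  if (!config$mode %in% c("two-slice", "single-slice")) {
    stop("mode must be 'two-slice' or 'single-slice'")
  }
  config$qc <- utils::modifyList(list(min_landmarks = 100), config$qc %||% list())
  sim_args <- config$simulate %||% list()
  config$simulate <- do.call(sim_config, sim_args)
  config$seed <- seed
  class(config) <- c("run_config", class(config))
  config
}

pipeline_steps <- function() {
  list(
    simulate = list(
      deps = character(),
      fn = function(cfg, art) simulate_dataset(cfg$simulate, seed = cfg$seed)),
    register = list(
      deps = character(),
      fn = function(cfg, art) {
        fx <- render_postmsi_fixture(n_col = 8, n_row = 8,
                                     stepsize_um = cfg$simulate$stepsize_um,
                                     seed = cfg$seed)
        enh <- enhance_marks(fx$image, detection_params(w = 0.5, t = 0.12))
        mk <- detect_marks(enh, detection_params(w = 0.5, t = 0.12),
                           cfg$simulate$stepsize_um)
        reg <- register_msi_grid(mk, fx$truth$col, fx$truth$row,
                                 cfg$simulate$stepsize_um)
        list(marks = mk, registration = reg, truth = fx$truth)
      }),
    qc = list(
      deps = "register",
      fn = function(cfg, art) {
        asg <- art$register$registration$assignment
        ok <- !is.na(asg$residual_um)
        rep <- qc_report("MSI-to-PostMSI",
                         mld_um = if (any(ok)) mld(asg$residual_um[ok]) else NA_real_,
                         n_landmarks = sum(ok),
                         min_landmarks = cfg$qc$min_landmarks)
        if (rep$excluded) {
          message("QC: step 'MSI-to-PostMSI' flagged for manual review (",
                  rep$n_landmarks, " landmarks)")
        }
        rep
      }),
    integrate = list(
      deps = "simulate",
      fn = function(cfg, art) art$simulate$grid),
    model = list(
      deps = "integrate",
      fn = function(cfg, art) {
        grid <- art$integrate
        covs <- grep("^frac_", names(grid), value = TRUE)
        fit <- fit_pixel_model(grid, grid$y, covs)
        tidy(fit)
      })
  )
}

#' Run one pipeline step (with caching)
#'
#' @param step step name: one of `simulate`, `register`, `qc`,
#'   `integrate`, `model`.
#' @param config a [run_config()].
#' @param cache environment used as the artifact store (created by
#'   [run_all()]; reuse it across calls to get caching).
#' @return The step's artifact (invisibly stored in `cache`).
#' @export
run_step <- function(step, config, cache = new.env(parent = emptyenv())) {
  steps <- pipeline_steps()
  if (!step %in% names(steps)) {
    stop("unknown step '", step, "'; available: ", paste(names(steps), collapse = ", "))
  }
  s <- steps[[step]]
  for (d in s$deps) {
    if (is.null(cache[[d]])) {
      stop("missing upstream artifact '", d, "' for step '", step,
           "'; run step '", d, "' first")
    }
  }
  upstream <- lapply(s$deps, function(d) cache[[paste0(d, ".hash")]])
  h <- content_hash(list(step = step, config = unclass(config), upstream = upstream))
  if (identical(cache[[paste0(step, ".hash")]], h) && !is.null(cache[[step]])) {
    return(invisible(cache[[step]]))
  }
  art <- s$fn(config, as.list(cache))
  cache[[step]] <- art
  cache[[paste0(step, ".hash")]] <- h
  invisible(art)
}

#' Run the whole pipeline
#'
#' Executes simulate, register, qc, integrate and model in order and
#' returns the artifacts plus a QC table. Deterministic for a fixed
#' `(config, seed)`.
#'
#' @param config a [run_config()].
#' @param cache artifact store (see [run_step()]).
#' @return List with all artifacts, the `qc` table and `cache`.
#' @export
run_all <- function(config, cache = new.env(parent = emptyenv())) {
  for (s in c("simulate", "register", "qc", "integrate", "model")) {
    run_step(s, config, cache)
  }
  list(simulate = cache$simulate, register = cache$register, qc = cache$qc,
       integrate = cache$integrate, model = cache$model, cache = cache)
}
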