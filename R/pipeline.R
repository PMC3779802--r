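#' Run the synth / fit / scan pipeline from a configuration file
#'
#' End-to-end orchestration: generate a synthetic competition dataset, fit
#' the competition model to it, and run the multilevel-selection scan, with
#' every stage's output written to `out_dir` as plain CSV/JSON and a run
#' manifest capturing the configuration, package version, seed, stage
#' timings and MD5 digests of every artifact. Stages read their
#' predecessors' outputs; when the `fit` stage is disabled the scan uses the
#' configured truth parameters directly, so a zero-noise run produces an
#' identical scan either way.
#'
#' The configuration (YAML or JSON file, or an equivalent named list) has
#' blocks:
#' \describe{
#'   \item{`seed`}{Top-level integer seed; every stochastic stage derives
#'     from it.}
#'   \item{`stages`}{Character vector among `"synth"`, `"fit"`, `"scan"`.}
#'   \item{`truth`}{Competition parameters (fields of
#'     [competition_params()]); unknown keys are rejected.}
#'   \item{`synth`}{`levels`, `replicates`, `inoculum`, `noise_cv`.}
#'   \item{`fit`}{`free` (optional), `n_starts`, `bootstrap_B`.}
#'   \item{`scan`}{`p_grid` and `sigma_grid` as `{from, to, num}` lists,
#'     `n_groups`.}
#' }
#'
#' @param config Path to a YAML/JSON file, or a named list.
#' @param out_dir Output directory, created if missing.
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
#' @examples
#' cfg <- system.file("extdata", "demo_pipeline.yaml", package = "swarmsel")
#' \donttest{
#' res <- run_pipeline(cfg, tempfile("swarmsel-demo-"))
#' }
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  known <- c("seed", "stages", "truth", "synth", "fit", "scan", "inoculum")
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  stages <- config$stages %||% c("synth", "fit", "scan")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  truth <- .params_from_config(config$truth)
  inoculum <- config$inoculum %||% 1e6
  results <- list()
  timings <- list()
  artifacts <- character(0)
  log_line <- function(...) message(sprintf(...))

  dataset <- NULL
  if ("synth" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    sc <- config$synth %||% list()
    .check_keys(sc, c("levels", "replicates", "noise_cv"), "synth")
    cfg <- synth_config(truth,
                        levels = sc$levels %||% c(0.01, 0.17, 0.5, 0.83, 0.99),
                        replicates = sc$replicates %||% 6,
                        inoculum = inoculum,
                        noise_cv = sc$noise_cv %||% 0.15,
                        seed = seed)
    dataset <- generate_competitions(cfg)
    f <- file.path(out_dir, "competitions.csv")
    utils::write.csv(as.data.frame(dataset), f, row.names = FALSE)
    artifacts <- c(artifacts, f)
    results$dataset <- dataset
    timings$synth <- proc.time()[["elapsed"]] - t0
    log_line("synth: %d rows -> %s (%.2fs)", nrow(dataset), f,
             timings$synth)
  }

  scan_params <- truth
  if ("fit" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    if (is.null(dataset))
      stop("fit stage requires the synth stage (no dataset available)",
           call. = FALSE)
    fc <- config$fit %||% list()
    .check_keys(fc, c("free", "n_starts", "bootstrap_B"), "fit")
    fit <- fit_competition(dataset, free = fc$free %||% .fittable,
                           n_starts = fc$n_starts %||% 20, seed = seed)
    B <- fc$bootstrap_B %||% 0
    if (B > 0) fit <- bootstrap_fit(dataset, fit = fit, B = B, seed = seed)
    f <- file.path(out_dir, "fit.json")
    jsonlite::write_json(list(
      estimates = fit$estimates, yield_ratio = fit$yield_ratio,
      loss = fit$loss, free = fit$free, seed = seed,
      intervals = if (!is.null(fit$bootstrap))
        as.data.frame(fit$bootstrap$intervals)),
      f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    artifacts <- c(artifacts, f)
    results$fit <- fit
    scan_params <- fit$params
    timings$fit <- proc.time()[["elapsed"]] - t0
    log_line("fit: loss %.4g, yield ratio %.3f (%.2fs)", fit$loss,
             fit$yield_ratio, timings$fit)
  }

  if ("scan" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    sc <- config$scan %||% list()
    .check_keys(sc, c("p_grid", "sigma_grid", "n_groups"), "scan")
    grid_spec <- function(g, default) {
      if (is.null(g)) default
      else if (is.list(g)) seq(g$from, g$to, length.out = g$num)
      else as.numeric(g)
    }
    scan <- mls_scan(scan_params,
                     p_grid = grid_spec(sc$p_grid,
                                        seq(0.05, 0.95, length.out = 19)),
                     sigma_grid = grid_spec(sc$sigma_grid,
                                            seq(0, 6, by = 0.5)),
                     n_groups = sc$n_groups %||% 201,
                     total_inoculum = inoculum)
    f <- file.path(out_dir, "scan.csv")
    utils::write.csv(scan$grid, f, row.names = FALSE)
    fs <- file.path(out_dir, "scan_summary.json")
    jsonlite::write_json(list(
      sigma_star = scan$sigma_star,
      equilibria = scan$equilibria, seed = seed),
      fs, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    artifacts <- c(artifacts, f, fs)
    results$scan <- scan
    timings$scan <- proc.time()[["elapsed"]] - t0
    log_line("scan: sigma* = %s (%.2fs)",
             format(scan$sigma_star, digits = 3), timings$scan)
  }

  manifest <- list(
    package = "swarmsel",
    version = as.character(utils::packageVersion("swarmsel")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, stages = stages, config = config,
    timings = timings,
    digests = as.list(tools::md5sum(artifacts)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_keys <- function(block, allowed, name) {
  bad <- setdiff(names(block), allowed)
  if (length(bad))
    stop(sprintf("unknown keys in '%s' block: %s", name,
                 paste(bad, collapse = ", ")), call. = FALSE)
}

# build params from a config block, rejecting unknown keys
.params_from_config <- function(block) {
  if (is.null(block)) stop("config must contain a 'truth' block",
                           call. = FALSE)
  if (!is.null(block$model) && block$model == "growth_driven") {
    block$model <- NULL
    allowed <- names(formals(growth_driven_params))
    bad <- setdiff(names(block), allowed)
    if (length(bad))
      stop("unknown truth parameters: ", paste(bad, collapse = ", "),
           call. = FALSE)
    return(do.call(growth_driven_params, block))
  }
  allowed <- names(formals(competition_params))
  bad <- setdiff(names(block), allowed)
  if (length(bad))
    stop("unknown truth parameters: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(competition_params, block)
}
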