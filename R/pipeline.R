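# End-to-end orchestration: config handling, staged pipeline, CLI.

#' Build or load a run configuration
#'
#' A run is driven either by a `synthetic` design block (the generator
#' produces the survey) or by an `inputs` block of CSV paths — exactly one
#' of the two. JSON is used as the on-disk key-value format.
#'
#' Recognized fields: `synthetic` (`n_sites`, `n_days`, `bin_days`, `beta`,
#' `p`), `inputs` (`records`, `deployments`, `sites`), `species`, `model`
#' (`prior_sd_beta`, `p_prior`), `mcmc` (`n_chains`, `n_adapt`, `n_burnin`,
#' `n_iter`), `idw` (`power`, `n_cols`, `margin`, `conditional`), `seed`,
#' `fast`, `output_dir`.
#'
#' @param config Named list of settings (see Details), or for
#'   `load_run_config` a JSON file path.
#' @return Validated config list of class `occu_run_config`.
#' @export
occu_run_config <- function(config = list()) {
  has_syn <- !is.null(config$synthetic)
  has_inp <- !is.null(config$inputs)
  if (has_syn == has_inp)
    stop2("config must contain exactly one of 'synthetic' or 'inputs'")
  defaults <- occu_design_defaults()
  if (has_syn) {
    syn <- config$synthetic
    config$synthetic <- list(
      n_sites = syn$n_sites %||% defaults$n_sites,
      n_days = syn$n_days %||% defaults$n_days,
      bin_days = syn$bin_days %||% defaults$bin_days,
      beta = unlist(syn$beta) %||% c(-0.75, 0, 0, 0, 1.5, -1.0, 0, 0),
      p = syn$p %||% 0.3)
  } else {
    need <- c("records", "deployments", "sites")
    miss <- setdiff(need, names(config$inputs))
    if (length(miss)) stop2("inputs block missing path(s): ",
                            paste(miss, collapse = ", "))
  }
  config$species <- config$species %||% "porcupine"
  config$seed <- as.integer(config$seed %||% 1L)
  config$fast <- isTRUE(config$fast)
  config$bin_days <- config$synthetic$bin_days %||% config$bin_days %||%
    defaults$bin_days
  m <- config$mcmc %||% list()
  config$mcmc <- if (config$fast) occu_mcmc_fast(seed = config$seed)
    else occu_mcmc_config(n_chains = m$n_chains %||% 3,
                          n_adapt = m$n_adapt %||% 1000,
                          n_burnin = m$n_burnin %||% 1000,
                          n_iter = m$n_iter %||% 10000,
                          seed = config$seed)
  mod <- config$model %||% list()
  config$model <- occu_model_spec(
    prior_sd_beta = mod$prior_sd_beta %||% 10,
    p_prior = mod$p_prior %||% "uniform")
  idw <- config$idw %||% list()
  config$idw <- list(power = idw$power %||% 2,
                     n_cols = idw$n_cols %||% 100,
                     margin = idw$margin %||% 1000,
                     conditional = isTRUE(idw$conditional))
  config$output_dir <- config$output_dir %||% "occupipe-run"
  structure(config, class = c("occu_run_config", "list"))
}

#' @rdname occu_run_config
#' @export
load_run_config <- function(config) {
  occu_run_config(jsonlite::read_json(config, simplifyVector = TRUE))
}

.stage <- function(name, log, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop2("stage '", name, "' failed: ", conditionMessage(e)))
  log(sprintf("stage %-12s %.2fs", name, proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full occupancy pipeline
#'
#' Stages: data (synthetic generation or CSV input), detection-matrix
#' construction, covariate preparation with collinearity screen, Bayesian
#' model fit with posterior summary, and IDW interpolation of per-site
#' posterior mean occupancy. All stage outputs are written to
#' `config$output_dir`; the run log records the seed, stage timings,
#' screen results and any Rhat warnings. Given a fixed seed, all outputs
#' except the log's timestamps are byte-identical across runs.
#'
#' @param config An [occu_run_config()] (or plain list coerced through it).
#' @return Invisibly, a result bundle: `matrix`, `covariates`, `summary`,
#'   `derived`, `surface`, `effort`, `naive`, `screen`, `paths`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "occu_run_config")) config <- occu_run_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$output_dir, "run.log")
  log_lines <- character(0)
  log <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    invisible(line)
  }
  log("run started ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  log("seed ", config$seed)

  data <- .stage("data", log, {
    if (!is.null(config$synthetic)) {
      syn <- config$synthetic
      sim <- simulate_survey(n_sites = syn$n_sites, n_days = syn$n_days,
                             bin_days = syn$bin_days, beta = syn$beta,
                             p = syn$p, seed = config$seed)
      log("synthetic design: ", syn$n_sites, " sites x ", syn$n_days,
          " days, bin ", syn$bin_days)
      sim
    } else {
      inp <- config$inputs
      dep <- read.csv(inp$deployments, stringsAsFactors = FALSE)
      dep$start_date <- as.Date(dep$start_date)
      dep$end_date <- as.Date(dep$end_date)
      rec <- read.csv(inp$records, stringsAsFactors = FALSE)
      rec$date <- as.Date(rec$date)
      sites <- read.csv(inp$sites, stringsAsFactors = FALSE)
      list(records = rec, deployments = dep, sites = sites)
    }
  })

  det <- .stage("detections", log, {
    daily <- build_daily_matrix(data$records, data$deployments,
                                config$species)
    occ <- collapse_occasions(daily, config$bin_days)
    eff <- effort(data$deployments)
    nv <- naive_occupancy(occ)
    log("effort ", eff, " trap nights; naive occupancy ",
        nv$n_detected, "/", nrow(occ), " = ", round(nv$fraction, 4))
    list(occ = occ, effort = eff, naive = nv)
  })

  covs <- .stage("covariates", log, {
    tab <- prepare_covariates(data$sites, data$records, data$deployments,
                              bin_days = config$bin_days)
    screen <- correlation_screen(tab, threshold = 0.7)
    if (nrow(screen))
      log("collinearity screen flagged: ",
          paste(sprintf("%s~%s r=%.3f", screen$var1, screen$var2, screen$r),
                collapse = "; "))
    else log("collinearity screen: no |r| > 0.7")
    list(tab = tab, screen = screen)
  })

  fit <- .stage("model", log, {
    chains <- run_mcmc(det$occ, covs$tab, spec = config$model,
                       config = config$mcmc)
    summ <- withCallingHandlers(
      summarize_posterior(chains),
      warning = function(w) { log("WARNING: ", conditionMessage(w))
                              invokeRestart("muffleWarning") })
    derived <- derived_occupancy(chains, covs$tab)
    log(sprintf("mean occupancy %.3f +/- %.3f; detection p %.3f",
                derived$mean_occupancy, derived$sd_occupancy,
                derived$p_mean))
    list(chains = chains, summary = summ, derived = derived)
  })

  surf <- .stage("spatial", log, {
    value <- if (config$idw$conditional) fit$derived$conditional
             else fit$derived$psi_site
    pts <- data.frame(x = data$sites$x, y = data$sites$y, value = value)
    idw_interpolate(pts, power = config$idw$power,
                    n_cols = config$idw$n_cols,
                    margin = config$idw$margin)
  })

  paths <- .stage("outputs", log, {
    p <- list(matrix = file.path(config$output_dir, "detection_matrix.csv"),
              covariates = file.path(config$output_dir, "covariates.csv"),
              summary = file.path(config$output_dir, "summary.csv"),
              surface = file.path(config$output_dir, "surface.asc"),
              log = log_path)
    write_detection_csv(det$occ, p$matrix)
    write_covariates_csv(covs$tab, p$covariates)
    write_summary_csv(fit$summary, p$summary)
    write_surface(surf, p$surface)
    p
  })
  log("run finished ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  writeLines(log_lines, log_path)
  invisible(list(matrix = det$occ, covariates = covs$tab,
                 summary = fit$summary, derived = fit$derived,
                 chains = fit$chains, surface = surf, effort = det$effort,
                 naive = det$naive, screen = covs$screen, paths = paths,
                 config = config))
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write synthetic survey CSVs), `fit` (detection
#' matrix through posterior summary), `interpolate` (IDW surface from a
#' point CSV), `run-all` (full pipeline). Flags: `--config <path>`,
#' `--seed <int>`, `--out-dir <path>`, `--fast`.
#'
#' @param args Character vector of CLI arguments (default: the command
#'   line).
#' @return Exit status, invisibly (0 on success); errors propagate so a
#'   wrapping script exits nonzero on stage failure.
#' @export
occu_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste0(
    "usage: occupipe <simulate|fit|interpolate|run-all> [--config path]\n",
    "                [--seed int] [--out-dir path] [--fast] [--points path]")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]; args <- args[-1]
  opt <- list(seed = NULL, config = NULL, out_dir = NULL, fast = FALSE,
              points = NULL)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    take <- function() { i <<- i + 1L; args[i] }
    switch(a,
      "--config" = opt$config <- take(),
      "--seed" = opt$seed <- as.integer(take()),
      "--out-dir" = opt$out_dir <- take(),
      "--points" = opt$points <- take(),
      "--fast" = opt$fast <- TRUE,
      stop2("unknown flag: ", a, "\n", usage))
    i <- i + 1L
  }
  cfg <- if (!is.null(opt$config)) jsonlite::read_json(opt$config,
                                                       simplifyVector = TRUE)
         else list(synthetic = list())
  if (!is.null(opt$seed)) cfg$seed <- opt$seed
  if (!is.null(opt$out_dir)) cfg$output_dir <- opt$out_dir
  if (opt$fast) cfg$fast <- TRUE

  if (cmd == "simulate") {
    cfg <- occu_run_config(cfg)
    syn <- cfg$synthetic
    if (is.null(syn)) stop2("simulate needs a synthetic config block")
    sim <- simulate_survey(n_sites = syn$n_sites, n_days = syn$n_days,
                           bin_days = syn$bin_days, beta = syn$beta,
                           p = syn$p, seed = cfg$seed)
    paths <- write_survey_csvs(sim, cfg$output_dir)
    message("wrote ", paste(paths, collapse = ", "))
  } else if (cmd == "interpolate") {
    if (is.null(opt$points)) stop2("interpolate needs --points <csv>")
    pts <- read.csv(opt$points)
    idw <- cfg$idw %||% list()
    s <- idw_interpolate(pts, power = idw$power %||% 2,
                         n_cols = idw$n_cols %||% 100,
                         margin = idw$margin %||% 1000)
    out_dir <- cfg$output_dir %||% "occupipe-run"
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- file.path(out_dir, "surface.asc")
    write_surface(s, out)
    message("wrote ", out)
  } else if (cmd %in% c("fit", "run-all")) {
    res <- run_pipeline(cfg)
    message("outputs in ", res$config$output_dir)
  } else stop2("unknown subcommand: ", cmd, "\n", usage)
  invisible(0L)
}
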