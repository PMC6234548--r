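#' Default run configuration
#'
#' Hyperparameter defaults follow the published settings for these
#' methods: K = floor(sqrt(p)) candidate covariates per split, a minimum
#' of 6 events (or unique cases) per terminal node, B = 1000 bootstrap
#' trees for the forest, M = 50 trees in each of 5 recursive-imputation
#' cycles.
#'
#' @return named list of defaults, overridable via a YAML config file or
#'   the \code{config} argument of [run_pipeline()].
#' @export
default_config <- function() {
  list(method = "msrist", structure = "illness_death", n_states = 3L,
       clock = NULL, markov_mode = "markov",
       K = NULL, nmin = 6L, n0 = 6L, B = 1000L, M = 50L, n_cycles = 5L,
       n_repeats = 10L, split_fraction = 0.67, tau_quantile = 0.9,
       vimp_repeats = 10L, seed = 1L,
       simulate = "hivlike", n_subjects = 500L)
}

config_structure <- function(config) {
  clock <- if (is.null(config$clock)) "forward" else unlist(config$clock)
  if (identical(config$structure, "illness_death"))
    illness_death_structure(clock = clock)
  else if (identical(config$structure, "progressive"))
    progressive_structure(config$n_states %||% 3L, clock = clock)
  else stop("unknown structure: ", config$structure)
}

read_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  if (!cfg$method %in% c("msrist", "msrsf", "baseline"))
    stop("method must be msrist, msrsf or baseline")
  if (cfg$method == "msrist" && cfg$n_cycles < 1L)
    stop("n_cycles must be at least 1")
  cfg
}

pipeline_log <- function(con, stage, seed, msg) {
  line <- sprintf("[%s] stage=%s seed=%s %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage, seed, msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full pipeline: data, fit, evaluate, variable importance
#'
#' Orchestrates the stages behind the command-line interface: load a
#' long-format CSV (or simulate a cohort when no data file is given), fit
#' the configured multistate ensemble, run the repeated train/test
#' evaluation against the covariate-free baseline, compute variable
#' importances on a held-out split, and write all artifacts (model
#' bundle, metrics CSV, VIMP CSV, manifest, log) into \code{out_dir}.
#' Deterministic given the seed.
#'
#' @param config a list or path to a YAML file; see [default_config()]
#'   for keys. Values supplied here override the defaults.
#' @param data optional path to a long-format multistate CSV; when
#'   \code{NULL}, a cohort is simulated according to
#'   \code{config$simulate}.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the fitted model, the evaluation
#'   summary and the VIMP table.
#' @export
run_pipeline <- function(config = list(), data = NULL, out_dir = "msforest_run") {
  cfg <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(logcon), add = TRUE)
  t0 <- Sys.time()

  if (is.null(data)) {
    scenario <- switch(cfg$simulate,
                       hivlike = hivlike_scenario(cfg$n_subjects),
                       markov_check = markov_check_scenario(cfg$n_subjects),
                       stop("unknown scenario: ", cfg$simulate))
    sim <- simulate_cohort(scenario, seed = derive_seed(cfg$seed, 1L))
    dataset <- sim$dataset
    write_long_csv(dataset, file.path(out_dir, "cohort.csv"))
    pipeline_log(logcon, "simulate", cfg$seed,
                 sprintf("scenario=%s n=%d", cfg$simulate, cfg$n_subjects))
  } else {
    dataset <- read_long_csv(data, config_structure(cfg))
    pipeline_log(logcon, "load", cfg$seed, sprintf("file=%s", data))
  }

  pars <- switch(cfg$method,
                 msrist = list(M = cfg$M, K = cfg$K, nmin = cfg$nmin,
                               n_cycles = cfg$n_cycles),
                 msrsf = list(B = cfg$B, K = cfg$K, n0 = cfg$n0),
                 baseline = list())
  model <- do.call(fit_multistate_model,
                   c(list(dataset = dataset, method = cfg$method,
                          markov_mode = cfg$markov_mode,
                          seed = derive_seed(cfg$seed, 2L)), pars))
  save_model(model, file.path(out_dir, "model.json"))
  pipeline_log(logcon, "fit", cfg$seed, sprintf("method=%s", cfg$method))

  configs <- stats::setNames(
    list(c(list(method = cfg$method, markov_mode = cfg$markov_mode), pars),
         list(method = "baseline")),
    c(cfg$method, "baseline"))
  ho <- repeated_holdout(dataset, configs, n_repeats = cfg$n_repeats,
                         split_fraction = cfg$split_fraction,
                         seed = derive_seed(cfg$seed, 3L),
                         tau_quantile = cfg$tau_quantile)
  utils::write.csv(ho$summary, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  pipeline_log(logcon, "evaluate", cfg$seed,
               sprintf("n_repeats=%d split=%.2f", cfg$n_repeats,
                       cfg$split_fraction))

  # VIMP on one held-out split
  set.seed(derive_seed(cfg$seed, 4L))
  ids <- sort(unique(dataset$records$id))
  train_ids <- sample(ids, floor(cfg$split_fraction * length(ids)))
  vmodel <- do.call(fit_multistate_model,
                    c(list(dataset = subset_subjects(dataset, train_ids),
                           method = cfg$method, markov_mode = cfg$markov_mode,
                           seed = derive_seed(cfg$seed, 5L)), pars))
  vtab <- vimp(vmodel, subset_subjects(dataset, setdiff(ids, train_ids)),
               n_repeats = cfg$vimp_repeats,
               seed = derive_seed(cfg$seed, 6L),
               tau_quantile = cfg$tau_quantile)
  utils::write.csv(vtab, file.path(out_dir, "vimp.csv"), row.names = FALSE)
  pipeline_log(logcon, "vimp", cfg$seed,
               sprintf("covariates=%d", length(unique(vtab$covariate))))

  manifest <- list(
    config = cfg,
    config_hash = sum(utf8ToInt(paste(deparse(cfg), collapse = ""))),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("msforest")),
    wall_clock_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             file.path(out_dir, "manifest.json"))
  pipeline_log(logcon, "done", cfg$seed,
               sprintf("elapsed=%.1fs", manifest$wall_clock_sec))
  invisible(list(model = model, summary = ho$summary, vimp = vtab))
}
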