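# Configuration schema: every key with its validator. Defaults are the
# illustrative baseline parameter set (r0 = 0.5, muJ = 0.2, L0 = 0.01,
# muA0 = 0.07).
.config_schema <- function() {
  pos <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0
  nonneg <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0
  prob <- function(x) nonneg(x) && x <= 1
  count <- function(x) is.numeric(x) && length(x) == 1L && x >= 1 &&
    x == floor(x)
  list(
    r0 = list(default = 0.5, check = pos, what = "a positive number"),
    muJ = list(default = 0.2, check = nonneg, what = "a non-negative number"),
    L0 = list(default = 0.01,
              check = function(x) pos(x) && x < 1, what = "in (0, 1)"),
    muA0 = list(default = 0.07,
                check = function(x) nonneg(x) && x < 1, what = "in [0, 1)"),
    alpha = list(default = 0, check = nonneg, what = "a non-negative number"),
    cv = list(default = 1, check = nonneg, what = "a non-negative number"),
    mean_r = list(default = NULL,
                  check = function(x) is.null(x) || pos(x),
                  what = "a positive number (defaults to r0)"),
    mean_brood = list(default = 2, check = nonneg,
                      what = "a non-negative number"),
    brood = list(default = NULL,
                 check = function(x) is.null(x) || nonneg(x),
                 what = "a non-negative number"),
    pmast = list(default = 0.25, check = prob, what = "a probability"),
    rgood = list(default = 0.2, check = pos, what = "a positive number"),
    rbad = list(default = 0.05, check = pos, what = "a positive number"),
    alpha_good = list(default = 0, check = nonneg,
                      what = "a non-negative number"),
    alpha_bad = list(default = 0.5, check = nonneg,
                     what = "a non-negative number"),
    years = list(default = 200L, check = count, what = "a positive integer"),
    replicates = list(default = 100L, check = count,
                      what = "a positive integer"),
    n_individuals = list(default = 100L, check = count,
                         what = "a positive integer"),
    figure = list(default = 1L,
                  check = function(x) count(x) && x <= 7,
                  what = "an integer in 1..7"),
    seed = list(default = 1L,
                check = function(x) is.numeric(x) && length(x) == 1L &&
                  x == floor(x), what = "an integer"),
    outdir = list(default = ".",
                  check = function(x) is.character(x) && length(x) == 1L,
                  what = "a directory path")
  )
}

#' Build a validated run configuration
#'
#' Reads an optional YAML configuration file, applies overrides (e.g. from
#' command-line flags — overrides always win over file values), fills the
#' remaining keys with the baseline defaults, and validates every value.
#' Unknown keys are rejected by name.
#'
#' @param path Optional path to a YAML file of configuration keys.
#' @param overrides Named list of values taking precedence over the file.
#' @return An object of class `"run_config"` (a validated named list).
#' @examples
#' parse_config()                      # all defaults
#' parse_config(overrides = list(alpha = 0.5, cv = 1))
#' @export
parse_config <- function(path = NULL, overrides = list()) {
  schema <- .config_schema()
  cfg <- lapply(schema, `[[`, "default")
  from_file <- if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    yaml::read_yaml(path)
  } else list()
  for (src in list(from_file, overrides)) {
    if (length(src) == 0) next
    if (is.null(names(src)) || any(names(src) == ""))
      stop("configuration values must be named", call. = FALSE)
    unknown <- setdiff(names(src), names(schema))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    cfg[names(src)] <- src
  }
  for (key in names(schema)) {
    if (!schema[[key]]$check(cfg[[key]]))
      stop(sprintf("invalid value for '%s': must be %s", key,
                   schema[[key]]$what), call. = FALSE)
  }
  if (is.null(cfg$mean_r)) cfg$mean_r <- cfg$r0
  structure(cfg, class = "run_config")
}

#' Write a run configuration to YAML
#'
#' The written file round-trips through [parse_config()] to an identical
#' configuration.
#'
#' @param cfg A `"run_config"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg)[!vapply(cfg, is.null, logical(1))], path)
  invisible(path)
}

.cfg_lh <- function(cfg) {
  life_history(juvenile_params(cfg$r0, cfg$muJ, cfg$L0),
               adult_params(cfg$muA0, cfg$alpha))
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.provenance <- function(cfg, command, outdir) {
  .write_json(list(command = command, config = unclass(cfg),
                   package_version = as.character(utils::packageVersion("broodopt")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
              file.path(outdir, paste0(command, "_provenance.json")))
}

# per-command implementations; each returns a named list of outputs that is
# also serialized under cfg$outdir
.cmd_optimize <- function(cfg, lh, outdir) {
  opt <- optimal_constant_brood(lh)
  out <- list(brood_size = opt$brood_size, growth_rate = opt$growth_rate,
              is_interior = opt$is_interior)
  .write_json(out, file.path(outdir, "optimize.json"))
  out
}

.cmd_lyapunov <- function(cfg, lh, outdir) {
  out <- list(
    deterministic = annual_growth_rate(cfg$mean_brood, lh),
    poisson_individual = lyapunov_poisson(cfg$mean_brood, lh),
    environmental_constant = lyapunov_env_constant(
      cfg$mean_brood, lh, resource_model(cfg$mean_r, cfg$cv)))
  .write_json(out, file.path(outdir, "lyapunov.json"))
  out
}

.cmd_simulate <- function(cfg, lh, outdir) {
  rc <- stochastic_run_config(cfg$n_individuals, cfg$years, cfg$replicates,
                              cfg$seed)
  draw <- simulate_annual_draw_map(cfg$mean_brood, lh, rc)
  branch <- simulate_branching(cfg$mean_brood, lh, rc)
  utils::write.csv(draw$trajectories,
                   file.path(outdir, "annual_draw_trajectories.csv"),
                   row.names = FALSE)
  utils::write.csv(branch$trajectories,
                   file.path(outdir, "branching_trajectories.csv"),
                   row.names = FALSE)
  out <- list(
    analytic_growth = lyapunov_poisson(cfg$mean_brood, lh),
    annual_draw = draw[c("growth", "log_growth", "log_growth_se",
                         "arithmetic_growth")],
    branching = branch[c("growth", "log_growth", "log_growth_se",
                         "arithmetic_growth", "extinct_fraction")],
    seed = cfg$seed)
  .write_json(out, file.path(outdir, "simulate_summary.json"))
  out
}

.cmd_plastic <- function(cfg, lh, outdir) {
  env <- resource_model(cfg$mean_r, cfg$cv)
  tr <- simulate_strategy_trajectories(lh, env, cfg$years, cfg$seed)
  utils::write.csv(rbind(tr$plastic, tr$constant),
                   file.path(outdir, "strategy_trajectories.csv"),
                   row.names = FALSE)
  best <- optimal_cv(lh, mean_r = cfg$mean_r)
  out <- list(plastic_growth = lyapunov_env_plastic(lh, env),
              constant_growth = optimal_constant_brood_env(lh, env)$growth_rate,
              best_cv = best$cv, growth_at_best_cv = best$growth,
              seed = cfg$seed)
  .write_json(out, file.path(outdir, "plastic_summary.json"))
  out
}

.cmd_casestudy <- function(cfg, lh, outdir) {
  env <- two_state_environment(cfg$pmast, cfg$rgood, cfg$rbad,
                               cfg$alpha_good, cfg$alpha_bad)
  res <- case_study(env, lh)
  out <- list(
    good_year = list(brood_size = res$masting$good$brood_size,
                     growth_rate = res$masting$good$growth_rate),
    bad_year = list(brood_size = res$masting$bad$brood_size,
                    growth_rate = res$masting$bad$growth_rate),
    overall_growth = res$baseline_growth,
    constant_species = res$constant,
    masting_to_constant = res$masting_to_constant,
    constant_to_masting = res$constant_to_masting)
  .write_json(out, file.path(outdir, "casestudy.json"))
  out
}

.cmd_figure <- function(cfg, lh, outdir) {
  alphas <- seq(0, 3, by = 0.05)
  cvs <- seq(0, 2, by = 0.05)
  file <- file.path(outdir, sprintf("figure%d.csv", cfg$figure))
  tab <- switch(as.character(cfg$figure),
    "1" = sweep_alpha_deterministic(lh, alphas),
    "2" = {
      rows <- lapply(alphas, function(a) {
        opt <- optimal_mean_brood_individual(.with_alpha(lh, a))
        data.frame(alpha = a, brood_size = opt$brood_size,
                   growth_rate = opt$growth_rate)
      })
      do.call(rbind, rows)
    },
    "3" = sweep_alpha_cv_env(lh, alphas, c(0, 0.25, 0.5, 1), cfg$mean_r),
    "4" = sweep_alpha_cv_env(lh, c(0, 0.5, 1, 1.5), cvs, cfg$mean_r),
    "5" = {
      tr <- simulate_strategy_trajectories(
        lh, resource_model(cfg$mean_r, cfg$cv), cfg$years, cfg$seed)
      rbind(tr$plastic, tr$constant)
    },
    "6" = sweep_plastic_vs_constant(lh, c(0, 0.5, 1, 1.5), cvs, cfg$mean_r),
    "7" = {
      lh7 <- life_history(juvenile_params(cfg$rbad, cfg$muJ, cfg$L0),
                          adult_params(0.1, 0))
      grids <- sweep_translocation_grid(seq(1, 10, by = 0.5),
                                        seq(0.02, 0.98, by = 0.04), lh7,
                                        r_bad = cfg$rbad)
      long <- expand.grid(r_ratio = as.numeric(rownames(grids[[1]])),
                          p_good = as.numeric(colnames(grids[[1]])))
      long$constant_to_masting <- as.vector(grids$constant_to_masting)
      long$masting_to_constant <- as.vector(grids$masting_to_constant)
      long
    },
    stop("figure must be 1..7", call. = FALSE))
  utils::write.csv(tab, file, row.names = FALSE)
  list(file = file, rows = nrow(tab))
}

#' Run a named analysis command
#'
#' Dispatches one of the package's end-to-end analyses, writing CSV/JSON
#' results and a provenance record (resolved configuration, seed, package
#' version) into `cfg$outdir`. Deterministic commands produce identical
#' outputs on repeat runs; stochastic ones are reproducible from the seed.
#'
#' Commands: `optimize` (optimal constant brood), `lyapunov` (growth rates
#' under each stochasticity mode), `simulate` (Poisson individual-variation
#' simulators), `plastic` (plastic-strategy analysis), `casestudy` (the
#' two-environment translocation analysis), `figure` (sweep table backing
#' figure `cfg$figure`).
#'
#' @param name Command name.
#' @param cfg A `"run_config"` from [parse_config()].
#' @return The command's result list, invisibly. On any computation error the
#'   command's partial outputs are removed before the error propagates.
#' @export
run_command <- function(name, cfg) {
  stopifnot(inherits(cfg, "run_config"))
  name <- match.arg(name, c("optimize", "lyapunov", "simulate", "plastic",
                            "casestudy", "figure"))
  outdir <- cfg$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  before <- list.files(outdir, full.names = TRUE)
  lh <- .cfg_lh(cfg)
  fn <- switch(name, optimize = .cmd_optimize, lyapunov = .cmd_lyapunov,
               simulate = .cmd_simulate, plastic = .cmd_plastic,
               casestudy = .cmd_casestudy, figure = .cmd_figure)
  res <- tryCatch(fn(cfg, lh, outdir), error = function(e) {
    created <- setdiff(list.files(outdir, full.names = TRUE), before)
    unlink(created)
    stop(e)
  })
  .provenance(cfg, name, outdir)
  invisible(res)
}
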